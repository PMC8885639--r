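# Independent oracles used across tests.

# Exhaustive hypergeometric oracle: enumerate every possible draw of n genes
# from a universe of N in which genes 1..K carry the term, and count tail
# events directly. Independent of any distribution function.
hyper_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  ov <- if (n == 1L) as.integer(draws <= K) else colSums(draws <= K)
  c(p_enrich = mean(ov >= k),
    p_deplete = mean(ov <= k),
    pmf = mean(ov == k))
}

# Random count table: features x samples of non-negative integers with
# positive lengths, at least one nonzero count per sample.
random_count_table <- function(n_features = 50L, n_samples = 3L,
                               max_count = 200L) {
  repeat {
    m <- matrix(rpois(n_features * n_samples, max_count / 4),
                nrow = n_features)
    if (all(colSums(m) > 0)) break
  }
  df <- data.frame(feature_id = sprintf("F%04d", seq_len(n_features)),
                   length = sample(50:2000, n_features, replace = TRUE))
  for (j in seq_len(n_samples)) df[[sprintf("s%d", j)]] <- m[, j]
  df
}

# A blank predictor-evidence row set (all predictors negative/NA).
blank_evidence <- function(protein_id) {
  data.frame(protein_id = protein_id,
             tmhmm_tm_count = 0L, phobius_tm_count = 0L,
             phobius_sp = FALSE, signalp_sp = FALSE,
             targetp_loc = "NA", wolfpsort_loc = "NA",
             stringsAsFactors = FALSE)
}
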