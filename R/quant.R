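# Label-free quantification: NSAF for spectral counts, FPKM for RNA-seq
# fragment counts, and median-of-ratios size factors for count matrices.

#' Normalized spectral abundance factor (NSAF)
#'
#' For each sample, a protein's spectral counts are divided by its length in
#' amino acids (the spectral abundance factor, SAF) and the SAFs are
#' normalized to sum to one over all proteins in the sample:
#' \deqn{NSAF_i = (SpC_i / L_i) / \sum_j (SpC_j / L_j).}
#' NSAF is a relative abundance measure defined over the identified proteome,
#' so the denominator runs over exactly the features present in the table.
#'
#' @param counts data frame with columns `feature_id`, `length` (amino
#'   acids), and one non-negative integer spectral-count column per sample.
#' @return data frame with `feature_id` and one NSAF column per sample; each
#'   NSAF column sums to 1. Attribute `measure` is `"NSAF"`.
#' @examples
#' spc <- data.frame(feature_id = c("P1", "P2"), length = c(100, 200),
#'                   s1 = c(10, 10))
#' compute_nsaf(spc)  # NSAF = 2/3, 1/3
#' @export
compute_nsaf <- function(counts) {
  .check_count_table(counts)
  m <- .sample_matrix(counts)
  saf <- m / counts$length
  tot <- colSums(saf)
  zero <- which(tot == 0)
  if (length(zero))
    .stop_val("sample '%s' has no nonzero spectral counts; NSAF undefined",
              colnames(m)[zero[1]])
  nsaf <- sweep(saf, 2, tot, "/")
  out <- data.frame(feature_id = counts$feature_id, nsaf,
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "measure") <- "NSAF"
  out
}

#' Fragments per kilobase of exon model per million mapped fragments (FPKM)
#'
#' \deqn{FPKM_i = fragments_i \cdot 10^9 / (total\_mapped \cdot length_i)}
#' with `length` in nucleotides. Zero fragments give FPKM 0.
#'
#' @param counts data frame with columns `feature_id`, `length`
#'   (nucleotides), and one fragment-count column per sample.
#' @param total_mapped positive total mapped fragments per sample, recycled
#'   or named by sample. Defaults to the per-sample column sums.
#' @return data frame with `feature_id` and one FPKM column per sample;
#'   attribute `measure` is `"FPKM"`.
#' @examples
#' fr <- data.frame(feature_id = "g1", length = 1000, s1 = 100)
#' compute_fpkm(fr, total_mapped = 1e6)  # 100.0
#' @export
compute_fpkm <- function(counts, total_mapped = NULL) {
  .check_count_table(counts)
  m <- .sample_matrix(counts)
  if (is.null(total_mapped)) total_mapped <- colSums(m)
  if (length(total_mapped) == 1L) total_mapped <- rep(total_mapped, ncol(m))
  if (!is.null(names(total_mapped))) total_mapped <- total_mapped[colnames(m)]
  if (length(total_mapped) != ncol(m) || anyNA(total_mapped) ||
      any(total_mapped <= 0))
    .stop_val("total_mapped must be a positive count for every sample")
  fpkm <- sweep(m * 1e9 / counts$length, 2, total_mapped, "/")
  out <- data.frame(feature_id = counts$feature_id, fpkm,
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "measure") <- "FPKM"
  out
}

#' Median-of-ratios size factors
#'
#' The standard count-normalization estimator: a per-gene reference is the
#' geometric mean across samples (computed in log space, restricted to genes
#' with a nonzero count in every sample), and a sample's size factor is the
#' median over those genes of count / reference. Dividing each sample's
#' counts by its factor equalizes the median ratios.
#'
#' @param counts data frame with `feature_id`, `length` and sample columns,
#'   or a bare numeric matrix (features x samples).
#' @return named numeric vector of positive per-sample factors.
#' @examples
#' x <- data.frame(feature_id = paste0("g", 1:4), length = 1,
#'                 a = c(1, 2, 4, 8), b = c(2, 4, 8, 16))
#' size_factors(x)  # c(1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts) {
  m <- if (is.matrix(counts)) counts else {
    .check_count_table(counts)
    .sample_matrix(counts)
  }
  ok <- rowSums(m > 0) == ncol(m)
  if (!any(ok))
    .stop_val(paste("no gene has nonzero counts in all samples;",
                    "filter low-coverage samples or genes first"))
  lg <- log(m[ok, , drop = FALSE])
  ref <- rowMeans(lg)                 # log geometric mean
  sf <- apply(exp(lg - ref), 2, stats::median)
  names(sf) <- colnames(m)
  sf
}
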