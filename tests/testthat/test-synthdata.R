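# Synthetic-data generator: determinism, planted structure, count emission.

test_that("the same seed reproduces the universe and files byte for byte", {
  cfg <- sim_config(n_genes = 200L, n_terms = 10L, seed = 7L)
  u1 <- generate_universe(cfg)
  u2 <- generate_universe(cfg)
  expect_identical(u1$genes, u2$genes)
  expect_identical(u1$sets$sets, u2$sets$sets)
  expect_identical(u1$truth, u2$truth)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_omics(cfg), d1)
  write_simulation(simulate_omics(cfg), d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f2))))
})

test_that("stage substreams are independent of later configuration", {
  base <- sim_config(n_genes = 100L, n_terms = 5L, seed = 3L)
  more_ds <- sim_config(n_genes = 100L, n_terms = 5L, seed = 3L,
                        n_datasets = 5L)
  expect_identical(generate_universe(base)$genes,
                   generate_universe(more_ds)$genes)
  u <- generate_universe(base)
  ab1 <- generate_abundance(u)
  d <- generate_detection(u)        # drawing detection must not move abundance
  ab2 <- generate_abundance(u)
  expect_identical(ab1$spc_counts, ab2$spc_counts)
})

test_that("degenerate term size range gives exactly that size", {
  cfg <- sim_config(n_genes = 100L, n_terms = 8L,
                    term_size_range = c(10L, 10L), seed = 2L)
  u <- generate_universe(cfg)
  expect_true(all(lengths(u$sets$sets) == 10L))
  expect_error(sim_config(n_genes = 5L, term_size_range = c(10L, 10L)),
               "exceed")
})

test_that("planted depleted terms reach their detection probability", {
  cfg <- sim_config(n_genes = 500L, n_terms = 10L,
                    term_size_range = c(40L, 40L),
                    baseline_detect_prob = 0.8,
                    planted_terms = list(planted_term(1, "depleted", 0.1)),
                    n_datasets = 60L, seed = 17L)
  u <- generate_universe(cfg)
  expect_equal(unname(u$truth$term_direction[1]), "depleted")
  profiles <- generate_detection(u)
  members <- u$sets$sets[["T001"]]
  # first planted term wins, so every member carries the 0.1 override
  fr <- vapply(profiles, function(p) mean(members %in% p$ids), 0)
  # Monte-Carlo mean over 60 datasets; binomial se = sqrt(.1*.9/(60*40))
  expect_lt(abs(mean(fr) - 0.1), 4 * sqrt(0.1 * 0.9 / (60 * 40)))
  base_members <- setdiff(unlist(u$sets$sets[-1]), members)
  fr_base <- vapply(profiles, function(p) mean(base_members %in% p$ids), 0)
  expect_gt(mean(fr_base), mean(fr))   # strictly lower detection when planted
})

test_that("detection is exact at the probability extremes and binomial otherwise", {
  all_cfg <- sim_config(n_genes = 50L, n_terms = 3L, term_size_range = c(5L, 10L),
                        baseline_detect_prob = 1, n_datasets = 1L, seed = 1L)
  u <- generate_universe(all_cfg)
  expect_setequal(generate_detection(u)[[1]]$ids, u$genes$gene_id)

  none_cfg <- sim_config(n_genes = 50L, n_terms = 3L, term_size_range = c(5L, 10L),
                         baseline_detect_prob = 0, n_datasets = 1L, seed = 1L)
  expect_length(generate_detection(generate_universe(none_cfg))[[1]]$ids, 0L)

  big <- sim_config(n_genes = 10000L, n_terms = 5L, seed = 4L,
                    baseline_detect_prob = 0.8, n_datasets = 1L)
  det <- generate_detection(generate_universe(big))[[1]]
  expect_lt(abs(length(det$ids) - 8000), 3 * sqrt(10000 * 0.8 * 0.2))
})

test_that("count tables are non-negative integers proportional to abundance x length", {
  cfg <- sim_config(n_genes = 300L, n_terms = 5L, seed = 9L)
  u <- generate_universe(cfg)
  ab <- generate_abundance(u)
  for (tab in list(ab$spc_counts, ab$frag_counts)) {
    m <- as.matrix(tab[, c("A", "B")])
    expect_true(all(m >= 0) && all(m == floor(m)))
    expect_true(all(tab$length > 0))
  }
  expect_true(all(abs(colSums(ab$nsaf[-1]) - 1) < 1e-9))
})

test_that("a null configuration leaves both conditions exchangeable", {
  cfg <- sim_config(n_genes = 200L, n_terms = 5L, abundance_log_sd = 0,
                    seed = 5L)
  ab <- generate_abundance(generate_universe(cfg))
  expect_equal(ab$abundance$A, ab$abundance$B)   # identical true abundance
  expect_error(sim_config(abundance_log_sd = -1), "abundance_log_sd")
})

test_that("planted fold changes appear in the emitted counts", {
  # 300 genes at log2FC = -2, flat abundance, deep counts: the pooled
  # count ratio estimates 2^-2 with CLT-scale error
  cfg <- sim_config(n_genes = 600L, n_terms = 5L, abundance_log_sd = 0,
                    abundance_log_mean = 2, depth_factor = 50,
                    planted_fc_genes = lapply(1:300, planted_fc, log2fc = -2),
                    seed = 23L)
  u <- generate_universe(cfg)
  ab <- generate_abundance(u)
  planted <- ab$spc_counts[1:300, ]
  ratio <- sum(planted$B) / sum(planted$A)
  expect_lt(abs(ratio - 0.25), 0.02)
  rest <- ab$spc_counts[301:600, ]
  expect_lt(abs(sum(rest$B) / sum(rest$A) - 1), 0.05)
})

test_that("noise-free predictor tables recover the planted labels exactly", {
  cfg <- sim_config(n_genes = 400L, n_terms = 5L, seed = 31L,
                    frac_membrane = 0.2, frac_secreted = 0.2,
                    frac_both = 0.05, predictor_error = 0)
  u <- generate_universe(cfg)
  pred <- generate_predictor_tables(u)
  calls <- classify_localization(pred$evidence)
  expect_identical(calls$membrane, pred$labels$membrane)
  expect_identical(calls$secreted, pred$labels$secreted)
  # label marginals follow the configured fractions
  expect_lt(abs(mean(pred$labels$membrane) - 0.2), 0.06)
  expect_lt(abs(mean(pred$labels$membrane & pred$labels$secreted) - 0.05), 0.04)

  nomem <- sim_config(n_genes = 400L, n_terms = 5L, seed = 31L,
                      frac_membrane = 0, frac_secreted = 0.2, frac_both = 0,
                      predictor_error = 0)
  u2 <- generate_universe(nomem)
  pred2 <- generate_predictor_tables(u2)
  expect_true(all(pred2$evidence$tmhmm_tm_count == 0))
  expect_true(all(pred2$evidence$phobius_tm_count == 0))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(baseline_detect_prob = 1.2), "probability")
  expect_error(sim_config(planted_terms = list(planted_term(99, "depleted", 0.1))),
               "out of range")
  expect_error(sim_config(frac_membrane = 0.1, frac_both = 0.2), "frac_both")
  expect_error(sim_config(term_size_range = c(30L, 10L)), "min <= max")
})
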