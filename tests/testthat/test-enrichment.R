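# Exact hypergeometric tails, collection testing, shared terms, matrices.

test_that("hypergeometric tails match the exhaustive draw enumeration", {
  # C(10,4) = 210 draws; 5 of them take all 4 genes from the 5-gene term
  r <- hypergeom_test(10, 5, 4, 4)
  expect_equal(r$p_enrich, 5 / 210, tolerance = 1e-12)
  r0 <- hypergeom_test(10, 5, 4, 0)
  expect_equal(r0$p_deplete, 5 / 210, tolerance = 1e-12)
  expect_equal(r0$p_enrich, 1.0)

  for (N in c(6L, 9L)) {
    for (K in 1:N) for (n in 1:N) {
      lo <- max(0, n + K - N); hi <- min(K, n)
      for (k in lo:hi) {
        got <- hypergeom_test(N, K, n, k)
        want <- hyper_oracle(N, K, n, k)
        expect_equal(got$p_enrich, unname(want["p_enrich"]), tolerance = 1e-12)
        expect_equal(got$p_deplete, unname(want["p_deplete"]), tolerance = 1e-12)
        expect_equal(got$pmf_at_k, unname(want["pmf"]), tolerance = 1e-12)
      }
    }
  }
})

test_that("inclusive tails satisfy p_enrich + p_deplete - pmf = 1 and monotonicity", {
  set.seed(19)
  for (i in 1:200) {
    N <- sample(10:20000, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    lo <- max(0, n + K - N); hi <- min(K, n)
    k <- if (lo == hi) lo else sample(lo:hi, 1)
    r <- hypergeom_test(N, K, n, k)
    expect_equal(r$p_enrich + r$p_deplete - r$pmf_at_k, 1, tolerance = 1e-10)
  }
  ks <- 0:10
  p <- hypergeom_test(100, 20, 30, ks)$p_enrich
  expect_true(all(diff(p) <= 0))
})

test_that("infeasible contingency counts are rejected with the violated bound", {
  expect_error(hypergeom_test(10, 5, 4, 5), "feasible range")
  expect_error(hypergeom_test(10, 8, 9, 2), "feasible range")  # k < n+K-N
  expect_error(hypergeom_test(10, 12, 4, 2), "K <= N")
})

make_sets <- function(sets, namespace = "custom", species = "synthetic") {
  gene_set_collection(sets, namespace = namespace, species = species)
}

test_that("test_collection builds correct counts and Bonferroni family", {
  sets <- make_sets(list(A = c("g1", "g2", "g3"),
                         B = c("g3", "g4"),
                         C = c("g5")))
  uni <- annotation_universe(sets)           # g1..g5
  rec <- test_collection(c("g1", "g3", "g4"), sets)
  expect_equal(rec$N, rep(5L, 3))
  expect_equal(rec$n, rep(3L, 3))
  expect_equal(rec$K, c(3L, 2L, 1L))
  expect_equal(rec$k[rec$term_id == "A"], 2L)
  # Bonferroni: family = number of tested terms, capped at 1
  expect_equal(rec$p_adj_deplete, pmin(1, rec$p_deplete * nrow(rec)))
  expect_equal(rec$p_adj_enrich, pmin(1, rec$p_enrich * nrow(rec)))

  # full detection: X = K with certainty, both inclusive tails are 1
  full <- test_collection(uni, sets)
  expect_equal(full$k, full$K)
  expect_equal(full$p_enrich, rep(1, 3))
  expect_equal(full$p_deplete, rep(1, 3))
})

test_that("detected genes outside the universe are ignored under annotation policy", {
  sets <- make_sets(list(A = c("g1", "g2")))
  rec <- test_collection(c("g1", "zz1", "zz2"), sets)
  expect_equal(rec$n, 1L)
  rec2 <- test_collection(c("g1", "zz1", "zz2"), sets,
                          universe = "detected_union")
  expect_equal(rec2$N, 4L)
  expect_equal(rec2$n, 3L)
})

test_that("shared terms match across species by KEGG map number", {
  cho <- make_sets(list(cge00561 = c("g1", "g2"), cge00100 = c("g3", "g4")),
                   namespace = "KEGG", species = "cge")
  mouse <- make_sets(list(mmu00561 = c("g1", "g5"), mmu04110 = c("g2", "g6")),
                     namespace = "KEGG", species = "mmu")
  r1 <- test_collection(c("g1", "g3"), cho)
  r2 <- test_collection(c("g1", "g2"), mouse)
  sh <- shared_terms(list(cho = r1, sp2 = r2))
  expect_equal(sh$shared_keys, "00561")
  expect_equal(sh$n_shared, 1L)
  expect_equal(sh$records$cho$term_id, "cge00561")

  # plain set intersection on non-KEGG namespaces
  d1 <- test_collection("g1", make_sets(list(A = "g1", B = "g2", C = "g3")))
  d2 <- test_collection("g2", make_sets(list(B = "g2", C = "g3", D = "g4")))
  sh2 <- shared_terms(list(x = d1, y = d2))
  expect_equal(sh2$shared_keys, c("B", "C"))
  expect_warning(shared_terms(list(x = d1[d1$term_id == "A", ],
                                   y = d2[d2$term_id == "D", ])),
                 "no terms shared")
})

test_that("significance matrices apply -log10 with flooring", {
  rec <- data.frame(term_id = c("A", "B", "C"),
                    p_enrich = c(1, 0.01, 1e-30),
                    p_adj_enrich = c(1, 1, 1))
  m <- significance_matrix(list(d1 = rec), direction = "enrich")
  expect_equal(unname(m[c("A", "B", "C"), "d1"]), c(0, 2, 16))
  expect_error(significance_matrix(list()), "no enrichment records")
})

test_that("rank_terms orders by p with deterministic tie breaking", {
  rec <- data.frame(term_id = c("T3", "T1", "T2"),
                    N = 100, K = c(10, 10, 10), n = 20, k = c(2, 2, 8),
                    p_deplete = c(0.2, 0.01, 0.05),
                    p_enrich = 1, p_adj_enrich = 1, p_adj_deplete = 1)
  expect_equal(rank_terms(rec, "deplete")$term_id, c("T1", "T2", "T3"))
  expect_equal(nrow(rank_terms(rec, "deplete", top_k = 100)), 3L)
  # equal p: larger |k - nK/N| first, then lexicographic term id
  tie <- data.frame(term_id = c("Tb", "Ta", "Tc"),
                    N = 100, K = 10, n = 20, k = c(2, 2, 8),
                    p_deplete = 0.5, p_enrich = 1,
                    p_adj_enrich = 1, p_adj_deplete = 1)
  expect_equal(rank_terms(tie, "deplete")$term_id, c("Tc", "Ta", "Tb"))
})

test_that("GMT files round-trip and agree with the reference parser", {
  sets <- make_sets(list(T1 = c("g1", "g2"), T2 = c("g2", "g3", "g4")))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_equal(back$sets, sets$sets)
  expect_equal(back$term_names, sets$term_names)

  skip_if_not_installed("fgsea")
  ref <- fgsea::gmtPathways(f)
  expect_equal(ref[names(sets$sets)], sets$sets)
})
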