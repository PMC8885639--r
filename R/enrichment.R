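# Exact hypergeometric enrichment/depletion testing of gene sets against a
# detection profile, Bonferroni adjustment, cross-dataset shared terms and
# heatmap-ready significance matrices.

#' Exact hypergeometric enrichment and depletion tails
#'
#' Models detection as drawing `n` genes without replacement from a universe
#' of `N` genes of which `K` belong to the term, observing `k` term genes.
#' Both tails are inclusive of the observed count:
#' `p_enrich = P(X >= k)` (over-representation) and
#' `p_deplete = P(X <= k)` (under-representation), so
#' `p_enrich + p_deplete - P(X = k) = 1`.
#'
#' @param N universe size.
#' @param K term genes in the universe.
#' @param n detected genes in the universe.
#' @param k detected genes in the term. All four may be equal-length vectors.
#' @return data frame with columns `p_enrich`, `p_deplete`, `pmf_at_k`.
#' @examples
#' hypergeom_test(10, 5, 4, 4)  # p_enrich = 5/210
#' @export
hypergeom_test <- function(N, K, n, k) {
  len <- max(length(N), length(K), length(n), length(k))
  N <- rep_len(as.numeric(N), len); K <- rep_len(as.numeric(K), len)
  n <- rep_len(as.numeric(n), len); k <- rep_len(as.numeric(k), len)
  if (anyNA(c(N, K, n, k)) || any(K > N) || any(n > N) || any(K < 0) ||
      any(n < 0) || any(N < 1))
    .stop_val("need 0 <= K <= N, 0 <= n <= N, N >= 1")
  lo <- pmax(0, n + K - N); hi <- pmin(K, n)
  bad <- which(k < lo | k > hi)
  if (length(bad))
    .stop_val("k = %g outside feasible range [%g, %g] for (N=%g, K=%g, n=%g)",
              k[bad[1]], lo[bad[1]], hi[bad[1]], N[bad[1]], K[bad[1]], n[bad[1]])
  data.frame(
    p_enrich  = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    p_deplete = stats::phyper(k, K, N - K, n),
    pmf_at_k  = stats::dhyper(k, K, N - K, n)
  )
}

#' Test every term of a collection against a detection profile
#'
#' For each term with at least one gene in the chosen universe, builds the
#' contingency counts (N, K, n, k) and computes exact hypergeometric
#' enrichment and depletion p-values plus Bonferroni-adjusted values. The
#' Bonferroni family is the number of tested terms in the collection; the
#' same family size applies to each direction, which are adjusted
#' separately.
#'
#' @param profile a [detection_profile()] (or character vector of detected
#'   gene ids).
#' @param sets a [gene_set_collection()].
#' @param universe universe policy: `"annotation"` (all genes annotated to
#'   any term of the collection; default), `"detected_union"` (union of the
#'   annotation universe and the profile), or `"custom"` with explicit
#'   `universe_ids`.
#' @param universe_ids character vector of gene ids when
#'   `universe = "custom"`.
#' @return data frame of class `enrichment_records` with columns `term_id`,
#'   `name`, `N`, `K`, `n`, `k`, `p_enrich`, `p_deplete`, `p_adj_enrich`,
#'   `p_adj_deplete`; attributes `namespace`, `universe_policy`, `dataset`.
#' @export
test_collection <- function(profile, sets,
                            universe = c("annotation", "detected_union", "custom"),
                            universe_ids = NULL) {
  universe <- match.arg(universe)
  stopifnot(inherits(sets, "gene_set_collection"))
  detected <- if (inherits(profile, "detection_profile")) profile$ids
              else unique(as.character(profile))
  if (length(detected) == 0L) .stop_val("empty detection profile")
  uni <- switch(universe,
    annotation     = annotation_universe(sets),
    detected_union = sort(unique(c(annotation_universe(sets), detected))),
    custom         = {
      if (is.null(universe_ids) || length(universe_ids) == 0L)
        .stop_val("universe = 'custom' requires non-empty universe_ids")
      sort(unique(as.character(universe_ids)))
    })
  if (length(uni) == 0L) .stop_val("empty universe")
  det_in_uni <- intersect(detected, uni)
  N <- length(uni); n <- length(det_in_uni)

  K <- vapply(sets$sets, function(g) length(intersect(g, uni)), 0L)
  keep <- names(K)[K >= 1L]
  if (length(keep) == 0L) .stop_val("no term has genes in the chosen universe")
  k <- vapply(sets$sets[keep], function(g)
    length(intersect(intersect(g, uni), det_in_uni)), 0L)

  p <- hypergeom_test(N, K[keep], n, k)
  m <- length(keep)
  rec <- data.frame(
    term_id = keep,
    name = unname(sets$term_names[keep]),
    N = N, K = unname(K[keep]), n = n, k = unname(k),
    p_enrich = p$p_enrich, p_deplete = p$p_deplete,
    p_adj_enrich = pmin(1, p$p_enrich * m),
    p_adj_deplete = pmin(1, p$p_deplete * m),
    stringsAsFactors = FALSE
  )
  rownames(rec) <- NULL
  attr(rec, "namespace") <- sets$namespace
  attr(rec, "universe_policy") <- universe
  attr(rec, "dataset") <- if (inherits(profile, "detection_profile"))
    profile$label else NA_character_
  class(rec) <- c("enrichment_records", class(rec))
  rec
}

# KEGG term ids carry a species prefix (e.g. "cge00561", "mmu00561"); the
# trailing map number is the species-agnostic key. Other namespaces (GO ids)
# match by term id directly.
.term_key <- function(term_id, namespace) {
  if (identical(namespace, "KEGG")) {
    key <- sub("^[A-Za-z]+", "", term_id)
    ifelse(nzchar(key), key, term_id)
  } else term_id
}

#' Restrict enrichment results to terms shared by all datasets
#'
#' Terms are matched across datasets by a species-agnostic key: the trailing
#' KEGG map number for KEGG collections (so `cge00561` and `mmu00561` count
#' as one shared pathway), the term id otherwise.
#'
#' @param records_by_dataset named list (>= 2) of `enrichment_records`.
#' @return list with `records` (the input records restricted to shared
#'   terms, each gaining a `term_key` column), `shared_keys`, and `n_shared`.
#'   Warns and returns zero rows when no term is shared.
#' @export
shared_terms <- function(records_by_dataset) {
  if (!is.list(records_by_dataset) || length(records_by_dataset) < 2L)
    .stop_val("need at least two datasets of enrichment records")
  keyed <- lapply(records_by_dataset, function(r) {
    ns <- attr(r, "namespace"); if (is.null(ns)) ns <- "custom"
    .term_key(r$term_id, ns)
  })
  shared <- Reduce(intersect, keyed)
  if (length(shared) == 0L)
    warning("no terms shared across all datasets", call. = FALSE)
  out <- Map(function(r, key) {
    r$term_key <- key
    r[key %in% shared, , drop = FALSE]
  }, records_by_dataset, keyed)
  list(records = out, shared_keys = sort(shared), n_shared = length(shared))
}

#' Heatmap-ready significance matrix
#'
#' Builds a terms x datasets matrix of `-log10(p)` for one test direction,
#' flooring p-values so entries stay finite.
#'
#' @param records_by_dataset named list of `enrichment_records` (a single
#'   records frame is treated as one dataset).
#' @param direction `"enrich"` or `"deplete"`.
#' @param p_floor smallest p-value before taking logs (default `1e-16`, i.e.
#'   a display ceiling of 16).
#' @param adjusted use Bonferroni-adjusted p-values instead of raw.
#' @return numeric matrix (rows = species-agnostic term keys, columns =
#'   datasets) with attributes `direction` and `adjusted`. Terms missing
#'   from a dataset are `NA`.
#' @export
significance_matrix <- function(records_by_dataset,
                                direction = c("enrich", "deplete"),
                                p_floor = 1e-16, adjusted = FALSE) {
  direction <- match.arg(direction)
  if (inherits(records_by_dataset, "enrichment_records"))
    records_by_dataset <- list(dataset = records_by_dataset)
  if (length(records_by_dataset) == 0L ||
      all(vapply(records_by_dataset, nrow, 0L) == 0L))
    .stop_val("no enrichment records supplied")
  col <- paste0(if (adjusted) "p_adj_" else "p_", direction)
  keyed <- lapply(records_by_dataset, function(r) {
    ns <- attr(r, "namespace"); if (is.null(ns)) ns <- "custom"
    stats::setNames(r[[col]], .term_key(r$term_id, ns))
  })
  keys <- sort(unique(unlist(lapply(keyed, names), use.names = FALSE)))
  m <- vapply(keyed, function(p) -log10(pmax(p[keys], p_floor)),
              numeric(length(keys)))
  m <- matrix(m, nrow = length(keys),
              dimnames = list(keys, names(records_by_dataset)))
  attr(m, "direction") <- direction
  attr(m, "adjusted") <- adjusted
  m
}

#' Rank terms by significance in one direction
#'
#' Orders records ascending by the requested p-value; ties are broken by the
#' larger absolute deviation of the observed count from its expectation
#' `n * K / N`, then lexicographically by `term_id`, so the order is
#' deterministic.
#'
#' @param records an `enrichment_records` data frame.
#' @param direction `"enrich"` or `"deplete"`.
#' @param top_k number of terms to return (default 15).
#' @param adjusted rank by Bonferroni-adjusted p-values.
#' @return the top `top_k` rows of `records`, reordered.
#' @export
rank_terms <- function(records, direction = c("enrich", "deplete"),
                       top_k = 15L, adjusted = FALSE) {
  direction <- match.arg(direction)
  if (top_k < 1L) .stop_val("top_k must be >= 1")
  p <- records[[paste0(if (adjusted) "p_adj_" else "p_", direction)]]
  dev <- abs(records$k - records$n * records$K / records$N)
  ord <- order(p, -dev, records$term_id)
  records[utils::head(ord, top_k), , drop = FALSE]
}
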