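# Multi-omics integration: identifier mapping, detection overlaps, and
# confidence-interval / fold-change flagging of abundance comparisons.

#' Construct a detection profile
#'
#' The set of gene (or protein-group) identifiers identified in one dataset
#' — one cell line, growth phase and omics layer. Detection profiles are the
#' "drawn" samples of the hypergeometric tests and the operands of overlap
#' accounting.
#'
#' @param ids character vector of detected identifiers (deduplicated).
#' @param label dataset label, e.g. `"CHO_exponential_protein"`.
#' @param layer omics layer, `"protein"` or `"mRNA"`.
#' @param namespace identifier namespace tag; overlap and set operations
#'   refuse to mix namespaces.
#' @return object of class `detection_profile`.
#' @export
detection_profile <- function(ids, label = "dataset", layer = c("protein", "mRNA"),
                              namespace = "gene_symbol") {
  layer <- match.arg(layer)
  ids <- unique(as.character(ids))
  if (any(!nzchar(ids))) .stop_val("empty identifiers are not allowed")
  structure(list(ids = ids, label = label, layer = layer,
                 namespace = namespace),
            class = "detection_profile")
}

#' @export
print.detection_profile <- function(x, ...) {
  cat(sprintf("detection_profile '%s' [%s, %s]: %d identifiers\n",
              x$label, x$layer, x$namespace, length(x$ids)))
  invisible(x)
}

#' Map a detection profile into another identifier namespace
#'
#' Applies a source -> target identifier map (many-to-one allowed; targets
#' are deduplicated). Typical use: mapping species gene ids to KEGG
#' identifiers or mouse/hamster orthologs to shared symbols.
#'
#' @param profile a [detection_profile()].
#' @param map data frame with columns `source` and `target` (or any
#'   two-column frame, taken in that order).
#' @param policy `"drop_unmapped"` (default) removes identifiers without a
#'   map entry; `"keep_unmapped"` passes them through unchanged.
#' @param namespace namespace tag for the mapped profile.
#' @return the mapped `detection_profile`; attribute `unmapped_count` holds
#'   the number of input identifiers without a map entry.
#' @export
map_identifiers <- function(profile, map,
                            policy = c("drop_unmapped", "keep_unmapped"),
                            namespace = "mapped") {
  policy <- match.arg(policy)
  stopifnot(inherits(profile, "detection_profile"))
  if (!is.data.frame(map) || ncol(map) < 2L || nrow(map) == 0L)
    .stop_val("map must be a non-empty two-column data frame (source, target)")
  src <- as.character(map[[1]]); tgt <- as.character(map[[2]])
  if (any(!nzchar(src)) || any(!nzchar(tgt)))
    .stop_val("map contains empty identifiers")
  hit <- match(profile$ids, src)
  unmapped <- sum(is.na(hit))
  mapped <- tgt[hit[!is.na(hit)]]
  if (policy == "keep_unmapped") mapped <- c(mapped, profile$ids[is.na(hit)])
  out <- detection_profile(mapped, label = profile$label, layer = profile$layer,
                           namespace = namespace)
  attr(out, "unmapped_count") <- unmapped
  out
}

#' Detection overlap between two datasets
#'
#' Partitions the union of two detection profiles into identifiers seen only
#' in the first, in both, and only in the second — the standard two-set
#' accounting of "identified at mRNA and/or protein level".
#'
#' @param a,b [detection_profile()] objects in the same namespace (bare
#'   character vectors are accepted).
#' @return list with `counts` (named integer vector `only_a`, `both`,
#'   `only_b`) and `sets` (the three disjoint identifier sets).
#' @export
overlap_profiles <- function(a, b) {
  ns <- function(x) if (inherits(x, "detection_profile")) x$namespace else NULL
  if (!is.null(ns(a)) && !is.null(ns(b)) && !identical(ns(a), ns(b)))
    .stop_val("namespace mismatch: '%s' vs '%s'", ns(a), ns(b))
  ids <- function(x) if (inherits(x, "detection_profile")) x$ids
                     else unique(as.character(x))
  A <- ids(a); B <- ids(b)
  sets <- list(only_a = setdiff(A, B), both = intersect(A, B),
               only_b = setdiff(B, A))
  list(counts = vapply(sets, length, 0L), sets = sets)
}

#' Flag differential features by confidence-interval and fold-change rules
#'
#' For features shared by two abundance vectors (e.g. NSAF of the same
#' proteins in two cell lines), computes the pseudocounted log2 ratio
#' `log2((a + eps) / (b + eps))`, standardizes it by a center and spread
#' estimated across all features, and flags features falling outside
#' two-sided normal confidence bands at each requested level. A feature is
#' additionally `fc_selected` when its linear fold change
#' `max(r, 1/r)` reaches `fc_threshold`.
#'
#' The default estimator is robust — median center and MAD spread (scaled by
#' 1.4826 to be consistent with the normal sd) — so a minority of genuinely
#' changed features does not inflate the band; `estimator = "parametric"`
#' uses mean and sd.
#'
#' @param a,b named numeric vectors of non-negative abundances, or
#'   single-measure abundance data frames as returned by [compute_nsaf()] /
#'   [compute_fpkm()] (multiple sample columns are averaged per feature).
#' @param ci_levels confidence levels for the bands (default 0.90 and 0.95).
#' @param fc_threshold linear fold-change selection threshold (> 1;
#'   default 1.8).
#' @param pseudocount additive constant before taking ratios; default half
#'   the smallest nonzero abundance across both inputs.
#' @param estimator `"robust"` (median / 1.4826 MAD) or `"parametric"`
#'   (mean / sd).
#' @return data frame with one row per shared feature: `feature_id`,
#'   `abundance_a`, `abundance_b`, `log2_ratio`, `z`, `ci_flag`
#'   (`"inside"`, `"outside_90"`, `"outside_95"`, ... per requested level,
#'   reporting the most extreme band exceeded), `fc_selected`, `direction`
#'   (`"up"` = higher in `a`). Attributes record the estimator, pseudocount
#'   and thresholds used.
#' @export
compare_abundance <- function(a, b, ci_levels = c(0.90, 0.95),
                              fc_threshold = 1.8, pseudocount = NULL,
                              estimator = c("robust", "parametric")) {
  estimator <- match.arg(estimator)
  if (fc_threshold <= 1) .stop_val("fc_threshold must be > 1")
  ci_levels <- sort(unique(ci_levels))
  .check_prob(ci_levels, "ci_levels")
  as_vec <- function(x) {
    if (is.data.frame(x)) {
      m <- .sample_matrix(x, meta_cols = c("feature_id", "length"))
      stats::setNames(rowMeans(m), x$feature_id)
    } else {
      if (is.null(names(x))) .stop_val("abundance vectors must be named")
      x
    }
  }
  va <- as_vec(a); vb <- as_vec(b)
  if (any(va < 0, na.rm = TRUE) || any(vb < 0, na.rm = TRUE))
    .stop_val("abundances must be non-negative")
  shared <- intersect(names(va), names(vb))
  if (length(shared) < 3L)
    .stop_val("need at least 3 shared features, got %d", length(shared))
  va <- va[shared]; vb <- vb[shared]

  if (is.null(pseudocount)) {
    nz <- c(va[va > 0], vb[vb > 0])
    pseudocount <- if (length(nz)) min(nz) / 2 else 1e-12
  }
  ratio <- (va + pseudocount) / (vb + pseudocount)
  lr <- log2(ratio)

  if (estimator == "robust") {
    center <- stats::median(lr)
    spread <- stats::mad(lr)              # 1.4826 * median |x - median|
  } else {
    center <- mean(lr)
    spread <- stats::sd(lr)
  }
  z <- if (spread > 0) (lr - center) / spread else rep(0, length(lr))

  flag <- rep("inside", length(lr))
  if (spread > 0) {
    for (lev in ci_levels) {             # ascending, so the widest band wins
      cut <- stats::qnorm(1 - (1 - lev) / 2)
      flag[abs(z) > cut] <- sprintf("outside_%g", round(100 * lev))
    }
  }
  fc <- pmax(ratio, 1 / ratio)
  out <- data.frame(
    feature_id = shared,
    abundance_a = unname(va), abundance_b = unname(vb),
    log2_ratio = unname(lr), z = unname(z), ci_flag = flag,
    fc_selected = unname(fc >= fc_threshold),
    direction = ifelse(lr >= 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  attr(out, "estimator") <- estimator
  attr(out, "pseudocount") <- pseudocount
  attr(out, "ci_levels") <- ci_levels
  attr(out, "fc_threshold") <- fc_threshold
  out
}
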