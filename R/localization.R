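# Consensus membrane/secreted classification from normalized
# localization-predictor outputs, and merged-catalog accounting across
# membrane-enrichment experiments.

.targetp_levels <- c("S", "M", "other", "NA")
.wolfpsort_levels <- c("plasma_membrane", "extracellular", "other", "NA")

#' Consensus membrane / secreted classification
#'
#' Consumes one normalized evidence row per protein — transmembrane-helix
#' counts from TMHMM and Phobius, signal-peptide calls from SignalP and
#' Phobius, and compartment predictions from TargetP and WoLF PSORT — and
#' derives two consensus flags:
#' \itemize{
#'   \item membrane: TMHMM TM count >= `tm_threshold`, or Phobius TM count
#'     >= `tm_threshold`, or WoLF PSORT plasma membrane;
#'   \item secreted: SignalP signal peptide, or TargetP secretory ("S"), or
#'     Phobius signal peptide, or WoLF PSORT extracellular.
#' }
#' The default consensus is a union: any firing predictor sets the flag, and
#' the firing predictors are listed as evidence. `min_votes` raises the bar
#' to a stricter vote count. A protein may be both membrane and secreted.
#' Missing predictor outputs are recorded as `NA` and never fire.
#'
#' @param evidence data frame with columns `protein_id`, `tmhmm_tm_count`,
#'   `phobius_tm_count`, `phobius_sp` (logical), `signalp_sp` (logical),
#'   `targetp_loc` (one of `"S"`, `"M"`, `"other"`, `"NA"`), `wolfpsort_loc`
#'   (one of `"plasma_membrane"`, `"extracellular"`, `"other"`, `"NA"`).
#' @param tm_threshold minimum predicted transmembrane helices to call a TM
#'   predictor positive (default 1).
#' @param min_votes minimum number of positive predictors per flag
#'   (default 1, the union rule).
#' @return data frame: `protein_id`, `membrane`, `secreted`,
#'   `membrane_evidence`, `secreted_evidence` (semicolon-separated predictor
#'   names, `""` when none fire).
#' @export
classify_localization <- function(evidence, tm_threshold = 1L, min_votes = 1L) {
  req <- c("protein_id", "tmhmm_tm_count", "phobius_tm_count", "phobius_sp",
           "signalp_sp", "targetp_loc", "wolfpsort_loc")
  miss <- setdiff(req, names(evidence))
  if (length(miss))
    .stop_val("evidence table is missing columns: %s", paste(miss, collapse = ", "))
  chk_enum <- function(col, levels) {
    v <- as.character(evidence[[col]])
    v[is.na(v)] <- "NA"
    bad <- which(!v %in% levels)
    if (length(bad))
      .stop_val("row %d: invalid %s value '%s' (allowed: %s)",
                bad[1], col, v[bad[1]], paste(levels, collapse = ", "))
    v
  }
  cnt <- function(col) {
    v <- evidence[[col]]
    if (any(!is.na(v) & (v < 0 | v != floor(v))))
      .stop_val("%s must be non-negative integer counts", col)
    v
  }
  tmhmm <- cnt("tmhmm_tm_count"); phob_tm <- cnt("phobius_tm_count")
  targetp <- chk_enum("targetp_loc", .targetp_levels)
  wolf <- chk_enum("wolfpsort_loc", .wolfpsort_levels)
  lgl <- function(col) {
    v <- as.logical(evidence[[col]])
    !is.na(v) & v
  }

  mem_votes <- cbind(
    TMHMM        = !is.na(tmhmm) & tmhmm >= tm_threshold,
    `Phobius-TM` = !is.na(phob_tm) & phob_tm >= tm_threshold,
    WoLFPSORT    = wolf == "plasma_membrane")
  sec_votes <- cbind(
    SignalP      = lgl("signalp_sp"),
    TargetP      = targetp == "S",
    `Phobius-SP` = lgl("phobius_sp"),
    WoLFPSORT    = wolf == "extracellular")

  ev_list <- function(v) apply(v, 1, function(r)
    paste(colnames(v)[r], collapse = ";"))
  data.frame(
    protein_id = evidence$protein_id,
    membrane = rowSums(mem_votes) >= min_votes,
    secreted = rowSums(sec_votes) >= min_votes,
    membrane_evidence = ev_list(mem_votes),
    secreted_evidence = ev_list(sec_votes),
    stringsAsFactors = FALSE
  )
}

#' Merge protein catalogs and count novel identifications
#'
#' Unions protein-id catalogs from successive experiments (whole-cell
#' proteome, glycoproteome, cell-surface biotinylation, ultracentrifugation
#' membrane enrichment, ...) in the supplied order and reports how many
#' proteins each catalog adds beyond all earlier ones.
#'
#' @param catalogs named list of character vectors of protein ids; the list
#'   order is the accounting order.
#' @return list with `merged` (the union), `novel` (named integer vector of
#'   per-catalog first-seen counts) and `order` (the catalog labels).
#' @export
catalog_merge <- function(catalogs) {
  if (!is.list(catalogs) || length(catalogs) == 0L)
    .stop_val("catalogs must be a non-empty list of protein-id vectors")
  if (is.null(names(catalogs)))
    names(catalogs) <- paste0("catalog", seq_along(catalogs))
  seen <- character(0)
  novel <- integer(length(catalogs))
  for (i in seq_along(catalogs)) {
    ids <- unique(as.character(catalogs[[i]]))
    novel[i] <- length(setdiff(ids, seen))
    seen <- union(seen, ids)
  }
  names(novel) <- names(catalogs)
  list(merged = seen, novel = novel, order = names(catalogs))
}

#' Proteins absent from an RNA detection profile
#'
#' Returns the members of a protein catalog that were never seen in the
#' RNA-seq detection profile — proteins identified only by protein-level
#' evidence.
#'
#' @param catalog character vector of protein/gene ids.
#' @param rna_profile a [detection_profile()] of layer `"mRNA"` (or a bare
#'   id vector).
#' @param namespace namespace of `catalog`, checked against the profile's.
#' @return list with `absent` (the set difference) and `n_absent`.
#' @export
crosscheck_against_rna <- function(catalog, rna_profile,
                                   namespace = NULL) {
  ids <- if (inherits(rna_profile, "detection_profile")) {
    if (!is.null(namespace) && !identical(namespace, rna_profile$namespace))
      .stop_val("namespace mismatch: '%s' vs '%s'", namespace,
                rna_profile$namespace)
    rna_profile$ids
  } else unique(as.character(rna_profile))
  absent <- setdiff(unique(as.character(catalog)), ids)
  list(absent = absent, n_absent = length(absent))
}

#' Partition a gene set's members by presence in a catalog
#'
#' For one term (e.g. the secretory-granule cellular component), reports
#' which of its genes appear in a catalog of identified proteins and which
#' are missing.
#'
#' @param catalog character vector of identified ids (or a
#'   [detection_profile()]).
#' @param genes character vector of the term's gene ids (non-empty).
#' @return list with `found`, `missing`, `n_found`, `n_missing`.
#' @export
term_membership_report <- function(catalog, genes) {
  if (length(genes) == 0L) .stop_val("gene set is empty")
  ids <- if (inherits(catalog, "detection_profile")) catalog$ids
         else unique(as.character(catalog))
  genes <- unique(as.character(genes))
  found <- intersect(genes, ids)
  missing <- setdiff(genes, ids)
  list(found = found, missing = missing,
       n_found = length(found), n_missing = length(missing))
}
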