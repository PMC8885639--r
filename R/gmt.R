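# Gene-set collections and GMT file I/O.

#' Construct a gene-set collection
#'
#' Namespace-tagged term -> gene-identifier sets (e.g. KEGG pathways or GO
#' terms of one ontology for one species).
#'
#' @param sets named list of character vectors (term_id -> gene ids).
#' @param namespace one of `"KEGG"`, `"GO:MF"`, `"GO:BP"`, `"GO:CC"`,
#'   `"custom"`.
#' @param species species tag (free text, e.g. `"cge"`, `"mmu"`).
#' @param term_names optional named character vector of human-readable term
#'   descriptions; defaults to the term ids.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, namespace = "custom",
                                species = "synthetic", term_names = NULL) {
  namespace <- match.arg(namespace, c("KEGG", "GO:MF", "GO:BP", "GO:CC", "custom"))
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    .stop_val("sets must be a named list of gene-identifier vectors")
  sizes <- lengths(sets)
  if (any(sizes == 0L))
    .stop_val("empty gene set: %s", names(sets)[sizes == 0L][1])
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(unlist(lapply(sets, function(g) any(!nzchar(g))))))
    .stop_val("gene identifiers must be non-empty strings")
  if (is.null(term_names)) {
    term_names <- stats::setNames(names(sets), names(sets))
  } else {
    term_names <- term_names[names(sets)]
    term_names[is.na(term_names)] <- names(sets)[is.na(term_names)]
  }
  structure(list(namespace = namespace, species = species,
                 sets = sets, term_names = term_names),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d terms [%s, %s], %d distinct genes\n",
              length(x$sets), x$namespace, x$species,
              length(unique(unlist(x$sets, use.names = FALSE)))))
  invisible(x)
}

#' All genes annotated in a collection
#'
#' @param sets a `gene_set_collection`.
#' @return character vector of distinct gene identifiers.
#' @export
annotation_universe <- function(sets) {
  sort(unique(unlist(sets$sets, use.names = FALSE)))
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `term_id TAB description TAB gene...`.
#'
#' @param path GMT file path.
#' @inheritParams gene_set_collection
#' @return a `gene_set_collection`.
#' @export
read_gmt <- function(path, namespace = "custom", species = "synthetic") {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) .stop_val("GMT file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    .stop_val("malformed GMT line (need term, description, >=1 gene) in '%s'", path)
  ids <- vapply(fields, `[[`, "", 1L)
  descs <- stats::setNames(vapply(fields, `[[`, "", 2L), ids)
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), ids)
  gene_set_collection(sets, namespace = namespace, species = species,
                      term_names = descs)
}

#' Write a gene-set collection to GMT
#'
#' @param sets a `gene_set_collection`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(names(sets$sets), function(id) {
    paste(c(id, sets$term_names[[id]], sets$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
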