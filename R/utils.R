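# Internal helpers shared across modules.

.stop_val <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

.check_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1))
    .stop_val("%s must be a probability in [0, 1], got %s", what,
              paste(format(x), collapse = ", "))
  invisible(x)
}

.check_range <- function(x, what) {
  if (length(x) != 2L || anyNA(x) || x[1] > x[2] || any(x < 1))
    .stop_val("%s must be an integer pair (min, max) with 1 <= min <= max", what)
  invisible(as.integer(x))
}

#' @keywords internal
#' @noRd
.substream_seed <- function(seed, stream) {
  # Deterministic per-stage seed derived from the global seed and a stream
  # name, so adding a pipeline stage never perturbs earlier random draws.
  # Cheap polynomial string hash folded into [0, 2^31 - 2].
  m <- 2147483647
  h <- as.double(seed %% m)
  for (cc in utf8ToInt(stream)) h <- (h * 31 + cc) %% m
  as.integer(h)
}

# sample() treats a scalar first argument as 1:x; this always samples from
# the elements of x, so degenerate ranges like (10, 10) behave correctly.
.resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Write a data frame as a deterministic TSV file
#'
#' Tab-separated, header row, UTF-8, `.` decimal separator, no quoting and no
#' row names, so identical in-memory tables always serialize byte-identically.
#'
#' @param x data frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", fileEncoding = "")
  invisible(path)
}

#' Read a TSV file written by this package
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Extract the numeric sample matrix from a count/abundance table
# (columns: feature_id [, length], sample columns).
.sample_matrix <- function(x, meta_cols = c("feature_id", "length")) {
  keep <- setdiff(names(x), meta_cols)
  if (length(keep) == 0L) .stop_val("table has no sample columns")
  m <- as.matrix(x[, keep, drop = FALSE])
  if (!is.numeric(m)) .stop_val("sample columns must be numeric")
  rownames(m) <- x$feature_id
  m
}

.check_count_table <- function(x) {
  if (!is.data.frame(x) || !all(c("feature_id", "length") %in% names(x)))
    .stop_val("count table needs 'feature_id' and 'length' columns plus sample columns")
  if (anyDuplicated(x$feature_id))
    .stop_val("duplicate feature_id: %s",
              x$feature_id[anyDuplicated(x$feature_id)])
  bad <- which(!is.finite(x$length) | x$length <= 0)
  if (length(bad))
    .stop_val("non-positive length for feature '%s'", x$feature_id[bad[1]])
  m <- .sample_matrix(x)
  if (any(m < 0)) .stop_val("negative counts are not allowed")
  invisible(x)
}
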