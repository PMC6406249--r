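# Readers and writers for the plain-text dialects the pipeline consumes:
# tab-separated matrices (optionally with a GEO series-matrix style "!"
# preamble), two-column probe annotations, drug-response and clinical tables.

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample ids and a first column of gene/probe ids.
#' Lines starting with `!` (series-matrix preamble) and blank lines are
#' skipped. Ragged rows, non-numeric cells and duplicated ids raise errors
#' that name the offending line or id.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "!") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2L) {
    stop(sprintf("'%s': need a header line and at least one data row", path),
         call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  samples <- header[-1L]
  if (!length(samples)) {
    stop(sprintf("'%s': header has no sample columns", path), call. = FALSE)
  }
  want <- length(samples) + 1L
  n <- lengths(fields[-1L])
  if (any(n != want)) {
    bad <- which(n != want)[1L] + 1L
    stop(sprintf("'%s' line %d: expected %d fields, found %d",
                 path, lineno[bad], want, n[bad - 1L]), call. = FALSE)
  }
  ids <- vapply(fields[-1L], `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("'%s': duplicated gene id '%s'",
                 path, ids[duplicated(ids)][1L]), call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(fields[-1L], function(f) as.numeric(f[-1L]), numeric(want - 1L))
  )
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = want - 1L)
  if (anyNA(vals)) {
    bad <- which(colSums(is.na(vals)) > 0)[1L] + 1L
    stop(sprintf("'%s' line %d: non-numeric value", path, lineno[bad]),
         call. = FALSE)
  }
  out <- t(vals)
  dimnames(out) <- list(ids, samples)
  check_expression_matrix(out, path)
  out
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: header of sample ids, first column of
#' gene ids, tab-separated.
#'
#' @param x Numeric gene x sample matrix.
#' @param path Output path.
#' @param id_column Name written above the id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_column = "gene_id") {
  check_expression_matrix(x)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene annotation table
#'
#' Two-column TSV (`probe_id`, `gene_symbol`). Repeated `probe_id` rows are
#' kept: [collapse_probes()] interprets them as a non-uniquely mapped probe.
#'
#' @param path Path to a TSV file with a header row.
#' @return Data frame with character columns `probe_id` and `gene_symbol`.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("probe_id", "gene_symbol") %in% names(df))) {
    stop(sprintf("'%s': need columns 'probe_id' and 'gene_symbol'", path),
         call. = FALSE)
  }
  df[c("probe_id", "gene_symbol")]
}

#' Read a per-sample drug-response table
#'
#' TSV with columns `sample_id` and `activity_area` (a scalar dose-response
#' summary; larger means more drug-sensitive).
#'
#' @param path Path to a TSV file with a header row.
#' @return Data frame with columns `sample_id` (character) and
#'   `activity_area` (numeric).
#' @export
read_drug_response <- function(path) {
  df <- utils::read.delim(path)
  if (!all(c("sample_id", "activity_area") %in% names(df))) {
    stop(sprintf("'%s': need columns 'sample_id' and 'activity_area'", path),
         call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$activity_area <- as.numeric(df$activity_area)
  as_activity_area(df) # validates; result discarded
  df[c("sample_id", "activity_area")]
}

#' Read a patient clinical table
#'
#' TSV with at least `sample_id`, `time` and `event` columns; any further
#' columns (e.g. `treated`, `residual_tumor_lt_1cm`, `figo_advanced`,
#' `grade_high`, `histology`, `endpoint`) are carried through unchanged.
#'
#' @param path Path to a TSV file with a header row.
#' @return Data frame with validated `time` (non-negative numeric) and
#'   `event` (0/1) columns.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s': need columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop(sprintf("'%s': duplicated sample ids", path), call. = FALSE)
  }
  if (any(!is.finite(df$time)) || any(df$time < 0)) {
    stop(sprintf("'%s': 'time' must be finite and >= 0", path), call. = FALSE)
  }
  if (!all(df$event %in% c(0, 1))) {
    stop(sprintf("'%s': 'event' must be 0 (censored) or 1 (event)", path),
         call. = FALSE)
  }
  df
}
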