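#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution:
#' values are replaced by the across-sample mean of the values holding the
#' same within-column rank. Tied values within a column receive the average
#' of the rank means spanned by the tie. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param x Numeric matrix, genes/probes in rows, samples in columns, with
#'   unique dimnames. At least two columns are required.
#' @return A matrix of the same dimensions and dimnames in which all columns
#'   share one multiset of values. The operation is idempotent.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' quantile_normalize(m)
#' @export
quantile_normalize <- function(x) {
  check_expression_matrix(x)
  if (ncol(x) < 2L) {
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Collapse a probe-level matrix to one row per gene
#'
#' Probes mapping to zero gene symbols or to more than one gene symbol are
#' dropped. When several remaining probes annotate the same gene, the probe
#' with the largest coefficient of variation (sample sd / mean across
#' samples) is kept as that gene's row.
#'
#' @param x Numeric probe x sample matrix; every row name must appear in
#'   `annotation`.
#' @param annotation Data frame with columns `probe_id` and `gene_symbol`.
#'   A probe listed on more than one row (or with an empty/`NA` symbol) is
#'   treated as non-uniquely mapped and excluded.
#' @return A gene x sample matrix, one row per uniquely mapped gene symbol,
#'   ordered by first appearance in `x`.
#' @examples
#' m <- matrix(c(10, 10, 10, 5, 10, 15), 2, 3, byrow = TRUE,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
#' ann <- data.frame(probe_id = c("p1", "p2"), gene_symbol = "G")
#' collapse_probes(m, ann) # keeps p2, the higher-CV probe
#' @export
collapse_probes <- function(x, annotation) {
  check_expression_matrix(x)
  if (!is.data.frame(annotation) ||
      !all(c("probe_id", "gene_symbol") %in% names(annotation))) {
    stop("'annotation' needs columns 'probe_id' and 'gene_symbol'",
         call. = FALSE)
  }
  probe <- as.character(annotation$probe_id)
  gene <- as.character(annotation$gene_symbol)
  unknown <- setdiff(rownames(x), probe)
  if (length(unknown)) {
    stop(sprintf("probes absent from annotation: %s",
                 paste(utils::head(unknown, 5L), collapse = ", ")),
         call. = FALSE)
  }
  # a probe annotated more than once, or without a symbol, is non-unique
  bad <- probe[duplicated(probe) | duplicated(probe, fromLast = TRUE)]
  unmapped <- probe[is.na(gene) | gene == ""]
  map <- stats::setNames(gene, probe)
  keep <- setdiff(rownames(x), union(bad, unmapped))
  if (!length(keep)) stop("no uniquely mapped probes remain", call. = FALSE)
  xs <- x[keep, , drop = FALSE]
  genes <- map[keep]

  m <- rowMeans(xs)
  if (any(m <= 0)) {
    off <- keep[m <= 0][1L]
    stop(sprintf("probe '%s' has mean <= 0; coefficient of variation undefined",
                 off), call. = FALSE)
  }
  cv <- row_sds(xs) / m
  # per gene, retain the probe with the largest CV (first wins on exact ties)
  ord <- order(match(genes, unique(genes)), -cv)
  first <- !duplicated(genes[ord])
  sel <- ord[first]
  out <- xs[sel, , drop = FALSE]
  rownames(out) <- unname(genes[sel])
  out
}

#' Standardize each gene to zero mean and unit variance
#'
#' Each row is centred on its across-sample mean and scaled by its sample
#' standard deviation (denominator `n - 1`).
#'
#' @param x Numeric gene x sample matrix.
#' @param drop_constant If `TRUE`, rows with zero standard deviation are
#'   removed with a message instead of raising an error.
#' @return The row-standardized matrix.
#' @examples
#' m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g", c("a", "b", "c")))
#' zscore_genes(m) # (-1, 0, 1)
#' @export
zscore_genes <- function(x, drop_constant = FALSE) {
  check_expression_matrix(x)
  if (ncol(x) < 2L) stop("z-scoring needs at least 2 samples", call. = FALSE)
  s <- row_sds(x)
  const <- s == 0
  if (any(const)) {
    if (drop_constant) {
      message(sprintf("dropping %d constant gene(s): %s", sum(const),
                      paste(utils::head(rownames(x)[const], 5L),
                            collapse = ", ")))
      x <- x[!const, , drop = FALSE]
      s <- s[!const]
      if (!nrow(x)) stop("all genes are constant", call. = FALSE)
    } else {
      stop(sprintf("constant gene(s) with zero standard deviation: %s",
                   paste(utils::head(rownames(x)[const], 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  (x - rowMeans(x)) / s
}
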