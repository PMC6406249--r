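#' Assign samples to ordinal response groups by drug activity area
#'
#' Samples are sorted by ascending activity area and cut into `n_groups`
#' near-equal groups: each group gets `floor(n / n_groups)` samples and the
#' remainder is distributed one per group starting from the lowest-response
#' group, so 25 samples split 9/8/8 into low/medium/high. Ties in activity
#' area are broken by input order, making the assignment deterministic.
#'
#' @param responses Data frame with columns `sample_id` and `activity_area`,
#'   or a named numeric vector of activity areas.
#' @param n_groups Number of ordinal groups (default 3:
#'   low < medium < high).
#' @return A factor named by sample id (in input order) with levels in
#'   ascending response order.
#' @examples
#' aa <- stats::setNames(seq(0.1, 2.5, by = 0.1), paste0("CL", 1:25))
#' table(assign_response_groups(aa))
#' @export
assign_response_groups <- function(responses, n_groups = 3L) {
  aa <- as_activity_area(responses)
  n <- length(aa)
  n_groups <- as.integer(n_groups)
  if (n_groups < 2L) stop("'n_groups' must be at least 2", call. = FALSE)
  if (n < n_groups) {
    stop(sprintf("need at least %d samples to form %d groups (got %d)",
                 n_groups, n_groups, n), call. = FALSE)
  }
  sizes <- rep(n %/% n_groups, n_groups)
  rem <- n %% n_groups
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  labels <- if (n_groups == 3L) c("low", "medium", "high")
            else sprintf("G%d", seq_len(n_groups))
  ord <- order(aa, seq_along(aa)) # stable on ties
  grp <- integer(n)
  grp[ord] <- rep(seq_len(n_groups), times = sizes)
  out <- factor(labels[grp], levels = labels)
  names(out) <- names(aa)
  out
}

#' Screen genes by Kruskal-Wallis rank test across response groups
#'
#' Runs a per-gene Kruskal-Wallis test (chi-square approximation with tie
#' correction, `n_groups - 1` degrees of freedom) of expression against the
#' response grouping and flags genes with `p < alpha`. A gene constant
#' across all samples has statistic 0 and p-value 1.
#'
#' @param x Gene x sample expression matrix; columns must cover all samples
#'   named in `groups`.
#' @param groups Factor of response labels named by sample id, as returned
#'   by [assign_response_groups()].
#' @param alpha Significance threshold (default 0.01).
#' @return Data frame with one row per gene: `gene`, `statistic`, `df`,
#'   `p_value`, `selected`. The selected gene pool is
#'   `out$gene[out$selected]`.
#' @export
kruskal_wallis_filter <- function(x, groups, alpha = 0.01) {
  check_expression_matrix(x)
  if (is.null(names(groups))) {
    stop("'groups' must be named by sample id", call. = FALSE)
  }
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  missing <- setdiff(names(groups), colnames(x))
  if (length(missing)) {
    stop(sprintf("samples absent from expression matrix: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  }
  xs <- x[, names(groups), drop = FALSE]
  stat <- p <- numeric(nrow(xs))
  for (i in seq_len(nrow(xs))) {
    v <- xs[i, ]
    if (length(unique(v)) == 1L) { # all tied: no rank variation
      stat[i] <- 0
      p[i] <- 1
    } else {
      kt <- stats::kruskal.test(v, groups)
      stat[i] <- unname(kt$statistic)
      p[i] <- kt$p.value
    }
  }
  data.frame(gene = rownames(xs), statistic = stat,
             df = nlevels(groups) - 1L, p_value = p,
             selected = p < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Number of candidate panels in a gene pool
#'
#' Counts the `panel_size`-subsets of a pool of `n_pool` genes — the search
#' space a wrapper selector faces. For a 575-gene pool and panels of 10 this
#' is about 1.01e21, far beyond exhaustive evaluation.
#'
#' @param n_pool Pool size.
#' @param panel_size Panel size.
#' @return The binomial coefficient `choose(n_pool, panel_size)`.
#' @export
panel_search_space <- function(n_pool, panel_size) {
  if (panel_size > n_pool) stop("'panel_size' exceeds pool size", call. = FALSE)
  choose(n_pool, panel_size)
}
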