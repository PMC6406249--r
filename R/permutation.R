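# Empirical permutation null for panel performance: how often does a random
# gene subset of the same size classify the training samples as well as the
# selected panel?

#' Empirical p-value from permutation counts
#'
#' @param n_success Number of trials reaching the observed performance.
#' @param n_trials Total number of trials.
#' @return `n_success / n_trials`.
#' @examples
#' empirical_p(570, 100000) # 0.0057
#' @export
empirical_p <- function(n_success, n_trials) {
  stopifnot(length(n_success) == 1L, length(n_trials) == 1L,
            n_trials >= 1, n_success >= 0, n_success <= n_trials)
  n_success / n_trials
}

#' Permutation test of panel performance against random gene subsets
#'
#' Each trial draws `panel_size` genes uniformly without replacement from
#' `pool` (independently across trials, so the same subset may recur) and
#' scores it by [loocv_accuracy()]. The empirical p-value is the fraction
#' of trials whose accuracy reaches `threshold_accuracy` — typically the
#' LOOCV accuracy of the selected panel.
#'
#' @param pool Character vector of candidate gene ids.
#' @param x Gene x sample expression matrix on the standardized scale.
#' @param groups Factor of response labels named by sample id.
#' @param n_trials Number of random subsets to score.
#' @param panel_size Subset size (default 10).
#' @param threshold_accuracy Accuracy in \[0, 1\] a trial must reach to
#'   count as a success.
#' @param classifier An [svm_control()] configuration.
#' @param seed Optional integer seed for exact reproducibility.
#' @return An object of class `"panel_permutation"`: `n_trials`,
#'   `n_success`, `empirical_p`, `accuracies` (per trial), `threshold`.
#' @export
permutation_test <- function(pool, x, groups, n_trials, panel_size = 10L,
                             threshold_accuracy = 1,
                             classifier = svm_control(), seed = NULL) {
  pool <- unique(as.character(pool))
  n_trials <- as.integer(n_trials)
  panel_size <- as.integer(panel_size)
  if (n_trials < 1L) stop("'n_trials' must be >= 1", call. = FALSE)
  if (length(pool) < panel_size) {
    stop(sprintf("pool has %d genes but panel_size is %d",
                 length(pool), panel_size), call. = FALSE)
  }
  if (threshold_accuracy < 0 || threshold_accuracy > 1) {
    stop("'threshold_accuracy' must be in [0, 1]", call. = FALSE)
  }
  acc <- with_seed(seed, {
    vapply(seq_len(n_trials), function(i) {
      loocv_accuracy(sample(pool, panel_size), x, groups, classifier)
    }, numeric(1L))
  })
  n_success <- sum(acc >= threshold_accuracy)
  structure(list(n_trials = n_trials, n_success = n_success,
                 empirical_p = empirical_p(n_success, n_trials),
                 accuracies = acc, threshold = threshold_accuracy,
                 panel_size = panel_size, seed = seed),
            class = "panel_permutation")
}

#' @export
print.panel_permutation <- function(x, ...) {
  cat(sprintf(
    "Permutation test: %d / %d random %d-gene panels reached accuracy >= %g\n",
    x$n_success, x$n_trials, x$panel_size, x$threshold))
  cat(sprintf("  empirical p = %.4g\n", x$empirical_p))
  invisible(x)
}
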