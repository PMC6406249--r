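# Seeded generators emulating the pipeline's inputs: a cell-line training
# set with planted response-associated genes, and patient validation
# cohorts whose hazard depends on the panel-predicted response group.

#' Simulate a cell-line discovery dataset with planted signal genes
#'
#' Draws a continuous (almost surely tie-free) activity-area phenotype per
#' cell line, splits the lines into response tertiles, and generates
#' Gaussian expression in which `n_signal_genes` randomly placed genes
#' carry a group-dependent mean shift of `-effect_size`, `0`,
#' `+effect_size` standard deviations for the low/medium/high groups while
#' all other genes are independent of the response. Intensities sit on a
#' positive baseline so coefficient-of-variation probe collapse stays
#' well defined.
#'
#' @param n_cell_lines Number of cell lines (default 25).
#' @param n_genes Total genes (default 2000).
#' @param n_signal_genes Planted response-associated genes (default 10).
#' @param effect_size Group mean shift in units of `noise_sd` (default 3).
#' @param noise_sd Within-group expression standard deviation (default 1).
#' @param baseline Mean intensity of null genes (default 8, a log2-like
#'   microarray scale).
#' @param aa_range Range of the uniform activity-area draw.
#' @param seed Optional integer seed; identical seeds give byte-identical
#'   datasets.
#' @return List with `expression` (gene x sample matrix), `response` (data
#'   frame `sample_id`, `activity_area`), `signal_genes` (planted ids) and
#'   `groups` (true tertile labels).
#' @export
gen_cell_line_dataset <- function(n_cell_lines = 25L, n_genes = 2000L,
                                  n_signal_genes = 10L, effect_size = 3,
                                  noise_sd = 1, baseline = 8,
                                  aa_range = c(0.5, 7.5), seed = NULL) {
  n_cell_lines <- as.integer(n_cell_lines)
  n_genes <- as.integer(n_genes)
  n_signal_genes <- as.integer(n_signal_genes)
  if (n_signal_genes > n_genes) {
    stop("'n_signal_genes' cannot exceed 'n_genes'", call. = FALSE)
  }
  if (effect_size < 0 || noise_sd <= 0) {
    stop("'effect_size' must be >= 0 and 'noise_sd' > 0", call. = FALSE)
  }
  if (n_cell_lines < 6L) {
    stop("need at least 6 cell lines for 3 groups of >= 2", call. = FALSE)
  }
  with_seed(seed, {
    samples <- sprintf("CL%02d", seq_len(n_cell_lines))
    genes <- sprintf("G%04d", seq_len(n_genes))
    aa <- stats::runif(n_cell_lines, aa_range[1L], aa_range[2L])
    names(aa) <- samples
    groups <- assign_response_groups(aa)

    expr <- matrix(stats::rnorm(n_genes * n_cell_lines, baseline, noise_sd),
                   n_genes, n_cell_lines, dimnames = list(genes, samples))
    signal <- sort(sample(genes, n_signal_genes))
    shift <- c(low = -1, medium = 0, high = 1) * effect_size * noise_sd
    expr[signal, ] <- expr[signal, ] +
      rep(shift[as.character(groups)], each = n_signal_genes)
    list(expression = expr,
         response = data.frame(sample_id = samples, activity_area = aa,
                               row.names = NULL, stringsAsFactors = FALSE),
         signal_genes = signal,
         groups = groups)
  })
}

#' Simulate a patient validation cohort from a fitted panel model
#'
#' Patients are assigned a true response group with probabilities
#' `group_probs` (by default high responders are the minority). Panel
#' expression is drawn gene-wise from Gaussians matching the model's
#' group-conditional training means (pooled within-group sd), so the
#' model's classifier can recover the groups when training separation was
#' real. Survival times are exponential with group-specific hazards —
#' `baseline_hazard` for the low group scaled by `hazard_ratios` for the
#' others — and censoring is independent exponential calibrated so each
#' patient is censored with probability `censoring_rate`.
#'
#' @param model A [chemopanel()] fit.
#' @param n_patients Cohort size (default 300).
#' @param group_probs Named probabilities for `low`, `medium`, `high`
#'   (default 0.60/0.25/0.15).
#' @param baseline_hazard Event hazard of the low-response group, per time
#'   unit (default 0.03 per month).
#' @param hazard_ratios Named hazard ratios vs the low group (default
#'   medium 0.7, high 0.52; values must be positive).
#' @param censoring_rate Probability a patient is censored (default 0.3).
#' @param seed Optional integer seed.
#' @return A list of class `"panel_cohort"`: `clinical` (data frame with
#'   `sample_id`, `time`, `event`, `treated` and clinical covariates),
#'   `expression` (panel-gene x patient matrix) and `true_group`.
#' @export
gen_cohort <- function(model, n_patients = 300L,
                       group_probs = c(low = 0.60, medium = 0.25,
                                       high = 0.15),
                       baseline_hazard = 0.03,
                       hazard_ratios = c(medium = 0.7, high = 0.52),
                       censoring_rate = 0.3, seed = NULL) {
  if (!inherits(model, "chemopanel")) {
    stop("'model' must be a chemopanel fit", call. = FALSE)
  }
  n_patients <- as.integer(n_patients)
  stopifnot(n_patients >= 2L, baseline_hazard > 0,
            censoring_rate >= 0, censoring_rate < 1)
  lv <- model$levels
  if (!all(lv %in% c(names(hazard_ratios), lv[1L]))) {
    stop("'hazard_ratios' must name every non-reference group",
         call. = FALSE)
  }
  hr <- c(1, hazard_ratios[lv[-1L]])
  names(hr) <- lv
  if (any(!is.finite(hr)) || any(hr <= 0)) {
    stop("hazard ratios must be positive and finite", call. = FALSE)
  }
  group_probs <- group_probs[lv]
  if (any(is.na(group_probs)) || any(group_probs < 0)) {
    stop("'group_probs' must name every group with a non-negative value",
         call. = FALSE)
  }

  # group-conditional moments of the standardized training panel
  tr <- model$training
  mu <- vapply(lv, function(g) {
    rowMeans(tr$x[, tr$groups == g, drop = FALSE])
  }, numeric(nrow(tr$x)))
  resid <- tr$x - mu[, as.character(tr$groups)]
  sd_pooled <- sqrt(rowSums(resid^2) / (ncol(tr$x) - length(lv)))
  sd_pooled[sd_pooled == 0] <- 1e-8

  with_seed(seed, {
    ids <- sprintf("PT%04d", seq_len(n_patients))
    grp <- factor(sample(lv, n_patients, replace = TRUE,
                         prob = group_probs / sum(group_probs)), levels = lv)
    k <- nrow(tr$x)
    z <- matrix(stats::rnorm(k * n_patients, mean = mu[, as.character(grp)],
                             sd = sd_pooled),
                k, n_patients, dimnames = list(rownames(tr$x), ids))
    # back to the training measurement scale; per-gene affine, so
    # cohort-wide z-scoring at prediction time is unaffected
    expr <- z * model$scale[rownames(z)] + model$center[rownames(z)]

    rate <- baseline_hazard * hr[as.character(grp)]
    t_event <- stats::rexp(n_patients, rate)
    if (censoring_rate > 0) {
      # P(censor first) = c/(rate + c) = q  =>  c = rate * q/(1-q)
      c_rate <- rate * censoring_rate / (1 - censoring_rate)
      t_cens <- stats::rexp(n_patients, c_rate)
    } else {
      t_cens <- rep(Inf, n_patients)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    clinical <- data.frame(
      sample_id = ids,
      time = time,
      event = event,
      treated = TRUE,
      residual_tumor_lt_1cm = stats::rbinom(n_patients, 1L, 0.5),
      figo_advanced = stats::rbinom(n_patients, 1L, 0.85),
      grade_high = stats::rbinom(n_patients, 1L, 0.6),
      histology = sample(c("serous", "endometrioid", "clear_cell",
                           "mucinous"), n_patients, replace = TRUE,
                         prob = c(0.70, 0.15, 0.10, 0.05)),
      row.names = NULL, stringsAsFactors = FALSE)
    clinical$histology <- stats::relevel(factor(clinical$histology),
                                         ref = "serous")

    structure(list(clinical = clinical, expression = expr, true_group = grp,
                   hazards = stats::setNames(rate[!duplicated(grp)],
                                             grp[!duplicated(grp)])),
              class = "panel_cohort")
  })
}

#' @export
print.panel_cohort <- function(x, ...) {
  cat(sprintf("Synthetic validation cohort: %d patients, %d panel genes\n",
              nrow(x$clinical), nrow(x$expression)))
  cat("  true groups:", paste(sprintf("%s=%d", names(table(x$true_group)),
                                      table(x$true_group)), collapse = ", "),
      "\n")
  cat(sprintf("  events: %d (%.0f%% censored)\n", sum(x$clinical$event),
              100 * mean(1 - x$clinical$event)))
  invisible(x)
}
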