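#' Fit a chemotherapy-response gene-panel model
#'
#' The full discovery procedure on a cell-line training set: samples are
#' split into low/medium/high response tertiles by drug activity area
#' ([assign_response_groups()]); genes are screened by a Kruskal-Wallis rank
#' test at `alpha` ([kruskal_wallis_filter()]); a genetic-algorithm wrapper
#' ([ga_select()]) picks the `panel_size`-gene subset of the significant
#' pool with the best leave-one-out cross-validated accuracy of a
#' multiclass SVM; and the final SVM is refit on all samples using the
#' selected panel.
#'
#' Expression is standardized before selection: optional quantile
#' normalization across samples, optional probe-to-gene collapse (largest
#' coefficient of variation wins), then per-gene z-scoring. The per-gene
#' training mean and standard deviation on the pre-z-score scale are stored
#' so the panel can be transferred to external cohorts (see
#' [predict.chemopanel()]).
#'
#' @param expr Numeric genes (or probes) x samples matrix.
#' @param response Data frame with columns `sample_id`, `activity_area`, or
#'   a named numeric vector of activity areas. Samples must match `expr`
#'   columns.
#' @param panel_size Number of genes in the panel (default 10).
#' @param n_groups Number of response tertile groups (default 3).
#' @param alpha Kruskal-Wallis screening threshold (default 0.01).
#' @param ga A [ga_control()] configuration.
#' @param classifier An [svm_control()] configuration.
#' @param quantile_normalize Apply quantile normalization first?
#' @param annotation Optional probe annotation (see [collapse_probes()]);
#'   when supplied, `expr` is treated as probe-level.
#' @param drop_constant Drop zero-variance genes before z-scoring instead of
#'   erroring.
#' @param seed Optional integer seed; overrides `ga$rng_seed`.
#' @return An object of class `"chemopanel"` with components `panel` (the
#'   selected gene ids), `loocv_accuracy`, `groups`, `kw` (per-gene screen
#'   results), `pool`, `ga` (fitness history and control), `fit` (the final
#'   SVM), `center`/`scale` (training standardization of the panel genes),
#'   and `training` (standardized panel submatrix and labels).
#' @seealso [predict.chemopanel()], [permutation_test()], [gen_cohort()]
#' @examples
#' sim <- gen_cell_line_dataset(n_genes = 60, n_signal_genes = 8,
#'                              effect_size = 3, seed = 1)
#' fit <- chemopanel(sim$expression, sim$response, panel_size = 5,
#'                   ga = ga_control(population_size = 20, generations = 3),
#'                   seed = 1)
#' print(fit)
#' @export
chemopanel <- function(expr, response, panel_size = 10L, n_groups = 3L,
                       alpha = 0.01, ga = ga_control(),
                       classifier = svm_control(),
                       quantile_normalize = FALSE, annotation = NULL,
                       drop_constant = TRUE, seed = NULL) {
  cl <- match.call()
  check_expression_matrix(expr)
  aa <- as_activity_area(response)
  shared <- intersect(colnames(expr), names(aa))
  if (length(shared) < length(aa)) {
    stop(sprintf("%d response sample(s) missing from expression matrix",
                 length(aa) - length(shared)), call. = FALSE)
  }
  expr <- expr[, names(aa), drop = FALSE]

  if (isTRUE(quantile_normalize)) expr <- chemopanel::quantile_normalize(expr)
  if (!is.null(annotation)) expr <- collapse_probes(expr, annotation)

  raw_center <- rowMeans(expr)
  raw_scale <- row_sds(expr)
  z <- zscore_genes(expr, drop_constant = drop_constant)

  groups <- assign_response_groups(aa, n_groups = n_groups)
  kw <- kruskal_wallis_filter(z, groups, alpha = alpha)
  pool <- kw$gene[kw$selected]
  if (length(pool) < panel_size) {
    stop(sprintf(
      "only %d gene(s) pass the Kruskal-Wallis screen at alpha = %g; need >= %d",
      length(pool), alpha, panel_size), call. = FALSE)
  }

  if (!is.null(seed)) ga$rng_seed <- as.integer(seed)
  sel <- ga_select(pool, z, groups, control = ga, panel_size = panel_size,
                   classifier = classifier)

  x_panel <- z[sel$panel, , drop = FALSE]
  fit <- fit_svm(t(x_panel), groups, classifier)

  structure(list(call = cl,
                 panel = sel$panel,
                 panel_size = as.integer(panel_size),
                 loocv_accuracy = sel$fitness,
                 groups = groups,
                 levels = levels(groups),
                 kw = kw,
                 pool = pool,
                 alpha = alpha,
                 ga = list(history = sel$history,
                           n_evaluated = sel$n_evaluated, control = ga),
                 classifier = classifier,
                 fit = fit,
                 center = raw_center[sel$panel],
                 scale = raw_scale[sel$panel],
                 training = list(x = x_panel, groups = groups),
                 seed = if (!is.null(seed)) as.integer(seed) else ga$rng_seed),
            class = "chemopanel")
}

#' @export
print.chemopanel <- function(x, ...) {
  cat("Chemotherapy-response gene panel model\n")
  cat(sprintf("  %d samples in groups: %s\n", length(x$groups),
              paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  cat(sprintf("  screen: %d of %d genes at p < %g\n",
              length(x$pool), nrow(x$kw), x$alpha))
  cat(sprintf("  panel (%d genes): %s\n", length(x$panel),
              paste(x$panel, collapse = ", ")))
  cat(sprintf("  LOOCV accuracy: %.3f\n", x$loocv_accuracy))
  invisible(x)
}

#' Summarize a fitted panel model
#'
#' @param object A [chemopanel()] fit.
#' @param ... Unused.
#' @return An object of class `"summary.chemopanel"`.
#' @export
summary.chemopanel <- function(object, ...) {
  structure(list(model = object,
                 group_sizes = table(object$groups),
                 n_genes = nrow(object$kw),
                 pool_size = length(object$pool),
                 search_space = panel_search_space(length(object$pool),
                                                  object$panel_size),
                 history = object$ga$history),
            class = "summary.chemopanel")
}

#' @export
print.summary.chemopanel <- function(x, ...) {
  print(x$model)
  cat(sprintf("  search space: %s candidate panels; %d evaluated\n",
              format(x$search_space, digits = 3),
              x$model$ga$n_evaluated))
  cat("  best-so-far LOOCV accuracy by generation:\n   ",
      paste(sprintf("%.2f", x$history), collapse = " "), "\n")
  invisible(x)
}

#' Panel genes and their training standardization statistics
#'
#' @param object A [chemopanel()] fit.
#' @param ... Unused.
#' @return Data frame with one row per panel gene: `gene`, `center`
#'   (training mean) and `scale` (training sd) on the pre-z-score scale.
#' @export
coef.chemopanel <- function(object, ...) {
  data.frame(gene = object$panel, center = unname(object$center),
             scale = unname(object$scale), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify new samples with a fitted panel model
#'
#' Restricts `newdata` to the panel genes, standardizes each gene and
#' predicts one of the ordinal response labels per sample. The default
#' standardization is cohort-wide (each panel gene z-scored with the new
#' cohort's own mean and sd), which makes predictions invariant to any
#' positive per-gene affine rescaling of the cohort matrix — the behaviour
#' needed to transfer a panel across measurement platforms.
#' `standardize = "training"` applies the stored training mean/sd instead.
#'
#' @param object A [chemopanel()] fit.
#' @param newdata Numeric gene x sample matrix covering all panel genes.
#' @param standardize `"cohort"` (default) or `"training"`.
#' @param ... Unused.
#' @return Factor of predicted labels (levels as in training), named by
#'   sample id.
#' @export
predict.chemopanel <- function(object, newdata,
                               standardize = c("cohort", "training"), ...) {
  standardize <- match.arg(standardize)
  check_expression_matrix(newdata)
  missing <- setdiff(object$panel, rownames(newdata))
  if (length(missing)) {
    stop(sprintf("panel gene(s) missing from cohort: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  xp <- newdata[object$panel, , drop = FALSE]
  if (standardize == "cohort") {
    if (ncol(xp) < 2L) {
      stop("cohort standardization needs at least 2 samples", call. = FALSE)
    }
    s <- row_sds(xp)
    if (any(s == 0)) {
      stop(sprintf("panel gene(s) constant in cohort: %s",
                   paste(object$panel[s == 0], collapse = ", ")),
           call. = FALSE)
    }
    xp <- (xp - rowMeans(xp)) / s
  } else {
    xp <- (xp - object$center) / object$scale
  }
  pred <- stats::predict(object$fit, t(xp))
  out <- factor(as.character(pred), levels = object$levels)
  names(out) <- colnames(newdata)
  out
}

#' @describeIn predict.chemopanel Spec-surface alias: classify an external
#'   cohort (a matrix or a `panel_cohort` from [gen_cohort()]).
#' @param model A [chemopanel()] fit.
#' @param cohort Gene x patient matrix or a `panel_cohort` list.
#' @export
classify_cohort <- function(model, cohort,
                            standardize = c("cohort", "training")) {
  if (inherits(cohort, "panel_cohort")) cohort <- cohort$expression
  predict(model, cohort, standardize = match.arg(standardize))
}

#' Plot the GA fitness trajectory of a fitted panel model
#'
#' @param x A [chemopanel()] fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.chemopanel <- function(x, ...) {
  h <- x$ga$history
  graphics::plot(seq_along(h), h, type = "b", pch = 19,
                 xlab = "generation", ylab = "best LOOCV accuracy",
                 ylim = c(0, 1),
                 main = "Genetic-algorithm panel search", ...)
  invisible(x)
}

#' Simulate validation cohorts from a fitted panel model
#'
#' Thin wrapper around [gen_cohort()]: draws `nsim` synthetic patient
#' cohorts whose panel expression follows the model's group-conditional
#' training distributions and whose survival depends on the response group.
#'
#' @param object A [chemopanel()] fit.
#' @param nsim Number of cohorts.
#' @param seed Optional integer seed.
#' @param ... Passed to [gen_cohort()].
#' @return A `panel_cohort` if `nsim = 1`, else a list of them.
#' @export
simulate.chemopanel <- function(object, nsim = 1, seed = NULL, ...) {
  seeds <- if (is.null(seed)) vector("list", nsim)
           else as.list(seed + seq_len(nsim) - 1L)
  out <- lapply(seeds, function(s) gen_cohort(object, seed = s, ...))
  if (nsim == 1) out[[1L]] else out
}
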