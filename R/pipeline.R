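#' Run the full discovery (and optional validation) pipeline from a config
#'
#' Drives preprocessing, tertile grouping, Kruskal-Wallis screening, GA
#' panel selection, final model training, the optional permutation test and
#' the optional cohort classification plus survival report, writing
#' human-diffable artifacts (JSON for the model and reports, CSV for
#' per-generation fitness and per-patient labels). Every artifact embeds
#' the run seed and a hash of the configuration.
#'
#' @param config Either a path to a YAML file or a list with entries:
#'   \describe{
#'     \item{expression}{path to an expression TSV, or a matrix}
#'     \item{response}{path to a drug-response TSV, or a data frame}
#'     \item{annotation}{optional probe-annotation TSV path or data frame}
#'     \item{quantile_normalize}{logical, default `FALSE`}
#'     \item{alpha}{Kruskal-Wallis threshold, default 0.01}
#'     \item{panel_size}{default 10}
#'     \item{ga}{list of [ga_control()] arguments}
#'     \item{classifier}{list of [svm_control()] arguments}
#'     \item{permutation}{optional list with `n_trials` (and optionally
#'       `threshold_accuracy`, defaulting to the fitted panel's accuracy)}
#'     \item{cohort}{optional list with `expression` and `clinical` (paths
#'       or objects) plus optional `min_survival_days`, `require_chemo`,
#'       `covariates`}
#'     \item{seed}{integer seed, default 1}
#'     \item{out_dir}{optional output directory for artifacts}
#'   }
#' @return Invisibly, a list with `model`, `permutation` (or `NULL`),
#'   `survival` (or `NULL`), `files` (paths written) and `config_hash`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("'config' must be a list or a YAML path",
                             call. = FALSE)
  for (field in c("expression", "response")) {
    if (is.null(config[[field]])) {
      stop(sprintf("config is missing required field '%s'", field),
           call. = FALSE)
    }
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  hash <- config_hash(config[setdiff(names(config), "out_dir")])

  load_tsv <- function(obj, reader) {
    if (is.character(obj) && length(obj) == 1L) reader(obj) else obj
  }
  expr <- load_tsv(config$expression, read_expression)
  response <- load_tsv(config$response, read_drug_response)
  annotation <- if (!is.null(config$annotation)) {
    load_tsv(config$annotation, read_probe_annotation)
  }

  message(sprintf("[pipeline] seed=%d config=%s | expression %d x %d",
                  seed, hash, nrow(expr), ncol(expr)))

  ga <- do.call(ga_control, as.list(config$ga))
  classifier <- do.call(svm_control, as.list(config$classifier))
  model <- chemopanel(
    expr, response,
    panel_size = if (is.null(config$panel_size)) 10L else config$panel_size,
    alpha = if (is.null(config$alpha)) 0.01 else config$alpha,
    ga = ga, classifier = classifier,
    quantile_normalize = isTRUE(config$quantile_normalize),
    annotation = annotation, seed = seed)
  message(sprintf("[discover] pool %d -> panel %d, LOOCV accuracy %.3f",
                  length(model$pool), length(model$panel),
                  model$loocv_accuracy))

  perm <- NULL
  if (!is.null(config$permutation)) {
    pc <- config$permutation
    thr <- if (is.null(pc$threshold_accuracy)) model$loocv_accuracy
           else pc$threshold_accuracy
    z <- zscore_genes(expr[, response$sample_id, drop = FALSE],
                      drop_constant = TRUE)
    perm <- permutation_test(model$pool, z, model$groups,
                             n_trials = pc$n_trials,
                             panel_size = model$panel_size,
                             threshold_accuracy = thr,
                             classifier = classifier, seed = seed + 1L)
    message(sprintf("[permute] %d/%d trials >= %.3f, empirical p = %.4g",
                    perm$n_success, perm$n_trials, thr, perm$empirical_p))
  }

  surv_report <- labels <- NULL
  if (!is.null(config$cohort)) {
    cc <- config$cohort
    cexpr <- load_tsv(cc$expression, read_expression)
    clin <- load_tsv(cc$clinical, read_clinical)
    clin <- filter_cohort(
      clin,
      min_survival_days = if (is.null(cc$min_survival_days)) 30
                          else cc$min_survival_days,
      require_chemo = !isFALSE(cc$require_chemo))
    cexpr <- cexpr[, clin$sample_id, drop = FALSE]
    labels <- classify_cohort(model, cexpr)
    clin$panel_group <- as.character(labels)
    clin$panel_responder <- panel_term(labels)
    lr <- logrank_test(clin$time, clin$event, clin$panel_responder)
    covs <- if (is.null(cc$covariates)) "panel_responder"
            else unique(c("panel_responder", cc$covariates))
    cox_uni <- cox_fit(clin, covs, "univariate")
    cox_multi <- if (length(covs) > 1L) cox_fit(clin, covs, "multivariate")
    surv_report <- list(logrank = lr, cox_univariate = cox_uni,
                        cox_multivariate = cox_multi,
                        groups = table(clin$panel_group))
    message(sprintf("[survive] %d patients, log-rank p = %.4g",
                    nrow(clin), lr$p_value))
  }

  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- list(seed = seed, config_hash = hash)
    panel_json <- file.path(config$out_dir, "panel.json")
    jsonlite::write_json(c(stamp, list(
      panel = model$panel,
      standardization = coef(model),
      loocv_accuracy = model$loocv_accuracy,
      pool_size = length(model$pool),
      alpha = model$alpha,
      groups = as.list(stats::setNames(as.character(model$groups),
                                       names(model$groups))))),
      panel_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- panel_json

    fit_csv <- file.path(config$out_dir, "fitness_history.csv")
    utils::write.csv(data.frame(generation = seq_along(model$ga$history),
                                best_loocv_accuracy = model$ga$history),
                     fit_csv, row.names = FALSE)
    files <- c(files, fit_csv)

    if (!is.null(perm)) {
      perm_json <- file.path(config$out_dir, "permutation.json")
      jsonlite::write_json(c(stamp, list(
        n_trials = perm$n_trials, n_success = perm$n_success,
        threshold_accuracy = perm$threshold,
        empirical_p = perm$empirical_p)),
        perm_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files <- c(files, perm_json)
    }
    if (!is.null(labels)) {
      lab_csv <- file.path(config$out_dir, "labels.csv")
      utils::write.csv(data.frame(sample_id = names(labels),
                                  panel_group = as.character(labels)),
                       lab_csv, row.names = FALSE)
      surv_json <- file.path(config$out_dir, "survival_report.json")
      jsonlite::write_json(c(stamp, list(
        logrank = surv_report$logrank,
        cox_univariate = surv_report$cox_univariate,
        cox_multivariate = surv_report$cox_multivariate)),
        surv_json, auto_unbox = TRUE, digits = NA, pretty = TRUE,
        force = TRUE)
      files <- c(files, lab_csv, surv_json)
    }
  }

  invisible(list(model = model, permutation = perm, survival = surv_report,
                 labels = labels, files = files, config_hash = hash,
                 seed = seed))
}
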