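# Survival validation of a transferred panel: cohort filtering,
# Kaplan-Meier curves, log-rank comparison, Cox proportional-hazards models
# and Schoenfeld sample-size planning. Estimation is delegated to the
# survival package (Efron tie handling for Cox).

#' Filter a patient cohort to treated early-survivors
#'
#' Keeps patients who received chemotherapy and survived strictly longer
#' than `min_survival_days`, removing early deaths that cannot reflect
#' treatment response.
#'
#' @param cohort Data frame with a `time` column (and `treated` when
#'   `require_chemo` is `TRUE`), or a `panel_cohort` list from
#'   [gen_cohort()] (both clinical table and expression matrix are
#'   filtered).
#' @param min_survival_days Exclusive lower bound on survival time, in the
#'   cohort's declared time unit (default 30).
#' @param require_chemo Require a truthy `treated` flag?
#' @return The filtered cohort, same shape as the input. Errors if no
#'   patient remains.
#' @export
filter_cohort <- function(cohort, min_survival_days = 30,
                          require_chemo = TRUE) {
  clin <- if (inherits(cohort, "panel_cohort")) cohort$clinical else cohort
  if (!is.data.frame(clin) || !"time" %in% names(clin)) {
    stop("cohort needs a clinical data frame with a 'time' column",
         call. = FALSE)
  }
  keep <- clin$time > min_survival_days
  if (isTRUE(require_chemo)) {
    if (!"treated" %in% names(clin)) {
      stop("cohort has no 'treated' column", call. = FALSE)
    }
    keep <- keep & (clin$treated %in% c(1, TRUE))
  }
  message(sprintf("filter_cohort: %d of %d patients retained",
                  sum(keep), nrow(clin)))
  if (!any(keep)) stop("no patients remain after filtering", call. = FALSE)
  if (inherits(cohort, "panel_cohort")) {
    cohort$clinical <- clin[keep, , drop = FALSE]
    cohort$expression <- cohort$expression[, keep, drop = FALSE]
    if (!is.null(cohort$true_group)) {
      cohort$true_group <- cohort$true_group[keep]
    }
    cohort
  } else {
    clin[keep, , drop = FALSE]
  }
}

#' Kaplan-Meier product-limit curve
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return Data frame step function with columns `time`, `surv`, `n_risk`,
#'   `n_event`, starting at `S(0) = 1` and dropping only at event times.
#' @export
km_curve <- function(time, event) {
  if (!length(time)) stop("empty input", call. = FALSE)
  stopifnot(length(time) == length(event), all(is.finite(time)),
            all(time >= 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  data.frame(time = c(0, fit$time), surv = c(1, fit$surv),
             n_risk = c(length(time), fit$n.risk),
             n_event = c(0, fit$n.event))
}

#' Log-rank test between survival groups
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param group Group labels (2 or more non-empty groups).
#' @return List with `statistic` (chi-square), `df`, `p_value` (two-sided),
#'   `n` (per-group sizes), `observed` and `expected` event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (nlevels(group) < 2L) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  for (g in levels(group)) {
    if (all(time[group == g] == 0)) {
      stop(sprintf("group '%s' has all follow-up times zero", g),
           call. = FALSE)
    }
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n = as.vector(sd$n), observed = as.vector(sd$obs),
       expected = as.vector(sd$exp))
}

#' Recode predicted response labels as the Cox model term
#'
#' The panel enters proportional-hazards models as a binary indicator. The
#' default contrast pools medium and high responders against the low
#' (reference) group; `"high_vs_low"` compares the two extreme groups and
#' sets medium responders to `NA` (the coding used when only the extreme
#' curves are displayed).
#'
#' @param labels Factor of predicted labels (`low`/`medium`/`high`).
#' @param contrast `"medium_high_vs_low"` (default) or `"high_vs_low"`.
#' @return Integer vector of 0/1 (with `NA` for the excluded group under
#'   `"high_vs_low"`).
#' @export
panel_term <- function(labels, contrast = c("medium_high_vs_low",
                                            "high_vs_low")) {
  contrast <- match.arg(contrast)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("low", "medium", "high"))
  if (length(bad)) {
    stop(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (contrast == "medium_high_vs_low") {
    as.integer(labels %in% c("medium", "high"))
  } else {
    ifelse(labels == "high", 1L, ifelse(labels == "low", 0L, NA_integer_))
  }
}

#' Cox proportional-hazards models for a cohort
#'
#' Fits either one model per covariate (`model_type = "univariate"`) or a
#' single joint model (`"multivariate"`), with Efron handling of tied event
#' times, and reports Wald hazard ratios, 95 percent confidence intervals
#' and p-values per model term. Factor covariates use their first level as
#' reference; covariates with a single observed level, and fits showing
#' signs of monotone-likelihood separation, raise errors.
#'
#' @param cohort Data frame with `time` and `event` columns plus the
#'   covariates.
#' @param covariates Character vector of covariate column names.
#' @param model_type `"univariate"` or `"multivariate"`.
#' @return Data frame with columns `covariate`, `term`, `hr`, `lower`,
#'   `upper`, `p_value`, `model`.
#' @export
cox_fit <- function(cohort, covariates,
                    model_type = c("univariate", "multivariate")) {
  model_type <- match.arg(model_type)
  stopifnot(is.data.frame(cohort),
            all(c("time", "event") %in% names(cohort)))
  missing <- setdiff(covariates, names(cohort))
  if (length(missing)) {
    stop(sprintf("covariate(s) absent from cohort: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (sum(cohort$event, na.rm = TRUE) == 0) {
    stop("cohort contains no events", call. = FALSE)
  }
  for (v in covariates) {
    if (length(unique(stats::na.omit(cohort[[v]]))) < 2L) {
      stop(sprintf("covariate '%s' has a single level", v), call. = FALSE)
    }
  }

  fit_one <- function(vars) {
    fml <- stats::reformulate(vars,
                              response = "survival::Surv(time, event)")
    fit <- withCallingHandlers(
      survival::coxph(fml, data = cohort, ties = "efron"),
      warning = function(w) {
        if (grepl("infinite|did not converge|out of iterations",
                  conditionMessage(w))) {
          stop(sprintf("Cox fit failed for [%s]: %s",
                       paste(vars, collapse = ", "), conditionMessage(w)),
               call. = FALSE)
        }
        invokeRestart("muffleWarning")
      })
    s <- summary(fit)
    ci <- stats::confint(fit) # Wald
    data.frame(term = rownames(s$coefficients),
               hr = unname(exp(s$coefficients[, "coef"])),
               lower = unname(exp(ci[, 1L])),
               upper = unname(exp(ci[, 2L])),
               p_value = unname(s$coefficients[, "Pr(>|z|)"]),
               row.names = NULL, stringsAsFactors = FALSE)
  }

  if (model_type == "univariate") {
    out <- do.call(rbind, lapply(covariates, function(v) {
      res <- fit_one(v)
      res$covariate <- v
      res
    }))
  } else {
    out <- fit_one(covariates)
    out$covariate <- vapply(out$term, function(tm) {
      hit <- covariates[startsWith(tm, covariates)]
      if (length(hit)) hit[which.max(nchar(hit))] else tm
    }, character(1L))
  }
  out$model <- model_type
  out[c("covariate", "term", "hr", "lower", "upper", "p_value", "model")]
}

#' Schoenfeld sample size for a two-group log-rank comparison
#'
#' Required number of events
#' \deqn{E = (z_{1-\alpha/2} + z_{power})^2 / (p(1-p)\,(\ln HR)^2)}
#' for allocation proportion `p` in one group, converted to a total sample
#' size by dividing by the overall event probability and rounding up.
#'
#' @param hazard_ratio Anticipated hazard ratio (positive, not 1).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Desired power.
#' @param event_probability Overall probability a patient has an event
#'   during follow-up (1 = everyone).
#' @param group_proportion Proportion of patients in one of the two groups.
#' @return Integer total sample size.
#' @examples
#' schoenfeld_sample_size(0.52, alpha = 0.05, power = 0.70,
#'                        event_probability = 1, group_proportion = 0.776)
#' @export
schoenfeld_sample_size <- function(hazard_ratio, alpha = 0.05, power,
                                   event_probability = 1,
                                   group_proportion = 0.5) {
  if (!is.finite(hazard_ratio) || hazard_ratio <= 0) {
    stop("'hazard_ratio' must be positive", call. = FALSE)
  }
  if (hazard_ratio == 1) {
    stop("'hazard_ratio' of 1 gives an infinite sample size", call. = FALSE)
  }
  for (nm in c("alpha", "power", "event_probability", "group_proportion")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0 || v > 1) {
      stop(sprintf("'%s' must be in (0, 1]", nm), call. = FALSE)
    }
  }
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  events <- z^2 / (group_proportion * (1 - group_proportion) *
                     log(hazard_ratio)^2)
  as.integer(ceiling(events / event_probability))
}
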