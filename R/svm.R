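# Three-class SVM fitness: configuration, fitting and leave-one-out
# cross-validated accuracy, the objective the GA wrapper maximizes.

#' Classifier configuration for the panel model
#'
#' The decision rule over the standardized panel features is a support
#' vector machine with one-vs-one multiclass reduction (the [e1071::svm()]
#' default). Defaults are a linear kernel with cost 1 — the
#' smallest-assumption choice when samples are few and features standardized
#' — but both are configurable.
#'
#' @param kernel Kernel name passed to [e1071::svm()].
#' @param cost Regularization constant C.
#' @param ... Further arguments forwarded to [e1071::svm()].
#' @return A list of class `"svm_control"`.
#' @export
svm_control <- function(kernel = "linear", cost = 1, ...) {
  stopifnot(is.character(kernel), length(kernel) == 1L,
            is.numeric(cost), cost > 0)
  structure(list(kernel = kernel, cost = cost, extra = list(...)),
            class = "svm_control")
}

# Fit the multiclass SVM on samples x features. Features arrive already
# standardized, so e1071's internal scaling is disabled.
fit_svm <- function(features, labels, control) {
  args <- c(list(x = features, y = labels, kernel = control$kernel,
                 cost = control$cost, scale = FALSE, probability = FALSE),
            control$extra)
  do.call(e1071::svm, args)
}

#' Leave-one-out cross-validated accuracy of a gene subset
#'
#' For each sample, a three-class SVM is trained on all remaining samples
#' restricted to `genes` and used to predict the held-out sample; the
#' returned value is the fraction of correct predictions. This is the
#' fitness the GA wrapper optimizes.
#'
#' @param genes Character vector of gene ids, all present in `x`.
#' @param x Gene x sample expression matrix (standardized scale expected).
#' @param groups Factor of response labels named by sample id; every group
#'   must contain at least 2 samples so each training fold keeps all
#'   classes.
#' @param classifier An [svm_control()] configuration.
#' @return Accuracy in \[0, 1\].
#' @export
loocv_accuracy <- function(genes, x, groups, classifier = svm_control()) {
  check_expression_matrix(x)
  missing <- setdiff(genes, rownames(x))
  if (length(missing)) {
    stop(sprintf("genes absent from matrix: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  }
  groups <- droplevels(as.factor(groups))
  samples <- names(groups)
  if (is.null(samples) || !all(samples %in% colnames(x))) {
    stop("'groups' must be named by sample ids present in the matrix",
         call. = FALSE)
  }
  if (any(table(groups) < 2L)) {
    stop("every group needs >= 2 samples for leave-one-out folds",
         call. = FALSE)
  }
  feats <- t(x[genes, samples, drop = FALSE])
  n <- nrow(feats)
  correct <- logical(n)
  for (i in seq_len(n)) {
    fit <- fit_svm(feats[-i, , drop = FALSE], groups[-i], classifier)
    pred <- stats::predict(fit, feats[i, , drop = FALSE])
    correct[i] <- as.character(pred) == as.character(groups[i])
  }
  mean(correct)
}
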