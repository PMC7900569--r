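#' Standardize a laterality feature matrix
#'
#' Column-wise z-scoring of the subjects x 28 laterality matrix, as done
#' before classifier training. The scale is the population standard
#' deviation (denominator `n`), so a two-subject column `(0, 2)` maps to
#' `(-1, +1)`. Constant columns cannot be standardized and raise an error
#' naming the offending feature.
#'
#' @param li_matrix Numeric matrix, subjects in rows.
#' @return The standardized matrix, with `center` and `scale` attributes
#'   holding the fitted parameters.
#' @export
standardize_features <- function(li_matrix) {
  stopifnot(is.matrix(li_matrix))
  if (nrow(li_matrix) < 2) stop("need at least 2 subjects", call. = FALSE)
  n <- nrow(li_matrix)
  s <- apply(li_matrix, 2, stats::sd) * sqrt((n - 1) / n)
  if (any(s < 1e-12)) {
    bad <- colnames(li_matrix)[s < 1e-12]
    if (is.null(bad)) bad <- which(s < 1e-12)
    stop("zero-variance feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m <- colMeans(li_matrix)
  out <- sweep(sweep(li_matrix, 2, m), 2, s, "/")
  attr(out, "center") <- m
  attr(out, "scale") <- s
  out
}

#' Leave-one-out cross-validated linear-SVM lateralization
#'
#' Trains a linear support vector machine (fixed hyperparameters: linear
#' kernel, cost 1, no class weighting) in a leave-one-out loop: each subject
#' is predicted exactly once by a model trained on all the others, giving
#' `n` iterations for `n` subjects. Posterior probabilities come from a
#' Platt-style sigmoid - a logistic regression of the training fold's
#' labels on the training fold's SVM decision values - evaluated at the
#' held-out subject's decision value.
#'
#' By default features are standardized over the whole dataset before
#' cross-validation, reproducing the common "standardized over the dataset"
#' protocol. That choice leaks the test subject's scale into training;
#' `standardization = "per_fold"` refits the scaling inside each training
#' fold and is the leakage-free alternative.
#'
#' @param features Subjects x features numeric matrix (e.g. [li_matrix()]).
#' @param labels Factor/character class per subject (2 classes).
#' @param positive Label of the positive (patient) class; default the first
#'   level encountered.
#' @param cost SVM box constraint (fixed, default 1).
#' @param standardization `"whole_dataset"` (as published) or `"per_fold"`.
#' @param seed Integer seed (the fit is deterministic; the seed is recorded
#'   for provenance and future-proofing).
#' @return A `meg_loocv` object; `$predictions` is a tibble with
#'   `subject_id`, `truth`, `predicted`, `posterior` (probability of the
#'   positive class), `decision_value`.
#' @export
loocv_svm <- function(features, labels, positive = NULL, cost = 1,
                      standardization = c("whole_dataset", "per_fold"),
                      seed = 1L) {
  standardization <- match.arg(standardization)
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  y <- factor(as.character(labels))
  if (nlevels(y) != 2) stop("labels must have exactly 2 classes", call. = FALSE)
  if (is.null(positive)) positive <- levels(y)[1]
  if (!positive %in% levels(y)) stop("positive class not in labels", call. = FALSE)
  if (any(table(y) < 2)) {
    stop("need at least 2 subjects per class", call. = FALSE)
  }
  negative <- setdiff(levels(y), positive)
  y <- factor(as.character(y), levels = c(positive, negative))
  n <- nrow(features)
  ids <- rownames(features)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))

  x_all <- if (standardization == "whole_dataset") {
    standardize_features(features)
  } else features

  withr_seed(seed, {
    res <- purrr::map_dfr(seq_len(n), function(i) {
      tr_y <- y[-i]
      if (nlevels(droplevels(tr_y)) < 2) {
        stop("training fold lost an entire class", call. = FALSE)
      }
      if (standardization == "per_fold") {
        sc <- standardize_features(features[-i, , drop = FALSE])
        tr_x <- sc
        te_x <- sweep(sweep(features[i, , drop = FALSE], 2,
                            attr(sc, "center")), 2, attr(sc, "scale"), "/")
      } else {
        tr_x <- x_all[-i, , drop = FALSE]
        te_x <- x_all[i, , drop = FALSE]
      }
      fit <- e1071::svm(tr_x, tr_y, kernel = "linear", cost = cost,
                        scale = FALSE)
      dv_tr <- oriented_decision_values(fit, tr_x, positive)
      dv_te <- oriented_decision_values(fit, te_x, positive)
      pred <- as.character(predict(fit, te_x))
      post <- platt_posterior(dv_tr, tr_y == positive, dv_te)
      tibble::tibble(subject_id = ids[i], truth = as.character(y[i]),
                     predicted = pred, posterior = post,
                     decision_value = dv_te)
    })
    structure(
      list(predictions = res, positive = positive, negative = negative,
           cost = cost, standardization = standardization, seed = seed,
           n_features = ncol(features), n_iterations = n),
      class = "meg_loocv"
    )
  })
}

# Decision values oriented so larger means more positive-class. e1071 signs
# the decision value toward the first class named in the column label.
oriented_decision_values <- function(fit, x, positive) {
  p <- predict(fit, x, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  toward <- strsplit(colnames(dv)[1], "/")[[1]][1]
  as.numeric(dv[, 1]) * if (toward == positive) 1 else -1
}

# Platt sigmoid: logistic fit of training labels on decision values.
# Separable folds produce a degenerate (steep) fit; the posterior remains a
# monotone map of the decision value, which is what ROC construction needs.
platt_posterior <- function(dv_train, is_pos, dv_test) {
  fit <- suppressWarnings(
    try(stats::glm(is_pos ~ dv_train, family = stats::binomial()),
        silent = TRUE)
  )
  if (inherits(fit, "try-error") || any(!is.finite(stats::coef(fit)))) {
    return(stats::plogis(dv_test))
  }
  as.numeric(suppressWarnings(
    stats::predict(fit, newdata = data.frame(dv_train = dv_test),
                   type = "response")
  ))
}

#' @export
print.meg_loocv <- function(x, ...) {
  cm <- confusion_metrics(x$predictions$predicted, x$predictions$truth,
                          positive = x$positive)
  cat(sprintf(
    "Leave-one-out linear SVM (%s vs %s): %d iterations, %d features\n",
    x$positive, x$negative, x$n_iterations, x$n_features))
  cat(sprintf("  accuracy %.3f  sensitivity %.3f  specificity %.3f\n",
              cm$accuracy, cm$sensitivity, cm$specificity))
  invisible(x)
}

#' @export
tidy.meg_loocv <- function(x, ...) x$predictions

#' @export
glance.meg_loocv <- function(x, ...) {
  cm <- confusion_metrics(x$predictions$predicted, x$predictions$truth,
                          positive = x$positive)
  roc <- roc_curve(x$predictions$posterior, x$predictions$truth,
                   positive = x$positive)
  tibble::tibble(
    positive = x$positive, n_iterations = x$n_iterations,
    n_features = x$n_features,
    accuracy = cm$accuracy, sensitivity = cm$sensitivity,
    specificity = cm$specificity, auc = roc$auc
  )
}
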