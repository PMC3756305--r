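#' Linear kernel (Gram) matrix of a feature dataset
#'
#' Computes the subject-by-subject matrix of dot products, optionally after
#' mean-centering each feature. Centering statistics are computed on the rows
#' of `dataset` itself, so when used inside cross-validation the kernel must
#' be built per training fold (no test-set leakage).
#'
#' @param dataset a [feature_dataset()] with at least two subjects.
#' @param center logical; subtract per-feature means first (default off).
#' @return A symmetric positive-semidefinite matrix of class `kernel_matrix`
#'   with attribute `centered`.
#' @export
linear_kernel <- function(dataset, center = FALSE) {
  x <- dataset$features
  if (nrow(x) < 2) stop("need at least 2 subjects")
  bad <- !apply(is.finite(x), 1, all)
  if (any(bad))
    stop("non-finite feature values for subject(s): ",
         paste(dataset$subject_ids[bad], collapse = ", "))
  if (center) x <- scale(x, center = TRUE, scale = FALSE)
  K <- tcrossprod(x)
  K <- (K + t(K)) / 2  # enforce exact symmetry
  structure(K, centered = center, class = c("kernel_matrix", class(K)))
}

#' Fit a linear-kernel soft-margin maximum-margin classifier
#'
#' Solves the hinge-loss maximum-margin (C-SVM) dual with box constraint
#' \eqn{0 \le \alpha_i \le C} by deterministic sequential minimal
#' optimization, then recovers the primal weight vector
#' \eqn{w = \sum_i \alpha_i y_i x_i} and bias. A linear kernel keeps the
#' weights in feature space, which is what makes discrimination maps possible
#' for high-dimensional morphometry data.
#'
#' @param dataset a [feature_dataset()] containing both classes.
#' @param C positive soft-margin regularization constant. The conventional
#'   default 1 is used.
#' @param center logical; mean-center features (statistics from these training
#'   rows only) before fitting.
#' @param eps stopping tolerance on the maximal KKT violation of the dual.
#' @return An object of class `margin_classifier` with elements `weights`,
#'   `bias`, `dual_coefficients` (\eqn{\alpha_i y_i}), `alpha`, `objective`,
#'   `C`, `center`, and `feature_means` (zero vector when `center = FALSE`).
#' @export
margin_fit <- function(dataset, C = 1, center = FALSE, eps = 1e-10) {
  if (!is.numeric(C) || length(C) != 1 || C <= 0) stop("C must be > 0")
  y <- dataset$labels
  if (length(unique(y)) < 2)
    stop("training data must contain both classes")
  x <- dataset$features
  mu <- if (center) colMeans(x) else rep(0, ncol(x))
  xc <- sweep(x, 2, mu)
  K <- tcrossprod(xc)
  sol <- smo_solve(K, as.numeric(y), C, eps = eps)
  dual <- sol$alpha * y
  w <- drop(crossprod(xc, dual))
  structure(list(weights = w,
                 bias = sol$bias,
                 dual_coefficients = dual,
                 alpha = sol$alpha,
                 objective = sol$objective,
                 C = C, center = center, feature_means = mu,
                 n_support = sum(sol$alpha > 1e-12)),
            class = "margin_classifier")
}

#' @export
print.margin_classifier <- function(x, ...) {
  cat(sprintf("<margin_classifier> %d features, C = %g, %d support vectors\n",
              length(x$weights), x$C, x$n_support))
  invisible(x)
}

#' Decision values and predicted labels
#'
#' The decision value of a subject is `weights . features + bias`, a signed
#' score proportional to the distance from the separating hyperplane; its
#' magnitude reflects classifier confidence. Predicted label is +1 (control)
#' for positive scores and -1 (patient) for negative scores; a score of
#' exactly 0 predicts `tie_label` (default control, favouring non-diagnosis
#' at equipoise).
#'
#' @param model a [margin_fit()] result.
#' @param dataset a [feature_dataset()] with matching feature dimension.
#' @param tie_label label assigned when the score is exactly zero.
#' @return A data.frame with columns `subject_id`, `true_label`,
#'   `predicted_label`, `decision_value`.
#' @export
decision_values <- function(model, dataset, tie_label = 1L) {
  x <- dataset$features
  if (ncol(x) != length(model$weights))
    stop("feature dimension (", ncol(x), ") does not match model (",
         length(model$weights), ")")
  score <- drop(sweep(x, 2, model$feature_means) %*% model$weights) +
    model$bias
  pred <- ifelse(score > 0, 1L, ifelse(score < 0, -1L, as.integer(tie_label)))
  data.frame(subject_id = dataset$subject_ids,
             true_label = dataset$labels,
             predicted_label = as.integer(pred),
             decision_value = as.numeric(score),
             stringsAsFactors = FALSE)
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject, a classifier is trained on all remaining subjects and
#' used to predict the held-out one, yielding one out-of-sample prediction
#' and decision value per subject. Deterministic and invariant to subject
#' ordering.
#'
#' @inheritParams margin_fit
#' @param tie_label see [decision_values()].
#' @return An object of class `cv_result`: a data.frame (one row per subject,
#'   columns as in [decision_values()]) with attribute `n_folds`.
#' @export
loso_cv <- function(dataset, C = 1, center = FALSE, tie_label = 1L) {
  n <- length(dataset$labels)
  if (n < 3) stop("need at least 3 subjects for leave-one-out")
  # canonicalize subject order so results are invariant to input ordering
  ord <- order(dataset$subject_ids)
  ds <- feature_dataset(dataset$features[ord, , drop = FALSE],
                        dataset$labels[ord], dataset$subject_ids[ord],
                        dataset$field_tag, dataset$tissue_tag)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    tr_idx <- setdiff(seq_len(n), i)
    tr_y <- ds$labels[tr_idx]
    if (length(unique(tr_y)) < 2)
      stop("training fold without subject '", ds$subject_ids[i],
           "' contains a single class")
    train <- feature_dataset(ds$features[tr_idx, , drop = FALSE],
                             tr_y, ds$subject_ids[tr_idx],
                             ds$field_tag, ds$tissue_tag)
    test <- feature_dataset(ds$features[i, , drop = FALSE],
                            ds$labels[i], ds$subject_ids[i],
                            ds$field_tag, ds$tissue_tag)
    model <- margin_fit(train, C = C, center = center)
    res[[i]] <- decision_values(model, test, tie_label = tie_label)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, n_folds = n, class = c("cv_result", "data.frame"))
}

#' Classification performance of a cross-validation result
#'
#' @param cv a [loso_cv()] result (or any data.frame with `true_label` and
#'   `predicted_label`).
#' @return Named numeric vector with `balanced_accuracy`, `sensitivity`,
#'   `specificity` (proportions; patient = positive condition).
#' @export
cv_performance <- function(cv) {
  sens <- mean(cv$predicted_label[cv$true_label == -1L] == -1L)
  spec <- mean(cv$predicted_label[cv$true_label == 1L] == 1L)
  c(balanced_accuracy = (sens + spec) / 2,
    sensitivity = sens, specificity = spec)
}

#' Discrimination mask: features driving the separation
#'
#' Thresholds the weight vector at a fraction of its extreme positive and
#' negative values: features with weight at or above
#' `fraction * max(positive weights)` form the positive set (pointing toward
#' controls, +1), features at or below `fraction * min(negative weights)`
#' form the negative set (pointing toward patients).
#'
#' @param weights numeric weight vector (or a `margin_classifier`).
#' @param fraction threshold fraction of the extreme weights, default 0.30.
#' @return List with integer index vectors `positive` and `negative` and
#'   logical flags `no_positive`, `no_negative` set when a side has no
#'   weights of that sign.
#' @export
discrimination_mask <- function(weights, fraction = 0.30) {
  if (inherits(weights, "margin_classifier")) weights <- weights$weights
  stopifnot(is.numeric(weights), fraction >= 0, fraction <= 1)
  if (all(weights == 0)) stop("all weights are zero")
  pos <- weights[weights > 0]
  neg <- weights[weights < 0]
  no_pos <- length(pos) == 0
  no_neg <- length(neg) == 0
  pos_idx <- if (no_pos) integer(0) else
    which(weights >= fraction * max(pos))
  neg_idx <- if (no_neg) integer(0) else
    which(weights <= fraction * min(neg))
  list(positive = pos_idx, negative = neg_idx,
       no_positive = no_pos, no_negative = no_neg)
}
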