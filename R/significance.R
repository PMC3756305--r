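#' Permutation significance test for cross-validated performance
#'
#' Re-runs the full leave-one-subject-out pipeline under random reassignments
#' of the patient/control labels (class counts preserved) and compares the
#' observed balanced accuracy, sensitivity and specificity against the null
#' distributions so obtained. P-values use the add-one estimator
#' \eqn{p = (r + 1) / (B + 1)} where \eqn{r} counts null statistics at least
#' as large as the observed one, which guarantees a valid test.
#'
#' @inheritParams margin_fit
#' @param n_permutations number of label permutations (the study design uses
#'   1000; smaller values are useful for simulation studies).
#' @param seed integer seed governing the label reassignments.
#' @return An object of class `permutation_result`: list with `observed`
#'   (named vector), `null` (matrix, one row per permutation), `p_values`,
#'   `n_permutations`, `seed`.
#' @export
permutation_test <- function(dataset, C = 1, n_permutations = 1000L,
                             seed = 1L, center = FALSE) {
  stopifnot(n_permutations >= 1)
  observed <- cv_performance(loso_cv(dataset, C = C, center = center))
  perms <- withr::with_seed(as.integer(seed), {
    replicate(n_permutations, sample(dataset$labels), simplify = FALSE)
  })
  null <- t(vapply(perms, function(lab) {
    ds <- feature_dataset(dataset$features, lab, dataset$subject_ids,
                          dataset$field_tag, dataset$tissue_tag)
    cv_performance(loso_cv(ds, C = C, center = center))
  }, numeric(3)))
  p <- vapply(names(observed), function(s) {
    (sum(null[, s] >= observed[[s]]) + 1) / (n_permutations + 1)
  }, numeric(1))
  structure(list(observed = observed, null = null, p_values = p,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d permutations (seed %d)\n",
              x$n_permutations, x$seed))
  for (s in names(x$observed))
    cat(sprintf("  %-18s %.3f  (p = %.4g)\n", s, x$observed[[s]],
                x$p_values[[s]]))
  invisible(x)
}

#' Paired t-test on matched value vectors
#'
#' Two-sided paired t-test, as used to compare per-patient decision values
#' between classifiers: \eqn{t = \bar d / (s_d / \sqrt n)} with
#' \eqn{d = a - b} and \eqn{df = n - 1}.
#'
#' @param values_a,values_b numeric vectors of equal length (n >= 2).
#' @return List with `t`, `df`, `p_value`, `mean_difference`.
#' @export
paired_ttest <- function(values_a, values_b) {
  stopifnot(is.numeric(values_a), is.numeric(values_b))
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length")
  n <- length(values_a)
  if (n < 2) stop("need at least 2 pairs")
  d <- values_a - values_b
  sd_d <- stats::sd(d)
  if (sd_d == 0)
    stop("degenerate input: paired differences have zero variance")
  t_stat <- mean(d) / (sd_d / sqrt(n))
  list(t = t_stat, df = n - 1L,
       p_value = 2 * stats::pt(-abs(t_stat), df = n - 1),
       mean_difference = mean(d))
}

#' Cohen's kappa between two binary labelings
#'
#' Chance-corrected agreement between two classifiers' predicted labels:
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with observed agreement \eqn{p_o}
#' and expected agreement \eqn{p_e} from the marginal label frequencies.
#'
#' @param labels_a,labels_b equal-length vectors over a shared binary
#'   alphabet.
#' @return List with `kappa`, `p_o`, `p_e`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  lv <- sort(unique(c(labels_a, labels_b)))
  if (length(lv) > 2) stop("labels must come from a binary alphabet")
  n <- length(labels_a)
  p_o <- mean(labels_a == labels_b)
  p_e <- sum(vapply(lv, function(l) {
    mean(labels_a == l) * mean(labels_b == l)
  }, numeric(1)))
  kappa <- if (p_e == 1) {
    if (p_o == 1) 1 else
      stop("expected agreement is 1 but observed agreement is below 1")
  } else (p_o - p_e) / (1 - p_e)
  list(kappa = kappa, p_o = p_o, p_e = p_e)
}
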