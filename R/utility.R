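#' Confusion matrix with patient as the positive condition
#'
#' @param TP,FN,FP,TN nonnegative integer counts. TP + FN is the number of
#'   patients, FP + TN the number of controls.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(TP, FN, FP, TN) {
  counts <- c(TP = TP, FN = FN, FP = FP, TN = TN)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  counts <- as.list(counts)
  counts[] <- lapply(counts, as.integer)
  structure(counts, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (patient = positive)\n")
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2, byrow = TRUE,
              dimnames = list(c("patient", "control"),
                              c("pred patient", "pred control")))
  print(m)
  invisible(x)
}

#' Tabulate a confusion matrix from cross-validation output
#'
#' Patients carry label -1 and are the positive condition: a patient
#' predicted -1 is a true positive.
#'
#' @param cv a [loso_cv()] result (or data.frame with `true_label`,
#'   `predicted_label`).
#' @return A [confusion_matrix()].
#' @export
confusion_from_cv <- function(cv) {
  if (nrow(cv) == 0) stop("empty cross-validation result")
  confusion_matrix(TP = sum(cv$true_label == -1L & cv$predicted_label == -1L),
                   FN = sum(cv$true_label == -1L & cv$predicted_label == 1L),
                   FP = sum(cv$true_label == 1L & cv$predicted_label == -1L),
                   TN = sum(cv$true_label == 1L & cv$predicted_label == 1L))
}

#' Reconstruct integer counts behind printed sensitivity/specificity
#'
#' Published reports usually print rates, not counts. Given the group sizes,
#' the counts are recovered as the nearest integers; a warning is raised if
#' the implied rate differs from the input by more than half a count, i.e.
#' if no integer count reproduces the printed rate.
#'
#' @param sensitivity,specificity proportions in \[0, 1\].
#' @param n_patients,n_controls group sizes (>= 1).
#' @return A [confusion_matrix()].
#' @examples
#' confusion_from_rates(0.789, 0.75, 19, 20)  # TP 15, FN 4, FP 5, TN 15
#' @export
confusion_from_rates <- function(sensitivity, specificity,
                                 n_patients, n_controls) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            n_patients >= 1, n_controls >= 1)
  TP <- round(sensitivity * n_patients)
  TN <- round(specificity * n_controls)
  # a rate exactly half a count away from the recovered integer is ambiguous
  # (two counts are equally near); warn rather than silently pick one
  tol <- (1 - 1e-9) * 0.5
  if (abs(TP / n_patients - sensitivity) >= tol / n_patients)
    warning("no integer count unambiguously reproduces sensitivity ",
            sensitivity, " with ", n_patients, " patients")
  if (abs(TN / n_controls - specificity) >= tol / n_controls)
    warning("no integer count unambiguously reproduces specificity ",
            specificity, " with ", n_controls, " controls")
  confusion_matrix(TP = TP, FN = n_patients - TP,
                   FP = n_controls - TN, TN = TN)
}

#' Clinical-utility panel of a confusion matrix
#'
#' Derives the diagnostic indices: sensitivity, specificity, balanced
#' accuracy, positive/negative predictive value (PPV/NPV), predictive summary
#' index (PSI = PPV + NPV - 1, the total gain in diagnostic certainty),
#' number needed to predict (NNP = 1/PSI, patients to examine per one
#' correct net prediction) and diagnostic odds ratio
#' (DOR = (TP/FN) / (FP/TN), prevalence-invariant).
#'
#' Two rounding policies are offered. `"exact"` carries full precision and
#' computes the DOR from the integer counts. `"published"` mirrors the
#' reporting chain common in clinical papers: rates are first rounded to one
#' decimal percent, and PSI, NNP and DOR are then computed from those rounded
#' proportions and reported to three decimals. The two policies can disagree
#' in the third decimal, which is why the policy used is recorded in the
#' output.
#'
#' @param cm a [confusion_matrix()].
#' @param rounding_policy `"exact"` or `"published"`.
#' @param continuity_correction add 0.5 to every cell before computing the
#'   DOR when any cell is zero (off by default; with a zero cell and no
#'   correction the DOR is infinite).
#' @return Object of class `utility_panel`: list with the indices (as
#'   proportions), `DOR`, `flags` (character vector naming undefined
#'   indices), and `rounding_policy`. Undefined indices are `NA`; `NNP` is
#'   `NA` (flagged) when PSI <= 0.
#' @examples
#' utility_panel(confusion_matrix(15, 4, 5, 15), "published")
#' @export
utility_panel <- function(cm, rounding_policy = c("exact", "published"),
                          continuity_correction = FALSE) {
  rounding_policy <- match.arg(rounding_policy)
  stopifnot(inherits(cm, "confusion_matrix"))
  flags <- character(0)
  rate <- function(num, den, name) {
    if (den == 0) { flags <<- c(flags, name); NA_real_ } else num / den
  }
  sens <- rate(cm$TP, cm$TP + cm$FN, "sensitivity")
  spec <- rate(cm$TN, cm$FP + cm$TN, "specificity")
  ppv <- rate(cm$TP, cm$TP + cm$FP, "PPV")
  npv <- rate(cm$TN, cm$TN + cm$FN, "NPV")

  if (rounding_policy == "published") {
    r1 <- function(x) round(100 * x, 1) / 100
    sens <- r1(sens); spec <- r1(spec); ppv <- r1(ppv); npv <- r1(npv)
  }
  bal <- (sens + spec) / 2
  psi <- ppv + npv - 1
  if (rounding_policy == "published" && !is.na(psi)) psi <- round(psi, 3)
  nnp <- if (is.na(psi) || psi <= 0) {
    if (!is.na(psi) && psi <= 0) flags <- c(flags, "NNP")
    NA_real_
  } else 1 / psi
  if (rounding_policy == "published" && !is.na(nnp)) nnp <- round(nnp, 3)

  dor <- if (rounding_policy == "exact") {
    cells <- c(cm$TP, cm$FN, cm$FP, cm$TN)
    if (any(cells == 0) && continuity_correction) cells <- cells + 0.5
    if (cells[2] * cells[3] == 0) {
      flags <- c(flags, "DOR")
      if (cells[1] * cells[4] == 0) NaN else Inf
    } else (cells[1] * cells[4]) / (cells[2] * cells[3])
  } else {
    if (is.na(sens) || is.na(spec)) NA_real_
    else if (sens == 1 || spec == 1) { flags <- c(flags, "DOR"); Inf }
    else round((sens / (1 - sens)) * (spec / (1 - spec)), 3)
  }

  structure(list(sensitivity = sens, specificity = spec,
                 balanced_accuracy = bal, PPV = ppv, NPV = npv,
                 PSI = psi, NNP = nnp, DOR = dor,
                 flags = unique(flags),
                 rounding_policy = rounding_policy,
                 confusion = cm),
            class = "utility_panel")
}

#' @export
print.utility_panel <- function(x, ...) {
  cat(sprintf("<utility_panel> (%s rounding)\n", x$rounding_policy))
  pct <- function(v) if (is.na(v)) "   NA" else sprintf("%5.1f%%", 100 * v)
  cat(sprintf("  balanced accuracy %s  sensitivity %s  specificity %s\n",
              pct(x$balanced_accuracy), pct(x$sensitivity),
              pct(x$specificity)))
  cat(sprintf("  PPV %s  NPV %s\n", pct(x$PPV), pct(x$NPV)))
  cat(sprintf("  PSI %.3f  NNP %s  DOR %s\n", x$PSI,
              ifelse(is.na(x$NNP), "undefined", sprintf("%.3f", x$NNP)),
              format(x$DOR)))
  if (length(x$flags))
    cat("  flagged undefined:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
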