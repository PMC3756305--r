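test_that("confusion tabulation treats patient (-1) as the positive condition", {
  cv <- data.frame(true_label = c(-1, -1, -1, 1, 1),
                   predicted_label = c(-1, -1, -1, 1, 1))
  cm <- confusion_from_cv(cv)
  expect_equal(unlist(cm[c("TP", "FN", "FP", "TN")]),
               c(TP = 3L, FN = 0L, FP = 0L, TN = 2L))
  # everything predicted control
  cv2 <- data.frame(true_label = c(-1, -1, 1), predicted_label = c(1, 1, 1))
  cm2 <- confusion_from_cv(cv2)
  expect_equal(cm2$TP, 0L)
  expect_equal(cm2$FP, 0L)
  expect_equal(cm2$TP + cm2$FN + cm2$FP + cm2$TN, 3L)
})

test_that("counts recovered from printed rates match a nearest-integer oracle", {
  nearest <- function(rate, n) which.min(abs((0:n) / n - rate)) - 1L
  cases <- list(c(0.789, 0.75), c(0.632, 0.70), c(0.579, 0.70),
                c(0.632, 0.75), c(1, 1))
  for (cs in cases) {
    cm <- confusion_from_rates(cs[1], cs[2], 19, 20)
    expect_equal(cm$TP, nearest(cs[1], 19))
    expect_equal(cm$TN, nearest(cs[2], 20))
    expect_equal(cm$TP + cm$FN, 19L)
    expect_equal(cm$FP + cm$TN, 20L)
  }
  expect_equal(unlist(confusion_from_rates(0.789, 0.75, 19, 20)),
               c(TP = 15L, FN = 4L, FP = 5L, TN = 15L), ignore_attr = TRUE)
  expect_equal(unlist(confusion_from_rates(0.632, 0.70, 19, 20)),
               c(TP = 12L, FN = 7L, FP = 6L, TN = 14L), ignore_attr = TRUE)
  expect_equal(unlist(confusion_from_rates(1, 1, 5, 5)),
               c(TP = 5L, FN = 0L, FP = 0L, TN = 5L), ignore_attr = TRUE)
  expect_warning(confusion_from_rates(0.5, 0.75, 19, 20), "sensitivity")
})

test_that("published-rounding panel reproduces the one-decimal reporting chain", {
  p <- utility_panel(confusion_matrix(15, 4, 5, 15), "published")
  expect_equal(p$sensitivity, 0.789)
  expect_equal(p$specificity, 0.750)
  expect_equal(p$PPV, 0.750)
  expect_equal(p$NPV, 0.789)
  expect_equal(p$PSI, 0.539)
  expect_equal(p$NNP, 1.855)
  p2 <- utility_panel(confusion_matrix(12, 7, 6, 14), "published")
  expect_equal(p2$PPV, 0.667)
  expect_equal(p2$NPV, 0.667)
  expect_equal(p2$PSI, 0.334)
  expect_equal(p2$NNP, 2.994)
})

test_that("exact panel arithmetic: DOR from counts, degenerate cases flagged", {
  p <- utility_panel(confusion_matrix(15, 4, 5, 15), "exact")
  expect_equal(p$DOR, 225 / 20)  # 11.25
  expect_equal(p$balanced_accuracy, (15 / 19 + 15 / 20) / 2)
  # uninformative test
  u <- utility_panel(confusion_matrix(5, 5, 5, 5), "exact")
  expect_equal(u$DOR, 1)
  expect_equal(u$PSI, 0)
  expect_true(is.na(u$NNP))
  expect_true("NNP" %in% u$flags)
  # zero cell: infinite DOR unless continuity correction requested
  z <- utility_panel(confusion_matrix(5, 0, 2, 8), "exact")
  expect_equal(z$DOR, Inf)
  zc <- utility_panel(confusion_matrix(5, 0, 2, 8), "exact",
                      continuity_correction = TRUE)
  expect_equal(zc$DOR, (5.5 * 8.5) / (0.5 * 2.5))
  # empty margin: affected indices undefined and flagged
  e <- utility_panel(confusion_matrix(0, 0, 5, 5), "exact")
  expect_true(is.na(e$sensitivity))
  expect_true("sensitivity" %in% e$flags)
})

test_that("panel identities hold on exhaustive small confusion matrices", {
  for (cts in enumerate_confusions(12)) {
    if (any(cts == 0)) next
    p <- utility_panel(do.call(confusion_matrix, as.list(cts)), "exact")
    # balanced accuracy is the mean of sensitivity and specificity
    expect_equal(p$balanced_accuracy, (p$sensitivity + p$specificity) / 2)
    # PSI identity and NNP reciprocal
    expect_equal(p$PSI, p$PPV + p$NPV - 1, tolerance = 1e-12)
    if (!is.na(p$NNP)) expect_equal(p$NNP * p$PSI, 1, tolerance = 1e-12)
    # DOR from counts equals DOR from exact rates
    dor_rates <- (p$sensitivity / (1 - p$sensitivity)) *
      (p$specificity / (1 - p$specificity))
    expect_equal(p$DOR, dor_rates, tolerance = 1e-12)
    # DOR = 1 exactly when sensitivity = 1 - specificity
    expect_equal(isTRUE(all.equal(p$DOR, 1)),
                 isTRUE(all.equal(p$sensitivity, 1 - p$specificity)))
  }
})

test_that("panel is invariant to scaling all counts by a common factor", {
  base <- confusion_matrix(6, 2, 3, 9)
  p1 <- utility_panel(base, "exact")
  p4 <- utility_panel(confusion_matrix(24, 8, 12, 36), "exact")
  for (f in c("sensitivity", "specificity", "balanced_accuracy",
              "PPV", "NPV", "PSI", "NNP", "DOR"))
    expect_equal(p1[[f]], p4[[f]], tolerance = 1e-12)
})
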