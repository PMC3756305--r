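test_that("linear kernel matches hand-computed dot products", {
  ds <- toy_dataset(rbind(c(1, 2), c(3, 4)), c(-1, 1))
  K <- linear_kernel(ds)
  expect_equal(unclass(K), matrix(c(5, 11, 11, 25), 2, 2),
               ignore_attr = TRUE)
  # orthogonal unit rows
  ds2 <- toy_dataset(rbind(c(1, 0), c(0, 1)), c(-1, 1))
  expect_equal(unclass(linear_kernel(ds2)),
               diag(2), ignore_attr = TRUE)
})

test_that("kernel is PSD, centering works, non-finite input is named", {
  ds <- random_2d(5, 1, seed = 3)
  for (ctr in c(FALSE, TRUE)) {
    K <- linear_kernel(ds, center = ctr)
    expect_gte(min(eigen(K, symmetric = TRUE)$values), -1e-8)
  }
  Kc <- linear_kernel(ds, center = TRUE)
  xc <- scale(ds$features, center = TRUE, scale = FALSE)
  expect_equal(unclass(Kc), tcrossprod(xc), ignore_attr = TRUE)
  bad <- ds
  bad$features[2, 1] <- NA
  expect_error(linear_kernel(bad), "S002")
})

test_that("symmetric separable pair gives the unit hyperplane", {
  ds <- toy_dataset(matrix(c(-1, 1), 2, 1), c(-1, 1))
  m <- margin_fit(ds, C = 1000)
  expect_equal(m$weights, 1, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(m$bias, 0, tolerance = 1e-8)
})

test_that("solver matches the QP oracle on small 2-D fixtures", {
  fixtures <- list(
    list(ds = toy_dataset(rbind(c(-1, 0), c(-2, 1), c(1, 0), c(2, -1)),
                          c(-1, -1, 1, 1)), C = 10),
    list(ds = toy_dataset(rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0),
                                c(2, 2), c(-1, -1)),
                          c(-1, -1, 1, 1, 1, -1)), C = 1),  # non-separable
    list(ds = random_2d(3, 2, seed = 11), C = 1),
    # overlapping classes: the dual has a nearly flat ridge, so equal
    # objectives still allow ~1e-6 hyperplane differences between solvers
    list(ds = random_2d(3, 0.5, seed = 12), C = 5, tol = 1e-5),
    list(ds = random_2d(2, 3, seed = 13), C = 100)
  )
  for (f in fixtures) {
    tol <- if (is.null(f$tol)) 1e-6 else f$tol
    m <- margin_fit(f$ds, C = f$C)
    o <- oracle_svm(f$ds, f$C)
    expect_equal(m$weights, o$weights, tolerance = tol,
                 ignore_attr = TRUE)
    expect_equal(m$bias, o$bias, tolerance = tol)
    expect_true(all(abs(m$alpha) <= f$C + 1e-8))
    # primal weights equal label-weighted sum of training rows
    expect_equal(m$weights,
                 drop(crossprod(f$ds$features, m$dual_coefficients)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("single-class input and non-positive C are rejected", {
  ds <- toy_dataset(rbind(c(0, 1), c(1, 0)), c(1, 1))
  expect_error(margin_fit(ds, C = 1), "both classes")
  ds2 <- random_2d(3, 1, seed = 1)
  expect_error(margin_fit(ds2, C = 0), "C must be > 0")
})

test_that("duplicating a correctly classified non-support point changes nothing", {
  ds <- random_2d(4, 3, seed = 21)
  m <- margin_fit(ds, C = 10)
  dv <- decision_values(m, ds)
  nsv <- which(abs(m$alpha) < 1e-10 & dv$predicted_label == dv$true_label)[1]
  expect_false(is.na(nsv))
  ds2 <- feature_dataset(rbind(ds$features, ds$features[nsv, ]),
                         c(ds$labels, ds$labels[nsv]))
  m2 <- margin_fit(ds2, C = 10)
  expect_equal(m2$weights, m$weights, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(m2$bias, m$bias, tolerance = 1e-6)
})

test_that("decision values are linear, respect margins, and flag mismatches", {
  m <- structure(list(weights = 1, bias = 0, feature_means = 0),
                 class = "margin_classifier")
  dv <- decision_values(m, toy_dataset(matrix(0.5), -1))
  expect_equal(dv$decision_value, 0.5)
  expect_equal(dv$predicted_label, 1L)
  # tie rule: exact zero predicts the configured label (control by default)
  dv0 <- decision_values(m, toy_dataset(matrix(0), -1))
  expect_equal(dv0$predicted_label, 1L)
  dv0p <- decision_values(m, toy_dataset(matrix(0), -1), tie_label = -1L)
  expect_equal(dv0p$predicted_label, -1L)
  expect_error(decision_values(m, toy_dataset(cbind(1, 2), 1)),
               "dimension")

  ds <- random_2d(4, 3, seed = 31)
  fit <- margin_fit(ds, C = 1000)
  dv <- decision_values(fit, ds)
  # support vectors of a separable problem sit on or outside the margin
  sv <- abs(fit$alpha) > 1e-8
  expect_true(all(abs(dv$decision_value[sv]) >= 1 - 1e-6))
  # linearity: score of the mean of two points is the mean of their scores
  mid <- toy_dataset(t((ds$features[1, ] + ds$features[2, ]) / 2), 1)
  expect_equal(decision_values(fit, mid)$decision_value,
               mean(dv$decision_value[1:2]), tolerance = 1e-10)
})

test_that("dual and primal decision values agree", {
  ds <- random_2d(5, 1, seed = 41)
  m <- margin_fit(ds, C = 2)
  K <- linear_kernel(ds)
  dual_scores <- drop(K %*% m$dual_coefficients) + m$bias
  expect_equal(decision_values(m, ds)$decision_value, dual_scores,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("LOSO yields one out-of-sample result per subject, order-invariantly", {
  ds <- random_2d(4, 2, seed = 51)
  cv <- loso_cv(ds, C = 1)
  expect_equal(nrow(cv), 8)
  expect_equal(attr(cv, "n_folds"), 8)
  expect_setequal(cv$subject_id, ds$subject_ids)
  # permuting subject order leaves per-subject results identical
  perm <- withr::with_seed(1, sample(8))
  ds2 <- feature_dataset(ds$features[perm, ], ds$labels[perm],
                         ds$subject_ids[perm])
  cv2 <- loso_cv(ds2, C = 1)
  expect_identical(as.data.frame(cv), as.data.frame(cv2))
  # repeated runs are deterministic
  expect_identical(as.data.frame(loso_cv(ds, C = 1)), as.data.frame(cv))
})

test_that("LOSO separates well-separated clusters perfectly", {
  ch <- generate_paired_cohort(synth_config(n_patients = 5, n_controls = 6,
                                            n_features = 20,
                                            effect_fraction = 1,
                                            effect_size = 8,
                                            noise_scale_low_field = 0.2,
                                            noise_scale_high_field = 0.1,
                                            seed = 5))
  perf <- cv_performance(loso_cv(ch$low_field))
  expect_equal(perf[["balanced_accuracy"]], 1)
})

test_that("LOSO refuses folds that lose a class", {
  ds <- toy_dataset(rbind(c(0, 0), c(1, 1), c(2, 2)), c(-1, 1, 1),
                    ids = c("P1", "C1", "C2"))
  expect_error(loso_cv(ds), "P1")
})

test_that("LOSO on null data performs at chance over many seeds", {
  ba <- sapply(1:20, function(s) {
    ch <- generate_paired_cohort(synth_config(n_patients = 10,
                                              n_controls = 10,
                                              n_features = 50,
                                              effect_size = 0, seed = s))
    cv_performance(loso_cv(ch$low_field))[["balanced_accuracy"]]
  })
  expect_gte(mean(ba), 0.45)
  expect_lte(mean(ba), 0.55)
})

test_that("discrimination mask thresholds at the stated weight fractions", {
  m <- discrimination_mask(c(1.0, 0.2, -0.5, -0.1), fraction = 0.3)
  expect_identical(m$positive, 1L)
  expect_identical(m$negative, 3L)
  # all equal positive weights -> everything in the positive set, none negative
  m2 <- discrimination_mask(rep(0.4, 5), fraction = 0.3)
  expect_identical(m2$positive, 1:5)
  expect_identical(m2$negative, integer(0))
  expect_true(m2$no_negative)
  # fraction 1 keeps only the extremes
  m3 <- discrimination_mask(c(0.1, 0.9, -0.2, -0.8), fraction = 1)
  expect_identical(m3$positive, 2L)
  expect_identical(m3$negative, 4L)
  expect_true(all(!(m3$positive %in% m3$negative)))
  expect_error(discrimination_mask(c(0, 0)), "zero")
})
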