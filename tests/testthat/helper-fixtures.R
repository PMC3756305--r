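# Small deterministic fixtures shared across tests.

toy_dataset <- function(x, y, ids = NULL) {
  feature_dataset(as.matrix(x), y, subject_ids = ids)
}

# Gaussian two-class 2-D dataset; sep controls class separation.
random_2d <- function(n_per_class, sep, seed) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(2 * n_per_class * 2), 2 * n_per_class, 2)
    y <- rep(c(-1L, 1L), each = n_per_class)
    x[y == 1L, 1] <- x[y == 1L, 1] + sep
    toy_dataset(x, y)
  })
}

# libsvm (via e1071) as the independent maximum-margin oracle. libsvm's
# decision values are positive for the class of the *first training row*;
# flip so they share this package's convention (+1 control positive).
oracle_svm <- function(dataset, C) {
  fit <- e1071::svm(dataset$features, factor(dataset$labels),
                    kernel = "linear", cost = C, scale = FALSE,
                    tolerance = 1e-10)
  s <- if (dataset$labels[1] == 1L) 1 else -1
  w <- s * drop(t(fit$coefs) %*% fit$SV)
  list(weights = w, bias = s * -fit$rho, model = fit)
}

oracle_decision <- function(oracle, dataset) {
  drop(dataset$features %*% oracle$weights) + oracle$bias
}

# exhaustive confusion matrices with total count <= n_max (positive cells
# where needed are handled by the caller)
enumerate_confusions <- function(n_max) {
  out <- list()
  for (tp in 0:n_max) for (fn in 0:(n_max - tp))
    for (fp in 0:(n_max - tp - fn)) for (tn in 0:(n_max - tp - fn - fp))
      out[[length(out) + 1]] <- c(TP = tp, FN = fn, FP = fp, TN = tn)
  out
}
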