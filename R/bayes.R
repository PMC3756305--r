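#' A diagnostic test defined by its operating characteristics
#'
#' @param name short label.
#' @param sensitivity,specificity proportions; strictly inside (0, 1) for
#'   likelihood-ratio use, boundary values are handled as limits by the
#'   posterior operations.
#' @return Object of class `diagnostic_test`.
#' @export
diagnostic_test <- function(sensitivity, specificity, name = "") {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  structure(list(name = name, sensitivity = sensitivity,
                 specificity = specificity),
            class = "diagnostic_test")
}

#' Post-test probability of disease after a positive result
#'
#' Bayes' theorem at prior prevalence `prior`:
#' \deqn{P(D \mid +) = \frac{\pi\,\mathrm{sens}}
#'   {\pi\,\mathrm{sens} + (1-\pi)(1-\mathrm{spec})}}
#' Boundary operating characteristics return the limit (1 when specificity
#' is 1 with positive sensitivity; 0 when sensitivity is 0).
#'
#' @param prior prior probability of disease, in (0, 1).
#' @param test a [diagnostic_test()].
#' @return Posterior probability of disease.
#' @export
posterior_positive <- function(prior, test) {
  stopifnot(prior > 0, prior < 1, inherits(test, "diagnostic_test"))
  s <- test$sensitivity; sp <- test$specificity
  if (s == 0) return(0)
  if (sp == 1) return(1)
  prior * s / (prior * s + (1 - prior) * (1 - sp))
}

#' Post-test probability of disease after a negative result
#'
#' \deqn{P(D \mid -) = \frac{\pi(1-\mathrm{sens})}
#'   {\pi(1-\mathrm{sens}) + (1-\pi)\,\mathrm{spec}}}
#' A perfect-sensitivity test returns 0.
#'
#' @inheritParams posterior_positive
#' @return Posterior probability of disease given a negative result.
#' @export
posterior_negative <- function(prior, test) {
  stopifnot(prior > 0, prior < 1, inherits(test, "diagnostic_test"))
  s <- test$sensitivity; sp <- test$specificity
  if (s == 1) return(0)
  if (sp == 0 && s < 1) return(1)
  prior * (1 - s) / (prior * (1 - s) + (1 - prior) * sp)
}

#' Combine independent tests that are all positive
#'
#' Multiplies the prior odds by each test's positive likelihood ratio
#' \eqn{\mathrm{sens}/(1-\mathrm{spec})}, assuming conditional independence
#' of the tests given disease status (an assumption, not a property the
#' package can verify). Order of the tests does not matter.
#'
#' @param prior prior probability of disease, in (0, 1).
#' @param tests list of [diagnostic_test()] objects (at least one).
#' @return List with `posterior`, `likelihood_ratios` (one per test) and
#'   `flags` (notes any infinite likelihood ratio, where the posterior is the
#'   limit 1).
#' @examples
#' combine_tests_all_positive(0.70, list(
#'   diagnostic_test(0.789, 0.75, "GM"),
#'   diagnostic_test(0.632, 0.75, "WM")))$posterior  # 0.949
#' @export
combine_tests_all_positive <- function(prior, tests) {
  stopifnot(prior > 0, prior < 1, length(tests) >= 1)
  if (inherits(tests, "diagnostic_test")) tests <- list(tests)
  lr <- vapply(tests, function(t) {
    stopifnot(inherits(t, "diagnostic_test"))
    if (t$specificity == 1) Inf else t$sensitivity / (1 - t$specificity)
  }, numeric(1))
  flags <- if (any(is.infinite(lr))) "infinite_likelihood_ratio"
           else character(0)
  odds <- prior / (1 - prior) * prod(lr)
  posterior <- if (is.infinite(odds)) 1 else odds / (1 + odds)
  list(posterior = posterior, likelihood_ratios = lr, flags = flags)
}

#' Treat/discharge decision scenario
#'
#' @param prior prior prevalence in (0, 1).
#' @param tests list of [diagnostic_test()] objects combined under the
#'   all-positive rule.
#' @param treat_threshold posterior at or above which treatment is initiated.
#' @param discharge_threshold posterior at or below which the subject is
#'   discharged; must be below `treat_threshold`. Defaults follow the
#'   worked scenario: 85% confidence to prescribe, 45% to discharge.
#' @return Object of class `bayes_scenario`.
#' @export
bayes_scenario <- function(prior, tests, treat_threshold = 0.85,
                           discharge_threshold = 0.45) {
  stopifnot(prior > 0, prior < 1,
            treat_threshold > 0, treat_threshold < 1,
            discharge_threshold > 0, discharge_threshold < 1,
            discharge_threshold < treat_threshold)
  if (inherits(tests, "diagnostic_test")) tests <- list(tests)
  structure(list(prior = prior, tests = tests, rule = "all_positive",
                 treat_threshold = treat_threshold,
                 discharge_threshold = discharge_threshold),
            class = "bayes_scenario")
}

#' Clinical decision from a posterior probability
#'
#' @param posterior post-test probability of disease.
#' @param scenario a [bayes_scenario()] supplying the thresholds.
#' @return `"treat"` if the posterior reaches the treat threshold,
#'   `"discharge"` if it is at or below the discharge threshold, otherwise
#'   `"inconclusive"`.
#' @export
decide <- function(posterior, scenario) {
  stopifnot(inherits(scenario, "bayes_scenario"),
            posterior >= 0, posterior <= 1)
  if (posterior >= scenario$treat_threshold) "treat"
  else if (posterior <= scenario$discharge_threshold) "discharge"
  else "inconclusive"
}

#' Evaluate a full Bayes scenario
#'
#' Combines the scenario's tests under the all-positive rule and applies the
#' decision thresholds.
#'
#' @param scenario a [bayes_scenario()].
#' @return List with `posterior`, `action`, `likelihood_ratios`, `flags`.
#' @export
evaluate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "bayes_scenario"))
  comb <- combine_tests_all_positive(scenario$prior, scenario$tests)
  c(comb[c("posterior")], list(action = decide(comb$posterior, scenario)),
    comb[c("likelihood_ratios", "flags")])
}
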