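#' Configuration for the end-to-end classifier comparison
#'
#' Exactly one of `dataset_paths` (named CSV paths readable by
#' [read_feature_csv()]) or `synth` (a [synth_config()], from which paired
#' low/high-field cohorts are generated for two tissues) must be supplied.
#'
#' @param dataset_paths named character vector with entries `low_gm`,
#'   `low_wm`, `high_gm`, `high_wm`.
#' @param synth a [synth_config()].
#' @param C soft-margin constant.
#' @param n_permutations label permutations per classifier.
#' @param seed master seed for permutations (and, with `synth`, generation).
#' @param rounding_policy passed to [utility_panel()].
#' @param prior,treat_threshold,discharge_threshold Bayes scenario applied to
#'   the two high-field classifiers' cross-validated operating
#'   characteristics.
#' @param label_map used when reading CSVs; see [read_feature_csv()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(dataset_paths = NULL, synth = NULL, C = 1,
                       n_permutations = 1000L, seed = 1L,
                       rounding_policy = "published", prior = 0.70,
                       treat_threshold = 0.85, discharge_threshold = 0.45,
                       label_map = c(control = "control",
                                     patient = "patient")) {
  if (is.null(dataset_paths) == is.null(synth))
    stop("supply exactly one of dataset_paths or synth")
  if (!is.null(dataset_paths)) {
    need <- c("low_gm", "low_wm", "high_gm", "high_wm")
    if (!all(need %in% names(dataset_paths)))
      stop("dataset_paths needs entries: ", paste(need, collapse = ", "))
    missing <- dataset_paths[!file.exists(dataset_paths)]
    if (length(missing))
      stop("unresolvable path(s): ", paste(missing, collapse = ", "))
  }
  structure(list(dataset_paths = dataset_paths, synth = synth, C = C,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 rounding_policy = rounding_policy, prior = prior,
                 treat_threshold = treat_threshold,
                 discharge_threshold = discharge_threshold,
                 label_map = label_map),
            class = "run_config")
}

# FNV-1a over the JSON form of the config, for the run log
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg <- lapply(cfg, function(x) if (is.object(x)) unclass(x) else x)
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null")
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # multiply by the FNV prime mod 2^32 without losing double precision
    a <- h %/% 65536; c <- h %% 65536
    h <- (((a * 16777619) %% 65536) * 65536 + c * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

load_comparison_datasets <- function(config) {
  if (!is.null(config$dataset_paths)) {
    p <- config$dataset_paths
    tags <- list(low_gm = c("3T", "GM"), low_wm = c("3T", "WM"),
                 high_gm = c("7T", "GM"), high_wm = c("7T", "WM"))
    ds <- lapply(names(tags), function(k) {
      read_feature_csv(p[[k]], label_map = config$label_map,
                       field_tag = tags[[k]][1], tissue_tag = tags[[k]][2])
    })
    names(ds) <- names(tags)
    return(ds)
  }
  # two tissues share subjects but have independent anatomy/noise draws
  sub_seeds <- derive_seeds(config$synth$seed, 2L)
  cfg_gm <- config$synth; cfg_gm$seed <- sub_seeds[1]
  cfg_wm <- config$synth; cfg_wm$seed <- sub_seeds[2]
  gm <- generate_paired_cohort(cfg_gm, tissue_tag = "GM")
  wm <- generate_paired_cohort(cfg_wm, tissue_tag = "WM")
  list(low_gm = gm$low_field, low_wm = wm$low_field,
       high_gm = gm$high_field, high_wm = wm$high_field)
}

#' Run the full two-field, two-tissue classifier comparison
#'
#' For each of the four datasets (field x tissue): leave-one-subject-out
#' cross-validation, permutation p-values for balanced accuracy /
#' sensitivity / specificity, and the clinical-utility panel. Pairwise
#' between classifiers: Cohen's kappa on predicted labels and paired t-tests
#' on the patients' decision values (tissue-vs-tissue within field,
#' field-vs-field within tissue). Finally the two high-field classifiers'
#' cross-validated operating characteristics are combined in the Bayes
#' scenario.
#'
#' @param config a [run_config()].
#' @return Object of class `comparison_report`: list with `panels`
#'   (data.frame, one row per classifier), `pairwise` (data.frame),
#'   `bayes`, and `config_echo`.
#' @export
run_comparison <- function(config) {
  stopifnot(inherits(config, "run_config"))
  datasets <- load_comparison_datasets(config)

  rosters <- lapply(datasets, function(d) d$subject_ids)
  if (length(unique(lapply(rosters, sort))) != 1)
    stop("datasets have mismatched subject rosters")
  same_labels <- length(unique(lapply(datasets, function(d)
    d$labels[order(d$subject_ids)]))) == 1
  if (!same_labels) stop("datasets disagree on subject labels")

  message(sprintf("[svmdx] run_comparison: config %s, seed %d, svmdx %s, R %s",
                  config_hash(config), config$seed,
                  as.character(utils::packageVersion("svmdx")),
                  paste(R.version$major, R.version$minor, sep = ".")))

  perm_seeds <- derive_seeds(config$seed + 1L, length(datasets))
  cvs <- list(); panels <- list()
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    cv <- loso_cv(d, C = config$C)
    pt <- permutation_test(d, C = config$C,
                           n_permutations = config$n_permutations,
                           seed = perm_seeds[i])
    pan <- utility_panel(confusion_from_cv(cv), config$rounding_policy)
    dv_pat <- cv$decision_value[cv$true_label == -1L]
    panels[[names(datasets)[i]]] <- data.frame(
      classifier = paste(d$field_tag, d$tissue_tag),
      balanced_accuracy = pan$balanced_accuracy,
      p_balanced_accuracy = pt$p_values[["balanced_accuracy"]],
      specificity = pan$specificity,
      p_specificity = pt$p_values[["specificity"]],
      sensitivity = pan$sensitivity,
      p_sensitivity = pt$p_values[["sensitivity"]],
      PPV = pan$PPV, NPV = pan$NPV,
      mean_decision_patients = mean(dv_pat),
      sd_decision_patients = stats::sd(dv_pat),
      PSI = pan$PSI, NNP = pan$NNP, DOR = pan$DOR,
      stringsAsFactors = FALSE)
    cvs[[names(datasets)[i]]] <- cv
  }
  panels <- do.call(rbind, panels)
  rownames(panels) <- NULL

  pairs <- list(c("low_gm", "low_wm"), c("high_gm", "high_wm"),
                c("high_gm", "low_gm"), c("high_wm", "low_wm"))
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    a <- cvs[[pr[1]]]; b <- cvs[[pr[2]]]
    stopifnot(identical(a$subject_id, b$subject_id))
    kap <- cohens_kappa(a$predicted_label, b$predicted_label)
    pat <- a$true_label == -1L
    tt <- tryCatch(paired_ttest(a$decision_value[pat], b$decision_value[pat]),
                   error = function(e) list(t = NA_real_, df = NA_integer_,
                                            p_value = NA_real_))
    lab <- function(k) paste(datasets[[k]]$field_tag, datasets[[k]]$tissue_tag)
    data.frame(comparison = paste(lab(pr[1]), "vs", lab(pr[2])),
               kappa = kap$kappa, t = tt$t, df = tt$df, p_value = tt$p_value,
               stringsAsFactors = FALSE)
  }))

  high_tests <- lapply(c("high_gm", "high_wm"), function(k) {
    perf <- cv_performance(cvs[[k]])
    diagnostic_test(perf[["sensitivity"]], perf[["specificity"]],
                    name = paste(datasets[[k]]$field_tag,
                                 datasets[[k]]$tissue_tag))
  })
  scen <- bayes_scenario(config$prior, high_tests,
                         config$treat_threshold, config$discharge_threshold)
  bayes <- evaluate_scenario(scen)

  structure(list(panels = panels, pairwise = pairwise, bayes = bayes,
                 config_echo = list(hash = config_hash(config),
                                    seed = config$seed, C = config$C,
                                    n_permutations = config$n_permutations,
                                    rounding_policy = config$rounding_policy)),
            class = "comparison_report")
}

#' Write a comparison report to disk
#'
#' Emits `report.json` (the full report), `panels.csv` (one row per
#' classifier with the utility columns) and `pairwise.csv`. Output contains
#' no timestamps, so identical configurations give byte-identical files.
#'
#' @param report a [run_comparison()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  utils::write.csv(report$panels, file.path(dir, "panels.csv"),
                   row.names = FALSE)
  utils::write.csv(report$pairwise, file.path(dir, "pairwise.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(x$panels, digits = 3)
  cat("\npairwise:\n")
  print(x$pairwise, digits = 3)
  cat(sprintf("\nBayes (high-field tests, all positive): posterior %.3f -> %s\n",
              x$bayes$posterior, x$bayes$action))
  invisible(x)
}
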