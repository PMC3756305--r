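#' Write a feature dataset to CSV (with optional config sidecar)
#'
#' Columns are `subject_id`, `label` (the strings "control"/"patient"), then
#' the features as `f0001...fNNNN`. If `config` is supplied, a YAML sidecar
#' `<path>.yaml` records the generating parameters.
#'
#' @param dataset a [feature_dataset()].
#' @param path output CSV path.
#' @param config optional [synth_config()] written as a sidecar.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(dataset, path, config = NULL) {
  df <- data.frame(subject_id = dataset$subject_ids,
                   label = ifelse(dataset$labels == 1L, "control", "patient"),
                   dataset$features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(config)) {
    stopifnot(inherits(config, "synth_config"))
    yaml::write_yaml(c(unclass(config),
                       list(field_tag = dataset$field_tag,
                            tissue_tag = dataset$tissue_tag)),
                     paste0(path, ".yaml"))
  }
  invisible(path)
}

#' Read a feature dataset from CSV
#'
#' The label column must contain exactly the two values named in
#' `label_map`, which states explicitly which value means control (+1) and
#' which patient (-1); labels are never guessed from the data.
#'
#' @param path CSV with a header row, a `subject_id` column, a `label`
#'   column and numeric feature columns.
#' @param label_map named character vector `c(control = ..., patient = ...)`
#'   mapping file values to classes.
#' @param field_tag,tissue_tag tags attached to the result.
#' @return A [feature_dataset()].
#' @export
read_feature_csv <- function(path,
                             label_map = c(control = "control",
                                           patient = "patient"),
                             field_tag = "", tissue_tag = "") {
  stopifnot(all(c("control", "patient") %in% names(label_map)))
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  req <- c("subject_id", "label")
  if (!all(req %in% names(df)))
    stop("missing required column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  unknown <- setdiff(unique(as.character(df$label)), label_map)
  if (length(unknown))
    stop("unknown label value(s): ", paste(unknown, collapse = ", "))
  labels <- ifelse(as.character(df$label) == label_map[["control"]], 1L, -1L)
  feat_cols <- setdiff(names(df), req)
  feats <- df[, feat_cols, drop = FALSE]
  non_num <- feat_cols[!vapply(feats, is.numeric, logical(1))]
  if (length(non_num))
    stop("non-numeric feature column(s): ", paste(non_num, collapse = ", "))
  m <- as.matrix(feats)
  colnames(m) <- feat_cols
  feature_dataset(m, labels, df$subject_id, field_tag, tissue_tag)
}
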