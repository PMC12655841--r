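## JSON/CSV artifact writers: trial logs (JSON-lines), pruning traces,
## stability reports, final-model cards, and basin-plot data.

#' Write a dual-objective trial log as JSON-lines
#'
#' One JSON object per line and per trial: trial_id, nu, C,
#' log10_gamma_scale, fold_maes, fold_sv_ratios, cv_mae, sv_ratio, status.
#'
#' @param trials a \code{"dooTrials"} object.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeTrialLog <- function(trials, path) {
  stopifnot(inherits(trials, "dooTrials"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(trials$table))) {
    row <- trials$table[i, ]
    obj <- list(
      trial_id = row$trial_id, nu = row$nu, C = row$C,
      log10_gamma_scale = row$log10_gamma_scale,
      fold_maes = trials$fold_maes[i, ],
      fold_sv_ratios = trials$fold_sv_ratios[i, ],
      cv_mae = row$cv_mae, sv_ratio = row$sv_ratio, status = row$status
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"), con)
  }
  invisible(path)
}

candidateToList <- function(cand) {
  list(
    n_features = cand$n_features,
    features = cand$feature_names,
    params = list(
      nu = cand$params$nu, C = cand$params$C,
      log10_gamma_scale = cand$params$log10_gamma_scale, gamma = cand$gamma
    ),
    trial_id = cand$trial_id,
    cv_mae = cand$cv_mae, cv_mae_se = cand$cv_mae_se, sv_ratio = cand$sv_ratio,
    train_mae = cand$train_mae, test_mae = cand$test_mae,
    train_r2 = cand$train_r2, test_r2 = cand$test_r2,
    importances = as.list(cand$importances),
    removed_feature = cand$removed_feature
  )
}

#' Serialize a pruning trace to JSON
#'
#' @param trace a \code{"pruningTrace"}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeTrace <- function(trace, path) {
  stopifnot(inherits(trace, "pruningTrace"))
  obj <- list(
    run_id = trace$run_id, split_seed = trace$split_seed,
    feature_set = trace$feature_set,
    levels = lapply(trace$candidates, candidateToList)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a serialized pruning trace back into its in-memory form
#'
#' @param path a JSON file written by [writeTrace()].
#' @return A \code{"pruningTrace"} object.
#' @export
readTrace <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  candidates <- lapply(obj$levels, function(lv) {
    list(
      feature_names = as.character(unlist(lv$features)),
      n_features = as.integer(lv$n_features),
      params = hyperParams(lv$params$nu, lv$params$C, lv$params$log10_gamma_scale),
      gamma = lv$params$gamma,
      trial_id = as.integer(lv$trial_id),
      cv_mae = lv$cv_mae, cv_mae_se = lv$cv_mae_se, sv_ratio = lv$sv_ratio,
      train_mae = lv$train_mae, test_mae = lv$test_mae,
      train_r2 = lv$train_r2, test_r2 = lv$test_r2,
      importances = unlist(lv$importances),
      removed_feature = if (is.null(lv$removed_feature)) NA_character_ else lv$removed_feature
    )
  })
  structure(
    list(
      run_id = obj$run_id, split_seed = obj$split_seed,
      feature_set = obj$feature_set, candidates = candidates
    ),
    class = "pruningTrace"
  )
}

#' Read an emitted feature table back into a DescriptorTable
#'
#' @param path a CSV written by [writeFeatureTables()] (or the synthetic
#'   exporter): record-key columns, descriptor columns, and a \code{log_x}
#'   target column.
#' @param manifest_path optional \code{feature_manifest.json} supplying the
#'   set tags; without it every present descriptor column is tagged
#'   \code{"set1"}.
#' @return A [DescriptorTable-class].
#' @export
readFeatureTable <- function(path, manifest_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"log_x" %in% colnames(df)) stop(path, " lacks the 'log_x' target column")
  key_cols <- intersect(
    c("record_id", "solute_id", "components", "mole_fractions", "T_K"),
    colnames(df)
  )
  feat_cols <- setdiff(colnames(df), c(key_cols, "log_x"))
  tags <- rep("set1", length(feat_cols))
  if (!is.null(manifest_path)) {
    man <- jsonlite::fromJSON(manifest_path)
    tags <- vapply(feat_cols, function(cn) {
      tg <- man$set_tag[[cn]]
      if (is.null(tg)) "set1" else tg
    }, character(1L))
  }
  DescriptorTable(
    features = df[, feat_cols, drop = FALSE],
    target = df$log_x,
    records = df[, key_cols, drop = FALSE],
    setTag = unname(tags)
  )
}

#' Basin table of a stability report
#'
#' The per-descriptor-count summary behind the stability plot: frequency
#' across runs and mean +- sd test MAE.
#'
#' @param report a \code{"stabilityReport"}.
#' @return data.frame with columns count, frequency, n_runs_at,
#'   mean_test_mae, sd_test_mae, mean_train_mae, mean_test_r2.
#' @export
basinTable <- function(report) {
  stopifnot(inherits(report, "stabilityReport"))
  report$counts
}

#' Write stability-report artifacts
#'
#' Emits \code{stability_report.json} and the basin-plot CSV
#' (\code{basins.csv}) into \code{dir}.
#'
#' @param report a \code{"stabilityReport"}.
#' @param dir output directory (created if absent).
#' @return Invisibly, \code{dir}.
#' @export
writeStabilityReport <- function(report, dir) {
  stopifnot(inherits(report, "stabilityReport"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  obj <- list(
    n_runs = report$n_runs,
    counts = report$counts,
    descriptor_freq = report$descriptor_freq
  )
  jsonlite::write_json(
    obj, file.path(dir, "stability_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  utils::write.csv(
    basinTable(report), file.path(dir, "basins.csv"),
    row.names = FALSE
  )
  invisible(dir)
}

#' Write the final-model card
#'
#' @param final a \code{"finalModel"} from [finalSelection()].
#' @param path output JSON path.
#' @return Invisibly, \code{path}.
#' @export
writeFinalModel <- function(final, path) {
  stopifnot(inherits(final, "finalModel"))
  obj <- list(
    candidate = candidateToList(final$candidate),
    composite = final$composite,
    descriptor_stability = final$stability,
    provenance = as.list(final$provenance),
    selected_counts = final$counts
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
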