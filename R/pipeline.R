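## End-to-end orchestration: many independent DOO-IT runs, stability
## aggregation, and final multi-criteria selection, all derived from one
## master seed.

#' Run the full DOO-IT pipeline
#'
#' Executes \code{config$n_runs} independent [dooitRun()]s, each on its own
#' 80/20 split (split seeds derived deterministically from the master seed),
#' aggregates the traces with [aggregateRuns()], and selects the final model
#' with [finalSelection()].
#'
#' @param table a [DescriptorTable-class].
#' @param config a [dooitConfig()].
#' @param features optional explicit starting feature vector (otherwise
#'   chosen by \code{config$feature_set}).
#' @param verbose print one progress line per run.
#' @return Object of class \code{"dooitResult"}: list with \code{traces},
#'   \code{report}, \code{final}, and \code{config}.
#' @export
dooitPipeline <- function(table, config = dooitConfig(), features = NULL,
                          verbose = FALSE) {
  stopifnot(is(table, "DescriptorTable"), inherits(config, "dooitConfig"))
  traces <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    split_seed <- deriveSeed(config$master_seed, 17L, r)
    traces[[r]] <- dooitRun(
      table, split_seed,
      config = config, features = features, run_id = r
    )
    if (verbose) {
      best <- min(vapply(traces[[r]]$candidates, `[[`, numeric(1L), "test_mae"))
      message(sprintf(
        "run %d/%d (split seed %d): best test MAE %.4f",
        r, config$n_runs, split_seed, best
      ))
    }
  }
  report <- aggregateRuns(traces)
  final <- finalSelection(
    report, traces,
    freq_threshold = config$freq_threshold, weights = config$weights
  )
  structure(
    list(traces = traces, report = report, final = final, config = config),
    class = "dooitResult"
  )
}

#' @export
print.dooitResult <- function(x, ...) {
  cat(sprintf(
    "dooitResult: %d runs x %d trials on feature set %s (master seed %d)\n",
    x$config$n_runs, x$config$n_trials, x$config$feature_set,
    x$config$master_seed
  ))
  cat(sprintf(
    "  stable descriptor counts: %s\n",
    paste(x$final$counts, collapse = ", ")
  ))
  print(x$final)
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Emits per-run trace JSONs (\code{trace_run_<r>.json}),
#' \code{stability_report.json}, \code{basins.csv},
#' \code{final_model.json}, and the resolved configuration
#' (\code{config.json}).
#'
#' @param result a \code{"dooitResult"}.
#' @param dir output directory (created if absent).
#' @return Invisibly, \code{dir}.
#' @export
writeResultArtifacts <- function(result, dir) {
  stopifnot(inherits(result, "dooitResult"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tr in result$traces) {
    writeTrace(tr, file.path(dir, sprintf("trace_run_%03d.json", tr$run_id)))
  }
  writeStabilityReport(result$report, dir)
  writeFinalModel(result$final, file.path(dir, "final_model.json"))
  jsonlite::write_json(
    unclass(result$config), file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Reproduce the published full-protocol analysis from user-supplied data
#'
#' Runs the complete protocol (by default 50 independent splits with 2000
#' trials per pruning level, global standardization as in the published
#' preprocessing) on the study's appendix tables, which the user must supply
#' as the four CSVs of the input schema (see [readers]) in \code{data_dir}:
#' \code{solubility.csv}, \code{species_energetics.csv},
#' \code{sigma_potentials.csv}, and optionally \code{fusion.csv}. This is a
#' multi-hour computation at full protocol scale.
#'
#' @param data_dir directory containing the input CSVs.
#' @param feature_set \code{"set1"} or \code{"set2"}.
#' @param config a [dooitConfig()]; defaults to the full protocol on the
#'   chosen feature set.
#' @param out_dir optional directory for [writeResultArtifacts()].
#' @return The \code{"dooitResult"}.
#' @export
reproducePublishedProtocol <- function(data_dir,
                                       feature_set = c("set2", "set1"),
                                       config = NULL,
                                       out_dir = NULL) {
  feature_set <- match.arg(feature_set)
  paths <- file.path(data_dir, c(
    "solubility.csv", "species_energetics.csv", "sigma_potentials.csv"
  ))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop(
      "input table(s) not found: ", paste(missing, collapse = ", "),
      "\nSupply the study's appendix data in the documented CSV schema."
    )
  }
  table <- assembleFeatureSets(
    readSolubilityTable(paths[1L]),
    readSpeciesEnergetics(paths[2L]),
    readSigmaPotentials(paths[3L])
  )
  if (is.null(config)) {
    config <- dooitConfig(
      feature_set = feature_set, standardization = "global"
    )
  }
  result <- dooitPipeline(table, config, verbose = TRUE)
  if (!is.null(out_dir)) writeResultArtifacts(result, out_dir)
  result
}
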