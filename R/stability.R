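## Cross-run stability analysis and multi-criteria final selection: aggregate
## many independent pruning traces, find architecturally stable descriptor
## counts, score finalists with the 50/30/20 composite, and emit one model.

traceCandidateAt <- function(trace, count) {
  counts <- vapply(trace$candidates, `[[`, integer(1L), "n_features")
  hit <- which(counts == count)
  if (length(hit)) trace$candidates[[hit[1L]]] else NULL
}

#' Aggregate pruning traces across independent runs
#'
#' For every descriptor count observed in any trace, computes the fraction
#' of runs producing a candidate at that count (runs whose trace misses the
#' count enter the denominator only), the mean and standard deviation of the
#' test MAE, the mean train MAE, and the per-descriptor occurrence
#' frequencies among the runs at that count.
#'
#' @param traces list of \code{"pruningTrace"} objects (>= 2 runs).
#' @return Object of class \code{"stabilityReport"}: list with
#'   \code{n_runs}, \code{counts} (data.frame: count, frequency, n_runs_at,
#'   mean_test_mae, sd_test_mae, mean_train_mae, mean_test_r2), and
#'   \code{descriptor_freq} (per count, named occurrence-frequency vector).
#' @export
aggregateRuns <- function(traces) {
  if (length(traces) < 2L) stop("stability aggregation needs >= 2 runs")
  stopifnot(all(vapply(traces, inherits, logical(1L), "pruningTrace")))
  n_runs <- length(traces)
  all_counts <- sort(unique(unlist(lapply(
    traces,
    function(tr) vapply(tr$candidates, `[[`, integer(1L), "n_features")
  ))), decreasing = TRUE)
  rows <- list()
  dfreq <- list()
  for (cnt in all_counts) {
    cands <- Filter(Negate(is.null), lapply(traces, traceCandidateAt, count = cnt))
    tmae <- vapply(cands, `[[`, numeric(1L), "test_mae")
    rows[[as.character(cnt)]] <- data.frame(
      count = cnt,
      frequency = length(cands) / n_runs,
      n_runs_at = length(cands),
      mean_test_mae = mean(tmae),
      sd_test_mae = if (length(tmae) > 1L) stats::sd(tmae) else 0,
      mean_train_mae = mean(vapply(cands, `[[`, numeric(1L), "train_mae")),
      mean_test_r2 = mean(vapply(cands, `[[`, numeric(1L), "test_r2"))
    )
    feats <- unlist(lapply(cands, `[[`, "feature_names"))
    dfreq[[as.character(cnt)]] <- table(feats) / length(cands)
  }
  structure(
    list(
      n_runs = n_runs,
      counts = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      descriptor_freq = lapply(dfreq, function(t) {
        stats::setNames(as.numeric(t), names(t))
      })
    ),
    class = "stabilityReport"
  )
}

#' @export
print.stabilityReport <- function(x, ...) {
  cat(sprintf("stabilityReport over %d runs\n", x$n_runs))
  df <- x$counts
  cat(sprintf(
    "  %2d descriptors: freq %.2f, test MAE %.4f +- %.4f\n",
    df$count, df$frequency, df$mean_test_mae, df$sd_test_mae
  ), sep = "")
  invisible(x)
}

#' Architecturally stable descriptor counts
#'
#' Applies the stability-enhanced one-standard-error rule at the
#' architecture level: a descriptor count qualifies when it appears in at
#' least \code{freq_threshold} of the runs and its mean test MAE is within
#' one standard error of the best qualifying count (SE computed as
#' \code{sd / sqrt(n_runs_at)} at the minimizing count). If no count clears
#' the frequency bar, falls back (with a warning) to the count with the
#' globally minimal mean test MAE.
#'
#' @param report a \code{"stabilityReport"}.
#' @param freq_threshold minimum frequency (default 0.30).
#' @return Integer vector of selected descriptor counts.
#' @export
architecturalSelection <- function(report, freq_threshold = 0.30) {
  stopifnot(inherits(report, "stabilityReport"))
  df <- report$counts
  qual <- df[df$frequency >= freq_threshold, , drop = FALSE]
  if (nrow(qual) == 0L) {
    warning("no descriptor count reaches the frequency threshold; ",
            "falling back to the count with minimal mean test MAE")
    return(df$count[which.min(df$mean_test_mae)])
  }
  best <- which.min(qual$mean_test_mae)
  se <- qual$sd_test_mae[best] / sqrt(qual$n_runs_at[best])
  threshold <- qual$mean_test_mae[best] + se
  sort(qual$count[qual$mean_test_mae <= threshold])
}

minmaxHigh <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) rep(1, length(v)) else (v - rng[1L]) / diff(rng)
}

#' Composite multi-criteria score of a candidate within a finalist cohort
#'
#' Scores balance predictive accuracy (weight 0.5, via test MAE),
#' explanatory power (weight 0.3, via test R-squared) and generalization
#' (weight 0.2, via the absolute train/test MAE gap). Each component is
#' min-max normalized within the cohort so the best candidate on a raw
#' metric receives 1 and the worst 0; in a single-member cohort (or when a
#' metric does not vary) every component is 1.
#'
#' @param candidate one candidate (a list with \code{test_mae},
#'   \code{train_mae}, \code{test_r2}), usually an element of a pruning
#'   trace.
#' @param cohort list of candidates constituting the comparison cohort
#'   (should include \code{candidate}).
#' @param weights named weights as in [dooitConfig()].
#' @return List of class \code{"compositeScore"} with
#'   \code{accuracy_component}, \code{r2_component},
#'   \code{generalization_component} and \code{total}, all in [0, 1].
#' @export
compositeScore <- function(candidate, cohort,
                           weights = c(accuracy = 0.5, r2 = 0.3, generalization = 0.2)) {
  if (length(cohort) < 1L) stop("cohort must contain at least one candidate")
  scores <- compositeScores(cohort, weights)
  ## locate the candidate inside its cohort by metric identity
  idx <- which(
    vapply(cohort, `[[`, numeric(1L), "test_mae") == candidate$test_mae &
      vapply(cohort, `[[`, numeric(1L), "test_r2") == candidate$test_r2 &
      vapply(cohort, `[[`, numeric(1L), "train_mae") == candidate$train_mae
  )
  if (!length(idx)) stop("'candidate' is not a member of 'cohort'")
  structure(
    as.list(scores[idx[1L], c(
      "accuracy_component", "r2_component", "generalization_component", "total"
    )]),
    class = "compositeScore"
  )
}

## Vectorized composite scoring of a whole cohort.
compositeScores <- function(cohort,
                            weights = c(accuracy = 0.5, r2 = 0.3, generalization = 0.2)) {
  test_mae <- vapply(cohort, `[[`, numeric(1L), "test_mae")
  train_mae <- vapply(cohort, `[[`, numeric(1L), "train_mae")
  test_r2 <- vapply(cohort, `[[`, numeric(1L), "test_r2")
  if (any(!is.finite(c(test_mae, train_mae, test_r2)))) {
    stop("composite scoring requires finite metrics")
  }
  acc <- minmaxHigh(-test_mae)
  r2c <- minmaxHigh(test_r2)
  gen <- minmaxHigh(-abs(test_mae - train_mae))
  data.frame(
    accuracy_component = acc,
    r2_component = r2c,
    generalization_component = gen,
    total = weights[["accuracy"]] * acc + weights[["r2"]] * r2c +
      weights[["generalization"]] * gen
  )
}

#' Final model selection across stable architectures
#'
#' Collects every run's candidate at the architecturally selected descriptor
#' counts, scores the cohort with the composite criterion, and returns the
#' top-scoring candidate; near-ties (total within 0.01 of the leader) are
#' broken in favour of the candidate whose descriptors occur most
#' consistently across runs (highest mean per-descriptor occurrence
#' frequency at its count).
#'
#' @param report a \code{"stabilityReport"} from [aggregateRuns()].
#' @param traces the list of \code{"pruningTrace"} objects behind the report.
#' @param freq_threshold frequency threshold for [architecturalSelection()].
#' @param weights composite weights.
#' @return List of class \code{"finalModel"}: the chosen \code{candidate},
#'   its \code{composite} breakdown, \code{stability} (mean descriptor
#'   frequency), \code{provenance} (run_id, split_seed, n_features), the
#'   selected \code{counts}, and the scored \code{cohort} data.frame.
#' @export
finalSelection <- function(report, traces,
                           freq_threshold = 0.30,
                           weights = c(accuracy = 0.5, r2 = 0.3, generalization = 0.2)) {
  counts <- architecturalSelection(report, freq_threshold)
  cohort <- list()
  meta <- list()
  for (tr in traces) {
    for (cnt in counts) {
      cand <- traceCandidateAt(tr, cnt)
      if (is.null(cand)) next
      cohort[[length(cohort) + 1L]] <- cand
      meta[[length(meta) + 1L]] <- data.frame(
        run_id = tr$run_id, split_seed = tr$split_seed, n_features = cnt
      )
    }
  }
  if (!length(cohort)) stop("no candidates at the selected descriptor counts")
  scores <- compositeScores(cohort, weights)
  stab <- vapply(seq_along(cohort), function(i) {
    freqs <- report$descriptor_freq[[as.character(meta[[i]]$n_features)]]
    mean(freqs[cohort[[i]]$feature_names])
  }, numeric(1L))
  top <- max(scores$total)
  near <- which(scores$total > top - 0.01)
  pick <- near[order(-stab[near], -scores$total[near])][1L]
  cohort_df <- cbind(do.call(rbind, meta), scores, descriptor_stability = stab)
  structure(
    list(
      candidate = cohort[[pick]],
      composite = as.list(scores[pick, ]),
      stability = stab[pick],
      provenance = meta[[pick]],
      counts = counts,
      cohort = cohort_df
    ),
    class = "finalModel"
  )
}

#' @export
print.finalModel <- function(x, ...) {
  cand <- x$candidate
  cat(sprintf(
    "finalModel: %d descriptors (run %s, split seed %d)\n",
    cand$n_features, x$provenance$run_id, x$provenance$split_seed
  ))
  cat("  descriptors:", paste(cand$feature_names, collapse = ", "), "\n")
  cat(sprintf(
    "  nu %.4f | C %.3f | log10_gamma_scale %.4f\n",
    cand$params$nu, cand$params$C, cand$params$log10_gamma_scale
  ))
  cat(sprintf(
    "  test MAE %.4f | test R2 %.4f | composite %.3f (stability %.3f)\n",
    cand$test_mae, cand$test_r2, x$composite$total, x$stability
  ))
  invisible(x)
}
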