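## Iterative model refinement: 1-SE candidate selection on the Pareto front,
## permutation-importance feature ranking, and the backward pruning loop that
## turns one train/test split into a full complexity trace.

#' Select a candidate from a Pareto front by the one-standard-error rule
#'
#' Identifies the most accurate front member (minimal cv_mae; ties broken by
#' lower trial id), computes the standard error of its per-fold MAEs
#' (\code{sd / sqrt(k)}), and among front members within
#' \code{best cv_mae + SE} returns the most parsimonious one (lowest
#' sv_ratio; ties broken by lower cv_mae, then lower trial id).
#'
#' @param front a \code{"dooTrials"} object, typically from [paretoFront()].
#' @return List of class \code{"selectedTrial"}: \code{trial_id},
#'   \code{params} ([hyperParams()]), \code{gamma}, \code{cv_mae},
#'   \code{cv_mae_se} (SE of the selected trial's own fold MAEs),
#'   \code{sv_ratio}, \code{fold_maes}, \code{threshold} (best + SE) and
#'   \code{best_trial_id}.
#' @export
select1SE <- function(front) {
  stopifnot(inherits(front, "dooTrials"))
  tab <- front$table
  ok <- which(tab$status == "ok")
  if (!length(ok)) stop("front contains no successful trials")
  best <- ok[order(tab$cv_mae[ok], tab$trial_id[ok])][1L]
  k <- ncol(front$fold_maes)
  se <- stats::sd(front$fold_maes[best, ]) / sqrt(k)
  threshold <- tab$cv_mae[best] + se
  elig <- ok[tab$cv_mae[ok] <= threshold]
  pick <- elig[order(tab$sv_ratio[elig], tab$cv_mae[elig], tab$trial_id[elig])][1L]
  structure(
    list(
      trial_id = tab$trial_id[pick],
      params = hyperParams(tab$nu[pick], tab$C[pick], tab$log10_gamma_scale[pick]),
      gamma = tab$gamma[pick],
      cv_mae = tab$cv_mae[pick],
      cv_mae_se = stats::sd(front$fold_maes[pick, ]) / sqrt(k),
      sv_ratio = tab$sv_ratio[pick],
      fold_maes = front$fold_maes[pick, ],
      threshold = threshold,
      best_trial_id = tab$trial_id[best]
    ),
    class = "selectedTrial"
  )
}

#' Permutation importance of each feature
#'
#' For each feature column, measures the mean increase in validation MAE
#' when that column is randomly permuted, over \code{n_repeats} seeded
#' permutations (one permutation per repeat, shared across features). A
#' feature the predictor ignores has importance exactly 0.
#'
#' @param model a fitted predictor usable with \code{predict(model, x)}, or
#'   a function \code{f(x)} returning predictions.
#' @param x validation feature matrix (>= 2 rows), on the scale the
#'   predictor expects.
#' @param y validation response.
#' @param n_repeats number of permutation repeats (default 10).
#' @param seed seed for the permutation draws.
#' @return Named numeric vector of mean MAE increases, one per column of
#'   \code{x}.
#' @export
permutationImportance <- function(model, x, y, n_repeats = 10L, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("permutation importance needs >= 2 validation rows")
  predfun <- if (is.function(model)) model else function(z) stats::predict(model, z)
  baseline <- maeOf(y, predfun(x))
  p <- ncol(x)
  perms <- withSeed(seed, replicate(n_repeats, sample.int(nrow(x)), simplify = FALSE))
  imp <- matrix(0, n_repeats, p)
  for (r in seq_len(n_repeats)) {
    prm <- perms[[r]]
    for (j in seq_len(p)) {
      xp <- x
      xp[, j] <- x[prm, j]
      imp[r, j] <- maeOf(y, predfun(xp)) - baseline
    }
  }
  stats::setNames(colMeans(imp), colnames(x))
}

## Refit a selected trial on given rows and score it elsewhere.
refitAndScore <- function(x, y, fit_idx, eval_idx, params, gamma) {
  std <- standardizeFeatures(
    x[fit_idx, , drop = FALSE],
    x[eval_idx, , drop = FALSE]
  )
  m <- fitNuSVR(std$train, y[fit_idx], params$nu, params$C, gamma)
  if (is.null(m)) stop("refit of the selected model failed to converge")
  list(
    model = m, std = std,
    fit_pred = stats::predict(m, std$train),
    eval_pred = stats::predict(m, std$other)
  )
}

#' One DOO-IT run: backward pruning over a single train/test split
#'
#' Starting from the complete descriptor set, repeats until
#' \code{min_features} remain: run the dual-objective search on the current
#' features ([runDoo()]), extract the Pareto front, select one candidate by
#' the 1-SE rule, refit it on the full training split to obtain train/test
#' metrics, rank its features by permutation importance on a seeded 20%
#' carve-out of the training split (the importance model is fitted on the
#' remaining 80% so the carve-out acts as validation data; the held-out test
#' set is never touched before final metrics), and drop the least important
#' feature.
#'
#' @param table a [DescriptorTable-class].
#' @param split_seed integer seed for this run's 80/20 split; all per-level
#'   seeds derive from it.
#' @param config a [dooitConfig()].
#' @param features optional explicit starting feature vector; defaults to
#'   the columns selected by \code{config$feature_set}.
#' @param run_id identifier stored in the trace.
#' @return Object of class \code{"pruningTrace"}: list with \code{run_id},
#'   \code{split_seed}, \code{feature_set}, and \code{candidates} — one
#'   candidate per complexity level from the full set down to
#'   \code{min_features}, each a list with \code{feature_names},
#'   \code{n_features}, \code{params}, \code{gamma}, \code{trial_id},
#'   \code{cv_mae}, \code{cv_mae_se}, \code{sv_ratio}, \code{train_mae},
#'   \code{test_mae}, \code{train_r2}, \code{test_r2}, \code{importances},
#'   and \code{removed_feature} (NA at the last level).
#' @export
dooitRun <- function(table, split_seed, config = dooitConfig(),
                     features = NULL, run_id = 1L) {
  stopifnot(is(table, "DescriptorTable"), inherits(config, "dooitConfig"))
  if (is.null(features)) {
    features <- switch(config$feature_set,
      set1 = featureNames(table, "set1"),
      featureNames(table, "set2")
    )
  }
  if (length(features) <= config$min_features) {
    stop("need more than 'min_features' starting descriptors")
  }
  x <- featureMatrix(table)[, features, drop = FALSE]
  y <- targetValues(table)
  split <- makeSplit(nrow(x), split_seed, config$train_fraction)
  tr <- split$train

  ## seeded 20% carve-out of the training split for importance validation
  n_val <- max(2L, as.integer(round(0.2 * length(tr))))
  val_idx <- withSeed(
    deriveSeed(split_seed, 7L, 1L),
    sort(sample(tr, n_val))
  )
  fit_idx <- setdiff(tr, val_idx)

  current <- features
  candidates <- list()
  it <- 0L
  while (length(current) >= config$min_features) {
    it <- it + 1L
    cand <- tryCatch(
      {
        lseed <- deriveSeed(split_seed, 11L, it)
        trials <- runDoo(
          x[tr, current, drop = FALSE], y[tr],
          n_trials = config$n_trials, seed = lseed, folds = config$folds,
          standardization = config$standardization,
          nu_range = config$nu_range, C_range = config$C_range,
          log10_gamma_scale_range = config$log10_gamma_scale_range
        )
        sel <- select1SE(paretoFront(trials))

        ## test metrics: refit on the full training split
        fin <- refitAndScore(
          x[, current, drop = FALSE], y, tr, split$test,
          sel$params, sel$gamma
        )
        ## importance: fit without the carve-out, validate on it
        impfit <- refitAndScore(
          x[, current, drop = FALSE], y, fit_idx, val_idx,
          sel$params, sel$gamma
        )
        imp <- permutationImportance(
          impfit$model, impfit$std$other, y[val_idx],
          n_repeats = config$perm_repeats,
          seed = deriveSeed(split_seed, 13L, it)
        )
        list(
          feature_names = current,
          n_features = length(current),
          params = sel$params,
          gamma = sel$gamma,
          trial_id = sel$trial_id,
          cv_mae = sel$cv_mae,
          cv_mae_se = sel$cv_mae_se,
          sv_ratio = sel$sv_ratio,
          train_mae = maeOf(y[tr], fin$fit_pred),
          test_mae = maeOf(y[split$test], fin$eval_pred),
          train_r2 = r2Of(y[tr], fin$fit_pred),
          test_r2 = r2Of(y[split$test], fin$eval_pred),
          importances = imp,
          removed_feature = NA_character_
        )
      },
      error = function(e) {
        stop(sprintf(
          "pruning iteration %d (%d features): %s",
          it, length(current), conditionMessage(e)
        ), call. = FALSE)
      }
    )
    if (length(current) > config$min_features) {
      drop_j <- which.min(cand$importances) # ties: first in feature order
      cand$removed_feature <- current[drop_j]
      current <- current[-drop_j]
    } else {
      current <- character()
    }
    candidates[[length(candidates) + 1L]] <- cand
  }
  structure(
    list(
      run_id = run_id, split_seed = split_seed,
      feature_set = config$feature_set, candidates = candidates
    ),
    class = "pruningTrace"
  )
}

#' @export
print.pruningTrace <- function(x, ...) {
  counts <- vapply(x$candidates, `[[`, integer(1L), "n_features")
  tmae <- vapply(x$candidates, `[[`, numeric(1L), "test_mae")
  cat(sprintf(
    "pruningTrace (run %s, split seed %d): levels %d..%d descriptors\n",
    x$run_id, x$split_seed, max(counts), min(counts)
  ))
  cat(sprintf(
    "  test MAE: %.4f (full) -> %.4f (best: %.4f at %d descriptors)\n",
    tmae[1L], tmae[length(tmae)], min(tmae), counts[which.min(tmae)]
  ))
  invisible(x)
}
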