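#' Configuration for the DOO-IT pipeline
#'
#' Collects every tunable of the workflow with the protocol defaults:
#' 50 independent train/test splits, 2000 dual-objective trials per pruning
#' level, 5-fold cross-validation, pruning down to 3 descriptors,
#' permutation importance with 10 repeats, a 30% frequency threshold for
#' architectural stability, and 50/30/20 composite weights.
#'
#' @param feature_set which descriptor set to model: \code{"set1"},
#'   \code{"set2"}, or \code{"custom"} (use the columns of the supplied
#'   table as-is).
#' @param n_runs number of independent DOO-IT runs (train/test splits).
#' @param n_trials number of hyperparameter trials per dual-objective search.
#' @param folds number of cross-validation folds.
#' @param min_features pruning stops when this many descriptors remain.
#' @param perm_repeats permutation-importance repeats.
#' @param freq_threshold minimum per-descriptor-count frequency across runs
#'   for architectural selection, in (0, 1].
#' @param weights composite-score weights, named
#'   \code{c(accuracy=, r2=, generalization=)}, summing to 1.
#' @param train_fraction fraction of records in the training split.
#' @param standardization \code{"fold"} to refit the standardizer inside each
#'   CV fold (leakage-free default) or \code{"global"} to fit it once on the
#'   whole training split, as in the published protocol.
#' @param nu_range,C_range,log10_gamma_scale_range hyperparameter search
#'   bounds; \code{C} is sampled log-uniformly, the others uniformly. The
#'   defaults bracket the published optima (nu about 0.25, C about 34-57,
#'   scale about 0.45-0.94).
#' @param master_seed integer master seed; every random draw in the pipeline
#'   is derived from it.
#' @return A validated list of class \code{"dooitConfig"}.
#' @export
dooitConfig <- function(feature_set = "set2",
                        n_runs = 50L,
                        n_trials = 2000L,
                        folds = 5L,
                        min_features = 3L,
                        perm_repeats = 10L,
                        freq_threshold = 0.30,
                        weights = c(accuracy = 0.5, r2 = 0.3, generalization = 0.2),
                        train_fraction = 0.8,
                        standardization = c("fold", "global"),
                        nu_range = c(0.05, 0.95),
                        C_range = c(1e-2, 1e3),
                        log10_gamma_scale_range = c(-2, 2),
                        master_seed = 1L) {
  standardization <- match.arg(standardization)
  feature_set <- match.arg(feature_set, c("set1", "set2", "custom"))
  cfg <- list(
    feature_set = feature_set,
    n_runs = as.integer(n_runs),
    n_trials = as.integer(n_trials),
    folds = as.integer(folds),
    min_features = as.integer(min_features),
    perm_repeats = as.integer(perm_repeats),
    freq_threshold = freq_threshold,
    weights = weights,
    train_fraction = train_fraction,
    standardization = standardization,
    nu_range = nu_range,
    C_range = C_range,
    log10_gamma_scale_range = log10_gamma_scale_range,
    master_seed = as.integer(master_seed)
  )
  counts <- c(cfg$n_runs, cfg$n_trials, cfg$folds, cfg$min_features, cfg$perm_repeats)
  if (any(counts < 1L)) stop("all count parameters must be >= 1")
  if (cfg$folds < 2L) stop("'folds' must be >= 2")
  if (cfg$freq_threshold <= 0 || cfg$freq_threshold > 1) {
    stop("'freq_threshold' must lie in (0, 1]")
  }
  if (!setequal(names(cfg$weights), c("accuracy", "r2", "generalization")) ||
      abs(sum(cfg$weights) - 1) > 1e-9) {
    stop("'weights' must be named accuracy/r2/generalization and sum to 1")
  }
  cfg$weights <- cfg$weights[c("accuracy", "r2", "generalization")]
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1) {
    stop("'train_fraction' must lie in (0, 1)")
  }
  if (cfg$nu_range[1L] <= 0 || cfg$nu_range[2L] > 1 || diff(cfg$nu_range) < 0) {
    stop("'nu_range' must be an increasing interval within (0, 1]")
  }
  if (cfg$C_range[1L] <= 0 || diff(cfg$C_range) < 0) {
    stop("'C_range' must be an increasing positive interval")
  }
  structure(cfg, class = "dooitConfig")
}

#' @export
print.dooitConfig <- function(x, ...) {
  cat("DOO-IT configuration\n")
  cat(sprintf(
    "  feature set %s | %d runs x %d trials | %d-fold CV | prune to %d\n",
    x$feature_set, x$n_runs, x$n_trials, x$folds, x$min_features
  ))
  cat(sprintf(
    "  perm repeats %d | freq threshold %.2f | weights %.2f/%.2f/%.2f | seed %d\n",
    x$perm_repeats, x$freq_threshold,
    x$weights[["accuracy"]], x$weights[["r2"]], x$weights[["generalization"]],
    x$master_seed
  ))
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [dooitConfig()]; absent keys keep their
#' defaults. \code{weights} may be a mapping with keys
#' \code{accuracy}/\code{r2}/\code{generalization}.
#'
#' @param path path to a YAML file.
#' @return A \code{"dooitConfig"} object.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(dooitConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$weights)) raw$weights <- unlist(raw$weights)
  for (k in c("nu_range", "C_range", "log10_gamma_scale_range")) {
    if (!is.null(raw[[k]])) raw[[k]] <- as.numeric(unlist(raw[[k]]))
  }
  do.call(dooitConfig, raw)
}

## --- seeding ------------------------------------------------------------

## Lehmer-style integer mixing on the 2^31 - 1 field; products stay below
## 2^53 so double arithmetic is exact. Two rounds decorrelate neighbouring
## master seeds.
MERSENNE31 <- 2147483647

#' Derive a stream seed from the master seed
#'
#' All randomness in the pipeline (splits, fold assignment, trial sampling,
#' permutation importance, synthetic data) flows from one master seed via
#' this deterministic integer hash, so that runs, levels and repeats draw
#' from decorrelated, reproducible streams with no hidden global state.
#'
#' @param master integer master seed.
#' @param ... one or more small non-negative integers identifying the stream
#'   (e.g. run index, pruning level, purpose code).
#' @return A single integer in \code{[1, 2^31 - 2]}.
#' @export
deriveSeed <- function(master, ...) {
  x <- (abs(as.numeric(master)) %% (MERSENNE31 - 1)) + 1
  for (k in c(...)) {
    x <- (x * 48271) %% MERSENNE31
    x <- (x + as.numeric(k) * 16807 + 1) %% MERSENNE31
    x <- (x * 69621) %% MERSENNE31
    if (x == 0) x <- 1
  }
  as.integer(x)
}

## Evaluate an expression under a local RNG seed, restoring the caller's
## RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
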