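## Dual-objective nu-SVR core: train/test splitting, standardization, the
## median-distance gamma anchor, cross-validated trial evaluation, the
## seeded random hyperparameter search, and Pareto-front extraction.

maeOf <- function(obs, pred) mean(abs(obs - pred))
r2Of <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)

#' Reproducible 80/20 train/test split
#'
#' @param n_records number of records (>= 10).
#' @param seed integer seed; the same seed always yields the same split.
#' @param train_fraction fraction assigned to training (default 0.8); the
#'   training size is \code{round(train_fraction * n_records)}.
#' @return List of class \code{"splitSpec"} with integer \code{train} and
#'   \code{test} index vectors (disjoint, covering \code{1:n_records}) and
#'   the \code{seed}.
#' @export
makeSplit <- function(n_records, seed, train_fraction = 0.8) {
  if (n_records < 10L) stop("need at least 10 records to split")
  n_train <- as.integer(round(train_fraction * n_records))
  train <- withSeed(seed, sort(sample.int(n_records, n_train)))
  structure(
    list(train = train, test = setdiff(seq_len(n_records), train), seed = seed),
    class = "splitSpec"
  )
}

#' Standardize features on training statistics
#'
#' Centers and scales every column to zero mean and unit variance using
#' statistics of the training matrix only; the identical affine map is then
#' applied to \code{other} (e.g. the held-out test set). Columns constant in
#' the training data carry no information at unit scale and are dropped with
#' a warning.
#'
#' @param train numeric matrix of training features.
#' @param other optional matrix with the same columns to transform with the
#'   training map.
#' @return List with \code{train}, \code{other} (or NULL), \code{center},
#'   \code{scale}, and \code{dropped} (names of constant columns removed).
#' @export
standardizeFeatures <- function(train, other = NULL) {
  train <- as.matrix(train)
  center <- colMeans(train)
  scale_ <- apply(train, 2L, stats::sd)
  const <- !is.finite(scale_) | scale_ == 0
  if (all(const)) stop("every feature column is constant in the training data")
  if (any(const)) {
    warning(
      "dropping constant training column(s): ",
      paste(colnames(train)[const], collapse = ", ")
    )
    train <- train[, !const, drop = FALSE]
    if (!is.null(other)) other <- as.matrix(other)[, !const, drop = FALSE]
    center <- center[!const]
    scale_ <- scale_[!const]
  }
  tr <- sweep(sweep(train, 2L, center, "-"), 2L, scale_, "/")
  ot <- if (is.null(other)) {
    NULL
  } else {
    sweep(sweep(as.matrix(other), 2L, center, "-"), 2L, scale_, "/")
  }
  list(
    train = tr, other = ot, center = center, scale = scale_,
    dropped = colnames(as.matrix(train))[const]
  )
}

applyStandardizer <- function(x, center, scale_) {
  sweep(sweep(as.matrix(x), 2L, center, "-"), 2L, scale_, "/")
}

#' RBF bandwidth anchor from the median pairwise squared distance
#'
#' The search for the kernel coefficient gamma is anchored at
#' \code{gamma_base = 1 / median(||x_i - x_j||^2)} over all training pairs
#' (the median heuristic); the optimizer then explores a logarithmic scaling
#' factor around this anchor. For more than \code{cap} rows a seeded
#' subsample of \code{cap} rows bounds the quadratic pair enumeration.
#'
#' @param x numeric matrix of (standardized) training features, >= 2 rows.
#' @param cap subsampling cap on the number of rows (default 2000).
#' @param seed seed for the subsample draw.
#' @return Positive scalar \code{1 / median squared distance}.
#' @export
gammaBase <- function(x, cap = 2000L, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows for pairwise distances")
  if (nrow(x) > cap) {
    keep <- withSeed(seed, sample.int(nrow(x), cap))
    x <- x[keep, , drop = FALSE]
  }
  med <- stats::median(stats::dist(x)^2)
  if (med <= 0) stop("median pairwise distance is zero (duplicate-only data)")
  1 / med
}

#' Hyperparameter triple for one nu-SVR trial
#'
#' @param nu nu parameter in (0, 1]: lower bound on the support-vector
#'   fraction, upper bound on the margin-error fraction.
#' @param C regularization parameter, > 0.
#' @param log10_gamma_scale logarithmic scaling factor applied to the
#'   median-heuristic anchor: \code{gamma = gamma_base * 10^log10_gamma_scale}.
#' @return List of class \code{"hyperParams"}.
#' @export
hyperParams <- function(nu, C, log10_gamma_scale) {
  if (!is.finite(nu) || nu <= 0 || nu > 1) stop("'nu' must lie in (0, 1]")
  if (!is.finite(C) || C <= 0) stop("'C' must be > 0")
  if (!is.finite(log10_gamma_scale)) stop("'log10_gamma_scale' must be finite")
  structure(
    list(nu = nu, C = C, log10_gamma_scale = log10_gamma_scale),
    class = "hyperParams"
  )
}

#' @export
predict.dooitConstantFit <- function(object, newdata, ...) {
  rep(object$const, nrow(as.matrix(newdata)))
}

fitNuSVR <- function(x, y, nu, C, gamma) {
  if (diff(range(y)) == 0) {
    ## degenerate constant response: libsvm returns an empty model, but the
    ## analytic limit is an exact constant predictor with the support-vector
    ## fraction pinned at its nu lower bound
    return(structure(
      list(const = y[1L], tot.nSV = max(1L, as.integer(ceiling(nu * length(y))))),
      class = "dooitConstantFit"
    ))
  }
  tryCatch(
    suppressWarnings(e1071::svm(
      x, y,
      scale = FALSE, type = "nu-regression", kernel = "radial",
      nu = nu, cost = C, gamma = gamma
    )),
    error = function(e) NULL
  )
}

## Precompute fold memberships and per-fold standardized matrices once per
## search so that every trial reuses them.
prepFolds <- function(x, y, folds, seed, standardization = "fold") {
  n <- nrow(x)
  if (folds < 2L || folds > n) stop("'folds' must lie in [2, n]")
  assign_ <- withSeed(seed, sample(rep_len(seq_len(folds), n)))
  if (standardization == "global") {
    std <- standardizeFeatures(x)
    xs <- std$train
  }
  lapply(seq_len(folds), function(f) {
    va <- which(assign_ == f)
    tr <- which(assign_ != f)
    if (standardization == "fold") {
      center <- colMeans(x[tr, , drop = FALSE])
      scale_ <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
      scale_[!is.finite(scale_) | scale_ == 0] <- 1 # guard constant fold columns
      list(
        xtr = applyStandardizer(x[tr, , drop = FALSE], center, scale_),
        ytr = y[tr],
        xva = applyStandardizer(x[va, , drop = FALSE], center, scale_),
        yva = y[va]
      )
    } else {
      list(
        xtr = xs[tr, , drop = FALSE], ytr = y[tr],
        xva = xs[va, , drop = FALSE], yva = y[va]
      )
    }
  })
}

evalOnFolds <- function(fold_data, nu, C, gamma) {
  k <- length(fold_data)
  fold_maes <- numeric(k)
  fold_svr <- numeric(k)
  for (f in seq_len(k)) {
    fd <- fold_data[[f]]
    m <- fitNuSVR(fd$xtr, fd$ytr, nu, C, gamma)
    if (is.null(m)) return(NULL)
    fold_maes[f] <- maeOf(fd$yva, stats::predict(m, fd$xva))
    fold_svr[f] <- m$tot.nSV / nrow(fd$xtr)
  }
  list(fold_maes = fold_maes, fold_sv_ratios = fold_svr)
}

#' Evaluate one hyperparameter trial by cross-validation
#'
#' Fits a nu-SVR with RBF kernel on each fold-train portion (with the
#' standardizer refit inside the fold by default), and records the held-fold
#' mean absolute error and the support-vector ratio (support vectors divided
#' by the number of training samples in that fold).
#'
#' @param x numeric feature matrix of the training split (raw scale).
#' @param y numeric response.
#' @param params a [hyperParams()] object.
#' @param folds number of CV folds (default 5).
#' @param seed seed for the fold assignment.
#' @param standardization \code{"fold"} or \code{"global"}.
#' @param gamma_base RBF anchor; computed from the (globally standardized)
#'   training features via [gammaBase()] when NULL.
#' @return List of class \code{"trialResult"}: \code{params},
#'   \code{fold_maes}, \code{fold_sv_ratios}, their means \code{cv_mae} and
#'   \code{sv_ratio}, \code{gamma}, and \code{status} (\code{"ok"} or
#'   \code{"failed"} if the solver did not converge; a failed trial never
#'   raises).
#' @export
evaluateTrial <- function(x, y, params, folds = 5L, seed = 1L,
                          standardization = c("fold", "global"),
                          gamma_base = NULL) {
  standardization <- match.arg(standardization)
  stopifnot(inherits(params, "hyperParams"))
  x <- as.matrix(x)
  if (is.null(gamma_base)) gamma_base <- gammaBase(standardizeFeatures(x)$train)
  fold_data <- prepFolds(x, y, folds, seed, standardization)
  gamma <- gamma_base * 10^params$log10_gamma_scale
  ev <- evalOnFolds(fold_data, params$nu, params$C, gamma)
  if (is.null(ev)) {
    return(structure(
      list(
        params = params, gamma = gamma, fold_maes = NULL,
        fold_sv_ratios = NULL, cv_mae = NA_real_, sv_ratio = NA_real_,
        status = "failed"
      ),
      class = "trialResult"
    ))
  }
  structure(
    list(
      params = params, gamma = gamma,
      fold_maes = ev$fold_maes, fold_sv_ratios = ev$fold_sv_ratios,
      cv_mae = mean(ev$fold_maes), sv_ratio = mean(ev$fold_sv_ratios),
      status = "ok"
    ),
    class = "trialResult"
  )
}

#' Dual-objective nu-SVR hyperparameter search
#'
#' Runs \code{n_trials} seeded trials over (nu, C, log10_gamma_scale),
#' evaluating each by k-fold cross-validation and minimizing the two
#' competing objectives jointly: predictive error (mean CV MAE) and model
#' complexity (mean support-vector ratio). Sampling is a seeded random
#' search over the bounded space (uniform in nu and in the log-gamma scale,
#' log-uniform in C); the whole search is reproducible from \code{seed}.
#' Trials whose solver fails are retained with status \code{"failed"} but
#' never enter the Pareto front.
#'
#' @param x,y training-split features (raw scale) and response.
#' @param n_trials number of trials (protocol default 2000).
#' @param seed integer seed for sampling, fold assignment and the
#'   gamma-anchor subsample.
#' @param folds number of CV folds.
#' @param standardization \code{"fold"} or \code{"global"}.
#' @param nu_range,C_range,log10_gamma_scale_range search bounds as in
#'   [dooitConfig()].
#' @return An object of class \code{"dooTrials"}: list with \code{table}
#'   (data.frame: trial_id, nu, C, log10_gamma_scale, gamma, cv_mae,
#'   sv_ratio, status), matrices \code{fold_maes} and \code{fold_sv_ratios}
#'   (one row per trial), and \code{gamma_base}.
#' @export
runDoo <- function(x, y, n_trials = 2000L, seed = 1L, folds = 5L,
                   standardization = c("fold", "global"),
                   nu_range = c(0.05, 0.95),
                   C_range = c(1e-2, 1e3),
                   log10_gamma_scale_range = c(-2, 2)) {
  standardization <- match.arg(standardization)
  if (n_trials < 1L) stop("'n_trials' must be >= 1")
  x <- as.matrix(x)
  ## One optimization cycle: anchor gamma on the standardized training split.
  gb <- gammaBase(
    standardizeFeatures(x)$train,
    seed = deriveSeed(seed, 3L)
  )
  fold_data <- prepFolds(x, y, folds, deriveSeed(seed, 2L), standardization)
  pars <- withSeed(deriveSeed(seed, 1L), data.frame(
    trial_id = seq_len(n_trials),
    nu = stats::runif(n_trials, nu_range[1L], nu_range[2L]),
    C = 10^stats::runif(n_trials, log10(C_range[1L]), log10(C_range[2L])),
    log10_gamma_scale = stats::runif(
      n_trials, log10_gamma_scale_range[1L], log10_gamma_scale_range[2L]
    )
  ))
  pars$gamma <- gb * 10^pars$log10_gamma_scale
  k <- length(fold_data)
  fmae <- matrix(NA_real_, n_trials, k)
  fsvr <- matrix(NA_real_, n_trials, k)
  status <- character(n_trials)
  for (i in seq_len(n_trials)) {
    ev <- evalOnFolds(fold_data, pars$nu[i], pars$C[i], pars$gamma[i])
    if (is.null(ev)) {
      status[i] <- "failed"
    } else {
      fmae[i, ] <- ev$fold_maes
      fsvr[i, ] <- ev$fold_sv_ratios
      status[i] <- "ok"
    }
  }
  if (!any(status == "ok")) stop("all ", n_trials, " trials failed")
  tab <- cbind(
    pars,
    data.frame(
      cv_mae = rowMeans(fmae), sv_ratio = rowMeans(fsvr), status = status
    )
  )
  structure(
    list(
      table = tab, fold_maes = fmae, fold_sv_ratios = fsvr,
      gamma_base = gb, folds = k
    ),
    class = "dooTrials"
  )
}

#' @export
print.dooTrials <- function(x, ...) {
  ok <- x$table$status == "ok"
  cat(sprintf(
    "dooTrials: %d trials (%d ok), %d-fold CV, gamma_base %.4g\n",
    nrow(x$table), sum(ok), x$folds, x$gamma_base
  ))
  if (any(ok)) {
    cat(sprintf(
      "  best cv_mae %.4f | sv_ratio range [%.3f, %.3f]\n",
      min(x$table$cv_mae[ok]),
      min(x$table$sv_ratio[ok]), max(x$table$sv_ratio[ok])
    ))
  }
  invisible(x)
}

subsetTrials <- function(trials, idx) {
  structure(
    list(
      table = trials$table[idx, , drop = FALSE],
      fold_maes = trials$fold_maes[idx, , drop = FALSE],
      fold_sv_ratios = trials$fold_sv_ratios[idx, , drop = FALSE],
      gamma_base = trials$gamma_base, folds = trials$folds
    ),
    class = "dooTrials"
  )
}

#' Extract the Pareto front of a dual-objective search
#'
#' Returns every successful trial not dominated in the
#' (cv_mae, sv_ratio) plane: a trial is dominated when some other trial is
#' no worse in both objectives and strictly better in at least one. Trials
#' tied on both objectives are all retained.
#'
#' @param trials a \code{"dooTrials"} object from [runDoo()].
#' @return A \code{"dooTrials"} object restricted to the front, ordered by
#'   increasing cv_mae.
#' @export
paretoFront <- function(trials) {
  stopifnot(inherits(trials, "dooTrials"))
  ok <- which(trials$table$status == "ok")
  if (!length(ok)) stop("no successful trials to form a front")
  mae <- trials$table$cv_mae[ok]
  svr <- trials$table$sv_ratio[ok]
  ord <- order(mae, svr)
  keep <- logical(length(ok))
  best_prev <- Inf # min sv_ratio over trials with strictly smaller cv_mae
  i <- 1L
  while (i <= length(ord)) {
    j <- i
    while (j < length(ord) && mae[ord[j + 1L]] == mae[ord[i]]) j <- j + 1L
    grp <- ord[i:j]
    gmin <- min(svr[grp])
    if (gmin < best_prev) keep[grp[svr[grp] == gmin]] <- TRUE
    best_prev <- min(best_prev, gmin)
    i <- j + 1L
  }
  front_idx <- ok[keep]
  front_idx <- front_idx[order(trials$table$cv_mae[front_idx])]
  subsetTrials(trials, front_idx)
}
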