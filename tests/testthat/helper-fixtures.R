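## Shared fixture builders: tiny descriptor inputs and hand-built trial /
## trace objects for exercising the selection machinery without SVM fits.

## A dooTrials object with prescribed objective values (one CV "fold" per
## trial unless fold_maes is given), for Pareto / 1-SE tests.
makeTrials <- function(cv_mae, sv_ratio, fold_maes = NULL, status = NULL) {
  n <- length(cv_mae)
  if (is.null(fold_maes)) fold_maes <- matrix(cv_mae, n, 1L)
  if (is.null(status)) status <- rep("ok", n)
  structure(
    list(
      table = data.frame(
        trial_id = seq_len(n),
        nu = rep(0.5, n), C = rep(1, n), log10_gamma_scale = rep(0, n),
        gamma = rep(0.1, n),
        cv_mae = cv_mae, sv_ratio = sv_ratio, status = status
      ),
      fold_maes = fold_maes,
      fold_sv_ratios = matrix(sv_ratio, n, ncol(fold_maes)),
      gamma_base = 0.1, folds = ncol(fold_maes)
    ),
    class = "dooTrials"
  )
}

## Brute-force O(n^2) non-domination oracle (minimize both objectives).
bruteForceFront <- function(mae, svr) {
  n <- length(mae)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j != i &&
          mae[j] <= mae[i] && svr[j] <= svr[i] &&
          (mae[j] < mae[i] || svr[j] < svr[i])) {
        dominated <- TRUE
        break
      }
    }
    keep[i] <- !dominated
  }
  which(keep)
}

## Minimal pruning-trace stand-in for stability-module tests.
makeFakeCandidate <- function(n_features, test_mae, train_mae = test_mae - 0.01,
                              test_r2 = 0.9, train_r2 = 0.95,
                              features = sprintf("D%02d", seq_len(n_features))) {
  list(
    feature_names = features, n_features = as.integer(n_features),
    params = hyperParams(0.25, 30, 0.5), gamma = 0.1, trial_id = 1L,
    cv_mae = test_mae, cv_mae_se = 0.01, sv_ratio = 0.3,
    train_mae = train_mae, test_mae = test_mae,
    train_r2 = train_r2, test_r2 = test_r2,
    importances = stats::setNames(rep(1, n_features), features),
    removed_feature = NA_character_
  )
}

makeFakeTrace <- function(run_id, counts, test_maes,
                          features_by_count = NULL, split_seed = run_id) {
  candidates <- lapply(seq_along(counts), function(i) {
    feats <- if (is.null(features_by_count)) {
      sprintf("D%02d", seq_len(counts[i]))
    } else {
      features_by_count[[i]]
    }
    makeFakeCandidate(counts[i], test_maes[i], features = feats)
  })
  structure(
    list(
      run_id = run_id, split_seed = split_seed, feature_set = "set1",
      candidates = candidates
    ),
    class = "pruningTrace"
  )
}

## Small but complete raw-input fixture for assembleFeatureSets: two solutes,
## three DES components, deterministic values.
makeRawInputs <- function() {
  species <- c("acidA", "acidB", "HBA1c", "HBD1g", "water")
  energetics <- data.frame(
    species_id = species,
    E_int = c(-42.1, -38.5, -20.2, -25.8, -10.1),
    E_misfit = c(6.2, 5.1, 3.3, 4.0, 1.2),
    E_HB = c(-12.5, -9.8, -5.5, -8.1, -6.3),
    E_vdW = c(-35.8, -33.8, -18.0, -21.7, -5.0),
    mu = c(-8.9, -7.5, -4.2, -5.1, -2.3)
  )
  curves <- lapply(seq_along(species), function(i) {
    g <- sigmaGrid()
    SigmaPotential(species[i], g, i * 2 + 3 * sin(150 * g + i) + 40 * g^2)
  })
  solubility <- data.frame(
    solute_id = c("acidA", "acidA", "acidB", "acidB"),
    components = c(
      "HBA1c;HBD1g", "HBA1c;HBD1g;water", "HBA1c;HBD1g", "HBD1g"
    ),
    mole_fractions = c("0.5;0.5", "0.4;0.4;0.2", "0.25;0.75", "1.0"),
    T_K = c(298.15, 298.15, 303.15, 298.15),
    log_x = c(-2.31, -2.05, -3.12, -2.88),
    log_x_cosmo = c(-2.10, -1.95, -3.40, -2.60),
    stringsAsFactors = FALSE
  )
  list(energetics = energetics, curves = curves, solubility = solubility)
}
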