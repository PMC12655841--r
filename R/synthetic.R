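## Synthetic benchmark generator: correlated descriptor blocks, a sparse
## (optionally mildly non-linear) response with Gaussian noise, and a noisy
## COSMO-like computed-solubility column correlated with the response.

#' Specification of a synthetic descriptor/solubility dataset
#'
#' The generator emulates the structure of the real modelling table: a
#' descriptor matrix with correlated blocks (mimicking the solute/DES/
#' relative triplication of the energetic descriptors, which is what makes
#' pruning hard in practice), a response that depends on a known sparse
#' subset of descriptors plus Gaussian noise, and a \code{log_x_cosmo}
#' column correlated with the response, standing in for the COSMO-RS
#' computed solubility. Defaults mirror the scale of the study data:
#' 1020 records and 16 descriptor columns (15 block-correlated descriptors
#' in five blocks of three, plus \code{log_x_cosmo}).
#'
#' @param n_records number of records (default 1020).
#' @param n_features total descriptor columns including \code{log_x_cosmo}
#'   when \code{cosmo_proxy_corr} is not NA (default 16).
#' @param informative_indices indices (among the block-correlated
#'   descriptors) that truly drive the response; by default the first
#'   descriptor of each of the first four correlation blocks (for the
#'   default geometry, \code{c(1, 4, 7, 10)}).
#' @param effect_sizes linear coefficients of the informative descriptors;
#'   defaults to the leading values of \code{c(1.0, 0.8, 0.6, 0.5)}.
#' @param rho within-block correlation in [0, 1) (default 0.5).
#' @param block_size descriptors per correlation block (default 3).
#' @param noise_sd standard deviation of the response noise; when NULL it is
#'   set from \code{target_r2} so the linear signal explains about that
#'   fraction of the response variance.
#' @param target_r2 intended noiseless-signal fraction of variance
#'   (default 0.95), used only when \code{noise_sd} is NULL.
#' @param nonlinear add a mild quadratic + interaction term in the first
#'   informative descriptors (default FALSE).
#' @param cosmo_proxy_corr correlation of the simulated \code{log_x_cosmo}
#'   column with the response (default 0.9); NA drops the column.
#' @param intercept response intercept, default -3 (a typical decadic log
#'   mole-fraction solubility level).
#' @param seed integer seed making the draw fully reproducible.
#' @return List of class \code{"syntheticSpec"}.
#' @export
syntheticSpec <- function(n_records = 1020L,
                          n_features = 16L,
                          informative_indices = NULL,
                          effect_sizes = NULL,
                          rho = 0.5,
                          block_size = 3L,
                          noise_sd = NULL,
                          target_r2 = 0.95,
                          nonlinear = FALSE,
                          cosmo_proxy_corr = 0.9,
                          intercept = -3,
                          seed = 1L) {
  n_gauss_default <- as.integer(n_features) - !is.na(cosmo_proxy_corr)
  if (is.null(informative_indices)) {
    informative_indices <- seq(1L, max(1L, n_gauss_default), by = as.integer(block_size))
    informative_indices <- utils::head(informative_indices, 4L)
    if (is.null(effect_sizes)) {
      effect_sizes <- c(1.0, 0.8, 0.6, 0.5)[seq_along(informative_indices)]
    }
  }
  if (is.null(effect_sizes)) {
    stop("'effect_sizes' must be given with explicit 'informative_indices'")
  }
  spec <- list(
    n_records = as.integer(n_records), n_features = as.integer(n_features),
    informative_indices = as.integer(informative_indices),
    effect_sizes = as.numeric(effect_sizes), rho = rho,
    block_size = as.integer(block_size), noise_sd = noise_sd,
    target_r2 = target_r2, nonlinear = isTRUE(nonlinear),
    cosmo_proxy_corr = cosmo_proxy_corr, intercept = intercept,
    seed = as.integer(seed)
  )
  n_gauss <- spec$n_features - !is.na(spec$cosmo_proxy_corr)
  if (spec$n_records < 2L || n_gauss < 1L) stop("dataset dimensions too small")
  if (length(spec$informative_indices) != length(spec$effect_sizes)) {
    stop("'informative_indices' and 'effect_sizes' lengths differ")
  }
  if (length(spec$informative_indices) > n_gauss ||
      any(spec$informative_indices < 1L) ||
      any(spec$informative_indices > n_gauss)) {
    stop("'informative_indices' must index the block-correlated descriptors")
  }
  if (spec$rho < 0 || spec$rho >= 1) stop("'rho' must lie in [0, 1)")
  if (!is.null(spec$noise_sd) && spec$noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!is.na(spec$cosmo_proxy_corr) &&
      (spec$cosmo_proxy_corr < -1 || spec$cosmo_proxy_corr > 1)) {
    stop("'cosmo_proxy_corr' must be a correlation")
  }
  structure(spec, class = "syntheticSpec")
}

#' Generate a synthetic dataset with known ground truth
#'
#' @param spec a [syntheticSpec()].
#' @return List with \code{table} (a [DescriptorTable-class]) and
#'   \code{truth}: the informative descriptor names and indices, effect
#'   sizes, the realized \code{noise_sd}, the realized signal R-squared, and
#'   the generator spec.
#' @export
generateSynthetic <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  withSeed(spec$seed, {
    has_cosmo <- !is.na(spec$cosmo_proxy_corr)
    p <- spec$n_features - has_cosmo
    n <- spec$n_records
    nm <- sprintf("D%02d", seq_len(p))

    ## block-correlated Gaussian descriptors (compound symmetry per block)
    x <- matrix(NA_real_, n, p, dimnames = list(NULL, nm))
    blocks <- split(seq_len(p), (seq_len(p) - 1L) %/% spec$block_size)
    for (b in blocks) {
      k <- length(b)
      sigma <- matrix(spec$rho, k, k)
      diag(sigma) <- 1
      x[, b] <- matrix(stats::rnorm(n * k), n, k) %*% chol(sigma)
    }

    signal <- spec$intercept +
      as.numeric(x[, spec$informative_indices, drop = FALSE] %*% spec$effect_sizes)
    if (spec$nonlinear) {
      i1 <- spec$informative_indices[1L]
      signal <- signal + 0.3 * x[, i1]^2
      if (length(spec$informative_indices) > 1L) {
        i2 <- spec$informative_indices[2L]
        signal <- signal + 0.3 * x[, i1] * x[, i2]
      }
    }
    noise_sd <- spec$noise_sd
    if (is.null(noise_sd)) {
      noise_sd <- stats::sd(signal) * sqrt((1 - spec$target_r2) / spec$target_r2)
    }
    y <- signal + stats::rnorm(n, 0, noise_sd)

    feats <- as.data.frame(x)
    if (has_cosmo) {
      zc <- spec$cosmo_proxy_corr
      zy <- as.numeric(scale(y))
      proxy <- zc * zy + sqrt(1 - zc^2) * stats::rnorm(n)
      feats$log_x_cosmo <- mean(y) + stats::sd(y) * proxy
    }
    tags <- c(rep("set1", min(ncol(feats), 16L)),
              rep("set2-extra", max(0L, ncol(feats) - 16L)))
    table <- DescriptorTable(
      features = feats, target = y,
      records = data.frame(record_id = sprintf("synth_%04d", seq_len(n))),
      setTag = tags
    )
    list(
      table = table,
      truth = list(
        informative = nm[spec$informative_indices],
        informative_indices = spec$informative_indices,
        effect_sizes = spec$effect_sizes,
        noise_sd = noise_sd,
        signal_r2 = stats::var(signal) / stats::var(y),
        spec = spec
      )
    )
  })
}

#' Generate smooth random sigma-potential curves
#'
#' Each curve is a sum of up to three Gaussian bumps in the charge density,
#' evaluated on the standard 61-point grid — smooth, species-specific shapes
#' of the kind COSMO-RS produces, without any quantum chemistry.
#'
#' @param n_species number of curves (>= 1).
#' @param seed integer seed; the same seed yields identical curves.
#' @return List of [SigmaPotential-class] objects named
#'   \code{synthetic_species_01}, ...
#' @export
generateSigmaCurves <- function(n_species, seed = 1L) {
  if (n_species < 1L) stop("'n_species' must be >= 1")
  grid <- sigmaGrid()
  withSeed(seed, {
    lapply(seq_len(n_species), function(i) {
      k <- sample(1:3, 1L)
      amp <- stats::runif(k, -10, 10)
      ctr <- stats::runif(k, -0.02, 0.02)
      wid <- stats::runif(k, 0.004, 0.012)
      mu <- rowSums(vapply(
        seq_len(k),
        function(j) amp[j] * exp(-(grid - ctr[j])^2 / (2 * wid[j]^2)),
        numeric(length(grid))
      ))
      SigmaPotential(sprintf("synthetic_species_%02d", i), grid, mu)
    })
  })
}
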