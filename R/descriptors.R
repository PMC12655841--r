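## Descriptor engineering for DES solubility QSPR: energetic descriptors,
## Gibbs energy of fusion, mole-fraction mixture weighting, relative
## (solute - solvent) descriptors, and assembly of the two feature sets.

ENERGETIC_FIELDS <- c("E_int", "E_misfit", "E_HB", "E_vdW", "mu")
DELTA <- "\u0394" # capital delta prefix for relative descriptors

#' Prefix a descriptor name for its relative (solute - DES) variant
#'
#' @param base character vector of base descriptor names.
#' @return The names prefixed with the capital-delta character.
#' @export
deltaName <- function(base) paste0(DELTA, base)

#' Gibbs free energy of fusion at a working temperature
#'
#' Uses the constant-heat-capacity approximation in which the entropy of
#' fusion is \eqn{\Delta S_{fus} = \Delta H_{fus} / T_m}, giving
#' \eqn{\Delta G_{fus}(T) = \Delta H_{fus} (1 - T / T_m)}.
#'
#' @param dH_fus enthalpy of fusion (energy/mol, source units), > 0.
#' @param T_m melting temperature in kelvin, > 0.
#' @param T working temperature in kelvin, > 0. Vectorized over all three.
#' @return \eqn{\Delta G_{fus}(T)} in the units of \code{dH_fus}.
#' @examples
#' gibbsFusion(30, 400, 298.15) # kJ/mol in, kJ/mol out
#' @export
gibbsFusion <- function(dH_fus, T_m, T) {
  if (any(!is.finite(dH_fus)) || any(dH_fus <= 0)) {
    stop("'dH_fus' must be finite and > 0")
  }
  if (any(!is.finite(T_m)) || any(T_m <= 0)) stop("'T_m' must be > 0 kelvin")
  if (any(!is.finite(T)) || any(T <= 0)) stop("'T' must be > 0 kelvin")
  dH_fus * (1 - T / T_m)
}

#' Construct a solute-free mixture specification
#'
#' Describes the composition of a DES (hydrogen-bond acceptor, donor(s),
#' optionally water) on a solute-free mole-fraction basis. Water, when
#' present, is simply a further component.
#'
#' @param species_id character vector of component identifiers.
#' @param mole_fraction numeric vector of solute-free mole fractions; must be
#'   positive and sum to 1 within 1e-9.
#' @return An object of class \code{"MixtureSpec"}.
#' @export
mixtureSpec <- function(species_id, mole_fraction) {
  species_id <- as.character(species_id)
  mole_fraction <- as.numeric(mole_fraction)
  if (length(species_id) != length(mole_fraction) || length(species_id) < 1L) {
    stop("'species_id' and 'mole_fraction' must have equal positive length")
  }
  if (any(!is.finite(mole_fraction)) || any(mole_fraction <= 0)) {
    stop("mole fractions must be finite and > 0")
  }
  if (abs(sum(mole_fraction) - 1) > 1e-9) {
    stop(sprintf(
      "mole fractions must sum to 1 (got %.12f) for mixture [%s]",
      sum(mole_fraction), paste(species_id, collapse = ";")
    ))
  }
  structure(
    list(species_id = species_id, mole_fraction = mole_fraction),
    class = "MixtureSpec"
  )
}

#' @export
print.MixtureSpec <- function(x, ...) {
  cat(
    "MixtureSpec:",
    paste(sprintf("%s (%.4f)", x$species_id, x$mole_fraction), collapse = " + "),
    "\n"
  )
  invisible(x)
}

#' Mole-fraction-weighted mixture descriptor
#'
#' Combines per-component descriptor values into a single DES-level value,
#' weighting each component by its solute-free mole fraction:
#' \eqn{v_{DES} = \sum_i x_i v_i}.
#'
#' @param values named numeric vector of per-species descriptor values.
#' @param mix a \code{"MixtureSpec"} object.
#' @return The weighted descriptor value (scalar).
#' @export
mixtureDescriptor <- function(values, mix) {
  stopifnot(inherits(mix, "MixtureSpec"))
  missing <- setdiff(mix$species_id, names(values))
  if (length(missing)) {
    stop(
      "no descriptor value for mixture component(s): ",
      paste(missing, collapse = ", ")
    )
  }
  sum(mix$mole_fraction * as.numeric(values[mix$species_id]))
}

#' Relative (solute minus solvent) descriptor
#'
#' @param solute_value solute-side descriptor value(s), finite.
#' @param des_value mixture-weighted DES descriptor value(s), finite.
#' @return \code{solute_value - des_value}.
#' @export
relativeDescriptor <- function(solute_value, des_value) {
  if (any(!is.finite(solute_value)) || any(!is.finite(des_value))) {
    stop("relative descriptors require finite inputs")
  }
  solute_value - des_value
}

parseMixture <- function(components, mole_fractions, sep = ";") {
  mixtureSpec(
    strsplit(components, sep, fixed = TRUE)[[1L]],
    as.numeric(strsplit(mole_fractions, sep, fixed = TRUE)[[1L]])
  )
}

#' Assemble the two descriptor feature sets
#'
#' Builds the full modelling table from raw per-species inputs. Feature
#' set 1 (16 columns) comprises the five solute energetic descriptors
#' (\code{E_int_API}, \code{E_misfit_API}, \code{E_HB_API}, \code{E_vdW_API},
#' \code{mu_API}), their five mole-fraction-weighted DES counterparts, the
#' five relative (solute minus DES) differences, and the COSMO-RS computed
#' log solubility \code{log_x_cosmo}. Feature set 2 (28 columns) adds the 12
#' relative binned sigma-potential descriptors (solute bins minus
#' mixture-weighted DES bins, delta-prefixed). Energies pass through in the
#' units of the source tables; solubility logarithms are decadic.
#'
#' @param solubility data.frame with columns \code{solute_id},
#'   \code{components}, \code{mole_fractions} (";"-separated strings),
#'   \code{T_K}, \code{log_x}, \code{log_x_cosmo}.
#' @param energetics data.frame with columns \code{species_id} and the five
#'   energetic fields \code{E_int}, \code{E_misfit}, \code{E_HB},
#'   \code{E_vdW}, \code{mu}.
#' @param sigma_curves list of [SigmaPotential-class] objects covering every
#'   solute and every DES component.
#' @return A [DescriptorTable-class] with 28 tagged columns (16 set1 +
#'   12 set2-extra) and target \code{log_x}.
#' @export
assembleFeatureSets <- function(solubility, energetics, sigma_curves) {
  req <- c("solute_id", "components", "mole_fractions", "T_K", "log_x", "log_x_cosmo")
  miss <- setdiff(req, colnames(solubility))
  if (length(miss)) {
    stop("solubility table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyNA(solubility[req])) stop("solubility table contains missing values")
  if (any(solubility$log_x > 0)) {
    stop("log mole-fraction solubility must be <= 0 (mole fraction <= 1)")
  }
  if (any(solubility$T_K <= 0)) stop("temperatures must be positive kelvin")

  emiss <- setdiff(c("species_id", ENERGETIC_FIELDS), colnames(energetics))
  if (length(emiss)) {
    stop("energetics table lacks column(s): ", paste(emiss, collapse = ", "))
  }
  emat <- as.matrix(energetics[, ENERGETIC_FIELDS])
  rownames(emat) <- energetics$species_id
  if (any(!is.finite(emat))) stop("energetic descriptors must all be finite")

  bins <- binSigmaPotentials(sigma_curves)
  bmat <- as.matrix(bins[, SIGMA_REGION_NAMES])
  rownames(bmat) <- bins$species_id

  n <- nrow(solubility)
  solute_cols <- paste0(ENERGETIC_FIELDS, "_API")
  des_cols <- paste0(ENERGETIC_FIELDS, "_DES")
  rel_cols <- deltaName(ENERGETIC_FIELDS)
  sigma_cols <- deltaName(SIGMA_REGION_NAMES)
  all_cols <- c(solute_cols, des_cols, rel_cols, "log_x_cosmo", sigma_cols)

  out <- matrix(NA_real_, n, length(all_cols), dimnames = list(NULL, all_cols))
  for (i in seq_len(n)) {
    rec <- solubility[i, ]
    label <- sprintf(
      "record %d (solute '%s' in [%s] at %g K)",
      i, rec$solute_id, rec$components, rec$T_K
    )
    mix <- tryCatch(
      parseMixture(rec$components, rec$mole_fractions),
      error = function(e) stop(label, ": ", conditionMessage(e), call. = FALSE)
    )
    needed <- c(rec$solute_id, mix$species_id)
    no_e <- setdiff(needed, rownames(emat))
    no_s <- setdiff(needed, rownames(bmat))
    if (length(no_e) || length(no_s)) {
      stop(
        label, ": missing ",
        if (length(no_e)) paste0("energetics for [", paste(no_e, collapse = ", "), "] "),
        if (length(no_s)) paste0("sigma-potential for [", paste(no_s, collapse = ", "), "]"),
        call. = FALSE
      )
    }
    sol_e <- emat[rec$solute_id, ]
    des_e <- vapply(
      ENERGETIC_FIELDS,
      function(f) mixtureDescriptor(emat[, f], mix),
      numeric(1L)
    )
    sol_b <- bmat[rec$solute_id, ]
    des_b <- vapply(
      SIGMA_REGION_NAMES,
      function(b) mixtureDescriptor(bmat[, b], mix),
      numeric(1L)
    )
    out[i, ] <- c(
      sol_e, des_e, relativeDescriptor(sol_e, des_e),
      rec$log_x_cosmo, relativeDescriptor(sol_b, des_b)
    )
  }

  DescriptorTable(
    features = as.data.frame(out, check.names = FALSE),
    target = solubility$log_x,
    records = solubility[, c("solute_id", "components", "mole_fractions", "T_K")],
    setTag = c(rep("set1", 16L), rep("set2-extra", 12L))
  )
}

#' Read the raw descriptor input tables
#'
#' Readers for the plain-CSV input schema: per-species energetics
#' (\code{species_id, E_int, E_misfit, E_HB, E_vdW, mu}), long-format
#' sigma-potentials (\code{species_id, sigma, value}), fusion data
#' (\code{solute_id, Tm_K, dHfus_kJmol}) and the solubility table
#' (\code{solute_id, components, mole_fractions, T_K, log_x, log_x_cosmo}).
#'
#' @param path path to a CSV file.
#' @return \code{readSigmaPotentials} returns a list of
#'   [SigmaPotential-class]; the others return validated data.frames
#'   (\code{readFusionData} adds the derived entropy of fusion
#'   \code{dSfus}).
#' @name readers
NULL

#' @rdname readers
#' @export
readSpeciesEnergetics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("species_id", ENERGETIC_FIELDS), colnames(df))
  if (length(miss)) stop(path, " lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname readers
#' @export
readSigmaPotentials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("species_id", "sigma", "value"), colnames(df))
  if (length(miss)) stop(path, " lacks column(s): ", paste(miss, collapse = ", "))
  lapply(split(df, df$species_id), function(d) {
    d <- d[order(d$sigma), ]
    SigmaPotential(d$species_id[1L], d$sigma, d$value)
  })
}

#' @rdname readers
#' @export
readFusionData <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("solute_id", "Tm_K", "dHfus_kJmol"), colnames(df))
  if (length(miss)) stop(path, " lacks column(s): ", paste(miss, collapse = ", "))
  if (any(df$Tm_K <= 0) || any(df$dHfus_kJmol <= 0)) {
    stop(path, ": melting temperatures and fusion enthalpies must be positive")
  }
  df$dSfus <- df$dHfus_kJmol / df$Tm_K
  df
}

#' @rdname readers
#' @export
readSolubilityTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("solute_id", "components", "mole_fractions", "T_K", "log_x", "log_x_cosmo")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) stop(path, " lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write the assembled feature tables and their manifest
#'
#' Emits \code{features_set1.csv}, \code{features_set2.csv} and
#' \code{feature_manifest.json} (column names, set tags, unit conventions)
#' into \code{dir}.
#'
#' @param dt a [DescriptorTable-class] holding all 28 columns.
#' @param dir output directory (created if absent).
#' @return Invisibly, the manifest list.
#' @export
writeFeatureTables <- function(dt, dir) {
  stopifnot(is(dt, "DescriptorTable"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set1 <- featureNames(dt, "set1")
  full <- cbind(dt@records, dt@features, log_x = dt@target)
  utils::write.csv(
    full[, c(colnames(dt@records), set1, "log_x")],
    file.path(dir, "features_set1.csv"),
    row.names = FALSE
  )
  utils::write.csv(full, file.path(dir, "features_set2.csv"), row.names = FALSE)
  manifest <- list(
    columns = colnames(dt@features),
    set_tag = as.list(setTags(dt)),
    target = "log_x",
    conventions = list(
      log_base = 10,
      energy_units = "as supplied by the source tables (not converted)",
      sigma_units = "e/A^2",
      temperature_units = "K"
    )
  )
  jsonlite::write_json(
    manifest, file.path(dir, "feature_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
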