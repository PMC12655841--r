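#' @import methods
NULL

## Grid constants for the sigma-potential representation: 61 points,
## evenly spaced over the screening-charge-density window [-0.03, +0.03] e/A^2.
SIGMA_GRID_N <- 61L
SIGMA_GRID_MIN <- -0.03
SIGMA_GRID_MAX <- 0.03
SIGMA_BIN_WIDTH <- 0.005
SIGMA_REGION_NAMES <- c(
  paste0("HBD", 1:4), # donor region, -0.03 .. -0.01
  paste0("HH", 1:4),  # hydrophobic region, -0.01 .. +0.01
  paste0("HBA", 1:4)  # acceptor region, +0.01 .. +0.03
)

#' SigmaPotential: a 61-point sigma-potential curve for one species
#'
#' Holds the chemical potential of a molecular surface segment as a function
#' of its screening charge density, tabulated on the standard 61-point grid
#' spanning \eqn{[-0.03, +0.03]} e/\eqn{\mbox{\AA}^2}.
#'
#' @slot species_id single character identifier of the species.
#' @slot sigma numeric(61), strictly increasing grid of charge densities;
#'   first point \eqn{-0.03}, last \eqn{+0.03} (to within 1e-12).
#' @slot mu numeric(61), potential values in the units of the source table.
#'
#' @seealso [SigmaPotential()] for the constructor,
#'   [binSigmaPotential()] for reduction to 12 region descriptors.
#' @exportClass SigmaPotential
setClass("SigmaPotential",
  representation(
    species_id = "character",
    sigma = "numeric",
    mu = "numeric"
  )
)

setValidity("SigmaPotential", function(object) {
  id <- if (length(object@species_id) == 1L) object@species_id else "<unnamed>"
  msgs <- character()
  if (length(object@species_id) != 1L || is.na(object@species_id)) {
    msgs <- c(msgs, "'species_id' must be a single non-NA string")
  }
  if (length(object@sigma) != SIGMA_GRID_N) {
    msgs <- c(msgs, sprintf(
      "species '%s': sigma grid has %d points, expected %d",
      id, length(object@sigma), SIGMA_GRID_N
    ))
  } else {
    if (any(diff(object@sigma) <= 0)) {
      msgs <- c(msgs, sprintf("species '%s': sigma grid must be strictly increasing", id))
    }
    if (abs(object@sigma[1L] - SIGMA_GRID_MIN) > 1e-12 ||
        abs(object@sigma[SIGMA_GRID_N] - SIGMA_GRID_MAX) > 1e-12) {
      msgs <- c(msgs, sprintf(
        "species '%s': sigma grid must span [%g, %g]",
        id, SIGMA_GRID_MIN, SIGMA_GRID_MAX
      ))
    }
  }
  if (length(object@mu) != length(object@sigma)) {
    msgs <- c(msgs, sprintf("species '%s': 'mu' and 'sigma' lengths differ", id))
  }
  if (anyNA(object@mu) || any(!is.finite(object@mu))) {
    msgs <- c(msgs, sprintf("species '%s': 'mu' must be finite", id))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SigmaPotential
#'
#' @param species_id single character identifier.
#' @param sigma numeric(61) grid of charge densities (e/\eqn{\mbox{\AA}^2}).
#' @param mu numeric(61) potential values.
#' @return A validated [SigmaPotential-class] object.
#' @examples
#' sp <- SigmaPotential("water", sigmaGrid(), rep(1, 61))
#' binSigmaPotential(sp)
#' @export
SigmaPotential <- function(species_id, sigma, mu) {
  new("SigmaPotential",
    species_id = as.character(species_id),
    sigma = as.numeric(sigma), mu = as.numeric(mu)
  )
}

#' The standard 61-point charge-density grid
#'
#' @return numeric(61), evenly spaced on \eqn{[-0.03, +0.03]}.
#' @export
sigmaGrid <- function() {
  seq(SIGMA_GRID_MIN, SIGMA_GRID_MAX, length.out = SIGMA_GRID_N)
}

setMethod("show", "SigmaPotential", function(object) {
  cat(sprintf(
    "SigmaPotential for '%s': %d points on [%g, %g], mu range [%.4g, %.4g]\n",
    object@species_id, length(object@sigma),
    object@sigma[1L], object@sigma[length(object@sigma)],
    min(object@mu), max(object@mu)
  ))
})

#' DescriptorTable: a per-record feature matrix with set tags
#'
#' The central data container: one row per solubility record
#' (solute, solvent system, composition, temperature), one column per named
#' molecular descriptor, with each column tagged by feature-set membership
#' (\code{"set1"} for the energetic/chemical-potential core,
#' \code{"set2-extra"} for the relative binned sigma-potential descriptors),
#' plus the modelling target, decadic log mole-fraction solubility.
#'
#' @slot features data.frame of numeric descriptor columns (no missing values).
#' @slot target numeric response, one value per row of \code{features}.
#' @slot records data.frame of record keys (solute id, system, temperature, ...)
#'   with as many rows as \code{features}, possibly zero columns.
#' @slot setTag named character vector, one tag per feature column, values in
#'   \code{c("set1", "set2-extra")}.
#'
#' @seealso [DescriptorTable()], [assembleFeatureSets()], [featureMatrix()].
#' @exportClass DescriptorTable
setClass("DescriptorTable",
  representation(
    features = "data.frame",
    target = "numeric",
    records = "data.frame",
    setTag = "character"
  )
)

setValidity("DescriptorTable", function(object) {
  msgs <- character()
  p <- ncol(object@features)
  if (p > 0L && !all(vapply(object@features, is.numeric, logical(1L)))) {
    msgs <- c(msgs, "all feature columns must be numeric")
  }
  if (anyNA(object@features)) {
    msgs <- c(msgs, "feature columns must not contain missing values")
  }
  if (length(object@target) != nrow(object@features)) {
    msgs <- c(msgs, "'target' length must equal the number of feature rows")
  }
  if (anyNA(object@target)) msgs <- c(msgs, "'target' must not contain NA")
  if (nrow(object@records) != nrow(object@features)) {
    msgs <- c(msgs, "'records' must have one row per feature row")
  }
  if (length(object@setTag) != p) {
    msgs <- c(msgs, "'setTag' must have one entry per feature column")
  } else if (p > 0L) {
    if (!identical(names(object@setTag), colnames(object@features))) {
      msgs <- c(msgs, "'setTag' names must match feature column names in order")
    }
    if (!all(object@setTag %in% c("set1", "set2-extra"))) {
      msgs <- c(msgs, "set tags must be 'set1' or 'set2-extra'")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DescriptorTable
#'
#' @param features data.frame of numeric descriptor columns.
#' @param target numeric response (decadic log mole-fraction solubility).
#' @param records optional data.frame of record keys.
#' @param setTag character vector of per-column tags (\code{"set1"} or
#'   \code{"set2-extra"}); defaults to \code{"set1"} for every column.
#' @return A validated [DescriptorTable-class] object.
#' @export
DescriptorTable <- function(features, target, records = NULL, setTag = NULL) {
  features <- as.data.frame(features)
  if (is.null(records)) {
    records <- data.frame(row.names = seq_len(nrow(features)))
  }
  if (is.null(setTag)) setTag <- rep("set1", ncol(features))
  names(setTag) <- colnames(features)
  new("DescriptorTable",
    features = features, target = as.numeric(target),
    records = records, setTag = setTag
  )
}

setMethod("show", "DescriptorTable", function(object) {
  tab <- table(factor(object@setTag, levels = c("set1", "set2-extra")))
  cat(sprintf(
    "DescriptorTable: %d records x %d descriptors (%d set1 + %d set2-extra)\n",
    nrow(object@features), ncol(object@features), tab[["set1"]],
    tab[["set2-extra"]]
  ))
  cat(sprintf(
    "  target log(x): range [%.3f, %.3f]\n",
    suppressWarnings(min(object@target)), suppressWarnings(max(object@target))
  ))
})
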