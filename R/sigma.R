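#' Reduce a sigma-potential curve to 12 region descriptors
#'
#' Averages the 61-point sigma-potential over twelve consecutive 0.005-wide
#' charge-density intervals, yielding a 12-step summary of the curve. The
#' twelve bins fall into three chemically characteristic regions: the
#' hydrogen-bond-donor region (\code{HBD1..HBD4}, \eqn{-0.03} to \eqn{-0.01}
#' e/\eqn{\mbox{\AA}^2}), the hydrophobic region (\code{HH1..HH4},
#' \eqn{-0.01} to \eqn{+0.01}), and the hydrogen-bond-acceptor region
#' (\code{HBA1..HBA4}, \eqn{+0.01} to \eqn{+0.03}), named in ascending
#' charge-density order.
#'
#' Bins are half-open \eqn{[lo, lo + 0.005)} except the last, which is closed
#' at \eqn{+0.03}; on the standard 0.001-step grid the first eleven bins hold
#' five points each and the last holds six. Bin membership is decided with a
#' 1e-9 tolerance so that grid points generated by floating-point arithmetic
#' land in the intended bin.
#'
#' @param curve a [SigmaPotential-class] object.
#' @return Named numeric vector of length 12 (names \code{HBD1..HBD4},
#'   \code{HH1..HH4}, \code{HBA1..HBA4}), each value the arithmetic mean of
#'   the potential values whose grid points fall in the bin, with attribute
#'   \code{species_id}.
#' @examples
#' sp <- SigmaPotential("glycerol", sigmaGrid(), sin(100 * sigmaGrid()))
#' binSigmaPotential(sp)
#' @export
binSigmaPotential <- function(curve) {
  if (!is(curve, "SigmaPotential")) {
    stop("'curve' must be a SigmaPotential object")
  }
  validObject(curve)
  sigma <- curve@sigma
  bin <- floor((sigma - SIGMA_GRID_MIN) / SIGMA_BIN_WIDTH + 1e-9) + 1L
  bin <- pmin(bin, 12L) # +0.03 endpoint joins the final bin
  means <- vapply(
    seq_len(12L),
    function(b) mean(curve@mu[bin == b]),
    numeric(1L)
  )
  names(means) <- SIGMA_REGION_NAMES
  attr(means, "species_id") <- curve@species_id
  means
}

#' Bin sigma-potentials for a list of species
#'
#' @param curves list of [SigmaPotential-class] objects.
#' @return data.frame with one row per species: \code{species_id} plus the
#'   12 region descriptors.
#' @export
binSigmaPotentials <- function(curves) {
  rows <- lapply(curves, function(cv) {
    v <- binSigmaPotential(cv)
    cbind(
      data.frame(species_id = attr(v, "species_id")),
      as.data.frame(as.list(v))
    )
  })
  do.call(rbind, rows)
}
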