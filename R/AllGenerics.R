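#' Accessors for DescriptorTable and SigmaPotential objects
#'
#' @param x a [DescriptorTable-class] or [SigmaPotential-class] object.
#' @name accessors
NULL

#' @describeIn accessors numeric feature matrix (records x descriptors).
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @describeIn accessors the response vector (decadic log mole fraction).
#' @export
setGeneric("targetValues", function(x) standardGeneric("targetValues"))

#' @describeIn accessors descriptor column names, optionally restricted to a
#'   feature set.
#' @param set one of \code{"set2"} (all columns), \code{"set1"}, or
#'   \code{"set2-extra"}.
#' @export
setGeneric("featureNames", function(x, set = "set2") standardGeneric("featureNames"))

#' @describeIn accessors per-column feature-set tags.
#' @export
setGeneric("setTags", function(x) standardGeneric("setTags"))

#' @describeIn accessors the record-key data.frame.
#' @export
setGeneric("recordKeys", function(x) standardGeneric("recordKeys"))

#' @describeIn accessors number of records (rows).
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' @describeIn accessors the charge-density grid of a sigma-potential curve.
#' @export
setGeneric("sigmaValues", function(x) standardGeneric("sigmaValues"))

#' @describeIn accessors the potential values of a sigma-potential curve.
#' @export
setGeneric("muValues", function(x) standardGeneric("muValues"))

#' @describeIn accessors the species identifier.
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))

setMethod("featureMatrix", "DescriptorTable", function(x) {
  as.matrix(x@features)
})
setMethod("targetValues", "DescriptorTable", function(x) x@target)
setMethod("featureNames", "DescriptorTable", function(x, set = "set2") {
  set <- match.arg(set, c("set2", "set1", "set2-extra"))
  if (set == "set2") return(colnames(x@features))
  names(x@setTag)[x@setTag == set]
})
setMethod("setTags", "DescriptorTable", function(x) x@setTag)
setMethod("recordKeys", "DescriptorTable", function(x) x@records)
setMethod("nRecords", "DescriptorTable", function(x) nrow(x@features))

setMethod("sigmaValues", "SigmaPotential", function(x) x@sigma)
setMethod("muValues", "SigmaPotential", function(x) x@mu)
setMethod("speciesId", "SigmaPotential", function(x) x@species_id)

#' Restrict a DescriptorTable to a subset of descriptor columns
#'
#' @param x a [DescriptorTable-class].
#' @param features character vector of descriptor names to keep (order kept
#'   as given).
#' @return A new [DescriptorTable-class] with the requested columns.
#' @export
selectFeatures <- function(x, features) {
  stopifnot(is(x, "DescriptorTable"))
  missing <- setdiff(features, colnames(x@features))
  if (length(missing)) {
    stop("unknown descriptor(s): ", paste(missing, collapse = ", "))
  }
  DescriptorTable(
    features = x@features[, features, drop = FALSE],
    target = x@target, records = x@records,
    setTag = unname(x@setTag[features])
  )
}

#' Extract the rows of a DescriptorTable
#'
#' @param x a [DescriptorTable-class].
#' @param i integer or logical row index.
#' @return A new [DescriptorTable-class] with the requested records.
#' @export
subsetRecords <- function(x, i) {
  stopifnot(is(x, "DescriptorTable"))
  DescriptorTable(
    features = x@features[i, , drop = FALSE],
    target = x@target[i],
    records = x@records[i, , drop = FALSE],
    setTag = unname(x@setTag)
  )
}
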