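#' @import methods
NULL

.MEAS_COLS <- c("h", "k", "l", "image_id", "i_partial", "sigma_partial",
                "partiality", "stol2")
.IMG_COLS <- c("image_id", "scale", "wilson_b", "wavelength")

#' Unmerged still-image reflection data
#'
#' Container for a set of partial reflection measurements together with the
#' per-image correction model. Each measurement row holds a Miller index, the
#' image it was observed on, the partial intensity and its photon-counting
#' sigma (photon units), the partiality fraction in (0, 1], and the
#' resolution term sin^2(theta)/lambda^2 in 1/A^2. After
#' \code{\link{applyCorrections}} the columns \code{i_full} and
#' \code{sigma_full} hold the full-intensity equivalents. The image table
#' holds, per image, the multiplicative scale G, the Wilson B factor (A^2)
#' and the incident wavelength (A).
#'
#' @slot measurements data.frame of per-measurement records.
#' @slot images data.frame of per-image correction models, one row per image.
#'
#' @exportClass ReflectionData
setClass("ReflectionData",
         representation(measurements = "data.frame", images = "data.frame"))

setValidity("ReflectionData", function(object) {
  m <- object@measurements
  im <- object@images
  msg <- character()
  miss <- setdiff(.MEAS_COLS, names(m))
  if (length(miss))
    msg <- c(msg, paste0("missing measurement column(s): ",
                         paste(miss, collapse = ", ")))
  missi <- setdiff(.IMG_COLS, names(im))
  if (length(missi))
    msg <- c(msg, paste0("missing image column(s): ",
                         paste(missi, collapse = ", ")))
  if (!length(msg) && nrow(m)) {
    if (any(!is.finite(m$sigma_partial) | m$sigma_partial <= 0))
      msg <- c(msg, "sigma_partial must be finite and > 0")
    if (any(m$partiality <= 0 | m$partiality > 1))
      msg <- c(msg, "partiality must lie in (0, 1]")
    if (any(m$stol2 < 0))
      msg <- c(msg, "stol2 must be >= 0")
  }
  if (!length(msg) && nrow(im)) {
    if (anyDuplicated(im$image_id))
      msg <- c(msg, "duplicated image_id in image table")
    if (any(im$scale <= 0)) msg <- c(msg, "image scale must be > 0")
    if (any(im$wavelength <= 0)) msg <- c(msg, "wavelength must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Measurements grouped by asymmetric-unit Miller index
#'
#' Result of \code{\link{groupByMiller}}: the measurement table augmented
#' with asymmetric-unit indices (\code{h_asu,k_asu,l_asu}) and an integer
#' \code{group} key, plus a per-group summary table. With
#' \code{anomalous = TRUE} Friedel mates of acentric reflections form
#' distinct groups.
#'
#' @slot measurements data.frame with grouping columns appended.
#' @slot groups data.frame with one row per group: \code{group}, asu
#'   \code{h,k,l}, multiplicity \code{n}.
#' @slot spaceGroup character; the space-group symbol used.
#' @slot anomalous logical; whether Friedel mates were kept separate.
#'
#' @exportClass ReflectionGroups
setClass("ReflectionGroups",
         representation(measurements = "data.frame", groups = "data.frame",
                        spaceGroup = "character", anomalous = "logical"))

#' Merged reflection intensities
#'
#' One row per asymmetric-unit Miller index: merged intensity, merged sigma,
#' multiplicity, the plain mean of the corrected measurements
#' (\code{mean_raw}, used for intensity binning and the error model), and the
#' mean resolution term.
#'
#' @slot table data.frame with columns \code{h,k,l,i_merged,sigma_merged,
#'   multiplicity,mean_raw,stol2}.
#' @slot protocol character; one of \code{"unweighted"},
#'   \code{"counting_weighted"}, \code{"ev11"}.
#'
#' @exportClass MergedReflections
setClass("MergedReflections",
         representation(table = "data.frame", protocol = "character"))

#' Error-model parameters (SDFAC, SDB, SDADD)
#'
#' The three terms of the sigma-inflation model
#' sigma' = sFac * [sigma^2 + sB * <I> + (sAdd * <I>)^2]^(1/2),
#' where <I> is the mean corrected intensity of the reflection the
#' measurement belongs to. \code{sFac} absorbs multiplicative miscalibration
#' such as an erroneous detector gain; \code{sAdd} captures
#' intensity-proportional error from instrument instability; \code{sB} has
#' no assigned physical meaning.
#'
#' @slot sFac non-negative scale factor on the whole sigma.
#' @slot sB coefficient of the term linear in mean intensity.
#' @slot sAdd non-negative coefficient of the intensity-proportional term.
#'
#' @exportClass ErrorModelParams
setClass("ErrorModelParams",
         representation(sFac = "numeric", sB = "numeric", sAdd = "numeric"))

setValidity("ErrorModelParams", function(object) {
  msg <- character()
  for (s in c("sFac", "sB", "sAdd")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, paste0(s, " must be a finite scalar"))
  }
  if (!length(msg)) {
    if (object@sFac < 0) msg <- c(msg, "sFac must be >= 0")
    if (object@sAdd < 0) msg <- c(msg, "sAdd must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Normal probability plot of normalized deviations
#'
#' Sorted leave-one-out normalized deviations against rankits (expected
#' standard-normal order statistics), with the straight line fitted to the
#' central region. Slope 1 and offset 0 indicate correctly calibrated error
#' estimates.
#'
#' @slot deviations sorted normalized deviations (ascending).
#' @slot rankits matching expected normal order statistics.
#' @slot slope,offset coefficients of the central-region line fit.
#' @slot fitRange rankit interval used for the fit.
#'
#' @exportClass NormalProbabilityPlot
setClass("NormalProbabilityPlot",
         representation(deviations = "numeric", rankits = "numeric",
                        slope = "numeric", offset = "numeric",
                        fitRange = "numeric"))

setValidity("NormalProbabilityPlot", function(object) {
  if (length(object@deviations) != length(object@rankits))
    return("deviations and rankits must have equal length")
  if (is.unsorted(object@rankits, strictly = TRUE))
    return("rankits must be strictly increasing")
  TRUE
})

#' Intensity bins for the error-model target function
#'
#' Equal-width bins over the range of per-reflection mean intensities; every
#' measurement of a reflection is assigned to the single bin containing that
#' reflection's mean. Holds per-bin measurement counts, the
#' root-mean-square normalized deviation, the sqrt(count) weights and the
#' scalar target value once evaluated.
#'
#' @slot nBins number of bins.
#' @slot edges numeric vector of length nBins + 1.
#' @slot counts per-bin measurement counts m_b.
#' @slot rmsd per-bin rms of normalized deviations (NA until evaluated).
#' @slot weights per-bin weights w_b = sqrt(m_b).
#' @slot targetValue the evaluated target (NA until evaluated).
#'
#' @exportClass IntensityBinSet
setClass("IntensityBinSet",
         representation(nBins = "integer", edges = "numeric",
                        counts = "integer", rmsd = "numeric",
                        weights = "numeric", targetValue = "numeric"))

#' Merge policy
#'
#' Which merging protocol to apply and its settings. Protocol
#' \code{"unweighted"} uses the plain mean with spread-based errors;
#' \code{"counting_weighted"} uses inverse-variance weights from the
#' photon-counting sigmas; \code{"ev11"} uses weights from the inflated
#' sigmas and requires \code{params}.
#'
#' @slot protocol character scalar.
#' @slot params ErrorModelParams or NULL (required iff protocol "ev11").
#' @slot minMultiplicity groups with fewer measurements are dropped.
#'
#' @exportClass MergePolicy
setClass("MergePolicy",
         representation(protocol = "character", params = "ANY",
                        minMultiplicity = "integer"))

setValidity("MergePolicy", function(object) {
  if (!object@protocol %in% c("unweighted", "counting_weighted", "ev11"))
    return("protocol must be one of unweighted, counting_weighted, ev11")
  if (object@protocol == "ev11" && !is(object@params, "ErrorModelParams"))
    return("protocol 'ev11' requires ErrorModelParams in 'params'")
  if (object@minMultiplicity < 1L)
    return("minMultiplicity must be >= 1")
  TRUE
})

## ---- constructors ----

#' Construct a ReflectionData object
#'
#' @param measurements data.frame with columns
#'   \code{h,k,l,image_id,i_partial,sigma_partial,partiality,stol2} (and
#'   optionally \code{i_full,sigma_full}).
#' @param images data.frame with columns
#'   \code{image_id,scale,wilson_b,wavelength}.
#' @return A \linkS4class{ReflectionData} object.
#' @export
ReflectionData <- function(measurements, images) {
  measurements <- as.data.frame(measurements)
  images <- as.data.frame(images)
  if (!"i_full" %in% names(measurements)) measurements$i_full <- NA_real_
  if (!"sigma_full" %in% names(measurements))
    measurements$sigma_full <- NA_real_
  new("ReflectionData", measurements = measurements, images = images)
}

#' Construct error-model parameters
#'
#' @param sFac,sB,sAdd numeric scalars; see
#'   \linkS4class{ErrorModelParams}.
#' @return An \linkS4class{ErrorModelParams} object.
#' @examples
#' ErrorModelParams(1, 0, 0)   # identity model: sigmas unchanged
#' @export
ErrorModelParams <- function(sFac = 1, sB = 0, sAdd = 0) {
  new("ErrorModelParams", sFac = as.numeric(sFac), sB = as.numeric(sB),
      sAdd = as.numeric(sAdd))
}

#' Construct a merge policy
#'
#' @param protocol \code{"unweighted"}, \code{"counting_weighted"} or
#'   \code{"ev11"}.
#' @param params \linkS4class{ErrorModelParams}, required for
#'   \code{"ev11"}.
#' @param minMultiplicity drop groups with fewer measurements (default 1:
#'   keep all).
#' @return A \linkS4class{MergePolicy} object.
#' @export
MergePolicy <- function(protocol = c("unweighted", "counting_weighted",
                                     "ev11"),
                        params = NULL, minMultiplicity = 1L) {
  protocol <- match.arg(protocol)
  new("MergePolicy", protocol = protocol, params = params,
      minMultiplicity = as.integer(minMultiplicity))
}

## ---- accessors ----

#' @describeIn ReflectionData-class measurement table accessor
#' @param x object
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))

#' @rdname ReflectionData-class
#' @export
setMethod("measurements", "ReflectionData", function(x) x@measurements)

#' @rdname ReflectionGroups-class
#' @param x object
#' @export
setMethod("measurements", "ReflectionGroups", function(x) x@measurements)

#' @describeIn ReflectionData-class image-model table accessor
#' @export
setGeneric("imageModels", function(x) standardGeneric("imageModels"))

#' @rdname ReflectionData-class
#' @export
setMethod("imageModels", "ReflectionData", function(x) x@images)

#' @describeIn ReflectionGroups-class per-group summary table
#' @export
setGeneric("groupTable", function(x) standardGeneric("groupTable"))

#' @rdname ReflectionGroups-class
#' @export
setMethod("groupTable", "ReflectionGroups", function(x) x@groups)

#' @describeIn MergedReflections-class merged table accessor
#' @param x object
#' @export
setGeneric("mergedTable", function(x) standardGeneric("mergedTable"))

#' @rdname MergedReflections-class
#' @export
setMethod("mergedTable", "MergedReflections", function(x) x@table)

#' @describeIn ErrorModelParams-class parameters as a named numeric vector
#' @param x object
#' @export
setGeneric("paramVector", function(x) standardGeneric("paramVector"))

#' @rdname ErrorModelParams-class
#' @export
setMethod("paramVector", "ErrorModelParams", function(x)
  c(s_fac = x@sFac, s_B = x@sB, s_add = x@sAdd))

## ---- show methods ----

setMethod("show", "ReflectionData", function(object) {
  m <- object@measurements
  cat("ReflectionData:", nrow(m), "measurements on",
      nrow(object@images), "images\n")
  if (nrow(m)) {
    cat("  corrected:", if (all(is.na(m$i_full))) "no" else "yes", "\n")
    d <- 1 / (2 * sqrt(pmax(m$stol2, 1e-12)))
    cat(sprintf("  resolution range: %.2f - %.2f A\n", max(d), min(d)))
  }
})

setMethod("show", "ReflectionGroups", function(object) {
  cat("ReflectionGroups:", nrow(object@groups), "unique indices,",
      nrow(object@measurements), "measurements\n")
  cat("  space group:", object@spaceGroup,
      if (object@anomalous) "(anomalous: Friedel mates separate)"
      else "(Friedel mates merged)", "\n")
  if (nrow(object@groups))
    cat(sprintf("  multiplicity: mean %.2f, max %d\n",
                mean(object@groups$n), max(object@groups$n)))
})

setMethod("show", "MergedReflections", function(object) {
  tb <- object@table
  cat("MergedReflections:", nrow(tb), "reflections, protocol",
      object@protocol, "\n")
  ok <- is.finite(tb$sigma_merged) & tb$sigma_merged > 0
  if (any(ok))
    cat(sprintf("  overall <I/sigma> = %.2f\n",
                mean(tb$i_merged[ok] / tb$sigma_merged[ok])))
})

setMethod("show", "ErrorModelParams", function(object) {
  cat(sprintf("ErrorModelParams: s_fac = %.4g, s_B = %.4g, s_add = %.4g\n",
              object@sFac, object@sB, object@sAdd))
})

setMethod("show", "NormalProbabilityPlot", function(object) {
  cat(sprintf(
    "NormalProbabilityPlot: m = %d, slope = %.4g, offset = %.4g (fit on [%g, %g])\n",
    length(object@rankits), object@slope, object@offset,
    object@fitRange[1], object@fitRange[2]))
})

setMethod("show", "IntensityBinSet", function(object) {
  cat("IntensityBinSet:", object@nBins, "bins,",
      sum(object@counts), "measurements\n")
  if (!all(is.na(object@targetValue)))
    cat(sprintf("  target f = %.6g\n", object@targetValue))
})
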