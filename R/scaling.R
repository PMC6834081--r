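# Scaling of partial still-image intensities to full equivalents.
#
# Each measurement of Miller index h on image c is corrected by
#   K = [G_c * exp(-2 * B_c * stol2) * P]^-1,
# i.e. the observed partial intensity is divided by the per-image scale, the
# Wilson falloff and the partiality fraction to recover the full-intensity
# equivalent. K >= 1 whenever P < 1 at G = 1, B = 0, as expected for a
# partially recorded reflection. K is treated as an exact constant: sigma is
# multiplied by the same factor, so per-measurement I/sigma is preserved.

#' Convert detector-unit intensities to photons
#'
#' Divides intensities and sigmas by the detector gain
#' (detector-units-per-photon). Optionally recomputes the counting sigma
#' from the converted counts, in which case I/sigma drops by the square
#' root of the gain (the basis for rescaling any I/sigma filter threshold,
#' see \code{\link{gainAdjustedThreshold}}).
#'
#' @param x a \linkS4class{ReflectionData} object or a numeric vector of
#'   intensities.
#' @param gain positive detector gain.
#' @param recomputeSigma logical; if TRUE, set the counting sigma to
#'   \code{sqrt(max(I, 1))} after conversion instead of dividing the stored
#'   sigma by the gain.
#' @return same class as \code{x}, converted to photon units.
#' @export
setGeneric("gainCorrect",
           function(x, gain, recomputeSigma = FALSE)
             standardGeneric("gainCorrect"))

#' @rdname gainCorrect
#' @export
setMethod("gainCorrect", "numeric", function(x, gain, recomputeSigma) {
  if (!is.finite(gain) || gain <= 0)
    stop("gain must be a positive number", call. = FALSE)
  x / gain
})

#' @rdname gainCorrect
#' @export
setMethod("gainCorrect", "ReflectionData", function(x, gain,
                                                    recomputeSigma) {
  if (!is.finite(gain) || gain <= 0)
    stop("gain must be a positive number", call. = FALSE)
  m <- x@measurements
  m$i_partial <- m$i_partial / gain
  m$sigma_partial <- if (recomputeSigma) {
    sqrt(pmax(m$i_partial, 1))
  } else {
    m$sigma_partial / gain
  }
  if (!all(is.na(m$i_full))) {
    m$i_full <- m$i_full / gain
    m$sigma_full <- if (recomputeSigma) NA_real_ else m$sigma_full / gain
  }
  initialize(x, measurements = m)
})

#' Rescale an I/sigma threshold for a change of gain
#'
#' I/sigma of counting statistics decreases with the square root of the
#' gain, so a per-image resolution-filter threshold chosen for
#' detector-unit data must be divided by \code{sqrt(gain)} when the data
#' are converted to photons.
#'
#' @param threshold threshold on mean I/sigma.
#' @param gain positive detector gain.
#' @return the rescaled threshold.
#' @examples
#' gainAdjustedThreshold(0.5, 25)  # 0.1
#' @export
gainAdjustedThreshold <- function(threshold, gain) {
  if (!is.finite(gain) || gain <= 0)
    stop("gain must be a positive number", call. = FALSE)
  threshold / sqrt(gain)
}

.correctionK <- function(scale, wilsonB, partiality, stol2) {
  1 / (scale * exp(-2 * wilsonB * stol2) * partiality)
}

#' Partiality/scale/Wilson correction factor
#'
#' The multiplicative factor K scaling a partial observed intensity (and
#' its sigma) to the full-intensity equivalent:
#' \deqn{K = [G \exp(-2 B \sin^2\theta/\lambda^2) \, P]^{-1}.}
#'
#' @param image one row of an image-model table (list or data.frame with
#'   \code{scale}, \code{wilson_b}), or a numeric scale if
#'   \code{wilsonB} is given directly.
#' @param measurement one row of a measurement table (list or data.frame
#'   with \code{partiality}, \code{stol2}, and \code{image_id} matching
#'   the image's).
#' @return list with \code{value} (K) and \code{components} (the scale,
#'   Wilson term and partiality it is built from).
#' @examples
#' im <- list(image_id = "a", scale = 2, wilson_b = 0, wavelength = 1.3)
#' m <- list(image_id = "a", partiality = 0.5, stol2 = 0.02)
#' correctionFactor(im, m)$value  # 1: scale 2 and partiality 0.5 cancel
#' @export
correctionFactor <- function(image, measurement) {
  if (!is.null(image$image_id) && !is.null(measurement$image_id) &&
      !identical(as.character(image$image_id),
                 as.character(measurement$image_id)))
    stop("image_id mismatch between image model and measurement",
         call. = FALSE)
  p <- measurement$partiality
  if (any(p <= 0))
    stop("partiality must be > 0 for a defined correction", call. = FALSE)
  wilson <- exp(-2 * image$wilson_b * measurement$stol2)
  k <- 1 / (image$scale * wilson * p)
  list(value = k,
       components = data.frame(scale = image$scale, wilson = wilson,
                               partiality = p))
}

#' Scale partial intensities and sigmas to full equivalents
#'
#' Sets \code{i_full = K * i_partial} and \code{sigma_full = K *
#' sigma_partial} for every measurement, looking up each measurement's
#' image model by \code{image_id}. K is treated as an exact constant, so
#' per-measurement I/sigma is unchanged.
#'
#' @param x a \linkS4class{ReflectionData} object.
#' @return \code{x} with \code{i_full} and \code{sigma_full} filled in.
#' @export
applyCorrections <- function(x) {
  stopifnot(is(x, "ReflectionData"))
  m <- x@measurements
  idx <- match(m$image_id, x@images$image_id)
  if (anyNA(idx)) {
    missing <- unique(m$image_id[is.na(idx)])
    stop("no image model for image_id: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  k <- .correctionK(x@images$scale[idx], x@images$wilson_b[idx],
                    m$partiality, m$stol2)
  m$i_full <- k * m$i_partial
  m$sigma_full <- k * m$sigma_partial
  initialize(x, measurements = m)
}

#' Per-image resolution filter on signal-to-noise
#'
#' For each image, measurements are binned into \code{nBins} equal-volume
#' resolution bins (equal width in 1/d^3, ordered low to high resolution).
#' The image's resolution cutoff is the low-resolution edge of the first
#' bin whose mean I/sigma falls below \code{threshold}; all measurements at
#' higher resolution than the cutoff are removed. Images with no bin below
#' the threshold are kept whole. By default the filter uses the partial
#' (pre-correction) intensities; set \code{useCorrected = TRUE} to filter
#' on full equivalents instead.
#'
#' @param x a \linkS4class{ReflectionData} object.
#' @param threshold mean-I/sigma threshold (default 0.1, appropriate for
#'   photon-unit data; see \code{\link{gainAdjustedThreshold}}).
#' @param nBins number of equal-volume resolution bins per image.
#' @param useCorrected filter on \code{i_full/sigma_full} instead of the
#'   partial values.
#' @return list with \code{data} (the filtered
#'   \linkS4class{ReflectionData}) and \code{cutoffs} (data.frame of
#'   \code{image_id}, d-spacing cutoff in Angstrom — NA when no cutoff
#'   applied — and measurements kept/removed).
#' @export
perImageResolutionFilter <- function(x, threshold = 0.1, nBins = 10L,
                                     useCorrected = FALSE) {
  stopifnot(is(x, "ReflectionData"))
  if (nBins < 1L) stop("nBins must be >= 1", call. = FALSE)
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  m <- x@measurements
  ivals <- if (useCorrected) m$i_full else m$i_partial
  svals <- if (useCorrected) m$sigma_full else m$sigma_partial
  if (useCorrected && all(is.na(ivals)))
    stop("useCorrected = TRUE but corrections have not been applied",
         call. = FALSE)
  isig <- ivals / svals
  res3 <- m$stol2^1.5                     # proportional to 1/d^3
  keep <- rep(TRUE, nrow(m))
  ids <- unique(m$image_id)
  cut_d <- rep(NA_real_, length(ids))
  removed <- integer(length(ids))
  for (ii in seq_along(ids)) {
    rows <- which(m$image_id == ids[ii])
    s <- res3[rows]
    lo <- min(s); hi <- max(s)
    if (hi <= lo) next                    # single resolution shell
    edges <- seq(lo, hi, length.out = nBins + 1L)
    bin <- pmin(pmax(findInterval(s, edges), 1L), nBins)
    cutoff_edge <- NA_real_
    for (b in seq_len(nBins)) {
      inb <- bin == b
      if (!any(inb)) next
      if (mean(isig[rows][inb]) < threshold) {
        cutoff_edge <- edges[b]
        break
      }
    }
    if (!is.na(cutoff_edge)) {
      drop <- s >= cutoff_edge
      keep[rows[drop]] <- FALSE
      removed[ii] <- sum(drop)
      cut_d[ii] <- 1 / (2 * sqrt(cutoff_edge^(2 / 3)))
    }
  }
  cutoffs <- data.frame(image_id = ids, d_cutoff = cut_d,
                        removed = removed)
  list(data = initialize(x, measurements = m[keep, , drop = FALSE]),
       cutoffs = cutoffs)
}
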