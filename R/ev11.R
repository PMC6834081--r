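# SDFAC/SDB/SDADD error model: normalized deviations, normal-probability
# initialization, binned root-mean-square target and its analytic gradient.
#
# The normalized deviation of measurement j among the n replicates of a
# reflection is
#   delta = sqrt((n - 1)/n) * (I_j - <I'_j>) / sigma_j
# with <I'_j> the leave-one-out mean. The (n - 1)/n prefactor is the
# equal-variance correction for the leave-one-out difference, so the
# denominator is the single measurement's sigma only. If the sigmas are
# correct, delta is standard normal. For n = 1 the deviation is defined as
# 0 and the measurement takes no part in the analysis.

#' Leave-one-out mean of a reflection group
#'
#' Mean of all measurements except the j-th. For a single measurement the
#' leave-one-out mean is defined as 0.
#'
#' @param values intensities of one reflection group.
#' @param j index of the held-out measurement.
#' @return the mean of the other \code{n - 1} values.
#' @examples
#' leaveOneOutMean(c(4, 6), 1)  # 6
#' leaveOneOutMean(7, 1)        # 0
#' @export
leaveOneOutMean <- function(values, j) {
  n <- length(values)
  stopifnot(j >= 1L, j <= n)
  if (n == 1L) return(0)
  (n * mean(values) - values[j]) / (n - 1)
}

#' Normalized deviation of one measurement
#'
#' @param values intensities of one reflection group.
#' @param j index of the measurement.
#' @param sigma error estimate for measurement j (counting sigma or
#'   inflated sigma).
#' @return \code{sqrt((n-1)/n) * (values[j] - leaveOneOutMean(values, j)) /
#'   sigma}; exactly 0 when \code{length(values) == 1}.
#' @export
normalizedDeviation <- function(values, j, sigma) {
  n <- length(values)
  if (n == 1L) return(0)
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be finite and > 0 for n >= 2", call. = FALSE)
  sqrt((n - 1) / n) * (values[j] - leaveOneOutMean(values, j)) / sigma
}

#' Normalized deviations for a whole grouped dataset
#'
#' Vectorized leave-one-out normalized deviations for every measurement.
#' Measurements in groups of size 1 get deviation 0. With \code{params}
#' supplied the denominator is the inflated sigma
#' \code{\link{sigmaEv11}} (using each group's plain mean corrected
#' intensity); otherwise the counting sigma is used.
#'
#' @param groups a \linkS4class{ReflectionGroups} object with corrections
#'   applied.
#' @param params optional \linkS4class{ErrorModelParams}.
#' @return numeric vector aligned with \code{measurements(groups)}.
#' @export
normalizedDeviations <- function(groups, params = NULL) {
  stopifnot(is(groups, "ReflectionGroups"))
  m <- groups@measurements
  if (all(is.na(m$i_full)))
    stop("corrections have not been applied", call. = FALSE)
  g <- m$group
  n <- groups@groups$n
  meanI <- .groupMeans(m$i_full, g, n)
  ng <- n[g]
  loo <- ifelse(ng > 1L, (ng * meanI[g] - m$i_full) / (ng - 1L), 0)
  sig <- if (is.null(params)) m$sigma_full
         else sigmaEv11(m$sigma_full, meanI[g], params)
  d <- sqrt((ng - 1) / ng) * (m$i_full - loo) / sig
  d[ng == 1L] <- 0
  d
}

#' Rankits: expected standard-normal order statistics
#'
#' The i-th rankit of a sample of m is
#' \eqn{z_i = \Phi^{-1}[(i - a)/(m + 1 - 2a)]} with \eqn{a = 3/8} for
#' \eqn{m \le 10} and \eqn{a = 1/2} for \eqn{m > 10} (the plotting
#' positions used by \code{qqnorm}). The result is strictly increasing and
#' antisymmetric.
#'
#' @param m sample count.
#' @return numeric vector of length \code{m}.
#' @examples
#' rankits(5)[3]  # 0: the median of the standard normal
#' @export
rankits <- function(m) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be >= 1", call. = FALSE)
  a <- if (m <= 10L) 3 / 8 else 0.5
  stats::qnorm((seq_len(m) - a) / (m + 1 - 2 * a))
}

#' Normal probability plot of a grouped dataset
#'
#' Sorts the leave-one-out normalized deviations (groups of size 1
#' excluded), pairs them with rankits, and fits a straight line to the
#' central region of the plot (rankits in \code{fitRange}, avoiding the
#' outlier-dominated tails). Correctly calibrated sigmas give slope 1 and
#' offset 0.
#'
#' @param x a \linkS4class{ReflectionGroups} object or a numeric vector of
#'   normalized deviations.
#' @param fitRange rankit interval for the line fit (default
#'   \code{c(-0.5, 0.5)}).
#' @param params optional \linkS4class{ErrorModelParams} used for the
#'   deviations when \code{x} is a grouped dataset.
#' @return A \linkS4class{NormalProbabilityPlot} object.
#' @export
normalProbabilityPlot <- function(x, fitRange = c(-0.5, 0.5),
                                  params = NULL) {
  d <- if (is(x, "ReflectionGroups")) {
    dd <- normalizedDeviations(x, params)
    ng <- x@groups$n[x@measurements$group]
    dd[ng > 1L]
  } else {
    as.numeric(x)
  }
  if (length(d) < 2L)
    stop("need at least 2 deviations for a normal probability plot",
         call. = FALSE)
  d <- sort(d)
  z <- rankits(length(d))
  plt <- new("NormalProbabilityPlot", deviations = d, rankits = z,
             slope = NA_real_, offset = NA_real_, fitRange = fitRange)
  fit <- fitNppLine(plt, fitRange[1], fitRange[2])
  initialize(plt, slope = fit[["slope"]], offset = fit[["offset"]])
}

#' Fit the central line of a normal probability plot
#'
#' Ordinary least squares of the sorted deviations on the rankits,
#' restricted to rankits in \code{[lo, hi]}.
#'
#' @param plot a \linkS4class{NormalProbabilityPlot}.
#' @param lo,hi rankit interval (defaults -0.5, 0.5).
#' @return named numeric vector \code{c(slope =, offset =)}.
#' @export
fitNppLine <- function(plot, lo = -0.5, hi = 0.5) {
  stopifnot(is(plot, "NormalProbabilityPlot"))
  sel <- plot@rankits >= lo & plot@rankits <= hi
  if (sum(sel) < 2L)
    stop("fewer than 2 points with rankit in [", lo, ", ", hi,
         "]; widen the fit range", call. = FALSE)
  z <- plot@rankits[sel]
  d <- plot@deviations[sel]
  fit <- stats::lm.fit(cbind(1, z), d)
  c(slope = unname(fit$coefficients[2]),
    offset = unname(fit$coefficients[1]))
}

#' Initialize error-model parameters from the normal-probability line
#'
#' sFac is set to the slope; sAdd to the offset (clamped at 0, both terms
#' being non-negative scales); sB to \code{sqrt(sAdd)}.
#'
#' @param slope,offset central-line fit of the normal probability plot.
#' @return An \linkS4class{ErrorModelParams} object.
#' @examples
#' paramVector(initializeParams(1.44, 0.45))  # s_B = sqrt(0.45) = 0.67
#' @export
initializeParams <- function(slope, offset) {
  sAdd <- max(offset, 0)
  ErrorModelParams(sFac = slope, sB = sqrt(sAdd), sAdd = sAdd)
}

#' Inflated sigma under the SDFAC/SDB/SDADD model
#'
#' \deqn{\sigma' = s_{fac} [\sigma^2 + s_B \langle I_h\rangle +
#'   (s_{add} \langle I_h\rangle)^2]^{1/2}}
#' where \eqn{\langle I_h\rangle} is the plain mean of the corrected
#' measurements of the reflection the measurement belongs to. A negative
#' radicand (possible for negative sB) is clamped to
#' \code{sFac * sigma}; the number of clamped values is attached as
#' attribute \code{"nClamped"} when nonzero.
#'
#' @param sigma counting sigma(s) of the measurement(s).
#' @param meanI mean corrected intensity of the parent reflection(s).
#' @param params an \linkS4class{ErrorModelParams} object.
#' @return inflated sigma(s).
#' @examples
#' sigmaEv11(3, 16, ErrorModelParams(2, 1, 0.5))  # 2 * sqrt(89)
#' @export
sigmaEv11 <- function(sigma, meanI, params) {
  stopifnot(is(params, "ErrorModelParams"))
  q <- sigma^2 + params@sB * meanI + (params@sAdd * meanI)^2
  bad <- q <= 0
  out <- params@sFac * sqrt(ifelse(bad, sigma^2, q))
  if (any(bad)) attr(out, "nClamped") <- sum(bad)
  out
}

## ---- binned target ----

# Precomputed, parameter-independent view of a grouped dataset for the
# error-model target: per measurement (groups of size >= 2 only) the
# leave-one-out numerator, counting sigma, parent mean intensity and bin
# index, plus per-bin counts and weights.
errorModelData <- function(groups, nBins = 100L) {
  stopifnot(is(groups, "ReflectionGroups"))
  m <- groups@measurements
  if (all(is.na(m$i_full)))
    stop("corrections have not been applied", call. = FALSE)
  g <- m$group
  n <- groups@groups$n
  meanI <- .groupMeans(m$i_full, g, n)
  ng <- n[g]
  keep <- ng > 1L
  if (!any(keep))
    stop("no reflection has multiplicity >= 2; cannot build error model",
         call. = FALSE)
  ii <- m$i_full[keep]
  ngk <- ng[keep]
  mik <- meanI[g][keep]
  loo <- (ngk * mik - ii) / (ngk - 1L)
  num <- sqrt((ngk - 1) / ngk) * (ii - loo)
  mis <- meanI[n > 1L]              # distinct group means entering bins
  lo <- min(mis)
  hi <- max(mis)
  nBins <- as.integer(nBins)
  if (hi <= lo) {
    warning("degenerate mean-intensity range; using a single bin")
    nBins <- 1L
    edges <- c(lo, lo + 1)
    bin <- rep(1L, sum(keep))
  } else {
    width <- (hi - lo) / nBins
    edges <- lo + width * 0:nBins
    bin <- pmin(as.integer(floor((mik - lo) / width)) + 1L, nBins)
  }
  counts <- tabulate(bin, nBins)
  list(num = num, sigma = m$sigma_full[keep], meanI = mik, bin = bin,
       nBins = nBins, edges = edges, counts = counts,
       weights = sqrt(counts))
}

.asEmData <- function(x, nBins = 100L) {
  if (is(x, "ReflectionGroups")) errorModelData(x, nBins) else x
}

#' Intensity bins for the error-model target
#'
#' Builds the equal-width bins over the range of per-reflection mean
#' corrected intensities. All measurements of a reflection land in the
#' single bin containing that reflection's mean (top edge inclusive);
#' groups of size 1 are excluded since their normalized deviation is
#' identically 0.
#'
#' @param groups a \linkS4class{ReflectionGroups} object with corrections
#'   applied.
#' @param nBins number of bins (default 100).
#' @return An \linkS4class{IntensityBinSet} skeleton (rmsd and target
#'   unset).
#' @export
binMeasurements <- function(groups, nBins = 100L) {
  d <- errorModelData(groups, nBins)
  new("IntensityBinSet", nBins = d$nBins, edges = d$edges,
      counts = as.integer(d$counts), rmsd = rep(NA_real_, d$nBins),
      weights = d$weights, targetValue = NA_real_)
}

# delta^2 for every retained measurement at the given parameters, plus the
# quantities the gradient reuses. Clamped measurements (negative radicand)
# fall back to sFac * sigma and contribute no sB/sAdd gradient.
.deltaSq <- function(par, d) {
  sFac <- par[1]; sB <- par[2]; sAdd <- par[3]
  q <- d$sigma^2 + sB * d$meanI + (sAdd * d$meanI)^2
  bad <- q <= 0
  qeff <- ifelse(bad, d$sigma^2, q)
  dsq <- d$num^2 / (sFac^2 * qeff)
  list(dsq = dsq, qeff = qeff, bad = bad)
}

#' Error-model target function
#'
#' The weighted sum over intensity bins of the squared departure of the
#' per-bin root-mean-square normalized deviation from 1:
#' \deqn{f = \sum_b \sqrt{m_b}\,( \mathrm{rmsd}_b - 1 )^2,}
#' with the deviations computed using the inflated sigmas at the given
#' parameters. Empty bins contribute 0.
#'
#' @param params an \linkS4class{ErrorModelParams} object or a numeric
#'   3-vector (sFac, sB, sAdd).
#' @param groups a \linkS4class{ReflectionGroups} object (or the
#'   precomputed data from an earlier call, for internal reuse).
#' @param nBins number of intensity bins (default 100).
#' @return the scalar target value.
#' @export
targetFunction <- function(params, groups, nBins = 100L) {
  par <- if (is(params, "ErrorModelParams")) paramVector(params)
         else as.numeric(params)
  d <- .asEmData(groups, nBins)
  ds <- .deltaSq(par, d)
  s <- rep(0, d$nBins)
  agg <- rowsum(ds$dsq, d$bin, reorder = TRUE)
  s[as.integer(rownames(agg))] <- agg
  nz <- d$counts > 0L
  rmsd <- sqrt(s[nz] / d$counts[nz])
  sum(d$weights[nz] * (rmsd - 1)^2)
}

#' Analytic gradient of the error-model target
#'
#' Chain-rule gradient of \code{\link{targetFunction}} with respect to
#' (sFac, sB, sAdd). At a point where every per-bin rmsd equals 1 the
#' gradient vanishes.
#'
#' @inheritParams targetFunction
#' @return numeric 3-vector \code{(df/dsFac, df/dsB, df/dsAdd)}.
#' @export
targetGradient <- function(params, groups, nBins = 100L) {
  par <- if (is(params, "ErrorModelParams")) paramVector(params)
         else as.numeric(params)
  d <- .asEmData(groups, nBins)
  ds <- .deltaSq(par, d)
  dsq <- ds$dsq
  # per-measurement derivatives of delta^2
  g_fac <- -2 * dsq / par[1]
  ratio <- ifelse(ds$bad, 0, dsq / ds$qeff)
  g_b <- -ratio * d$meanI
  g_add <- -ratio * 2 * par[3] * d$meanI^2
  s <- s1 <- s2 <- s3 <- rep(0, d$nBins)
  agg <- rowsum(cbind(dsq, g_fac, g_b, g_add), d$bin, reorder = TRUE)
  rows <- as.integer(rownames(agg))
  s[rows] <- agg[, 1]; s1[rows] <- agg[, 2]
  s2[rows] <- agg[, 3]; s3[rows] <- agg[, 4]
  nz <- d$counts > 0L & s > 0
  rmsd <- sqrt(s[nz] / d$counts[nz])
  # d/dp (rmsd - 1)^2 = (rmsd - 1) / (rmsd * m_b) * sum_k d(delta_k^2)/dp
  coef <- d$weights[nz] * (rmsd - 1) / (rmsd * d$counts[nz])
  c(sum(coef * s1[nz]), sum(coef * s2[nz]), sum(coef * s3[nz]))
}
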