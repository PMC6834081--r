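# Merging of corrected full-equivalent intensities, three protocols.
#
# Protocol 1 (unweighted): plain mean; error from the observed spread,
#   sigma_res = sd (n - 1 denominator), sigma_h = sigma_res / sqrt(n).
# Protocol 2 (counting-weighted): inverse-variance weights from the
#   photon-counting sigmas, sigma_h = (sum w)^(-1/2).
# Protocol 3 (ev11): as protocol 2, with weights 1 / sigma_Ev11^2 from the
#   refined error model.

#' Unweighted merge of one reflection group
#'
#' Mean intensity, spread-based residual sigma (standard deviation with
#' n - 1 denominator) and standard error of the mean. For a single
#' measurement the spread is undefined; its own sigma is reported instead
#' and flagged (spread-based errors are unreliable at low redundancy).
#'
#' @param intensities corrected intensities of one reflection group.
#' @param sigmas per-measurement sigmas; only used as the fallback error
#'   when \code{length(intensities) == 1}.
#' @return list with \code{i_merged}, \code{sigma_res},
#'   \code{sigma_merged}, \code{multiplicity}, \code{flagged} (TRUE when
#'   the n = 1 fallback was used).
#' @examples
#' mergeUnweighted(c(1, 2, 3))  # mean 2, sd 1, sem 1/sqrt(3)
#' @export
mergeUnweighted <- function(intensities, sigmas = NULL) {
  n <- length(intensities)
  stopifnot(n >= 1L)
  ih <- mean(intensities)
  if (n == 1L) {
    s <- if (is.null(sigmas)) NA_real_ else sigmas[1]
    return(list(i_merged = ih, sigma_res = NA_real_, sigma_merged = s,
                multiplicity = 1L, flagged = TRUE))
  }
  sres <- sqrt(sum((intensities - ih)^2) / (n - 1))
  list(i_merged = ih, sigma_res = sres, sigma_merged = sres / sqrt(n),
       multiplicity = n, flagged = FALSE)
}

#' Inverse-variance weights from counting sigmas
#'
#' @param sigmas positive per-measurement error estimates.
#' @return weights \code{1 / sigmas^2}.
#' @export
countingWeights <- function(sigmas) {
  if (any(!is.finite(sigmas) | sigmas <= 0))
    stop("all sigmas must be finite and > 0", call. = FALSE)
  1 / sigmas^2
}

#' Weighted merge of one reflection group
#'
#' Weighted mean intensity with the propagated weighted standard error
#' \code{(sum w)^(-1/2)}.
#'
#' @param intensities corrected intensities of one reflection group.
#' @param weights positive weights, one per measurement (typically
#'   \code{\link{countingWeights}} or 1/sigma_Ev11^2).
#' @return list with \code{i_merged}, \code{sigma_merged},
#'   \code{multiplicity}.
#' @export
mergeWeighted <- function(intensities, weights) {
  if (length(intensities) != length(weights))
    stop("intensities and weights must have the same length",
         call. = FALSE)
  if (any(!is.finite(weights) | weights <= 0))
    stop("weights must be finite and > 0", call. = FALSE)
  sw <- sum(weights)
  list(i_merged = sum(weights * intensities) / sw,
       sigma_merged = 1 / sqrt(sw),
       multiplicity = length(intensities))
}

# Vectorized group means via rowsum on the integer group key.
.groupMeans <- function(values, group, n) {
  as.vector(rowsum(values, group, reorder = TRUE)) / n
}

#' Merge a grouped dataset under a merge policy
#'
#' Applies the selected protocol to every reflection group. Protocol
#' \code{"unweighted"} uses \code{\link{mergeUnweighted}};
#' \code{"counting_weighted"} uses \code{\link{mergeWeighted}} with
#' \code{\link{countingWeights}} of the full-equivalent sigmas;
#' \code{"ev11"} uses weights \code{1/sigmaEv11^2} with the policy's
#' error-model parameters (the per-reflection mean intensity entering the
#' inflation is the plain mean of the corrected measurements). Groups below
#' the policy's \code{minMultiplicity} are dropped.
#'
#' @param groups a \linkS4class{ReflectionGroups} object with corrections
#'   applied.
#' @param policy a \linkS4class{MergePolicy}.
#' @param weightedSem for the weighted protocols: \code{"propagated"}
#'   (default, \code{(sum w)^(-1/2)}) or \code{"spread"} (weighted
#'   spread-based standard error, for sensitivity analysis).
#' @return A \linkS4class{MergedReflections} object.
#' @export
mergeDataset <- function(groups, policy = MergePolicy("unweighted"),
                         weightedSem = c("propagated", "spread")) {
  stopifnot(is(groups, "ReflectionGroups"), is(policy, "MergePolicy"))
  validObject(policy)
  weightedSem <- match.arg(weightedSem)
  m <- groups@measurements
  if (all(is.na(m$i_full)))
    stop("corrections have not been applied; run applyCorrections() first",
         call. = FALSE)
  g <- m$group
  gt <- groups@groups
  n <- gt$n
  meanI <- .groupMeans(m$i_full, g, n)
  meanStol2 <- .groupMeans(m$stol2, g, n)
  if (policy@protocol == "unweighted") {
    dev2 <- (m$i_full - meanI[g])^2
    ss <- as.vector(rowsum(dev2, g, reorder = TRUE))
    sres <- ifelse(n > 1, sqrt(ss / pmax(n - 1, 1)), NA_real_)
    sigma <- sres / sqrt(n)
    # n = 1: spread undefined, fall back to the measurement's own sigma
    single <- n == 1L
    if (any(single)) {
      own <- m$sigma_full[match(gt$group[single], g)]
      sigma[single] <- own
    }
    ih <- meanI
    flagged <- single
  } else {
    w <- if (policy@protocol == "counting_weighted") {
      countingWeights(m$sigma_full)
    } else {
      p <- policy@params
      denom <- p@sFac^2 * (m$sigma_full^2 + p@sB * meanI[g] +
                             (p@sAdd * meanI[g])^2)
      bad <- denom <= 0
      if (any(bad)) denom[bad] <- (p@sFac * m$sigma_full[bad])^2
      1 / denom
    }
    sw <- as.vector(rowsum(w, g, reorder = TRUE))
    ih <- as.vector(rowsum(w * m$i_full, g, reorder = TRUE)) / sw
    if (weightedSem == "propagated") {
      sigma <- 1 / sqrt(sw)
    } else {
      dev2 <- w * (m$i_full - ih[g])^2
      ss <- as.vector(rowsum(dev2, g, reorder = TRUE))
      sigma <- ifelse(n > 1, sqrt(ss / (pmax(n - 1, 1) * sw)),
                      1 / sqrt(sw))
    }
    flagged <- rep(FALSE, length(n))
  }
  tb <- data.frame(h = gt$h, k = gt$k, l = gt$l, i_merged = ih,
                   sigma_merged = sigma, multiplicity = n,
                   mean_raw = meanI, stol2 = meanStol2,
                   flagged = flagged)
  keep <- n >= policy@minMultiplicity
  tb <- tb[keep, , drop = FALSE]
  rownames(tb) <- NULL
  new("MergedReflections", table = tb, protocol = policy@protocol)
}
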