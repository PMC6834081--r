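# Merging diagnostics: half-dataset correlation, resolution-binned
# signal-to-noise tables, intensity / signal-to-noise histograms.

.subsetGroups <- function(groups, rows) {
  m <- groups@measurements[rows, , drop = FALSE]
  gt <- groups@groups
  n <- tabulate(m$group, nbins = max(gt$group))
  keep <- n[gt$group] > 0L
  gt <- gt[keep, , drop = FALSE]
  gt$n <- n[gt$group]
  new("ReflectionGroups", measurements = m, groups = gt,
      spaceGroup = groups@spaceGroup, anomalous = groups@anomalous)
}

#' Half-dataset correlation coefficient (CC1/2)
#'
#' Randomly splits each reflection group's measurements into two halves
#' (the odd measurement of odd-multiplicity groups is assigned to a random
#' half), merges each half under the given policy and returns the Pearson
#' correlation of the two half-dataset merged intensities. Reproducible
#' from \code{seed}.
#'
#' @param groups a \linkS4class{ReflectionGroups} object with corrections
#'   applied; only groups with multiplicity >= 2 contribute.
#' @param seed RNG seed for the split.
#' @param policy \linkS4class{MergePolicy} used for merging the halves
#'   (default unweighted).
#' @return the correlation coefficient, or NA (with a warning) if fewer
#'   than 3 groups are usable.
#' @export
ccHalf <- function(groups, seed = 1L, policy = MergePolicy("unweighted")) {
  stopifnot(is(groups, "ReflectionGroups"))
  m <- groups@measurements
  n <- groups@groups$n
  usable <- groups@groups$group[n >= 2L]
  if (length(usable) < 3L) {
    warning("fewer than 3 groups with multiplicity >= 2; CC1/2 undefined")
    return(NA_real_)
  }
  .runWithSeed(seed, function() {
    rows <- which(m$group %in% usable)
    g <- m$group[rows]
    ord <- rows[order(g, stats::runif(length(rows)))]
    g2 <- m$group[ord]
    pos <- sequence(tabulate(g2)[unique(g2)])
    ng <- n[g2]
    # split point: n/2, odd groups get the extra member on a random side
    coin <- stats::rbinom(max(m$group), 1L, 0.5)
    cut <- floor(ng / 2) + (ng %% 2L) * coin[g2]
    inA <- pos <= cut
    halfA <- mergeDataset(.subsetGroups(groups, ord[inA]), policy)
    halfB <- mergeDataset(.subsetGroups(groups, ord[!inA]), policy)
    ta <- halfA@table
    tb <- halfB@table
    key <- function(t) paste(t$h, t$k, t$l)
    idx <- match(key(ta), key(tb))
    ok <- !is.na(idx)
    if (sum(ok) < 3L) {
      warning("fewer than 3 paired half-dataset reflections")
      return(NA_real_)
    }
    stats::cor(ta$i_merged[ok], tb$i_merged[idx[ok]])
  })
}

#' Resolution-binned merged statistics
#'
#' Bins merged reflections into equal-volume resolution shells (equal
#' width in 1/d^3) and tabulates per-shell mean intensity, mean sigma,
#' mean I/sigma and reflection count.
#'
#' @param merged a \linkS4class{MergedReflections} object (table must
#'   carry \code{stol2}).
#' @param nBins number of resolution shells.
#' @return data.frame with columns \code{d_max, d_min, n, mean_i,
#'   mean_sigma, mean_i_over_sigma}.
#' @export
iOverSigmaTable <- function(merged, nBins = 10L) {
  stopifnot(is(merged, "MergedReflections"))
  tb <- merged@table
  if (is.null(tb$stol2))
    stop("merged table carries no resolution information", call. = FALSE)
  s <- tb$stol2^1.5
  lo <- min(s); hi <- max(s)
  if (hi <= lo) {
    edges <- c(lo, hi + 1)
    nBins <- 1L
  } else {
    edges <- seq(lo, hi, length.out = nBins + 1L)
  }
  bin <- pmin(pmax(findInterval(s, edges), 1L), nBins)
  d_edge <- 1 / (2 * sqrt(pmax(edges, 1e-300)^(2 / 3)))
  out <- data.frame(bin = seq_len(nBins),
                    d_max = d_edge[seq_len(nBins)],
                    d_min = d_edge[seq_len(nBins) + 1L],
                    n = as.integer(tabulate(bin, nBins)))
  isig <- tb$i_merged / tb$sigma_merged
  agg <- function(v) {
    s <- rep(NA_real_, nBins)
    a <- rowsum(v, bin, reorder = TRUE)
    rows <- as.integer(rownames(a))
    s[rows] <- a / out$n[rows]
    s
  }
  out$mean_i <- agg(tb$i_merged)
  out$mean_sigma <- agg(tb$sigma_merged)
  out$mean_i_over_sigma <- agg(isig)
  out
}

#' 2-D histogram of I/sigma versus I
#'
#' Counts unmerged measurements on a fixed grid over (intensity,
#' I/sigma). Total counts are conserved when the break ranges span the
#' data (the defaults do).
#'
#' @param intensities,sigmas unmerged intensities and error estimates
#'   (e.g. corrected intensities with counting or inflated sigmas).
#' @param iBreaks,isigBreaks either a break count or an explicit vector
#'   of break points for each axis.
#' @return list with \code{counts} (matrix, intensity rows by I/sigma
#'   columns), \code{iEdges}, \code{isigEdges}.
#' @export
iVsIsigmaHistogram <- function(intensities, sigmas, iBreaks = 50L,
                               isigBreaks = 50L) {
  if (length(intensities) != length(sigmas))
    stop("intensities and sigmas must have the same length",
         call. = FALSE)
  if (any(sigmas <= 0)) stop("sigmas must be > 0", call. = FALSE)
  isig <- intensities / sigmas
  mkEdges <- function(breaks, v) {
    if (length(breaks) > 1L) return(breaks)
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = breaks + 1L)
  }
  ie <- mkEdges(iBreaks, intensities)
  se <- mkEdges(isigBreaks, isig)
  bi <- findInterval(intensities, ie, rightmost.closed = TRUE)
  bs <- findInterval(isig, se, rightmost.closed = TRUE)
  ok <- bi >= 1L & bi <= length(ie) - 1L & bs >= 1L & bs <= length(se) - 1L
  counts <- matrix(0L, length(ie) - 1L, length(se) - 1L)
  if (any(ok)) {
    t2 <- table(factor(bi[ok], seq_len(length(ie) - 1L)),
                factor(bs[ok], seq_len(length(se) - 1L)))
    counts <- matrix(as.integer(t2), nrow = length(ie) - 1L)
  }
  list(counts = counts, iEdges = ie, isigEdges = se)
}
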