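# Quasi-Newton refinement of the error-model parameters.

#' Refine the error-model parameters
#'
#' Minimizes the binned root-mean-square target
#' (\code{\link{targetFunction}}) over (sFac, sB, sAdd) with the
#' limited-memory BFGS quasi-Newton minimizer (\code{stats::optim},
#' method \code{"L-BFGS-B"}) using the analytic gradient
#' (\code{\link{targetGradient}}). All three parameters are bounded below
#' at zero (refined values of exactly 0 are reported at the bound).
#'
#' When no starting point is supplied, two deterministic quasi-Newton
#' runs are performed and the lower final target wins: one from the
#' normal-probability-plot initialization
#' (\code{\link{initializeParams}}), which encodes a gain-dominated error
#' hypothesis (all inflation in sFac), and one from the complementary
#' counting-calibrated hypothesis (sFac = 1, inflation in sAdd). The two
#' hypotheses sit in different basins of the target when
#' intensity-proportional error dominates, and a single slope-based start
#' can stall in the wrong one. Because sAdd enters the model only
#' through its square, its gradient vanishes identically at sAdd = 0, so
#' zero sAdd starts are lifted to a small floor (0.02) to keep the axis
#' searchable.
#'
#' @param groups a \linkS4class{ReflectionGroups} object with corrections
#'   applied.
#' @param init optional \linkS4class{ErrorModelParams} starting point;
#'   default: initialize from the normal probability plot.
#' @param nBins number of intensity bins (default 100).
#' @param maxIter iteration cap (default 200).
#' @param gtol projected-gradient tolerance (default 1e-8).
#' @param ftol relative function-decrease tolerance (default 1e-10).
#' @param fitRange rankit interval for the initialization line fit.
#' @return list with components \code{params} (refined
#'   \linkS4class{ErrorModelParams}), \code{init} (starting parameters),
#'   \code{trace} (target value at the start and at each accepted,
#'   improving step — non-increasing by construction), \code{nSteps}
#'   (\code{length(trace) - 1}), \code{initialF}, \code{finalF},
#'   \code{convergence} (0 = converged), \code{message},
#'   \code{bins} (the evaluated \linkS4class{IntensityBinSet} at the
#'   solution) and \code{npp} (the initialization plot, when used).
#' @export
refineErrorModel <- function(groups, init = NULL, nBins = 100L,
                             maxIter = 200L, gtol = 1e-8, ftol = 1e-10,
                             fitRange = c(-0.5, 0.5)) {
  d <- .asEmData(groups, nBins)
  npp <- NULL
  starts <- list()
  if (is.null(init)) {
    if (!is(groups, "ReflectionGroups"))
      stop("init must be supplied when groups is precomputed data",
           call. = FALSE)
    npp <- normalProbabilityPlot(groups, fitRange = fitRange)
    init <- initializeParams(npp@slope, npp@offset)
    alt <- ErrorModelParams(1, 0, max(npp@offset, 0.02))
    starts <- list(init, alt)
  } else {
    stopifnot(is(init, "ErrorModelParams"))
    validObject(init)
    starts <- list(init)
  }
  runOne <- function(start) {
    p0 <- unname(paramVector(start))
    p0[1] <- max(p0[1], 1e-6)
    if (length(starts) > 1L) p0[3] <- max(p0[3], 0.02)
    state <- new.env(parent = emptyenv())
    state$best <- Inf
    state$trace <- numeric()
    fn <- function(p) {
      f <- targetFunction(p, d)
      if (!is.finite(f)) {
        ds <- .deltaSq(p, d)
        badbin <- unique(d$bin[!is.finite(ds$dsq)])
        stop("non-finite target at parameters (",
             paste(signif(p, 6), collapse = ", "),
             "); offending bin(s): ",
             paste(utils::head(badbin, 5), collapse = ", "),
             call. = FALSE)
      }
      if (f < state$best) {
        state$trace <- c(state$trace, f)
        state$best <- f
      }
      f
    }
    gr <- function(p) {
      g <- targetGradient(p, d)
      if (any(!is.finite(g)))
        stop("non-finite gradient at parameters (",
             paste(signif(p, 6), collapse = ", "), ")", call. = FALSE)
      g
    }
    opt <- stats::optim(p0, fn, gr, method = "L-BFGS-B",
                        lower = c(1e-6, 0, 0),
                        control = list(maxit = as.integer(maxIter),
                                       pgtol = gtol,
                                       factr = ftol /
                                         .Machine$double.eps))
    list(opt = opt, trace = state$trace)
  }
  runs <- lapply(starts, runOne)
  best <- runs[[which.min(vapply(runs, function(r) r$opt$value,
                                 numeric(1)))]]
  opt <- best$opt
  params <- ErrorModelParams(opt$par[1], opt$par[2], opt$par[3])
  binset <- evaluateBins(params, d)
  list(params = params, init = init, trace = best$trace,
       nSteps = length(best$trace) - 1L,
       initialF = best$trace[1], finalF = opt$value,
       convergence = opt$convergence, message = opt$message,
       bins = binset, npp = npp)
}

#' Evaluate the intensity bins at given parameters
#'
#' Fills an \linkS4class{IntensityBinSet} with the per-bin rms normalized
#' deviations and the scalar target value at \code{params}.
#'
#' @inheritParams targetFunction
#' @return An \linkS4class{IntensityBinSet} with \code{rmsd} and
#'   \code{targetValue} set.
#' @export
evaluateBins <- function(params, groups, nBins = 100L) {
  par <- if (is(params, "ErrorModelParams")) paramVector(params)
         else as.numeric(params)
  d <- .asEmData(groups, nBins)
  ds <- .deltaSq(par, d)
  s <- rep(0, d$nBins)
  agg <- rowsum(ds$dsq, d$bin, reorder = TRUE)
  s[as.integer(rownames(agg))] <- agg
  rmsd <- rep(NA_real_, d$nBins)
  nz <- d$counts > 0L
  rmsd[nz] <- sqrt(s[nz] / d$counts[nz])
  f <- sum(d$weights[nz] * (rmsd[nz] - 1)^2)
  new("IntensityBinSet", nBins = d$nBins, edges = d$edges,
      counts = as.integer(d$counts), rmsd = rmsd, weights = d$weights,
      targetValue = f)
}

#' Overall rms of normalized deviations
#'
#' Root-mean-square of the leave-one-out normalized deviations over all
#' measurements in groups of multiplicity >= 2, at the given error-model
#' parameters (identity model by default). Close to 1 when the sigmas
#' explain the observed spread.
#'
#' @param groups a \linkS4class{ReflectionGroups} object.
#' @param params \linkS4class{ErrorModelParams} (default identity).
#' @return scalar rms.
#' @export
overallRmsd <- function(groups, params = ErrorModelParams(1, 0, 0)) {
  stopifnot(is(groups, "ReflectionGroups"))
  dd <- normalizedDeviations(groups, params)
  ng <- groups@groups$n[groups@measurements$group]
  sqrt(mean(dd[ng > 1L]^2))
}
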