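test_that("leave-one-out mean matches its algebraic identity", {
  expect_equal(leaveOneOutMean(c(4, 6), 1), 6)
  expect_equal(leaveOneOutMean(7, 1), 0)
  set.seed(31)
  for (rep in 1:25) {
    v <- rnorm(sample(2:10, 1), 10, 4)
    j <- sample(length(v), 1)
    expect_equal(leaveOneOutMean(v, j), mean(v[-j]), tolerance = 1e-12)
    expect_equal(leaveOneOutMean(v, j),
                 (length(v) * mean(v) - v[j]) / (length(v) - 1),
                 tolerance = 1e-12)
  }
})

test_that("normalized deviation handles the n = 1 and zero-spread cases", {
  expect_equal(normalizedDeviation(42, 1, 3), 0)
  expect_equal(normalizedDeviation(c(10, 10), 1, 2), 0)
  expect_equal(normalizedDeviation(c(10, 10), 2, 0.1), 0)
  expect_error(normalizedDeviation(c(1, 2), 1, 0), "sigma")
})

test_that("(n-1)/n prefactor calibrates the deviations to unit variance", {
  # Monte-Carlo oracle: pure Gaussian groups with the true sigma supplied
  # must give empirical SD of delta equal to 1 within 3 standard errors
  set.seed(77)
  n_per <- 4L
  n_grp <- 25000L                       # 1e5 deviations
  x <- matrix(rnorm(n_per * n_grp, 100, 2), n_grp, n_per)
  d <- vapply(seq_len(n_per), function(j) {
    loo <- (rowSums(x) - x[, j]) / (n_per - 1)
    sqrt((n_per - 1) / n_per) * (x[, j] - loo) / 2
  }, numeric(n_grp))
  m <- length(d)
  se <- 1 / sqrt(2 * m)                 # SE of an SD estimate
  expect_lt(abs(sd(d) - 1), 3 * se)
  # without the prefactor the spread is inflated by sqrt(n/(n-1))
  expect_gt(sd(d / sqrt((n_per - 1) / n_per)), 1 + 3 * se)
})

test_that("rankits are normal order-statistic plotting positions", {
  z5 <- rankits(5)
  a <- 3 / 8
  expect_equal(z5, qnorm(((1:5) - a) / (5 + 1 - 2 * a)),
               tolerance = 1e-12)
  expect_equal(z5[3], 0)                         # exact normal median
  # second and fourth rankits approximate the outer quartiles
  expect_lt(abs(z5[2] - qnorm(0.25)), 0.2)
  expect_lt(abs(z5[4] - qnorm(0.75)), 0.2)
  expect_equal(rankits(1), 0)
  expect_error(rankits(0), "m")
  # antisymmetry for all m
  for (m in c(2, 3, 7, 10, 11, 20, 49)) {
    z <- rankits(m)
    expect_equal(z + rev(z), rep(0, m), tolerance = 1e-12)
    expect_true(all(diff(z) > 0))
  }
})

test_that("rankits match a numerical inverse-CDF oracle for m in 1..50", {
  # oracle: invert pnorm by bisection, independent of qnorm
  invPhi <- function(p) uniroot(function(z) pnorm(z) - p, c(-10, 10),
                                tol = 1e-13)$root
  for (m in 1:50) {
    a <- if (m <= 10) 3 / 8 else 0.5
    expected <- vapply(seq_len(m),
                       function(i) invPhi((i - a) / (m + 1 - 2 * a)),
                       numeric(1))
    expect_equal(rankits(m), expected, tolerance = 1e-10)
  }
})

test_that("the central line fit recovers exact and sampled relations", {
  z <- rankits(200)
  plt <- new("NormalProbabilityPlot", deviations = z, rankits = z,
             slope = NA_real_, offset = NA_real_,
             fitRange = c(-0.5, 0.5))
  fit <- fitNppLine(plt)
  expect_equal(unname(fit["slope"]), 1, tolerance = 1e-10)
  expect_equal(unname(fit["offset"]), 0, tolerance = 1e-10)
  plt2 <- new("NormalProbabilityPlot", deviations = 2 * z + 0.3,
              rankits = z, slope = NA_real_, offset = NA_real_,
              fitRange = c(-0.5, 0.5))
  fit2 <- fitNppLine(plt2)
  expect_equal(unname(fit2["slope"]), 2, tolerance = 1e-10)
  expect_equal(unname(fit2["offset"]), 0.3, tolerance = 1e-10)
  expect_error(fitNppLine(plt, 0.001, 0.0012), "widen")
  # Monte-Carlo: N(0, 1.5) deviations give slope ~1.5, offset ~0
  set.seed(55)
  plt3 <- normalProbabilityPlot(rnorm(1e5, 0, 1.5))
  expect_lt(abs(plt3@slope - 1.5), 0.05)
  expect_lt(abs(plt3@offset), 0.05)
})

test_that("initialization follows slope/offset/sqrt(offset)", {
  p <- paramVector(initializeParams(1, 0))
  expect_equal(unname(p), c(1, 0, 0))
  p <- paramVector(initializeParams(1.44, 0.45))
  expect_equal(unname(p[["s_fac"]]), 1.44)
  expect_equal(unname(p[["s_add"]]), 0.45)
  expect_equal(unname(p[["s_B"]]), sqrt(0.45), tolerance = 1e-12)
  expect_equal(round(unname(p[["s_B"]]), 2), 0.67)
  p2 <- paramVector(initializeParams(7.47, 0.52))
  expect_equal(round(unname(p2[["s_B"]]), 2), 0.72)
  # negative offsets clamp the non-negative scale terms to 0
  p3 <- paramVector(initializeParams(2, -0.3))
  expect_equal(unname(p3[c("s_B", "s_add")]), c(0, 0))
})

test_that("sigma inflation follows the quadrature form", {
  expect_equal(sigmaEv11(3, 100, ErrorModelParams(1, 0, 0)), 3)
  got <- sigmaEv11(3, 16, ErrorModelParams(2, 1, 0.5))
  expect_equal(got, 2 * sqrt(9 + 16 + 64), tolerance = 1e-12)
  # monotone non-decreasing in each parameter for positive <I>
  base <- sigmaEv11(2, 50, ErrorModelParams(1.2, 0.3, 0.1))
  expect_gte(sigmaEv11(2, 50, ErrorModelParams(1.3, 0.3, 0.1)), base)
  expect_gte(sigmaEv11(2, 50, ErrorModelParams(1.2, 0.4, 0.1)), base)
  expect_gte(sigmaEv11(2, 50, ErrorModelParams(1.2, 0.3, 0.2)), base)
  # negative radicand clamps to sFac * sigma and counts the event
  out <- sigmaEv11(1, 100, ErrorModelParams(2, -5, 0))
  expect_equal(as.numeric(out), 2)
  expect_equal(attr(out, "nClamped"), 1L)
})

test_that("intensity bins assign whole groups and conserve counts", {
  vals <- list(c(0, 0), c(50, 150), c(99.5, 100.5), c(42))
  sigs <- lapply(vals, function(v) rep(1, length(v)))
  grp <- groupsFromValues(vals, sigs)
  bins <- binMeasurements(grp, nBins = 100L)
  # group means 0, 100, 100 span [0, 100]; width 1; mean 100 -> bin 100
  expect_equal(bins@edges[1], 0)
  expect_equal(bins@edges[101], 100)
  expect_equal(bins@counts[1], 2L)      # the mean-0 pair
  expect_equal(bins@counts[100], 4L)    # both mean-100 groups, top edge in
  # the n = 1 group is excluded entirely
  expect_equal(sum(bins@counts), 6L)
  expect_equal(sum(bins@weights^2), sum(bins@counts))
})

test_that("bin counts conserve the multiplicity >= 2 measurements", {
  grp <- calibratedGroups()
  bins <- binMeasurements(grp, 100L)
  n <- groupTable(grp)$n
  expect_equal(sum(bins@counts), sum(n[n >= 2L]))
})

test_that("target matches a straight-loop reference implementation", {
  grp <- calibratedGroups()
  m <- measurements(grp)
  n <- groupTable(grp)$n
  bruteTarget <- function(par) {
    sfac <- par[1]; sb <- par[2]; sadd <- par[3]
    mi <- tapply(m$i_full, m$group, mean)
    keep_groups <- as.integer(names(mi))[tabulate(m$group) >= 2]
    mis <- mi[as.character(keep_groups)]
    lo <- min(mis); hi <- max(mis); width <- (hi - lo) / 100
    dsq <- c(); bin <- c()
    for (g in keep_groups) {
      rows <- which(m$group == g)
      v <- m$i_full[rows]
      b <- min(floor((mi[[as.character(g)]] - lo) / width) + 1, 100)
      for (j in seq_along(v)) {
        loo <- mean(v[-j])
        sig <- sfac * sqrt(m$sigma_full[rows[j]]^2 +
                             sb * mi[[as.character(g)]] +
                             (sadd * mi[[as.character(g)]])^2)
        d <- sqrt((length(v) - 1) / length(v)) * (v[j] - loo) / sig
        dsq <- c(dsq, d^2); bin <- c(bin, b)
      }
    }
    f <- 0
    for (b in unique(bin)) {
      db <- dsq[bin == b]
      f <- f + sqrt(length(db)) * (sqrt(mean(db)) - 1)^2
    }
    f
  }
  for (par in list(c(1, 0, 0), c(1.5, 0.2, 0.3))) {
    expect_equal(targetFunction(par, grp), bruteTarget(par),
                 tolerance = 1e-10)
  }
})

test_that("doubling sFac from a solution halves every rmsd", {
  grp <- calibratedGroups()
  fit <- refineErrorModel(grp)
  p <- paramVector(fit$params)
  b1 <- evaluateBins(fit$params, grp)
  b2 <- evaluateBins(c(2 * p[1], p[2], p[3]), grp)
  nz <- b1@counts > 0
  expect_equal(b2@rmsd[nz], b1@rmsd[nz] / 2, tolerance = 1e-12)
  expect_equal(b2@targetValue,
               sum(b1@weights[nz] * (b1@rmsd[nz] / 2 - 1)^2),
               tolerance = 1e-12)
})

test_that("analytic gradient agrees with central finite differences", {
  grp <- calibratedGroups()
  set.seed(19)
  for (rep in 1:10) {
    p <- c(runif(1, 0.5, 3), runif(1, 0, 2), runif(1, 0, 1))
    g <- targetGradient(p, grp)
    fd <- vapply(1:3, function(i) {
      h <- 1e-6 * max(1, abs(p[i]))
      e <- numeric(3); e[i] <- h
      (targetFunction(p + e, grp) - targetFunction(p - e, grp)) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-5)
    # sign consistency at (1, 0, 0)
    g0 <- targetGradient(c(1, 0, 0), grp)
    fd0 <- (targetFunction(c(1 + 1e-6, 0, 0), grp) -
              targetFunction(c(1 - 1e-6, 0, 0), grp)) / 2e-6
    expect_equal(sign(g0[1]), sign(fd0))
  }
})

test_that("sB gradient vanishes when all group means are zero", {
  vals <- list(c(-2, 2), c(-5, 5), c(-1, 1, -1, 1))
  sigs <- lapply(vals, function(v) rep(1.5, length(v)))
  grp <- groupsFromValues(vals, sigs)
  # all means equal collapses the bin range to a single bin
  expect_warning(g <- targetGradient(c(1.3, 0.4, 0.2), grp),
                 "single bin")
  expect_equal(g[2], 0)
})

test_that("scale property: sigma * c with sFac / c leaves delta and f fixed", {
  set.seed(23)
  vals <- lapply(1:50, function(i) rnorm(4, 100, 10))
  sigs <- lapply(vals, function(v) runif(4, 1, 5))
  cc <- 2.5
  grp <- groupsFromValues(vals, sigs)
  grp2 <- groupsFromValues(vals, lapply(sigs, `*`, cc))
  p <- c(1.4, 0, 0)
  p2 <- c(1.4 / cc, 0, 0)
  expect_equal(normalizedDeviations(grp2,
                 ErrorModelParams(p2[1], 0, 0)),
               normalizedDeviations(grp, ErrorModelParams(p[1], 0, 0)),
               tolerance = 1e-12)
  expect_equal(targetFunction(p2, grp2), targetFunction(p, grp),
               tolerance = 1e-12)
})
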