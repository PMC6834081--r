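test_that("unweighted merge reproduces hand-computed statistics", {
  z <- mergeUnweighted(c(5, 5, 5))
  expect_equal(z$i_merged, 5)
  expect_equal(z$sigma_res, 0)
  expect_equal(z$sigma_merged, 0)
  z <- mergeUnweighted(c(1, 2, 3))
  expect_equal(z$i_merged, 2)
  expect_equal(z$sigma_res, 1)
  expect_equal(z$sigma_merged, 1 / sqrt(3))
  # n = 1: spread undefined, the measurement's own sigma is used, flagged
  z <- mergeUnweighted(7, sigmas = 2.5)
  expect_equal(z$sigma_merged, 2.5)
  expect_true(z$flagged)
})

test_that("merge protocols match straight-loop references on random groups", {
  set.seed(21)
  vals <- lapply(1:1000, function(i) rnorm(sample(2:12, 1), 50, 20))
  sigs <- lapply(vals, function(v) runif(length(v), 0.5, 5))
  grp <- groupsFromValues(vals, sigs)
  m1 <- mergedTable(mergeDataset(grp, MergePolicy("unweighted")))
  m2 <- mergedTable(mergeDataset(grp, MergePolicy("counting_weighted")))
  ord <- order(m1$h)
  m1 <- m1[ord, ]; m2 <- m2[order(m2$h), ]
  # independent textbook implementations
  ref_mean <- vapply(vals, function(v) sum(v) / length(v), numeric(1))
  ref_sem <- vapply(vals, function(v)
    sqrt(sum((v - mean(v))^2) / (length(v) - 1)) / sqrt(length(v)),
    numeric(1))
  ref_wmean <- mapply(function(v, s) {
    w <- 1 / s^2
    sum(w * v) / sum(w)
  }, vals, sigs)
  ref_wsig <- vapply(sigs, function(s) 1 / sqrt(sum(1 / s^2)), numeric(1))
  expect_equal(m1$i_merged, ref_mean, tolerance = 1e-12)
  expect_equal(m1$sigma_merged, ref_sem, tolerance = 1e-12)
  expect_equal(m2$i_merged, unname(ref_wmean), tolerance = 1e-12)
  expect_equal(m2$sigma_merged, ref_wsig, tolerance = 1e-12)
  expect_equal(m1$multiplicity, lengths(vals))
})

test_that("counting weights are inverse variances", {
  expect_equal(countingWeights(1), 1)
  expect_equal(countingWeights(2), 0.25)
  s <- c(0.5, 1.5, 3)
  expect_equal(countingWeights(s), 1 / s^2)
  expect_error(countingWeights(c(1, 0)), "sigma")
})

test_that("weighted merge degenerates correctly", {
  v <- c(3, 9, 6)
  eq <- mergeWeighted(v, rep(2, 3))
  expect_equal(eq$i_merged, mean(v))
  one <- mergeWeighted(5, 1 / 0.7^2)
  expect_equal(one$i_merged, 5)
  expect_equal(one$sigma_merged, 0.7)
  expect_error(mergeWeighted(c(1, 2), 1), "length")
  set.seed(3)
  w <- runif(3, 0.1, 4)
  got <- mergeWeighted(v, w)
  expect_equal(got$i_merged, sum(w * v) / sum(w), tolerance = 1e-12)
  expect_equal(got$sigma_merged, 1 / sqrt(sum(w)), tolerance = 1e-12)
})

test_that("equal sigmas make protocols 1 and 2 agree on intensities", {
  vals <- list(c(1, 5, 9), c(10, 14), c(2, 2, 2, 8))
  sigs <- lapply(vals, function(v) rep(1.7, length(v)))
  grp <- groupsFromValues(vals, sigs)
  m1 <- mergedTable(mergeDataset(grp, MergePolicy("unweighted")))
  m2 <- mergedTable(mergeDataset(grp, MergePolicy("counting_weighted")))
  expect_equal(m1$i_merged, m2$i_merged)
  expect_false(isTRUE(all.equal(m1$sigma_merged, m2$sigma_merged)))
})

test_that("identity error model reduces protocol 3 to protocol 2 bit-for-bit", {
  grp <- calibratedGroups()
  m2 <- mergedTable(mergeDataset(grp, MergePolicy("counting_weighted")))
  m3 <- mergedTable(mergeDataset(grp,
    MergePolicy("ev11", ErrorModelParams(1, 0, 0))))
  expect_identical(m3$i_merged, m2$i_merged)
  expect_identical(m3$sigma_merged, m2$sigma_merged)
})

test_that("merging is scale-equivariant under all protocols", {
  set.seed(8)
  vals <- lapply(1:20, function(i) rnorm(sample(2:8, 1), 100, 30))
  sigs <- lapply(vals, function(v) runif(length(v), 1, 6))
  cc <- 3.7
  grp <- groupsFromValues(vals, sigs)
  grp_scaled <- groupsFromValues(lapply(vals, `*`, cc),
                                 lapply(sigs, `*`, cc))
  for (pol in list(MergePolicy("unweighted"),
                   MergePolicy("counting_weighted"),
                   MergePolicy("ev11", ErrorModelParams(1.4, 0, 0.1)))) {
    a <- mergedTable(mergeDataset(grp, pol))
    b <- mergedTable(mergeDataset(grp_scaled, pol))
    expect_equal(b$i_merged, cc * a$i_merged, tolerance = 1e-12)
    expect_equal(b$sigma_merged, cc * a$sigma_merged, tolerance = 1e-12)
  }
})

test_that("counting weights understate partiality scatter versus spread", {
  # partiality-dominated spread: weighted sigma_h (counting only) comes
  # out far below the spread-based unweighted sigma_h at high multiplicity
  sim <- simulateDataset(presetConfig("partiality-heavy", seed = 5L))
  cfg <- sim$config
  grp <- groupByMiller(applyCorrections(sim$data), "P1")
  m1 <- mergedTable(mergeDataset(grp, MergePolicy("unweighted")))
  m2 <- mergedTable(mergeDataset(grp, MergePolicy("counting_weighted")))
  hi <- m1$multiplicity >= 10
  expect_gt(sum(hi), 50)
  expect_true(mean(m2$sigma_merged[hi] < m1$sigma_merged[hi]) > 0.95)
})

test_that("minimum multiplicity drops sparse groups", {
  grp <- groupsFromValues(list(c(1, 2), 5, c(3, 3, 3)),
                          list(c(1, 1), 1, c(1, 1, 1)))
  out <- mergedTable(mergeDataset(grp,
    MergePolicy("unweighted", minMultiplicity = 2L)))
  expect_equal(nrow(out), 2L)
  expect_true(all(out$multiplicity >= 2L))
  expect_error(MergePolicy("ev11"), "requires")
})
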