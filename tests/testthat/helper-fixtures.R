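# Shared in-code fixtures. Built lazily and memoized so expensive
# simulations run once per test session.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
  if (is.null(.fixtureCache[[name]]))
    .fixtureCache[[name]] <- builder()
  .fixtureCache[[name]]
}

# Tiny hand-built ReflectionData: explicit values, P1 indices.
tinyReflectionData <- function(i_partial = c(10, 12, 9, 20, 22),
                               sigma = NULL, hkl = NULL,
                               partiality = NULL,
                               scale = 1, wilson_b = 0) {
  n <- length(i_partial)
  if (is.null(sigma)) sigma <- rep(1, n)
  if (is.null(hkl)) hkl <- cbind(seq_len(n), 0L, 1L)
  if (is.null(partiality)) partiality <- rep(1, n)
  ids <- sprintf("im%04d", seq_len(n))
  m <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                  image_id = ids, i_partial = i_partial,
                  sigma_partial = sigma, partiality = partiality,
                  stol2 = 0.01)
  im <- data.frame(image_id = ids, scale = scale, wilson_b = wilson_b,
                   wavelength = 1.3)
  ReflectionData(m, im)
}

# Grouped dataset from explicit per-group corrected intensities/sigmas.
# 'values' and 'sigmas' are lists, one numeric vector per group.
groupsFromValues <- function(values, sigmas) {
  stopifnot(length(values) == length(sigmas))
  n <- lengths(values)
  g <- rep(seq_along(values), n)
  nn <- sum(n)
  m <- data.frame(h = g, k = 0L, l = 1L,
                  image_id = sprintf("im%04d", seq_len(nn)),
                  i_partial = unlist(values),
                  sigma_partial = unlist(sigmas),
                  partiality = 1, stol2 = 0.01)
  im <- data.frame(image_id = m$image_id, scale = 1, wilson_b = 0,
                   wavelength = 1.3)
  rd <- applyCorrections(ReflectionData(m, im))
  groupByMiller(rd, "P1", anomalous = TRUE)
}

# Moderate calibrated simulation, grouped (shared by several files).
calibratedGroups <- function() {
  cachedFixture("calibrated", function() {
    sim <- simulateDataset(simulationConfig(nImages = 300L,
                                            reflectionsPerImage = 40L,
                                            nUnique = 600L, seed = 42L))
    groupByMiller(applyCorrections(sim$data), "P1")
  })
}
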