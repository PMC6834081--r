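# Synthetic still-diffraction generator with known ground truth.
#
# Error structure emulated: Wilson (exponential) true intensities,
# per-image multiplicative scale and Wilson B, partiality fractions in
# (0, 1], Poisson photon counting, a detector-gain misestimation factor
# (detector units = gain_true * photons, the analyst divides by
# gain_assumed and takes sigma from the resulting counts — so sigmas are
# mis-scaled by exactly the unknown gain ratio), and an optional Gaussian
# instrumental error proportional to the expected intensity.

.runWithSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code())
}

#' Simulation configuration
#'
#' Settings of the synthetic still-diffraction generator. Defaults describe
#' a moderately strong, calibrated experiment: exponential (Wilson) true
#' intensities with mean \code{wilsonMean} photons, per-image scales and
#' Wilson B factors drawn uniformly from \code{gRange} / \code{bRange},
#' partialities from a rescaled Beta(2, 1.5) law on (0.05, 1] (left-skewed
#' towards zero, as estimated partialities of still images are), Poisson
#' counting noise, and no gain misestimation or instrumental error.
#'
#' @param nImages number of still images.
#' @param reflectionsPerImage measurements per image.
#' @param nUnique number of distinct Miller indices.
#' @param wilsonMean mean of the exponential true-intensity law (photons).
#' @param bRange interval for the per-image Wilson B factor (A^2).
#' @param gRange interval for the per-image scale factor.
#' @param partialityLaw list describing the partiality distribution:
#'   \code{list(shape1, shape2, min, max)} for a Beta law rescaled to
#'   (min, max].
#' @param gainTrue,gainAssumed true and assumed detector gain; their ratio
#'   is the gain misestimation factor g (sigmas end up mis-scaled by
#'   sqrt(g)).
#' @param sAddTrue SD of the Gaussian instrumental error as a fraction of
#'   the expected intensity.
#' @param resolutionRange d-spacing interval (A); reflections are placed
#'   uniformly in reciprocal volume (1/d^3).
#' @param wavelength incident wavelength (A), one value for all images.
#' @param anomalousSignal fractional Bijvoet difference added between
#'   Friedel mates (default 0: no anomalous signal; 0.021 mimics a
#'   two-Zn/four-Ca thermolysin-sized signal).
#' @param seed integer RNG seed.
#' @return a named list of settings (class \code{"SimulationConfig"}).
#' @export
simulationConfig <- function(nImages = 1000L, reflectionsPerImage = 50L,
                             nUnique = 2000L, wilsonMean = 2000,
                             bRange = c(0, 10), gRange = c(0.5, 2),
                             partialityLaw = list(shape1 = 2,
                                                  shape2 = 1.5,
                                                  min = 0.05, max = 1),
                             gainTrue = 1, gainAssumed = 1,
                             sAddTrue = 0,
                             resolutionRange = c(1.8, 30),
                             wavelength = 1.3,
                             anomalousSignal = 0, seed = 1L) {
  cfg <- list(nImages = as.integer(nImages),
              reflectionsPerImage = as.integer(reflectionsPerImage),
              nUnique = as.integer(nUnique), wilsonMean = wilsonMean,
              bRange = bRange, gRange = gRange,
              partialityLaw = partialityLaw, gainTrue = gainTrue,
              gainAssumed = gainAssumed, sAddTrue = sAddTrue,
              resolutionRange = sort(resolutionRange),
              wavelength = wavelength,
              anomalousSignal = anomalousSignal, seed = as.integer(seed))
  stopifnot(cfg$nImages >= 1L, cfg$reflectionsPerImage >= 1L,
            cfg$nUnique >= 1L, cfg$gainTrue > 0, cfg$gainAssumed > 0,
            cfg$sAddTrue >= 0)
  if (cfg$partialityLaw$min <= 0 || cfg$partialityLaw$max <= 0 ||
      cfg$partialityLaw$max > 1)
    stop("partiality law support must lie within (0, 1]", call. = FALSE)
  class(cfg) <- "SimulationConfig"
  cfg
}

.drawPartiality <- function(n, law) {
  law$min + stats::rbeta(n, law$shape1, law$shape2) * (law$max - law$min)
}

#' Simulate a still-diffraction measurement table
#'
#' Generates measurements according to the configured error structure and
#' returns them together with the per-image correction models and a
#' ground-truth table. For each unique index h: true intensity
#' \code{J ~ Exp(mean = wilsonMean)}; for each measurement on image c:
#' expected photons \code{mu = G_c exp(-2 B_c stol2) P J}; observed
#' photons \code{~ Poisson(mu) + N(0, (sAddTrue mu)^2)}; recorded
#' intensity \code{= photons * gainTrue / gainAssumed} with counting sigma
#' \code{sqrt(max(I, 1))} (1 photon-equivalent floor for empty cells).
#' Fully reproducible from the config seed; the caller's RNG state is left
#' untouched.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{data} (a \linkS4class{ReflectionData}),
#'   \code{truth} (list of \code{reflections} — h, k, l, true J, d,
#'   stol2 — and \code{images}) and \code{config}.
#' @export
simulateDataset <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  .runWithSeed(config$seed, function() {
    nu <- config$nUnique
    # distinct Miller indices with l > 0 so no accidental Friedel pairs
    hkl <- NULL
    while (is.null(hkl) || nrow(hkl) < nu) {
      cand <- unique(data.frame(h = sample.int(61, 3 * nu, TRUE) - 31L,
                                k = sample.int(61, 3 * nu, TRUE) - 31L,
                                l = sample.int(30, 3 * nu, TRUE)))
      hkl <- utils::head(cand, nu)
    }
    dmin <- config$resolutionRange[1]
    dmax <- config$resolutionRange[2]
    invd3 <- stats::runif(nu, dmax^-3, dmin^-3)
    d <- invd3^(-1 / 3)
    stol2 <- 1 / (4 * d^2)
    j_true <- stats::rexp(nu, 1 / config$wilsonMean)
    if (config$anomalousSignal > 0) {
      # mates get J * (1 +/- delta/2); each measurement picks a sign
      delta <- config$anomalousSignal
      j_plus <- j_true * (1 + delta / 2)
      j_minus <- j_true * (1 - delta / 2)
    }
    ni <- config$nImages
    g_img <- stats::runif(ni, config$gRange[1], config$gRange[2])
    b_img <- stats::runif(ni, config$bRange[1], config$bRange[2])
    image_id <- sprintf("img%05d", seq_len(ni))
    rpi <- min(config$reflectionsPerImage, nu)
    refl <- vapply(seq_len(ni),
                   function(i) sample.int(nu, rpi),
                   integer(rpi))
    refl <- as.vector(refl)
    img <- rep(seq_len(ni), each = rpi)
    n <- length(refl)
    p <- .drawPartiality(n, config$partialityLaw)
    jj <- j_true[refl]
    sign <- rep(1L, n)
    if (config$anomalousSignal > 0) {
      sign <- sample(c(1L, -1L), n, TRUE)
      jj <- ifelse(sign > 0, j_plus[refl], j_minus[refl])
    }
    mu <- g_img[img] * exp(-2 * b_img[img] * stol2[refl]) * p * jj
    photons <- stats::rpois(n, mu)
    if (config$sAddTrue > 0)
      photons <- photons + stats::rnorm(n, 0, config$sAddTrue * mu)
    g_ratio <- config$gainTrue / config$gainAssumed
    i_partial <- photons * g_ratio
    sigma_partial <- sqrt(pmax(i_partial, 1))
    meas <- data.frame(h = sign * hkl$h[refl], k = sign * hkl$k[refl],
                       l = sign * hkl$l[refl],
                       image_id = image_id[img],
                       i_partial = i_partial,
                       sigma_partial = sigma_partial,
                       partiality = p, stol2 = stol2[refl])
    imgs <- data.frame(image_id = image_id, scale = g_img,
                       wilson_b = b_img, wavelength = config$wavelength)
    truth_refl <- data.frame(h = hkl$h, k = hkl$k, l = hkl$l,
                             j_true = j_true, d = d, stol2 = stol2)
    rd <- ReflectionData(meas, imgs)
    list(data = rd,
         truth = list(reflections = truth_refl, images = imgs,
                      mu = mu),
         config = config)
  })
}

#' Fixture presets
#'
#' Named simulation configurations exercising one error component each:
#' \describe{
#'   \item{clean-poisson}{calibrated counting statistics only (120000
#'     measurements): refined parameters should be near the identity
#'     (1, 0, 0) and normalized deviations near unit rms.}
#'   \item{gain25}{detector gain 25 treated as 1: sigmas understate the
#'     spread by a factor sqrt(25), absorbed by sFac.}
#'   \item{instability}{intensity-proportional Gaussian error with true
#'     fraction 0.5, absorbed by sAdd.}
#'   \item{partiality-heavy}{strongly zero-skewed partialities, stressing
#'     the correction and the weighted protocols.}
#' }
#'
#' @param name preset name.
#' @param seed RNG seed for the generated config.
#' @return a \code{\link{simulationConfig}}.
#' @export
presetConfig <- function(name = c("clean-poisson", "gain25",
                                  "instability", "partiality-heavy"),
                         seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "clean-poisson" = simulationConfig(nImages = 2000L,
                                       reflectionsPerImage = 60L,
                                       seed = seed),
    "gain25" = simulationConfig(nImages = 5000L,
                                reflectionsPerImage = 50L,
                                gainTrue = 25, gainAssumed = 1,
                                seed = seed),
    "instability" = simulationConfig(nImages = 5000L,
                                     reflectionsPerImage = 50L,
                                     sAddTrue = 0.5, seed = seed),
    "partiality-heavy" = simulationConfig(nImages = 1000L,
                                          reflectionsPerImage = 50L,
                                          partialityLaw = list(
                                            shape1 = 1, shape2 = 3,
                                            min = 0.02, max = 1),
                                          seed = seed))
}

#' Write a preset fixture to disk
#'
#' Simulates the named preset and writes the columnar measurement and
#' image tables plus a \code{truth.tsv} ground-truth sidecar.
#'
#' @param name preset name (see \code{\link{presetConfig}}).
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @return invisibly, a named list of the written paths.
#' @export
makeFixture <- function(name, dir, seed = 1L) {
  cfg <- presetConfig(name, seed)
  sim <- simulateDataset(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(measurements = file.path(dir, "measurements.tsv"),
                images = file.path(dir, "images.tsv"),
                truth = file.path(dir, "truth.tsv"))
  writeReflectionTable(sim$data, paths$measurements, paths$images)
  .writeTsv(sim$truth$reflections, paths$truth)
  invisible(paths)
}
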