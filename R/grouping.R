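#' Group measurements by asymmetric-unit Miller index
#'
#' Maps every measurement's Miller index to a canonical asymmetric-unit
#' representative under the rotational symmetry of the given space group and
#' partitions the measurements into reflection groups. With
#' \code{anomalous = TRUE} the orbit excludes the Friedel inversion, so
#' \eqn{h} and \eqn{-h} of acentric reflections form distinct groups and
#' Bijvoet pairs stay separable; with \code{anomalous = FALSE} Friedel mates
#' merge.
#'
#' @param x a \linkS4class{ReflectionData} object (typically after
#'   \code{\link{applyCorrections}}).
#' @param spaceGroup space-group symbol (see
#'   \code{\link{symmetryOperators}}).
#' @param anomalous logical; keep Friedel mates separate (default TRUE).
#' @param partialityMin optional floor: measurements with partiality below
#'   it are dropped before grouping. Default 0 keeps all.
#' @return A \linkS4class{ReflectionGroups} object.
#' @examples
#' m <- data.frame(h = c(1, 1, -1), k = c(2, 2, -2), l = c(3, 3, -3),
#'                 image_id = c("a", "b", "c"), i_partial = c(10, 12, 9),
#'                 sigma_partial = 1, partiality = 1, stol2 = 0.01)
#' im <- data.frame(image_id = c("a", "b", "c"), scale = 1, wilson_b = 0,
#'                  wavelength = 1.3)
#' rd <- applyCorrections(ReflectionData(m, im))
#' groupTable(groupByMiller(rd, "P1", anomalous = TRUE))   # two groups
#' groupTable(groupByMiller(rd, "P1", anomalous = FALSE))  # one group
#' @export
groupByMiller <- function(x, spaceGroup = "P1", anomalous = TRUE,
                          partialityMin = 0) {
  stopifnot(is(x, "ReflectionData"))
  ops <- symmetryOperators(spaceGroup)
  m <- x@measurements
  if (partialityMin > 0) m <- m[m$partiality >= partialityMin, , drop = FALSE]
  if (!nrow(m)) stop("no measurements to group", call. = FALSE)
  asu <- .mapToAsu(m$h, m$k, m$l, ops, anomalous)
  m$h_asu <- asu$h
  m$k_asu <- asu$k
  m$l_asu <- asu$l
  key <- paste(asu$h, asu$k, asu$l)
  m$group <- match(key, unique(key))
  ord <- order(m$group)
  m <- m[ord, , drop = FALSE]
  rownames(m) <- NULL
  first <- !duplicated(m$group)
  groups <- data.frame(group = m$group[first], h = m$h_asu[first],
                       k = m$k_asu[first], l = m$l_asu[first],
                       n = as.integer(tabulate(m$group)))
  new("ReflectionGroups", measurements = m, groups = groups,
      spaceGroup = spaceGroup, anomalous = anomalous)
}
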