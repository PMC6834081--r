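# Columnar text formats: tab-separated, header row, '#' comment lines.

.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.writeTsv <- function(df, path, digits = 15L) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  out <- df
  out[num] <- lapply(df[num], formatC, digits = digits, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.checkColumns <- function(df, required, what, path) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s) in ", what, " file '", path, "': ",
         paste(miss, collapse = ", "), call. = FALSE)
}

#' Read an unmerged reflection table and its per-image model table
#'
#' The measurement file is tab-separated with a header row and required
#' columns \code{h k l image_id i_partial sigma_partial partiality stol2};
#' the image file requires \code{image_id scale wilson_b wavelength}.
#' Lines starting with \code{#} are comments. Intensities are expected in
#' photon units (gain conversion is an explicit step, see
#' \code{\link{gainCorrect}}).
#'
#' @param measurementsPath path to the measurement table.
#' @param imagesPath path to the per-image model table.
#' @return A \linkS4class{ReflectionData} object.
#' @seealso \code{\link{writeReflectionTable}}
#' @export
readReflectionTable <- function(measurementsPath, imagesPath) {
  m <- .readTsv(measurementsPath)
  .checkColumns(m, .MEAS_COLS, "measurement", measurementsPath)
  im <- .readTsv(imagesPath)
  .checkColumns(im, .IMG_COLS, "image", imagesPath)
  bad <- which(!is.finite(m$sigma_partial) | m$sigma_partial <= 0)
  if (length(bad))
    stop("non-positive sigma_partial in '", measurementsPath,
         "' at data row ", bad[1], call. = FALSE)
  badp <- which(m$partiality <= 0 | m$partiality > 1)
  if (length(badp))
    stop("partiality outside (0, 1] in '", measurementsPath,
         "' at data row ", badp[1], call. = FALSE)
  ReflectionData(m, im)
}

#' Write an unmerged reflection table and its per-image model table
#'
#' Inverse of \code{\link{readReflectionTable}}; numeric values are written
#' with 15 significant digits so a round trip preserves them to at least 12.
#'
#' @param x a \linkS4class{ReflectionData} object.
#' @param measurementsPath,imagesPath output paths.
#' @return invisibly, the measurement path.
#' @export
writeReflectionTable <- function(x, measurementsPath, imagesPath) {
  stopifnot(is(x, "ReflectionData"))
  m <- x@measurements
  if (all(is.na(m$i_full))) m$i_full <- m$sigma_full <- NULL
  .writeTsv(m, measurementsPath)
  .writeTsv(x@images, imagesPath)
  invisible(measurementsPath)
}

#' Write a merged reflection table
#'
#' Tab-separated columns \code{h k l i_merged sigma_merged multiplicity}
#' (plus \code{mean_raw} and \code{stol2} when present).
#'
#' @param x a \linkS4class{MergedReflections} object.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeMergedTable <- function(x, path) {
  stopifnot(is(x, "MergedReflections"))
  .writeTsv(x@table, path)
  invisible(path)
}

#' Read a merged reflection table written by \code{\link{writeMergedTable}}
#'
#' @param path input path.
#' @param protocol protocol label to attach (default "unweighted" if the
#'   file carries no annotation).
#' @return A \linkS4class{MergedReflections} object.
#' @export
readMergedTable <- function(path, protocol = "unweighted") {
  df <- .readTsv(path)
  .checkColumns(df, c("h", "k", "l", "i_merged", "sigma_merged",
                      "multiplicity"), "merged", path)
  new("MergedReflections", table = df, protocol = protocol)
}
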