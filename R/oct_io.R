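#' @include AllClasses.R
NULL

.OCTGRAFT_VERSION <- "0.1.0"

#' Load a grayscale PNG or TIFF B-scan
#'
#' Reads an 8- or 16-bit grayscale image and rescales intensities to
#' [0, 1] by the bit-depth maximum (the png and tiff readers already
#' return this normalisation). Colour images are rejected: a B-scan is a
#' single-channel intensity grid.
#'
#' @param path path to a PNG or TIFF file.
#' @param calibration a \code{\linkS4class{Calibration}}; calibration is a
#'   required user input because export pixel pitch varies by device and
#'   is not read from image metadata.
#' @param imageId identifier; defaults to the file name.
#' @param meta optional acquisition metadata list.
#' @return an \code{\linkS4class{OCTImage}}.
#' @export
loadImage <- function(path, calibration, imageId = basename(path), meta = list()) {
  if (!file.exists(path))
    .octError(sprintf("image file not found: %s", path), "octgraft_io_error")
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = ,
           tiff = tiff::readTIFF(path),
           .octError(sprintf("unsupported image format '.%s' (need PNG or TIFF)", ext),
                     "octgraft_format_error")),
    error = function(e) {
      if (inherits(e, "octgraft_error")) stop(e)
      .octError(sprintf("unreadable image file %s: %s", path, conditionMessage(e)),
                "octgraft_io_error")
    })
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    # grey+alpha: keep the grey channel; true colour is an error
    if (nch == 2) arr <- arr[, , 1]
    else .octError(sprintf("expected a grayscale image but found %d channels", nch),
                   "octgraft_format_error")
  }
  octImage(arr, calibration, imageId = imageId, meta = meta)
}

#' Save an OCTImage as an 8-bit grayscale PNG
#'
#' Intensities are quantised to the 8-bit grid (the PNG writer used emits
#' 8-bit samples); an image already on that grid round-trips
#' pixel-identically through \code{\link{loadImage}}.
#'
#' @param image an \code{\linkS4class{OCTImage}}.
#' @param path output path (.png).
#' @return the path, invisibly.
#' @export
saveImage <- function(image, path) {
  stopifnot(is(image, "OCTImage"))
  png::writePNG(round(image@pixels * 255) / 255, target = path)
  invisible(path)
}

#' Quantise an image to the 8-bit intensity grid
#'
#' Convenience for constructing images whose save/load round trip is exact.
#'
#' @param image an \code{\linkS4class{OCTImage}}.
#' @return the image with pixels snapped to multiples of 1/255.
#' @export
quantiseImage <- function(image) {
  image@pixels <- round(image@pixels * 255) / 255
  image
}

#' Serialise a graft segmentation to JSON
#'
#' The record carries the segmentation (corners and both curves' control
#' points, >= 6 decimal digits), the image id, the mode tag and the
#' software version; \code{\link{loadSegmentation}} restores it
#' field-for-field.
#'
#' @param seg a \code{\linkS4class{GraftSegmentation}}.
#' @param path output path (.json).
#' @return the path, invisibly.
#' @export
saveSegmentation <- function(seg, path) {
  stopifnot(is(seg, "GraftSegmentation"))
  rec <- list(
    image_id = seg@imageId,
    mode = seg@mode,
    software_version = .OCTGRAFT_VERSION,
    corners = apply(seg@corners@points, 1, function(p) c(col = p[[1]], row = p[[2]]),
                    simplify = FALSE),
    anterior = unname(apply(seg@anterior@controlPoints, 1, as.numeric, simplify = FALSE)),
    posterior = unname(apply(seg@posterior@controlPoints, 1, as.numeric, simplify = FALSE))
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Restore a graft segmentation from JSON
#'
#' @param path path written by \code{\link{saveSegmentation}}.
#' @return a \code{\linkS4class{GraftSegmentation}}.
#' @export
loadSegmentation <- function(path) {
  if (!file.exists(path))
    .octError(sprintf("segmentation file not found: %s", path), "octgraft_io_error")
  rec <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    .octError(sprintf("malformed segmentation JSON in %s: %s",
                                      path, conditionMessage(e)),
                              "octgraft_parse_error"))
  for (key in c("corners", "anterior", "posterior", "image_id", "mode"))
    if (is.null(rec[[key]]))
      .octError(sprintf("segmentation record %s is missing the \"%s\" key", path, key),
                "octgraft_parse_error")
  if (!all(.CORNER_LABELS %in% names(rec$corners)))
    .octError(sprintf("segmentation record %s has an incomplete \"corners\" set", path),
              "octgraft_parse_error")
  cs <- do.call(cornerSet, stats::setNames(
    lapply(.CORNER_LABELS, function(l) unlist(rec$corners[[l]], use.names = FALSE)),
    c("leftAnterior", "leftPosterior", "rightAnterior", "rightPosterior")))
  toMat <- function(lst) {
    m <- do.call(rbind, lapply(lst, unlist, use.names = FALSE))
    colnames(m) <- c("col", "row")
    m
  }
  new("GraftSegmentation",
      anterior = new("GraftCurve", controlPoints = toMat(rec$anterior)),
      posterior = new("GraftCurve", controlPoints = toMat(rec$posterior)),
      corners = cs, mode = rec$mode, imageId = rec$image_id)
}
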