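#' @include AllClasses.R config.R graft_metrics.R
NULL

#' Batch area measurement over a directory of B-scans
#'
#' Runs the automated pipeline on every PNG/TIFF image in a directory, in
#' deterministic filename order, and returns one area row per image per
#' mode. When a truth JSON written by the phantom CLI sits next to an
#' image (\code{<image>.truth.json}), a truth-snapped semi-automated
#' reading is added, giving the paired automated/semi-automated series.
#' Per-image failures are reported in the \code{exception} column and the
#' batch continues.
#'
#' @param imageDir directory of .png/.tif/.tiff images.
#' @param config an \code{\link{octConfig}}; supplies the calibration.
#' @param verbose log per-stage timings.
#' @return a data.frame with columns image_id, mode, area_um2, exception.
#' @export
runBatch <- function(imageDir, config = octConfig(), verbose = FALSE) {
  if (!dir.exists(imageDir))
    .octError(sprintf("image directory not found: %s", imageDir), "octgraft_io_error")
  files <- sort(list.files(imageDir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  cal <- .configCalibration(config)
  rows <- lapply(files, function(f) {
    id <- basename(f)
    out <- tryCatch({
      img <- loadImage(f, cal)
      seg <- segmentAutomated(img, config, verbose = verbose)
      area <- computeArea(seg, cal)
      r <- data.frame(image_id = id, mode = "automated",
                      area_um2 = areaUm2(area), exception = "",
                      stringsAsFactors = FALSE)
      truthFile <- paste0(f, ".truth.json")
      if (file.exists(truthFile)) {
        truth <- .truthFromJson(truthFile)
        segSemi <- snapSegmentationToTruth(seg, truth)
        r <- rbind(r, data.frame(image_id = id, mode = "semi_automated",
                                 area_um2 = areaUm2(computeArea(segSemi, cal)),
                                 exception = "", stringsAsFactors = FALSE))
      }
      r
    }, octgraft_error = function(e)
      data.frame(image_id = id, mode = "automated", area_um2 = NA_real_,
                 exception = conditionMessage(e), stringsAsFactors = FALSE))
    out
  })
  if (!length(rows))
    return(data.frame(image_id = character(), mode = character(),
                      area_um2 = numeric(), exception = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Serialise phantom truth to JSON / restore it
#'
#' Plumbing used by the command-line phantom generator so that a truth
#' file can accompany a rendered image.
#'
#' @param truth a \code{\linkS4class{PhantomTruth}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
saveTruth <- function(truth, path) {
  stopifnot(is(truth, "PhantomTruth"))
  sp <- truth@spec
  rec <- list(
    spec = list(image_height = sp@imageHeight, image_width = sp@imageWidth,
                cal_lateral = sp@calibration@lateral, cal_axial = sp@calibration@axial,
                cornea_anterior_sagitta = sp@corneaAnteriorSagitta,
                cornea_thickness = sp@corneaThickness,
                graft_left_corner = sp@graftLeftCorner,
                graft_right_corner = sp@graftRightCorner,
                graft_central_thickness = sp@graftCentralThickness,
                graft_edge_thickness = sp@graftEdgeThickness,
                graft_anterior_sagitta = sp@graftAnteriorSagitta,
                interface_contrast = sp@interfaceContrast,
                speckle_sigma = sp@speckleSigma,
                background_level = sp@backgroundLevel, seed = sp@seed),
    true_area_um2 = truth@areaUm2)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.specFromJsonList <- function(s) {
  phantomSpec(imageHeight = s$image_height, imageWidth = s$image_width,
              calibration = calibrationSpec(s$cal_lateral, s$cal_axial),
              corneaAnteriorSagitta = s$cornea_anterior_sagitta,
              corneaThickness = s$cornea_thickness,
              graftLeftCorner = unlist(s$graft_left_corner),
              graftRightCorner = unlist(s$graft_right_corner),
              graftCentralThickness = s$graft_central_thickness,
              graftEdgeThickness = s$graft_edge_thickness,
              graftAnteriorSagitta = s$graft_anterior_sagitta,
              interfaceContrast = s$interface_contrast,
              speckleSigma = s$speckle_sigma,
              backgroundLevel = s$background_level, seed = s$seed)
}

.truthFromJson <- function(path) {
  rec <- jsonlite::read_json(path)
  .phantomTruth(.specFromJsonList(rec$spec))
}

#' Write a measurement table as CSV
#'
#' RFC-4180 output used by the batch and agreement subcommands.
#'
#' @param df a data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMeasurementCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
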