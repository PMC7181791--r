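.sidecarPath <- function(path) paste0(sub("\\.[Tt][Ii][Ff]{1,2}$", "", path),
                                      ".json")

.readSidecar <- function(path) {
  sc <- .sidecarPath(path)
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else list()
}

#' Read a video from a multi-page TIFF
#'
#' Frames are the TIFF pages in order. Acquisition metadata (frame rate and
#' pixel size) is taken from the arguments or, when absent, from a JSON
#' sidecar next to the file (same stem, `.json` extension, keys `fps` and
#' `pixel_size_um`).
#'
#' @param path path to the multi-page TIFF.
#' @param fps,pixelSize acquisition metadata; override the sidecar.
#' @return a [VideoStream-class].
#' @export
readVideoTIFF <- function(path, fps = NULL, pixelSize = NULL) {
  meta <- .readSidecar(path)
  fps <- fps %||% meta$fps
  pixelSize <- pixelSize %||% meta$pixel_size_um %||% 1
  if (is.null(fps)) stop("fps not given and no sidecar metadata found")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  videoStream(pages, fps = fps, pixelSize = pixelSize)
}

#' Write a video to a multi-page TIFF with a JSON sidecar
#'
#' Intensities are clamped to [0, 1] and written as 16-bit pages; fps and
#' pixel size go to the sidecar.
#'
#' @param video a [VideoStream-class].
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
writeVideoTIFF <- function(video, path) {
  stopifnot(is(video, "VideoStream"))
  d <- dim(video@frames)
  pages <- lapply(seq_len(d[3]), function(tt) {
    pmax(pmin(video@frames[, , tt], 1), 0)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(
    list(fps = video@fps, pixel_size_um = video@pixelSize,
         n_frames = d[3], duration_s = d[3] / video@fps),
    .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read/write a kymograph as 16-bit TIFF plus JSON sidecar
#'
#' The sidecar stores `fps`, `pixel_size_um` and `scanline_row`.
#'
#' @param kym a [Kymograph-class].
#' @param path TIFF path.
#' @param fps,pixelSize,scanlineRow metadata overrides when reading a file
#'   without a sidecar.
#' @return `writeKymographTIFF` the path invisibly; `readKymographTIFF` a
#'   [Kymograph-class].
#' @export
writeKymographTIFF <- function(kym, path) {
  stopifnot(is(kym, "Kymograph"))
  tiff::writeTIFF(pmax(pmin(kym@mat, 1), 0), path, bits.per.sample = 16)
  jsonlite::write_json(
    list(fps = kym@fps, pixel_size_um = kym@pixelSize,
         scanline_row = kym@scanlineRow),
    .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeKymographTIFF
#' @export
readKymographTIFF <- function(path, fps = NULL, pixelSize = NULL,
                              scanlineRow = NULL) {
  meta <- .readSidecar(path)
  fps <- fps %||% meta$fps
  if (is.null(fps)) stop("fps not given and no sidecar metadata found")
  mat <- tiff::readTIFF(path)
  if (length(dim(mat)) == 3) mat <- mat[, , 1]
  new("Kymograph", mat = mat, fps = fps,
      pixelSize = pixelSize %||% meta$pixel_size_um %||% 1,
      scanlineRow = as.integer(scanlineRow %||% meta$scanline_row %||% 1L))
}

#' Write post locations to CSV
#'
#' Columns: `well,side,x_px,y_px`.
#'
#' @param posts a [detectPosts()] result (or a named list of them; names
#'   become the `well` column).
#' @param path output CSV path.
#' @param well well id used when a single result is given.
#' @return the path, invisibly.
#' @export
writePostLocations <- function(posts, path, well = "A1") {
  if (is.data.frame(posts)) posts <- stats::setNames(list(posts), well)
  tab <- do.call(rbind, lapply(names(posts), function(w) {
    data.frame(well = w, side = posts[[w]]$side,
               x_px = posts[[w]]$x, y_px = posts[[w]]$y)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write per-well contractility metrics to CSV
#'
#' @param metrics a named list of [ContractilityMetrics-class] (see
#'   [metricsTable()]).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeMetricsCSV <- function(metrics, path) {
  utils::write.csv(metricsTable(metrics), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
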