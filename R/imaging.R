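#' Construct a WellImage
#'
#' @param pixels numeric intensity matrix (row = y, column = x, origin
#'   top-left, 1-based).
#' @param pixelSize physical pixel size, um/px.
#' @param bitDepth nominal camera bit depth.
#' @return a [WellImage-class].
#' @export
wellImage <- function(pixels, pixelSize = 1, bitDepth = 16L) {
  new("WellImage", pixels = as.matrix(pixels), pixelSize = pixelSize,
      bitDepth = as.integer(bitDepth))
}

#' Construct a VideoStream
#'
#' @param frames height x width x n_frames numeric array, or a list of
#'   equal-sized matrices (stacked in order).
#' @param fps frame rate, frames per second.
#' @param pixelSize physical pixel size, um/px.
#' @return a [VideoStream-class].
#' @export
videoStream <- function(frames, fps, pixelSize = 1) {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1)))) {
      stop("all frames must have the same shape")
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(d, length(frames)))
  }
  new("VideoStream", frames = frames, fps = fps, pixelSize = pixelSize)
}

.asPixels <- function(image) {
  if (is(image, "WellImage")) image@pixels else as.matrix(image)
}

#' Locate cantilever posts in a low-magnification well image
#'
#' Posts appear as dark, vertically elongated blobs under transmitted light.
#' The image is thresholded with Otsu's method, connected components are
#' labelled, and components are filtered by area and by height/width aspect
#' ratio before taking the `expectedPosts` largest survivors, sorted by their
#' centroid x. Detection is fully deterministic.
#'
#' @param image a [WellImage-class] or plain matrix.
#' @param expectedPosts number of posts expected in the field (1 or 2).
#' @param darkPosts posts darker than background (transmitted light,
#'   the default); set FALSE for inverted polarity.
#' @param minArea minimal component area, px.
#' @param maxAreaFrac maximal component area as a fraction of the image.
#' @param minAspect minimal height/width ratio of the component bounding box
#'   (posts are vertical).
#' @return a data.frame with one row per post: `side` (`"left"`/`"right"`),
#'   centroid `x`, `y` (px, 1-based), `area`, and the bounding box
#'   `row0, col0, row1, col1` (1-based, inclusive).
#' @examples
#' img <- matrix(0.9, 60, 120)
#' img[15:45, 20:30] <- 0.1; img[15:45, 90:100] <- 0.1
#' detectPosts(img)
#' @export
detectPosts <- function(image, expectedPosts = 2, darkPosts = TRUE,
                        minArea = 20, maxAreaFrac = 0.25, minAspect = 1.5) {
  stopifnot(expectedPosts %in% c(1L, 2L))
  px <- .asPixels(image)
  rng <- range(px)
  if (diff(rng) == 0) {
    stop("post detection failed: 0 candidate components ",
         "(image has no contrast)")
  }
  norm <- (px - rng[1]) / diff(rng)
  thr <- EBImage::otsu(norm, range = c(0, 1))
  mask <- if (darkPosts) norm < thr else norm > thr
  lab <- EBImage::bwlabel(mask)
  idx <- which(lab > 0)
  cand <- data.frame(x = numeric(0), y = numeric(0), area = numeric(0),
                     row0 = integer(0), col0 = integer(0),
                     row1 = integer(0), col1 = integer(0))
  if (length(idx) > 0) {
    ij <- arrayInd(idx, dim(lab))
    g <- as.integer(lab[idx])
    area <- tabulate(g)
    keepLab <- which(area >= minArea & area <= maxAreaFrac * length(px))
    for (l in keepLab) {
      sel <- g == l
      rows <- ij[sel, 1]; cols <- ij[sel, 2]
      h <- diff(range(rows)) + 1
      w <- diff(range(cols)) + 1
      if (h / w < minAspect) next
      cand <- rbind(cand, data.frame(
        x = mean(cols), y = mean(rows), area = area[l],
        row0 = min(rows), col0 = min(cols),
        row1 = max(rows), col1 = max(cols)))
    }
  }
  if (nrow(cand) < expectedPosts) {
    stop(sprintf(
      "post detection failed: %d candidate component(s) after filtering, %d expected%s",
      nrow(cand), expectedPosts,
      if (nrow(cand) > 0) {
        paste0(" (candidates at x = ",
               paste(round(cand$x, 1), collapse = ", "), ")")
      } else ""))
  }
  ## keep the largest expectedPosts components, then order left-to-right
  cand <- cand[order(-cand$area, cand$x), , drop = FALSE]
  cand <- cand[seq_len(expectedPosts), , drop = FALSE]
  cand <- cand[order(cand$x), , drop = FALSE]
  cand$side <- if (expectedPosts == 2) c("left", "right") else "left"
  rownames(cand) <- NULL
  cand[, c("side", "x", "y", "area", "row0", "col0", "row1", "col1")]
}

#' Contrast-based focus score
#'
#' Variance of the discrete Laplacian over the image (or a sub-region): a
#' standard contrast-maximizing autofocus figure of merit. Sharper images
#' score higher; a constant image scores exactly 0. The argmax over a focal
#' stack selects the best-focused slice; no hardware is driven.
#'
#' @param image a [WellImage-class] or matrix.
#' @param bbox optional region of interest `c(row0, col0, row1, col1)`
#'   (1-based, inclusive), e.g. a post bounding box from [detectPosts()].
#' @return a non-negative scalar score.
#' @export
focusScore <- function(image, bbox = NULL) {
  px <- .asPixels(image)
  if (!is.null(bbox)) {
    px <- px[bbox[1]:bbox[3], bbox[2]:bbox[4], drop = FALSE]
  }
  nr <- nrow(px); nc <- ncol(px)
  if (nr < 3 || nc < 3) stop("region too small for a Laplacian")
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  lap <- 4 * px[i, j] - px[i - 1, j] - px[i + 1, j] -
    px[i, j - 1] - px[i, j + 1]
  stats::var(as.vector(lap))
}

#' Crop a video to a region of interest around a post
#'
#' Extracts a window of nominally `2 * halfHeightPx` rows by
#' `2 * halfWidthPx` columns centred on the post location, clipped to the
#' frame bounds; acquisition metadata is preserved.
#'
#' @param video a [VideoStream-class].
#' @param post one row of the [detectPosts()] result (or any list with
#'   numeric `x` and `y`).
#' @param halfWidthPx,halfHeightPx window half-sizes, px.
#' @return a cropped [VideoStream-class].
#' @export
extractROI <- function(video, post, halfWidthPx, halfHeightPx) {
  stopifnot(is(video, "VideoStream"))
  d <- dim(video@frames)
  cy <- round(post$y); cx <- round(post$x)
  rows <- max(1, cy - halfHeightPx + 1):min(d[1], cy + halfHeightPx)
  cols <- max(1, cx - halfWidthPx + 1):min(d[2], cx + halfWidthPx)
  if (length(rows) == 0 || length(cols) == 0) stop("empty ROI")
  new("VideoStream", frames = video@frames[rows, cols, , drop = FALSE],
      fps = video@fps, pixelSize = video@pixelSize)
}

#' Build a kymograph from a video
#'
#' Projects one pixel row of every frame over time: row t of the kymograph is
#' pixel row `scanlineRow` of frame t, so the number of kymograph rows equals
#' the number of frames and the number of columns equals the frame width.
#'
#' @param video a [VideoStream-class].
#' @param scanlineRow source row (1-based), or `"center"` for the middle row
#'   `floor(height / 2) + 1`.
#' @return a [Kymograph-class].
#' @examples
#' v <- videoStream(array(runif(20 * 40 * 50), c(20, 40, 50)), fps = 100)
#' buildKymograph(v)
#' @export
buildKymograph <- function(video, scanlineRow = "center") {
  stopifnot(is(video, "VideoStream"))
  d <- dim(video@frames)
  if (identical(scanlineRow, "center")) {
    scanlineRow <- floor(d[1] / 2) + 1L
  }
  scanlineRow <- as.integer(scanlineRow)
  if (scanlineRow < 1L || scanlineRow > d[1]) {
    stop(sprintf("scanline row %d outside frame height %d", scanlineRow, d[1]))
  }
  mat <- t(video@frames[scanlineRow, , , drop = TRUE])
  dim(mat) <- c(d[3], d[2])
  new("Kymograph", mat = mat, fps = video@fps, pixelSize = video@pixelSize,
      scanlineRow = scanlineRow)
}
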