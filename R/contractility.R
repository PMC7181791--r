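## Locate the first half-range threshold crossing in one kymograph row,
## scanning left-to-right within [lo, hi]. The edge is the dark->bright
## transition (post on the left of the crossing); position is the linear
## interpolation of the threshold between the two straddling pixel centres.
.firstCrossing <- function(row, thr, lo, hi) {
  lo <- max(1L, lo); hi <- min(length(row) - 1L, hi)
  if (lo > hi) return(NA_real_)
  j <- lo:hi
  hit <- which(row[j] <= thr & row[j + 1] > thr)
  if (length(hit) == 0) return(NA_real_)
  i <- j[hit[1]]
  i + (thr - row[i]) / (row[i + 1] - row[i])
}

#' Track the post edge through a kymograph at sub-pixel resolution
#'
#' Per kymograph row, the edge is the first crossing of the half-range
#' intensity threshold encountered when scanning away from the post (for the
#' left post: left to right, finding the dark-to-bright transition at its
#' inner edge). Sub-pixel position comes from linear interpolation of the
#' threshold between the two straddling pixels. Temporal continuity is
#' enforced by restricting the search to +/- `window` px around the previous
#' row's edge. Rows without a crossing (at most 5\%) inherit the neighbouring
#' estimate; more than 5\% missing rows is a tracking error.
#'
#' When the trace covers at least two seconds, the diastolic baseline and the
#' signed displacement are filled in via [computeBaseline()].
#'
#' @param kym a [Kymograph-class].
#' @param side which post the kymograph edge belongs to: `"left"` (default;
#'   the standard acquisition images the left post only) or `"right"`.
#'   Fixes both the scan direction and the sign convention (motion toward the
#'   well centre is positive).
#' @param window half-width of the per-row search window, px.
#' @param startCol optional column near the edge in the first row, e.g. from
#'   [detectPosts()]; by default the whole first row is scanned.
#' @return an [EdgeTrace-class].
#' @export
trackEdge <- function(kym, side = c("left", "right"), window = 15,
                      startCol = NULL) {
  stopifnot(is(kym, "Kymograph"))
  side <- match.arg(side)
  mat <- kym@mat
  w <- ncol(mat)
  if (side == "right") mat <- mat[, w:1, drop = FALSE]
  thr <- (max(mat) + min(mat)) / 2
  n <- nrow(mat)
  pos <- rep(NA_real_, n)
  prev <- NA_real_
  start <- if (is.null(startCol)) NULL else {
    if (side == "right") w + 1 - startCol else startCol
  }
  for (r in seq_len(n)) {
    if (is.na(prev)) {
      if (is.null(start)) {
        p <- .firstCrossing(mat[r, ], thr, 1L, w - 1L)
      } else {
        p <- .firstCrossing(mat[r, ], thr,
                            as.integer(floor(start - window)),
                            as.integer(ceiling(start + window)))
      }
    } else {
      p <- .firstCrossing(mat[r, ], thr,
                          as.integer(floor(prev - window)),
                          as.integer(ceiling(prev + window)))
    }
    pos[r] <- p
    if (!is.na(p)) prev <- p
  }
  bad <- which(is.na(pos))
  if (length(bad) > 0.05 * n) {
    stop(sprintf(
      "edge tracking failed: no threshold crossing in %d of %d rows (rows %s%s)",
      length(bad), n, paste(utils::head(bad, 10), collapse = ", "),
      if (length(bad) > 10) ", ..." else ""))
  }
  if (length(bad) > 0) {  # carry the nearest estimate into missing rows
    ok <- which(!is.na(pos))
    pos[bad] <- pos[vapply(bad, function(b) ok[which.min(abs(ok - b))], 1L)]
  }
  if (side == "right") pos <- w + 1 - pos
  trace <- new("EdgeTrace",
               t = (seq_len(n) - 1) / kym@fps, rawPosition = pos,
               displacement = rep(NA_real_, n), baselinePx = NA_real_,
               fps = kym@fps, pixelSize = kym@pixelSize, side = side)
  if (n / kym@fps >= 2) trace <- computeBaseline(trace) else trace
}

## Contraction moves the left post's edge rightwards and the right post's
## edge leftwards; this sign makes contraction positive for either side.
.traceSign <- function(trace) if (trace@side == "left") 1 else -1

#' Estimate the diastolic baseline of an edge trace
#'
#' The baseline is the rolling 10th percentile of the raw edge position over
#' a 2-second window (windows stepped by a quarter window), summarised by the
#' median across windows. Contraction pulses occupy a minority of each window,
#' so the low percentile sits on the diastolic rest position. Displacement is
#' then `(position - baseline) * pixelSize`, signed so contraction is
#' positive.
#'
#' @param trace an [EdgeTrace-class] covering at least 2 s.
#' @param windowS window length, s.
#' @param prob percentile used within each window.
#' @return the trace with `baselinePx` and `displacement` filled in.
#' @export
computeBaseline <- function(trace, windowS = 2, prob = 0.1) {
  stopifnot(is(trace, "EdgeTrace"))
  n <- length(trace@t)
  if (n < 2 * trace@fps) stop("trace must cover at least 2 s")
  sgn <- .traceSign(trace)
  adj <- sgn * trace@rawPosition
  w <- max(2L, as.integer(round(windowS * trace@fps)))
  step <- max(1L, w %/% 4L)
  starts <- seq(1L, max(1L, n - w + 1L), by = step)
  qs <- vapply(starts, function(s) {
    stats::quantile(adj[s:min(n, s + w - 1L)], prob, names = FALSE)
  }, numeric(1))
  baseAdj <- stats::median(qs)
  trace@baselinePx <- sgn * baseAdj
  trace@displacement <- (adj - baseAdj) * trace@pixelSize
  trace
}

## Topographic prominence of peak i among values x: height above the higher
## of the two minima separating it from higher terrain (or the trace ends).
.prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    lmin <- h
    i <- p
    while (i > 1) {
      i <- i - 1
      if (x[i] > h) break
      if (x[i] < lmin) lmin <- x[i]
    }
    rmin <- h
    i <- p
    n <- length(x)
    while (i < n) {
      i <- i + 1
      if (x[i] > h) break
      if (x[i] < rmin) rmin <- x[i]
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect beats in a baseline-corrected edge trace
#'
#' Peaks are local maxima of the displacement with topographic prominence of
#' at least `minProminenceUm` and pairwise spacing of at least
#' `minIntervalS`; when two candidates are closer than the minimum interval
#' the higher one wins (ties to the earlier index). Each beat's onset and end
#' are the nearest samples flanking the peak at which the displacement falls
#' to 10\% of the peak height. Per-beat upstroke/downstroke velocities use a
#' central-difference derivative at the acquisition rate.
#'
#' @param trace an [EdgeTrace-class] with displacement filled in.
#' @param minProminenceUm minimal peak prominence, um.
#' @param minIntervalS minimal spacing between peaks, s.
#' @return a data.frame with one row per beat: `onset_idx`, `peak_idx`,
#'   `end_idx` (1-based row indices), `amplitude_um`,
#'   `contraction_velocity_um_s`, `relaxation_velocity_um_s`. Zero rows when
#'   no beat qualifies (not an error).
#' @export
detectBeats <- function(trace, minProminenceUm = 1, minIntervalS = 0.25) {
  stopifnot(is(trace, "EdgeTrace"))
  x <- trace@displacement
  if (anyNA(x)) stop("displacement not computed; run computeBaseline first")
  n <- length(x)
  empty <- data.frame(onset_idx = integer(0), peak_idx = integer(0),
                      end_idx = integer(0), amplitude_um = numeric(0),
                      contraction_velocity_um_s = numeric(0),
                      relaxation_velocity_um_s = numeric(0))
  if (n < 3) return(empty)
  ## local maxima, first sample of any plateau
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0) return(empty)
  prom <- .prominence(x, cand)
  cand <- cand[prom >= minProminenceUm]
  if (length(cand) == 0) return(empty)
  ## enforce minimal spacing, higher peak wins, ties to the earlier index
  ord <- cand[order(-x[cand], cand)]
  minGap <- minIntervalS * trace@fps
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(kept - p) >= minGap)) kept <- c(kept, p)
  }
  peaks <- sort(kept)
  ## derivative, um/s (central differences; one-sided at the ends)
  v <- c(x[2] - x[1],
         (x[3:n] - x[1:(n - 2)]) / 2,
         x[n] - x[n - 1]) * trace@fps
  beats <- lapply(seq_along(peaks), function(i) {
    p <- peaks[i]
    thr10 <- 0.1 * x[p]
    loBound <- if (i > 1) peaks[i - 1] else 1L
    hiBound <- if (i < length(peaks)) peaks[i + 1] else n
    below <- which(x[loBound:p] <= thr10)
    onset <- if (length(below) > 0) loBound + max(below) - 1L else loBound
    below <- which(x[p:hiBound] <= thr10)
    end <- if (length(below) > 0) p + min(below) - 1L else hiBound
    ## the central difference at the peak itself averages the upstroke and
    ## downstroke slopes, so the peak sample is excluded from both phases
    up <- onset:max(onset, p - 1L)
    down <- min(end, p + 1L):end
    data.frame(onset_idx = onset, peak_idx = p, end_idx = end,
               amplitude_um = x[p],
               contraction_velocity_um_s = max(v[up]),
               relaxation_velocity_um_s = max(abs(v[down])))
  })
  do.call(rbind, beats)
}

#' Summarise a recording into contractility metrics
#'
#' Aggregates per-beat quantities by the median: beats per minute from the
#' median inter-peak interval (robust to partial beats at the recording
#' boundaries; 0 when fewer than two beats), amplitude as the median per-beat
#' peak displacement, and velocities as medians of the per-beat maxima.
#' When a calibration curve is supplied the contraction amplitude is
#' converted to force via [forceFromDeflection()].
#'
#' @param trace the [EdgeTrace-class] the beats were detected on.
#' @param beats the data.frame returned by [detectBeats()].
#' @param curve optional [CalibrationCurve-class].
#' @return a [ContractilityMetrics-class].
#' @export
computeMetrics <- function(trace, beats, curve = NULL) {
  stopifnot(is(trace, "EdgeTrace"), is.data.frame(beats))
  n <- length(trace@t)
  need <- c("onset_idx", "peak_idx", "end_idx", "amplitude_um",
            "contraction_velocity_um_s", "relaxation_velocity_um_s")
  if (!all(need %in% names(beats))) stop("beats is not a detectBeats result")
  if (nrow(beats) > 0 && (max(beats$end_idx) > n || min(beats$onset_idx) < 1)) {
    stop("beat indices outside the trace: beats do not match this trace")
  }
  nb <- nrow(beats)
  if (nb == 0) {
    return(new("ContractilityMetrics", beatsPerMinute = 0,
               contractionAmplitude = NA_real_,
               contractionVelocity = NA_real_, relaxationVelocity = NA_real_,
               force = NA_real_, nBeats = 0L, durationS = n / trace@fps))
  }
  bpm <- if (nb >= 2) {
    60 / stats::median(diff(trace@t[beats$peak_idx]))
  } else 0
  amp <- stats::median(beats$amplitude_um)
  force <- if (!is.null(curve) && is.finite(amp)) {
    as.numeric(forceFromDeflection(amp, curve))
  } else NA_real_
  new("ContractilityMetrics",
      beatsPerMinute = bpm, contractionAmplitude = amp,
      contractionVelocity = stats::median(beats$contraction_velocity_um_s),
      relaxationVelocity = stats::median(beats$relaxation_velocity_um_s),
      force = force, nBeats = as.integer(nb), durationS = n / trace@fps)
}

#' Full kymograph-to-metrics convenience pipeline
#'
#' Runs [trackEdge()], [detectBeats()] and [computeMetrics()] in sequence
#' with the given parameters.
#'
#' @param kym a [Kymograph-class].
#' @param side post side, passed to [trackEdge()].
#' @param curve optional [CalibrationCurve-class] for force conversion.
#' @param minProminenceUm,minIntervalS beat-detection parameters.
#' @param ... further arguments to [trackEdge()].
#' @return a [ContractilityMetrics-class].
#' @export
analyzeKymograph <- function(kym, side = "left", curve = NULL,
                             minProminenceUm = 1, minIntervalS = 0.25, ...) {
  trace <- trackEdge(kym, side = side, ...)
  beats <- detectBeats(trace, minProminenceUm, minIntervalS)
  computeMetrics(trace, beats, curve)
}

#' One-row summary table of contractility metrics
#'
#' @param metrics a [ContractilityMetrics-class] or a named list of them
#'   (names become the `well` column).
#' @return a data.frame with columns `well`, `n_beats`, `bpm`,
#'   `amplitude_um`, `contraction_velocity_um_s`, `relaxation_velocity_um_s`,
#'   `force_uN`.
#' @export
metricsTable <- function(metrics) {
  if (is(metrics, "ContractilityMetrics")) metrics <- list(well = metrics)
  do.call(rbind, lapply(names(metrics), function(nm) {
    m <- metrics[[nm]]
    data.frame(well = nm, n_beats = m@nBeats, bpm = m@beatsPerMinute,
               amplitude_um = m@contractionAmplitude,
               contraction_velocity_um_s = m@contractionVelocity,
               relaxation_velocity_um_s = m@relaxationVelocity,
               force_uN = m@force)
  }))
}

#' Agreement between automated and manual amplitude measurements
#'
#' Pearson correlation and the least-squares line of automated against
#' manual contraction amplitudes, the standard validation that an automated
#' tracking script reproduces hand measurements made on the same kymographs.
#'
#' @param auto automated amplitudes, um.
#' @param manual manual amplitudes, um (same recordings, same order).
#' @return a list with `r` (Pearson), `slope`, `intercept`, `residuals`
#'   and `n`.
#' @examples
#' compareAutomatedManual(c(1, 2, 3.1), c(1, 2, 3))
#' @export
compareAutomatedManual <- function(auto, manual) {
  if (length(auto) != length(manual)) stop("vectors must have equal length")
  if (length(auto) < 3) stop("need at least 3 paired measurements")
  if (stats::sd(auto) == 0 || stats::sd(manual) == 0) {
    stop("zero variance in one of the vectors; correlation undefined")
  }
  fit <- stats::lm(auto ~ manual)
  list(r = stats::cor(auto, manual),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       residuals = unname(stats::residuals(fit)),
       n = length(auto))
}
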