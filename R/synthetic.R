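## Run fun() under a fixed RNG seed without disturbing the caller's RNG
## stream; with seed = NULL the global stream is used as-is.
.withSeed <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  fun()
}

#' Synthetic contraction waveform with ground truth
#'
#' Generates a displacement time series emulating the post-edge motion of a
#' beating cardiac ring: per beat, a fast linear upstroke over
#' `contractionTime` followed by a slower linear relaxation over
#' `relaxationTime`, repeated at the beat period 60/bpm, resting at zero in
#' between (optionally with cosine-smoothed ramps). Additive Gaussian noise
#' and a linear drift can be superimposed; the returned ground truth always
#' refers to the clean waveform.
#'
#' @param bpm beat rate, 1/min.
#' @param amplitudeUm peak displacement per beat, um.
#' @param fps sampling rate, frames per second.
#' @param durationS duration, s.
#' @param contractionTime upstroke duration, s.
#' @param relaxationTime downstroke duration, s
#'   (`contractionTime + relaxationTime` must be below the beat period).
#' @param noiseSd additive Gaussian noise SD, um.
#' @param driftRateUmS linear baseline drift, um/s.
#' @param onsetOffsetS time of the first beat onset; defaults to a tenth of
#'   the beat period.
#' @param smooth use cosine-smoothed ramps instead of linear ones.
#' @param seed RNG seed; the generator is a pure function of its arguments
#'   for a fixed seed and does not disturb the caller's RNG stream.
#' @return a list: `t`, `displacement` (um, noise and drift included),
#'   `clean` (noise-free, drift-free waveform) and `truth` — a list with the
#'   beat annotation data.frame (`onset_idx`, `peak_idx`, `end_idx`, 1-based
#'   sample indices), `amplitude_um`, `bpm`, `max_rise_slope` and
#'   `max_fall_slope` (um/s, analytic).
#' @examples
#' w <- makeWaveform(60, 10, fps = 100, durationS = 20)
#' nrow(w$truth$beats)  # 20 beats
#' @export
makeWaveform <- function(bpm, amplitudeUm, fps, durationS,
                         contractionTime = 0.15, relaxationTime = 0.35,
                         noiseSd = 0, driftRateUmS = 0, onsetOffsetS = NULL,
                         smooth = FALSE, seed = NULL) {
  n <- round(fps * durationS)
  t <- (seq_len(n) - 1) / fps
  beats <- data.frame(onset_idx = integer(0), peak_idx = integer(0),
                      end_idx = integer(0))
  clean <- numeric(n)
  if (amplitudeUm > 0 && bpm > 0) {
    period <- 60 / bpm
    if (contractionTime + relaxationTime >= period) {
      stop("contractionTime + relaxationTime must be below the beat period")
    }
    if (is.null(onsetOffsetS)) onsetOffsetS <- 0.1 * period
    onsets <- seq(onsetOffsetS, durationS, by = period)
    onsets <- onsets[onsets + contractionTime + relaxationTime <= durationS]
    for (on in onsets) {
      rise <- t >= on & t < on + contractionTime
      fall <- t >= on + contractionTime &
        t <= on + contractionTime + relaxationTime
      sr <- (t[rise] - on) / contractionTime
      sf <- (t[fall] - on - contractionTime) / relaxationTime
      if (smooth) {
        clean[rise] <- amplitudeUm * (1 - cos(pi * sr)) / 2
        clean[fall] <- amplitudeUm * (1 + cos(pi * sf)) / 2
      } else {
        clean[rise] <- amplitudeUm * sr
        clean[fall] <- amplitudeUm * (1 - sf)
      }
    }
    beats <- data.frame(
      onset_idx = pmin(n, round(onsets * fps) + 1L),
      peak_idx = pmin(n, round((onsets + contractionTime) * fps) + 1L),
      end_idx = pmin(n, round((onsets + contractionTime + relaxationTime) *
                                fps) + 1L))
  }
  noise <- if (noiseSd > 0) {
    .withSeed(seed, function() stats::rnorm(n, 0, noiseSd))
  } else numeric(n)
  slopeScale <- if (smooth) pi / 2 else 1
  list(
    t = t,
    displacement = clean + noise + driftRateUmS * t,
    clean = clean,
    truth = list(
      beats = beats, amplitude_um = amplitudeUm, bpm = bpm,
      max_rise_slope = slopeScale * amplitudeUm / contractionTime,
      max_fall_slope = slopeScale * amplitudeUm / relaxationTime))
}

#' Scene description for synthetic well videos
#'
#' Describes a transmitted-light field of view holding two dark vertical
#' posts on a bright background, as seen by the contractility acquisition
#' (defaults: 20 s at 100 frames per second, 0.2 um/px as at a 20x
#' objective). `postSepPx` is the distance between the two inner post edges;
#' the left post's inner edge is the tracked, moving edge.
#'
#' @param frameHeight,frameWidth frame size, px.
#' @param pixelSize physical pixel size, um/px.
#' @param postWidthPx,postHeightPx post cross-section size in the image, px.
#' @param postSepPx separation between inner post edges, px.
#' @param bgLevel,postLevel background and post intensity (0-1 scale).
#' @param noiseSd additive Gaussian pixel noise SD (intensity units).
#' @param fps frame rate, frames per second.
#' @param durationS video duration, s.
#' @param seed RNG seed for the pixel noise.
#' @return a list of class `sceneSpec`.
#' @export
sceneSpec <- function(frameHeight = 60, frameWidth = 220, pixelSize = 0.2,
                      postWidthPx = 24, postHeightPx = round(0.8 * frameHeight),
                      postSepPx = 120,
                      bgLevel = 0.85, postLevel = 0.15, noiseSd = 0,
                      fps = 100, durationS = 20, seed = NULL) {
  if (2 * postWidthPx + postSepPx > frameWidth - 4) {
    stop("posts do not fit in the frame")
  }
  if (postHeightPx > frameHeight) stop("posts taller than the frame")
  if (abs(fps * durationS - round(fps * durationS)) > 1e-9) {
    stop("fps * durationS must be an integer frame count")
  }
  spec <- list(frameHeight = frameHeight, frameWidth = frameWidth,
               pixelSize = pixelSize, postWidthPx = postWidthPx,
               postHeightPx = postHeightPx, postSepPx = postSepPx,
               bgLevel = bgLevel, postLevel = postLevel, noiseSd = noiseSd,
               fps = fps, durationS = durationS, seed = seed)
  class(spec) <- "sceneSpec"
  spec
}

## Coverage of pixel columns j (centres at integers, each covering
## [j - 0.5, j + 0.5]) by the interval [a, b]; vectorised over j.
.pixelCoverage <- function(j, a, b) {
  pmax(0, pmin(b, j + 0.5) - pmax(a, j - 0.5))
}

#' Render a synthetic post-deflection video
#'
#' Draws two dark vertical posts on a bright background; the left post
#' translates horizontally following the supplied waveform (positive
#' displacement moves it toward the well centre, i.e. to the right). Post
#' edges are rendered with sub-pixel anti-aliasing: a boundary pixel's
#' intensity is the area-weighted mix of post and background, so the
#' ground-truth edge positions are meaningful at sub-pixel resolution.
#' Seeded Gaussian pixel noise is added last.
#'
#' @param scene a [sceneSpec()].
#' @param waveformUm displacement per frame, um (e.g.
#'   `makeWaveform(...)$displacement`); its length must equal the frame
#'   count `fps * durationS`.
#' @return a list: `video` (a [VideoStream-class]) and `truth` — a list with
#'   `edge_col` (true sub-pixel inner-edge column of the left post per
#'   frame, pixel-centre coordinates), `posts` (true centroid data.frame),
#'   and the scene.
#' @export
renderVideo <- function(scene, waveformUm) {
  stopifnot(inherits(scene, "sceneSpec"))
  nT <- round(scene$fps * scene$durationS)
  if (length(waveformUm) != nT) {
    stop(sprintf("waveform length %d != frame count %d",
                 length(waveformUm), nT))
  }
  H <- scene$frameHeight; W <- scene$frameWidth
  dispPx <- waveformUm / scene$pixelSize
  eL0 <- (W - scene$postSepPx) / 2      # left post inner edge, at rest
  eR0 <- eL0 + scene$postSepPx          # right post inner edge (static)
  pw <- scene$postWidthPx
  edge <- eL0 + dispPx
  if (any(edge - pw < 1.5) || any(edge > eR0 - 2)) {
    stop("displacement moves the post outside its lane")
  }
  rows <- floor((H - scene$postHeightPx) / 2) + seq_len(scene$postHeightPx)
  bg <- scene$bgLevel; fg <- scene$postLevel
  frames <- array(bg, dim = c(H, W, nT))
  ## static right post, drawn once
  colsR <- floor(eR0 - 0.5):ceiling(eR0 + pw + 0.5)
  colsR <- colsR[colsR >= 1 & colsR <= W]
  covR <- .pixelCoverage(colsR, eR0, eR0 + pw)
  rowR <- bg + (fg - bg) * covR
  for (tt in seq_len(nT)) {
    frames[rows, colsR, tt] <- matrix(rowR, length(rows), length(colsR),
                                      byrow = TRUE)
    a <- edge[tt] - pw
    colsL <- floor(a - 0.5):ceiling(edge[tt] + 0.5)
    colsL <- colsL[colsL >= 1 & colsL <= W]
    covL <- .pixelCoverage(colsL, a, edge[tt])
    frames[rows, colsL, tt] <- matrix(bg + (fg - bg) * covL,
                                      length(rows), length(colsL),
                                      byrow = TRUE)
  }
  if (scene$noiseSd > 0) {
    frames <- frames + .withSeed(scene$seed, function() {
      array(stats::rnorm(length(frames), 0, scene$noiseSd), dim = dim(frames))
    })
  }
  posts <- data.frame(
    side = c("left", "right"),
    x = c(eL0 - pw / 2, eR0 + pw / 2),
    y = mean(rows))
  list(video = videoStream(frames, fps = scene$fps,
                           pixelSize = scene$pixelSize),
       truth = list(edge_col = edge, posts = posts, scene = scene))
}

#' Synthetic single-frame well image with two posts
#'
#' Convenience wrapper rendering one frame of [renderVideo()] at rest, for
#' testing post detection and focus scoring.
#'
#' @param scene a [sceneSpec()].
#' @return a list: `image` (a [WellImage-class]) and `truth` (post
#'   centroids).
#' @export
renderWellImage <- function(scene = sceneSpec()) {
  scene$durationS <- 1 / scene$fps
  out <- renderVideo(scene, 0)
  list(image = wellImage(out$video@frames[, , 1],
                         pixelSize = scene$pixelSize),
       truth = out$truth)
}

#' Simulate responses from a known quadratic surface on a CCD
#'
#' Evaluates y = X beta + noise over the design's coded runs, where X is the
#' full quadratic model matrix and `coefficients` is named like the
#' [fitQuadratic()] coefficient vector.
#'
#' @param design a [CCDDesign-class].
#' @param coefficients named coefficient vector over the full quadratic term
#'   set (see [coef()] on an [RSMFit-class] for the naming).
#' @param noiseSd Gaussian noise SD.
#' @param seed RNG seed.
#' @return a list: `responses`, `beta` (the truth, in model-matrix order)
#'   and `X` (the model matrix).
#' @export
makeCCDResponses <- function(design, coefficients, noiseSd = 0, seed = NULL) {
  stopifnot(is(design, "CCDDesign"))
  X <- .quadModelMatrix(design@coded)
  if (!setequal(names(coefficients), colnames(X))) {
    stop("coefficients must be named after the full quadratic term set: ",
         paste(colnames(X), collapse = ", "))
  }
  beta <- coefficients[colnames(X)]
  y <- drop(X %*% beta)
  if (noiseSd > 0) {
    y <- y + .withSeed(seed, function() {
      stats::rnorm(length(y), 0, noiseSd)
    })
  }
  list(responses = y, beta = beta, X = X)
}

#' Coefficient preset for the tissue-formulation surface
#'
#' A quadratic surface over [tissueFormulationFactors()] emulating the
#' optimisation outcome of the ring-formulation experiment: a strong
#' positive linear effect of the cardiomyocyte fraction (so its optimum sits
#' on the +1 face, 90\%) and concave effects of collagen and total cells
#' with interior stationary values at coded +0.15 and +0.18 — decoding to
#' 2.03 mg/mL collagen and 75,400 cells. Response units are micrometres of
#' post deflection.
#'
#' @return a named coefficient vector for [makeCCDResponses()].
#' @export
tissueSurfacePreset <- function() {
  nms <- tissueFormulationFactors()$name
  coefs <- stats::setNames(numeric(10), .quadTerms(nms))
  coefs[["(Intercept)"]] <- 6
  coefs[["cardiomyocyte_pct"]] <- 3
  coefs[["collagen_mg_ml"]] <- 0.6     # stationary at  0.6 / (2 * 2) = 0.15
  coefs[["total_cells"]] <- 0.54       # stationary at 0.54 / (2 * 1.5) = 0.18
  coefs[["collagen_mg_ml^2"]] <- -2
  coefs[["total_cells^2"]] <- -1.5
  coefs
}

#' Hill-type dose-response profiles for known inotropes
#'
#' `inotropePreset("negative")` emulates a myosin-inhibitor-like compound
#' (contraction amplitude suppressed with dose); `"positive"` a
#' beta-agonist-like compound whose effect saturates near the micromolar
#' range.
#'
#' @param direction `"negative"` or `"positive"`.
#' @return a list with `emax`, `ec50` (molar), `hill` and `direction`
#'   (+1/-1), for [makeDoseResponse()].
#' @export
inotropePreset <- function(direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  if (direction == "negative") {
    list(emax = 0.8, ec50 = 1e-7, hill = 1, direction = -1)
  } else {
    list(emax = 0.4, ec50 = 5e-8, hill = 1.2, direction = 1)
  }
}

#' Simulate a drug-screen dose-response table
#'
#' Amplitudes follow `vehicleAmplitude * (1 + direction * effect(dose))`
#' with a Hill effect `emax * dose^h / (dose^h + ec50^h)`, plus Gaussian
#' noise, for `nPerDose` replicate wells per dose in each of `nExperiments`
#' independent experiments (vehicle wells included per experiment). The
#' default dose panel is 1 nM, 10 nM, 100 nM, 1 uM, 10 uM.
#'
#' @param profile a list with `emax`, `ec50`, `hill`, `direction`
#'   (see [inotropePreset()]).
#' @param doses dose panel, molar.
#' @param nPerDose replicate wells per dose per experiment.
#' @param nExperiments number of independent experiments.
#' @param vehicleAmplitude mean vehicle contraction amplitude, um.
#' @param noiseSd additive amplitude noise SD, um.
#' @param seed RNG seed.
#' @param compound compound label in the table.
#' @return a list: `table` (columns `well`, `compound`, `dose`,
#'   `amplitude`, `experiment`) and `truth` (`doses`,
#'   `relative_change` of the noiseless curve per dose, and the profile).
#' @export
makeDoseResponse <- function(profile, doses = c(1e-9, 1e-8, 1e-7, 1e-6, 1e-5),
                             nPerDose = 3, nExperiments = 3,
                             vehicleAmplitude = 10, noiseSd = 0.5,
                             seed = NULL, compound = "compound") {
  stopifnot(all(doses > 0), nPerDose >= 1, nExperiments >= 1)
  effect <- function(d) {
    profile$emax * d^profile$hill / (d^profile$hill + profile$ec50^profile$hill)
  }
  relTruth <- profile$direction * effect(doses)
  levels <- c(0, doses)  # 0 = vehicle
  nrows <- length(levels) * nPerDose * nExperiments
  tab <- data.frame(
    well = paste0("W", seq_len(nrows)),
    compound = compound,
    dose = rep(rep(levels, each = nPerDose), nExperiments),
    amplitude = NA_real_,
    experiment = rep(paste0("E", seq_len(nExperiments)),
                     each = length(levels) * nPerDose))
  mu <- vehicleAmplitude *
    (1 + profile$direction * effect(pmax(tab$dose, 0)) * (tab$dose > 0))
  tab$amplitude <- mu + if (noiseSd > 0) {
    .withSeed(seed, function() stats::rnorm(nrows, 0, noiseSd))
  } else 0
  list(table = tab,
       truth = list(doses = doses, relative_change = relTruth,
                    vehicle_amplitude = vehicleAmplitude, profile = profile))
}
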