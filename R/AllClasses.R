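#' @import methods
#' @importFrom stats coef
NULL

#' CantileverSpec: geometry and material of one elastomeric post
#'
#' Describes a prismatic PDMS microcantilever with a rectangular cross-section
#' (bending axis along the thickness) and an angled tissue anchor at the tip.
#' Geometry is stored in millimetres and the Young's modulus in MPa; deflection
#' and force conversions report micrometres and micronewtons.
#'
#' @slot length post height from base to tip, mm.
#' @slot width cross-section width, mm.
#' @slot thickness cross-section thickness (bending direction), mm.
#' @slot youngsModulus elastic modulus of the elastomer, MPa.
#' @slot anchorLength length of the angled anchor segment at the tip, mm.
#' @slot anchorAngle anchor angle from the horizontal, degrees in (0, 90].
#'
#' @seealso [cantileverSpec()], [secondMoment()], [theoreticalDeflection()]
#' @export
setClass("CantileverSpec",
  representation(
    length = "numeric", width = "numeric", thickness = "numeric",
    youngsModulus = "numeric", anchorLength = "numeric",
    anchorAngle = "numeric"
  )
)

setValidity("CantileverSpec", function(object) {
  v <- c(
    length = object@length, width = object@width,
    thickness = object@thickness, youngsModulus = object@youngsModulus,
    anchorLength = object@anchorLength, anchorAngle = object@anchorAngle
  )
  if (any(!is.finite(v)) || any(v <= 0)) {
    return("all cantilever parameters must be finite and positive")
  }
  if (object@anchorLength >= object@length) {
    return("anchorLength must be smaller than the post length")
  }
  if (object@anchorAngle > 90) {
    return("anchorAngle must lie in (0, 90] degrees")
  }
  TRUE
})

#' LoadConfig: where force is applied and where motion is observed
#'
#' The tissue ring applies a point load at height `loadHeight` above the post
#' base; displacement is imaged at `measureHeight` (the post tip by default,
#' since the autofocus routine locks onto the top edge of the post).
#'
#' @slot loadHeight height of the point load above the base, mm.
#' @slot measureHeight height at which displacement is observed, mm
#'   (must be >= loadHeight).
#'
#' @seealso [loadConfig()], [defaultLoadConfig()]
#' @export
setClass("LoadConfig",
  representation(loadHeight = "numeric", measureHeight = "numeric")
)

setValidity("LoadConfig", function(object) {
  if (!is.finite(object@loadHeight) || object@loadHeight <= 0) {
    return("loadHeight must be finite and positive")
  }
  if (!is.finite(object@measureHeight) ||
      object@measureHeight < object@loadHeight) {
    return("measureHeight must be finite and >= loadHeight")
  }
  TRUE
})

#' CalibrationCurve: empirical force-displacement map of a post
#'
#' Holds the (displacement, force) samples measured with a force transducer
#' pressed against the post, the fitted model and its coefficients. The
#' linear-through-origin model summarises the post by a single stiffness k
#' (uN/um); the cubic model (also through the origin) accommodates mild
#' nonlinearity at large deflections.
#'
#' @slot samples data.frame with columns `displacement_um`, `force_uN` and
#'   `residual` (fit diagnostics), displacements strictly increasing.
#' @slot modelKind `"linear_through_origin"` or `"cubic_polynomial"`.
#' @slot coefficients named numeric vector of fitted coefficients
#'   (`k` for linear; `c1`, `c2`, `c3` for cubic).
#' @slot loadHeight height at which the calibration was performed, mm
#'   (NA when unknown).
#'
#' @seealso [fitCalibration()], [forceFromDeflection()]
#' @export
setClass("CalibrationCurve",
  representation(
    samples = "data.frame", modelKind = "character",
    coefficients = "numeric", loadHeight = "numeric"
  )
)

setValidity("CalibrationCurve", function(object) {
  s <- object@samples
  if (!all(c("displacement_um", "force_uN") %in% names(s))) {
    return("samples must have displacement_um and force_uN columns")
  }
  if (!object@modelKind %in% c("linear_through_origin", "cubic_polynomial")) {
    return("unknown modelKind")
  }
  nmin <- if (object@modelKind == "linear_through_origin") 2L else 4L
  if (nrow(s) < nmin) {
    return(sprintf("at least %d samples required for %s", nmin,
                   object@modelKind))
  }
  if (any(diff(s$displacement_um) <= 0)) {
    return("displacements must be strictly increasing")
  }
  ## fitted force must be monotone non-decreasing over the sampled range
  grid <- seq(min(s$displacement_um), max(s$displacement_um), length.out = 256)
  f <- .evalCalibration(object@coefficients, object@modelKind, grid)
  if (any(diff(f) < -1e-9 * max(abs(f), 1))) {
    return("fitted force is not monotone non-decreasing over the sampled range")
  }
  TRUE
})

#' WellImage: a single low-magnification image of one well
#'
#' @slot pixels numeric matrix of intensities; row = y, column = x, origin at
#'   the top-left, 1-based indices (the convention used throughout the
#'   package).
#' @slot pixelSize physical pixel size, um/px.
#' @slot bitDepth nominal bit depth of the source camera.
#'
#' @seealso [wellImage()], [detectPosts()], [focusScore()]
#' @export
setClass("WellImage",
  representation(pixels = "matrix", pixelSize = "numeric",
                 bitDepth = "integer")
)

setValidity("WellImage", function(object) {
  if (length(object@pixels) == 0) return("empty pixel grid")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0) {
    return("pixelSize must be positive")
  }
  TRUE
})

#' VideoStream: an ordered stack of equal-sized frames
#'
#' @slot frames numeric array of dimension height x width x n_frames.
#' @slot fps acquisition rate, frames per second.
#' @slot pixelSize physical pixel size, um/px.
#'
#' @seealso [videoStream()], [buildKymograph()], [extractROI()]
#' @export
setClass("VideoStream",
  representation(frames = "array", fps = "numeric", pixelSize = "numeric")
)

setValidity("VideoStream", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3 || any(d == 0)) {
    return("frames must be a non-empty height x width x n_frames array")
  }
  if (!is.finite(object@fps) || object@fps <= 0) return("fps must be positive")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0) {
    return("pixelSize must be positive")
  }
  TRUE
})

#' Kymograph: one scanline of every frame, stacked over time
#'
#' Row t of the matrix is pixel row `scanlineRow` of frame t, so post motion
#' along the scanline appears as a wavy intensity edge running down the image.
#'
#' @slot mat time x position intensity matrix (one row per frame).
#' @slot fps frame rate of the source video, frames per second.
#' @slot pixelSize physical pixel size, um/px.
#' @slot scanlineRow source pixel row in the video frames (1-based).
#'
#' @seealso [buildKymograph()], [trackEdge()]
#' @export
setClass("Kymograph",
  representation(mat = "matrix", fps = "numeric", pixelSize = "numeric",
                 scanlineRow = "integer")
)

setValidity("Kymograph", function(object) {
  if (length(object@mat) == 0) return("empty kymograph")
  if (!is.finite(object@fps) || object@fps <= 0) return("fps must be positive")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0) {
    return("pixelSize must be positive")
  }
  TRUE
})

#' EdgeTrace: sub-pixel post-edge position over time
#'
#' `rawPosition` is the tracked edge column per kymograph row (sub-pixel,
#' original image coordinates). After baseline estimation, `displacement`
#' holds the baseline-corrected motion in micrometres, signed so that motion
#' toward the well centre (contraction) is positive for either post.
#'
#' @slot t time of each sample, s.
#' @slot rawPosition sub-pixel edge column per row, px.
#' @slot displacement baseline-corrected displacement, um (NA until
#'   [computeBaseline()] has been applied).
#' @slot baselinePx diastolic baseline position, px (NA until computed).
#' @slot fps sampling rate, frames per second.
#' @slot pixelSize physical pixel size, um/px.
#' @slot side which post was tracked, `"left"` or `"right"` (fixes the sign
#'   convention: toward the well centre is positive).
#'
#' @seealso [trackEdge()], [computeBaseline()], [detectBeats()]
#' @export
setClass("EdgeTrace",
  representation(
    t = "numeric", rawPosition = "numeric", displacement = "numeric",
    baselinePx = "numeric", fps = "numeric", pixelSize = "numeric",
    side = "character"
  )
)

setValidity("EdgeTrace", function(object) {
  n <- length(object@t)
  if (n < 2) return("trace needs at least two samples")
  if (length(object@rawPosition) != n || length(object@displacement) != n) {
    return("t, rawPosition and displacement must have equal length")
  }
  dt <- diff(object@t)
  if (any(dt <= 0)) return("t must be strictly increasing")
  if (!object@side %in% c("left", "right")) {
    return("side must be 'left' or 'right'")
  }
  TRUE
})

#' ContractilityMetrics: the per-tissue summary of one recording
#'
#' @slot beatsPerMinute beat rate from the median inter-peak interval, 1/min.
#' @slot contractionAmplitude median per-beat peak displacement above the
#'   diastolic baseline, um.
#' @slot contractionVelocity median over beats of the maximal upstroke
#'   slope, um/s.
#' @slot relaxationVelocity median over beats of the maximal downstroke
#'   slope magnitude, um/s.
#' @slot force contractile force from the calibration curve at the
#'   contraction amplitude, uN (NA when no calibration supplied).
#' @slot nBeats number of detected beats.
#' @slot durationS analysed duration, s.
#'
#' @seealso [computeMetrics()], [analyzeKymograph()]
#' @export
setClass("ContractilityMetrics",
  representation(
    beatsPerMinute = "numeric", contractionAmplitude = "numeric",
    contractionVelocity = "numeric", relaxationVelocity = "numeric",
    force = "numeric", nBeats = "integer", durationS = "numeric"
  )
)

setValidity("ContractilityMetrics", function(object) {
  mags <- c(object@beatsPerMinute, object@contractionAmplitude,
            object@contractionVelocity, object@relaxationVelocity,
            object@force)
  if (any(mags < 0, na.rm = TRUE)) return("all magnitudes must be >= 0")
  if (object@nBeats < 0) return("nBeats must be >= 0")
  TRUE
})

#' CCDDesign: a face-centred central composite design
#'
#' Coded levels are -1/0/+1 (face-centred, so the axial distance alpha = 1 and
#' every factor is run at exactly three levels). Runs are ordered factorial
#' block, axial block, centre block, deterministically within block.
#'
#' @slot factors data.frame with columns `name`, `low`, `mid`, `high`
#'   (natural units).
#' @slot coded runs x factors matrix of coded levels in \{-1, 0, +1\}.
#' @slot pointType `"factorial"`, `"axial"` or `"center"` per run.
#' @slot reps named integer vector of replicate counts
#'   (`factorial`, `axial`, `center`).
#'
#' @seealso [generateCCD()], [designTable()], [fitQuadratic()]
#' @export
setClass("CCDDesign",
  representation(factors = "data.frame", coded = "matrix",
                 pointType = "character", reps = "integer")
)

setValidity("CCDDesign", function(object) {
  k <- nrow(object@factors)
  if (k < 2) return("a CCD needs at least two factors")
  r <- object@reps
  expected <- 2^k * r[["factorial"]] + 2 * k * r[["axial"]] + r[["center"]]
  if (nrow(object@coded) != expected) {
    return(sprintf("run count %d does not match 2^k*r_f + 2k*r_a + r_c = %d",
                   nrow(object@coded), expected))
  }
  if (!all(object@coded %in% c(-1, 0, 1))) {
    return("coded levels must be -1, 0 or +1 (face-centred)")
  }
  if (length(object@pointType) != nrow(object@coded)) {
    return("pointType length must equal run count")
  }
  TRUE
})

#' RSMFit: a fitted full quadratic response surface
#'
#' Ordinary least squares on the full second-order model in coded units
#' (intercept, k linear, k(k-1)/2 two-way interaction and k pure quadratic
#' terms), with a per-term partial (Type III) ANOVA.
#'
#' @slot coefficients named coefficient vector on the coded scale.
#' @slot se standard errors of the coefficients.
#' @slot anova data.frame with one row per model term plus a residual row:
#'   `term`, `df`, `sum_sq`, `mean_sq`, `F`, `p`.
#' @slot rSquared coefficient of determination (0 by convention when the
#'   total sum of squares is zero).
#' @slot residualDf residual degrees of freedom.
#' @slot sigma residual standard error.
#' @slot factors the factor table of the design the fit was computed on.
#'
#' @seealso [fitQuadratic()], [predictOptimum()]
#' @export
setClass("RSMFit",
  representation(
    coefficients = "numeric", se = "numeric", anova = "data.frame",
    rSquared = "numeric", residualDf = "numeric", sigma = "numeric",
    factors = "data.frame"
  )
)

setValidity("RSMFit", function(object) {
  p <- object@anova$p
  p <- p[is.finite(p)]
  if (any(p < 0 | p > 1)) return("p-values must lie in [0, 1]")
  if (object@residualDf < 0) return("negative residual df")
  TRUE
})

#' OptimumPrediction: the response-maximizing factor settings
#'
#' @slot coded optimal settings on the coded scale, within the [-1, 1] box.
#' @slot natural the same settings decoded to natural units.
#' @slot predictedResponse fitted response at the optimum.
#' @slot objective `"maximize"` or `"minimize"`.
#'
#' @seealso [predictOptimum()]
#' @export
setClass("OptimumPrediction",
  representation(coded = "numeric", natural = "numeric",
                 predictedResponse = "numeric", objective = "character")
)

setValidity("OptimumPrediction", function(object) {
  if (any(object@coded < -1 - 1e-8 | object@coded > 1 + 1e-8)) {
    return("coded settings must lie within the [-1, 1] box")
  }
  TRUE
})
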