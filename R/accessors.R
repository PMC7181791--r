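#' Accessors for imaging containers
#'
#' `pixelSize()` returns the physical pixel size in um/px, `fps()` the frame
#' rate in frames per second, `nFrames()` the number of frames of a video,
#' `frames()` the raw frame array, and `kymoMatrix()` the time x position
#' intensity matrix of a kymograph.
#'
#' @param x a [WellImage-class], [VideoStream-class], [Kymograph-class] or
#'   [EdgeTrace-class] object (as applicable).
#' @return a numeric scalar, array or matrix, as described above.
#' @name imaging-accessors
#' @examples
#' v <- videoStream(array(0.5, c(4, 6, 10)), fps = 100, pixelSize = 0.2)
#' fps(v)
#' nFrames(v)
NULL

#' @rdname imaging-accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname imaging-accessors
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' @rdname imaging-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname imaging-accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname imaging-accessors
#' @export
setGeneric("kymoMatrix", function(x) standardGeneric("kymoMatrix"))

#' @rdname imaging-accessors
setMethod("pixelSize", "WellImage", function(x) x@pixelSize)
#' @rdname imaging-accessors
setMethod("pixelSize", "VideoStream", function(x) x@pixelSize)
#' @rdname imaging-accessors
setMethod("pixelSize", "Kymograph", function(x) x@pixelSize)
#' @rdname imaging-accessors
setMethod("pixelSize", "EdgeTrace", function(x) x@pixelSize)

#' @rdname imaging-accessors
setMethod("fps", "VideoStream", function(x) x@fps)
#' @rdname imaging-accessors
setMethod("fps", "Kymograph", function(x) x@fps)
#' @rdname imaging-accessors
setMethod("fps", "EdgeTrace", function(x) x@fps)

#' @rdname imaging-accessors
setMethod("nFrames", "VideoStream", function(x) dim(x@frames)[3])
#' @rdname imaging-accessors
setMethod("frames", "VideoStream", function(x) x@frames)
#' @rdname imaging-accessors
setMethod("kymoMatrix", "Kymograph", function(x) x@mat)

#' @describeIn CalibrationCurve-class fitted coefficients of the calibration
#'   model.
#' @param object a `CalibrationCurve` or `RSMFit` object.
#' @param ... ignored.
#' @export
setMethod("coef", "CalibrationCurve", function(object, ...) object@coefficients)

#' @describeIn RSMFit-class fitted quadratic coefficients on the coded scale.
#' @param object an `RSMFit` object.
#' @param ... ignored.
#' @export
setMethod("coef", "RSMFit", function(object, ...) object@coefficients)

setMethod("show", "CantileverSpec", function(object) {
  cat(sprintf(
    "CantileverSpec: L=%.3g mm, w=%.3g mm, t=%.3g mm, E=%.3g MPa\n",
    object@length, object@width, object@thickness, object@youngsModulus))
  cat(sprintf("  anchor: %.3g mm at %.3g deg; I = %.4g mm^4\n",
              object@anchorLength, object@anchorAngle, secondMoment(object)))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve (%s), %d samples over [%.3g, %.3g] um\n",
              object@modelKind, nrow(object@samples),
              min(object@samples$displacement_um),
              max(object@samples$displacement_um)))
  cat("  coefficients:",
      paste(names(object@coefficients),
            signif(object@coefficients, 5), sep = " = ", collapse = ", "),
      "\n")
})

setMethod("show", "VideoStream", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "VideoStream: %d frames of %d x %d px, %.5g fps (%.3g s), %.3g um/px\n",
    d[3], d[1], d[2], object@fps, d[3] / object@fps, object@pixelSize))
})

setMethod("show", "Kymograph", function(object) {
  cat(sprintf(
    "Kymograph: %d rows (frames) x %d columns (px), %.5g fps, %.3g um/px, scanline row %d\n",
    nrow(object@mat), ncol(object@mat), object@fps, object@pixelSize,
    object@scanlineRow))
})

setMethod("show", "EdgeTrace", function(object) {
  cat(sprintf("EdgeTrace (%s post): %d samples over %.3g s\n",
              object@side, length(object@t), max(object@t)))
  if (is.finite(object@baselinePx)) {
    cat(sprintf("  baseline %.3f px; displacement range [%.3g, %.3g] um\n",
                object@baselinePx, min(object@displacement),
                max(object@displacement)))
  } else {
    cat("  baseline not yet computed (see computeBaseline)\n")
  }
})

setMethod("show", "ContractilityMetrics", function(object) {
  cat("ContractilityMetrics:\n")
  cat(sprintf("  %d beats in %.3g s -> %.4g BPM\n",
              object@nBeats, object@durationS, object@beatsPerMinute))
  cat(sprintf("  amplitude %.4g um; contraction %.4g um/s; relaxation %.4g um/s\n",
              object@contractionAmplitude, object@contractionVelocity,
              object@relaxationVelocity))
  if (is.finite(object@force)) cat(sprintf("  force %.4g uN\n", object@force))
})

setMethod("show", "CCDDesign", function(object) {
  k <- nrow(object@factors)
  cat(sprintf(
    "Face-centred CCD: %d factors, %d runs (%d factorial x %d, %d axial x %d, centre x %d)\n",
    k, nrow(object@coded), 2^k, object@reps[["factorial"]], 2 * k,
    object@reps[["axial"]], object@reps[["center"]]))
  cat("  factors:", paste(object@factors$name, collapse = ", "), "\n")
})

setMethod("show", "RSMFit", function(object) {
  cat(sprintf("RSMFit: full quadratic, R^2 = %.4f, residual df = %d\n",
              object@rSquared, as.integer(object@residualDf)))
  print(object@anova, digits = 4, row.names = FALSE)
})

setMethod("show", "OptimumPrediction", function(object) {
  cat(sprintf("Predicted %s of the fitted surface: %.5g\n",
              if (object@objective == "maximize") "maximum" else "minimum",
              object@predictedResponse))
  for (nm in names(object@coded)) {
    cat(sprintf("  %s: coded %+.4f -> %.6g\n", nm, object@coded[[nm]],
                object@natural[[nm]]))
  }
})
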