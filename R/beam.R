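#' Construct a cantilever specification
#'
#' @param length post height from base to tip, mm.
#' @param width cross-section width, mm.
#' @param thickness cross-section thickness (bending direction), mm.
#' @param youngsModulus Young's modulus of the elastomer, MPa.
#' @param anchorLength length of the angled tissue anchor, mm (must be
#'   shorter than the post).
#' @param anchorAngle anchor angle from the horizontal, degrees in (0, 90].
#' @return a [CantileverSpec-class] object.
#' @examples
#' cantileverSpec(3, 0.6, 0.6, youngsModulus = 1.8)
#' @export
cantileverSpec <- function(length, width, thickness, youngsModulus,
                           anchorLength = 0.5, anchorAngle = 45) {
  new("CantileverSpec", length = length, width = width, thickness = thickness,
      youngsModulus = youngsModulus, anchorLength = anchorLength,
      anchorAngle = anchorAngle)
}

#' Nominal placeholder cantilever
#'
#' A synthetic, nominal post specification (3 mm post, 0.6 x 0.6 mm section,
#' 1.8 MPa elastomer, 0.5 mm anchor at 45 degrees). These are placeholder
#' values in the plausible range for cast PDMS pillars, NOT measurements of
#' any particular device: every quantitative force result should use either a
#' user-measured spec or an empirical [fitCalibration()] curve.
#'
#' @return a [CantileverSpec-class] object.
#' @export
defaultCantileverSpec <- function() {
  cantileverSpec(length = 3, width = 0.6, thickness = 0.6,
                 youngsModulus = 1.8, anchorLength = 0.5, anchorAngle = 45)
}

#' Construct a load configuration
#'
#' @param loadHeight height of the ring's point load above the post base, mm.
#' @param measureHeight height at which displacement is observed, mm;
#'   defaults to the load height (deflection at the load point).
#' @return a [LoadConfig-class] object.
#' @export
loadConfig <- function(loadHeight, measureHeight = loadHeight) {
  new("LoadConfig", loadHeight = loadHeight, measureHeight = measureHeight)
}

#' Default load configuration for a cantilever
#'
#' The ring sits against the anchor, so the load is applied at
#' `length - anchorLength`; the imaging pipeline tracks the post's top edge,
#' so displacement is observed at the tip (`measureHeight = length`).
#'
#' @param spec a [CantileverSpec-class].
#' @return a [LoadConfig-class] object.
#' @export
defaultLoadConfig <- function(spec) {
  loadConfig(loadHeight = spec@length - spec@anchorLength,
             measureHeight = spec@length)
}

#' Second moment of area of the rectangular cross-section
#'
#' I = width * thickness^3 / 12, with the bending axis along the thickness.
#'
#' @param spec a [CantileverSpec-class].
#' @return second moment of area, mm^4.
#' @examples
#' secondMoment(cantileverSpec(3, 1, 1, 1.5))  # 1/12
#' @export
secondMoment <- function(spec) {
  stopifnot(is(spec, "CantileverSpec"))
  validObject(spec)
  spec@width * spec@thickness^3 / 12
}

#' Unit scale of the beam equations
#'
#' The closed-form deflection F * a^2 (3x - a) / (6 E I) is evaluated with
#' force in uN, lengths in mm, modulus in MPa and I in mm^4. Since
#' 1 MPa * mm^4 = 1 N * mm^2 and 1 uN = 1e-6 N, the raw expression comes out
#' in units of 1e-6 mm * mm^2 / mm^2 = 1e-6 mm = 1e-3 um. This function
#' returns that single conversion factor (um per uN mm^3 / (MPa mm^4)), kept
#' in one place so the unit bookkeeping is testable in isolation.
#'
#' @return the scalar 1e-3.
#' @export
beamUnitScale <- function() 1e-3

#' Euler-Bernoulli deflection of a post under a point load
#'
#' Small-deflection theory for a prismatic cantilever fixed at the base with
#' a point load F at height a (`loadHeight`): the deflection observed at
#' height x >= a is delta(x) = F a^2 (3x - a) / (6 E I), which reduces to the
#' familiar F a^3 / (3 E I) when x = a. The anchor taper is ignored
#' (prismatic assumption); any discrepancy is absorbed by empirical
#' calibration.
#'
#' @param force applied force, uN (vectorised, must be >= 0).
#' @param spec a [CantileverSpec-class].
#' @param load a [LoadConfig-class]; defaults to [defaultLoadConfig()] (load
#'   at the anchor, observation at the tip).
#' @return deflection at `measureHeight`, um.
#' @examples
#' sp <- cantileverSpec(3, 0.6, 0.6, 1.5)
#' theoreticalDeflection(10, sp, loadConfig(1.5, 3))
#' @export
theoreticalDeflection <- function(force, spec, load = defaultLoadConfig(spec)) {
  stopifnot(is(spec, "CantileverSpec"), is(load, "LoadConfig"))
  validObject(spec); validObject(load)
  if (any(force < 0)) stop("force must be >= 0")
  a <- load@loadHeight
  x <- load@measureHeight
  if (a > spec@length + 1e-12) stop("loadHeight exceeds the post length")
  if (x > spec@length + 1e-12) stop("measureHeight exceeds the post length")
  I <- secondMoment(spec)
  force * a^2 * (3 * x - a) / (6 * spec@youngsModulus * I) * beamUnitScale()
}

#' Theoretical stiffness of a post
#'
#' The inverse slope of [theoreticalDeflection()]: force per unit observed
#' displacement, uN/um.
#'
#' @inheritParams theoreticalDeflection
#' @return stiffness k, uN/um.
#' @export
theoreticalStiffness <- function(spec, load = defaultLoadConfig(spec)) {
  1 / theoreticalDeflection(1, spec, load)
}

## Evaluate a calibration polynomial (through the origin) at displacement d.
.evalCalibration <- function(coefficients, modelKind, d) {
  if (modelKind == "linear_through_origin") {
    coefficients[["k"]] * d
  } else {
    coefficients[["c1"]] * d + coefficients[["c2"]] * d^2 +
      coefficients[["c3"]] * d^3
  }
}

#' Fit an empirical force-displacement calibration
#'
#' Least-squares fit of force against displacement for samples measured by
#' pressing a calibrated force transducer against the post. Both models pass
#' through the origin (zero displacement exerts zero force): the linear model
#' summarises the post by a single stiffness k (uN/um), the cubic model adds
#' quadratic and cubic terms for large deflections.
#'
#' @param samples a data.frame (or 2-column matrix) of displacement (um) and
#'   force (uN) pairs; columns `displacement_um`, `force_uN` or the first two
#'   columns positionally.
#' @param modelKind `"linear_through_origin"` (default) or
#'   `"cubic_polynomial"`.
#' @param loadHeight optional height at which the transducer contacted the
#'   post, mm.
#' @return a [CalibrationCurve-class]; residuals of the fit are kept in the
#'   `samples` slot for diagnostics.
#' @examples
#' cal <- fitCalibration(data.frame(displacement_um = 1:5,
#'                                  force_uN = 2 * (1:5)))
#' coef(cal)  # k = 2
#' @export
fitCalibration <- function(samples,
                           modelKind = c("linear_through_origin",
                                         "cubic_polynomial"),
                           loadHeight = NA_real_) {
  modelKind <- match.arg(modelKind)
  samples <- as.data.frame(samples)
  if (ncol(samples) < 2) stop("samples must have two columns")
  if (!all(c("displacement_um", "force_uN") %in% names(samples))) {
    names(samples)[1:2] <- c("displacement_um", "force_uN")
  }
  samples <- samples[order(samples$displacement_um),
                     c("displacement_um", "force_uN")]
  d <- samples$displacement_um
  f <- samples$force_uN
  nmin <- if (modelKind == "linear_through_origin") 2L else 4L
  if (length(d) < nmin) {
    stop(sprintf("need at least %d samples for %s", nmin, modelKind))
  }
  if (any(diff(d) == 0)) {
    stop("degenerate samples: displacements must be distinct")
  }
  if (modelKind == "linear_through_origin") {
    fit <- stats::lm(f ~ 0 + d)
    coefs <- c(k = unname(stats::coef(fit)))
  } else {
    fit <- stats::lm(f ~ 0 + d + I(d^2) + I(d^3))
    coefs <- stats::setNames(unname(stats::coef(fit)), c("c1", "c2", "c3"))
  }
  samples$residual <- unname(stats::residuals(fit))
  new("CalibrationCurve", samples = samples, modelKind = modelKind,
      coefficients = coefs, loadHeight = loadHeight)
}

#' Convert measured deflection to contractile force
#'
#' Evaluates the fitted calibration at the measured displacement. For the
#' linear model this is simply k * displacement. Displacements beyond twice
#' the calibrated range are still converted but flagged: a warning is issued
#' and the returned vector carries an `extrapolated` attribute marking the
#' affected entries.
#'
#' @param displacement measured deflection, um (vectorised, must be >= 0).
#' @param curve a [CalibrationCurve-class].
#' @return force, uN, with attribute `extrapolated` (logical vector).
#' @examples
#' cal <- fitCalibration(data.frame(displacement_um = 1:5,
#'                                  force_uN = 2 * (1:5)))
#' forceFromDeflection(10.1, cal)  # 20.2 uN
#' @export
forceFromDeflection <- function(displacement, curve) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (any(displacement < 0)) stop("displacement must be >= 0")
  dmax <- max(curve@samples$displacement_um)
  extrapolated <- displacement > 2 * dmax
  if (any(extrapolated)) {
    warning(sprintf(
      "%d displacement(s) beyond 2x the calibrated range (%.3g um)",
      sum(extrapolated), dmax))
  }
  force <- .evalCalibration(curve@coefficients, curve@modelKind, displacement)
  attr(force, "extrapolated") <- extrapolated
  force
}

#' Read a calibration table from CSV
#'
#' Expects a header with columns `displacement_um,force_uN`.
#'
#' @param path path to the CSV file.
#' @param ... passed on to [fitCalibration()].
#' @return a [CalibrationCurve-class].
#' @export
readCalibration <- function(path, ...) {
  tab <- utils::read.csv(path)
  if (!all(c("displacement_um", "force_uN") %in% names(tab))) {
    stop("calibration CSV must have columns displacement_um,force_uN")
  }
  fitCalibration(tab, ...)
}

#' Read a cantilever specification from JSON
#'
#' Keys: `length_mm`, `width_mm`, `thickness_mm`, `youngs_modulus_mpa`,
#' `anchor_length_mm`, `anchor_angle_deg`.
#'
#' @param path path to the JSON file.
#' @return a [CantileverSpec-class].
#' @export
readCantileverSpec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("length_mm", "width_mm", "thickness_mm", "youngs_modulus_mpa")
  if (!all(need %in% names(j))) {
    stop("cantilever JSON must define ", paste(need, collapse = ", "))
  }
  cantileverSpec(
    length = j$length_mm, width = j$width_mm, thickness = j$thickness_mm,
    youngsModulus = j$youngs_modulus_mpa,
    anchorLength = if (!is.null(j$anchor_length_mm)) j$anchor_length_mm else 0.5,
    anchorAngle = if (!is.null(j$anchor_angle_deg)) j$anchor_angle_deg else 45)
}
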