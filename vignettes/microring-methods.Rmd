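---
title: "Measuring contractile force of cardiac microrings: models and methods"
author: "microring package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring contractile force of cardiac microrings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microring)
```

## The assay

A cardiac microring (CaMiRi) is a ring-shaped microtissue of cardiomyocytes
and cardiac fibroblasts in a collagen matrix, self-organised around two
elastomeric PDMS microcantilevers at the bottom of a 96-well plate well.
Every beat pulls the posts toward the well centre; because the posts behave
as calibrated springs, the bending amplitude is a direct, label-free readout
of contractile force. The acquisition is brightfield only: a low-magnification
image locates the posts, an autofocus step locks onto the top edge of one
post, and a 20-second video at 100 frames per second records the post edge
through one ROI. This package implements everything downstream of the
camera, plus the designed-experiment and drug-screen statistics around the
assay, plus generators of fully ground-truthed synthetic data.

## Beam mechanics

The post is modelled as a prismatic Euler–Bernoulli cantilever, clamped at
the base, with a rectangular cross-section (second moment
$I = w t^3 / 12$). The ring applies a point load $F$ at height $a$
(`loadHeight`); displacement is observed at height $x \ge a$
(`measureHeight`), by default the tip, because the imaging focuses on the top
edge of the post. Small-deflection theory gives

$$\delta(x) = \frac{F a^2 (3x - a)}{6 E I},$$

which reduces to $F a^3 / (3 E I)$ at the load point. Geometry is stored in
mm, the modulus in MPa, deflection reported in µm, force in µN; with these
units the raw expression is in units of $10^{-3}$ µm, the single conversion
factor exposed (and tested in isolation) as `beamUnitScale()`.

Assumptions worth stating: deflections are small relative to the post length
(true at the ~10 µm scale against a 3 mm post); the angled anchor tip is
ignored in the closed form (prismatic assumption); PDMS viscoelasticity is
ignored. Any discrepancy from these idealisations is exactly what the
empirical calibration absorbs: `fitCalibration()` fits force–displacement
pairs measured with a micro-force transducer, either linear through the
origin (a single stiffness $k$ in µN/µm — the small-deflection regime) or a
cubic through the origin for large deflections. Fitted curves must be
monotone non-decreasing over the sampled range (a validity condition of the
object); conversions beyond twice the calibrated range are flagged, not
refused. The default load configuration places the ring at
`length - anchorLength` (it rests against the anchor) and observes at the
tip.

The deflection observed depends strongly on where the ring sits on the post
($\delta \propto a^2(3x-a)$), which is why consistent vertical positioning
of the tissue — enforced mechanically by the anchor — matters for comparable
force numbers across wells. `defaultCantileverSpec()` is a *placeholder*
post (3 mm, 0.6 × 0.6 mm, 1.8 MPa): plausible for cast PDMS pillars, but
quantitative force work must supply a measured spec or calibration.

## Imaging pipeline

**Post detection.** Posts are dark, vertically elongated blobs under
transmitted light. `detectPosts()` thresholds with Otsu's method, labels
connected components, filters by area and by a height/width aspect ratio of
at least 1.5, and keeps the expected number of largest components sorted by
x. The method is deterministic; polarity can be inverted for fluorescence.
All coordinates in the package are 1-based, origin top-left, row = y,
col = x (R's native matrix convention); bounding boxes are inclusive.

**Focus.** `focusScore()` is the variance of a discrete Laplacian — a
standard contrast-maximising autofocus figure of merit. It is a pure
function over a provided stack: the package drives no hardware. A constant
image scores exactly zero, and blurring strictly decreases the score.

**Kymographs.** `buildKymograph()` stacks one pixel row (by default the
centre row) of every frame, so row count equals frame count (2000 for the
standard 20 s × 100 fps acquisition) and post motion appears as a wavy
intensity edge. Only the left post is analysed by default — the two posts
of a ring report essentially the same signal — but both sides are
supported.

**Edge tracking.** Per kymograph row, `trackEdge()` finds the first
crossing of the half-range intensity threshold scanning away from the post
and interpolates linearly between the two straddling pixels, giving
sub-pixel resolution (worst-case bias under ideal anti-aliased edges is
about 0.09 px). Temporal continuity restricts the search to ±15 px (the
`window` parameter) around the previous row's edge; isolated missing rows
inherit the neighbouring estimate, but more than 5% missing rows is an
error, not a silent degradation.

## Contraction metrics

`computeBaseline()` estimates the diastolic rest position as the rolling
10th percentile of the raw edge position over 2-second windows, summarised
by the median across windows. The low percentile sits on the diastolic
plateau because contraction pulses occupy a minority of each window; the
median across windows buys robustness to slow drift. Displacement is
`(position - baseline) * pixelSize`, signed so contraction (motion toward
the well centre) is positive for either post.

`detectBeats()` finds local maxima with topographic prominence of at least
1 µm (default) and spacing of at least 0.25 s; the higher peak wins a
spacing conflict, ties go to the earlier index, and zero beats is a valid
result (0 BPM), not an error. Onset and end are the nearest
10%-of-amplitude crossings flanking each peak.

`computeMetrics()` aggregates per-beat quantities by the median, which
tolerates one aberrant beat per recording:

* beats per minute = 60 / median inter-peak interval — robust to partial
  beats at the video boundaries, unlike count/duration;
* amplitude = median per-beat peak displacement above baseline;
* contraction/relaxation velocity = median over beats of the maximal
  upstroke/downstroke slope (central differences at the acquisition rate;
  the derivative *at* the peak sample averages the two phases across the
  kink, so that sample is excluded from both);
* force = calibration curve evaluated at the amplitude, when supplied.

`compareAutomatedManual()` reports Pearson r and the least-squares line of
automated against manual amplitudes — the standard check that a tracking
script reproduces hand measurements; manual values are user input, not
something the package re-derives.

## Formulation optimisation

Tissue formulation (cardiomyocyte percentage 50–90, collagen 1.8–2.2
mg/mL, total cells 40,000–100,000 — `tissueFormulationFactors()`) is
optimised with a three-level *face-centred* central composite design:
axial points sit at ±1 on the coded scale (the cube faces), so every factor
is run at exactly three levels. `generateCCD()` produces
$2^k r_F + 2k\,r_A + r_C$ runs in a deterministic order; the standard
experiment (k = 3, four factorial and axial replicates, eight centre
replicates) has 64 runs over 15 distinct conditions.

`fitQuadratic()` fits the full second-order polynomial in coded units by
ordinary least squares and reports a per-term partial (Type III) ANOVA:
each term's single-df sum of squares adjusted for all others, computed as
$t^2 \cdot \mathrm{MSE}$ from the coefficient t-statistic. For this
balanced, sign-symmetric design the linear and interaction columns are
mutually orthogonal, so partial and sequential sums of squares coincide for
them; the pure quadratic columns are not orthogonal to the intercept or to
each other, which is why the partial convention is stated explicitly.
Constant responses yield $R^2 = 0$ by convention (zero total sum of
squares) with NA F and p. Rank deficiency is an error naming the aliased
terms.

`predictOptimum()` maximises the fitted quadratic over the coded box
$[-1,1]^k$: the interior stationary point when it exists with the right
curvature, and in all cases a coarse grid (21 per axis by default) seeding
multiple L-BFGS-B polishes, so boundary optima of monotone or saddle
surfaces are found reliably; tests hold it to within $10^{-6}$ of a 51³
brute-force grid. Both coded and decoded natural settings are returned;
rounding for bench practicality (e.g. 75,400 → 75,000 cells) is left to the
user, as presentation rather than computation.

The generator preset `tissueSurfacePreset()` encodes the effect structure
such an optimisation finds: a strong positive linear effect of
cardiomyocyte fraction (optimum pinned at the 90% face) and concave
collagen and cell-number effects with interior optima at 2.03 mg/mL and
75,400 cells. Those stationary values are properties of the preset's
coefficients (stationary coded values +0.15 and +0.18), fixed once; fitting
noisy responses from this surface and optimising recovers them up to
sampling error.

## Drug-screen statistics

`relativeChange()` summarises a dose–response table as
$(c_\text{dose} - c_\text{vehicle}) / c_\text{vehicle}$ per experiment,
then aggregates across experiments — normalising *before* aggregating makes
the summary invariant to experiment-wide amplitude rescaling, the natural
choice for "three independent experiments, each with three replicates"
layouts. The centre statistic is a configuration switch (mean ± SD default,
median ± MAD alternative). Each dose is compared to the pooled vehicle
wells with `mannWhitneyU()`: the exact U distribution when both groups have
at most 8 observations and no ties, otherwise the normal approximation with
tie and continuity corrections. Pairwise p-values are reported unadjusted
by default, matching common practice in screening figures; a
clearly-labelled Holm-adjusted column is available because unadjusted
five-dose panels inflate the family-wise error.

`seedingPlan()` emits the liquid-handler schedule: wells in plate row-major
order, 16 per robot cycle (6 cycles for a full 96-well plate), four 2.5 µL
droplets per well at the north/east/south/west positions. The plan is a
partition of the well set by construction and by test.

## Synthetic data: what it does and does not show

All generators are pure functions of their arguments and a seed, and return
machine-readable ground truth sufficient to score every downstream
operation.

* `makeWaveform()` — per beat, a fast rise over `contractionTime` (default
  0.15 s) and slower fall over `relaxationTime` (default 0.35 s), repeated
  at 60/bpm, flat diastole between; piecewise linear (analytic slopes
  exact) or cosine-smoothed. A triangular peak falling between samples
  undershoots the nominal amplitude by up to slope·Δt/2 — a property of
  the sampled waveform, not of any tracker — so amplitude-accuracy checks
  use the smooth template, whose sampled peak is within O(Δt²) of nominal.
  Optional Gaussian noise and linear drift stress the baseline estimator.
* `renderVideo()` — two dark posts on a bright background, the left post
  translating with the waveform; edges are rendered with area-weighted
  anti-aliasing so sub-pixel ground-truth positions are meaningful. Default
  scene: 0.2 µm/px (a 20× objective with ~4 µm camera pixels), 20 s at
  100 fps.
* `makeCCDResponses()` / `makeDoseResponse()` — linear-algebra and
  Hill-pharmacology generators ($E_{max}$, EC50, Hill slope, direction)
  with noiseless truth attached. `inotropePreset("negative")` emulates a
  myosin-inhibitor-like suppression (E~max~ 0.8, EC50 100 nM);
  `"positive"` a β-agonist-like potentiation saturating near 1 µM.

What passing these tests shows: the algorithms are correct on data whose
generating process is known exactly. What it does not show: robustness to
optical effects absent from the generator — defocus blur and PSF tails,
uneven illumination, debris crossing the scanline, tissue rotation moving
the ring along the post (which changes the force scale through $a$), or
frame-rate jitter. Those require real recordings; the
`compareAutomatedManual()` interface exists precisely to validate against
hand measurements on such data.

## Numerical choices and problem sizes

Tolerances asserted by the test suite: beam closed form vs two-pass
numerical integration of the curvature equation, relative error < 10⁻⁶;
OLS vs explicit normal equations, 10⁻¹⁰; box-constrained optimum vs 51³
brute force, 10⁻⁶; exact Mann–Whitney p vs full enumeration for all
tie-free group sizes ≤ 6, exact. Parameter recovery runs a 12-point grid
(BPM ∈ {30, 60, 90, 120} × amplitude ∈ {2, 5, 10} µm) on 10-second
synthetic videos, noiseless and at 5% pixel noise: beat count exact, rate
exact up to the one-frame quantisation of the median inter-peak interval
(e.g. 90 BPM has a 66.7-frame period at 100 fps), amplitude within 2%
noiseless and 5% under noise. Coefficient coverage uses 500 seeded
replicates of the 64-run design at noise SD 1 µm, requiring every
coefficient within 3 estimated SEs in ≥ 99% of fits. These sizes keep the
whole suite under a minute on one CPU while leaving each check
statistically meaningful.

Degenerate inputs are handled by stated convention rather than silently:
zero beats → 0 BPM with NA amplitudes; constant responses → R² = 0;
fully tied Mann–Whitney samples → p = 1; blank images and lost edges are
errors that name the offending rows or candidates.

## Reproducing the headline numbers

`scripts/acceptance.R` (repository root) regenerates, from scratch and
under a caller-supplied seed, the design arithmetic (64 runs, 15
conditions, 6 seeding batches), the recovered formulation optimum, the
strong (10.1 µm) and weak (0.9 µm) condition amplitude recoveries at 5%
pixel noise, the theory-vs-calibration stiffness consistency, and the
negative-inotrope screen summary, writing them as JSON. See the README for
invocation.
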