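## Independent oracles used across the suite. Each re-derives its quantity
## from first principles (numerical integration, normal equations, full
## enumeration) without calling the code paths it checks.

## Euler-Bernoulli cantilever deflection by two-pass numerical integration of
## the curvature equation w''(x) = M(x) / (EI), M(x) = F (a - x)_+ for a
## base-clamped post with a point load F at height a, observed at height x.
## Works in N and mm, converts to um at the end.
odeDeflection <- function(force_uN, spec, load, nGrid = 20001) {
  a <- load@loadHeight
  xm <- load@measureHeight
  E <- spec@youngsModulus                      # MPa = N/mm^2
  I <- spec@width * spec@thickness^3 / 12      # mm^4
  F_N <- force_uN * 1e-6
  ## grid over [0, xm] with a node exactly at the moment kink x = a
  x <- sort(unique(c(seq(0, xm, length.out = nGrid), min(a, xm))))
  M <- F_N * pmax(a - x, 0)                    # N mm
  curv <- M / (E * I)                          # 1/mm
  cumtrap <- function(y, x) {
    c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
  }
  slope <- cumtrap(curv, x)                    # w'(x), w'(0) = 0
  w <- cumtrap(slope, x)                       # w(x),  w(0) = 0
  w[length(w)] * 1e3                           # mm -> um
}

## OLS coefficients by explicit normal equations.
normalEqCoefs <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

## Exact two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1)
## group assignments of the pooled sample (tie-free inputs only):
## p = fraction of assignments at least as extreme in |U - n1 n2 / 2|.
enumerateMW <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  stopifnot(!anyDuplicated(pool))
  uStat <- function(xi, yi) sum(outer(xi, yi, ">"))
  uObs <- uStat(x, y)
  centre <- n1 * n2 / 2
  picks <- utils::combn(n1 + n2, n1)
  us <- apply(picks, 2, function(ix) uStat(pool[ix], pool[-ix]))
  p <- mean(abs(us - centre) >= abs(uObs - centre) - 1e-9)
  list(U = uObs, p = p)
}

## Build a kymograph directly from known sub-pixel edge columns with
## area-sampled (anti-aliased) step edges: dark on [edge - postWidth, edge],
## bright elsewhere. Independent of renderVideo.
stepKymograph <- function(edgeCols, width = 200, postWidth = 30,
                          bg = 0.85, fg = 0.15, noiseSd = 0,
                          fps = 100, pixelSize = 0.2) {
  n <- length(edgeCols)
  mat <- matrix(bg, n, width)
  j <- seq_len(width)
  for (r in seq_len(n)) {
    a <- edgeCols[r] - postWidth
    cov <- pmax(0, pmin(edgeCols[r], j + 0.5) - pmax(a, j - 0.5))
    mat[r, ] <- bg + (fg - bg) * pmin(1, cov)
  }
  if (noiseSd > 0) mat <- mat + matrix(rnorm(n * width, 0, noiseSd), n, width)
  new("Kymograph", mat = mat, fps = fps, pixelSize = pixelSize,
      scanlineRow = 1L)
}

## EdgeTrace straight from a displacement waveform (um), bypassing imaging:
## raw position = basePx + displacement / pixelSize for a left post.
traceFromDisplacement <- function(displacementUm, fps = 100, pixelSize = 0.2,
                                  basePx = 50) {
  n <- length(displacementUm)
  tr <- new("EdgeTrace",
            t = (seq_len(n) - 1) / fps,
            rawPosition = basePx + displacementUm / pixelSize,
            displacement = rep(NA_real_, n), baselinePx = NA_real_,
            fps = fps, pixelSize = pixelSize, side = "left")
  computeBaseline(tr)
}

## Full quadratic model matrix, rebuilt independently for oracle fits.
oracleQuadMatrix <- function(coded) {
  k <- ncol(coded)
  X <- cbind(1, coded)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) X <- cbind(X, coded[, i] * coded[, j])
  }
  cbind(X, coded^2)
}

## Evaluate a named quadratic coefficient vector (fitQuadratic naming) on a
## matrix of coded points, independently of the package's evaluator.
oracleQuadEval <- function(coefs, nms, pts) {
  k <- length(nms)
  y <- rep(coefs[["(Intercept)"]], nrow(pts))
  for (i in seq_len(k)) y <- y + coefs[[nms[i]]] * pts[, i]
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      y <- y + coefs[[paste(nms[i], nms[j], sep = ":")]] * pts[, i] * pts[, j]
    }
  }
  for (i in seq_len(k)) y <- y + coefs[[paste0(nms[i], "^2")]] * pts[, i]^2
  y
}

## Random named coefficient vector over the full quadratic term set for the
## default 3-factor formulation design.
randomSurface <- function(seed, concave = FALSE) {
  set.seed(seed)
  nms <- tissueFormulationFactors()$name
  terms <- c("(Intercept)", nms,
             apply(utils::combn(nms, 2), 2, paste, collapse = ":"),
             paste0(nms, "^2"))
  coefs <- stats::setNames(rnorm(length(terms), 0, 2), terms)
  if (concave) coefs[paste0(nms, "^2")] <- -abs(coefs[paste0(nms, "^2")]) - 0.5
  coefs
}
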