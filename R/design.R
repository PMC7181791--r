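#' Define a design factor by its three levels
#'
#' A face-centred three-level factor: the mid level must be the midpoint of
#' the low and high levels (within a small tolerance), because coded 0 is the
#' centre of the coded [-1, +1] interval.
#'
#' @param name factor name.
#' @param low,high the extreme levels, natural units.
#' @param mid the centre level; defaults to `(low + high) / 2`.
#' @return a one-row data.frame with columns `name`, `low`, `mid`, `high`;
#'   rows from several calls can be `rbind`-ed into a factor table.
#' @examples
#' factorSpec("collagen_mg_ml", 1.8, 2.2)
#' @export
factorSpec <- function(name, low, high, mid = (low + high) / 2) {
  if (!(low < mid && mid < high)) stop("need low < mid < high")
  if (abs(mid - (low + high) / 2) > 1e-6 * (high - low)) {
    stop("mid must be the midpoint of low and high (face-centred design)")
  }
  data.frame(name = name, low = low, mid = mid, high = high,
             stringsAsFactors = FALSE)
}

#' The default tissue-formulation factor table
#'
#' The three formulation factors explored when optimising ring formation and
#' force generation: cardiomyocyte percentage (50/70/90, remainder cardiac
#' fibroblasts), collagen concentration (1.8/2.0/2.2 mg/mL) and total input
#' cells per tissue (40,000/70,000/100,000).
#'
#' @return a three-row factor table for [generateCCD()].
#' @export
tissueFormulationFactors <- function() {
  rbind(
    factorSpec("cardiomyocyte_pct", 50, 90),
    factorSpec("collagen_mg_ml", 1.8, 2.2),
    factorSpec("total_cells", 40000, 100000))
}

#' Generate a face-centred central composite design
#'
#' Builds the three-level face-centred CCD (axial distance alpha = 1): all
#' 2^k factorial corners replicated `rF` times, the 2k axial points (one
#' factor at +/-1, the rest at 0) replicated `rA` times, and the centre point
#' replicated `rC` times, giving `2^k rF + 2k rA + rC` runs. Run order is
#' deterministic: factorial block, axial block, centre block, lexicographic
#' within block with replicates consecutive.
#'
#' @param factors a factor table from [factorSpec()] rows (k >= 2).
#' @param rF,rA,rC replicate counts at the factorial, axial and centre
#'   points (all >= 1).
#' @return a [CCDDesign-class].
#' @examples
#' d <- generateCCD(tissueFormulationFactors(), rF = 4, rA = 4, rC = 8)
#' nrow(designTable(d))  # 64 runs
#' @export
generateCCD <- function(factors, rF = 1, rA = 1, rC = 1) {
  factors <- as.data.frame(factors)
  k <- nrow(factors)
  if (k < 2) stop("a CCD needs at least two factors")
  if (rF < 1 || rA < 1 || rC < 1) stop("replicate counts must be >= 1")
  corners <- as.matrix(expand.grid(rep(list(c(-1, 1)), k))[, k:1, drop = FALSE])
  corners <- corners[do.call(order, as.data.frame(corners)), , drop = FALSE]
  axial <- do.call(rbind, lapply(seq_len(k), function(i) {
    m <- matrix(0, 2, k); m[1, i] <- -1; m[2, i] <- 1; m
  }))
  centre <- matrix(0, 1, k)
  coded <- rbind(corners[rep(seq_len(nrow(corners)), each = rF), , drop = FALSE],
                 axial[rep(seq_len(nrow(axial)), each = rA), , drop = FALSE],
                 centre[rep(1, rC), , drop = FALSE])
  colnames(coded) <- factors$name
  rownames(coded) <- NULL
  pointType <- c(rep("factorial", 2^k * rF), rep("axial", 2 * k * rA),
                 rep("center", rC))
  new("CCDDesign", factors = factors, coded = coded, pointType = pointType,
      reps = c(factorial = as.integer(rF), axial = as.integer(rA),
               center = as.integer(rC)))
}

#' Coded-unit transforms
#'
#' `encodeFactor()` maps a natural value to the coded scale,
#' `(x - mid) / ((high - low) / 2)`, so the low/mid/high levels map to
#' -1/0/+1; `decodeFactor()` is its exact inverse. Values outside
#' `[low, high]` are allowed but flagged via the `outside` attribute.
#'
#' @param value natural-unit value(s).
#' @param coded coded value(s).
#' @param factor a one-row factor table (see [factorSpec()]).
#' @return the transformed value(s); `encodeFactor` attaches an `outside`
#'   logical attribute.
#' @examples
#' f <- factorSpec("total_cells", 40000, 100000)
#' encodeFactor(75000, f)  # +0.1667
#' @export
encodeFactor <- function(value, factor) {
  half <- (factor$high - factor$low) / 2
  out <- (value - factor$mid) / half
  attr(out, "outside") <- value < factor$low | value > factor$high
  out
}

#' @rdname encodeFactor
#' @export
decodeFactor <- function(coded, factor) {
  half <- (factor$high - factor$low) / 2
  factor$mid + coded * half
}

#' Design table in long form
#'
#' @param design a [CCDDesign-class].
#' @return a data.frame with `run`, `point_type`, one `<name>_coded` column
#'   per factor and one `<name>` column with the decoded natural setting.
#' @export
designTable <- function(design) {
  stopifnot(is(design, "CCDDesign"))
  out <- data.frame(run = seq_len(nrow(design@coded)),
                    point_type = design@pointType)
  for (i in seq_len(nrow(design@factors))) {
    f <- design@factors[i, ]
    out[[paste0(f$name, "_coded")]] <- design@coded[, i]
    out[[f$name]] <- decodeFactor(design@coded[, i], f)
  }
  out
}

## Full quadratic model matrix in coded units; terms named after the factors.
.quadTerms <- function(nms) {
  k <- length(nms)
  inter <- if (k >= 2) {
    utils::combn(k, 2, function(ij) paste(nms[ij[1]], nms[ij[2]], sep = ":"))
  } else character(0)
  c("(Intercept)", nms, inter, paste0(nms, "^2"))
}

.quadModelMatrix <- function(coded) {
  nms <- colnames(coded)
  k <- ncol(coded)
  inter <- if (k >= 2) {
    do.call(cbind, utils::combn(k, 2, function(ij) {
      coded[, ij[1]] * coded[, ij[2]]
    }, simplify = FALSE))
  } else NULL
  X <- cbind(1, coded, inter, coded^2)
  colnames(X) <- .quadTerms(nms)
  X
}

#' Fit a full quadratic response-surface model
#'
#' Ordinary least squares on the full second-order polynomial in coded units
#' (intercept, linear, two-way interaction and pure quadratic terms), with a
#' per-term ANOVA using partial (Type III) sums of squares, i.e. the sum of
#' squares attributable to each term adjusted for all others; for every term
#' here this is the single-df quantity `t^2 * MSE` from the coefficient
#' t-statistic. For this balanced, sign-symmetric design the linear and
#' interaction terms are orthogonal, so partial and sequential sums of
#' squares coincide for them.
#'
#' When the responses are constant the total sum of squares is zero and
#' R-squared is reported as 0 by convention; F and p are NA.
#'
#' @param design a [CCDDesign-class].
#' @param responses numeric response vector, one value per run.
#' @return an [RSMFit-class].
#' @export
fitQuadratic <- function(design, responses) {
  stopifnot(is(design, "CCDDesign"))
  n <- nrow(design@coded)
  if (length(responses) != n) {
    stop(sprintf("expected %d responses, got %d", n, length(responses)))
  }
  X <- .quadModelMatrix(design@coded)
  p <- ncol(X)
  if (n - p <= 0) stop("design leaves no residual degrees of freedom")
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient model; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  fit <- stats::lm.fit(X, responses)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  dfRes <- n - p
  sigma2 <- rss / dfRes
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(0, diag(XtXinv)) * sigma2)
  tss <- sum((responses - mean(responses))^2)
  r2 <- if (tss <= 0) 0 else 1 - rss / tss
  terms <- colnames(X)[-1]
  if (sigma2 > 0) {
    ss <- beta[-1]^2 / diag(XtXinv)[-1]
    Fv <- ss / sigma2
    pv <- stats::pf(Fv, 1, dfRes, lower.tail = FALSE)
  } else {
    ss <- beta[-1]^2 / diag(XtXinv)[-1]
    Fv <- rep(NA_real_, length(terms))
    pv <- rep(NA_real_, length(terms))
  }
  anova <- rbind(
    data.frame(term = terms, df = 1, sum_sq = unname(ss),
               mean_sq = unname(ss), F = unname(Fv), p = unname(pv)),
    data.frame(term = "Residuals", df = dfRes, sum_sq = rss,
               mean_sq = sigma2, F = NA_real_, p = NA_real_))
  rownames(anova) <- NULL
  new("RSMFit", coefficients = stats::setNames(beta, colnames(X)),
      se = stats::setNames(se, colnames(X)), anova = anova, rSquared = r2,
      residualDf = dfRes, sigma = sqrt(sigma2), factors = design@factors)
}

## Split a named quadratic coefficient vector into (b0, b, B) with
## B the symmetric matrix of the quadratic form x' B x.
.quadForm <- function(coefs, nms) {
  k <- length(nms)
  b0 <- coefs[["(Intercept)"]]
  b <- unname(coefs[nms])
  B <- diag(unname(coefs[paste0(nms, "^2")]), k)
  if (k >= 2) {
    for (ij in utils::combn(k, 2, simplify = FALSE)) {
      val <- coefs[[paste(nms[ij[1]], nms[ij[2]], sep = ":")]] / 2
      B[ij[1], ij[2]] <- B[ij[2], ij[1]] <- val
    }
  }
  list(b0 = b0, b = b, B = B)
}

.evalQuad <- function(qf, X) {
  drop(qf$b0 + X %*% qf$b + rowSums((X %*% qf$B) * X))
}

#' Predict the response-optimal factor settings
#'
#' Optimises the fitted quadratic surface over the coded box [-1, +1]^k. The
#' interior stationary point is used when it lies in the box with the right
#' curvature (negative definite Hessian for maximisation); in every case a
#' coarse grid over the box seeds multiple L-BFGS-B polishes, so boundary
#' optima of saddle-shaped or monotone surfaces are found reliably.
#'
#' @param fit an [RSMFit-class].
#' @param objective `"maximize"` (default) or `"minimize"`.
#' @param nGrid coarse-grid resolution per axis used to seed the polish.
#' @return an [OptimumPrediction-class] with both coded and natural-unit
#'   settings.
#' @export
predictOptimum <- function(fit, objective = c("maximize", "minimize"),
                           nGrid = 21) {
  stopifnot(is(fit, "RSMFit"))
  objective <- match.arg(objective)
  nms <- fit@factors$name
  k <- length(nms)
  qf <- .quadForm(fit@coefficients, nms)
  sgn <- if (objective == "maximize") 1 else -1
  f <- function(x) sgn * .evalQuad(qf, matrix(x, 1))
  starts <- list()
  ## interior stationary point of the quadratic, if well-defined
  st <- tryCatch(solve(qf$B, -qf$b / 2), error = function(e) NULL)
  if (!is.null(st) && all(is.finite(st)) && all(abs(st) <= 1)) {
    starts <- c(starts, list(st))
  }
  ngrid <- max(3, min(nGrid, floor(2e5^(1 / k))))
  grid <- as.matrix(expand.grid(rep(list(seq(-1, 1, length.out = ngrid)), k)))
  vals <- sgn * .evalQuad(qf, grid)
  top <- order(vals, decreasing = TRUE)[seq_len(min(20, nrow(grid)))]
  starts <- c(starts, lapply(top, function(i) grid[i, ]))
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(pmin(1, pmax(-1, s)), function(x) -f(x),
                        method = "L-BFGS-B", lower = rep(-1, k),
                        upper = rep(1, k))
    if (is.null(best) || -opt$value > best$value) {
      best <- list(par = opt$par, value = -opt$value)
    }
  }
  coded <- stats::setNames(pmin(1, pmax(-1, best$par)), nms)
  natural <- stats::setNames(vapply(seq_len(k), function(i) {
    decodeFactor(coded[[i]], fit@factors[i, ])
  }, numeric(1)), nms)
  new("OptimumPrediction", coded = coded, natural = natural,
      predictedResponse = .evalQuad(qf, matrix(coded, 1)),
      objective = objective)
}
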