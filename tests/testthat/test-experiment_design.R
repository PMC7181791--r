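test_that("CCD run counts match the replicate arithmetic", {
  facs <- tissueFormulationFactors()
  ## the full formulation experiment: 4 factorial + 4 axial + 8 centre reps
  expect_identical(nrow(generateCCD(facs, 4, 4, 8)@coded), 64L)
  ## minimal three-level designs
  expect_identical(nrow(generateCCD(facs[1:2, ], 1, 1, 1)@coded), 9L)
  ## the unreplicated design enumerates the fifteen distinct conditions
  expect_identical(nrow(generateCCD(facs, 1, 1, 1)@coded), 15L)
  expect_error(generateCCD(facs[1, , drop = FALSE]), "two factors")
  expect_error(generateCCD(facs, rF = 0), "replicate")
})

test_that("run-count formula and blocks hold across random designs", {
  set.seed(31)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    rF <- sample(1:3, 1); rA <- sample(1:3, 1); rC <- sample(1:8, 1)
    facs <- do.call(rbind, lapply(seq_len(k), function(j) {
      factorSpec(paste0("f", j), j, j + 2)
    }))
    d <- generateCCD(facs, rF, rA, rC)
    expect_identical(nrow(d@coded), as.integer(2^k * rF + 2 * k * rA + rC))
    expect_identical(sum(d@pointType == "factorial"), as.integer(2^k * rF))
    expect_identical(sum(d@pointType == "axial"), as.integer(2 * k * rA))
    expect_identical(sum(d@pointType == "center"), as.integer(rC))
    ## face-centred: axial rows have exactly one +/-1 entry
    ax <- d@coded[d@pointType == "axial", , drop = FALSE]
    expect_true(all(rowSums(abs(ax)) == 1))
    ## sign-flip symmetry: negating any factor permutes the run set
    for (j in seq_len(k)) {
      flipped <- d@coded
      flipped[, j] <- -flipped[, j]
      key <- function(m) sort(apply(m, 1, paste, collapse = ","))
      expect_identical(key(flipped), key(d@coded))
    }
  }
})

test_that("coded-unit transforms are exact inverses with flagged overshoot", {
  collagen <- factorSpec("collagen_mg_ml", 1.8, 2.2)
  expect_equal(as.numeric(encodeFactor(2.0, collagen)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(encodeFactor(2.2, collagen)), 1, tolerance = 1e-12)
  cells <- factorSpec("total_cells", 40000, 100000)
  expect_equal(as.numeric(encodeFactor(75000, cells)), 1 / 6,
               tolerance = 1e-9)
  for (x in c(41000, 63000, 99000)) {
    expect_equal(decodeFactor(as.numeric(encodeFactor(x, cells)), cells), x,
                 tolerance = 1e-9)
  }
  flagged <- encodeFactor(c(30000, 70000, 120000), cells)
  expect_identical(attr(flagged, "outside"), c(TRUE, FALSE, TRUE))
  expect_error(factorSpec("bad", 1, 3, mid = 2.5), "midpoint")
})

test_that("design table decodes coded levels to natural units", {
  d <- generateCCD(tissueFormulationFactors(), 1, 1, 1)
  tab <- designTable(d)
  expect_identical(nrow(tab), 15L)
  expect_equal(sort(unique(tab$collagen_mg_ml)), c(1.8, 2.0, 2.2),
               tolerance = 1e-9)
  expect_equal(sort(unique(tab$total_cells)), c(40000, 70000, 100000),
               tolerance = 1e-9)
  centre <- tab[tab$point_type == "center", ]
  expect_equal(centre$cardiomyocyte_pct, 70)
})

test_that("noiseless quadratic surfaces are recovered exactly", {
  d <- generateCCD(tissueFormulationFactors(), 1, 1, 2)
  truth <- randomSurface(7)
  sim <- makeCCDResponses(d, truth)
  fit <- fitQuadratic(d, sim$responses)
  expect_equal(coef(fit)[names(truth)], truth, tolerance = 1e-8)
  expect_equal(fit@rSquared, 1, tolerance = 1e-8)
})

test_that("OLS coefficients equal the normal-equation solution to 1e-10", {
  set.seed(17)
  for (i in 1:5) {
    k <- sample(2:3, 1)
    facs <- do.call(rbind, lapply(seq_len(k), function(j) {
      factorSpec(paste0("f", j), 0, 2)
    }))
    d <- generateCCD(facs, sample(1:2, 1), sample(1:2, 1), sample(2:5, 1))
    y <- rnorm(nrow(d@coded))
    fit <- fitQuadratic(d, y)
    oracle <- normalEqCoefs(oracleQuadMatrix(d@coded), y)
    expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-10)
  }
})

test_that("the ANOVA table is coherent and flags the simulated effects", {
  d <- generateCCD(tissueFormulationFactors(), 4, 4, 8)
  sim <- makeCCDResponses(d, tissueSurfacePreset(), noiseSd = 1, seed = 12)
  fit <- fitQuadratic(d, sim$responses)
  an <- fit@anova
  expect_identical(nrow(an), 10L)       # 9 terms + residual
  expect_true(all(an$p >= 0 & an$p <= 1, na.rm = TRUE))
  ## fitted + residual SS = total SS
  X <- oracleQuadMatrix(d@coded)
  yhat <- drop(X %*% coef(fit))
  rss <- an$sum_sq[an$term == "Residuals"]
  tss <- sum((sim$responses - mean(sim$responses))^2)
  expect_equal(sum((yhat - mean(sim$responses))^2) + rss, tss,
               tolerance = 1e-8)
  ## the two seeded effects dominate
  expect_lt(an$p[an$term == "cardiomyocyte_pct"], 0.05)
  expect_lt(an$p[an$term == "collagen_mg_ml^2"], 0.01)
  ## partial F equals the squared coefficient t-statistic
  expect_equal(an$F[an$term == "cardiomyocyte_pct"],
               (coef(fit)[["cardiomyocyte_pct"]] /
                  fit@se[["cardiomyocyte_pct"]])^2, tolerance = 1e-10)
})

test_that("degenerate fits are handled by convention or error", {
  d <- generateCCD(tissueFormulationFactors(), 1, 1, 2)
  constFit <- fitQuadratic(d, rep(4.2, 16))
  expect_equal(unname(coef(constFit)[-1]), rep(0, 9), tolerance = 1e-10)
  expect_identical(constFit@rSquared, 0)
  expect_error(fitQuadratic(d, rnorm(10)), "expected 16 responses")
  ## two perfectly aliased factor columns -> rank deficiency named
  facs <- tissueFormulationFactors()
  dup <- generateCCD(facs, 1, 1, 1)
  dup@coded[, 3] <- dup@coded[, 2]
  expect_error(fitQuadratic(dup, rnorm(15)), "aliased")
})

test_that("optimum prediction solves analytic cases exactly", {
  facs <- rbind(factorSpec("x1", -1, 1), factorSpec("x2", -1, 1))
  d <- generateCCD(facs, 2, 2, 4)
  ## concave surface y = 5 - (x1 - 0.2)^2 - x2^2
  coefs <- c("(Intercept)" = 5 - 0.04, x1 = 0.4, x2 = 0,
             "x1:x2" = 0, "x1^2" = -1, "x2^2" = -1)
  fit <- fitQuadratic(d, makeCCDResponses(d, coefs)$responses)
  opt <- predictOptimum(fit)
  expect_equal(unname(opt@coded), c(0.2, 0), tolerance = 1e-6)
  expect_equal(opt@predictedResponse, 5, tolerance = 1e-8)
  ## monotone increasing in x1 -> boundary optimum on the +1 face
  coefsMono <- c("(Intercept)" = 1, x1 = 2, x2 = 0,
                 "x1:x2" = 0, "x1^2" = 0.1, "x2^2" = -0.5)
  fitMono <- fitQuadratic(d, makeCCDResponses(d, coefsMono)$responses)
  optMono <- predictOptimum(fitMono)
  expect_equal(unname(optMono@coded[["x1"]]), 1, tolerance = 1e-8)
  ## minimisation flips the objective
  optMin <- predictOptimum(fit, objective = "minimize")
  expect_equal(unname(optMin@coded[["x1"]]), -1, tolerance = 1e-6)
})

test_that("grid-plus-polish optimum beats a brute-force grid", {
  d <- generateCCD(tissueFormulationFactors(), 1, 1, 2)
  grid <- as.matrix(expand.grid(rep(list(seq(-1, 1, length.out = 51)), 3)))
  nms <- tissueFormulationFactors()$name
  for (seed in 1:20) {
    truth <- randomSurface(seed)
    fit <- fitQuadratic(d, makeCCDResponses(d, truth)$responses)
    opt <- predictOptimum(fit)
    brute <- max(oracleQuadEval(truth, nms, grid))
    expect_gte(opt@predictedResponse, brute - 1e-6)
  }
})

test_that("with vanishing noise the predicted optimum converges to truth", {
  d <- generateCCD(tissueFormulationFactors(), 2, 2, 4)
  nms <- tissueFormulationFactors()$name
  ## concave surface with a known interior stationary point (0.3, -0.4, 0.1)
  star <- c(0.3, -0.4, 0.1)
  quad <- c(-1.5, -1, -2)
  truth <- stats::setNames(numeric(10),
                           c("(Intercept)", nms,
                             apply(utils::combn(nms, 2), 2, paste,
                                   collapse = ":"),
                             paste0(nms, "^2")))
  truth[["(Intercept)"]] <- 4
  truth[nms] <- -2 * quad * star
  truth[paste0(nms, "^2")] <- quad
  for (noise in c(1e-2, 1e-5)) {
    fit <- fitQuadratic(d, makeCCDResponses(d, truth, noise, seed = 8)$responses)
    opt <- predictOptimum(fit)
    if (noise <= 1e-5) {
      expect_lt(max(abs(opt@coded - star)), 1e-3)
    }
  }
})

test_that("the formulation preset decodes to the expected optimum", {
  d <- generateCCD(tissueFormulationFactors(), 4, 4, 8)
  fit <- fitQuadratic(d, makeCCDResponses(d, tissueSurfacePreset())$responses)
  opt <- predictOptimum(fit)
  expect_equal(unname(opt@natural[["cardiomyocyte_pct"]]), 90,
               tolerance = 1e-6)
  expect_equal(unname(opt@natural[["collagen_mg_ml"]]), 2.03,
               tolerance = 1e-6)
  expect_equal(unname(opt@natural[["total_cells"]]), 75400, tolerance = 1e-6)
})
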