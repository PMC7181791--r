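test_that("edge tracking recovers a noiseless sinusoidal edge to 0.25 px", {
  t <- (0:499) / 100
  edge <- 60 + 8 * (1 + sin(2 * pi * 1.2 * t)) / 2
  kym <- stepKymograph(edge)
  tr <- trackEdge(kym)
  expect_lt(max(abs(tr@rawPosition - edge)), 0.25)
})

test_that("a static edge gives a constant trace with zero displacement", {
  kym <- stepKymograph(rep(57.3, 300))
  tr <- trackEdge(kym)
  expect_equal(tr@rawPosition, rep(57.3, 300), tolerance = 0.25)
  expect_true(all(tr@rawPosition == tr@rawPosition[1]))
  expect_equal(tr@displacement, rep(0, 300), tolerance = 1e-12)
})

test_that("amplitude recovery stays within 2% under 5% pixel noise", {
  w <- makeWaveform(60, 10, fps = 100, durationS = 10)
  set.seed(11)
  kym <- stepKymograph(60 + w$clean / 0.2, noiseSd = 0.05 * 0.7)
  tr <- trackEdge(kym)
  beats <- detectBeats(tr)
  m <- computeMetrics(tr, beats)
  expect_equal(m@contractionAmplitude, 10, tolerance = 0.02)
})

test_that("tracking errors out when too many rows lack a crossing", {
  edge <- rep(60, 100)
  kym <- stepKymograph(edge)
  mat <- kymoMatrix(kym)
  mat[30:40, ] <- 0.85            # 11% of rows lose the edge entirely
  bad <- new("Kymograph", mat = mat, fps = 100, pixelSize = 0.2,
             scanlineRow = 1L)
  expect_error(trackEdge(bad), "no threshold crossing in 11")
})

test_that("right-post tracking mirrors left-post tracking", {
  t <- (0:399) / 100
  edge <- 60 + 6 * (1 + sin(2 * pi * t)) / 2
  kymL <- stepKymograph(edge)
  ## mirror the image: the post is now on the right, moving leftwards
  matR <- kymoMatrix(kymL)[, ncol(kymoMatrix(kymL)):1]
  kymR <- new("Kymograph", mat = matR, fps = 100, pixelSize = 0.2,
              scanlineRow = 1L)
  trL <- trackEdge(kymL, side = "left")
  trR <- trackEdge(kymR, side = "right")
  expect_equal(trR@rawPosition, 201 - trL@rawPosition, tolerance = 1e-9)
  ## contraction is positive for both sides
  expect_equal(trR@displacement, trL@displacement, tolerance = 1e-9)
})

test_that("baseline sits on the diastolic rest position", {
  ## constant trace: baseline equals the constant
  trConst <- traceFromDisplacement(rep(0, 400))
  expect_equal(trConst@baselinePx, 50, tolerance = 1e-9)
  expect_equal(trConst@displacement, rep(0, 400), tolerance = 1e-12)
  ## beats on a flat diastole: baseline within 0.3 px of truth
  w <- makeWaveform(60, 10, fps = 100, durationS = 10)
  tr <- traceFromDisplacement(w$clean, basePx = 80)
  expect_equal(tr@baselinePx, 80, tolerance = 0.3)
  ## slow drift: per-beat amplitudes still within 3% of truth
  wd <- makeWaveform(60, 10, fps = 100, durationS = 20, driftRateUmS = 0.1 * 0.2)
  trd <- traceFromDisplacement(wd$displacement)
  beats <- detectBeats(trd)
  m <- computeMetrics(trd, beats)
  expect_equal(m@contractionAmplitude, 10, tolerance = 0.03)
})

test_that("beat detection counts and filters beats correctly", {
  ## flat trace -> no beats, 0 BPM
  flat <- traceFromDisplacement(rep(0, 400))
  expect_identical(nrow(detectBeats(flat)), 0L)
  m0 <- computeMetrics(flat, detectBeats(flat))
  expect_identical(m0@beatsPerMinute, 0)
  expect_identical(m0@nBeats, 0L)
  ## 20 beats in 20 s -> exactly 20 detected
  w <- makeWaveform(60, 10, fps = 100, durationS = 20)
  tr <- traceFromDisplacement(w$clean)
  expect_identical(nrow(detectBeats(tr)), 20L)
  ## a 0.2 um beat class is suppressed by the 1 um prominence default
  small <- makeWaveform(60, 0.2, fps = 100, durationS = 20,
                        onsetOffsetS = 0.55)
  mixed <- traceFromDisplacement(w$clean + small$clean)
  beats <- detectBeats(mixed, minProminenceUm = 1)
  expect_identical(nrow(beats), 20L)
  expect_true(all(beats$amplitude_um > 5))
})

test_that("metrics reproduce analytic rates, slopes and force", {
  ## 1 Hz beats -> 60 BPM exactly
  w <- makeWaveform(60, 10, fps = 100, durationS = 20)
  tr <- traceFromDisplacement(w$clean)
  beats <- detectBeats(tr)
  m <- computeMetrics(tr, beats)
  expect_identical(m@beatsPerMinute, 60)
  expect_equal(m@contractionAmplitude, 10, tolerance = 1e-6)
  ## triangular rise over 0.1 s of 10 um -> 100 um/s (within one sample slope)
  w2 <- makeWaveform(60, 10, fps = 100, durationS = 10,
                     contractionTime = 0.1, relaxationTime = 0.4)
  tr2 <- traceFromDisplacement(w2$clean)
  m2 <- computeMetrics(tr2, detectBeats(tr2))
  oneSample <- 10 / 0.1 / (0.1 * 100)   # one-step slope quantum, um/s
  expect_equal(m2@contractionVelocity, 100, tolerance = oneSample / 100)
  expect_equal(m2@relaxationVelocity, 10 / 0.4, tolerance = oneSample / 25)
  ## force via a linear k = 2 uN/um calibration at 10.1 um amplitude
  w3 <- makeWaveform(60, 10.1, fps = 100, durationS = 10)
  tr3 <- traceFromDisplacement(w3$clean)
  cal <- fitCalibration(data.frame(displacement_um = 1:5,
                                   force_uN = 2 * (1:5)))
  suppressWarnings(m3 <- computeMetrics(tr3, detectBeats(tr3), cal))
  expect_equal(m3@force, 20.2, tolerance = 1e-4)
  ## beats from a different trace are rejected
  longBeats <- detectBeats(traceFromDisplacement(
    makeWaveform(60, 10, fps = 100, durationS = 30)$clean))
  expect_error(computeMetrics(tr3, longBeats), "do not match")
})

test_that("metrics scale with pixel size but BPM does not", {
  w <- makeWaveform(90, 6, fps = 100, durationS = 10)
  m1 <- computeMetrics(tr1 <- traceFromDisplacement(w$clean, pixelSize = 0.2),
                       detectBeats(tr1))
  ## same pixel trace interpreted at twice the pixel size
  tr2 <- traceFromDisplacement(2 * w$clean, pixelSize = 0.4)
  m2 <- computeMetrics(tr2, detectBeats(tr2))
  expect_equal(m2@contractionAmplitude, 2 * m1@contractionAmplitude,
               tolerance = 1e-9)
  expect_equal(m2@contractionVelocity, 2 * m1@contractionVelocity,
               tolerance = 1e-9)
  expect_equal(m2@relaxationVelocity, 2 * m1@relaxationVelocity,
               tolerance = 1e-9)
  expect_equal(m2@beatsPerMinute, m1@beatsPerMinute, tolerance = 1e-12)
})

test_that("time reversal swaps contraction and relaxation velocities", {
  w <- makeWaveform(60, 8, fps = 100, durationS = 10,
                    contractionTime = 0.1, relaxationTime = 0.4)
  fw <- traceFromDisplacement(w$clean)
  bw <- traceFromDisplacement(rev(w$clean))
  mf <- computeMetrics(fw, detectBeats(fw))
  mb <- computeMetrics(bw, detectBeats(bw))
  oneSample <- 8 / 0.1 / 10
  expect_equal(mb@contractionVelocity, mf@relaxationVelocity,
               tolerance = oneSample / mf@relaxationVelocity)
  expect_equal(mb@relaxationVelocity, mf@contractionVelocity,
               tolerance = oneSample / mf@contractionVelocity)
})

test_that("the pipeline is deterministic for identical inputs", {
  w <- makeWaveform(60, 10, fps = 100, durationS = 5, noiseSd = 0.2,
                    seed = 99)
  kym <- stepKymograph(60 + w$displacement / 0.2)
  m1 <- analyzeKymograph(kym)
  m2 <- analyzeKymograph(kym)
  expect_identical(metricsTable(list(a = m1)), metricsTable(list(a = m2)))
})

test_that("automated-vs-manual agreement reporting is correct", {
  expect_error(compareAutomatedManual(1:5, 1:4), "equal length")
  expect_error(compareAutomatedManual(c(1, 1, 1), c(1, 2, 3)), "variance")
  idlike <- compareAutomatedManual(c(2, 4, 6, 9), c(2, 4, 6, 9))
  expect_equal(idlike$r, 1)
  expect_equal(idlike$slope, 1, tolerance = 1e-12)
  expect_equal(idlike$intercept, 0, tolerance = 1e-12)
  neg <- compareAutomatedManual(c(1, 2, 3), -c(1, 2, 3))
  expect_equal(neg$r, -1)
  ## near-proportional data: closed-form regression oracle
  set.seed(5)
  manual <- runif(50, 2, 12)
  auto <- 1.02 * manual + rnorm(50, 0, 0.1)
  rep50 <- compareAutomatedManual(auto, manual)
  slopeOracle <- sum((manual - mean(manual)) * (auto - mean(auto))) /
    sum((manual - mean(manual))^2)
  expect_equal(rep50$slope, slopeOracle, tolerance = 1e-12)
  expect_gt(rep50$r, 0.99)
  expect_gt(rep50$slope, 0.98)
  expect_lt(rep50$slope, 1.06)
  expect_equal(length(rep50$residuals), 50L)
})
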