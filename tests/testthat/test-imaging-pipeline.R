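test_that("rigid registration recovers injected shifts exactly", {
  masks <- makeRoiGrid(48, 48, 4, radius = 3, margin = 12)
  rois <- roiSet(masks)
  ft <- seq(0, 30 - 1/7, by = 1/7)
  nT <- length(ft)
  k <- calciumKernelParams(noiseSd = 0)
  dff <- matrix(0, nT, 4)
  dff[, 1] <- approx(seq(0, 30, 0.01),
                     spikesToDff(c(5, 12, 20), seq(0, 30, 0.01), k),
                     ft, rule = 2)$y
  set.seed(1)
  sh <- matrix(sample(-3:3, 2 * nT, TRUE), nT, 2)
  sh[1, ] <- 0L
  mv <- renderMovie(rois, dff, ft, shifts = sh, kernel = k, seed = 2)
  reg <- registerMovie(mv, reference = movieFrames(mv)[, , 1])
  expect_identical(reg$shifts[, 1], sh[, 1])
  expect_identical(reg$shifts[, 2], sh[, 2])
  # corrected frames equal the unshifted render away from the borders
  mv0 <- renderMovie(rois, dff, ft, kernel = k, seed = 2)
  expect_equal(movieFrames(reg$movie)[5:44, 5:44, ],
               movieFrames(mv0)[5:44, 5:44, ])
  # already-aligned movie: all shifts zero
  reg0 <- registerMovie(mv0)
  expect_true(all(reg0$shifts == 0))
  # all-zero frame: warned, shift (0, 0)
  mvz <- mv0
  mvz@frames[, , 3] <- 0
  expect_warning(regz <- registerMovie(mvz, movieFrames(mv0)[, , 1]),
                 "all-zero")
  expect_true(all(regz$shifts[3, ] == 0))
})

test_that("rolling baseline matches a sort-based percentile oracle", {
  fr <- 7
  # constant trace
  expect_equal(rollingBaseline(rep(3.5, 100), fr), rep(3.5, 100))
  # constant plus rare transients (< 20% of any window)
  F <- rep(2, 400)
  F[seq(10, 390, by = 40)] <- 9
  expect_equal(rollingBaseline(F, fr), rep(2, 400))
  # linear ramp: compare every frame against the brute-force oracle
  F2 <- seq_len(300) / 10
  got <- rollingBaseline(F2, fr, window = 10, percentile = 20)
  half <- round(10 * fr / 2)
  oracle <- vapply(seq_along(F2), function(i)
    sortPercentile(F2[max(1, i - half):min(300, i + half)], 0.2),
    numeric(1))
  expect_equal(got, oracle)
  expect_error(rollingBaseline(c(-1, -1, -1), fr), "non-positive")
  expect_error(rollingBaseline(5, fr), "more than one frame")
})

test_that("dF/F is the fractional change and scale invariant", {
  expect_equal(computeDff(c(2, 4, 1), c(2, 2, 2)), c(0, 1, -0.5))
  expect_error(computeDff(1:3, c(1, 0, 1)), "positive")
  # dff o rollingBaseline is invariant to positive rescaling of F
  F <- 10 + spikesToDff(c(2, 6), seq(0, 10, 1/7), calciumKernelParams())
  d1 <- computeDff(F, rollingBaseline(F, 7))
  d2 <- computeDff(5 * F, rollingBaseline(5 * F, 7))
  expect_equal(d1, d2)
})

test_that("ROI trace extraction respects masks and disjointness", {
  masks <- makeRoiGrid(40, 40, 2, radius = 3, margin = 12)
  rois <- roiSet(masks)
  ft <- seq(0, 5 - 1/7, by = 1/7)
  nT <- length(ft)
  k <- calciumKernelParams(noiseSd = 0, baselineF = 80)
  # uniform frames: every trace equals the frame value
  mv <- renderMovie(rois, matrix(0, nT, 2), ft, kernel = k, roiContrast = 0)
  tr <- extractRoiTraces(mv, rois)
  expect_true(all(tr$roi == 80))
  expect_true(all(tr$annulus == 80))
  # signal confined to ROI 1 leaves annuli and ROI 2 unchanged
  dff <- matrix(0, nT, 2)
  dff[, 1] <- 0.7
  mv2 <- renderMovie(rois, dff, ft, kernel = k, roiContrast = 0)
  tr2 <- extractRoiTraces(mv2, rois)
  expect_equal(tr2$roi[, 1], rep(80 * 1.7, nT))
  expect_equal(tr2$roi[, 2], tr$roi[, 2])
  expect_equal(tr2$annulus, tr$annulus)
  # annuli are doughnuts: disjoint from all ROIs, non-empty
  expect_true(all(vapply(roiAnnuli(rois), sum, numeric(1)) > 0))
  allRoi <- Reduce(`|`, roiMasks(rois))
  for (a in roiAnnuli(rois)) expect_false(any(a & allRoi))
  bad <- rois
  bad@masks[[1]][] <- FALSE
  expect_error(extractRoiTraces(mv, bad), "empty mask")
})

test_that("neuropil correction removes shared contamination", {
  expect_equal(neuropilCorrect(c(1, 2), c(0, 0)), c(1, 2))
  expect_equal(neuropilCorrect(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(neuropilCorrect(c(1, 2), c(1, 2), coefficient = 0.5),
               c(0.5, 1))
  # round trip through a rendered movie with a shared neuropil field
  masks <- makeRoiGrid(48, 48, 2, radius = 3, margin = 14)
  rois <- roiSet(masks)
  ft <- seq(0, 60 - 1/7, by = 1/7)
  k <- calciumKernelParams(noiseSd = 0)
  clock <- seq(0, 60, 0.01)
  soma <- approx(clock, spikesToDff(c(5, 21, 40), clock, k), ft,
                 rule = 2)$y
  np <- 0.5 * approx(clock,
                     spikesToDff(sort(runif(30, 2, 55)), clock, k),
                     ft, rule = 2)$y
  mv <- renderMovie(rois, cbind(soma, 0), ft, neuropilDff = np, kernel = k,
                    seed = 3)
  corrected <- roiDffTraces(mv, rois)
  rms <- sqrt(mean((corrected[, 1] - soma)^2))
  expect_lt(rms / sqrt(mean(soma^2)), 0.05)
})

test_that("pixelwise maps find each pixel's preferred distance", {
  bts <- imagingSession(seed = 4)
  ft <- seq(0, max(sampleTimes(bts)) - 1/7, by = 1/7)
  btsF <- downsampleToFrames(bts, ft)
  u <- wallDistance(btsF)
  nT <- length(ft)
  h <- 8; w <- 8
  frames <- array(0, c(h, w, nT))
  breaks <- seq(0, 42, 3)
  binOf <- cut(u, breaks, labels = FALSE, right = FALSE)
  # pixel (1,1): noiseless indicator of bin 5; pixel (2,2): constant;
  # pixel (3,3): i.i.d. noise
  frames[1, 1, ] <- as.numeric(!is.na(binOf) & binOf == 5)
  frames[2, 2, ] <- 1
  set.seed(5)
  frames[3, 3, ] <- rnorm(nT)
  mv <- new("CalciumMovie", frames = frames, frameTimes = ft, plane = 1L,
            groundTruth = list())
  map <- pixelwiseMap(mv, btsF)
  expect_equal(map@preferred[1, 1], (breaks[5] + breaks[6]) / 2)
  expect_equal(map@r2[1, 1], 1)
  expect_equal(map@r2[2, 2], 0)  # SStot = 0 handled by convention
  # noise pixel: r2 below the 99th percentile of its permutation null
  running <- runningMask(btsF)
  keep <- running & !is.na(binOf)
  obs <- map@r2[3, 3]
  set.seed(6)
  null <- vapply(1:200, function(i) {
    y <- frames[3, 3, ][keep][sample(sum(keep))]
    g <- factor(binOf[keep])
    fit <- tapply(y, g, mean)[g]
    1 - sum((y - fit)^2) / sum((y - mean(y))^2)
  }, numeric(1))
  expect_lt(obs, quantile(null, 0.99))
  # r2 equals squared correlation with the bin-mean prediction
  y <- frames[3, 3, ][keep]
  g <- factor(binOf[keep])
  pred <- tapply(y, g, mean)[g]
  expect_equal(obs, unname(cor(y, pred)^2), tolerance = 1e-9)
  expect_error(pixelwiseMap(mv, btsF, breaks = c(0, 100, 200)),
               "fewer than 2")
})

test_that("ROI classification applies the active and tuned rules", {
  bts <- imagingSession(seed = 7)
  ft <- seq(0, max(sampleTimes(bts)) - 1/7, by = 1/7)
  btsF <- downsampleToFrames(bts, ft)
  flatCurve <- distanceTuning(rep(0, length(ft)), btsF, unit = "dff")
  expect_equal(classifyRoi(rep(0, length(ft)), flatCurve)$status,
               "inactive")
  # high-dff but untuned trace
  set.seed(8)
  act <- abs(rnorm(length(ft), 0, 1.2))
  actCurve <- suppressMessages(distanceTuning(act, btsF, unit = "dff"))
  cl <- classifyRoi(act, actCurve)
  expect_gt(cl$q90, 1.0)
  expect_equal(classifyRoi(act, actCurve, p = 0.5)$status, "active_untuned")
  # forced rule check: tuned requires both p < alpha and range > 0.3
  strong <- actCurve
  strong@mean <- strong@mean + ifelse(binCenters(strong) < 12, 0.8, 0)
  expect_equal(classifyRoi(act, strong, p = 0.01)$status, "tuned")
  expect_equal(classifyRoi(act, strong, p = 0.2)$status, "active_untuned")
  weak <- actCurve
  weak@mean <- 0.1 * seq_along(weak@mean) / length(weak@mean)
  expect_equal(classifyRoi(rep(0, length(ft)), weak, p = 0.01)$status,
               "inactive")
})

test_that("spline smoothing regularizes without distorting", {
  bts <- ephysSession(seed = 9)
  flat <- distanceTuning(rep(4, nSamples(bts)), bts)
  expect_equal(curveMean(smoothTuning(flat)), curveMean(flat))
  # sampled Gaussian tuning with Poisson noise: smoothing moves no bin by
  # more than its SE, and preserves the curve mean within 1%
  m <- neuronModel("unimodal", baseline = 4, amplitude = 12, preferred = 18,
                   width = 6)
  cu <- suppressMessages(distanceTuning(unitRateSeries(m, bts, seed = 10),
                                        bts))
  sm <- smoothTuning(cu)
  ok <- is.finite(curveMean(cu))
  expect_true(all(abs(curveMean(sm)[ok] - curveMean(cu)[ok]) <=
                    pmax(curveSE(cu)[ok], 1e-6)))
  expect_lt(abs(mean(curveMean(sm)[ok]) - mean(curveMean(cu)[ok])) /
              mean(curveMean(cu)[ok]), 0.01)
  # fewer than 4 bins: unchanged with a warning
  short <- new("TuningCurve", binCenters = c(1.5, 4.5, 7.5),
               mean = c(1, 2, 1), se = rep(0.1, 3), nTrials = rep(5L, 3),
               baseline = 1, trialMeans = matrix(0, 0, 3), unit = "Hz")
  expect_warning(out <- smoothTuning(short), "fewer than 4")
  expect_equal(curveMean(out), c(1, 2, 1))
})

test_that("monotonic units give monotone smoothed curves", {
  bts <- ephysSession(seed = 11)
  pop <- makePopulation(c(monotonic_decreasing = 5,
                          monotonic_increasing = 5), seed = 12)
  for (i in seq_along(pop)) {
    rs <- unitRateSeries(pop[[i]], bts, seed = 30 + i)
    sm <- suppressWarnings(smoothTuning(
      suppressMessages(distanceTuning(rs, bts)), spar = 1))
    ok <- is.finite(curveMean(sm))
    rho <- suppressWarnings(cor(curveMean(sm)[ok], binCenters(sm)[ok],
                                method = "spearman"))
    expect_gt(abs(rho), 0.9)
  }
})

test_that("registration commutes with trace extraction", {
  masks <- makeRoiGrid(48, 48, 3, radius = 3, margin = 13)
  rois <- roiSet(masks)
  ft <- seq(0, 20 - 1/7, by = 1/7)
  nT <- length(ft)
  k <- calciumKernelParams(noiseSd = 0)
  dff <- matrix(0, nT, 3)
  dff[, 2] <- approx(seq(0, 20, 0.01),
                     spikesToDff(c(3, 9), seq(0, 20, 0.01), k), ft,
                     rule = 2)$y
  set.seed(13)
  sh <- matrix(sample(-2:2, 2 * nT, TRUE), nT, 2); sh[1, ] <- 0L
  shifted <- renderMovie(rois, dff, ft, shifts = sh, kernel = k, seed = 14)
  plain <- renderMovie(rois, dff, ft, kernel = k, seed = 14)
  reg <- registerMovie(shifted, movieFrames(shifted)[, , 1])
  trReg <- extractRoiTraces(reg$movie, rois)
  trPlain <- extractRoiTraces(plain, rois)
  expect_equal(trReg$roi, trPlain$roi)
  expect_equal(trReg$annulus, trPlain$annulus)
})

test_that("movie TIFF round trip preserves intensities and times", {
  masks <- makeRoiGrid(32, 32, 1, radius = 3, margin = 10)
  rois <- roiSet(masks)
  ft <- seq(0, 3 - 1/7, by = 1/7)
  mv <- renderMovie(rois, matrix(0.4, length(ft), 1), ft,
                    kernel = calciumKernelParams(noiseSd = 0), seed = 1)
  path <- withr::local_tempfile(fileext = ".tif")
  writeMovieTiff(mv, path)
  back <- readMovieTiff(path)
  expect_equal(movieFrames(back), movieFrames(mv), tolerance = 1e-6)
  expect_equal(sampleTimes(back), sampleTimes(mv))
})
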