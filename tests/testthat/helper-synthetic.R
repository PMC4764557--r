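# Shared fixture builders. Everything is generated in code at test time;
# sessions are small by design so the whole suite stays fast.

# Canonical open-loop ephys-style session: 2-ms clock, 4-s trials
# (1 s in / 2 s hold / 1 s out), hold distances tiling 4-40 mm.
ephysSession <- function(seed = 1L, repetitions = 3, speedSd = 0) {
  cfg <- sessionConfig(seed = seed,
                       trials = list(repetitions = repetitions),
                       policy = list(speedSd = speedSd))
  simulateConfigBehavior(cfg)
}

# Imaging-style session: 10-ms clock, 8-s trials (2 s / 4 s / 2 s).
imagingSession <- function(seed = 1L, repetitions = 3) {
  cfg <- sessionConfig(seed = seed,
                       trials = list(schedule = c(2, 4, 2)),
                       coupling = list(dt = 0.01))
  simulateConfigBehavior(cfg)
}

# Simulate one unit on a session and return its binned rate series.
unitRateSeries <- function(model, bts, seed = 1L) {
  rate <- neuronRate(model, wallDistance(bts), wallVelocity(bts),
                     runSpeed(bts))
  sp <- generateSpikes(rate, sampleTimes(bts), seed = seed)
  binSpikeRate(sp, times = sampleTimes(bts))
}

# dF/F traces on a frame clock for a list of neuron models driven by a
# behavioral session (forward model on a 10-ms clock, resampled to frames).
modelDffTraces <- function(models, bts, frameTimes, kernel, seedBase = 100L) {
  tt <- sampleTimes(bts)
  clock <- seq(0, max(tt), by = 0.01)
  uC <- stats::approx(tt, wallDistance(bts), clock, rule = 2)$y
  wvC <- stats::approx(tt, wallVelocity(bts), clock, method = "constant",
                       rule = 2)$y
  vC <- stats::approx(tt, runSpeed(bts), clock, rule = 2)$y
  vapply(seq_along(models), function(r) {
    rate <- neuronRate(models[[r]], uC, wvC, vC)
    sp <- generateSpikes(rate, clock, seed = seedBase + r)
    stats::approx(clock, spikesToDff(sp, clock, kernel), frameTimes,
                  rule = 2)$y
  }, numeric(length(frameTimes)))
}

# Brute-force percentile oracle: explicit sort plus type-7 interpolation.
sortPercentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
}

expect_curve_peak <- function(curve, expected, tol = 3) {
  est <- binCenters(curve)[which.max(curveMean(curve))]
  expect_lte(abs(est - expected), tol)
}
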