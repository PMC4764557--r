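# Calcium-imaging pipeline: rigid FFT registration, rolling-percentile
# baseline and dF/F, ROI/neuropil trace extraction, pixelwise tuning maps,
# ROI classification and spline smoothing of tuning curves.

# Integer (dy, dx) shift of `frame` relative to `ref`, from the peak of the
# FFT cross-correlation (means removed so the flat background does not
# dominate). If frame == shiftMatrix(ref, dy, dx), the returned shift is
# (dy, dx).
fftShift <- function(frame, ref) {
  h <- nrow(ref); w <- ncol(ref)
  f1 <- stats::fft(frame - mean(frame))
  f2 <- stats::fft(ref - mean(ref))
  cc <- Re(stats::fft(f1 * Conj(f2), inverse = TRUE))
  peak <- which(cc == max(cc))[1] - 1L
  dy <- peak %% h
  dx <- peak %/% h
  if (dy > h / 2) dy <- dy - h
  if (dx > w / 2) dx <- dx - w
  c(dy = dy, dx = dx)
}

#' Rigid registration of a movie to a reference frame
#'
#' Each frame's global integer shift relative to the reference image is
#' estimated from the peak of an FFT-based cross-correlation, and the frame
#' is shifted back. Exposed border pixels are filled with the frame median.
#'
#' @param movie a \code{CalciumMovie}
#' @param reference reference image (H x W matrix); default is the mean
#'   frame
#' @return list(shifts = T x 2 integer matrix (dy, dx), movie = corrected
#'   \code{CalciumMovie})
#' @export
registerMovie <- function(movie, reference = NULL) {
  stopifnot(is(movie, "CalciumMovie"))
  fr <- movie@frames
  nT <- dim(fr)[3]
  if (is.null(reference)) reference <- apply(fr, c(1, 2), mean)
  stopifnot(identical(dim(reference), dim(fr)[1:2]))
  shifts <- matrix(0L, nT, 2, dimnames = list(NULL, c("dy", "dx")))
  out <- fr
  for (t in seq_len(nT)) {
    f <- fr[, , t]
    if (all(f == 0)) {
      warning("registerMovie: all-zero frame ", t, "; shift set to (0, 0)")
      next
    }
    s <- fftShift(f, reference)
    shifts[t, ] <- as.integer(s)
    if (any(s != 0))
      out[, , t] <- shiftMatrix(f, -s[1], -s[2], fill = stats::median(f))
  }
  corrected <- movie
  corrected@frames <- out
  list(shifts = shifts, movie = corrected)
}

#' Rolling-percentile baseline fluorescence
#'
#' Per-frame 20th percentile of fluorescence in a 160-s rolling window,
#' centered on the frame and truncated at the session edges.
#'
#' @param F fluorescence trace
#' @param frameRate frames per second
#' @param window window length, seconds (default 160)
#' @param percentile percentile in [0, 100] (default 20)
#' @return baseline trace F0 of the same length
#' @export
rollingBaseline <- function(F, frameRate, window = 160, percentile = 20) {
  n <- length(F)
  if (n < 2) stop("rollingBaseline: trace must have more than one frame")
  half <- max(1L, round(window * frameRate / 2))
  F0 <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    stats::quantile(F[lo:hi], percentile / 100, names = FALSE, type = 7)
  }, numeric(1))
  if (any(F0 <= 0))
    stop("rollingBaseline: non-positive baseline; dF/F undefined")
  F0
}

#' Fractional fluorescence change
#'
#' dF/F = (F - F0) / F0, elementwise.
#'
#' @param F fluorescence trace
#' @param F0 baseline trace (positive)
#' @return dF/F trace
#' @export
computeDff <- function(F, F0) {
  stopifnot(length(F) == length(F0))
  if (any(F0 <= 0)) stop("computeDff: F0 must be positive")
  (F - F0) / F0
}

#' Extract ROI and neuropil-annulus traces from a movie
#'
#' Per-frame mean intensity over the ROI mask pixels and, separately, over
#' the neuropil annulus pixels.
#'
#' @param movie a (registered) \code{CalciumMovie}
#' @param rois a \code{RoiSet}
#' @return list(roi = T x R matrix, annulus = T x R matrix)
#' @export
extractRoiTraces <- function(movie, rois) {
  stopifnot(is(movie, "CalciumMovie"), is(rois, "RoiSet"))
  fr <- movie@frames
  d <- dim(fr)
  flat <- matrix(fr, d[1] * d[2], d[3])
  getTraces <- function(masks) {
    vapply(masks, function(m) {
      idx <- which(m)
      if (!length(idx)) stop("extractRoiTraces: empty mask")
      colMeans(flat[idx, , drop = FALSE])
    }, numeric(d[3]))
  }
  list(roi = getTraces(rois@masks), annulus = getTraces(rois@annuli))
}

#' Neuropil correction of an ROI dF/F trace
#'
#' The annulus dF/F, scaled by \code{coefficient}, is subtracted from the
#' ROI dF/F to remove out-of-focus contamination.
#'
#' @param roiDff ROI dF/F trace (vector or T x R matrix)
#' @param annulusDff annulus dF/F of the same shape
#' @param coefficient subtraction coefficient (default 1)
#' @return corrected dF/F
#' @export
neuropilCorrect <- function(roiDff, annulusDff, coefficient = 1) {
  stopifnot(length(roiDff) == length(annulusDff))
  roiDff - coefficient * annulusDff
}

#' Full ROI dF/F extraction pipeline
#'
#' Extracts ROI and annulus traces, computes the rolling-percentile baseline
#' and dF/F for each, and returns the neuropil-corrected dF/F.
#'
#' @param movie a registered \code{CalciumMovie}
#' @param rois a \code{RoiSet}
#' @param window baseline window, seconds
#' @param percentile baseline percentile
#' @param coefficient neuropil subtraction coefficient
#' @return T x R matrix of corrected dF/F traces
#' @export
roiDffTraces <- function(movie, rois, window = 160, percentile = 20,
                         coefficient = 1) {
  tr <- extractRoiTraces(movie, rois)
  frameRate <- 1 / (movie@frameTimes[2] - movie@frameTimes[1])
  dffOf <- function(Fmat) {
    apply(Fmat, 2, function(F)
      computeDff(F, rollingBaseline(F, frameRate, window, percentile)))
  }
  neuropilCorrect(dffOf(tr$roi), dffOf(tr$annulus), coefficient)
}

#' Downsample a behavioral series to the imaging frame clock
#'
#' Within-frame means of speed and wall distances; trial id by majority.
#'
#' @param bts a \code{BehaviorTimeSeries}
#' @param frameTimes frame times, seconds (frame i covers
#'   [frameTimes[i], frameTimes[i+1]))
#' @return a \code{BehaviorTimeSeries} on the frame clock
#' @export
downsampleToFrames <- function(bts, frameTimes) {
  n <- length(frameTimes)
  dt <- frameTimes[2] - frameTimes[1]
  idx <- findInterval(bts@t, c(frameTimes, frameTimes[n] + dt))
  keep <- idx >= 1 & idx <= n
  idx <- idx[keep]
  agg <- function(x) as.numeric(tapply(x[keep], idx, mean))
  present <- sort(unique(idx))
  if (!identical(present, seq_len(n)))
    stop("downsampleToFrames: behavior does not cover every frame")
  trial <- as.integer(tapply(bts@trialId[keep], idx, function(z)
    as.integer(names(which.max(table(z))))))
  new("BehaviorTimeSeries", t = frameTimes, v = agg(bts@v),
      phi = agg(bts@phi), uLeft = agg(bts@uLeft), uRight = agg(bts@uRight),
      trialId = trial, clamped = rep(FALSE, n), trials = bts@trials)
}

#' Pixelwise wall-distance tuning map
#'
#' Regresses each pixel's fluorescence time series on an indicator basis of
#' 3-mm wall-distance bins (equivalent to per-bin means), restricted to
#' running frames. Each pixel's preferred distance is the bin with the
#' maximum fitted response, and r-squared is 1 - SSres/SStot from the binned
#' model (0 by convention for constant pixels).
#'
#' @param movie a registered \code{CalciumMovie}
#' @param btsFrames behavior downsampled to the frame clock
#'   (see \code{downsampleToFrames})
#' @param side which wall
#' @param breaks distance bin edges, mm
#' @param speedThreshold running threshold, cm/s
#' @return a \code{PixelwiseMap}
#' @export
pixelwiseMap <- function(movie, btsFrames, side = "right",
                         breaks = seq(0, 42, by = 3), speedThreshold = 3) {
  stopifnot(is(movie, "CalciumMovie"),
            length(btsFrames@t) == dim(movie@frames)[3])
  u <- wallDistance(btsFrames, side)
  running <- runningMask(btsFrames, speedThreshold)
  bin <- cut(u, breaks, labels = FALSE, right = FALSE)
  keep <- running & !is.na(bin)
  if (length(unique(bin[keep])) < 2)
    stop("pixelwiseMap: fewer than 2 occupied distance bins")
  d <- dim(movie@frames)
  flat <- t(matrix(movie@frames, d[1] * d[2], d[3]))  # T x P
  flat <- flat[keep, , drop = FALSE]
  g <- factor(bin[keep], levels = sort(unique(bin[keep])))
  counts <- as.integer(table(g))
  ind <- stats::model.matrix(~ g - 1)
  binMeans <- (t(ind) %*% flat) / counts          # B x P fitted bin means
  fitted <- ind %*% binMeans
  ssRes <- colSums((flat - fitted)^2)
  grand <- colMeans(flat)
  ssTot <- colSums((flat - rep(grand, each = nrow(flat)))^2)
  r2 <- ifelse(ssTot > 0, 1 - ssRes / ssTot, 0)
  r2 <- pmin(pmax(r2, 0), 1)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  pref <- centers[as.integer(levels(g))[apply(binMeans, 2, which.max)]]
  new("PixelwiseMap",
      preferred = matrix(pref, d[1], d[2]),
      r2 = matrix(r2, d[1], d[2]),
      binCenters = centers[sort(unique(bin[keep]))])
}

#' Render a pixelwise map to a PNG (hue = preferred distance,
#' brightness = r-squared)
#'
#' @param map a \code{PixelwiseMap}
#' @param path output PNG path
#' @return \code{path}, invisibly
#' @export
writeMapPng <- function(map, path) {
  pref <- map@preferred
  rng <- range(map@binCenters)
  hue <- 0.8 * (pref - rng[1]) / max(rng[2] - rng[1], 1e-9)
  col <- grDevices::hsv(h = pmin(pmax(hue, 0), 1), s = 1,
                        v = pmin(pmax(map@r2, 0), 1))
  img <- grDevices::as.raster(matrix(col, nrow(pref), ncol(pref)))
  grDevices::png(path, width = ncol(pref), height = nrow(pref))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({graphics::par(op); grDevices::dev.off()})
  graphics::plot.new()
  graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
  invisible(path)
}

#' Classify an ROI as inactive, active-untuned or tuned
#'
#' An ROI is active if the 90th percentile of its corrected dF/F exceeds
#' \code{activeThreshold} (default 1.0 dF/F); it is tuned if the tuning
#' ANOVA p-value is below \code{alpha} (default 0.05) and the range of its
#' tuning curve exceeds \code{rangeThreshold} (default 0.3 dF/F). Tuned
#' takes precedence over active.
#'
#' @param dff corrected dF/F trace
#' @param curve the ROI's wall-distance \code{TuningCurve} (dF/F units)
#' @param p ANOVA p-value for the tuning (default: computed from the curve)
#' @param activeThreshold 90th-percentile dF/F threshold for "active"
#' @param rangeThreshold tuning-curve range threshold for "tuned"
#' @param alpha ANOVA significance level
#' @return list(status, p, range, q90)
#' @export
classifyRoi <- function(dff, curve, p = NULL, activeThreshold = 1.0,
                        rangeThreshold = 0.3, alpha = 0.05) {
  if (is.null(p))
    p <- tryCatch(suppressMessages(anovaTuningTest(curve)),
                  error = function(e) NA_real_)
  rng <- curveRange(curve)
  q90 <- stats::quantile(dff, 0.9, names = FALSE)
  status <- if (is.finite(p) && p < alpha && is.finite(rng) &&
                rng > rangeThreshold) "tuned"
  else if (q90 > activeThreshold) "active_untuned"
  else "inactive"
  list(status = status, p = p, range = rng, q90 = q90)
}

#' Spline smoothing of a tuning curve
#'
#' Fits a cubic smoothing spline to the binned means (weighted by the number
#' of contributing trials) and evaluates it at the bin centers. With fewer
#' than 4 defined bins the curve is returned unchanged with a warning.
#'
#' @param curve a \code{TuningCurve}
#' @param spar smoothing parameter passed to \code{stats::smooth.spline};
#'   \code{NULL} (default) selects it by generalized cross-validation
#' @return a \code{TuningCurve} with smoothed means
#' @export
smoothTuning <- function(curve, spar = NULL) {
  stopifnot(is(curve, "TuningCurve"))
  ok <- is.finite(curve@mean)
  if (sum(ok) < 4) {
    warning("smoothTuning: fewer than 4 defined bins; returning input")
    return(curve)
  }
  x <- curve@binCenters[ok]
  y <- curve@mean[ok]
  if (stats::var(y) == 0) return(curve)  # flat curves are fixed points
  w <- pmax(curve@nTrials[ok], 1)
  fit <- if (is.null(spar)) stats::smooth.spline(x, y, w = w)
  else stats::smooth.spline(x, y, w = w, spar = spar)
  sm <- curve
  sm@mean[ok] <- stats::predict(fit, x)$y
  sm
}
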