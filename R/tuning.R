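# Spike-train analyses: binning, wall-distance tuning curves, ANOVA tuning
# tests, activation/suppression modulation, direction, laterality,
# open-vs-closed and speed-gain indices.

#' Bin spike times into a rate series
#'
#' Counts per bin divided by the bin width. With \code{times} given, the
#' rate is aligned to that (uniform) clock, e.g. the behavior clock.
#'
#' @param spikes sorted spike times, seconds
#' @param binWidth bin width in seconds (default 0.002, i.e. 2 ms)
#' @param span session span \code{c(start, end)} in seconds; ignored when
#'   \code{times} is given
#' @param times optional explicit clock of bin start times
#' @return numeric rate series in Hz with attribute \code{"times"} (bin
#'   start times)
#' @export
binSpikeRate <- function(spikes, binWidth = 0.002, span = NULL,
                         times = NULL) {
  if (length(spikes) && is.unsorted(spikes))
    stop("binSpikeRate: spikes must be sorted")
  if (is.null(times)) {
    if (is.null(span)) span <- c(0, if (length(spikes)) max(spikes) else 1)
    times <- seq(span[1], span[2], by = binWidth)
  } else {
    binWidth <- times[2] - times[1]
  }
  n <- length(times)
  counts <- tabulate(
    findInterval(spikes, c(times, times[n] + binWidth)), nbins = n)
  rate <- counts / binWidth
  attr(rate, "times") <- times
  rate
}

# Per-(trial, bin) means of `response` over samples where `sampleMask` is
# TRUE, binning `x` with `breaks`. Returns the trials x bins matrix plus the
# across-trial mean/SE per bin. Bins with fewer than `minTrials` contributing
# trials are set to NA in the mean (and logged via message).
binnedTrialMeans <- function(response, x, trialId, breaks, sampleMask,
                             minTrials = 3) {
  stopifnot(length(response) == length(x), length(x) == length(trialId))
  bin <- cut(x, breaks, labels = FALSE, right = FALSE)
  keep <- sampleMask & !is.na(bin)
  trials <- sort(unique(trialId))
  nb <- length(breaks) - 1L
  tm <- matrix(NA_real_, length(trials), nb,
               dimnames = list(as.character(trials), NULL))
  if (any(keep)) {
    sums <- tapply(response[keep], list(match(trialId[keep], trials),
                                        bin[keep]), mean)
    tm[as.integer(rownames(sums)), as.integer(colnames(sums))] <- sums
  }
  nTrials <- colSums(!is.na(tm))
  mu <- colMeans(tm, na.rm = TRUE)
  se <- apply(tm, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) > 1) stats::sd(col) / sqrt(length(col)) else 0
  })
  drop <- nTrials < minTrials
  if (any(drop & nTrials > 0))
    message(sum(drop & nTrials > 0),
            " bin(s) dropped for having fewer than ", minTrials, " trials")
  mu[drop] <- NA_real_
  se[drop] <- NA_real_
  mu[!is.finite(mu)] <- NA_real_
  list(trialMeans = tm, mean = as.numeric(mu), se = as.numeric(se),
       nTrials = as.integer(nTrials))
}

#' Wall-distance tuning curve
#'
#' Bins the response (spike rate or dF/F) by wall distance in 3-mm bins,
#' averaging within trials first and then across trials (mean +/- SE).
#' Samples are restricted to running (speed > \code{speedThreshold}), and
#' only trials whose mean speed exceeds the threshold contribute. The
#' out-of-reach baseline is the mean response during running while the wall
#' is farther than \code{baselineThreshold} (per-trial means averaged across
#' trials).
#'
#' @param response response series on the behavior clock (Hz or dF/F)
#' @param bts a \code{BehaviorTimeSeries} on the same clock
#' @param side which wall drives the tuning ("right" = contralateral by
#'   convention)
#' @param breaks distance bin edges, mm (default 3-mm bins spanning 0-42 mm)
#' @param speedThreshold running threshold, cm/s (default 3, strict)
#' @param minTrials minimum trials for a bin to enter the curve (default 3)
#' @param baselineThreshold out-of-reach distance threshold, mm (default 30)
#' @param unit response unit label ("Hz" or "dff")
#' @param trials optional vector of trial ids to include (e.g. the fast or
#'   slow half from \code{splitTrialsBySpeed}); default all
#' @return a \code{TuningCurve}
#' @export
distanceTuning <- function(response, bts, side = c("right", "left"),
                           breaks = seq(0, 42, by = 3), speedThreshold = 3,
                           minTrials = 3, baselineThreshold = 30,
                           unit = "Hz", trials = NULL) {
  side <- match.arg(side)
  stopifnot(is(bts, "BehaviorTimeSeries"),
            length(response) == length(bts@t))
  u <- wallDistance(bts, side)
  running <- runningMask(bts, speedThreshold)
  trialSpeed <- tapply(bts@v, bts@trialId, mean)
  goodTrials <- as.numeric(names(trialSpeed))[trialSpeed > speedThreshold]
  if (!is.null(trials)) goodTrials <- intersect(goodTrials, trials)
  if (!length(goodTrials))
    stop("distanceTuning: no trials with mean speed above ", speedThreshold,
         " cm/s")
  inTrial <- bts@trialId %in% goodTrials
  bt <- binnedTrialMeans(response, u, bts@trialId, breaks,
                         sampleMask = running & inTrial,
                         minTrials = minTrials)
  baseMask <- running & inTrial & u > baselineThreshold
  baseline <- if (any(baseMask)) {
    mean(tapply(response[baseMask], bts@trialId[baseMask], mean))
  } else NA_real_
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  new("TuningCurve", binCenters = centers, mean = bt$mean, se = bt$se,
      nTrials = bt$nTrials, baseline = baseline,
      trialMeans = bt$trialMeans, unit = unit)
}

#' ANOVA test for wall-distance tuning
#'
#' One-way fixed-effects ANOVA on the per-trial binned means, with distance
#' bins as groups and trials as replicates. Degenerate input (no variance
#' anywhere) returns p = 1 by convention.
#'
#' @param x a \code{TuningCurve} or a trials x bins matrix of per-trial
#'   binned means (NA allowed for unvisited bins)
#' @return p-value in [0, 1]
#' @export
anovaTuningTest <- function(x) {
  tm <- if (is(x, "TuningCurve")) x@trialMeans else as.matrix(x)
  y <- as.vector(tm)
  g <- factor(rep(seq_len(ncol(tm)), each = nrow(tm)))
  ok <- !is.na(y)
  y <- y[ok]; g <- droplevels(g[ok])
  perBin <- table(g)
  if (sum(perBin >= 2) < 2)
    stop("anovaTuningTest: need at least 2 bins with at least 2 trials")
  if (stats::var(y) == 0) {
    message("anovaTuningTest: zero variance, returning p = 1")
    return(1)
  }
  # perfect separation (no within-bin variance but bins differ): p -> 0
  withinVar <- tapply(y, g, stats::var)
  if (all(withinVar == 0, na.rm = TRUE)) return(0)
  a <- suppressWarnings(stats::anova(stats::lm(y ~ g)))
  p <- a[["Pr(>F)"]][1]
  if (!is.finite(p)) 1 else p
}

#' Activation, suppression and the modulation index
#'
#' From a tuning curve and its out-of-reach baseline: activation is peak
#' minus baseline, suppression is baseline minus minimum, and the modulation
#' index is (activation - suppression) / (activation + suppression). Units
#' that are purely activated have index 1, purely suppressed units have
#' index -1, and units that are both activated and suppressed fall near 0.
#' The index is NA when activation + suppression is not positive.
#'
#' @param curve a \code{TuningCurve} with a defined baseline
#' @param outOfReachThreshold if given, peak and minimum are taken over bins
#'   with centers at or below this distance (mm); by default all defined
#'   bins are used
#' @param alpha significance level for the tuned flag (default 0.05)
#' @return one-row data.frame: baseline, peak, minimum, activation,
#'   suppression, modulation, p, tuned
#' @export
tuningSummary <- function(curve, outOfReachThreshold = NULL, alpha = 0.05) {
  stopifnot(is(curve, "TuningCurve"))
  if (!is.finite(curve@baseline))
    stop("tuningSummary: curve has no defined baseline (no out-of-reach epochs)")
  m <- curve@mean
  if (!is.null(outOfReachThreshold))
    m[curve@binCenters > outOfReachThreshold] <- NA_real_
  m <- m[is.finite(m)]
  if (!length(m)) stop("tuningSummary: no defined in-reach bins")
  peak <- max(m); minimum <- min(m)
  act <- peak - curve@baseline
  sup <- curve@baseline - minimum
  mod <- if ((act + sup) > 0) (act - sup) / (act + sup) else NA_real_
  p <- tryCatch(suppressMessages(anovaTuningTest(curve)),
                error = function(e) NA_real_)
  data.frame(baseline = curve@baseline, peak = peak, minimum = minimum,
             activation = act, suppression = sup, modulation = mod,
             p = p, tuned = is.finite(p) && p < alpha)
}

#' Direction tuning during open-loop wall movement
#'
#' Builds trial-averaged rate profiles over the epochs when the wall moves
#' towards vs away from the animal (detected from the sign of the wall
#' velocity with a dead band), takes the range (max - min) of each profile
#' within the movement window, and forms the direction modulation index
#' (towards - away) / (towards + away) on the ranges. Units responding only
#' to approach have index 1, only to withdrawal -1.
#'
#' @param rate rate series on the behavior clock, Hz
#' @param bts a \code{BehaviorTimeSeries} on the same clock
#' @param side which wall ("right" or "left")
#' @param window profile window from movement onset, seconds (default 1,
#'   the duration of the open-loop movement segments)
#' @param deadband wall-velocity dead band, mm/s (default 1)
#' @param speedThreshold trials must have mean speed above this, cm/s
#' @return list with elements \code{towardsProfile}, \code{awayProfile}
#'   (mean rate vs time from movement onset), \code{towardsRange},
#'   \code{awayRange} and \code{index}
#' @export
directionSummary <- function(rate, bts, side = c("right", "left"),
                             window = 1, deadband = 1, speedThreshold = 3) {
  side <- match.arg(side)
  stopifnot(length(rate) == length(bts@t))
  dt <- bts@t[2] - bts@t[1]
  nw <- max(2L, round(window / dt))
  vel <- wallVelocity(bts, side)
  trialSpeed <- tapply(bts@v, bts@trialId, mean)
  goodTrials <- as.numeric(names(trialSpeed))[trialSpeed > speedThreshold]

  collect <- function(dirMask, label) {
    segs <- list()
    for (tr in goodTrials) {
      idx <- which(bts@trialId == tr)
      on <- idx[dirMask[idx]]
      if (!length(on)) next
      start <- on[1]
      end <- min(start + nw - 1L, idx[length(idx)])
      if (end - start + 1L < nw / 2) next  # window barely covered, skip
      segs[[length(segs) + 1L]] <- rate[start:end]
    }
    if (!length(segs))
      stop("directionSummary: no ", label, " movement epochs found")
    len <- min(lengths(segs))
    colMeans(do.call(rbind, lapply(segs, function(s) s[seq_len(len)])))
  }
  towardsProfile <- collect(vel < -deadband, "towards")
  awayProfile <- collect(vel > deadband, "away")
  tr <- max(towardsProfile) - min(towardsProfile)
  ar <- max(awayProfile) - min(awayProfile)
  idx <- if ((tr + ar) > 0) (tr - ar) / (tr + ar) else NA_real_
  list(towardsProfile = towardsProfile, awayProfile = awayProfile,
       towardsRange = tr, awayRange = ar, index = idx)
}

#' Laterality index from contralateral and ipsilateral tuning curves
#'
#' Range (max - min) of each curve; index = (contra - ipsi) /
#' (contra + ipsi). 1 means the unit responds only to the contralateral
#' wall, -1 only to the ipsilateral wall. NA when both ranges are 0.
#'
#' @param contra \code{TuningCurve} for the contralateral wall
#' @param ipsi \code{TuningCurve} for the ipsilateral wall, on matching bins
#' @return list(kind, value, contraRange, ipsiRange)
#' @export
lateralityIndex <- function(contra, ipsi) {
  stopifnot(is(contra, "TuningCurve"), is(ipsi, "TuningCurve"))
  if (!isTRUE(all.equal(contra@binCenters, ipsi@binCenters)))
    stop("lateralityIndex: curves must share bin centers")
  cr <- curveRange(contra); ir <- curveRange(ipsi)
  val <- if (is.finite(cr) && is.finite(ir) && (cr + ir) > 0)
    (cr - ir) / (cr + ir) else NA_real_
  list(kind = "laterality", value = val, contraRange = cr, ipsiRange = ir)
}

#' Open-loop vs closed-loop modulation index
#'
#' (open - closed) / (open + closed) on mean rates restricted to a shared
#' wall-distance range and to running epochs. 0 means equal rates in both
#' conditions. NA when both means are 0.
#'
#' @param openRates rate samples from open-loop epochs, already restricted
#'   to the shared distance range (Hz)
#' @param closedRates rate samples from closed-loop epochs, same restriction
#' @return list(kind, value, openMean, closedMean)
#' @export
openClosedIndex <- function(openRates, closedRates) {
  if (!length(openRates) || !length(closedRates))
    stop("openClosedIndex: both rate vectors must be non-empty")
  o <- mean(openRates); cl <- mean(closedRates)
  val <- if ((o + cl) > 0) (o - cl) / (o + cl) else NA_real_
  list(kind = "open_vs_closed", value = val, openMean = o, closedMean = cl)
}

#' Open-vs-closed index from full series
#'
#' Convenience wrapper that finds the shared wall-distance range between an
#' open-loop and a closed-loop session, restricts both rate series to that
#' range and to running samples, and calls \code{openClosedIndex}.
#'
#' @param rateOpen,btsOpen rate series and behavior for the open-loop session
#' @param rateClosed,btsClosed same for the closed-loop session
#' @param side which wall
#' @param speedThreshold running threshold, cm/s
#' @return list as in \code{openClosedIndex}, plus \code{range}
#' @export
openClosedFromSeries <- function(rateOpen, btsOpen, rateClosed, btsClosed,
                                 side = "right", speedThreshold = 3) {
  uo <- wallDistance(btsOpen, side); uc <- wallDistance(btsClosed, side)
  ro <- runningMask(btsOpen, speedThreshold)
  rc <- runningMask(btsClosed, speedThreshold)
  lo <- max(min(uo[ro]), min(uc[rc]))
  hi <- min(max(uo[ro]), max(uc[rc]))
  if (lo >= hi) stop("openClosedFromSeries: no shared wall-distance range")
  mo <- ro & uo >= lo & uo <= hi
  mc <- rc & uc >= lo & uc <= hi
  out <- openClosedIndex(rateOpen[mo], rateClosed[mc])
  out$range <- c(lo, hi)
  out
}

#' Running-speed tuning when the wall is out of reach
#'
#' Bins the rate by running speed over out-of-reach samples (per-trial means
#' first, then across trials) and tests significance with a one-way ANOVA
#' across speed bins.
#'
#' @param rate rate series, Hz
#' @param bts a \code{BehaviorTimeSeries} on the same clock
#' @param outOfReachMask logical mask of out-of-reach samples (e.g.
#'   \code{wallDistance(bts) > 30})
#' @param breaks speed bin edges, cm/s
#' @param minTrials minimum trials per bin
#' @return list(curve = \code{TuningCurve} over speed bins (centers in
#'   cm/s), p = ANOVA p-value)
#' @export
speedTuning <- function(rate, bts, outOfReachMask,
                        breaks = seq(0, 60, by = 5), minTrials = 3) {
  stopifnot(length(rate) == length(bts@t),
            length(outOfReachMask) == length(bts@t))
  if (!any(outOfReachMask))
    stop("speedTuning: no out-of-reach samples")
  bt <- binnedTrialMeans(rate, bts@v, bts@trialId, breaks,
                         sampleMask = outOfReachMask, minTrials = minTrials)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  curve <- new("TuningCurve", binCenters = centers, mean = bt$mean,
               se = bt$se, nTrials = bt$nTrials, baseline = NA_real_,
               trialMeans = bt$trialMeans, unit = "Hz")
  p <- anovaTuningTest(curve)
  list(curve = curve, p = p)
}

#' Speed-gain index between fast- and slow-trial tuning curves
#'
#' Least-squares multiplicative gain g mapping the slow curve onto the fast
#' curve over bins defined in both (closed form: <fast, slow> /
#' <slow, slow>); the index is ln(g). Positive values mean the unit is more
#' active during fast running.
#'
#' @param fast \code{TuningCurve} from trials above the median speed
#' @param slow \code{TuningCurve} from trials below the median speed
#' @return list(kind, value = ln(g), gain = g)
#' @export
speedGainIndex <- function(fast, slow) {
  stopifnot(is(fast, "TuningCurve"), is(slow, "TuningCurve"))
  if (!isTRUE(all.equal(fast@binCenters, slow@binCenters)))
    stop("speedGainIndex: curves must share bin centers")
  ok <- is.finite(fast@mean) & is.finite(slow@mean)
  s <- slow@mean[ok]; f <- fast@mean[ok]
  if (!length(s) || all(s == 0)) {
    warning("speedGainIndex: slow curve is undefined or identically zero")
    return(list(kind = "speed_gain", value = NA_real_, gain = NA_real_))
  }
  g <- sum(f * s) / sum(s * s)
  list(kind = "speed_gain", value = log(g), gain = g)
}

#' Split trials into fast and slow halves at the median trial speed
#'
#' @param bts a \code{BehaviorTimeSeries}
#' @param speedThreshold running threshold for a trial to qualify, cm/s
#' @return list(fast, slow) of trial ids
#' @export
splitTrialsBySpeed <- function(bts, speedThreshold = 3) {
  trialSpeed <- tapply(bts@v, bts@trialId, mean)
  trialSpeed <- trialSpeed[trialSpeed > speedThreshold]
  med <- stats::median(trialSpeed)
  ids <- as.numeric(names(trialSpeed))
  list(fast = ids[trialSpeed > med], slow = ids[trialSpeed <= med])
}

#' Restrict a behavioral series to a subset of trials
#'
#' @param bts a \code{BehaviorTimeSeries}
#' @param ids trial ids to keep
#' @return a \code{BehaviorTimeSeries}; the clock is re-based to be uniform
#' @export
subsetTrials <- function(bts, ids) {
  keep <- bts@trialId %in% ids
  if (!any(keep)) stop("subsetTrials: no samples for the requested trials")
  dt <- bts@t[2] - bts@t[1]
  new("BehaviorTimeSeries",
      t = seq(0, by = dt, length.out = sum(keep)),
      v = bts@v[keep], phi = bts@phi[keep],
      uLeft = bts@uLeft[keep], uRight = bts@uRight[keep],
      trialId = bts@trialId[keep], clamped = bts@clamped[keep],
      trials = list())
}
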