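#' @import methods
NULL

#' Coupling parameters for the virtual corridor
#'
#' Parameters of the closed-loop wall coupling rule
#' \eqn{\Delta u = \gamma v \sin(\epsilon) \Delta t}, together with the
#' geometry of the corridor. Distances from snout to wall are in mm; the
#' corridor is \code{corridorHalfwidth} mm wide on each side of the center,
#' and the walls are never allowed closer than \code{minWallDistance} mm.
#'
#' @slot gain dimensionless coupling gain \eqn{\gamma}
#' @slot dt simulation update step, seconds
#' @slot corridorHalfwidth snout-to-wall distance at the corridor center, mm
#' @slot minWallDistance closest allowed snout-to-wall distance, mm
#' @slot trialLength length of a closed-loop trial along the corridor, cm
#'
#' @export
setClass("CouplingParams",
  representation(
    gain = "numeric",
    dt = "numeric",
    corridorHalfwidth = "numeric",
    minWallDistance = "numeric",
    trialLength = "numeric"
  ),
  prototype(
    gain = 1, dt = 0.01, corridorHalfwidth = 19,
    minWallDistance = 4, trialLength = 200
  )
)

setValidity("CouplingParams", function(object) {
  msg <- character()
  if (length(object@dt) != 1 || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number")
  if (!is.finite(object@gain)) msg <- c(msg, "gain must be finite")
  if (object@minWallDistance < 0)
    msg <- c(msg, "minWallDistance must be >= 0")
  if (object@corridorHalfwidth <= object@minWallDistance)
    msg <- c(msg, "corridorHalfwidth must exceed minWallDistance")
  if (object@trialLength <= 0) msg <- c(msg, "trialLength must be > 0")
  if (length(msg)) msg else TRUE
})

#' Constructor for CouplingParams
#'
#' @param gain coupling gain (dimensionless), default 1
#' @param dt update step in seconds, default 0.01
#' @param corridorHalfwidth snout-to-wall distance at corridor center (mm)
#' @param minWallDistance closest allowed wall distance (mm)
#' @param trialLength trial length along the corridor (cm)
#' @return a \code{CouplingParams} object
#' @examples
#' couplingParams(gain = 1, dt = 0.01)
#' @export
couplingParams <- function(gain = 1, dt = 0.01, corridorHalfwidth = 19,
                           minWallDistance = 4, trialLength = 200) {
  new("CouplingParams", gain = gain, dt = dt,
      corridorHalfwidth = corridorHalfwidth,
      minWallDistance = minWallDistance, trialLength = trialLength)
}

#' A single corridor trial
#'
#' Describes one trial: a closed-loop bend (wall position coupled to
#' locomotion), an open-loop wall presentation (wall moved on a fixed
#' schedule to \code{openLoopDistance}), or an illusory-corridor trial
#' (closed-loop with the walls replaced by position-scaled photostimulation).
#'
#' @slot turnAngle corridor turn angle \eqn{\psi}, degrees
#' @slot mode one of \code{"closed_loop"}, \code{"open_loop"}, \code{"illusory"}
#' @slot openLoopDistance hold distance of the contralateral wall (mm);
#'   \code{NA} unless \code{mode == "open_loop"}
#' @slot schedule numeric vector \code{c(moveIn, hold, moveOut)} of open-loop
#'   segment durations in seconds
#' @slot farDistance wall distance representing "far out of reach" (mm), the
#'   start/end position of the open-loop wall sweep
#' @slot stimCondition free-form stimulation label
#' @export
setClass("CorridorTrial",
  representation(
    turnAngle = "numeric",
    mode = "character",
    openLoopDistance = "numeric",
    schedule = "numeric",
    farDistance = "numeric",
    stimCondition = "character"
  ),
  prototype(
    turnAngle = 0, mode = "closed_loop", openLoopDistance = NA_real_,
    schedule = c(moveIn = 1, hold = 2, moveOut = 1), farDistance = 45,
    stimCondition = "none"
  )
)

setValidity("CorridorTrial", function(object) {
  msg <- character()
  if (!object@mode %in% c("closed_loop", "open_loop", "illusory"))
    msg <- c(msg, "mode must be closed_loop, open_loop or illusory")
  if (object@mode == "open_loop" && !is.finite(object@openLoopDistance))
    msg <- c(msg, "open_loop trials require a finite openLoopDistance")
  if (object@mode != "open_loop" && is.finite(object@openLoopDistance))
    msg <- c(msg, "openLoopDistance only applies to open_loop trials")
  if (length(object@schedule) != 3 || any(object@schedule < 0))
    msg <- c(msg, "schedule must be three non-negative durations")
  if (length(msg)) msg else TRUE
})

#' Constructor for CorridorTrial
#'
#' @param turnAngle corridor turn angle in degrees (e.g. -11.3, 0, 16.7)
#' @param mode trial mode: "closed_loop", "open_loop" or "illusory"
#' @param openLoopDistance hold distance (mm) for open-loop trials
#' @param schedule open-loop segment durations c(moveIn, hold, moveOut), s.
#'   The default is the 4-s electrophysiology structure (1 s in, 2 s hold,
#'   1 s out); imaging sessions use c(2, 4, 2).
#' @param farDistance out-of-reach wall distance (mm) at the start and end
#'   of an open-loop sweep
#' @param stimCondition stimulation label carried through to outputs
#' @return a \code{CorridorTrial}
#' @export
corridorTrial <- function(turnAngle = 0, mode = "closed_loop",
                          openLoopDistance = NA_real_,
                          schedule = c(1, 2, 1), farDistance = 45,
                          stimCondition = "none") {
  new("CorridorTrial", turnAngle = turnAngle, mode = mode,
      openLoopDistance = openLoopDistance, schedule = schedule,
      farDistance = farDistance, stimCondition = stimCondition)
}

#' Tracking policy: a synthetic stand-in for the animal
#'
#' The corridor is closed-loop: something must steer. In the experiments the
#' animal is the controller; for simulation we provide explicit policies.
#' \code{"ideal"} runs exactly along the corridor (\eqn{\phi = \psi});
#' \code{"proportional"} steers against the lateral offset sensed as
#' wall-distance asymmetry; \code{"noisy"} adds angular random-walk noise to
#' the proportional controller.
#'
#' @slot kind "ideal", "proportional" or "noisy"
#' @slot steeringGain degrees of run angle per mm of lateral offset
#' @slot noiseSd angular noise intensity, degrees per sqrt(second)
#' @slot speed mean run speed, cm/s; constant within a trial
#' @slot speedSd across-trial SD of the run speed, cm/s (0 = constant)
#' @export
setClass("TrackingPolicy",
  representation(
    kind = "character",
    steeringGain = "numeric",
    noiseSd = "numeric",
    speed = "numeric",
    speedSd = "numeric"
  ),
  prototype(kind = "ideal", steeringGain = 2, noiseSd = 0, speed = 20,
            speedSd = 0)
)

setValidity("TrackingPolicy", function(object) {
  msg <- character()
  if (!object@kind %in% c("ideal", "proportional", "noisy"))
    msg <- c(msg, "kind must be ideal, proportional or noisy")
  if (object@speed <= 0) msg <- c(msg, "speed must be positive")
  if (object@noiseSd < 0 || object@speedSd < 0)
    msg <- c(msg, "noiseSd and speedSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Constructor for TrackingPolicy
#' @param kind "ideal", "proportional" or "noisy"
#' @param steeringGain deg of run angle per mm of lateral offset (proportional
#'   and noisy policies)
#' @param noiseSd angular random-walk noise, deg/sqrt(s) (noisy policy)
#' @param speed mean run speed, cm/s (constant within a trial)
#' @param speedSd across-trial speed SD, cm/s
#' @return a \code{TrackingPolicy}
#' @export
trackingPolicy <- function(kind = "ideal", steeringGain = 2, noiseSd = 0,
                           speed = 20, speedSd = 0) {
  new("TrackingPolicy", kind = kind, steeringGain = steeringGain,
      noiseSd = noiseSd, speed = speed, speedSd = speedSd)
}

#' Behavioral time series
#'
#' A uniformly sampled trajectory through the corridor: run speed, run angle,
#' snout-to-wall distances on both sides and a trial label per sample.
#'
#' @slot t sample times, seconds, strictly increasing and uniform
#' @slot v run speed, cm/s
#' @slot phi run angle, degrees
#' @slot uLeft snout to left wall, mm
#' @slot uRight snout to right wall, mm
#' @slot trialId integer trial label per sample
#' @slot clamped logical, TRUE where the wall position was clamped at a bound
#' @slot trials list of the \code{CorridorTrial} objects that produced the
#'   series (may be empty for imported data)
#' @export
setClass("BehaviorTimeSeries",
  representation(
    t = "numeric", v = "numeric", phi = "numeric",
    uLeft = "numeric", uRight = "numeric", trialId = "integer",
    clamped = "logical", trials = "list"
  )
)

setValidity("BehaviorTimeSeries", function(object) {
  n <- length(object@t)
  msg <- character()
  for (s in c("v", "phi", "uLeft", "uRight", "trialId", "clamped"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("slot '%s' must have length %d", s, n))
  if (n > 1) {
    dt <- diff(object@t)
    if (any(dt <= 0)) msg <- c(msg, "t must be strictly increasing")
    if (diff(range(dt)) > 1e-6 * max(dt))
      msg <- c(msg, "t must be uniformly sampled")
  }
  if (length(msg)) msg else TRUE
})

#' Parametric ground-truth neuron model
#'
#' A rate model for one neuron as a function of contralateral wall distance,
#' wall movement direction, and run speed. Tuning families mirror those seen
#' in barrel cortex during wall tracking: monotonically increasing rate as
#' the wall approaches (logistic in distance), suppression as the wall
#' approaches, unimodal (Gaussian) preference for a particular distance,
#' multimodal (sum of Gaussians), or untuned. The full rate is
#' tuning(u) x directionFactor(sign of wall velocity) x speedFactor(v),
#' floored at zero.
#'
#' @slot kind one of "monotonic_decreasing" (rate decreases with distance,
#'   i.e. activated by wall approach), "monotonic_increasing" (suppressed by
#'   wall approach), "unimodal", "multimodal", "untuned"
#' @slot baseline baseline rate when the wall is out of reach, Hz
#' @slot amplitude tuning amplitude(s), Hz (one per component for multimodal)
#' @slot preferred preferred wall distance(s), mm
#' @slot width tuning width(s), mm
#' @slot directionGain multiplicative factor applied while the wall moves
#'   towards the animal (wall velocity < 0); 1 means direction-insensitive
#' @slot speedModel list(kind = "none"|"linear", coef); "linear" scales the
#'   rate by max(0, 1 + coef * v) with v in cm/s
#' @slot laterality "contra", "ipsi" or "both" — which wall drives the tuning
#' @export
setClass("NeuronModel",
  representation(
    kind = "character", baseline = "numeric", amplitude = "numeric",
    preferred = "numeric", width = "numeric", directionGain = "numeric",
    speedModel = "list", laterality = "character"
  ),
  prototype(
    kind = "untuned", baseline = 3, amplitude = numeric(),
    preferred = numeric(), width = numeric(), directionGain = 1,
    speedModel = list(kind = "none", coef = 0), laterality = "contra"
  )
)

setValidity("NeuronModel", function(object) {
  msg <- character()
  kinds <- c("monotonic_decreasing", "monotonic_increasing", "unimodal",
             "multimodal", "untuned")
  if (!object@kind %in% kinds)
    msg <- c(msg, paste("kind must be one of:", paste(kinds, collapse = ", ")))
  if (object@baseline < 0) msg <- c(msg, "baseline must be >= 0")
  if (object@kind != "untuned") {
    k <- length(object@amplitude)
    if (k < 1 || length(object@preferred) != k || length(object@width) != k)
      msg <- c(msg, "amplitude, preferred and width must have equal length >= 1")
    if (any(object@width <= 0)) msg <- c(msg, "width must be positive")
  }
  if (object@directionGain < 0) msg <- c(msg, "directionGain must be >= 0")
  if (!object@laterality %in% c("contra", "ipsi", "both"))
    msg <- c(msg, "laterality must be contra, ipsi or both")
  if (length(msg)) msg else TRUE
})

#' Constructor for NeuronModel
#'
#' @param kind tuning family (see \code{\linkS4class{NeuronModel}})
#' @param baseline out-of-reach rate, Hz
#' @param amplitude tuning amplitude(s), Hz
#' @param preferred preferred distance(s), mm
#' @param width tuning width(s), mm
#' @param directionGain factor applied while the wall approaches
#' @param speedModel list(kind, coef) speed scaling
#' @param laterality which wall drives the tuning
#' @return a \code{NeuronModel}
#' @examples
#' m <- neuronModel("unimodal", baseline = 2, amplitude = 10,
#'                  preferred = 15, width = 5)
#' neuronRate(m, u = 15, wallVelocity = 0, v = 20)  # baseline + amplitude
#' @export
neuronModel <- function(kind = "untuned", baseline = 3, amplitude = numeric(),
                        preferred = numeric(), width = numeric(),
                        directionGain = 1,
                        speedModel = list(kind = "none", coef = 0),
                        laterality = "contra") {
  new("NeuronModel", kind = kind, baseline = baseline, amplitude = amplitude,
      preferred = preferred, width = width, directionGain = directionGain,
      speedModel = speedModel, laterality = laterality)
}

#' Calcium indicator kernel parameters
#'
#' Parameters of the GCaMP-like forward model that maps spikes to a
#' fluorescence transient: a difference-of-exponentials kernel with a given
#' rise time, calibrated so that the response to a single isolated spike
#' peaks at \code{spikeAmplitude} dF/F and decays to half that peak
#' \code{halfDecay} seconds after the peak (GCaMP6s-like defaults: 200 ms
#' rise, 600 ms half-decay, 0.3 dF/F per spike).
#'
#' @slot riseTime kernel rise time constant, seconds
#' @slot halfDecay time from peak to half peak, seconds
#' @slot spikeAmplitude peak dF/F of an isolated single spike
#' @slot baselineF baseline fluorescence, arbitrary units
#' @slot noiseSd pixel noise SD for rendered movies, arbitrary units
#' @export
setClass("CalciumKernelParams",
  representation(
    riseTime = "numeric", halfDecay = "numeric", spikeAmplitude = "numeric",
    baselineF = "numeric", noiseSd = "numeric"
  ),
  prototype(riseTime = 0.2, halfDecay = 0.6, spikeAmplitude = 0.3,
            baselineF = 100, noiseSd = 0)
)

setValidity("CalciumKernelParams", function(object) {
  ok <- c(object@riseTime > 0, object@halfDecay > 0,
          object@spikeAmplitude > 0, object@baselineF > 0,
          object@noiseSd >= 0)
  if (all(ok)) TRUE else "riseTime, halfDecay, spikeAmplitude, baselineF must be positive and noiseSd >= 0"
})

#' Constructor for CalciumKernelParams
#' @param riseTime rise time, s
#' @param halfDecay post-peak half-decay time, s
#' @param spikeAmplitude single-spike peak dF/F
#' @param baselineF baseline fluorescence (a.u.)
#' @param noiseSd additive Gaussian pixel noise SD (a.u.)
#' @return a \code{CalciumKernelParams}
#' @export
calciumKernelParams <- function(riseTime = 0.2, halfDecay = 0.6,
                                spikeAmplitude = 0.3, baselineF = 100,
                                noiseSd = 0) {
  new("CalciumKernelParams", riseTime = riseTime, halfDecay = halfDecay,
      spikeAmplitude = spikeAmplitude, baselineF = baselineF,
      noiseSd = noiseSd)
}

#' Recording of one sorted unit
#'
#' Spike times plus the metadata the analyses carry through: laminar depth,
#' spike-width class and laterality of the recorded hemisphere relative to
#' the stimulated wall. Waveform quality control is accepted as input
#' metadata, not computed here.
#'
#' @slot spikes spike times, seconds, sorted, non-negative
#' @slot depth depth relative to the middle of layer 4, micrometers
#' @slot widthClass "regular" (> 450 us), "fast" (< 350 us) or "intermediate"
#' @slot laterality "contra" or "ipsi"
#' @slot unitId identifier
#' @export
setClass("UnitRecording",
  representation(
    spikes = "numeric", depth = "numeric", widthClass = "character",
    laterality = "character", unitId = "character"
  ),
  prototype(spikes = numeric(), depth = NA_real_, widthClass = "regular",
            laterality = "contra", unitId = "unit")
)

setValidity("UnitRecording", function(object) {
  msg <- character()
  if (length(object@spikes) && (is.unsorted(object@spikes) ||
                                any(object@spikes < 0)))
    msg <- c(msg, "spikes must be sorted and non-negative")
  if (!object@widthClass %in% c("regular", "fast", "intermediate"))
    msg <- c(msg, "widthClass must be regular, fast or intermediate")
  if (length(msg)) msg else TRUE
})

#' Constructor for UnitRecording
#' @param spikes spike times (s)
#' @param depth depth relative to middle of layer 4 (um)
#' @param widthClass spike width class
#' @param laterality hemisphere relative to stimulated wall
#' @param unitId identifier
#' @return a \code{UnitRecording}
#' @export
unitRecording <- function(spikes, depth = NA_real_, widthClass = "regular",
                          laterality = "contra", unitId = "unit") {
  new("UnitRecording", spikes = as.numeric(spikes), depth = depth,
      widthClass = widthClass, laterality = laterality, unitId = unitId)
}

#' Calcium imaging movie
#'
#' A fluorescence stack with frame times, stored as an H x W x T array.
#' Synthetic movies carry their ground truth (ROI masks, injected per-frame
#' rigid shifts, injected dF/F traces and spike times) in \code{groundTruth}.
#'
#' @slot frames numeric array, dim = c(height, width, nframes), non-negative
#' @slot frameTimes frame acquisition times, seconds, uniform
#' @slot plane imaging plane id
#' @slot groundTruth list; for synthetic movies: \code{masks} (list of logical
#'   matrices), \code{shifts} (T x 2 integer matrix, columns dy, dx),
#'   \code{roiDff} (T x R matrix), \code{neuropilDff}, \code{spikes} (list)
#' @export
setClass("CalciumMovie",
  representation(
    frames = "array", frameTimes = "numeric", plane = "integer",
    groundTruth = "list"
  ),
  prototype(plane = 1L, groundTruth = list())
)

setValidity("CalciumMovie", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3) msg <- c(msg, "frames must be an H x W x T array")
  else if (length(object@frameTimes) != d[3])
    msg <- c(msg, "frameTimes must match the number of frames")
  if (!all(is.finite(object@frames)))
    msg <- c(msg, "frame intensities must be finite")
  if (length(object@frameTimes) > 1) {
    dt <- diff(object@frameTimes)
    if (any(dt <= 0) || diff(range(dt)) > 1e-6 * max(dt))
      msg <- c(msg, "frameTimes must be strictly increasing and uniform")
  }
  if (length(msg)) msg else TRUE
})

#' A set of ROI masks with neuropil annuli
#'
#' @slot masks list of logical H x W matrices, one per ROI
#' @slot annuli list of logical H x W matrices (neuropil doughnuts), disjoint
#'   from every ROI mask
#' @slot labels character ROI labels
#' @export
setClass("RoiSet",
  representation(masks = "list", annuli = "list", labels = "character")
)

setValidity("RoiSet", function(object) {
  msg <- character()
  n <- length(object@masks)
  if (length(object@annuli) != n || length(object@labels) != n)
    msg <- c(msg, "masks, annuli and labels must have equal length")
  allRoi <- NULL
  for (m in object@masks) {
    if (!is.logical(m) || is.null(dim(m)))
      msg <- c(msg, "each mask must be a logical matrix")
    allRoi <- if (is.null(allRoi)) m else allRoi | m
  }
  if (n > 0 && !length(msg)) {
    for (i in seq_len(n)) {
      if (any(object@annuli[[i]] & allRoi)) {
        msg <- c(msg, "annuli must not overlap any ROI mask")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Wall-distance tuning curve
#'
#' Mean response (spike rate in Hz or dF/F) in 3-mm bins of wall distance,
#' averaged across qualifying trials, with the per-trial binned means kept
#' for significance testing. \code{baseline} is the mean response during
#' running while the wall is out of reach.
#'
#' @slot binCenters bin centers, mm, increasing
#' @slot mean mean response per bin (NA where fewer than minTrials trials)
#' @slot se standard error of the across-trial mean per bin
#' @slot nTrials number of trials contributing to each bin
#' @slot baseline out-of-reach response (scalar, may be NA)
#' @slot trialMeans trials x bins matrix of per-trial binned means
#' @slot unit "Hz" or "dff"
#' @export
setClass("TuningCurve",
  representation(
    binCenters = "numeric", mean = "numeric", se = "numeric",
    nTrials = "integer", baseline = "numeric", trialMeans = "matrix",
    unit = "character"
  ),
  prototype(baseline = NA_real_, unit = "Hz")
)

setValidity("TuningCurve", function(object) {
  msg <- character()
  nb <- length(object@binCenters)
  if (length(object@mean) != nb || length(object@se) != nb ||
      length(object@nTrials) != nb)
    msg <- c(msg, "mean, se and nTrials must match binCenters")
  if (nb > 1 && any(diff(object@binCenters) <= 0))
    msg <- c(msg, "binCenters must be increasing")
  if (any(object@se < 0, na.rm = TRUE)) msg <- c(msg, "se must be >= 0")
  if (any(object@nTrials < 0)) msg <- c(msg, "nTrials must be >= 0")
  if (ncol(object@trialMeans) && ncol(object@trialMeans) != nb)
    msg <- c(msg, "trialMeans must have one column per bin")
  if (length(msg)) msg else TRUE
})

#' Pixelwise wall-distance tuning map
#'
#' Per-pixel preferred wall distance and regression r-squared from the
#' binned-distance regression of each pixel's fluorescence time series.
#'
#' @slot preferred H x W matrix of preferred wall distance, mm
#' @slot r2 H x W matrix of r-squared values in [0, 1]
#' @slot binCenters distance bin centers used in the regression, mm
#' @export
setClass("PixelwiseMap",
  representation(preferred = "matrix", r2 = "matrix", binCenters = "numeric")
)

setValidity("PixelwiseMap", function(object) {
  msg <- character()
  if (!identical(dim(object@preferred), dim(object@r2)))
    msg <- c(msg, "preferred and r2 must have identical dimensions")
  r2 <- object@r2[is.finite(object@r2)]
  if (length(r2) && (min(r2) < -1e-9 || max(r2) > 1 + 1e-9))
    msg <- c(msg, "r2 must lie in [0, 1]")
  p <- object@preferred[is.finite(object@preferred)]
  if (length(p) && length(object@binCenters) &&
      (min(p) < min(object@binCenters) - 1e-9 ||
       max(p) > max(object@binCenters) + 1e-9))
    msg <- c(msg, "preferred distances must lie within the sampled bins")
  if (length(msg)) msg else TRUE
})
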