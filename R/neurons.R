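# Ground-truth synthetic neurons: parametric wall-distance tuning, Poisson
# spike generation, and the spike -> dF/F calcium forward model.

logistic <- function(z) 1 / (1 + exp(-z))

# Tuning component of the rate as a function of wall distance u (mm).
# All families return `baseline` far from the wall so that out-of-reach
# epochs measure the true baseline.
tuningRate <- function(model, u) {
  b <- model@baseline
  switch(model@kind,
    untuned = rep(b, length(u)),
    unimodal = b + model@amplitude[1] *
      exp(-(u - model@preferred[1])^2 / (2 * model@width[1]^2)),
    multimodal = {
      r <- rep(b, length(u))
      for (k in seq_along(model@amplitude))
        r <- r + model@amplitude[k] *
          exp(-(u - model@preferred[k])^2 / (2 * model@width[k]^2))
      r
    },
    # rate decreases with distance: activated as the wall approaches
    monotonic_decreasing = b + model@amplitude[1] *
      logistic((model@preferred[1] - u) / model@width[1]),
    # rate increases with distance towards baseline: suppressed by approach
    monotonic_increasing = b - model@amplitude[1] *
      logistic((model@preferred[1] - u) / model@width[1])
  )
}

#' Instantaneous firing rate of a neuron model
#'
#' rate = tuning(u) * directionFactor(sign of wall velocity) * speedFactor(v),
#' floored at 0. The direction factor is \code{directionGain} while the wall
#' moves towards the animal (wall velocity < 0) and 1 while it moves away or
#' is stationary. Out of reach (large u), every tuning family returns the
#' baseline, so the rate there is baseline x speed factor.
#'
#' @param model a \code{NeuronModel}
#' @param u wall distance, mm (vectorized)
#' @param wallVelocity signed wall velocity, mm/s (vectorized or scalar)
#' @param v run speed, cm/s (vectorized or scalar)
#' @return firing rate in Hz, same length as \code{u}
#' @export
neuronRate <- function(model, u, wallVelocity = 0, v = 20) {
  stopifnot(is(model, "NeuronModel"))
  if (any(u < 0)) stop("neuronRate: wall distance must be >= 0")
  r <- tuningRate(model, u)
  dirFactor <- ifelse(wallVelocity < 0, model@directionGain, 1)
  sp <- model@speedModel
  spFactor <- switch(sp$kind,
    none = 1,
    linear = pmax(0, 1 + sp$coef * v),
    stop("unknown speed model kind: ", sp$kind))
  pmax(0, r * dirFactor * spFactor)
}

#' Generate spikes from a rate series (inhomogeneous Poisson)
#'
#' Spike counts per clock bin are Poisson with mean rate * dt; spike times
#' are placed uniformly within their bin. Reproducible given the seed.
#'
#' @param rate rate series in Hz, sampled on a uniform clock
#' @param times clock sample times, seconds (bin starts)
#' @param seed integer seed
#' @return sorted spike times in seconds
#' @examples
#' tt <- seq(0, 100, by = 0.002)
#' s <- generateSpikes(rep(10, length(tt)), tt, seed = 1)
#' length(s) / 100  # close to 10 Hz
#' @export
generateSpikes <- function(rate, times, seed = 1L) {
  stopifnot(length(rate) == length(times), all(rate >= 0))
  n <- length(times)
  if (n < 2) return(numeric())
  dt <- times[2] - times[1]
  lam <- rate * dt
  if (any(lam > 1))
    warning("generateSpikes: rate * dt exceeds 1 in some bins; ",
            "use a finer clock (<= 2 ms recommended)")
  set.seed(seed)
  counts <- stats::rpois(n, lam)
  tot <- sum(counts)
  if (tot == 0) return(numeric())
  starts <- rep.int(times, counts)
  sort(starts + stats::runif(tot, 0, dt))
}

# Solve the decay constant of the kernel (1 - exp(-t/tauR)) * exp(-t/tauD)
# so that the time from the kernel peak to half of the peak equals
# `halfDecay`. The peak is at tStar = tauR * log(1 + tauD/tauR).
solveKernelDecay <- function(riseTime, halfDecay) {
  halfTime <- function(tauD) {
    tStar <- riseTime * log(1 + tauD / riseTime)
    peak <- (1 - exp(-tStar / riseTime)) * exp(-tStar / tauD)
    f <- function(t) (1 - exp(-t / riseTime)) * exp(-t / tauD) - peak / 2
    stats::uniroot(f, c(tStar, tStar + 20 * tauD), tol = 1e-12)$root - tStar
  }
  stats::uniroot(function(tauD) halfTime(tauD) - halfDecay,
                 c(halfDecay / 5, halfDecay * 5), tol = 1e-10)$root
}

#' Single-spike calcium kernel sampled on a clock
#'
#' Difference-of-exponentials kernel (1 - exp(-t/tauR)) * exp(-t/tauD),
#' with tauD solved numerically so that the post-peak half-decay time equals
#' \code{halfDecay}, and normalized so the continuous peak equals
#' \code{spikeAmplitude}.
#'
#' @param kernel a \code{CalciumKernelParams}
#' @param dt clock step, seconds
#' @param duration kernel support to sample, seconds (default covers the
#'   transient to well below 1 percent of peak)
#' @return numeric vector of kernel samples starting at t = 0
#' @export
calciumKernel <- function(kernel, dt, duration = NULL) {
  stopifnot(is(kernel, "CalciumKernelParams"))
  tauR <- kernel@riseTime
  tauD <- solveKernelDecay(tauR, kernel@halfDecay)
  if (is.null(duration)) duration <- tauR + 10 * tauD
  tt <- seq(0, duration, by = dt)
  tStar <- tauR * log(1 + tauD / tauR)
  peak <- (1 - exp(-tStar / tauR)) * exp(-tStar / tauD)
  kernel@spikeAmplitude * (1 - exp(-tt / tauR)) * exp(-tt / tauD) / peak
}

#' Convolve spikes with the calcium kernel to obtain dF/F
#'
#' Linear, time-invariant forward model: the dF/F trace is the superposition
#' of one kernel per spike. An isolated spike peaks at
#' \code{kernel@spikeAmplitude} dF/F (0.3 by default) and decays to half the
#' peak after \code{kernel@halfDecay} seconds (600 ms by default).
#'
#' @param spikes spike times, seconds
#' @param times output clock, seconds, uniform; should be much finer than
#'   the rise time
#' @param kernel a \code{CalciumKernelParams}
#' @return dF/F trace on \code{times}
#' @export
spikesToDff <- function(spikes, times, kernel = calciumKernelParams()) {
  n <- length(times)
  stopifnot(n >= 2)
  dt <- times[2] - times[1]
  counts <- tabulate(
    findInterval(spikes, c(times, times[n] + dt), left.open = FALSE,
                 rightmost.closed = FALSE),
    nbins = n)
  if (sum(counts) == 0) return(numeric(n) + 0)
  k <- calciumKernel(kernel, dt)
  out <- stats::convolve(counts, rev(k), type = "open")[seq_len(n)]
  # convolution round-off can leave tiny negative values
  out[abs(out) < 1e-12] <- 0
  out
}

#' Draw a population of ground-truth neuron models
#'
#' Counts per tuning family plus parameter distributions. Preferred
#' distances are drawn from a beta-shaped distribution over
#' \code{preferredRange}, biased towards small distances so that preferred
#' distances tile the sampled range the way barrel cortex populations tile
#' whisker reach.
#'
#' @param counts named integer vector/list, names from the tuning families
#'   (e.g. \code{c(unimodal = 10, untuned = 5)})
#' @param seed integer seed
#' @param preferredRange range of preferred distances, mm. The default
#'   (4 to 40 mm) matches the range of wall distances an open-loop session
#'   actually samples.
#' @param baselineRange range of baseline rates, Hz
#' @param amplitudeRange range of tuning amplitudes, Hz
#' @param widthRange range of tuning widths, mm
#' @param directionGainRange range of direction gains (log-uniform)
#' @param smallDistanceBias beta shape pair controlling the bias towards
#'   small preferred distances
#' @return list of \code{NeuronModel} objects
#' @export
makePopulation <- function(counts, seed = 1L,
                           preferredRange = c(4, 40),
                           baselineRange = c(1, 6),
                           amplitudeRange = c(5, 20),
                           widthRange = c(3, 8),
                           directionGainRange = c(1, 1),
                           smallDistanceBias = c(1.2, 2)) {
  counts <- unlist(counts)
  stopifnot(all(counts >= 0))
  kinds <- c("monotonic_decreasing", "monotonic_increasing", "unimodal",
             "multimodal", "untuned")
  if (!all(names(counts) %in% kinds))
    stop("makePopulation: unknown tuning kind(s): ",
         paste(setdiff(names(counts), kinds), collapse = ", "))
  set.seed(seed)
  drawPref <- function(k) {
    preferredRange[1] + diff(preferredRange) *
      stats::rbeta(k, smallDistanceBias[1], smallDistanceBias[2])
  }
  pop <- list()
  for (kind in names(counts)) {
    for (j in seq_len(counts[[kind]])) {
      ncomp <- if (kind == "multimodal") 2L else
        if (kind == "untuned") 0L else 1L
      baseline <- stats::runif(1, baselineRange[1], baselineRange[2])
      amp <- stats::runif(ncomp, amplitudeRange[1], amplitudeRange[2])
      if (kind == "monotonic_increasing")  # suppression cannot exceed baseline
        amp <- pmin(amp, baseline)
      dg <- exp(stats::runif(1, log(directionGainRange[1]),
                             log(directionGainRange[2])))
      pop[[length(pop) + 1L]] <- neuronModel(
        kind = kind, baseline = baseline, amplitude = amp,
        preferred = drawPref(ncomp),
        width = stats::runif(ncomp, widthRange[1], widthRange[2]),
        directionGain = dg)
    }
  }
  pop
}

#' Write / read spike times as CSV
#'
#' Long format with columns \code{unit_id} and \code{t}.
#'
#' @param spikes named list of spike-time vectors (one per unit)
#' @param path CSV file path
#' @return \code{writeSpikes} returns \code{path} invisibly;
#'   \code{readSpikes} returns a named list of spike-time vectors
#' @export
writeSpikes <- function(spikes, path) {
  ids <- names(spikes)
  if (is.null(ids)) ids <- sprintf("unit%03d", seq_along(spikes))
  df <- data.frame(
    unit_id = rep(ids, lengths(spikes)),
    t = unlist(spikes, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpikes
#' @export
readSpikes <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("unit_id", "t") %in% names(df)))
  split(df$t, factor(df$unit_id, levels = unique(df$unit_id)))
}
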