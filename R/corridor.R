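# Closed-loop corridor behavior: the wall-coupling rule, trial simulation,
# and the behavioral metrics (angle error, wall-distance bias, illusory
# photostimulus power, running mask).

#' Wall position update of the closed-loop corridor
#'
#' One step of the coupling rule Delta u = gamma * v * sin(epsilon) * dt,
#' with epsilon = phi - psi the angle error between the run angle and the
#' corridor turn angle. Speed is in cm/s and dt in seconds, so the raw
#' product is in cm; the return value is converted to mm, the unit of wall
#' distance. The caller clamps the resulting wall position to
#' [minWallDistance, 2*corridorHalfwidth - minWallDistance] so corridor
#' width is conserved.
#'
#' @param v run speed, cm/s
#' @param phi run angle, degrees
#' @param psi corridor turn angle, degrees
#' @param params a \code{CouplingParams}
#' @return wall displacement in mm (vectorized over v and phi)
#' @examples
#' p <- couplingParams(gain = 1, dt = 0.01)
#' updateWallPosition(20, 30, 0, p)  # 1 mm
#' @export
updateWallPosition <- function(v, phi, psi, params) {
  stopifnot(is(params, "CouplingParams"))
  if (!all(is.finite(v)) || !all(is.finite(phi)) || !all(is.finite(psi)))
    stop("updateWallPosition: non-finite input")
  eps <- (phi - psi) * pi / 180
  10 * params@gain * v * sin(eps) * params@dt  # cm -> mm
}

# Run-angle command of a tracking policy given lateral offset x (mm, positive
# towards the right wall). The proportional controller steers against the
# offset; noise enters as an angular random walk maintained by the caller.
policyAngle <- function(policy, psi, x, noise) {
  switch(policy@kind,
    ideal = psi,
    proportional = -policy@steeringGain * x,
    noisy = -policy@steeringGain * x + noise)
}

#' Simulate a single corridor trial
#'
#' Closed-loop (and illusory) trials integrate the coupling rule: the
#' animal's lateral offset x from the corridor center evolves as
#' dx = gamma * v * sin(phi - psi) * dt, with snout-to-wall distances
#' uLeft = halfwidth + x and uRight = halfwidth - x, clamped so neither wall
#' comes closer than \code{minWallDistance}; the trial ends when the
#' distance run reaches \code{trialLength}. Open-loop trials move the
#' contralateral (right) wall on a fixed schedule — move in from
#' \code{farDistance} to the hold distance, hold, move out — regardless of
#' locomotion, with the ipsilateral wall parked at \code{farDistance}.
#'
#' @param trial a \code{CorridorTrial}
#' @param policy a \code{TrackingPolicy} standing in for the animal
#' @param params a \code{CouplingParams}
#' @param seed integer seed; the simulation is deterministic given the seed
#' @return a \code{BehaviorTimeSeries} with a single trial id
#' @examples
#' tr <- simulateTrial(corridorTrial(turnAngle = 11.3),
#'                     trackingPolicy("ideal"), couplingParams(), seed = 1)
#' angleError(tr)  # 0 for the ideal policy
#' @export
simulateTrial <- function(trial, policy, params, seed = 1L) {
  stopifnot(is(trial, "CorridorTrial"), is(policy, "TrackingPolicy"),
            is(params, "CouplingParams"))
  validObject(trial); validObject(policy); validObject(params)
  set.seed(seed)
  dt <- params@dt
  spd <- if (policy@speedSd > 0)
    max(1, stats::rnorm(1, policy@speed, policy@speedSd)) else policy@speed
  if (trial@mode == "open_loop")
    return(simulateOpenLoopTrial(trial, spd, params))

  hw <- params@corridorHalfwidth
  xmax <- hw - params@minWallDistance
  nmax <- ceiling(params@trialLength / (spd * dt)) + 1L
  t <- v <- phi <- x <- clamped <- numeric(nmax)
  noise <- 0
  xi <- 0
  dist <- 0
  i <- 0L
  while (dist < params@trialLength) {
    i <- i + 1L
    if (policy@kind == "noisy")
      noise <- noise + stats::rnorm(1, 0, policy@noiseSd * sqrt(dt))
    t[i] <- (i - 1L) * dt
    v[i] <- spd
    phi[i] <- policyAngle(policy, trial@turnAngle, xi, noise)
    x[i] <- xi
    du <- updateWallPosition(v[i], phi[i], trial@turnAngle, params)
    xnew <- xi + du
    cl <- xnew > xmax || xnew < -xmax
    clamped[i] <- cl
    xi <- min(max(xnew, -xmax), xmax)
    dist <- dist + v[i] * dt
  }
  idx <- seq_len(i)
  new("BehaviorTimeSeries",
      t = t[idx], v = v[idx], phi = phi[idx],
      uLeft = hw + x[idx], uRight = hw - x[idx],
      trialId = rep(1L, i), clamped = as.logical(clamped[idx]),
      trials = list(trial))
}

simulateOpenLoopTrial <- function(trial, spd, params) {
  dt <- params@dt
  sch <- trial@schedule
  far <- trial@farDistance
  hold <- max(trial@openLoopDistance, params@minWallDistance)
  n <- max(2L, round(sum(sch) / dt))
  t <- (seq_len(n) - 1L) * dt
  u <- numeric(n)
  t1 <- sch[1]; t2 <- sch[1] + sch[2]; t3 <- sum(sch)
  seg1 <- t < t1
  seg2 <- t >= t1 & t < t2
  seg3 <- t >= t2
  u[seg1] <- if (sch[1] > 0) far + (hold - far) * t[seg1] / sch[1] else far
  u[seg2] <- hold
  u[seg3] <- if (sch[3] > 0) hold + (far - hold) * (t[seg3] - t2) / sch[3] else far
  new("BehaviorTimeSeries",
      t = t, v = rep(spd, n), phi = rep(0, n),
      uLeft = rep(far, n), uRight = u,
      trialId = rep(1L, n), clamped = rep(FALSE, n), trials = list(trial))
}

#' Simulate a session of consecutive trials
#'
#' Runs \code{simulateTrial} for each trial and concatenates the results on
#' a continuous clock with increasing trial ids. Each trial gets its own
#' sub-seed derived from \code{seed} so sessions are reproducible and
#' individual trials can be re-simulated in isolation.
#'
#' @param trials list of \code{CorridorTrial} objects
#' @param policy a \code{TrackingPolicy}
#' @param params a \code{CouplingParams}
#' @param seed integer seed
#' @return a \code{BehaviorTimeSeries} spanning all trials
#' @export
simulateSession <- function(trials, policy, params, seed = 1L) {
  stopifnot(length(trials) >= 1)
  parts <- vector("list", length(trials))
  t0 <- 0
  dt <- params@dt
  for (i in seq_along(trials)) {
    bt <- simulateTrial(trials[[i]], policy, params,
                        seed = seed * 1000L + i)
    bt@t <- bt@t + t0
    bt@trialId <- rep(as.integer(i), length(bt@t))
    t0 <- bt@t[length(bt@t)] + dt
    parts[[i]] <- bt
  }
  new("BehaviorTimeSeries",
      t = unlist(lapply(parts, function(b) b@t)),
      v = unlist(lapply(parts, function(b) b@v)),
      phi = unlist(lapply(parts, function(b) b@phi)),
      uLeft = unlist(lapply(parts, function(b) b@uLeft)),
      uRight = unlist(lapply(parts, function(b) b@uRight)),
      trialId = unlist(lapply(parts, function(b) b@trialId)),
      clamped = unlist(lapply(parts, function(b) b@clamped)),
      trials = trials)
}

#' Angle error of a trial
#'
#' The absolute difference between the run angle and the corridor turn
#' angle, evaluated at the end of the turn (the final sample of the trial's
#' trajectory). This is the behavioral performance metric for wall tracking.
#'
#' @param traj a \code{BehaviorTimeSeries} covering the turn
#' @param trial the \code{CorridorTrial}; defaults to the trial stored in
#'   \code{traj} when it contains exactly one
#' @return angle error in degrees, >= 0
#' @export
angleError <- function(traj, trial = NULL) {
  if (length(traj@t) == 0) stop("angleError: empty trajectory")
  if (is.null(trial)) {
    if (length(traj@trials) != 1)
      stop("angleError: supply `trial` for multi-trial series")
    trial <- traj@trials[[1]]
  }
  abs(traj@phi[length(traj@phi)] - trial@turnAngle)
}

#' Wall-distance bias under photostimulation
#'
#' Mean over stimulated trials of the end-of-trial wall distance, minus the
#' mean wall distance across unstimulated trials. Signed: positive values
#' mean the stimulation pushed the animal further from the (contralateral)
#' wall.
#'
#' @param stimTrials list of \code{BehaviorTimeSeries}, stimulated trials
#' @param unstimTrials list of \code{BehaviorTimeSeries}, unstimulated trials
#' @param side which wall distance to use ("right" or "left")
#' @return bias in mm
#' @export
wallDistanceBias <- function(stimTrials, unstimTrials,
                             side = c("right", "left")) {
  side <- match.arg(side)
  if (!length(stimTrials) || !length(unstimTrials))
    stop("wallDistanceBias: both trial groups must be non-empty")
  endDist <- vapply(stimTrials, function(b) {
    u <- wallDistance(b, side); u[length(u)]
  }, numeric(1))
  unstimMean <- mean(unlist(lapply(unstimTrials, wallDistance, side = side)))
  mean(endDist) - unstimMean
}

#' Laser power in the illusory corridor
#'
#' In illusory-corridor trials the walls are replaced by closed-loop
#' photostimulation of layer 4: laser power scales linearly with the
#' animal's distance from the corridor center, from 0 mW at the center to
#' \code{maxPower} at the corridor edge, and only the hemisphere opposite
#' to the offset side is stimulated (right of center stimulates the left
#' hemisphere, and vice versa).
#'
#' @param lateralOffset offset from the corridor center, mm; positive =
#'   right of center
#' @param params a \code{CouplingParams} (supplies the corridor halfwidth)
#' @param maxPower power at the corridor edge, mW (default 4.5)
#' @return named numeric c(left, right) hemisphere powers in mW
#' @examples
#' illusoryPower(0, couplingParams())            # c(0, 0)
#' illusoryPower(19, couplingParams())           # left hemisphere at 4.5 mW
#' @export
illusoryPower <- function(lateralOffset, params, maxPower = 4.5) {
  stopifnot(is(params, "CouplingParams"), length(lateralOffset) == 1)
  hw <- params@corridorHalfwidth
  if (abs(lateralOffset) > hw) {
    warning("illusoryPower: offset beyond the corridor edge, clamping")
    lateralOffset <- sign(lateralOffset) * hw
  }
  p <- maxPower * abs(lateralOffset) / hw
  if (lateralOffset > 0) c(left = p, right = 0)
  else if (lateralOffset < 0) c(left = 0, right = p)
  else c(left = 0, right = 0)
}

#' Running mask
#'
#' TRUE where the run speed strictly exceeds the threshold. All analyses of
#' neural data are restricted to running periods (speed > 3 cm/s), when the
#' animal is actively whisking against the walls.
#'
#' @param v run speed series, cm/s (or a \code{BehaviorTimeSeries})
#' @param threshold speed threshold, cm/s (default 3); strict inequality
#' @return logical vector
#' @export
runningMask <- function(v, threshold = 3) {
  if (is(v, "BehaviorTimeSeries")) v <- v@v
  v > threshold
}

#' Write / read a behavioral time series as CSV
#'
#' Columns: t, v, phi, u_left, u_right, trial_id.
#'
#' @param x a \code{BehaviorTimeSeries}
#' @param path CSV file path
#' @return \code{writeBehavior} returns \code{path} invisibly;
#'   \code{readBehavior} returns a \code{BehaviorTimeSeries}
#' @export
writeBehavior <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBehavior
#' @export
readBehavior <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "v", "phi", "u_left", "u_right", "trial_id")
  if (!all(need %in% names(df)))
    stop("readBehavior: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  new("BehaviorTimeSeries", t = df$t, v = df$v, phi = df$phi,
      uLeft = df$u_left, uRight = df$u_right,
      trialId = as.integer(df$trial_id),
      clamped = rep(FALSE, nrow(df)), trials = list())
}
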