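#' @include AllClasses.R
NULL

#' Construct band-cell population parameters
#'
#' Defaults are the model's standard parameter set: six populations with
#' baseline phase offsets and preferred headings both at
#' `[0, 60, ..., 300]` degrees, baseline angular frequency `2*pi*6` rad/s,
#' grid-spacing scale `beta = 0.002` (use `0.00385` for the straight-line
#' two-field configuration), sigmoid slope 4 and inflection 1, and input
#' scaling 100.
#'
#' The printed model update mixes a phase and a rate term; here the
#' velocity modulation is integrated as an instantaneous angular frequency
#' `omega_b + gain*beta*s(t)*cos(heading - preferred)`, so each
#' population's accumulated phase, relative to its baseline, equals
#' `gain*beta` times the displacement projected on its preferred
#' direction. The dimensionless `gain` calibrates the unit convention of
#' `beta`; the default (30) is fixed once so that `beta = 0.00385` yields
#' two discrete firing fields across a 200 cm straight transect.
#'
#' @param phiOffset baseline phase offsets in degrees.
#' @param phiPreferred preferred headings in degrees.
#' @param omegaB baseline angular frequency in rad/s.
#' @param beta grid-spacing scale factor.
#' @param gain dimensionless phase gain.
#' @param a,T sigmoid slope and inflection point.
#' @param GI input scaling constant.
#' @return a [BandParams-class].
#' @export
bandParams <- function(phiOffset = seq(0, 300, by = 60),
                       phiPreferred = seq(0, 300, by = 60),
                       omegaB = 2 * pi * 6, beta = 0.002, gain = 30,
                       a = 4, T = 1, GI = 100) {
  new("BandParams", phiOffset = phiOffset, phiPreferred = phiPreferred,
      omegaB = omegaB, beta = beta, gain = gain, a = a, T = T, GI = GI)
}

#' Signed angular difference
#'
#' Wrapped signed difference `a - b` in degrees, in `(-180, 180]`.
#'
#' @param a,b angles in degrees.
#' @return the wrapped difference in degrees.
#' @examples
#' angularDifference(350, 10)   # -20
#' @export
angularDifference <- function(a, b) {
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Sigmoid activation used to half-wave rectify band-cell output
#'
#' `S(x) = 1/(1 + exp(-a*(x - T))) - 1/(1 + exp(a*T))`; the subtracted
#' constant makes `S(0) = 0`, so a silent population produces zero output.
#'
#' @param x input (dimensionless).
#' @param a sigmoid slope (default 4).
#' @param T sigmoid inflection point (default 1).
#' @return the rectified activation.
#' @examples
#' sigmoidActivation(0)   # 0
#' sigmoidActivation(2)   # ~0.964
#' @export
sigmoidActivation <- function(x, a = 4, T = 1) {
  1 / (1 + exp(-a * (x - T))) - 1 / (1 + exp(a * T))
}

#' Head-direction gate
#'
#' Heaviside gate on the absolute heading difference: 1 when the current
#' heading is within 90 degrees (inclusive) of the preferred heading, else
#' 0.
#'
#' @param current current heading in degrees.
#' @param preferred preferred heading in degrees.
#' @return 0 or 1 (vectorized).
#' @examples
#' directionGate(90, 0)    # 1 (boundary inclusive)
#' directionGate(91, 0)    # 0
#' @export
directionGate <- function(current, preferred) {
  as.numeric(abs(angularDifference(current, preferred)) <= 90)
}

#' Accumulated VCO phases along a trajectory
#'
#' Integrates each population's instantaneous angular frequency
#' `omega_b + gain*beta*speed(t)*cos(heading(t) - preferred)` over the
#' trajectory. Phases are initialized at the population's own baseline
#' offset, so every oscillator starts phase-aligned with its baseline and
#' the trajectory origin is a constructive-interference point.
#'
#' @param traj a [Trajectory-class].
#' @param params a [BandParams-class].
#' @return numeric matrix (samples x populations) of accumulated phases in
#'   radians.
#' @export
bandPhases <- function(traj, params) {
  n <- length(traj@t)
  pref <- params@phiPreferred * pi / 180
  hd <- traj@heading * pi / 180
  theta <- matrix(0, n, length(pref))
  for (k in seq_along(pref)) {
    omega <- params@omegaB +
      params@gain * params@beta * traj@speed * cos(hd - pref[k])
    ## increment over [t_i, t_{i+1}) uses the kinematics at sample i
    theta[, k] <- params@phiOffset[k] * pi / 180 +
      c(0, cumsum(omega[-n] * traj@dt))
  }
  theta
}

#' Band-cell population outputs along a trajectory
#'
#' Evaluates the rectified, direction-gated output of every population:
#' `HD_n(t) = S(cos(omega_b*t + phi_offset_n) + cos(theta_n(t))) * H_n(t)`
#' where `theta_n` is the accumulated VCO phase ([bandPhases()]) and `H_n`
#' gates on the instantaneous heading ([directionGate()]).
#'
#' @param traj a [Trajectory-class].
#' @param params a [BandParams-class].
#' @param gate if `FALSE`, the direction gate is omitted (useful to
#'   inspect the full band pattern of a population over the arena).
#' @return numeric matrix (samples x populations) of non-negative outputs.
#' @export
bandActivity <- function(traj, params, gate = TRUE) {
  theta <- bandPhases(traj, params)
  out <- matrix(0, nrow(theta), ncol(theta))
  for (k in seq_len(ncol(theta))) {
    base <- cos(params@omegaB * traj@t + params@phiOffset[k] * pi / 180)
    ## the sigmoid's small negative tail (for strongly destructive
    ## interference) is clipped: population output is a firing rate
    out[, k] <- pmax(sigmoidActivation(base + cos(theta[, k]),
                                       a = params@a, T = params@T), 0)
    if (gate)
      out[, k] <- out[, k] *
        directionGate(traj@heading, params@phiPreferred[k])
  }
  out
}

#' Summed grid-cell input current
#'
#' `I(t) = sum_n G_I * HD_n(t)`; non-negative because every population
#' output is rectified.
#'
#' @param activity matrix of population outputs from [bandActivity()].
#' @param GI input scaling constant (default 100).
#' @return numeric vector of input current.
#' @export
summedInput <- function(activity, GI = 100) {
  GI * rowSums(activity)
}
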