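#' @include AllClasses.R
NULL

#' Construct grid-cell membrane parameters
#'
#' Defaults: leak time constant 0.1 s, resting potential -67 mV, spiking
#' threshold -56 mV, time step 0.002 s.
#'
#' @param tauGL membrane leak time constant in seconds.
#' @param EL resting potential in mV.
#' @param Vt spiking threshold in mV.
#' @param dt integration time step in seconds.
#' @return a [CellParams-class].
#' @export
cellParams <- function(tauGL = 0.1, EL = -67, Vt = -56, dt = 0.002) {
  new("CellParams", tauGL = tauGL, EL = EL, Vt = Vt, dt = dt)
}

#' One explicit Euler step of the membrane equation
#'
#' `Vm(t+dt) = Vm(t) + [I(t) - (Vm(t) - E_L)/tau_GL] * dt`. There is no
#' spike reset and no refractory period.
#'
#' @param Vm membrane potential in mV.
#' @param I input current.
#' @param params a [CellParams-class].
#' @return the updated membrane potential.
#' @export
stepMembrane <- function(Vm, I, params) {
  if (params@tauGL < params@dt)
    warning("tauGL < dt: explicit Euler update is unstable")
  Vm + (I - (Vm - params@EL) / params@tauGL) * params@dt
}

#' Simulate the leaky integrate-and-fire grid cell along a trajectory
#'
#' Computes the six band-cell population outputs, sums and scales them
#' into the input current, and integrates the membrane equation with
#' explicit Euler from `Vm(0) = E_L`. Every sample with `Vm > Vt` is
#' marked as a spike sample (no reset, so several spike samples can occur
#' within one theta cycle).
#'
#' @param traj a [Trajectory-class] with `traj@dt == params@dt`.
#' @param bands a [BandParams-class] (default [bandParams()]).
#' @param params a [CellParams-class] (default [cellParams()]).
#' @return a [MembraneTrace-class].
#' @examples
#' tr <- straightLineTrajectory(c(-100, 0), c(100, 0), speed = 10)
#' trace <- simulateGridCell(tr, bandParams(beta = 0.00385))
#' sum(spikeSamples(trace))
#' @export
simulateGridCell <- function(traj, bands = bandParams(),
                             params = cellParams()) {
  if (abs(traj@dt - params@dt) > 1e-9)
    stop("trajectory and cell parameters use different time steps")
  if (params@tauGL < params@dt)
    warning("tauGL < dt: explicit Euler update is unstable")
  I <- summedInput(bandActivity(traj, bands), GI = bands@GI)
  if (any(!is.finite(I)))
    stop("non-finite input current at step ", which(!is.finite(I))[1L])
  n <- length(I)
  dt <- params@dt
  decay <- 1 - dt / params@tauGL
  ## linear recurrence Vm[i] = decay*Vm[i-1] + I[i-1]*dt + EL*dt/tau,
  ## evaluated with a recursive filter
  drive <- I[-n] * dt + params@EL * dt / params@tauGL
  Vm <- c(params@EL,
          stats::filter(drive, decay, method = "recursive",
                        init = params@EL))
  Vm <- as.numeric(Vm)
  new("MembraneTrace", t = traj@t, Vm = Vm, I = I, spike = Vm > params@Vt,
      dt = dt, cellParams = params, bandParams = bands)
}

#' Spiking threshold adapted to the membrane time constant
#'
#' For the leak time constant sweep the threshold is co-varied with
#' `tau_GL`: the listed pairing maps `tau_GL = 10, 20, ..., 100` ms to
#' `V_t = -65, -64, ..., -56` mV (1 mV per 10 ms), with linear
#' interpolation between listed values. This keeps spike counts and grid
#' fields comparable as the integration window grows.
#'
#' @param tauMs leak time constant in milliseconds, in `[10, 100]`.
#' @return the adapted threshold in mV.
#' @examples
#' thresholdForTau(10)    # -65
#' thresholdForTau(55)    # -60.5
#' @export
thresholdForTau <- function(tauMs) {
  stopifnot(all(is.finite(tauMs)))
  if (any(tauMs < 10 | tauMs > 100))
    stop("'tauMs' must lie in [10, 100] ms")
  -65 + (tauMs - 10) / 10
}
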