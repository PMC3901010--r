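#' @import methods
NULL

#' Trajectory of a simulated or recorded animal
#'
#' Time-stamped positions in a square arena together with the per-step
#' movement vector, running speed and heading that drive the band-cell
#' oscillators. Time is uniformly sampled with step `dt` (seconds),
#' positions are in cm, speeds in cm/s, headings in degrees in `[0, 360)`.
#'
#' @slot t numeric, sample times in seconds (uniform, strictly increasing).
#' @slot x,y numeric, position in cm.
#' @slot dx,dy numeric, movement per step in cm (`dx[i] = x[i+1] - x[i]`,
#'   last element carried forward).
#' @slot speed numeric, running speed `sqrt(dx^2 + dy^2)/dt` in cm/s.
#' @slot heading numeric, movement direction `atan2(dy, dx)` in degrees,
#'   wrapped to `[0, 360)`; carried forward over zero-speed samples.
#' @slot dt numeric(1), time step in seconds.
#' @slot arenaHalfWidth numeric(1), half-width of the square arena in cm
#'   (`NA` for unconstrained trajectories such as straight lines).
#'
#' @seealso [randomWalk()], [straightLineTrajectory()], [readTrajectory()]
#' @export
setClass("Trajectory",
  representation(
    t = "numeric", x = "numeric", y = "numeric",
    dx = "numeric", dy = "numeric",
    speed = "numeric", heading = "numeric",
    dt = "numeric", arenaHalfWidth = "numeric"
  )
)

setValidity("Trajectory", function(object) {
  n <- length(object@t)
  msg <- character()
  lens <- vapply(c("x", "y", "dx", "dy", "speed", "heading"),
                 function(s) length(slot(object, s)), integer(1))
  if (any(lens != n))
    msg <- c(msg, "all series must have the same length as 't'")
  if (n >= 2) {
    steps <- diff(object@t)
    if (any(steps <= 0) ||
        max(abs(steps - object@dt)) > 1e-6 * object@dt)
      msg <- c(msg, "'t' must increase in constant steps of 'dt'")
  }
  if (any(object@speed < 0)) msg <- c(msg, "speed must be non-negative")
  if (any(object@heading < 0 | object@heading >= 360))
    msg <- c(msg, "heading must lie in [0, 360)")
  if (!is.na(object@arenaHalfWidth)) {
    w <- object@arenaHalfWidth + 1e-9
    if (any(abs(object@x) > w) || any(abs(object@y) > w))
      msg <- c(msg, "positions must lie within the arena bounds")
  }
  if (length(msg)) msg else TRUE
})

#' Head-direction band-cell population parameters
#'
#' Parameters of the six head-direction selective band-cell populations that
#' act as velocity-controlled oscillators (VCOs). Each population receives a
#' baseline theta oscillation at angular frequency `omegaB` with its own
#' phase offset, accumulates VCO phase at a speed- and heading-dependent
#' rate, and emits the sigmoid-rectified sum of the two oscillations, gated
#' to zero when the current heading differs from the population's preferred
#' heading by more than 90 degrees.
#'
#' @slot phiOffset numeric(6), baseline phase offsets in degrees.
#' @slot phiPreferred numeric(6), preferred headings in degrees.
#' @slot omegaB numeric(1), baseline angular frequency in rad/s.
#' @slot beta numeric(1), grid-spacing scale factor.
#' @slot gain numeric(1), dimensionless phase-gain calibration applied
#'   multiplicatively with `beta`; the spatial band wavelength of each
#'   population is `2*pi/(gain*beta)` cm.
#' @slot a,T numeric(1), sigmoid slope and inflection point.
#' @slot GI numeric(1), input scaling constant.
#'
#' @seealso [bandParams()], [bandActivity()]
#' @export
setClass("BandParams",
  representation(
    phiOffset = "numeric", phiPreferred = "numeric",
    omegaB = "numeric", beta = "numeric", gain = "numeric",
    a = "numeric", T = "numeric", GI = "numeric"
  )
)

setValidity("BandParams", function(object) {
  msg <- character()
  if (length(object@phiOffset) != length(object@phiPreferred))
    msg <- c(msg, "'phiOffset' and 'phiPreferred' must have equal length")
  for (s in c("omegaB", "beta", "gain", "a", "T", "GI"))
    if (length(slot(object, s)) != 1 || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
  if (length(object@beta) == 1 && object@beta < 0)
    msg <- c(msg, "'beta' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Leaky integrate-and-fire grid cell parameters
#'
#' @slot tauGL numeric(1), membrane leak time constant in seconds
#'   (`G_L = 1/tauGL`).
#' @slot EL numeric(1), resting potential in mV.
#' @slot Vt numeric(1), spiking threshold in mV.
#' @slot dt numeric(1), integration time step in seconds.
#'
#' @seealso [cellParams()], [simulateGridCell()]
#' @export
setClass("CellParams",
  representation(tauGL = "numeric", EL = "numeric",
                 Vt = "numeric", dt = "numeric")
)

setValidity("CellParams", function(object) {
  msg <- character()
  if (object@tauGL <= 0) msg <- c(msg, "'tauGL' must be positive")
  if (object@dt <= 0) msg <- c(msg, "'dt' must be positive")
  if (object@Vt <= object@EL) msg <- c(msg, "'Vt' must exceed 'EL'")
  if (length(msg)) msg else TRUE
})

#' Membrane potential trace of the simulated grid cell
#'
#' Result of Euler integration of the leaky integrate-and-fire equation
#' driven by the summed, rectified band-cell input. There is no spike reset
#' or refractory period: every sample with `Vm > Vt` is marked as a spike
#' sample, so several spike samples may fall within one theta cycle.
#'
#' @slot t numeric, sample times in seconds.
#' @slot Vm numeric, membrane potential in mV.
#' @slot I numeric, summed input current (model units).
#' @slot spike logical, per-sample threshold crossings (`Vm > Vt`).
#' @slot dt numeric(1), time step in seconds.
#' @slot cellParams the [CellParams-class] used for the simulation.
#' @slot bandParams the [BandParams-class] used for the simulation.
#'
#' @seealso [simulateGridCell()], [amplitudeSeries()],
#'   [subsampleSpikesToThetaPeaks()]
#' @export
setClass("MembraneTrace",
  representation(
    t = "numeric", Vm = "numeric", I = "numeric", spike = "logical",
    dt = "numeric", cellParams = "CellParams", bandParams = "BandParams"
  )
)

setValidity("MembraneTrace", function(object) {
  n <- length(object@t)
  if (length(object@Vm) != n || length(object@I) != n ||
      length(object@spike) != n)
    return("'t', 'Vm', 'I' and 'spike' must have equal length")
  TRUE
})

#' Occupancy-normalized spatial firing-rate map
#'
#' @slot rate matrix of firing rates in Hz (rows index x bins, columns y
#'   bins); bins with insufficient occupancy are `NA`, not zero.
#' @slot occupancy matrix of per-bin dwell times in seconds.
#' @slot count matrix of per-bin spike-sample counts.
#' @slot xCenters,yCenters numeric, bin-center coordinates in cm.
#' @slot binSize numeric(1), bin side length in cm.
#'
#' @seealso [rateMap()], [gridnessScore()]
#' @export
setClass("RateMap",
  representation(
    rate = "matrix", occupancy = "matrix", count = "matrix",
    xCenters = "numeric", yCenters = "numeric", binSize = "numeric"
  )
)

#' In-field / out-of-field classification of the arena
#'
#' Per-bin empirical percentiles of the observed firing rate against a
#' circular spike-shuffle null, and the derived three-way labelling: bins in
#' a 3x3 block all above the 85th percentile (plus adjacent bins above the
#' 70th) are in-field; bins in a 2x2 block all at or below the 5th
#' percentile are out-of-field; everything else is unassigned.
#'
#' @slot percentile matrix of per-bin `1 - P` values (`NA` where occupancy
#'   was insufficient).
#' @slot label character matrix with values `"in_field"`, `"out_of_field"`,
#'   `"unassigned"`.
#' @slot sampleLabel character, the label inherited by every trajectory
#'   sample from its containing bin.
#' @slot xCenters,yCenters numeric, bin centers in cm.
#' @slot binSize numeric(1), bin side in cm (5 by default).
#' @slot nShuffles numeric(1), number of circular shuffles used.
#'
#' @seealso [shuffleNull()], [classifyFields()]
#' @export
setClass("FieldClassification",
  representation(
    percentile = "matrix", label = "matrix", sampleLabel = "character",
    xCenters = "numeric", yCenters = "numeric",
    binSize = "numeric", nShuffles = "numeric"
  )
)

setValidity("FieldClassification", function(object) {
  ok <- all(object@label %in% c("in_field", "out_of_field", "unassigned"))
  if (!ok) return("labels must be in_field/out_of_field/unassigned")
  TRUE
})

#' DC-shift and theta-envelope decomposition of a membrane trace
#'
#' The 0.1-3 Hz component of the membrane potential with its out-of-field
#' mean subtracted (so the out-of-field mean of `dcShift` is zero by
#' construction), and the Hilbert envelope of the 5-10 Hz component.
#'
#' @slot dcShift numeric, DC-shift series in mV.
#' @slot mpoEnvelope numeric, theta-band envelope in mV (non-negative).
#' @slot t numeric, sample times in seconds.
#' @slot dt numeric(1), time step in seconds.
#'
#' @seealso [amplitudeSeries()], [deltaAmplitudes()]
#' @export
setClass("AmplitudeSeries",
  representation(dcShift = "numeric", mpoEnvelope = "numeric",
                 t = "numeric", dt = "numeric")
)

setValidity("AmplitudeSeries", function(object) {
  if (length(object@dcShift) != length(object@mpoEnvelope))
    return("'dcShift' and 'mpoEnvelope' must have equal length")
  if (any(object@mpoEnvelope < -1e-9))
    return("'mpoEnvelope' must be non-negative")
  TRUE
})

#' Theta phase-precession analysis result
#'
#' Per-spike pairs of a linear progress variable (pass index in radians, or
#' position in cm for straight-line runs) and the baseline theta phase at
#' the spike, together with the Kempter circular-linear correlation.
#'
#' @slot spikeTime numeric, retained spike times in seconds.
#' @slot linear numeric, pass index (rad) or position (cm) per spike.
#' @slot phase numeric, baseline theta phase per spike in `(-pi, pi]`.
#' @slot rho numeric(1), circular-linear correlation (`NA` if under 5
#'   spikes).
#' @slot p numeric(1), p-value of `rho`.
#' @slot slope numeric(1), fitted phase slope in rad per unit of `linear`.
#' @slot mode character(1), `"pass_index"` or `"position"`.
#'
#' @seealso [precessionAnalysis()], [circularLinearCorr()]
#' @export
setClass("PrecessionResult",
  representation(
    spikeTime = "numeric", linear = "numeric", phase = "numeric",
    rho = "numeric", p = "numeric", slope = "numeric", mode = "character"
  )
)
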