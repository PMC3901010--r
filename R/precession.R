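#' @include AllClasses.R
NULL

#' Instantaneous baseline theta phase
#'
#' Wrapped phase of the baseline oscillation `cos(omega_b*t + offset)`;
#' by convention precession is measured against the baseline received by
#' the 0-degree head-direction population (offset 0).
#'
#' @param t times in seconds.
#' @param omegaB baseline angular frequency in rad/s (default `2*pi*6`).
#' @param offset baseline phase offset in radians (default 0).
#' @return phases in `(-pi, pi]`.
#' @export
baselineThetaPhase <- function(t, omegaB = 2 * pi * 6, offset = 0) {
  wrapPhase(omegaB * t + offset)
}

## wrap radians into (-pi, pi]
wrapPhase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Subsample spike samples to one spike per membrane theta cycle
#'
#' Cycles of the 5-10 Hz membrane-potential component are delimited by
#' its troughs; within each cycle the above-threshold sample closest in
#' time to the cycle's peak is retained and all other spike samples are
#' discarded. This sparse series drives the phase-precession and
#' firing-rate analyses.
#'
#' @param trace a [MembraneTrace-class].
#' @param mpoTheta optional precomputed 5-10 Hz component of `Vm`;
#'   computed from the trace when omitted.
#' @return integer vector of retained sample indices (use
#'   `trace@t[idx]` for spike times).
#' @export
subsampleSpikesToThetaPeaks <- function(trace, mpoTheta = NULL) {
  if (!any(trace@spike)) return(integer())
  if (is.null(mpoTheta))
    mpoTheta <- bandpassZeroPhase(trace@Vm - mean(trace@Vm), 5, 10,
                                  1 / trace@dt)
  n <- length(mpoTheta)
  i <- 2:(n - 1L)
  troughs <- i[mpoTheta[i] < mpoTheta[i - 1L] &
               mpoTheta[i] <= mpoTheta[i + 1L]]
  bounds <- c(1L, troughs, n)
  spikeIdx <- which(trace@spike)
  cyc <- pmin(findInterval(spikeIdx, bounds), length(bounds) - 1L)
  keep <- vapply(split(spikeIdx, cyc), function(ss) {
    lo <- bounds[cyc[match(ss[1L], spikeIdx)]]
    hi <- bounds[cyc[match(ss[1L], spikeIdx)] + 1L]
    seg <- lo:hi
    peak <- seg[which.max(mpoTheta[seg])]
    ss[which.min(abs(ss - peak))]
  }, integer(1))
  sort(unname(keep))
}

#' Pass index: analytic phase of the field-index series
#'
#' The mean-centered field-index series is transformed to its analytic
#' signal; the instantaneous angle sweeps from about `-pi` through 0 (at
#' the field center) to `+pi` across a complete pass through a firing
#' field.
#'
#' @param fieldIndex numeric series in `[0, 1]` from
#'   [fieldIndexSeries()].
#' @return phase series in `(-pi, pi]`.
#' @export
passIndex <- function(fieldIndex) {
  if (stats::sd(fieldIndex) == 0)
    stop("field-index series is constant; pass index undefined")
  Arg(analyticSignal(fieldIndex - mean(fieldIndex)))
}

#' Kempter circular-linear correlation
#'
#' Fits the slope `a` maximizing the resultant length of
#' `phase - 2*pi*a*x`, then computes the circular-circular correlation
#' `rho` between the measured phases and the fitted linear phases, with
#' its large-sample p-value.
#'
#' @param phase angles in radians.
#' @param x linear covariate.
#' @param slopeRange search interval for the slope `a` in cycles per unit
#'   of `x` (default `c(-2, 2)`).
#' @return list with `rho`, `p`, `slope` (rad per unit of `x`) and `n`.
#' @export
circularLinearCorr <- function(phase, x, slopeRange = c(-2, 2)) {
  n <- length(phase)
  stopifnot(length(x) == n)
  if (n < 5) stop("need at least 5 observations")
  if (stats::sd(x) == 0) stop("degenerate linear variable")
  resultant <- function(a)
    sqrt(mean(cos(phase - 2 * pi * a * x))^2 +
         mean(sin(phase - 2 * pi * a * x))^2)
  grid <- seq(slopeRange[1L], slopeRange[2L], length.out = 512L)
  a0 <- grid[which.max(vapply(grid, resultant, numeric(1)))]
  step <- grid[2L] - grid[1L]
  opt <- stats::optimize(resultant, c(a0 - step, a0 + step),
                         maximum = TRUE)
  a <- opt$maximum
  ## circular transform of x uses |a| so that the sign of rho carries the
  ## direction of the phase-position relation (negative = precession)
  phi <- wrapPhase(2 * pi * abs(a) * x)
  mphase <- circularMean(phase)
  mphi <- circularMean(phi)
  sp <- sin(phase - mphase)
  sx <- sin(phi - mphi)
  denom <- sqrt(sum(sp^2) * sum(sx^2))
  ## degenerate (constant) phase sets carry no association
  rho <- if (denom < n * 1e-10) 0 else sum(sp * sx) / denom
  lam22 <- mean(sp^2 * sx^2)
  lam20 <- mean(sp^2)
  lam02 <- mean(sx^2)
  z <- if (lam22 > 0) rho * sqrt(n * lam20 * lam02 / lam22) else 0
  p <- 2 * stats::pnorm(-abs(z))
  list(rho = rho, p = p, slope = 2 * pi * a, n = n)
}

circularMean <- function(x) atan2(mean(sin(x)), mean(cos(x)))

#' Theta phase-precession analysis
#'
#' Subsamples spikes to one per membrane theta cycle, computes the
#' baseline theta phase at each retained spike, pairs it with either the
#' pass index (random-walk mode) or position along the path
#' (straight-line mode), and reports the Kempter circular-linear
#' correlation. For `mode = "pass_index"` only in-field spikes (field
#' index above `minFieldIndex`) enter the correlation.
#'
#' @param trace a [MembraneTrace-class].
#' @param traj the [Trajectory-class] the trace was simulated on.
#' @param mode `"pass_index"` or `"position"`.
#' @param map optional precomputed [fieldIndexMap()] result.
#' @param minFieldIndex field-index cutoff defining in-field spikes for
#'   pass-index mode (default 0.3).
#' @param slopeRange slope search range for [circularLinearCorr()],
#'   cycles per unit of the linear variable.
#' @return a [PrecessionResult-class]; `rho` is `NA` with `p = NA` when
#'   fewer than 5 spikes survive.
#' @export
precessionAnalysis <- function(trace, traj,
                               mode = c("pass_index", "position"),
                               map = NULL, minFieldIndex = 0.3,
                               slopeRange = NULL) {
  mode <- match.arg(mode)
  idx <- subsampleSpikesToThetaPeaks(trace)
  phase <- baselineThetaPhase(trace@t[idx],
                              omegaB = trace@bandParams@omegaB)
  if (mode == "pass_index") {
    if (is.null(map)) map <- fieldIndexMap(traj, trace@spike)
    fi <- fieldIndexSeries(traj, map)
    pass <- passIndex(fi)
    keep <- fi[idx] >= minFieldIndex
    idx <- idx[keep]
    phase <- phase[keep]
    lin <- pass[idx]
    if (is.null(slopeRange)) slopeRange <- c(-2, 2) / (2 * pi)
  } else {
    lin <- traj@x[idx]
    if (is.null(slopeRange)) slopeRange <- c(-0.2, 0.2)
  }
  if (length(idx) < 5) {
    return(new("PrecessionResult", spikeTime = trace@t[idx],
               linear = as.numeric(lin), phase = as.numeric(phase),
               rho = NA_real_, p = NA_real_, slope = NA_real_,
               mode = mode))
  }
  cl <- circularLinearCorr(phase, lin, slopeRange = slopeRange)
  new("PrecessionResult", spikeTime = trace@t[idx],
      linear = as.numeric(lin), phase = as.numeric(phase),
      rho = cl$rho, p = cl$p, slope = cl$slope, mode = mode)
}
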