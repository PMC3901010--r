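#' @include AllClasses.R
NULL

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 2nd-order Butterworth band-pass forwards and backwards
#' (`filtfilt` scheme) so the net phase shift is zero. To suppress edge
#' transients the series is extended by mirror reflection over three
#' filter time constants (`3/lo` seconds) at each end before filtering;
#' the padding is discarded afterwards.
#'
#' @param x numeric series.
#' @param lo,hi band edges in Hz, `0 < lo < hi < fs/2`.
#' @param fs sampling rate in Hz.
#' @param order filter order (default 2, doubled by the two passes).
#' @return the filtered series, same length as `x`.
#' @export
bandpassZeroPhase <- function(x, lo, hi, fs, order = 2) {
  stopifnot(lo > 0, hi > lo, hi < fs / 2)
  n <- length(x)
  pad <- min(n - 1L, ceiling(3 / lo * fs))
  if (n < 3L * (order * 2L + 1L))
    stop("series too short relative to the filter settling length")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  xp <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  y <- signal::filter(bf, xp)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[(pad + 1L):(pad + n)]
}

#' Analytic signal via the Hilbert transform
#'
#' FFT implementation of the analytic signal `x + i*H(x)`; `Mod()` of the
#' result is the instantaneous envelope and `Arg()` the instantaneous
#' phase.
#'
#' @param x numeric series.
#' @return complex analytic signal.
#' @details The series is extended by mirror reflection to a highly
#'   composite length before the FFT (and truncated afterwards) so the
#'   transform stays fast for arbitrary series lengths and the circular
#'   wrap-around does not contaminate the edges.
#' @export
analyticSignal <- function(x) {
  n0 <- length(x)
  n <- stats::nextn(n0, c(2, 3, 5))
  if (n > n0) {
    pad <- pmin(n - n0, n0 - 1L)
    x <- c(x, x[seq(n0 - 1L, by = -1L, length.out = pad)],
           rep(x[1L], n - n0 - pad))
  }
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  (stats::fft(stats::fft(x) * h, inverse = TRUE) / n)[seq_len(n0)]
}

#' DC-shift and theta-envelope series of a membrane trace
#'
#' Removes the trace mean, band-pass filters the membrane potential at
#' 0.1-3 Hz (DC-shift component) and 5-10 Hz (theta component), takes
#' the Hilbert envelope of the theta component, and subtracts the
#' out-of-field mean from the DC series so the out-of-field DC mean is
#' zero by construction. When no classification is supplied the raw
#' (mean-removed, filtered) series are returned without the out-of-field
#' re-centering, as used by the firing-rate correlation pipeline.
#'
#' @param trace a [MembraneTrace-class] (or numeric Vm series, in which
#'   case `dt` must be given).
#' @param labels optional [FieldClassification-class]; required for
#'   out-of-field re-centering.
#' @param dt time step in seconds when `trace` is a plain numeric series.
#' @param dcBand,thetaBand band edges in Hz.
#' @return an [AmplitudeSeries-class].
#' @export
amplitudeSeries <- function(trace, labels = NULL, dt = NULL,
                            dcBand = c(0.1, 3), thetaBand = c(5, 10)) {
  if (is(trace, "MembraneTrace")) {
    vm <- trace@Vm
    dt <- trace@dt
    tt <- trace@t
  } else {
    vm <- as.numeric(trace)
    if (is.null(dt)) stop("'dt' required for a plain numeric series")
    tt <- seq_along(vm) * dt - dt
  }
  fs <- 1 / dt
  vm0 <- vm - mean(vm)
  dc <- bandpassZeroPhase(vm0, dcBand[1L], dcBand[2L], fs)
  theta <- bandpassZeroPhase(vm0, thetaBand[1L], thetaBand[2L], fs)
  env <- Mod(analyticSignal(theta))
  if (!is.null(labels)) {
    out <- sampleLabels(labels) == "out_of_field"
    if (!any(out))
      stop("no out-of-field samples: cannot anchor the DC series")
    dc <- dc - mean(dc[out])
  }
  new("AmplitudeSeries", dcShift = dc, mpoEnvelope = env, t = tt, dt = dt)
}

#' In-field minus out-of-field amplitude differences
#'
#' `Delta_DC` is the mean DC-shift over in-field samples (the out-of-field
#' DC mean is zero by construction); `Delta_MPO` is the difference between
#' the in-field and out-of-field means of the theta envelope. The first
#' and last `trim` seconds are excluded to avoid residual filter
#' transients.
#'
#' @param series an [AmplitudeSeries-class] built with a classification.
#' @param labels the [FieldClassification-class] used.
#' @param trim seconds excluded at each end (default 2).
#' @return named numeric vector `c(dc = ..., mpo = ...)` in mV.
#' @export
deltaAmplitudes <- function(series, labels, trim = 2) {
  lab <- sampleLabels(labels)
  n <- length(lab)
  keep <- rep(TRUE, n)
  nTrim <- round(trim / series@dt)
  if (2L * nTrim < n && nTrim > 0L)
    keep[c(seq_len(nTrim), (n - nTrim + 1L):n)] <- FALSE
  inF <- keep & lab == "in_field"
  outF <- keep & lab == "out_of_field"
  if (!any(inF) || !any(outF))
    stop("both in-field and out-of-field samples are required")
  c(dc = mean(series@dcShift[inF]) - mean(series@dcShift[outF]),
    mpo = mean(series@mpoEnvelope[inF]) - mean(series@mpoEnvelope[outF]))
}

#' Add a field-rhythm sinusoid to a membrane trace
#'
#' Emulates contamination of the intracellular trace by an extracellular
#' local-field rhythm of a slightly different frequency than the 6 Hz
#' baseline; raising the out-of-field theta envelope lowers the
#' theta-amplitude/firing-rate correlation.
#'
#' @param vm numeric membrane potential series (mV).
#' @param t sample times in seconds.
#' @param freq rhythm frequency in Hz (default 6.5).
#' @param amp rhythm amplitude in mV (default 0, identity).
#' @return the augmented series.
#' @export
addFieldRhythm <- function(vm, t, freq = 6.5, amp = 0) {
  stopifnot(amp >= 0, length(vm) == length(t))
  vm + amp * sin(2 * pi * freq * t)
}

#' Sweep the membrane time constant with co-adapted threshold
#'
#' For each leak time constant, runs `nReps` random-walk simulations with
#' the spiking threshold set by [thresholdForTau()], classifies fields,
#' and averages (i) the mean of the in-field local maxima of the DC-shift
#' series and (ii) the mean in-field theta envelope.
#'
#' @param tauMs leak time constants in ms (default `seq(10, 100, 10)`).
#' @param nReps simulations per time constant (default 50).
#' @param duration seconds per simulation (default 600).
#' @param nShuffles shuffles for field classification (default 200).
#' @param seed integer seed; per-run seeds are derived from it.
#' @param bands a [BandParams-class] (default [bandParams()]).
#' @return a data.frame with columns `tauMs`, `dcInFieldMax`,
#'   `mpoInField`.
#' @export
tauSweep <- function(tauMs = seq(10, 100, by = 10), nReps = 50,
                     duration = 600, nShuffles = 200, seed = 1,
                     bands = bandParams()) {
  res <- lapply(tauMs, function(tau) {
    vals <- vapply(seq_len(nReps), function(r) {
      s <- seed + 1000L * match(tau, tauMs) + r
      tr <- randomWalk(duration, seed = s)
      trace <- simulateGridCell(tr, bands,
                                cellParams(tauGL = tau / 1000,
                                           Vt = thresholdForTau(tau)))
      null <- shuffleNull(tr, trace@spike, nShuffles = nShuffles,
                          seed = s)
      cls <- classifyFields(null)
      if (!any(sampleLabels(cls) == "in_field") ||
          !any(sampleLabels(cls) == "out_of_field"))
        return(c(NA_real_, NA_real_))
      amp <- amplitudeSeries(trace, cls)
      inF <- sampleLabels(cls) == "in_field"
      dcMax <- localSeriesMaxima(amp@dcShift, inF)
      c(if (length(dcMax)) mean(dcMax) else NA_real_,
        mean(amp@mpoEnvelope[inF]))
    }, numeric(2))
    c(mean(vals[1L, ], na.rm = TRUE), mean(vals[2L, ], na.rm = TRUE))
  })
  res <- do.call(rbind, res)
  data.frame(tauMs = tauMs, dcInFieldMax = res[, 1L],
             mpoInField = res[, 2L])
}

## values of local maxima of `x` restricted to samples where `mask` holds
localSeriesMaxima <- function(x, mask) {
  n <- length(x)
  if (n < 3L) return(numeric())
  i <- 2:(n - 1L)
  pk <- i[x[i] > x[i - 1L] & x[i] >= x[i + 1L] & mask[i]]
  x[pk]
}
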