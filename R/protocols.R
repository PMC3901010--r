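#' @include AllClasses.R
NULL

## One default random-walk simulation plus the derived per-sample series
## used by the statistics protocols (theta-subsampled spikes, DC/theta
## amplitude series without out-of-field re-centering).
simulateForStats <- function(duration, seed, bands = bandParams(),
                             params = cellParams()) {
  traj <- randomWalk(duration, dt = params@dt, seed = seed)
  trace <- simulateGridCell(traj, bands, params)
  amp <- amplitudeSeries(trace)
  idx <- subsampleSpikesToThetaPeaks(trace)
  list(traj = traj, trace = trace, amp = amp,
       spikeTimes = trace@t[idx])
}

#' In-field vs out-of-field amplitude differences over repeated runs
#'
#' Runs `nSeeds` default random-walk simulations of `duration` seconds,
#' classifies fields by the circular-shuffle bootstrap, and computes the
#' in-field minus out-of-field DC-shift and theta-envelope differences
#' for each run.
#'
#' @param nSeeds number of independent simulations (default 5).
#' @param duration seconds per simulation (default 2000).
#' @param seed base integer seed; run `i` uses `seed + i`.
#' @param nShuffles shuffles for the classification null (default 1000).
#' @param bands,params model parameter objects.
#' @return a data.frame with one row per run: `seed`, `dc`, `mpo` (mV).
#' @export
deltaAmpProtocol <- function(nSeeds = 5, duration = 2000, seed = 1,
                             nShuffles = 1000, bands = bandParams(),
                             params = cellParams()) {
  rows <- lapply(seq_len(nSeeds), function(i) {
    s <- seed + i
    traj <- randomWalk(duration, dt = params@dt, seed = s)
    trace <- simulateGridCell(traj, bands, params)
    cls <- classifyFields(shuffleNull(traj, trace@spike,
                                      nShuffles = nShuffles, seed = s))
    amp <- amplitudeSeries(trace, cls)
    d <- deltaAmplitudes(amp, cls)
    data.frame(seed = s, dc = d[["dc"]], mpo = d[["mpo"]])
  })
  do.call(rbind, rows)
}

#' Per-interspike-interval correlation protocol
#'
#' The pooled ISI analysis: `nSims` random-walk simulations, spikes
#' subsampled to one per membrane theta cycle, one record per ISI
#' (rate = 1/ISI, interval means of the DC-shift and theta-envelope
#' series), pooled across simulations. Pearson correlations of each
#' amplitude with rate are computed unbinned and after averaging within
#' 8 equal-width amplitude bins.
#'
#' @param nSims number of simulations (default 10).
#' @param duration seconds per simulation (default 60).
#' @param seed base seed; simulation `i` uses `seed + i`.
#' @param nBins bins for the binned correlation (default 8).
#' @param bands,params model parameter objects.
#' @return a list with `records` (pooled data.frame), `unbinned` and
#'   `binned` (each a list with `dc` and `mpo` correlation results), and
#'   `steiger` (test of the unbinned dc vs mpo correlation difference).
#' @export
isiCorrelationProtocol <- function(nSims = 10, duration = 60, seed = 1,
                                   nBins = 8, bands = bandParams(),
                                   params = cellParams()) {
  recs <- lapply(seq_len(nSims), function(i) {
    sim <- simulateForStats(duration, seed + i, bands, params)
    isiRatePairs(sim$spikeTimes, sim$amp)
  })
  records <- do.call(rbind, recs)
  unb <- list(
    dc = correlateAmplitudeRate(records$dc, records$rate),
    mpo = correlateAmplitudeRate(records$mpo, records$rate))
  bin <- list(
    dc = correlateAmplitudeRate(records$dc, records$rate, binned = TRUE,
                                nBins = nBins),
    mpo = correlateAmplitudeRate(records$mpo, records$rate,
                                 binned = TRUE, nBins = nBins))
  st <- steigerZ(unb$dc$r, unb$mpo$r,
                 stats::cor(records$dc, records$mpo), nrow(records))
  list(records = records, unbinned = unb, binned = bin, steiger = st)
}

#' Sliding-window correlation protocol
#'
#' `nSims` random-walk simulations; within each, a 1 s window slides
#' along the trace, pairing the window spike count (normalized by the
#' simulation's mean rate) with the window means of the DC-shift and
#' theta-envelope series. Correlations are computed on the pooled
#' windows. The first and last 2 s of each trace are excluded (filter
#' transients).
#'
#' @param nSims number of simulations (default 20).
#' @param duration seconds per simulation (default 600).
#' @param seed base seed; simulation `i` uses `seed + i`.
#' @param window window length in seconds (default 1).
#' @param step window step in seconds (default 0.002).
#' @param bands,params model parameter objects.
#' @return a list with `dc` and `mpo` unbinned correlation results,
#'   `steiger`, `n` (pooled windows) and `windows` (pooled data.frame
#'   with columns `normRate`, `dc`, `mpo`).
#' @export
slidingWindowProtocol <- function(nSims = 20, duration = 600, seed = 1,
                                  window = 1, step = 0.002,
                                  bands = bandParams(),
                                  params = cellParams()) {
  pool <- lapply(seq_len(nSims), function(i) {
    sim <- simulateForStats(duration, seed + i, bands, params)
    sw <- slidingWindowRate(sim$spikeTimes, duration, window = window,
                            step = step)
    dt <- sim$amp@dt
    wlen <- round(window / dt)
    rdc <- rollMean(sim$amp@dcShift, wlen)
    rmp <- rollMean(sim$amp@mpoEnvelope, wlen)
    ## window centers align with rolling-mean centers
    ci <- round((sw$center - window / 2) / dt) + 1L
    ci <- pmin(pmax(ci, 1L), length(rdc))
    keep <- sw$center > 2 & sw$center < duration - 2
    data.frame(normRate = sw$normRate[keep], dc = rdc[ci][keep],
               mpo = rmp[ci][keep])
  })
  w <- do.call(rbind, pool)
  dc <- correlateAmplitudeRate(w$dc, w$normRate)
  mpo <- correlateAmplitudeRate(w$mpo, w$normRate)
  st <- steigerZ(dc$r, mpo$r, stats::cor(w$dc, w$mpo), nrow(w))
  list(dc = dc, mpo = mpo, steiger = st, n = nrow(w), windows = w)
}

## centered rolling mean over k samples; result[i] is the mean of
## x[i .. i+k-1] (window starting at i)
rollMean <- function(x, k) {
  cs <- cumsum(x)
  n <- length(x)
  if (k >= n) return(rep(mean(x), 1L))
  (cs[k:n] - c(0, cs[seq_len(n - k)])) / k
}

#' Mutual-information ratio protocol
#'
#' For each simulation: the field-index series (1 cm smoothed normalized
#' rate map sampled along the trajectory), the DC-shift series and the
#' theta-envelope series; the per-simulation ratio
#' `MI(dc; field index) / MI(mpo; field index)` with a binned plug-in
#' estimator.
#'
#' @param nSims number of simulations (default 10).
#' @param duration seconds per simulation (default 60).
#' @param seed base seed; simulation `i` uses `seed + i`.
#' @param nBins histogram bins per axis (default 8).
#' @param bands,params model parameter objects.
#' @return a data.frame with per-simulation `miDc`, `miMpo`, `ratio`.
#' @export
miRatioProtocol <- function(nSims = 10, duration = 60, seed = 1,
                            nBins = 8, bands = bandParams(),
                            params = cellParams()) {
  rows <- lapply(seq_len(nSims), function(i) {
    sim <- simulateForStats(duration, seed + i, bands, params)
    fi <- fieldIndexSeries(sim$traj,
                           fieldIndexMap(sim$traj, sim$trace@spike))
    miDc <- mutualInformation(sim$amp@dcShift, fi, nBins = nBins)
    miMpo <- mutualInformation(sim$amp@mpoEnvelope, fi, nBins = nBins)
    data.frame(miDc = miDc, miMpo = miMpo, ratio = miDc / miMpo)
  })
  do.call(rbind, rows)
}
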