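#' @include AllClasses.R
NULL

#' Per-interspike-interval rate and amplitude records
#'
#' For each pair of consecutive (theta-subsampled) spikes: the firing
#' rate `1/ISI` and the mean of the DC-shift and theta-envelope series
#' over the interval.
#'
#' @param spikeTimes spike times in seconds (ascending).
#' @param series an [AmplitudeSeries-class].
#' @return a data.frame with columns `rate`, `dc`, `mpo` (one row per
#'   interval; empty with fewer than 2 spikes).
#' @export
isiRatePairs <- function(spikeTimes, series) {
  if (length(spikeTimes) < 2)
    return(data.frame(rate = numeric(), dc = numeric(),
                      mpo = numeric()))
  dt <- series@dt
  idx <- round((spikeTimes - series@t[1L]) / dt) + 1L
  n <- length(series@dcShift)
  idx <- pmin(pmax(idx, 1L), n)
  cdc <- cumsum(series@dcShift)
  cmp <- cumsum(series@mpoEnvelope)
  i0 <- idx[-length(idx)]
  i1 <- idx[-1L]
  len <- i1 - i0 + 1L
  segMean <- function(cs, x) (cs[i1] - cs[i0] + x[i0]) / len
  data.frame(rate = 1 / diff(spikeTimes),
             dc = segMean(cdc, series@dcShift),
             mpo = segMean(cmp, series@mpoEnvelope))
}

#' Pearson correlation of amplitude against firing rate
#'
#' Unbinned: Pearson r and p on the raw pairs. Binned: `nBins`
#' equal-width bins spanning the range of `x`; empty bins are dropped
#' (sparse bins kept, with large standard errors); the correlation is
#' computed between the bin means of `x` and the bin means of `y`.
#'
#' @param x amplitude values (the binning variable).
#' @param y firing rates.
#' @param binned logical; bin before correlating?
#' @param nBins number of equal-width bins (default 8).
#' @return a list with `r`, `p`, `n`, `binned`, and for binned mode
#'   `binMeansX`, `binMeansY`, `binSem`, `binCount`.
#' @export
correlateAmplitudeRate <- function(x, y, binned = FALSE, nBins = 8) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in 'x' or 'y'")
  if (!binned) {
    ct <- stats::cor.test(x, y)
    return(list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                binned = FALSE))
  }
  edges <- seq(min(x), max(x), length.out = nBins + 1L)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
              nBins)
  cnt <- tabulate(bin, nBins)
  keep <- cnt > 0L
  mx <- vapply(which(keep), function(b) mean(x[bin == b]), numeric(1))
  my <- vapply(which(keep), function(b) mean(y[bin == b]), numeric(1))
  sem <- vapply(which(keep), function(b) {
    v <- y[bin == b]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))
  if (sum(keep) < 3) stop("fewer than 3 occupied bins")
  ct <- stats::cor.test(mx, my)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep),
       binned = TRUE, binMeansX = mx, binMeansY = my, binSem = sem,
       binCount = cnt[keep])
}

#' Mean-normalized firing rate in a sliding window
#'
#' Counts spikes in a sliding window of `window` seconds advanced by
#' `step` seconds, divides by the window length, and normalizes by the
#' experiment's mean firing rate (total spikes / total duration), so the
#' normalized series has mean about 1.
#'
#' @param spikeTimes spike times in seconds.
#' @param duration total trace duration in seconds.
#' @param window window length in seconds (default 1).
#' @param step window step in seconds (default 0.002).
#' @param dt sample step used to place windows (default `step`).
#' @return a data.frame with columns `center` (window center time),
#'   `rate` (Hz) and `normRate`.
#' @export
slidingWindowRate <- function(spikeTimes, duration, window = 1,
                              step = 0.002, dt = step) {
  stopifnot(duration > window)
  centers <- seq(window / 2, duration - window / 2, by = step)
  st <- sort(spikeTimes)
  lo <- findInterval(centers - window / 2, st, left.open = TRUE)
  hi <- findInterval(centers + window / 2, st)
  count <- hi - lo
  rate <- count / window
  meanRate <- length(st) / duration
  norm <- if (meanRate > 0) rate / meanRate else rate * 0
  data.frame(center = centers, rate = rate, normRate = norm)
}

#' Plug-in mutual information between two series
#'
#' Discretizes both series into equal-width bins, forms the joint
#' histogram and returns the plug-in mutual information in bits.
#' Constant inputs carry no information (MI = 0).
#'
#' @param x,y numeric series of equal length.
#' @param nBins equal-width bins per axis (default 8).
#' @return mutual information in bits.
#' @export
mutualInformation <- function(x, y, nBins = 8) {
  stopifnot(length(x) == length(y), nBins >= 2)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  cutBin <- function(v) {
    e <- seq(min(v), max(v), length.out = nBins + 1L)
    pmin(pmax(findInterval(v, e, rightmost.closed = TRUE), 1L), nBins)
  }
  joint <- table(cutBin(x), cutBin(y)) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

#' Steiger's test for two dependent correlations sharing one variable
#'
#' Tests whether `r1 = cor(x1, y)` differs from `r2 = cor(x2, y)` given
#' `r12 = cor(x1, x2)`, using Fisher-transformed correlations and the
#' Dunn-Clark covariance term (Steiger's Z_H, which plugs the mean of
#' `r1` and `r2` into the covariance).
#'
#' @param r1,r2 the two dependent correlations (each sharing variable
#'   `y`).
#' @param r12 correlation between the two non-shared variables.
#' @param n sample size (`> 3`).
#' @return a list with `Z` and two-sided `p`.
#' @export
steigerZ <- function(r1, r2, r12, n) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, abs(r12) <= 1, n > 3)
  det3 <- 1 + 2 * r1 * r2 * r12 - r1^2 - r2^2 - r12^2
  if (det3 < -1e-8)
    stop("invalid correlation matrix (not positive semi-definite)")
  rb <- (r1 + r2) / 2
  cov12 <- (r12 * (1 - 2 * rb^2) - 0.5 * rb^2 *
              (1 - 2 * rb^2 - r12^2)) / (1 - rb^2)^2
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  Z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov12))
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)))
}
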