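#' @include AllClasses.R
NULL

## Common binning: bin index per trajectory sample on a square grid of
## `binSize` cm covering [-halfWidth, halfWidth]. Returns list with per
## sample flat bin id and the grid geometry.
binGrid <- function(traj, binSize, halfWidth = NULL) {
  if (is.null(halfWidth)) {
    halfWidth <- traj@arenaHalfWidth
    if (is.na(halfWidth)) halfWidth <- max(abs(c(traj@x, traj@y)))
  }
  nBins <- ceiling(2 * halfWidth / binSize)
  edges <- -halfWidth + binSize * (0:nBins)
  ix <- pmin(pmax(findInterval(traj@x, edges, rightmost.closed = TRUE),
                  1L), nBins)
  iy <- pmin(pmax(findInterval(traj@y, edges, rightmost.closed = TRUE),
                  1L), nBins)
  list(id = (iy - 1L) * nBins + ix, nBins = nBins,
       centers = edges[-1L] - binSize / 2, binSize = binSize)
}

#' Occupancy-normalized firing-rate map
#'
#' Bins the trajectory into square spatial bins, accumulates dwell time
#' and spike-sample counts, and returns per-bin rate = count/occupancy.
#' Bins visited for fewer than `minSamples` samples are flagged `NA`
#' rather than zero-filled.
#'
#' @param traj a [Trajectory-class].
#' @param spikes logical per-sample spike indicator (e.g.
#'   `spikeSamples(trace)`).
#' @param binSize bin side in cm (default 5).
#' @param minSamples minimum samples for a defined bin (default 2).
#' @return a [RateMap-class].
#' @export
rateMap <- function(traj, spikes, binSize = 5, minSamples = 2) {
  stopifnot(length(spikes) == length(traj@t))
  g <- binGrid(traj, binSize)
  nb <- g$nBins
  occN <- tabulate(g$id, nb * nb)
  cnt <- tabulate(g$id[spikes], nb * nb)
  rate <- cnt / (occN * traj@dt)
  rate[occN < minSamples] <- NA_real_
  dim(rate) <- dim(occN) <- dim(cnt) <- c(nb, nb)
  new("RateMap", rate = rate, occupancy = occN * traj@dt, count = cnt,
      xCenters = g$centers, yCenters = g$centers, binSize = binSize)
}

#' Per-bin percentile of the observed rate against a circular-shuffle null
#'
#' Builds the bootstrap null by circularly rotating the entire spike
#' series `nShuffles` times, each time by an integer offset drawn
#' uniformly from `[0.05*N, 0.95*N]`, recomputing each 5 cm bin's firing
#' rate against the original occupancy. The per-bin empirical percentile
#' `1 - P` is the fraction of shuffles whose rate is strictly below the
#' observed rate; ties count into `P`, so a visited bin with zero
#' observed spikes has `1 - P = 0` and can classify out-of-field.
#'
#' @param traj a [Trajectory-class].
#' @param spikes logical per-sample spike indicator.
#' @param binSize spatial bin side in cm (default 5).
#' @param nShuffles number of circular shuffles (default 1000).
#' @param minSamples minimum samples for a defined bin (default 2).
#' @param seed optional integer seed.
#' @return a list with `percentile` (matrix, `NA` where occupancy is
#'   insufficient or no spikes exist), `xCenters`, `yCenters`, `binSize`,
#'   `nShuffles`, and `sampleBin` (per-sample flat bin index).
#' @export
shuffleNull <- function(traj, spikes, binSize = 5, nShuffles = 1000,
                        minSamples = 2, seed = NULL) {
  stopifnot(nShuffles >= 1, length(spikes) == length(traj@t))
  if (!is.null(seed)) set.seed(seed)
  g <- binGrid(traj, binSize)
  nb <- g$nBins
  n <- length(g$id)
  occN <- tabulate(g$id, nb * nb)
  spikeIdx <- which(spikes)
  obs <- tabulate(g$id[spikeIdx], nb * nb)
  notHigher <- integer(nb * nb)
  if (length(spikeIdx)) {
    shifts <- sample.int(ceiling(0.95 * n) - floor(0.05 * n) + 1L,
                         nShuffles, replace = TRUE) +
      floor(0.05 * n) - 1L
    for (s in shifts) {
      idx <- ((spikeIdx + s - 1L) %% n) + 1L
      cnt <- tabulate(g$id[idx], nb * nb)
      notHigher <- notHigher + (cnt < obs)
    }
  }
  pct <- notHigher / nShuffles
  pct[occN < minSamples] <- NA_real_
  if (!length(spikeIdx)) pct[] <- NA_real_
  dim(pct) <- c(nb, nb)
  list(percentile = pct, xCenters = g$centers, yCenters = g$centers,
       binSize = g$binSize, nShuffles = nShuffles, sampleBin = g$id)
}

## TRUE for every bin belonging to a k x k axis-aligned block where `ok`
## holds everywhere (NA counts as FALSE)
blockMember <- function(ok, k) {
  ok[is.na(ok)] <- FALSE
  nr <- nrow(ok)
  nc <- ncol(ok)
  out <- matrix(FALSE, nr, nc)
  if (nr < k || nc < k) return(out)
  ## block top-left corners where all k x k cells hold
  corner <- matrix(TRUE, nr - k + 1L, nc - k + 1L)
  for (di in 0:(k - 1L)) for (dj in 0:(k - 1L))
    corner <- corner & ok[(1:(nr - k + 1L)) + di, (1:(nc - k + 1L)) + dj,
                          drop = FALSE]
  idx <- which(corner, arr.ind = TRUE)
  for (r in seq_len(nrow(idx)))
    out[idx[r, 1L] + 0:(k - 1L), idx[r, 2L] + 0:(k - 1L)] <- TRUE
  out
}

## TRUE for bins 8-adjacent to any TRUE bin in `m`
dilate8 <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(FALSE, nr, nc)
  for (di in 0:2) for (dj in 0:2) {
    if (di == 1L && dj == 1L) next
    out <- out | p[(1:nr) + di, (1:nc) + dj]
  }
  out
}

#' Classify arena bins as in-field, out-of-field or unassigned
#'
#' Applies the bootstrap classification rule to the percentile map from
#' [shuffleNull()]: in-field bins are members of a 3x3 block whose bins
#' all reach the 85th percentile, extended (single pass) by 8-adjacent
#' bins reaching the 70th percentile; out-of-field bins are members of a
#' 2x2 block entirely at or below the 5th percentile; everything else is
#' unassigned. Every trajectory sample inherits its containing bin's
#' label.
#'
#' @param null result of [shuffleNull()].
#' @param inHigh percentile for in-field blocks (default 0.85).
#' @param extHigh percentile for extension bins (default 0.70).
#' @param outLow percentile for out-of-field blocks (default 0.05).
#' @return a [FieldClassification-class].
#' @export
classifyFields <- function(null, inHigh = 0.85, extHigh = 0.70,
                           outLow = 0.05) {
  pct <- null$percentile
  inCore <- blockMember(pct >= inHigh, 3L)
  ext <- dilate8(inCore) & !is.na(pct) & pct >= extHigh & !inCore
  inField <- inCore | ext
  outField <- blockMember(pct <= outLow, 2L) & !inField
  label <- matrix("unassigned", nrow(pct), ncol(pct))
  label[inField] <- "in_field"
  label[outField] <- "out_of_field"
  label[is.na(pct)] <- "unassigned"
  new("FieldClassification",
      percentile = pct, label = label,
      sampleLabel = label[null$sampleBin],
      xCenters = null$xCenters, yCenters = null$yCenters,
      binSize = null$binSize, nShuffles = null$nShuffles)
}

## separable Gaussian smoothing of a matrix, kernel SD in bins
gaussSmooth <- function(m, sdBins, radius = ceiling(3 * sdBins)) {
  k <- dnorm(-radius:radius, sd = sdBins)
  k <- k / sum(k)
  smooth1 <- function(v) {
    n <- length(v)
    padded <- c(rep(v[1L], radius), v, rep(v[n], radius))
    as.numeric(stats::filter(padded, k, sides = 2))[(radius + 1L):(radius + n)]
  }
  m <- apply(m, 2L, smooth1)
  t(apply(t(m), 2L, smooth1))
}

#' Field-index map: smoothed, normalized firing-rate map
#'
#' Builds a 1 x 1 cm occupancy-normalized rate map (unvisited bins set to
#' zero before smoothing), smooths it by a two-dimensional Gaussian with a
#' 5-bin (5 cm) standard deviation, and min-max normalizes the result to
#' `[0, 1]`. The map value measures how "in-field" a position is, 1 at a
#' field center. If the smoothed map is constant the normalization is
#' degenerate; an all-zero map is returned with a warning.
#'
#' @param traj a [Trajectory-class].
#' @param spikes logical per-sample spike indicator; at least one spike is
#'   required.
#' @param binSize bin side in cm (default 1).
#' @param smoothSd Gaussian kernel SD in bins (default 5).
#' @return a list with `map` (matrix in `[0, 1]`), `xCenters`,
#'   `yCenters`, `binSize`.
#' @export
fieldIndexMap <- function(traj, spikes, binSize = 1, smoothSd = 5) {
  if (!any(spikes)) stop("field index map requires at least one spike")
  g <- binGrid(traj, binSize)
  nb <- g$nBins
  occN <- tabulate(g$id, nb * nb)
  cnt <- tabulate(g$id[spikes], nb * nb)
  rate <- ifelse(occN > 0, cnt / (occN * traj@dt), 0)
  dim(rate) <- c(nb, nb)
  sm <- gaussSmooth(rate, smoothSd)
  rng <- range(sm)
  if (rng[2L] - rng[1L] <= .Machine$double.eps * max(1, abs(rng[2L]))) {
    warning("degenerate normalization: smoothed rate map is constant")
    sm[] <- 0
  } else {
    sm <- (sm - rng[1L]) / (rng[2L] - rng[1L])
  }
  list(map = sm, xCenters = g$centers, yCenters = g$centers,
       binSize = binSize)
}

#' Field-index value at every trajectory sample
#'
#' Looks up the field-index map at the bin center nearest each sample.
#'
#' @param traj a [Trajectory-class].
#' @param map result of [fieldIndexMap()].
#' @return numeric series in `[0, 1]`, one value per sample.
#' @export
fieldIndexSeries <- function(traj, map) {
  ix <- findNearest(traj@x, map$xCenters)
  iy <- findNearest(traj@y, map$yCenters)
  map$map[cbind(ix, iy)]
}

## index of the nearest center for each value (centers uniform ascending)
findNearest <- function(v, centers) {
  step <- centers[2L] - centers[1L]
  pmin(pmax(round((v - centers[1L]) / step) + 1L, 1L), length(centers))
}

#' Spatial autocorrelogram of a rate map
#'
#' Pearson correlation of the map with itself at every integer bin offset,
#' computed over the bins defined (non-`NA`) in both copies; offsets with
#' fewer than `minOverlap` overlapping bins are `NA`.
#'
#' @param m numeric matrix (`NA` for undefined bins).
#' @param minOverlap minimum overlapping bins per offset (default 20).
#' @return a square matrix of size `2*nrow(m)-1` with the zero offset at
#'   the center.
#' @export
spatialAutocorrelogram <- function(m, minOverlap = 20) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(NA_real_, 2L * nr - 1L, 2L * nc - 1L)
  for (di in -(nr - 1L):(nr - 1L)) {
    r1 <- max(1L, 1L + di):min(nr, nr + di)
    r2 <- r1 - di
    for (dj in -(nc - 1L):(nc - 1L)) {
      c1 <- max(1L, 1L + dj):min(nc, nc + dj)
      c2 <- c1 - dj
      a <- m[r1, c1]
      b <- m[r2, c2]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) >= minOverlap) {
        a <- a[ok]
        b <- b[ok]
        if (stats::sd(a) > 0 && stats::sd(b) > 0)
          out[nr + di, nc + dj] <- stats::cor(a, b)
      }
    }
  }
  out
}

## sample matrix `m` at fractional (row, col) coordinates via bilinear
## interpolation; NA outside or where any corner is NA
bilinear <- function(m, r, cc) {
  nr <- nrow(m)
  nc <- ncol(m)
  r0 <- floor(r)
  c0 <- floor(cc)
  fr <- r - r0
  fc <- cc - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  val <- rep(NA_real_, length(r))
  if (any(ok)) {
    i <- which(ok)
    v00 <- m[cbind(r0[i], c0[i])]
    v10 <- m[cbind(r0[i] + 1L, c0[i])]
    v01 <- m[cbind(r0[i], c0[i] + 1L)]
    v11 <- m[cbind(r0[i] + 1L, c0[i] + 1L)]
    val[i] <- v00 * (1 - fr[i]) * (1 - fc[i]) + v10 * fr[i] * (1 - fc[i]) +
      v01 * (1 - fr[i]) * fc[i] + v11 * fr[i] * fc[i]
  }
  val
}

#' Gridness score of a rate map
#'
#' Computes the spatial autocorrelogram, isolates an annulus that excludes
#' the central peak and reaches out to the surrounding six-peak ring, and
#' correlates the annulus with rotated copies of itself. The score is
#' `min(cor at 60, 120 deg) - max(cor at 30, 90, 150 deg)`: positive for
#' hexagonal (six-fold) symmetry, negative for four-fold symmetry, near
#' zero for unstructured maps.
#'
#' The annulus inner radius is the first zero crossing of the central
#' autocorrelation peak (radial profile); the outer radius is 1.25 times
#' the median distance to the six nearest ring peaks. When ring peaks
#' cannot be found the radii fall back to fixed fractions (0.15 and 0.75)
#' of the map half-size.
#'
#' @param map a [RateMap-class] or a numeric matrix of rates.
#' @param minCoverage minimum fraction of defined bins required (default
#'   0.5); maps with poorer coverage give an error.
#' @return a list with `score`, `innerRadius`, `outerRadius` (bins) and
#'   the `autocorrelogram` matrix.
#' @export
gridnessScore <- function(map, minCoverage = 0.5) {
  m <- if (is(map, "RateMap")) map@rate else map
  if (mean(!is.na(m)) < minCoverage)
    stop("insufficient coverage to compute a gridness score")
  ac <- spatialAutocorrelogram(m)
  ctr <- c((nrow(ac) + 1L) / 2, (ncol(ac) + 1L) / 2)
  maxR <- floor(min(nrow(ac), ncol(ac)) / 2)

  ## radial profile of the central peak -> inner radius at first zero cross
  radial <- vapply(seq_len(maxR), function(r) {
    ang <- seq(0, 2 * pi, length.out = 64L)[-64L]
    mean(bilinear(ac, ctr[1L] + r * sin(ang), ctr[2L] + r * cos(ang)),
         na.rm = TRUE)
  }, numeric(1))
  zc <- which(radial <= 0)[1L]
  inner <- if (is.na(zc)) 0.15 * maxR else zc

  ## six nearest local maxima outside the central peak -> outer radius
  pk <- localMaxima(ac)
  if (nrow(pk)) {
    d <- sqrt((pk[, 1L] - ctr[1L])^2 + (pk[, 2L] - ctr[2L])^2)
    pk <- pk[d > inner & d < maxR, , drop = FALSE]
    d <- d[d > inner & d < maxR]
  }
  outer <- if (nrow(pk) >= 3) {
    1.25 * stats::median(sort(d)[seq_len(min(6L, length(d)))])
  } else {
    0.75 * maxR
  }
  outer <- min(outer, maxR)
  if (outer <= inner + 1) outer <- min(maxR, inner + max(3, 0.3 * maxR))

  ## annulus sample points
  ii <- which(!is.na(ac), arr.ind = TRUE)
  d <- sqrt((ii[, 1L] - ctr[1L])^2 + (ii[, 2L] - ctr[2L])^2)
  sel <- ii[d >= inner & d <= outer, , drop = FALSE]
  base <- ac[sel]
  rotCor <- vapply(c(30, 60, 90, 120, 150) * pi / 180, function(ang) {
    dr <- sel[, 1L] - ctr[1L]
    dc <- sel[, 2L] - ctr[2L]
    rot <- bilinear(ac,
                    ctr[1L] + dr * cos(ang) - dc * sin(ang),
                    ctr[2L] + dr * sin(ang) + dc * cos(ang))
    ok <- !is.na(rot) & !is.na(base)
    if (sum(ok) < 10) return(NA_real_)
    stats::cor(base[ok], rot[ok])
  }, numeric(1))
  score <- min(rotCor[c(2L, 4L)]) - max(rotCor[c(1L, 3L, 5L)])
  list(score = score, innerRadius = inner, outerRadius = outer,
       autocorrelogram = ac)
}

## strict local maxima over the 8-neighborhood, NA-safe
localMaxima <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  mm <- m
  mm[is.na(mm)] <- -Inf
  isMax <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    shifted <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + di):min(nr, nr + di)
    cs <- max(1, 1 + dj):min(nc, nc + dj)
    shifted[rs, cs] <- mm[rs - di, cs - dj]
    isMax <- isMax & (mm > shifted)
  }
  isMax[!is.finite(mm)] <- FALSE
  which(isMax, arr.ind = TRUE)
}
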