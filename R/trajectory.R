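#' @include AllClasses.R
NULL

## Build a Trajectory from positions; kinematics derived as the exact
## inverse of integration: dx[i] = x[i+1]-x[i], speed = |step|/dt,
## heading = atan2(dy, dx) wrapped to [0, 360), carried over zero-speed
## samples.
newTrajectory <- function(t, x, y, dt, arenaHalfWidth = NA_real_) {
  n <- length(t)
  dx <- c(diff(x), NA_real_)
  dy <- c(diff(y), NA_real_)
  dx[n] <- dx[n - 1L]
  dy[n] <- dy[n - 1L]
  spd <- sqrt(dx^2 + dy^2) / dt
  hd <- atan2(dy, dx) * 180 / pi
  hd <- hd %% 360
  still <- spd == 0
  if (any(still)) {
    if (all(still)) {
      hd[] <- 0
    } else {
      ## carry the previous moving heading over stationary samples
      ## (leading stationary samples take the first moving heading)
      hd[still] <- NA_real_
      hd <- fillForward(hd)
    }
  }
  new("Trajectory", t = t, x = x, y = y, dx = dx, dy = dy,
      speed = spd, heading = hd, dt = dt,
      arenaHalfWidth = as.numeric(arenaHalfWidth))
}

## last-observation-carried-forward with back-fill for leading NAs
fillForward <- function(x) {
  ok <- !is.na(x)
  idx <- cummax(ifelse(ok, seq_along(x), 0L))
  idx[idx == 0L] <- which(ok)[1L]
  x[idx]
}

#' Wall reflection of a candidate movement step
#'
#' When a candidate position would leave the arena in one dimension, the
#' step in that dimension is replaced by `-R * step`, so the simulated
#' animal moves away from, rather than hugging, the walls.
#'
#' @param step candidate step in cm (may be a vector).
#' @param R reverse step size factor (default 0.6).
#' @return the reflected step, `-R * step`.
#' @examples
#' reflectStep(2, 0.6)   # -1.2
#' @export
reflectStep <- function(step, R = 0.6) {
  stopifnot(is.finite(R), R > 0)
  -R * step
}

#' Generate a momentum random-walk trajectory
#'
#' Each movement component follows
#' `dx(t) = s*(1-m)*p + m*dx(t-1)` with `p ~ N(0, 1)` drawn independently
#' for x and y at every step. If a candidate position exits the square
#' arena, the offending component of the step is reflected as `-R * step`
#' ([reflectStep()]); in the rare case that the reflected step still exits,
#' the position is clamped to the wall. The walk starts at the arena
#' center.
#'
#' @param duration walk duration in seconds.
#' @param stepSize average step size `s` in cm (default 1.7).
#' @param momentum momentum term `m` in `[0, 1)` (default 0.999).
#' @param reverseFactor reverse step size `R` (default 0.6).
#' @param arenaHalfWidth half-width of the square arena in cm (default 100,
#'   i.e. a 200 x 200 cm enclosure).
#' @param dt time step in seconds (default 0.002).
#' @param initialStep initial `(dx, dy)` in cm (default `c(0.35, 0.35)`).
#' @param seed optional integer seed for reproducibility.
#' @return a [Trajectory-class].
#' @examples
#' tr <- randomWalk(20, seed = 1)
#' mean(speed(tr))
#' @export
randomWalk <- function(duration, stepSize = 1.7, momentum = 0.999,
                       reverseFactor = 0.6, arenaHalfWidth = 100,
                       dt = 0.002, initialStep = c(0.35, 0.35),
                       seed = NULL) {
  stopifnot(is.finite(duration), duration > 0,
            is.finite(stepSize), stepSize >= 0,
            is.finite(momentum), momentum >= 0, momentum < 1,
            is.finite(reverseFactor), reverseFactor > 0,
            is.finite(arenaHalfWidth), arenaHalfWidth > 0,
            is.finite(dt), dt > 0, all(is.finite(initialStep)))
  if (!is.null(seed)) set.seed(seed)
  nStep <- round(duration / dt)
  w <- arenaHalfWidth
  px <- stepSize * (1 - momentum) * rnorm(nStep)
  py <- stepSize * (1 - momentum) * rnorm(nStep)
  x <- numeric(nStep + 1L)
  y <- numeric(nStep + 1L)
  dxp <- initialStep[1L]
  dyp <- initialStep[2L]
  xc <- 0
  yc <- 0
  for (i in seq_len(nStep)) {
    dx <- px[i] + momentum * dxp
    dy <- py[i] + momentum * dyp
    if (abs(xc + dx) > w) {
      dx <- -reverseFactor * dx
      if (abs(xc + dx) > w) dx <- sign(xc + dx) * w - xc
    }
    if (abs(yc + dy) > w) {
      dy <- -reverseFactor * dy
      if (abs(yc + dy) > w) dy <- sign(yc + dy) * w - yc
    }
    xc <- xc + dx
    yc <- yc + dy
    x[i + 1L] <- xc
    y[i + 1L] <- yc
    dxp <- dx
    dyp <- dy
  }
  newTrajectory(t = seq(0, by = dt, length.out = nStep + 1L),
                x = x, y = y, dt = dt, arenaHalfWidth = arenaHalfWidth)
}

#' Generate a constant-velocity straight-line trajectory
#'
#' @param start,end `(x, y)` endpoints in cm.
#' @param speed running speed in cm/s (default 5).
#' @param dt time step in seconds (default 0.002).
#' @return a [Trajectory-class] with constant speed and heading.
#' @examples
#' tr <- straightLineTrajectory(c(-100, 0), c(100, 0), speed = 5)
#' duration(tr)   # 40 s
#' @export
straightLineTrajectory <- function(start, end, speed = 5, dt = 0.002) {
  stopifnot(length(start) == 2, length(end) == 2,
            all(is.finite(c(start, end))),
            is.finite(speed), speed > 0, is.finite(dt), dt > 0)
  len <- sqrt(sum((end - start)^2))
  if (len == 0) stop("zero-length path: 'start' and 'end' coincide")
  dur <- len / speed
  nStep <- round(dur / dt)
  frac <- seq(0, 1, length.out = nStep + 1L)
  newTrajectory(t = seq(0, by = dt, length.out = nStep + 1L),
                x = start[1L] + frac * (end[1L] - start[1L]),
                y = start[2L] + frac * (end[2L] - start[2L]),
                dt = dt, arenaHalfWidth = NA_real_)
}

#' Read a recorded trajectory and up-sample it
#'
#' Reads a headered delimited table with columns `t, x, y` (seconds, cm,
#' cm) sampled at a uniform step (typically 0.02 s) and linearly
#' interpolates the positions to `targetDt` (typically 0.002 s). The
#' target step must divide the source step.
#'
#' @param path file path, or a data.frame with columns `t, x, y`.
#' @param targetDt target time step in seconds (default 0.002).
#' @param arenaHalfWidth optional arena half-width in cm used for
#'   downstream binning; defaults to the smallest half-width covering the
#'   positions.
#' @return a [Trajectory-class] sampled at `targetDt`.
#' @export
readTrajectory <- function(path, targetDt = 0.002, arenaHalfWidth = NULL) {
  tab <- if (is.data.frame(path)) path else
    utils::read.csv(path, header = TRUE)
  if (!all(c("t", "x", "y") %in% names(tab)))
    stop("trajectory table must have columns 't', 'x', 'y'")
  tt <- as.numeric(tab$t)
  if (length(tt) < 2) stop("trajectory table needs at least two samples")
  steps <- diff(tt)
  if (any(steps <= 0))
    stop("time column must be strictly increasing")
  srcDt <- stats::median(steps)
  if (max(abs(steps - srcDt)) > 1e-6 * srcDt)
    stop("time column must be uniformly sampled")
  ratio <- srcDt / targetDt
  if (abs(ratio - round(ratio)) > 1e-6)
    stop("'targetDt' must divide the source time step")
  tNew <- seq(tt[1L], tt[length(tt)], by = targetDt)
  x <- stats::approx(tt, tab$x, xout = tNew)$y
  y <- stats::approx(tt, tab$y, xout = tNew)$y
  if (is.null(arenaHalfWidth))
    arenaHalfWidth <- max(abs(c(x, y)))
  newTrajectory(t = tNew - tNew[1L], x = x, y = y, dt = targetDt,
                arenaHalfWidth = arenaHalfWidth)
}

#' Write a trajectory to a delimited file
#'
#' Emits a headered CSV with columns `t, x, y, speed, heading`; the `t, x,
#' y` columns round-trip through [readTrajectory()].
#'
#' @param traj a [Trajectory-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
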