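test_that("baseline theta phase follows the cosine convention", {
  expect_equal(baselineThetaPhase(0), 0)
  halfPeriod <- 1 / 12
  expect_equal(abs(baselineThetaPhase(halfPeriod)), pi)
  # matches the Hilbert phase of the sampled cosine away from edges
  t <- seq(0, 20 - 0.002, by = 0.002)
  hp <- Arg(analyticSignal(cos(2 * pi * 6 * t)))
  mid <- 2000:8000
  d <- oscgrid:::wrapPhase(baselineThetaPhase(t[mid]) - hp[mid])
  expect_lt(max(abs(d)), 0.01)
})

test_that("spike subsampling keeps one spike per membrane theta cycle", {
  p <- cellParams()
  dt <- p@dt
  t <- seq(0, 4 - dt, by = dt)
  mpo <- sin(2 * pi * 6 * t)
  mkTrace <- function(spike) {
    new("MembraneTrace", t = t, Vm = rep(-60, length(t)),
        I = rep(0, length(t)), spike = spike, dt = dt,
        cellParams = p, bandParams = bandParams())
  }
  # one contiguous run inside one cycle
  spike <- rep(FALSE, length(t))
  spike[120:140] <- TRUE
  expect_length(subsampleSpikesToThetaPeaks(mkTrace(spike), mpo), 1)
  # runs in two separate cycles
  spike[290:300] <- TRUE
  expect_length(subsampleSpikesToThetaPeaks(mkTrace(spike), mpo), 2)
  # retained sample is the run sample nearest each cycle peak
  # (cycle peaks of sin(2*pi*6*t) at t = 1/24 + k/6: 0.2083, 0.5417)
  idx <- subsampleSpikesToThetaPeaks(mkTrace(spike), mpo)
  expect_equal(idx, c(120L, 290L))
  expect_length(subsampleSpikesToThetaPeaks(mkTrace(rep(FALSE, length(t))),
                                            mpo), 0)
})

test_that("pass index is the analytic phase of the field-index series", {
  t <- seq(0, 20 - 0.002, by = 0.002)
  fi <- 0.5 + 0.4 * sin(2 * pi * 0.25 * t)
  pass <- passIndex(fi)
  mid <- 2000:8000
  expected <- oscgrid:::wrapPhase(2 * pi * 0.25 * t - pi / 2)
  expect_lt(max(abs(oscgrid:::wrapPhase(pass[mid] - expected[mid]))),
            0.02)
  expect_error(passIndex(rep(0.3, 100)), "constant")

  # symmetric bump: monotone sweep crossing 0 at the peak
  bump <- exp(-(t - 10)^2 / 2)
  pb <- passIndex(bump)
  core <- abs(t - 10) < 1.5
  expect_true(all(diff(pb[core]) > 0))
  expect_lt(abs(pb[which.max(bump)]), 0.05)
})

test_that("circular-linear correlation recovers known slopes", {
  set.seed(61)
  x <- runif(200, 0, 2)
  for (slope in c(-2, 2)) {
    ph <- oscgrid:::wrapPhase(slope * x + rnorm(200, 0, 0.3))
    cl <- circularLinearCorr(ph, x, slopeRange = c(-1, 1))
    expect_equal(cl$slope, slope, tolerance = 0.2)
    expect_equal(sign(cl$rho), sign(slope))
    expect_gt(abs(cl$rho), 0.8)
    expect_lt(cl$p, 0.05)
  }
  phN <- runif(200, -pi, pi)
  clN <- circularLinearCorr(phN, x)
  expect_lt(abs(clN$rho), 0.2)
  expect_gt(clN$p, 0.05)
  expect_error(circularLinearCorr(phN, rep(1, 200)), "degenerate")
  expect_error(circularLinearCorr(phN[1:4], x[1:4]), "at least 5")
})

test_that("straight-line simulation precesses against baseline theta", {
  s <- straightSim()
  pos <- precessionAnalysis(s$trace, s$traj, mode = "position")
  expect_lt(pos@rho, -0.5)
  expect_lt(pos@p, 0.05)
  # within each field, phase decreases with position
  cl <- spikeClusters(pos@linear)
  for (k in unique(cl)) {
    ph <- pos@phase[order(pos@linear)][cl == k]
    if (length(ph) >= 5)
      expect_gt(mean(diff(ph) < 0), 0.8)
  }
  pas <- precessionAnalysis(s$trace, s$traj, mode = "pass_index")
  expect_lt(pas@rho, -0.5)
  expect_lt(pas@p, 0.05)
})

test_that("phase-locked spikes give a zero correlation", {
  # 5 Hz rhythm: the sample grid hits the same phase every cycle exactly
  p <- cellParams()
  dt <- p@dt
  t <- seq(0, 30 - dt, by = dt)
  spike <- abs(oscgrid:::wrapPhase(2 * pi * 5 * t)) < 1e-9
  tr <- new("MembraneTrace", t = t, Vm = rep(-60, length(t)),
            I = rep(0, length(t)), spike = spike, dt = dt,
            cellParams = p, bandParams = bandParams())
  idx <- subsampleSpikesToThetaPeaks(tr, sin(2 * pi * 5 * t))
  ph <- baselineThetaPhase(t[idx], omegaB = 2 * pi * 5)
  cl <- circularLinearCorr(ph, t[idx], slopeRange = c(-0.5, 0.5))
  expect_equal(cl$rho, 0)
})

test_that("band populations precess against their own baselines in-field", {
  # straight eastward pass: the 0-degree population's output bumps move
  # to earlier phases of its own baseline as the field is traversed
  p <- bandParams(beta = 0.00385)
  traj <- straightLineTrajectory(c(-100, 0), c(0, 0), speed = 5)
  act <- bandActivity(traj, p)[, 1]
  n <- length(act)
  # activity bumps: local maxima above 0.9, one per theta cycle in-field
  i <- 2:(n - 1L)
  pks <- i[act[i] > act[i - 1L] & act[i] >= act[i + 1L] & act[i] > 0.9]
  pks <- pks[traj@x[pks] < -60]          # first band field only
  expect_gt(length(pks), 10)
  # bump occurs at own-baseline phase -delta/2 with delta the relative
  # VCO phase; as delta grows through the field the bump phase falls
  lag <- oscgrid:::wrapPhase(p@omegaB * traj@t[pks])
  delta <- p@gain * p@beta * (traj@x[pks] + 100)
  expect_equal(lag, -delta / 2, tolerance = 0.15)
  expect_true(all(diff(lag) < 0))
})
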