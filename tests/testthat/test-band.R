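test_that("angular difference wraps to (-180, 180]", {
  expect_equal(angularDifference(90, 30), 60)
  expect_equal(angularDifference(350, 10), -20)
  expect_equal(angularDifference(180, -180), 0)
  expect_equal(angularDifference(0, 180), 180)   # boundary maps to +180
})

test_that("sigmoid rectification passes zero and saturates as expected", {
  expect_equal(sigmoidActivation(0), 0)
  expect_equal(sigmoidActivation(1), 0.482014, tolerance = 1e-6)
  expect_equal(sigmoidActivation(2), 0.964028, tolerance = 1e-6)
  x <- seq(-2, 2, by = 0.01)
  expect_true(all(diff(sigmoidActivation(x)) >= 0))
})

test_that("direction gate admits a 180-degree arc, boundary inclusive", {
  expect_equal(directionGate(90, 0), 1)
  expect_equal(directionGate(91, 0), 0)
  expect_equal(directionGate(0, 0), 1)
  expect_equal(directionGate(269.9, 0), 0)
  expect_equal(directionGate(270, 0), 1)
})

test_that("VCO phase accumulates omega_b plus the projected velocity term", {
  p <- bandParams()
  still <- straightLineTrajectory(c(0, 0), c(1e-9, 0), speed = 1e-9 / 10)
  # zero-speed limit: phase advances at exactly omega_b
  th <- bandPhases(still, p)
  n <- length(still@t)
  expect_equal(th[n, 1], p@omegaB * still@t[n], tolerance = 1e-4)

  # motion perpendicular to the preferred direction adds nothing
  north <- straightLineTrajectory(c(0, 0), c(0, 50), speed = 10)
  thN <- bandPhases(north, p)
  expect_equal(thN[nrow(thN), 1],
               p@omegaB * north@t[nrow(thN)], tolerance = 1e-6)

  # motion along the preferred direction adds gain*beta*s*T
  east <- straightLineTrajectory(c(0, 0), c(50, 0), speed = 10)
  thE <- bandPhases(east, p)
  tEnd <- east@t[nrow(thE)]
  expect_equal(thE[nrow(thE), 1] - p@omegaB * tEnd,
               p@gain * p@beta * 10 * tEnd, tolerance = 1e-6)
})

test_that("relative VCO phase equals gain*beta times projected displacement", {
  p <- bandParams()
  tr <- randomWalk(20, seed = 13)
  th <- bandPhases(tr, p)
  n <- length(tr@t)
  for (k in c(1, 3, 5)) {
    pref <- p@phiPreferred[k] * pi / 180
    proj <- c(0, cumsum(tr@dx[-n] * cos(pref) + tr@dy[-n] * sin(pref)))
    rel <- th[, k] - p@omegaB * tr@t - p@phiOffset[k] * pi / 180
    expect_equal(rel, p@gain * p@beta * proj, tolerance = 1e-8)
  }
})

test_that("band output respects the gate, rectification and bounds", {
  p <- bandParams()
  east <- straightLineTrajectory(c(0, 0), c(20, 0), speed = 10)
  act <- bandActivity(east, p)
  # populations at 120, 180, 240 degrees are gated off for heading 0
  expect_true(all(act[, 3:5] == 0))
  expect_true(all(act >= 0))
  expect_true(all(act <= sigmoidActivation(2) + 1e-12))
  # ungated activity is nonzero for all populations
  full <- bandActivity(east, p, gate = FALSE)
  expect_true(all(colSums(full) > 0))
})

test_that("at most four populations are simultaneously active", {
  tr <- randomWalk(60, seed = 17)
  act <- bandActivity(tr, bandParams())
  gates <- vapply(seq(0, 300, by = 60),
                  function(pref) directionGate(tr@heading, pref),
                  numeric(length(tr@t)))
  expect_lte(max(rowSums(gates)), 4)
  expect_gte(min(rowSums(gates)), 3)
})

test_that("summed input scales, sums and stays non-negative", {
  act <- matrix(0, 5, 6)
  expect_equal(summedInput(act), rep(0, 5))
  act[1, 2] <- sigmoidActivation(2)
  expect_equal(summedInput(act)[1], 100 * sigmoidActivation(2))
  tr <- randomWalk(30, seed = 19)
  expect_true(all(summedInput(bandActivity(tr, bandParams())) >= 0))
})

test_that("zero baseline offsets keep field positions but boost theta", {
  traj <- straightSim()$traj
  spread <- straightSim()$trace
  zero <- simulateGridCell(traj, bandParams(beta = 0.00385,
                                            phiOffset = rep(0, 6)))
  cs <- spikeClusters(traj@x[spikeSamples(spread)])
  cz <- spikeClusters(traj@x[spikeSamples(zero)])
  centS <- tapply(sort(traj@x[spikeSamples(spread)]), cs, mean)
  centZ <- tapply(sort(traj@x[spikeSamples(zero)]), cz, mean)
  expect_equal(length(centS), length(centZ))
  expect_true(all(abs(centS - centZ) < 10))
  envS <- mpoEnvelope(amplitudeSeries(spread))
  envZ <- mpoEnvelope(amplitudeSeries(zero))
  expect_gt(mean(envZ), mean(envS))
})
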