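test_that("rate maps are occupancy-normalized with NA for unvisited bins", {
  s <- defaultSim()
  rm5 <- rateMap(s$traj, spikeSamples(s$trace))
  rate <- rateMatrix(rm5)
  ok <- !is.na(rate)
  expect_true(any(ok))
  expect_equal(rate[ok], (rm5@count / rm5@occupancy)[ok])
  expect_true(all(is.na(rate[rm5@occupancy < 2 * s$traj@dt])))
  expect_true(all(rate[ok] >= 0))
})

test_that("spikes confined to one block push that block's percentile up", {
  # 60 s raster-scan trajectory covering a 40 cm arena uniformly
  dt <- 0.002
  n <- 30000
  xs <- rep(seq(-19, 19, by = 2), each = 1500)
  ys <- rep(seq(-19, 19, length.out = 1500), times = 20)
  traj <- oscgrid:::newTrajectory(seq(0, by = dt, length.out = n),
                                  xs, ys, dt, arenaHalfWidth = 20)
  spikes <- rep(FALSE, n)
  inBlock <- abs(traj@x) < 7.5 & abs(traj@y) < 7.5
  spikes[inBlock][seq(1, sum(inBlock), by = 4)] <- TRUE
  null <- shuffleNull(traj, spikes, binSize = 5, nShuffles = 200,
                      seed = 31)
  blockBins <- abs(null$xCenters) < 7.5
  expect_true(all(null$percentile[blockBins, blockBins] >= 0.85,
                  na.rm = TRUE))
  cls <- classifyFields(null)
  expect_true(any(fieldLabels(cls)[blockBins, blockBins] == "in_field"))
})

test_that("zero spikes yield no classified in-field bins", {
  tr <- randomWalk(30, seed = 37)
  null <- shuffleNull(tr, rep(FALSE, length(tr@t)), nShuffles = 50,
                      seed = 1)
  expect_true(all(is.na(null$percentile)))
  cls <- classifyFields(null)
  expect_true(all(fieldLabels(cls) == "unassigned"))
})

test_that("uniform random spiking stays near the nominal false-positive rate", {
  dt <- 0.002
  n <- 50000
  xs <- rep(seq(-19, 19, by = 2), each = 2500)
  ys <- rep(seq(-19, 19, length.out = 2500), times = 20)
  traj <- oscgrid:::newTrajectory(seq(0, by = dt, length.out = n),
                                  xs, ys, dt, arenaHalfWidth = 20)
  set.seed(41)
  spikes <- runif(n) < 0.02
  null <- shuffleNull(traj, spikes, binSize = 5, nShuffles = 400,
                      seed = 41)
  pct <- null$percentile[!is.na(null$percentile)]
  expect_lt(mean(pct <= 0.05), 0.15)   # few spuriously low bins
  expect_lt(mean(pct >= 0.85), 0.30)   # few spuriously high bins
  cls <- classifyFields(null)
  expect_lt(mean(fieldLabels(cls) == "in_field"), 0.05)
})

test_that("classification applies the block and extension rules", {
  mk <- function(pct) list(percentile = pct,
                           xCenters = seq_len(nrow(pct)),
                           yCenters = seq_len(ncol(pct)), binSize = 5,
                           nShuffles = 100,
                           sampleBin = rep(1L, 4))
  pct <- matrix(0.5, 7, 7)
  pct[3:5, 3:5] <- 0.9          # qualifying 3x3 block
  pct[2, 3] <- 0.75             # adjacent extension bin
  pct[6, 6] <- 0.75             # adjacent (diagonal) extension bin
  pct[1, 1] <- 0.75             # not adjacent: stays unassigned
  cls <- classifyFields(mk(pct))
  lab <- fieldLabels(cls)
  expect_true(all(lab[3:5, 3:5] == "in_field"))
  expect_equal(lab[2, 3], "in_field")
  expect_equal(lab[6, 6], "in_field")
  expect_equal(lab[1, 1], "unassigned")

  expect_true(all(fieldLabels(classifyFields(mk(matrix(0.5, 5, 5)))) ==
                    "unassigned"))

  pct2 <- matrix(0.5, 5, 5)
  pct2[2:3, 2:3] <- 0.01        # qualifying 2x2 low block
  pct2[5, 5] <- 0.01            # isolated low bin: unassigned
  lab2 <- fieldLabels(classifyFields(mk(pct2)))
  expect_true(all(lab2[2:3, 2:3] == "out_of_field"))
  expect_equal(lab2[5, 5], "unassigned")
})

test_that("classification partitions the arena and is reproducible", {
  s <- defaultSim()
  lab <- fieldLabels(s$cls)
  expect_equal(sum(table(lab)), length(lab))
  null2 <- shuffleNull(s$traj, spikeSamples(s$trace), nShuffles = 200,
                       seed = 101)
  expect_identical(null2$percentile, s$null$percentile)
})

test_that("field-index map is a smoothed unit-normalized rate map", {
  # point source: all spikes at one position on a uniform scan
  dt <- 0.002
  n <- 40000
  xs <- rep(seq(-19.5, 19.5, by = 1), each = 1000)
  ys <- rep(seq(-19.5, 19.5, length.out = 1000), times = 40)
  traj <- oscgrid:::newTrajectory(seq(0, by = dt, length.out = n),
                                  xs, ys, dt, arenaHalfWidth = 20)
  spikes <- abs(traj@x - 0.5) < 0.5 & abs(traj@y - 0.5) < 0.5
  fim <- fieldIndexMap(traj, spikes)
  expect_true(all(fim$map >= 0 & fim$map <= 1))
  expect_equal(max(fim$map), 1)
  peak <- which(fim$map == 1, arr.ind = TRUE)[1, ]
  expect_lt(abs(fim$xCenters[peak[1]] - 0.5), 1.5)
  # profile matches a 5 cm SD Gaussian within discretization error
  prof <- fim$map[, peak[2]]
  d <- fim$xCenters - fim$xCenters[peak[1]]
  expect_equal(prof, exp(-d^2 / (2 * 25)), tolerance = 0.05)

  expect_error(fieldIndexMap(traj, rep(FALSE, n)), "at least one spike")
  expect_warning(fieldIndexMap(traj, rep(TRUE, n)), "degenerate")
})

test_that("field-index series samples the nearest bin", {
  s <- defaultSim()
  fim <- fieldIndexMap(s$traj, spikeSamples(s$trace))
  fi <- fieldIndexSeries(s$traj, fim)
  expect_equal(length(fi), length(s$traj@t))
  expect_true(all(fi >= 0 & fi <= 1))
  # a sample exactly at a bin center returns that bin's value
  ix <- 25L; iy <- 40L
  trj <- oscgrid:::newTrajectory(c(0, 0.002),
                                 rep(fim$xCenters[ix], 2),
                                 rep(fim$yCenters[iy], 2), 0.002, 100)
  expect_equal(fieldIndexSeries(trj, fim),
               rep(fim$map[ix, iy], 2))
  cmap <- fim; cmap$map[] <- 0.42
  expect_true(all(fieldIndexSeries(s$traj, cmap) == 0.42))
})

test_that("gridness separates hexagonal, random and square maps", {
  centers <- seq(-97.5, 97.5, by = 5)
  xy <- expand.grid(x = centers, y = centers)
  hexMap <- function(spacing, angles = c(0, 60, 120)) {
    k <- 4 * pi / (sqrt(3) * spacing)
    m <- rep(0, nrow(xy))
    for (a in angles * pi / 180)
      m <- m + cos(k * (xy$x * cos(a) + xy$y * sin(a)))
    matrix(pmax(m, 0), length(centers))
  }
  hex <- gridnessScore(hexMap(60))
  expect_gt(hex$score, 0.5)

  sq <- matrix(pmax(cos(2 * pi * outer(centers, centers * 0, "+") / 50) +
                      cos(2 * pi * outer(centers * 0, centers, "+") / 50),
                    0), length(centers))
  expect_lt(gridnessScore(sq)$score, 0)

  set.seed(51)
  noise <- oscgrid:::gaussSmooth(matrix(runif(1600), 40), 2)
  expect_lt(abs(gridnessScore(noise)$score), 0.4)

  sparse <- matrix(NA_real_, 40, 40)
  sparse[1:5, 1:5] <- 1
  expect_error(gridnessScore(sparse), "coverage")
})
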