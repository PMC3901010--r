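# Shared fixtures, built once per test run. Short simulations keep the
# unit tests fast; the acceptance tests run the full protocols.

fixtureEnv <- new.env(parent = emptyenv())

# 300 s default random walk + simulation + classification
defaultSim <- function() {
  if (is.null(fixtureEnv$sim)) {
    traj <- randomWalk(300, seed = 101)
    trace <- simulateGridCell(traj)
    null <- shuffleNull(traj, spikeSamples(trace), nShuffles = 200,
                        seed = 101)
    fixtureEnv$sim <- list(traj = traj, trace = trace, null = null,
                           cls = classifyFields(null))
  }
  fixtureEnv$sim
}

# straight-line run with the two-field spacing configuration
straightSim <- function() {
  if (is.null(fixtureEnv$straight)) {
    traj <- straightLineTrajectory(c(-100, 0), c(100, 0), speed = 5)
    trace <- simulateGridCell(traj, bandParams(beta = 0.00385))
    fixtureEnv$straight <- list(traj = traj, trace = trace)
  }
  fixtureEnv$straight
}

# cluster spike x-positions separated by gaps larger than `gap` cm
spikeClusters <- function(xs, gap = 10) {
  if (!length(xs)) return(integer())
  xs <- sort(xs)
  cumsum(c(1, diff(xs) > gap))
}

# minimal classification object from a per-sample label vector
labelClassification <- function(lab) {
  m <- matrix("unassigned", 2, 2)
  new("FieldClassification", percentile = matrix(NA_real_, 2, 2),
      label = m, sampleLabel = lab, xCenters = c(-1, 1),
      yCenters = c(-1, 1), binSize = 2, nShuffles = 0)
}
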