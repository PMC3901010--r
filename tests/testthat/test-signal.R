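t60 <- seq(0, 60 - 0.002, by = 0.002)

test_that("zero-phase band-pass keeps in-band sines and rejects the rest", {
  x <- sin(2 * pi * 6 * t60)
  mid <- 1000:28000
  y <- bandpassZeroPhase(x, 5, 10, 500)
  expect_equal(max(abs(y[mid])), 1, tolerance = 0.1)
  expect_gt(cor(y[mid], x[mid]), 0.999)          # no phase shift
  expect_lt(max(abs(bandpassZeroPhase(x, 0.1, 3, 500)[mid])), 0.2)
  expect_lt(max(abs(bandpassZeroPhase(rep(3, 5000), 1, 10, 500))), 1e-4)
  expect_error(bandpassZeroPhase(1:5, 5, 10, 500), "too short")
})

test_that("analytic signal recovers envelope and phase of a sine", {
  x <- 2.5 * sin(2 * pi * 6 * t60)
  a <- analyticSignal(x)
  mid <- 2000:28000
  expect_equal(mean(Mod(a)[mid]), 2.5, tolerance = 0.01)
  # instantaneous frequency = 6 Hz
  dphi <- diff(Arg(a)[mid])
  dphi <- dphi[abs(dphi) < pi]
  expect_equal(mean(dphi) / 0.002 / (2 * pi), 6, tolerance = 0.01)
})

test_that("amplitude decomposition handles constants and sines", {
  lab <- labelClassification(ifelse(floor(t60) %% 2 == 0,
                                    "in_field", "out_of_field"))
  amp <- amplitudeSeries(rep(-67, length(t60)), lab, dt = 0.002)
  expect_true(all(abs(dcShift(amp)) < 1e-6))
  expect_true(all(mpoEnvelope(amp) < 1e-6))

  vm <- 2.5 * sin(2 * pi * 6 * t60)
  amp2 <- amplitudeSeries(vm, dt = 0.002)
  expect_equal(mean(mpoEnvelope(amp2)[2000:28000]), 2.5,
               tolerance = 0.05)
})

test_that("a 3 mV in-field boxcar is recovered by the DC pipeline", {
  inF <- floor(t60) %% 2 == 0
  lab <- labelClassification(ifelse(inF, "in_field", "out_of_field"))
  vm <- -67 + 3 * inF
  amp <- amplitudeSeries(vm, lab, dt = 0.002)
  expect_equal(mean(dcShift(amp)[lab@sampleLabel == "out_of_field"]), 0,
               tolerance = 1e-9)
  d <- deltaAmplitudes(amp, lab)
  expect_equal(unname(d["dc"]), 3, tolerance = 0.15)
  expect_lt(abs(d["mpo"]), 0.3)
})

test_that("the decomposition is linear in its input", {
  x1 <- 1.5 * sin(2 * pi * 0.7 * t60)
  x2 <- 0.8 * sin(2 * pi * 6 * t60)
  a1 <- amplitudeSeries(x1, dt = 0.002)
  a2 <- amplitudeSeries(x2, dt = 0.002)
  a12 <- amplitudeSeries(x1 + x2, dt = 0.002)
  expect_equal(dcShift(a12), dcShift(a1) + dcShift(a2),
               tolerance = 1e-8)
})

test_that("delta amplitudes require both label classes", {
  lab <- labelClassification(rep("out_of_field", length(t60)))
  amp <- amplitudeSeries(sin(2 * pi * 6 * t60), lab, dt = 0.002)
  expect_error(deltaAmplitudes(amp, lab), "in-field")
})

test_that("an added field rhythm raises the out-of-field theta envelope", {
  expect_equal(addFieldRhythm(c(1, 2), c(0, 0.002), amp = 0), c(1, 2))
  vm <- rep(-67, length(t60))
  withRhythm <- addFieldRhythm(vm, t60, freq = 6.5, amp = 1.2)
  env <- mpoEnvelope(amplitudeSeries(withRhythm, dt = 0.002))
  expect_equal(mean(env[2000:28000]), 1.2, tolerance = 0.06)

  s <- defaultSim()
  base <- amplitudeSeries(s$trace)
  contaminated <- amplitudeSeries(
    addFieldRhythm(membranePotential(s$trace), s$trace@t, amp = 1),
    dt = 0.002)
  out <- sampleLabels(s$cls) == "out_of_field"
  expect_gt(mean(mpoEnvelope(contaminated)[out]),
            mean(mpoEnvelope(base)[out]))
})

test_that("a single tau-sweep cell is deterministic under a fixed seed", {
  a <- tauSweep(tauMs = 50, nReps = 1, duration = 120, nShuffles = 50,
                seed = 3)
  b <- tauSweep(tauMs = 50, nReps = 1, duration = 120, nShuffles = 50,
                seed = 3)
  expect_identical(a, b)
})
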