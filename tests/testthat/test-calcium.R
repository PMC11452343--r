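cfg <- analysisConfig()

test_that("dF/F uses per-trial 10-s baselines and is gain-invariant", {
  st <- stimSchedule(nTrials = 2, firstOnset = 12, stimDur = 10, iti = 15)
  ft <- seq(0, 48, by = 1 / 7.1)
  ## constant F -> dF/F identically 0; doubling -> 1
  tr0 <- new("FluorescenceTrace", roi = "r", frameTimes = ft,
             F = rep(50, length(ft)), dff = numeric(), f0 = numeric(),
             trial = integer(), compartment = "soma")
  d0 <- computeDff(tr0, st, cfg)
  expect_equal(dff(d0), rep(0, length(ft)))
  expect_equal(baselineF0(d0), c(50, 50))

  Fv <- rep(50, length(ft))
  Fv[ft >= 12 & ft < 22] <- 100
  tr1 <- new("FluorescenceTrace", roi = "r", frameTimes = ft, F = Fv,
             dff = numeric(), f0 = numeric(), trial = integer(),
             compartment = "soma")
  d1 <- computeDff(tr1, st, cfg)
  expect_equal(unique(dff(d1)[ft >= 12 & ft < 22]), 1)

  ## multiplying F by a positive gain leaves dF/F unchanged
  tr2 <- tr1
  tr2@F <- Fv * 3.7
  expect_equal(dff(computeDff(tr2, st, cfg)), dff(d1), tolerance = 1e-12)

  ## missing baseline span skips the trial with a warning
  stBad <- stimSchedule(nTrials = 1, firstOnset = 3)
  expect_warning(computeDff(tr0, stBad, cfg), "skipped")
})

test_that("voxel binning averages 2x2 blocks and preserves z-planes", {
  A <- array(0, c(2, 3, 4, 4))
  plane <- matrix(1:16, 4, 4)
  for (t in 1:2) for (z in 1:3) A[t, z, , ] <- plane * t
  mv <- new("VoxelMovie", F = A, frameTimes = c(0, 1), binFactor = 1,
            isDff = FALSE)
  b <- binVoxels(mv, 2L)
  expect_identical(dim(movieData(b)), c(2L, 3L, 2L, 2L))
  want <- matrix(c(mean(plane[1:2, 1:2]), mean(plane[3:4, 1:2]),
                   mean(plane[1:2, 3:4]), mean(plane[3:4, 3:4])), 2, 2)
  expect_equal(movieData(b)[1, 1, , ], want)
  expect_equal(movieData(b)[2, 2, , ], want * 2)

  ## constant movie stays constant; remainder columns are dropped
  C <- array(5, c(2, 1, 5, 5))
  mvc <- new("VoxelMovie", F = C, frameTimes = c(0, 1), binFactor = 1,
             isDff = FALSE)
  bc <- binVoxels(mvc, 2L)
  expect_identical(dim(movieData(bc))[3:4], c(2L, 2L))
  expect_true(all(movieData(bc) == 5))
})

test_that("responsiveness t-test flags stimulus-driven neurons", {
  st <- stimSchedule(nTrials = 12)
  ## stimulus-locked activity: gains on song states that occur only
  ## during stimulation under the default generator
  hits <- 0
  for (s in 1:20) {
    ex <- simulateTransitionExperiment(seed = 3000 + s,
                                       gains = c(quiet = 0, pulse = 1,
                                                 sine = 1, flight = 0),
                                       nTrials = 12, sigma = 5)
    r <- responsivenessTest(ex$trace, ex$stim, config = cfg)
    if (r$p < 0.05 && r$meanResponse > 0) hits <- hits + 1
  }
  expect_gte(hits, 19)

  ## all-zero responses: not significant, mean 0
  ft <- seq(0, 100, by = 1 / 7.1)
  flat <- new("FluorescenceTrace", roi = "r", frameTimes = ft,
              F = rep(10, length(ft)), dff = numeric(), f0 = numeric(),
              trial = integer(), compartment = "soma")
  st2 <- stimSchedule(nTrials = 3, firstOnset = 12, stimDur = 10, iti = 15)
  flat <- computeDff(flat, st2, cfg)
  r0 <- responsivenessTest(flat, st2, config = cfg)
  expect_equal(r0$meanResponse, 0)
  expect_false(r0$responsive)
})

test_that("transition-triggered averages align segments on the boundary", {
  ## single event: average equals the segment
  d <- sin(seq(0, 8 * pi, length.out = 200))
  tr <- traceFromDff(d)
  ev <- data.frame(kind = "pulse_to_sine", boundary = 100L,
                   preBout = 1, postBout = 1)
  tta <- transitionTriggeredAverage(tr, ev, window = c(-0.5, 0.5))
  offs <- seq(floor(-0.5 / 0.141), ceiling(0.5 / 0.141))
  expect_equal(tta$mean, d[100 + offs])
  expect_equal(tta$n, rep(1, nrow(tta)))

  ## periodic signal, events one period apart: average equals one period
  period <- 20L
  d2 <- rep(cos(2 * pi * (0:(period - 1)) / period), 10)
  tr2 <- traceFromDff(d2)
  ev2 <- data.frame(kind = "sine_to_pulse",
                    boundary = as.integer(seq(41, 141, by = period)),
                    preBout = 1, postBout = 1)
  tta2 <- transitionTriggeredAverage(tr2, ev2, window = c(-1, 1))
  one <- transitionTriggeredAverage(tr2, ev2[1, ], window = c(-1, 1))
  expect_equal(tta2$mean, one$mean, tolerance = 1e-12)

  ## truncated windows are excluded
  evEdge <- data.frame(kind = "pulse_to_sine", boundary = c(2L, 100L),
                       preBout = 1, postBout = 1)
  ttaE <- transitionTriggeredAverage(tr, evEdge, window = c(-1, 1))
  expect_equal(unique(ttaE$n), 1)
})

test_that("transition deltas implement the compartment windows and are linear", {
  ## soma: post = frames +3,+4 (boundary+2, boundary+3); trans = b-1, b
  d <- rep(0.5, 20)
  d[12:13] <- 0.8
  tr <- traceFromDff(d, compartment = "soma")
  ev <- data.frame(kind = "sine_to_pulse", boundary = 10L,
                   preBout = 1, postBout = 1)
  out <- transitionDelta(tr, ev, "soma", config = cfg)
  expect_equal(out$delta, 0.3)
  expect_equal(out$baseMean, 0.5)

  ## neurite: post = frames +2,+3 (boundary+1, boundary+2)
  dn <- rep(0.5, 20)
  dn[11:12] <- 0.9
  outN <- transitionDelta(traceFromDff(dn), ev, "neurite", config = cfg)
  expect_equal(outN$delta, 0.4, tolerance = 1e-12)

  ## constant trace -> delta 0; scaling the trace scales delta
  expect_equal(transitionDelta(traceFromDff(rep(0.7, 20)), ev, "soma",
                               config = cfg)$delta, 0)
  sc <- transitionDelta(traceFromDff(d * 3), ev, "soma", config = cfg)
  expect_equal(sc$delta, 0.9, tolerance = 1e-12)

  ## masked frame in a window excludes the event
  b <- frameTrackFromStates(rep("quiet", 20),
                            masked = replace(rep(FALSE, 20), 12, TRUE))
  outM <- transitionDelta(tr, ev, "soma", binned = b, config = cfg)
  expect_equal(nrow(outM), 0)
  expect_equal(attr(outM, "nExcluded"), 1)
})

test_that("normalized transition change enforces event and baseline floors", {
  resp <- data.frame(delta = rep(0.3, 6), baseMean = rep(0.5, 6))
  out <- normalizedTransitionChange(resp, cfg)
  expect_equal(out$value, 0.6)
  expect_false(out$excluded)

  ## baseline below the 0.1 floor -> excluded
  low <- data.frame(delta = rep(0.3, 6), baseMean = rep(0.05, 6))
  expect_true(normalizedTransitionChange(low, cfg)$excluded)

  ## fewer than 5 events -> excluded
  few <- data.frame(delta = rep(0.3, 4), baseMean = rep(0.5, 4))
  expect_true(normalizedTransitionChange(few, cfg)$excluded)
})

test_that("quiet-to-pulse deltas subtract the 2-s windows around the transition", {
  ## step from 0 to 1 at the boundary frame
  d <- c(rep(0, 30), rep(1, 30))
  tr <- traceFromDff(d)
  ev <- data.frame(kind = "quiet_to_pulse", boundary = 31L,
                   preBout = 3, postBout = 3)
  expect_equal(unname(quietToPulseDelta(tr, ev, cfg)), 1)

  ## constant trace -> 0
  expect_equal(unname(quietToPulseDelta(traceFromDff(rep(0.4, 60)), ev,
                                        cfg)), 0)

  ## windows out of range -> event dropped
  evEdge <- data.frame(kind = "quiet_to_pulse", boundary = 3L,
                       preBout = 3, postBout = 3)
  expect_length(quietToPulseDelta(tr, evEdge, cfg), 0)
})

test_that("decay fits recover the half-time of an exact exponential", {
  t <- (0:5) * 0.141
  fit <- fitDecayHalftime(exp(-t / 0.5), t, cfg)
  expect_false(fit@flagged)
  expect_equal(halfDecay(fit), log(2) * 0.5, tolerance = 1e-6)
  expect_equal(fit@rate, 2, tolerance = 1e-6)

  ## constant positive trace -> rate ~ 0, flagged or half-decay huge
  flat <- fitDecayHalftime(rep(1, 6), t, cfg)
  expect_lt(abs(flat@rate), 1e-6)

  ## growing trace -> flagged, half-decay undefined
  grow <- fitDecayHalftime(exp(t / 0.5), t, cfg)
  expect_true(grow@flagged)
  expect_true(is.na(halfDecay(grow)))
})
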