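cfg <- analysisConfig()

test_that("median smoothing removes short spurs and matches the naive oracle", {
  ## constant track unchanged
  tr <- labelTrack(rep("sine", 200))
  expect_identical(trackLabels(smoothPredictions(tr, cfg)),
                   trackLabels(tr))

  ## single-sample pulse spur inside ambient removed by the 11-sample window
  lab <- rep("ambient", 41)
  lab[21] <- "pulse"
  sm <- smoothPredictions(labelTrack(lab), cfg)
  expect_true(all(trackLabels(sm) == "ambient"))

  ## random tracks match the naive sliding-median oracle
  set.seed(101)
  for (i in 1:25) {
    lab <- sample(c("pulse", "sine", "ambient", "others", "flight"),
                  300, replace = TRUE,
                  prob = c(0.3, 0.3, 0.3, 0.05, 0.05))
    got <- as.character(trackLabels(smoothPredictions(labelTrack(lab), cfg)))
    expect_identical(got, naiveSmooth(lab, cfg))
  }
})

test_that("smoothing a generator track with realistic bouts is idempotent", {
  st <- stimSchedule(nTrials = 2)
  tr <- simulateSongStates(songGenParams(st), seed = 42)
  once <- smoothPredictions(tr, cfg)
  twice <- smoothPredictions(once, cfg)
  expect_identical(trackLabels(once), trackLabels(twice))
})

test_that("pulse-train merging equals interval union under gap closing", {
  got <- mergePulseTrain(rbind(c(0, 0.010), c(0.050, 0.060),
                               c(0.120, 0.130)), 0.050)
  expect_equal(got$start, c(0, 0.120))
  expect_equal(got$end, c(0.060, 0.130))

  one <- mergePulseTrain(cbind(0.2, 0.5), 0.05)
  expect_equal(one, data.frame(start = 0.2, end = 0.5))
  expect_equal(nrow(mergePulseTrain(matrix(numeric(), 0, 2), 0.05)), 0)
  expect_error(mergePulseTrain(rbind(c(0, 1), c(0.5, 2)), 0.05),
               "non-overlapping")

  set.seed(7)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    starts <- sort(runif(n, 0, 2))
    ends <- starts + runif(n, 0.001, 0.04)
    ends <- pmin(ends, c(starts[-1], Inf) - 1e-6)
    segs <- cbind(starts, ends)
    gap <- runif(1, 0, 0.1)
    expect_equal(unname(as.matrix(mergePulseTrain(segs, gap))),
                 unname(as.matrix(naiveMerge(segs, gap))),
                 tolerance = 1e-12)
  }
})

test_that("frame binning applies strict thresholds and matches brute force", {
  ## 20% pulse occupancy in a frame -> flag (0.2 > 0.1)
  per <- cfg@labelPeriod
  lab <- rep("ambient", 400)
  lab[1:18] <- "pulse"  # 18/88 samples of frame 1 ~ 0.205
  b <- binToFrames(labelTrack(lab), frameTimes = c(0, 0.141, 0.282), cfg)
  expect_true(classFlags(b)[1, "pulse"])
  expect_identical(as.character(frameStates(b))[1], "pulse")

  ## mean exactly at the threshold is NOT an event (strict inequality)
  probs <- matrix(rep(c(0.1, 0.5, 0.4, 0, 0), each = 88), 88, 5)
  colnames(probs) <- c("pulse", "sine", "ambient", "others", "flight")
  pt <- new("ClassProbTrack", time = (0:87) * per, probs = probs,
            period = per)
  b2 <- binToFrames(pt, frameTimes = 0, cfg)
  expect_false(classFlags(b2)[1, "pulse"])
  expect_equal(unname(classMeans(b2)[1, "pulse"]), 0.1)

  ## random 10-frame constructions match the per-frame recomputation
  set.seed(33)
  for (i in 1:20) {
    n <- 10 * 88
    raw <- matrix(rexp(n * 5), n, 5)
    probs <- raw / rowSums(raw)
    colnames(probs) <- c("pulse", "sine", "ambient", "others", "flight")
    times <- (seq_len(n) - 1) * per
    ftimes <- (0:9) * 0.141
    pt <- new("ClassProbTrack", time = times, probs = probs, period = per)
    got <- classFlags(binToFrames(pt, ftimes, cfg))
    expect_identical(got, naiveBinFrames(times, probs, ftimes, cfg))
  }
})

test_that("frames outside the track span are undefined", {
  b <- binToFrames(labelTrack(rep("sine", 88)),
                   frameTimes = c(0, 0.141, 10), cfg)
  expect_identical(as.character(frameStates(b))[3], "undefined")
})

test_that("flight masking pads one second on each side", {
  states <- rep("quiet", 60)
  states[30] <- "flight"
  b <- frameTrackFromStates(states)
  m <- applyFlightMask(b, cfg)
  ft <- frameTimes(b)
  per <- b@framePeriod
  tFlight <- ft[30]
  expected <- ft < tFlight + per + 1 & (ft + per) > tFlight - 1
  expect_identical(frameMask(m), expected)

  ## no flight -> nothing masked
  b0 <- frameTrackFromStates(rep("quiet", 20))
  expect_false(any(frameMask(applyFlightMask(b0, cfg))))
})

test_that("transition detection matches exhaustive enumeration", {
  ## hand cases
  ev <- detectTypeTransitions(frameTrackFromStates(
    c("pulse", "pulse", "sine", "sine")))
  expect_equal(nrow(ev), 1)
  expect_identical(ev$kind, "pulse_to_sine")
  expect_equal(ev$boundary, 3)
  expect_equal(ev$preBout, 2 * 0.141)
  expect_equal(ev$postBout, 2 * 0.141)

  ev2 <- detectTypeTransitions(frameTrackFromStates(
    c("pulse", "sine", "pulse")))
  expect_identical(sort(ev2$kind), c("pulse_to_sine", "sine_to_pulse"))

  ## masked frame adjacent to the boundary suppresses the event
  ev3 <- detectTypeTransitions(frameTrackFromStates(
    c("pulse", "pulse", "sine"), masked = c(FALSE, TRUE, FALSE)))
  expect_equal(nrow(ev3), 0)

  ## random state strings against the exhaustive oracle
  set.seed(55)
  for (i in 1:50) {
    n <- sample(3:400, 1)
    states <- sample(c("pulse", "sine", "quiet", "flight", "undefined"),
                     n, replace = TRUE)
    masked <- runif(n) < 0.15
    got <- detectTypeTransitions(frameTrackFromStates(states, masked))
    want <- naiveTransitions(states, masked)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_identical(got$kind, want$kind)
      expect_equal(got$boundary, want$boundary)
      expect_equal(got$preBout, want$preLen * 0.141)
      expect_equal(got$postBout, want$postLen * 0.141)
    }
  }
})

test_that("adding flight frames never increases detected transitions", {
  set.seed(66)
  for (i in 1:20) {
    states <- sample(c("pulse", "sine", "quiet"), 300, replace = TRUE)
    b <- frameTrackFromStates(states)
    n0 <- nrow(detectTypeTransitions(applyFlightMask(b, cfg)))
    statesF <- states
    statesF[sample(300, 5)] <- "flight"
    bF <- frameTrackFromStates(statesF)
    nF <- nrow(detectTypeTransitions(applyFlightMask(bF, cfg)))
    expect_lte(nF, n0)
  }
})

test_that("quiet-to-pulse requires two continuous quiet seconds", {
  ## 15 quiet frames = 2.115 s -> event
  s1 <- c(rep("quiet", 15), rep("pulse", 3))
  ev1 <- detectQuietToPulse(frameTrackFromStates(s1), cfg)
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$boundary, 16)

  ## 1.5 s of quiet (10 frames = 1.41 s; 11 frames = 1.551 s) -> no event
  s2 <- c(rep("quiet", 11), rep("pulse", 3))
  expect_equal(nrow(detectQuietToPulse(frameTrackFromStates(s2), cfg)), 0)

  ## interrupted quiet resets the run
  s3 <- c(rep("quiet", 10), "sine", rep("quiet", 10), rep("pulse", 2))
  expect_equal(nrow(detectQuietToPulse(frameTrackFromStates(s3), cfg)), 0)
})

test_that("bout partition uses strictly-longer-than thresholds", {
  ev <- data.frame(kind = c("pulse_to_sine", "sine_to_pulse",
                            "pulse_to_sine"),
                   boundary = c(10L, 20L, 30L),
                   preBout = c(0.282, 0.845, 0.422),
                   postBout = c(0.845, 0.282, 0.704))
  tagged <- boutLengthPartition(ev, cfg)
  expect_identical(tagged$preTag, c("short", "long", "short"))  # 0.422 ties short
  expect_identical(tagged$postTag, c("long", "short", "short")) # 0.704 ties short
})
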