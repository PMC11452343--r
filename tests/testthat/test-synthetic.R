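test_that("song-state simulation is seed-deterministic and respects absorbing states", {
  st <- stimSchedule(nTrials = 2)
  p <- songGenParams(st)
  t1 <- simulateSongStates(p, seed = 11)
  t2 <- simulateSongStates(p, seed = 11)
  expect_identical(trackLabels(t1), trackLabels(t2))
  expect_identical(trackTimes(t1), trackTimes(t2))
  t3 <- simulateSongStates(p, seed = 12)
  expect_false(identical(trackLabels(t1), trackLabels(t3)))

  ## quiet absorbing in both regimes -> all-ambient track
  I <- diag(4)
  dimnames(I) <- list(c("quiet", "pulse", "sine", "flight"),
                      c("quiet", "pulse", "sine", "flight"))
  pAbs <- songGenParams(st, transOn = I, transOff = I)
  tAbs <- simulateSongStates(pAbs, seed = 1)
  expect_true(all(trackLabels(tAbs) == "ambient"))
})

test_that("generator parameters fail validation when rows do not sum to 1", {
  st <- stimSchedule(nTrials = 1)
  bad <- diag(4) * 0.9
  dimnames(bad) <- list(c("quiet", "pulse", "sine", "flight"),
                        c("quiet", "pulse", "sine", "flight"))
  expect_error(songGenParams(st, transOn = bad, transOff = bad),
               "sum to 1")
})

test_that("empirical pulse dwell matches the geometric mean within 3 SE", {
  ## one long stimulation epoch; interior bouts only
  st <- stimSchedule(nTrials = 1, firstOnset = 0, stimDur = 2500, iti = 0)
  p <- songGenParams(st, meanDwellOn = c(quiet = 0.3, pulse = 0.5,
                                         sine = 0.5, flight = 0.2))
  tr <- simulateSongStates(p, duration = 2500, seed = 21)
  r <- rle(as.character(trackLabels(tr)))
  bouts <- r$lengths[r$values == "pulse"] * samplePeriod(tr)
  bouts <- bouts[-c(1, length(bouts))]
  expect_gt(length(bouts), 1000)
  se <- sd(bouts) / sqrt(length(bouts))
  expect_lt(abs(mean(bouts) - 0.5), 3 * se)
})

test_that("class probabilities are rows of a stochastic matrix with the contracted argmax", {
  tr <- labelTrack(sample(c("pulse", "sine", "ambient"), 10000,
                          replace = TRUE))
  p0 <- simulateClassProbabilities(tr, flipNoise = 0, seed = 3)
  P <- classProbs(p0)
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-9)
  am <- colnames(P)[max.col(P)]
  expect_identical(am, as.character(trackLabels(tr)))

  p1 <- simulateClassProbabilities(tr, flipNoise = 0.1, seed = 4)
  err <- mean(colnames(classProbs(p1))[max.col(classProbs(p1))] !=
                as.character(trackLabels(tr)))
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(err - 0.1), 3 * se)
  expect_error(simulateClassProbabilities(tr, flipNoise = 0.5), "flipNoise")
})

test_that("calcium forward model reduces to baseline and decays with tauDecay", {
  st <- stimSchedule(nTrials = 0, onsets = numeric(), offsets = numeric())
  quietTrack <- labelTrack(rep("ambient", 10000))
  flat <- simulateCalciumTrace(quietTrack,
                               tuningSpec(gains = c(quiet = 0, pulse = 0,
                                                    sine = 0, flight = 0),
                                          sigma = 0), stim = st)
  expect_equal(rawF(flat), rep(100, length(rawF(flat))), tolerance = 1e-9)

  ## long pulse bout then quiet: tail of F - F0 is a tauDecay exponential
  tun <- tuningSpec(gains = c(quiet = 0, pulse = 1, sine = 0, flight = 0),
                    tauRise = 0.05, tauDecay = 0.5, sigma = 0)
  tr <- labelTrack(c(rep("pulse", 5000), rep("ambient", 10000)))
  tc <- simulateCalciumTrace(tr, tun, stim = st)
  ft <- frameTimes(tc)
  ## sample the tail well after rise transients (> 5 tauRise past offset)
  offT <- 5000 * 0.0016
  sel <- ft > offT + 0.5 & ft < offT + 1.5
  y <- rawF(tc)[sel] - 100
  fit <- lm(log(y) ~ ft[sel])
  expect_equal(-1 / coef(fit)[[2]], 0.5, tolerance = 0.02)

  s1 <- simulateCalciumTrace(tr, tuningSpec(), stim = st, seed = 1)
  s2 <- simulateCalciumTrace(tr, tuningSpec(), stim = st, seed = 2)
  expect_false(identical(rawF(s1), rawF(s2)))
})

test_that("tuning and layout parameter validation rejects inconsistent kinetics", {
  expect_error(tuningSpec(tauRise = 0.5, tauDecay = 0.2), "tauDecay")
  expect_error(tuningSpec(f0 = 0), "f0")
  expect_error(voxelLayout(array(2L, c(1, 1, 1)), list(tuningSpec())),
               "tunings")
})

test_that("voxel movie matches the trace path and the planted cluster responds", {
  st <- stimSchedule(nTrials = 4)
  p <- songGenParams(st)
  tr <- simulateSongStates(p, seed = 31)
  tun <- tuningSpec(sigma = 2)

  ## single voxel reproduces the trace simulation under the same seed
  lay1 <- voxelLayout(array(1L, c(1, 1, 1)), list(tun))
  mv1 <- simulateVoxelMovie(lay1, tr, stim = st, seed = 7)
  tc <- simulateCalciumTrace(tr, tun, stim = st, seed = 7)
  expect_equal(as.numeric(movieData(mv1)), rawF(tc), tolerance = 1e-12)

  ## shape contract and planted pulse-selective cluster
  cmap <- array(1L, c(2, 4, 4))
  cmap[1, 1:2, 1:2] <- 2L
  quietTun <- tuningSpec(gains = c(quiet = 0, pulse = 0, sine = 0,
                                   flight = 0), sigma = 2)
  lay <- voxelLayout(cmap, list(quietTun, tun))
  mv <- simulateVoxelMovie(lay, tr, stim = st, seed = 8)
  expect_identical(dim(movieData(mv))[2:4], dim(cmap))
  mv <- computeDff(mv, st)
  ev <- detectTypeTransitions(binToFrames(tr, frameTimes(mv)))
  resp <- songCalcium:::.voxelEventResponses(mv, ev, analysisConfig())
  s2p <- resp$sign > 0
  perVox <- colMeans(resp$V[s2p, , drop = FALSE])
  inCluster <- as.vector(cmap == 2L)
  expect_gt(mean(perVox[inCluster]), mean(perVox[!inCluster]))
})

test_that("toy connectomes have the requested block structure", {
  pr <- connectomeGenParams(groupSizes = c(10L, 10L), meanWithin = 30,
                            meanBetween = 0)
  cn <- simulateConnectome(pr, seed = 5)
  g <- cn$meta$group[match(cn$synapses$pre_id, cn$meta$body_id)]
  h <- cn$meta$group[match(cn$synapses$post_id, cn$meta$body_id)]
  expect_true(all(g == h))  # zero between-group mean -> no cross edges

  ## within-block mean count within 3 SE of the Poisson parameter
  nPairs <- 2 * 10 * 9  # ordered within-group pairs
  tot <- sum(cn$synapses$count)
  se <- sqrt(nPairs * 30)  # Poisson variance
  expect_lt(abs(tot - nPairs * 30), 3 * se)

  ## transmitter rows sum to 1
  pc <- grep("^p_", names(cn$transmitters))
  expect_equal(rowSums(cn$transmitters[, pc]),
               rep(1, nrow(cn$transmitters)), tolerance = 1e-9)
})
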