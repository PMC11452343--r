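# Shared simulation studies for the calibration tests. The 100-run
# selectivity study is cached so that the sign-recovery and delta-pattern
# checks reuse the same runs instead of re-simulating them.

.studyCache <- new.env(parent = emptyenv())

# per-run summary of a pulse-selective and a sine-leaning synthetic neuron
selectivityStudy <- function(nRuns = 100, seedBase = 42000,
                             nTrials = 14, nPerm = 1000) {
  key <- sprintf("sel_%d_%d", nRuns, seedBase)
  if (!is.null(.studyCache[[key]])) return(.studyCache[[key]])
  out <- data.frame(run = seq_len(nRuns), S_pulse = NA_real_,
                    p_pulse = NA_real_, meanP2S = NA_real_,
                    meanS2P = NA_real_, S_sine = NA_real_,
                    nP2S = NA_integer_, nS2P = NA_integer_)
  for (s in seq_len(nRuns)) {
    ex <- simulateTransitionExperiment(seed = seedBase + s,
                                       nTrials = nTrials)
    d <- ex$deltas
    p2s <- d$delta[d$kind == "pulse_to_sine"]
    s2p <- d$delta[d$kind == "sine_to_pulse"]
    out$nP2S[s] <- length(p2s); out$nS2P[s] <- length(s2p)
    out$S_pulse[s] <- songTypePreference(p2s, s2p)
    out$p_pulse[s] <- pValue(preferencePermutationTest(p2s, s2p, nPerm,
                                                       seed = seedBase + s))
    out$meanP2S[s] <- mean(p2s); out$meanS2P[s] <- mean(s2p)

    exS <- simulateTransitionExperiment(seed = seedBase + 10000 + s,
                                        gains = c(quiet = 0, pulse = 0.7,
                                                  sine = 1, flight = 0),
                                        nTrials = nTrials)
    dS <- exS$deltas
    out$S_sine[s] <- songTypePreference(
      dS$delta[dS$kind == "pulse_to_sine"],
      dS$delta[dS$kind == "sine_to_pulse"])
  }
  .studyCache[[key]] <- out
  out
}
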