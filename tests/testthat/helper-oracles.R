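# Independent brute-force oracles. These re-derive the same quantities as
# the package by the most literal method available (explicit loops, pairwise
# comparison, fixed-point merging) and stay independent of the package code.

# sliding-window median of a binary vector, odd window, edge replication
naiveBinaryMedian <- function(x, k) {
  h <- (k - 1) / 2
  n <- length(x)
  xp <- c(rep(x[1], h), x, rep(x[n], h))
  vapply(seq_len(n), function(i) {
    as.integer(median(xp[i:(i + k - 1)]))
  }, integer(1))
}

# per-class indicator smoothing + priority resolution, mirroring the
# documented algorithm but via the naive median
naiveSmooth <- function(labels, config) {
  classes <- c("pulse", "sine", "ambient", "others", "flight")
  per <- config@labelPeriod
  ind <- lapply(classes, function(cl) {
    x <- as.integer(labels == cl)
    if (cl %in% names(config@medianWindows)) {
      w <- config@medianWindows[[cl]] / per
      k <- 2 * ceiling(w / 2) - 1
      naiveBinaryMedian(x, k)
    } else x
  })
  names(ind) <- classes
  out <- rep("ambient", length(labels))
  for (cl in c("ambient", "others", "sine", "pulse", "flight"))
    out[ind[[cl]] == 1] <- cl
  out
}

# fixed-point interval union under gap closing
naiveMerge <- function(segments, maxIpi) {
  segs <- as.data.frame(segments)
  names(segs) <- c("start", "end")
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(segs)) {
      if (segs$start[i + 1] - segs$end[i] <= maxIpi) {
        segs$end[i] <- segs$end[i + 1]
        segs <- segs[-(i + 1), , drop = FALSE]
        merged <- TRUE
      } else i <- i + 1
    }
    if (!merged) break
  }
  rownames(segs) <- NULL
  segs
}

# exhaustive transition scan over a state string with a mask
naiveTransitions <- function(states, masked) {
  n <- length(states)
  boutLen <- function(k) {
    len <- 1
    i <- k - 1
    while (i >= 1 && states[i] == states[k]) { len <- len + 1; i <- i - 1 }
    i <- k + 1
    while (i <= n && states[i] == states[k]) { len <- len + 1; i <- i + 1 }
    len
  }
  out <- list()
  for (k in seq_len(n - 1)) {
    if (masked[k] || masked[k + 1]) next
    kind <- if (states[k] == "pulse" && states[k + 1] == "sine")
      "pulse_to_sine"
    else if (states[k] == "sine" && states[k + 1] == "pulse")
      "sine_to_pulse"
    else next
    out[[length(out) + 1]] <- data.frame(
      kind = kind, boundary = k + 1,
      preLen = boutLen(k), postLen = boutLen(k + 1))
  }
  if (!length(out))
    return(data.frame(kind = character(), boundary = integer(),
                      preLen = integer(), postLen = integer()))
  do.call(rbind, out)
}

# pairwise win/tie AUC statistic
naivePreference <- function(p2s, s2p) {
  wins <- 0
  for (x in s2p) for (y in p2s) {
    wins <- wins + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  2 * (wins / (length(p2s) * length(s2p))) - 1
}

# frame binning by explicit per-frame sample selection
naiveBinFrames <- function(times, probs, frameTimes, config) {
  nf <- length(frameTimes)
  per <- if (nf > 1) median(diff(frameTimes)) else config@framePeriod
  edges <- c(frameTimes, frameTimes[nf] + per)
  th <- config@frameThresholds
  flags <- matrix(FALSE, nf, 4,
                  dimnames = list(NULL, c("pulse", "sine", "ambient",
                                          "flight")))
  for (k in seq_len(nf)) {
    sel <- times >= edges[k] & times < edges[k + 1]
    if (!any(sel)) next
    for (cl in colnames(flags))
      flags[k, cl] <- mean(probs[sel, cl]) > th[[cl]]
  }
  flags
}

# build a FrameBinTrack directly from a state string (test fixture)
frameTrackFromStates <- function(states, masked = NULL, per = 0.141) {
  n <- length(states)
  if (is.null(masked)) masked <- rep(FALSE, n)
  flags <- matrix(FALSE, n, 4,
                  dimnames = list(NULL, c("pulse", "sine", "ambient",
                                          "flight")))
  flags[, "pulse"] <- states == "pulse"
  flags[, "sine"] <- states == "sine"
  flags[, "ambient"] <- states == "quiet"
  flags[, "flight"] <- states == "flight"
  new("FrameBinTrack", frameTimes = (seq_len(n) - 1) * per,
      classMeans = matrix(NA_real_, n, 5,
                          dimnames = list(NULL, c("pulse", "sine", "ambient",
                                                  "others", "flight"))),
      flags = flags,
      state = factor(states, levels = c("pulse", "sine", "quiet", "flight",
                                        "undefined")),
      masked = masked, framePeriod = per)
}

# a trace whose dF/F is set directly (test fixture)
traceFromDff <- function(d, per = 0.141, compartment = "neurite") {
  new("FluorescenceTrace", roi = "fixture",
      frameTimes = (seq_along(d) - 1) * per,
      F = rep(1, length(d)), dff = as.numeric(d), f0 = 1,
      trial = integer(0), compartment = compartment)
}

# symmetric generator (pulse and sine statistically exchangeable)
symmetricParams <- function(stim) {
  songGenParams(stim,
                meanDwellOn = c(quiet = 0.5, pulse = 0.8, sine = 0.8,
                                flight = 0.2),
                switchOn = local({
                  m <- matrix(0, 4, 4,
                              dimnames = list(c("quiet", "pulse", "sine",
                                                "flight"),
                                              c("quiet", "pulse", "sine",
                                                "flight")))
                  m["quiet", c("pulse", "sine")] <- 0.5
                  m["pulse", c("sine", "quiet")] <- c(0.7, 0.3)
                  m["sine", c("pulse", "quiet")] <- c(0.7, 0.3)
                  m["flight", "quiet"] <- 1
                  m
                }))
}
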