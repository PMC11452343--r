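#' Simulate a song-state label track
#'
#' Runs the per-bin Markov chain of \code{\link{songGenParams}} over the
#' label grid, switching between the stimulation-on and stimulation-off
#' transition matrices at the trial boundaries of the schedule. Dwell times
#' are geometric in label bins (memoryless), so downstream per-bin hazard
#' estimators have closed-form targets. Generator states map onto classifier
#' labels with quiet emitted as "ambient".
#'
#' @param params a \code{SongGenParams}
#' @param duration track duration (s); default runs to one inter-trial
#'   interval past the last stimulus offset
#' @param seed integer seed; identical seeds give identical tracks
#' @param initState initial state (default "quiet")
#' @return a \code{\link{labelTrack}}
#' @examples
#' tr <- simulateSongStates(songGenParams(stimSchedule(nTrials = 1)),
#'                          duration = 30, seed = 1)
#' table(trackLabels(tr))
#' @export
simulateSongStates <- function(params, duration = NULL, seed = NULL,
                               initState = "quiet") {
  validObject(params)
  per <- params@labelPeriod
  stim <- params@stim
  if (is.null(duration)) {
    duration <- if (nTrials(stim))
      max(trialOffsets(stim)) + 20 else 60
  }
  n <- as.integer(round(duration / per))
  if (n < 1L) stop("duration too short for one label bin")

  ## segment the bin grid by stimulation state
  binTimes <- (seq_len(n) - 1) * per
  onIdx <- rep(FALSE, n)
  for (i in seq_len(nTrials(stim))) {
    sel <- binTimes >= trialOnsets(stim)[i] & binTimes < trialOffsets(stim)[i]
    onIdx[sel] <- TRUE
  }
  segId <- cumsum(c(1L, diff(onIdx) != 0L))
  segStart <- which(!duplicated(segId))
  segEnd <- c(segStart[-1L] - 1L, n)
  segOn <- onIdx[segStart]

  .withSeed(seed, {
    state <- match(initState, .GEN_STATES)
    labels <- integer(n)
    for (s in seq_along(segStart)) {
      P <- if (segOn[s]) params@transOn else params@transOff
      cursor <- segStart[s]
      while (cursor <= segEnd[s]) {
        pExit <- 1 - P[state, state]
        dwell <- if (pExit <= 0) Inf else stats::rgeom(1L, pExit) + 1
        take <- min(dwell, segEnd[s] - cursor + 1)
        labels[cursor:(cursor + take - 1)] <- state
        cursor <- cursor + take
        if (dwell <= take && cursor <= segEnd[s] + 1L) {
          q <- P[state, ]
          q[state] <- 0
          state <- sample.int(4L, 1L, prob = q / sum(q))
        }
      }
    }
    lab <- c(quiet = "ambient", pulse = "pulse", sine = "sine",
             flight = "flight")[.GEN_STATES[labels]]
    labelTrack(lab, period = per, time = binTimes)
  })
}

#' Simulate classifier-style probability tracks
#'
#' Emulates a song classifier's per-sample output on a label track: with
#' probability \code{flipNoise} the reported top class is a uniformly chosen
#' wrong class; the top class receives a probability drawn from U(0.6, 0.9)
#' and the remainder is spread evenly, so rows sum to 1 and the argmax
#' error rate is \code{flipNoise} in expectation.
#'
#' @param track a \code{LabelTrack}
#' @param flipNoise misclassification probability in [0, 0.5)
#' @param seed integer seed
#' @return a \code{ClassProbTrack}
#' @examples
#' tr <- labelTrack(rep(c("pulse", "sine"), each = 50))
#' pt <- simulateClassProbabilities(tr, flipNoise = 0, seed = 1)
#' all(colnames(classProbs(pt))[max.col(classProbs(pt))] ==
#'     as.character(trackLabels(tr)))
#' @export
simulateClassProbabilities <- function(track, flipNoise = 0, seed = NULL) {
  stopifnot(is(track, "LabelTrack"))
  if (flipNoise < 0 || flipNoise >= 0.5)
    stop("flipNoise must lie in [0, 0.5)")
  n <- length(track@time)
  k <- length(.SONG_CLASSES)
  .withSeed(seed, {
    top <- as.integer(track@label)
    if (flipNoise > 0) {
      flip <- stats::runif(n) < flipNoise
      if (any(flip)) {
        shift <- sample.int(k - 1L, sum(flip), replace = TRUE)
        top[flip] <- 1L + (top[flip] - 1L + shift) %% k
      }
    }
    peak <- stats::runif(n, 0.6, 0.9)
    rest <- (1 - peak) / (k - 1)
    probs <- matrix(rest, n, k)
    probs[cbind(seq_len(n), top)] <- peak
    colnames(probs) <- .SONG_CLASSES
    new("ClassProbTrack", time = track@time, probs = probs,
        period = track@period)
  })
}

## Unit-peak difference-of-exponentials kernel on the label grid, and the
## state-gated drive convolved with it (continuous-time convolution
## discretized with the label period as the integration step).
.calciumDrive <- function(track, tuning) {
  per <- track@period
  stateGain <- c(pulse = unname(tuning@gains["pulse"]),
                 sine = unname(tuning@gains["sine"]),
                 ambient = unname(tuning@gains["quiet"]),
                 others = unname(tuning@gains["quiet"]),
                 flight = unname(tuning@gains["flight"]))
  drive <- stateGain[as.character(track@label)]
  tk <- seq(0, 8 * tuning@tauDecay, by = per)
  kern <- exp(-tk / tuning@tauDecay) - exp(-tk / tuning@tauRise)
  kern <- kern / max(kern)
  n <- length(drive)
  conv <- stats::convolve(drive, rev(kern), type = "open")[seq_len(n)] * per
  pmax(conv, 0)
}

#' Simulate a calcium fluorescence trace
#'
#' Forward model of GCaMP dynamics: per-state activity gains on the label
#' grid are convolved with a unit-peak difference-of-exponentials kernel
#' (rise tauRise, decay tauDecay), scaled as
#' F(t) = F0 (1 + response(t)), sampled at the imaging frame rate, and read
#' out with additive Gaussian noise of standard deviation sigma.
#'
#' @param track a \code{LabelTrack} of song states
#' @param tuning a \code{TuningSpec}
#' @param frameRate imaging volume rate (Hz)
#' @param stim the stimulation schedule (stored for trial bookkeeping)
#' @param seed integer seed
#' @param roi ROI identifier
#' @param compartment "soma" or "neurite"
#' @return a \code{FluorescenceTrace} with raw F (dF/F not yet computed)
#' @examples
#' tr <- simulateSongStates(songGenParams(stimSchedule(nTrials = 1)),
#'                          duration = 30, seed = 2)
#' tun <- tuningSpec(sigma = 0)
#' tc <- simulateCalciumTrace(tr, tun, stim = stimSchedule(nTrials = 1))
#' @export
simulateCalciumTrace <- function(track, tuning, frameRate = 7.1,
                                 stim = stimSchedule(), seed = NULL,
                                 roi = "roi1", compartment = "neurite") {
  stopifnot(is(track, "LabelTrack"), is(tuning, "TuningSpec"))
  validObject(tuning)
  if (frameRate <= 0) stop("frameRate must be positive")
  conv <- .calciumDrive(track, tuning)
  cleanF <- tuning@f0 * (1 + conv)
  tmax <- track@time[length(track@time)]
  ft <- seq(0, tmax, by = 1 / frameRate)
  cleanFrames <- stats::approx(track@time, cleanF, xout = ft, rule = 2)$y
  .withSeed(seed, {
    Fv <- cleanFrames + stats::rnorm(length(ft), 0, tuning@sigma)
    trial <- .assignTrial(ft, stim)
    new("FluorescenceTrace", roi = roi, frameTimes = ft, F = Fv,
        dff = numeric(), f0 = numeric(), trial = trial,
        compartment = compartment)
  })
}

## trial index per frame: i while t in [onset_i, offset_i), else 0
.assignTrial <- function(t, stim) {
  trial <- integer(length(t))
  for (i in seq_len(nTrials(stim))) {
    trial[t >= trialOnsets(stim)[i] & t < trialOffsets(stim)[i]] <- i
  }
  trial
}

#' Simulate a voxel movie
#'
#' Every voxel follows the \code{\link{simulateCalciumTrace}} forward model
#' with its cluster's tuning; voxel noise is independent. With a
#' single-voxel layout and the same seed the movie reproduces the trace
#' simulation exactly.
#'
#' @param layout a \code{VoxelLayout}
#' @param track a \code{LabelTrack}
#' @param frameRate imaging volume rate (Hz)
#' @param stim stimulation schedule
#' @param seed integer seed
#' @return a \code{VoxelMovie} of raw F, dimensions (t, z, y, x)
#' @export
simulateVoxelMovie <- function(layout, track, frameRate = 7.1,
                               stim = stimSchedule(), seed = NULL) {
  stopifnot(is(layout, "VoxelLayout"), is(track, "LabelTrack"))
  validObject(layout)
  dims <- dim(layout@clusterMap)
  tmax <- track@time[length(track@time)]
  ft <- seq(0, tmax, by = 1 / frameRate)
  nf <- length(ft)
  cleanByCluster <- lapply(layout@tunings, function(tun) {
    validObject(tun)
    conv <- .calciumDrive(track, tun)
    cleanF <- tun@f0 * (1 + conv)
    stats::approx(track@time, cleanF, xout = ft, rule = 2)$y
  })
  sigmaByCluster <- vapply(layout@tunings, function(tun) tun@sigma, 0)
  nvox <- prod(dims)
  clusters <- as.integer(layout@clusterMap)
  .withSeed(seed, {
    M <- matrix(0, nf, nvox)
    for (v in seq_len(nvox)) {
      cl <- clusters[v]
      M[, v] <- cleanByCluster[[cl]] +
        stats::rnorm(nf, 0, sigmaByCluster[cl])
    }
    new("VoxelMovie", F = array(M, c(nf, dims)), frameTimes = ft,
        binFactor = 1, isDff = FALSE)
  })
}

#' Simulate a toy block-structured connectome
#'
#' Draws Poisson synapse counts between every ordered pair of distinct
#' neurons (mean \code{meanWithin} within a group, \code{meanBetween}
#' across groups) and per-synapse transmitter-probability rows sampled from
#' a Dirichlet around each group's profile.
#'
#' @param params a \code{ConnectomeGenParams}
#' @param seed integer seed
#' @param maxTransmitterRows cap on transmitter rows sampled per neuron
#' @return a list with elements \code{synapses} (data.frame pre_id,
#'   post_id, count), \code{transmitters} (data.frame synapse_id,
#'   neuron_id, p_<transmitter>...), \code{meta} (data.frame body_id,
#'   traced, pre, post, group)
#' @examples
#' cn <- simulateConnectome(connectomeGenParams(c(3L, 3L)), seed = 1)
#' head(cn$synapses)
#' @export
simulateConnectome <- function(params, seed = NULL,
                               maxTransmitterRows = 100L) {
  validObject(params)
  sizes <- params@groupSizes
  nn <- sum(sizes)
  group <- rep(seq_along(sizes), sizes)
  ids <- sprintf("n%03d", seq_len(nn))
  .withSeed(seed, {
    pre <- rep(seq_len(nn), each = nn)
    post <- rep(seq_len(nn), times = nn)
    keep <- pre != post
    pre <- pre[keep]; post <- post[keep]
    mu <- ifelse(group[pre] == group[post],
                 params@meanWithin, params@meanBetween)
    count <- stats::rpois(length(mu), mu)
    sel <- count > 0
    synapses <- data.frame(pre_id = ids[pre[sel]], post_id = ids[post[sel]],
                           count = count[sel], stringsAsFactors = FALSE)
    outTot <- vapply(seq_len(nn), function(i)
      sum(synapses$count[synapses$pre_id == ids[i]]), 0)
    inTot <- vapply(seq_len(nn), function(i)
      sum(synapses$count[synapses$post_id == ids[i]]), 0)
    prof <- params@transmitterProfiles
    conc <- params@concentration
    trList <- vector("list", nn)
    sid <- 0L
    for (i in seq_len(nn)) {
      nRows <- min(as.integer(outTot[i]), maxTransmitterRows)
      if (nRows < 1L) nRows <- 1L
      alpha <- prof[group[i], ] * conc
      g <- matrix(stats::rgamma(nRows * length(alpha),
                                shape = rep(alpha, each = nRows)),
                  nRows, length(alpha))
      p <- g / rowSums(g)
      colnames(p) <- paste0("p_", colnames(prof))
      trList[[i]] <- data.frame(synapse_id = sid + seq_len(nRows),
                                neuron_id = ids[i], p,
                                stringsAsFactors = FALSE)
      sid <- sid + nRows
    }
    transmitters <- do.call(rbind, trList)
    meta <- data.frame(body_id = ids, traced = TRUE, pre = outTot,
                       post = inTot, group = group,
                       stringsAsFactors = FALSE)
    list(synapses = synapses, transmitters = transmitters, meta = meta)
  })
}

#' Simulate a complete transition-imaging experiment
#'
#' Convenience wrapper chaining the generators with the analysis
#' preprocessing: song states, calcium trace, per-trial dF/F, frame
#' binning with flight masking, song-type transition detection and
#' per-event transition responses. This is the workhorse for property
#' tests and calibration studies.
#'
#' @param seed integer seed (the calcium noise uses seed + 1)
#' @param gains named activity gains passed to \code{\link{tuningSpec}}
#' @param nTrials number of 10-s stimulation trials
#' @param sigma noise standard deviation on F (a.u.)
#' @param compartment compartment whose response window is used
#' @param params optional \code{SongGenParams} overriding the default
#' @param stim optional \code{StimSchedule}
#' @param config an \code{\link{analysisConfig}}
#' @return list with track, trace (dF/F computed), binned, events,
#'   deltas (from \code{\link{transitionDelta}}), tuning and stim
#' @export
simulateTransitionExperiment <- function(seed = NULL,
                                         gains = c(quiet = 0, pulse = 1,
                                                   sine = 0, flight = 0),
                                         nTrials = 12L, sigma = 5,
                                         compartment = "neurite",
                                         params = NULL, stim = NULL,
                                         config = analysisConfig()) {
  if (is.null(stim)) stim <- stimSchedule(nTrials = nTrials)
  if (is.null(params)) params <- songGenParams(stim)
  track <- simulateSongStates(params, seed = seed)
  tun <- tuningSpec(gains = gains, sigma = sigma)
  trace <- simulateCalciumTrace(track, tun, stim = stim,
                                seed = if (is.null(seed)) NULL else seed + 1L)
  trace <- computeDff(trace, stim, config)
  binned <- applyFlightMask(binToFrames(track, frameTimes(trace), config),
                            config)
  events <- detectTypeTransitions(binned)
  deltas <- transitionDelta(trace, events, compartment, binned, config)
  list(track = track, trace = trace, binned = binned, events = events,
       deltas = deltas, tuning = tun, stim = stim)
}
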