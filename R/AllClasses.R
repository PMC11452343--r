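#' @import methods
NULL

## Canonical label sets. Classifier labels follow the annotation scheme of
## SongExplorer-style song segmentation; frame states add "quiet" (the
## resolved no-song state) and "undefined" (frames with no information).
.SONG_CLASSES <- c("pulse", "sine", "ambient", "others", "flight")
.FRAME_STATES <- c("pulse", "sine", "quiet", "flight", "undefined")
.GEN_STATES <- c("quiet", "pulse", "sine", "flight")

#' Analysis configuration
#'
#' Houses every numeric parameter of the song/calcium analysis pipeline:
#' median-filter windows, the pulse-train merge gap, imaging-frame binning
#' thresholds, flight exclusion padding, transition windows for soma and
#' neurite compartments, bout-length split thresholds, decay-fit span,
#' permutation counts and connectome filters. Defaults are the values used
#' throughout the package.
#'
#' @slot labelPeriod sampling period of classifier labels (s)
#' @slot medianWindows named median-filter windows (s) for pulse, sine, flight
#' @slot maxIpi maximum inter-pulse interval merged into one pulse train (s)
#' @slot framePeriod nominal imaging frame period (s)
#' @slot frameThresholds per-class mean-probability thresholds for calling an
#'   event in a frame (strict inequality)
#' @slot flightPad exclusion pad around flight frames (s)
#' @slot minQuietRun minimum continuous quiet before a quiet-to-pulse
#'   transition (s)
#' @slot somaPostOffsets,neuritePostOffsets frame offsets (relative to the
#'   first new-state frame) averaged for the post-transition window
#' @slot minEventsTransition,minEventsQuietPulse minimum event counts
#' @slot baselineFloor minimum transition-window dF/F for normalization
#' @slot boutSplit named bout-length split thresholds (s) for pulse and sine
#' @slot decaySpan span of the one-term exponential decay fit (s)
#' @slot nPerm default permutation count
#' @slot behaviorBin behavioral reporting bin (s)
#' @slot dffBaselineWindow pre-stimulus baseline window for dF/F (s)
#' @slot behaviorPreWindow pre-stimulus window for stimulation effects (s)
#' @slot voxelAlpha per-voxel significance level
#' @slot minTotalSynapses,minUpstreamSynapses connectome filters
#' @slot embeddingPerplexity perplexity recorded for downstream embeddings
#' @export
setClass("AnalysisConfig", representation(
  labelPeriod = "numeric",
  medianWindows = "numeric",
  maxIpi = "numeric",
  framePeriod = "numeric",
  frameThresholds = "numeric",
  flightPad = "numeric",
  minQuietRun = "numeric",
  somaPostOffsets = "integer",
  neuritePostOffsets = "integer",
  minEventsTransition = "integer",
  minEventsQuietPulse = "integer",
  baselineFloor = "numeric",
  boutSplit = "numeric",
  decaySpan = "numeric",
  nPerm = "integer",
  behaviorBin = "numeric",
  dffBaselineWindow = "numeric",
  behaviorPreWindow = "numeric",
  voxelAlpha = "numeric",
  minTotalSynapses = "numeric",
  minUpstreamSynapses = "numeric",
  embeddingPerplexity = "numeric"
))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  pos <- c(object@labelPeriod, object@framePeriod, object@flightPad,
           object@minQuietRun, object@decaySpan, object@behaviorBin,
           object@dffBaselineWindow, object@behaviorPreWindow,
           object@medianWindows, object@boutSplit)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "all windows and periods must be positive")
  if (!all(c("pulse", "sine", "flight") %in% names(object@medianWindows)))
    msg <- c(msg, "medianWindows must name pulse, sine and flight")
  th <- object@frameThresholds
  if (!all(c("pulse", "sine", "ambient", "flight") %in% names(th)))
    msg <- c(msg, "frameThresholds must name pulse, sine, ambient, flight")
  if (any(th <= 0) || any(th >= 1))
    msg <- c(msg, "frameThresholds must lie in (0,1)")
  if (object@maxIpi < 0) msg <- c(msg, "maxIpi must be >= 0")
  if (object@voxelAlpha <= 0 || object@voxelAlpha >= 1)
    msg <- c(msg, "voxelAlpha must lie in (0,1)")
  if (object@nPerm < 1L) msg <- c(msg, "nPerm must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct an analysis configuration
#'
#' @param labelPeriod classifier label period in seconds
#' @param medianWindows named numeric vector of median-filter windows (s)
#' @param maxIpi pulse-train merge gap (s)
#' @param framePeriod nominal imaging frame period (s)
#' @param frameThresholds per-class frame occurrence thresholds
#' @param flightPad flight exclusion pad (s)
#' @param minQuietRun minimum quiet run before quiet-to-pulse (s)
#' @param somaPostOffsets,neuritePostOffsets integer frame offsets from the
#'   first post-transition frame defining the response window
#' @param minEventsTransition,minEventsQuietPulse minimum event counts
#' @param baselineFloor transition-window dF/F floor for normalization
#' @param boutSplit named short/long bout split thresholds (s)
#' @param decaySpan decay-fit span (s)
#' @param nPerm default permutation count
#' @param behaviorBin behavioral bin width (s)
#' @param dffBaselineWindow dF/F baseline window (s)
#' @param behaviorPreWindow behavioral pre-stimulation window (s)
#' @param voxelAlpha per-voxel significance level
#' @param minTotalSynapses,minUpstreamSynapses connectome synapse filters
#' @param embeddingPerplexity perplexity recorded for embeddings
#' @return an \code{AnalysisConfig} object
#' @examples
#' cfg <- analysisConfig()
#' cfg@frameThresholds
#' @export
analysisConfig <- function(labelPeriod = 0.0016,
                           medianWindows = c(pulse = 0.0176, sine = 0.0256,
                                             flight = 0.080),
                           maxIpi = 0.050,
                           framePeriod = 0.141,
                           frameThresholds = c(pulse = 0.1, sine = 0.6,
                                               ambient = 0.9, flight = 0.01),
                           flightPad = 1.0,
                           minQuietRun = 2.0,
                           somaPostOffsets = c(2L, 3L),
                           neuritePostOffsets = c(1L, 2L),
                           minEventsTransition = 5L,
                           minEventsQuietPulse = 2L,
                           baselineFloor = 0.1,
                           boutSplit = c(pulse = 0.422, sine = 0.704),
                           decaySpan = 0.845,
                           nPerm = 10000L,
                           behaviorBin = 0.150,
                           dffBaselineWindow = 10,
                           behaviorPreWindow = 5,
                           voxelAlpha = 0.001,
                           minTotalSynapses = 100,
                           minUpstreamSynapses = 50,
                           embeddingPerplexity = 10) {
  new("AnalysisConfig",
      labelPeriod = labelPeriod, medianWindows = medianWindows,
      maxIpi = maxIpi, framePeriod = framePeriod,
      frameThresholds = frameThresholds, flightPad = flightPad,
      minQuietRun = minQuietRun,
      somaPostOffsets = as.integer(somaPostOffsets),
      neuritePostOffsets = as.integer(neuritePostOffsets),
      minEventsTransition = as.integer(minEventsTransition),
      minEventsQuietPulse = as.integer(minEventsQuietPulse),
      baselineFloor = baselineFloor, boutSplit = boutSplit,
      decaySpan = decaySpan, nPerm = as.integer(nPerm),
      behaviorBin = behaviorBin, dffBaselineWindow = dffBaselineWindow,
      behaviorPreWindow = behaviorPreWindow, voxelAlpha = voxelAlpha,
      minTotalSynapses = minTotalSynapses,
      minUpstreamSynapses = minUpstreamSynapses,
      embeddingPerplexity = embeddingPerplexity)
}

#' Optogenetic stimulation schedule
#'
#' Trial onsets and offsets in seconds with a power label per trial.
#'
#' @slot onsets,offsets trial boundaries (s); non-overlapping, offset > onset
#' @slot power numeric power label per trial (units recorded only)
#' @export
setClass("StimSchedule", representation(
  onsets = "numeric", offsets = "numeric", power = "numeric"))

setValidity("StimSchedule", function(object) {
  n <- length(object@onsets)
  if (length(object@offsets) != n || length(object@power) != n)
    return("onsets, offsets and power must have equal length")
  if (n == 0L) return(TRUE)
  if (any(object@offsets <= object@onsets))
    return("every offset must exceed its onset")
  if (is.unsorted(object@onsets, strictly = TRUE))
    return("onsets must be strictly increasing")
  if (n > 1L && any(object@onsets[-1L] < object@offsets[-n]))
    return("trials must not overlap")
  TRUE
})

#' Construct a stimulation schedule
#'
#' Default emulates a block design of constant 10-s stimulation trials with a
#' 20-s inter-trial interval.
#'
#' @param nTrials number of trials
#' @param stimDur stimulus duration (s)
#' @param iti inter-trial interval (s)
#' @param firstOnset onset of the first trial (s)
#' @param power power label(s), recycled across trials
#' @param onsets,offsets explicit trial boundaries overriding the block design
#' @return a \code{StimSchedule}
#' @examples
#' stimSchedule(nTrials = 3)
#' @export
stimSchedule <- function(nTrials = 6L, stimDur = 10, iti = 20,
                         firstOnset = 15, power = 1,
                         onsets = NULL, offsets = NULL) {
  if (is.null(onsets)) {
    onsets <- firstOnset + (seq_len(nTrials) - 1) * (stimDur + iti)
    offsets <- onsets + stimDur
  }
  new("StimSchedule", onsets = as.numeric(onsets),
      offsets = as.numeric(offsets),
      power = rep_len(as.numeric(power), length(onsets)))
}

#' Categorical song-label track
#'
#' One label per sample on a uniform grid (1.6 ms by default), from the
#' closed set pulse / sine / ambient / others / flight.
#'
#' @slot time sample times (s), uniform and strictly increasing
#' @slot label factor of labels
#' @slot period sampling period (s)
#' @export
setClass("LabelTrack", representation(
  time = "numeric", label = "factor", period = "numeric"))

setValidity("LabelTrack", function(object) {
  if (length(object@time) != length(object@label))
    return("time and label must have equal length")
  if (!identical(levels(object@label), .SONG_CLASSES))
    return("label levels must be pulse, sine, ambient, others, flight")
  if (object@period <= 0) return("period must be positive")
  if (length(object@time) > 1L) {
    d <- diff(object@time)
    if (any(d <= 0)) return("times must be strictly increasing")
    if (max(abs(d - object@period)) > 1e-6)
      return("times must lie on a uniform grid with the stated period")
  }
  TRUE
})

#' @rdname LabelTrack-class
#' @param label character or factor of labels
#' @param period sampling period (s)
#' @param time optional explicit sample times (s)
#' @return a \code{LabelTrack}
#' @export
labelTrack <- function(label, period = 0.0016, time = NULL) {
  label <- factor(as.character(label), levels = .SONG_CLASSES)
  if (anyNA(label)) stop("unknown song label")
  if (is.null(time)) time <- (seq_along(label) - 1) * period
  new("LabelTrack", time = time, label = label, period = period)
}

#' Classifier probability track
#'
#' Per-sample class probabilities (rows sum to 1) on the label grid.
#'
#' @slot time sample times (s)
#' @slot probs numeric matrix, one column per class
#' @slot period sampling period (s)
#' @export
setClass("ClassProbTrack", representation(
  time = "numeric", probs = "matrix", period = "numeric"))

setValidity("ClassProbTrack", function(object) {
  if (nrow(object@probs) != length(object@time))
    return("probs must have one row per sample")
  if (!identical(colnames(object@probs), .SONG_CLASSES))
    return("probs columns must be pulse, sine, ambient, others, flight")
  if (any(object@probs < -1e-9) || any(object@probs > 1 + 1e-9))
    return("probabilities must lie in [0,1]")
  if (nrow(object@probs) &&
      max(abs(rowSums(object@probs) - 1)) > 1e-6)
    return("probability rows must sum to 1")
  TRUE
})

#' Imaging-frame binned song track
#'
#' Classifier output reduced to the imaging-frame grid: per-class mean
#' occurrence probabilities, thresholded event flags, a resolved single state
#' per frame, and a mask for flight-excluded frames.
#'
#' @slot frameTimes frame start times (s)
#' @slot classMeans per-frame mean class probabilities
#' @slot flags per-frame logical event flags (pulse, sine, ambient, flight)
#' @slot state resolved state factor (pulse, sine, quiet, flight, undefined)
#' @slot masked logical; TRUE for frames excluded by the flight pad
#' @slot framePeriod frame period (s)
#' @export
setClass("FrameBinTrack", representation(
  frameTimes = "numeric", classMeans = "matrix", flags = "matrix",
  state = "factor", masked = "logical", framePeriod = "numeric"))

setValidity("FrameBinTrack", function(object) {
  n <- length(object@frameTimes)
  if (nrow(object@classMeans) != n || nrow(object@flags) != n ||
      length(object@state) != n || length(object@masked) != n)
    return("frame-wise slots must agree in length")
  if (!identical(levels(object@state), .FRAME_STATES))
    return("state levels must be pulse, sine, quiet, flight, undefined")
  if (any(object@flags[, "flight"] & object@state != "flight"))
    return("state must be flight wherever the flight flag is set")
  TRUE
})

#' Fluorescence trace for one ROI
#'
#' Raw fluorescence at the imaging frame rate with trial structure and,
#' after \code{computeDff}, per-trial baselines and dF/F.
#'
#' @slot roi ROI identifier
#' @slot frameTimes frame times (s)
#' @slot F raw fluorescence (a.u.)
#' @slot dff dF/F per frame (empty until computed)
#' @slot f0 per-trial baseline fluorescence (empty until computed)
#' @slot trial trial index per frame (0 outside any trial epoch)
#' @slot compartment "soma" or "neurite"
#' @export
setClass("FluorescenceTrace", representation(
  roi = "character", frameTimes = "numeric", F = "numeric",
  dff = "numeric", f0 = "numeric", trial = "integer",
  compartment = "character"))

setValidity("FluorescenceTrace", function(object) {
  n <- length(object@frameTimes)
  if (length(object@F) != n) return("F must have one value per frame")
  if (length(object@dff) && length(object@dff) != n)
    return("dff, if present, must have one value per frame")
  if (length(object@trial) && length(object@trial) != n)
    return("trial, if present, must have one value per frame")
  if (!object@compartment %in% c("soma", "neurite"))
    return("compartment must be 'soma' or 'neurite'")
  if (length(object@f0) && any(object@f0[!is.na(object@f0)] <= 0))
    return("baseline F0 must be positive")
  TRUE
})

#' Voxel movie
#'
#' A 4-D fluorescence (or dF/F) array ordered (t, z, y, x).
#'
#' @slot F 4-D numeric array
#' @slot frameTimes frame times (s)
#' @slot binFactor spatial binning factor already applied
#' @slot isDff TRUE once the array holds dF/F rather than raw F
#' @export
setClass("VoxelMovie", representation(
  F = "array", frameTimes = "numeric", binFactor = "numeric",
  isDff = "logical"))

setValidity("VoxelMovie", function(object) {
  if (length(dim(object@F)) != 4L)
    return("movie must be a 4-D (t, z, y, x) array")
  if (dim(object@F)[1L] != length(object@frameTimes))
    return("first array dimension must match frameTimes")
  TRUE
})

#' Song-type preference result
#'
#' The ROC-based song-type preference S = 2 AUC - 1 comparing dF/F changes
#' at sine-to-pulse versus pulse-to-sine transitions, with its permutation
#' p-value. S = +1: perfectly higher calcium changes for pulse; -1: for sine.
#'
#' @slot S preference in [-1, 1]
#' @slot p two-sided permutation p-value (NA if the test was not run)
#' @slot nP2S,nS2P event counts per transition kind
#' @slot nPerm permutation count
#' @export
setClass("PreferenceResult", representation(
  S = "numeric", p = "numeric", nP2S = "integer", nS2P = "integer",
  nPerm = "integer"))

setValidity("PreferenceResult", function(object) {
  if (!is.na(object@S) && (object@S < -1 - 1e-12 || object@S > 1 + 1e-12))
    return("S must lie in [-1, 1]")
  if (!is.na(object@p) && (object@p <= 0 || object@p > 1))
    return("p must lie in (0, 1]")
  TRUE
})

#' One-term exponential decay fit
#'
#' Fit of a * exp(-r t) to a dF/F time course over a short span; the
#' half-decay time is ln(2) / r.
#'
#' @slot amplitude fitted amplitude (dF/F units)
#' @slot rate fitted decay rate (1/s)
#' @slot halfDecay ln(2)/rate (s); NA when flagged
#' @slot span fit span (s)
#' @slot residualNorm L2 norm of residuals
#' @slot flagged TRUE when the data do not decay (rate <= 0)
#' @export
setClass("DecayFit", representation(
  amplitude = "numeric", rate = "numeric", halfDecay = "numeric",
  span = "numeric", residualNorm = "numeric", flagged = "logical"))

#' Connectivity matrix
#'
#' Square synapse-count matrix over an ordered neuron list; entry (i, j) is
#' the number of synapses from neuron i onto neuron j.
#'
#' @slot ids ordered neuron identifiers
#' @slot counts synapse-count matrix
#' @export
setClass("ConnectivityMatrix", representation(
  ids = "character", counts = "matrix"))

setValidity("ConnectivityMatrix", function(object) {
  n <- length(object@ids)
  if (!identical(dim(object@counts), c(n, n)))
    return("counts must be square over the listed neurons")
  if (any(object@counts < 0)) return("synapse counts must be >= 0")
  TRUE
})

#' Voxel preference map
#'
#' Per-voxel transition-response difference (sine-to-pulse minus
#' pulse-to-sine), its permutation p-value, and the significance mask.
#'
#' @slot difference 3-D (z, y, x) array of mean differences
#' @slot pvalue 3-D array of two-sided permutation p-values
#' @slot mask logical 3-D array; TRUE iff p < alpha
#' @slot alpha significance level
#' @slot nEvents number of events used
#' @export
setClass("VoxelPreferenceMap", representation(
  difference = "array", pvalue = "array", mask = "array",
  alpha = "numeric", nEvents = "integer"))

setValidity("VoxelPreferenceMap", function(object) {
  if (any(object@mask & !(object@pvalue < object@alpha), na.rm = TRUE))
    return("mask may be TRUE only where p < alpha")
  TRUE
})

#' Song-state generator parameters
#'
#' A per-bin Markov chain over quiet / pulse / sine / flight with separate
#' transition matrices for stimulation-on and stimulation-off bins. Mean
#' dwell time in state s is period / (1 - P[s, s]) (geometric dwell).
#'
#' @slot transOn,transOff row-stochastic 4x4 per-bin transition matrices
#' @slot labelPeriod label sampling period (s)
#' @slot stim stimulation schedule
#' @export
setClass("SongGenParams", representation(
  transOn = "matrix", transOff = "matrix", labelPeriod = "numeric",
  stim = "StimSchedule"))

.checkStochastic <- function(P) {
  if (!identical(dim(P), c(4L, 4L)) ||
      !identical(rownames(P), .GEN_STATES) ||
      !identical(colnames(P), .GEN_STATES))
    return("transition matrices must be 4x4 over quiet, pulse, sine, flight")
  if (any(P < 0) || any(P > 1))
    return("switch probabilities must lie in [0,1]")
  if (max(abs(rowSums(P) - 1)) > 1e-9)
    return("transition-matrix rows must sum to 1")
  NULL
}

setValidity("SongGenParams", function(object) {
  msg <- c(.checkStochastic(object@transOn), .checkStochastic(object@transOff))
  if (object@labelPeriod <= 0) msg <- c(msg, "labelPeriod must be positive")
  if (length(msg)) msg else TRUE
})

.dwellMatrix <- function(meanDwell, switchTo, period) {
  h <- pmin(1, period / meanDwell[.GEN_STATES])
  P <- switchTo * h
  diag(P) <- 0
  diag(P) <- 1 - rowSums(P)
  P
}

#' Construct song-state generator parameters
#'
#' Either supply full per-bin transition matrices, or mean dwell times plus
#' conditional switch targets from which the matrices are built (exit hazard
#' per bin = period / mean dwell; geometric dwell). Defaults emulate a fly
#' that sings alternating pulse/sine bouts during 10-s stimulation epochs
#' and is mostly quiet otherwise; flight is off by default.
#'
#' @param stim stimulation schedule
#' @param labelPeriod label period (s)
#' @param transOn,transOff explicit 4x4 row-stochastic matrices (optional)
#' @param meanDwellOn,meanDwellOff named mean dwell times (s) per state
#' @param switchOn,switchOff named 4x4 matrices of conditional next-state
#'   probabilities given a switch (rows sum to 1, zero diagonal)
#' @return a \code{SongGenParams}
#' @examples
#' p <- songGenParams(stimSchedule(nTrials = 2))
#' rowSums(p@transOn)
#' @export
songGenParams <- function(stim = stimSchedule(),
                          labelPeriod = 0.0016,
                          transOn = NULL, transOff = NULL,
                          meanDwellOn = c(quiet = 0.5, pulse = 0.7,
                                          sine = 1.0, flight = 0.2),
                          meanDwellOff = c(quiet = 60, pulse = 0.3,
                                           sine = 0.3, flight = 0.2),
                          switchOn = NULL, switchOff = NULL) {
  mk <- function(x) {
    m <- matrix(0, 4, 4, dimnames = list(.GEN_STATES, .GEN_STATES))
    for (s in names(x)) m[s, names(x[[s]])] <- x[[s]]
    m
  }
  if (is.null(switchOn))
    switchOn <- mk(list(quiet = c(pulse = 0.6, sine = 0.4),
                        pulse = c(sine = 0.7, quiet = 0.3),
                        sine = c(pulse = 0.6, quiet = 0.4),
                        flight = c(quiet = 1)))
  if (is.null(switchOff))
    switchOff <- mk(list(quiet = c(pulse = 0.5, sine = 0.5),
                         pulse = c(quiet = 1),
                         sine = c(quiet = 1),
                         flight = c(quiet = 1)))
  if (is.null(transOn))
    transOn <- .dwellMatrix(meanDwellOn, switchOn, labelPeriod)
  if (is.null(transOff))
    transOff <- .dwellMatrix(meanDwellOff, switchOff, labelPeriod)
  new("SongGenParams", transOn = transOn, transOff = transOff,
      labelPeriod = labelPeriod, stim = stim)
}

#' Calcium forward-model tuning
#'
#' State-gated activity gains convolved with a difference-of-exponentials
#' kernel (unit peak), scaled by a baseline and read out with additive
#' Gaussian noise — a minimal forward model of GCaMP dynamics.
#'
#' @slot gains named non-negative activity gains per generator state
#' @slot tauRise,tauDecay kernel rise and decay time constants (s);
#'   tauDecay > tauRise
#' @slot f0 baseline fluorescence (a.u., > 0)
#' @slot sigma noise standard deviation on F (a.u., >= 0)
#' @export
setClass("TuningSpec", representation(
  gains = "numeric", tauRise = "numeric", tauDecay = "numeric",
  f0 = "numeric", sigma = "numeric"))

setValidity("TuningSpec", function(object) {
  msg <- character()
  if (!all(.GEN_STATES %in% names(object@gains)))
    msg <- c(msg, "gains must name quiet, pulse, sine, flight")
  if (any(object@gains < 0)) msg <- c(msg, "gains must be >= 0")
  if (object@tauRise <= 0) msg <- c(msg, "tauRise must be positive")
  if (object@tauDecay <= object@tauRise)
    msg <- c(msg, "tauDecay must exceed tauRise")
  if (object@f0 <= 0) msg <- c(msg, "f0 must be positive")
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname TuningSpec-class
#' @param gains named activity gains per state
#' @param tauRise,tauDecay kernel time constants (s)
#' @param f0 baseline fluorescence
#' @param sigma noise standard deviation
#' @return a \code{TuningSpec}
#' @export
tuningSpec <- function(gains = c(quiet = 0, pulse = 1, sine = 0, flight = 0),
                       tauRise = 0.05, tauDecay = 0.5, f0 = 100,
                       sigma = 5) {
  g <- c(quiet = 0, pulse = 0, sine = 0, flight = 0)
  g[names(gains)] <- gains
  new("TuningSpec", gains = g, tauRise = tauRise, tauDecay = tauDecay,
      f0 = f0, sigma = sigma)
}

#' Voxel cluster layout
#'
#' Assigns every voxel of a (z, y, x) volume to a tuning cluster.
#'
#' @slot clusterMap integer (z, y, x) array of cluster indices
#' @slot tunings list of \code{TuningSpec}, one per cluster
#' @export
setClass("VoxelLayout", representation(
  clusterMap = "array", tunings = "list"))

setValidity("VoxelLayout", function(object) {
  if (length(dim(object@clusterMap)) != 3L)
    return("clusterMap must be a 3-D (z, y, x) array")
  if (length(object@clusterMap) == 0L) return("layout must be non-empty")
  k <- max(object@clusterMap)
  if (min(object@clusterMap) < 1L || k > length(object@tunings))
    return("cluster indices must address the tunings list")
  if (!all(vapply(object@tunings, is, TRUE, "TuningSpec")))
    return("tunings must be TuningSpec objects")
  TRUE
})

#' @rdname VoxelLayout-class
#' @param clusterMap integer (z, y, x) array of cluster indices
#' @param tunings list of \code{TuningSpec}
#' @return a \code{VoxelLayout}
#' @export
voxelLayout <- function(clusterMap, tunings) {
  new("VoxelLayout", clusterMap = clusterMap, tunings = tunings)
}

#' Toy connectome generator parameters
#'
#' Block-structured synapse-count model: Poisson counts with one mean within
#' groups and another between groups, plus per-group transmitter profiles.
#'
#' @slot groupSizes neurons per group (>= 1)
#' @slot meanWithin,meanBetween mean synapse counts per ordered pair
#' @slot transmitterProfiles matrix (group x transmitter), rows sum to 1
#' @slot concentration Dirichlet concentration for per-synapse profiles
#' @export
setClass("ConnectomeGenParams", representation(
  groupSizes = "integer", meanWithin = "numeric", meanBetween = "numeric",
  transmitterProfiles = "matrix", concentration = "numeric"))

setValidity("ConnectomeGenParams", function(object) {
  msg <- character()
  if (any(object@groupSizes < 1L)) msg <- c(msg, "group sizes must be >= 1")
  if (object@meanWithin < 0 || object@meanBetween < 0)
    msg <- c(msg, "mean synapse counts must be >= 0")
  if (nrow(object@transmitterProfiles) != length(object@groupSizes))
    msg <- c(msg, "one transmitter profile per group is required")
  if (nrow(object@transmitterProfiles) &&
      max(abs(rowSums(object@transmitterProfiles) - 1)) > 1e-9)
    msg <- c(msg, "each transmitter profile must sum to 1")
  if (length(msg)) msg else TRUE
})

#' @rdname ConnectomeGenParams-class
#' @param groupSizes neurons per group
#' @param meanWithin,meanBetween mean synapse counts per ordered pair
#' @param transmitterProfiles matrix (group x transmitter); default gives
#'   each group its own dominant transmitter
#' @param concentration Dirichlet concentration for per-synapse rows
#' @return a \code{ConnectomeGenParams}
#' @export
connectomeGenParams <- function(groupSizes = c(8L, 8L),
                                meanWithin = 40, meanBetween = 2,
                                transmitterProfiles = NULL,
                                concentration = 50) {
  k <- length(groupSizes)
  if (is.null(transmitterProfiles)) {
    tr <- c("acetylcholine", "gaba", "glutamate")
    transmitterProfiles <- matrix(0.1, k, 3, dimnames = list(NULL, tr))
    for (g in seq_len(k))
      transmitterProfiles[g, 1 + (g - 1) %% 3] <- 0.8
  }
  new("ConnectomeGenParams", groupSizes = as.integer(groupSizes),
      meanWithin = meanWithin, meanBetween = meanBetween,
      transmitterProfiles = transmitterProfiles,
      concentration = concentration)
}
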