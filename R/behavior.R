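#' Behavioral summary container
#'
#' Stimulus-locked time courses of song statistics: either song fractions
#' (per-fly, with across-fly mean and s.e.m.) or conditional next-sample
#' event probabilities pooled across flies, with the per-bin source-state
#' sample counts so that empty bins stay flagged (NA), never imputed.
#'
#' @slot time bin-center times relative to stimulus onset (s)
#' @slot stats matrix statistic x time of means (pooled or across flies)
#' @slot sem matrix of s.e.m. (NA where not applicable)
#' @slot perFly array statistic x time x fly (empty for pooled outputs)
#' @slot counts matrix of source-sample counts (0 rows when not applicable)
#' @export
setClass("BehaviorSummary", representation(
  time = "numeric", stats = "matrix", sem = "matrix", perFly = "array",
  counts = "matrix"))

setValidity("BehaviorSummary", function(object) {
  if (ncol(object@stats) != length(object@time))
    return("stats must have one column per time bin")
  ok <- object@stats[is.finite(object@stats)]
  if (length(ok) && (min(ok) < -1e-9 || max(ok) > 1 + 1e-9))
    return("probabilities must lie in [0,1]")
  TRUE
})

setMethod("show", "BehaviorSummary", function(object) {
  cat("BehaviorSummary:", nrow(object@stats), "statistics x",
      length(object@time), "time bins\n")
  cat("  statistics:", paste(rownames(object@stats), collapse = ", "), "\n")
})

## relative sample times and labels per trial, over a window around onset
.trialSamples <- function(track, stim, window) {
  labs <- as.character(trackLabels(track))
  t <- trackTimes(track)
  out <- vector("list", nTrials(stim))
  for (i in seq_len(nTrials(stim))) {
    rel <- t - trialOnsets(stim)[i]
    sel <- rel >= window[1] & rel < window[2]
    out[[i]] <- list(rel = rel[sel], lab = labs[sel], idx = which(sel))
  }
  out
}

#' Stimulus-locked song-fraction time course
#'
#' Per fly, the fraction of label samples that are pulse song (pulse-train
#' membership after merging pulses with gaps up to the configured maximum
#' inter-pulse interval) or sine song at each stimulus-locked time point,
#' combining repeated presentations; then the across-fly mean and s.e.m.
#'
#' @param tracks list of \code{LabelTrack}, one per fly
#' @param stim a \code{StimSchedule} (shared across flies)
#' @param window stimulus-locked window (s relative to onset)
#' @param config an \code{\link{analysisConfig}}
#' @return a \code{BehaviorSummary} with statistics p_pulse, p_sine
#' @export
songFractionTimecourse <- function(tracks, stim,
                                   window = NULL,
                                   config = analysisConfig()) {
  if (!length(tracks)) stop("at least one fly track is required")
  if (nTrials(stim) < 1L) stop("at least one trial is required")
  if (is.null(window))
    window <- c(-config@behaviorPreWindow,
                max(trialOffsets(stim) - trialOnsets(stim)) +
                  config@behaviorPreWindow)
  per <- samplePeriod(tracks[[1]])
  relGrid <- seq(window[1], window[2] - per / 2, by = per)
  nG <- length(relGrid)
  nFly <- length(tracks)
  perFly <- array(NA_real_, c(2L, nG, nFly),
                  dimnames = list(c("p_pulse", "p_sine"), NULL, NULL))
  for (f in seq_len(nFly)) {
    track <- tracks[[f]]
    ## pulse-train membership on the sample grid
    segs <- labelSegments(track, "pulse")
    train <- rep(FALSE, length(trackTimes(track)))
    if (nrow(segs)) {
      merged <- mergePulseTrain(segs, config@maxIpi)
      t <- trackTimes(track)
      for (m in seq_len(nrow(merged)))
        train <- train | (t >= merged$start[m] & t < merged$end[m])
    }
    isSine <- trackLabels(track) == "sine"
    pulseAcc <- sineAcc <- cntAcc <- rep(0, nG)
    t <- trackTimes(track)
    for (i in seq_len(nTrials(stim))) {
      rel <- t - trialOnsets(stim)[i]
      sel <- which(rel >= window[1] & rel < window[2])
      g <- round((rel[sel] - window[1]) / per) + 1L
      okg <- g >= 1L & g <= nG
      sel <- sel[okg]; g <- g[okg]
      pulseAcc <- pulseAcc + tabulate(g[train[sel]], nG)
      sineAcc <- sineAcc + tabulate(g[isSine[sel]], nG)
      cntAcc <- cntAcc + tabulate(g, nG)
    }
    perFly[1, , f] <- ifelse(cntAcc > 0, pulseAcc / cntAcc, NA)
    perFly[2, , f] <- ifelse(cntAcc > 0, sineAcc / cntAcc, NA)
  }
  m <- apply(perFly, c(1, 2), mean, na.rm = TRUE)
  s <- apply(perFly, c(1, 2), function(v)
    stats::sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v))))
  new("BehaviorSummary", time = relGrid, stats = m, sem = s,
      perFly = perFly, counts = matrix(numeric(), 0, 0))
}

.EVENT_STATS <- c("p_pulse_given_quiet", "p_sine_given_quiet",
                  "p_quiet_given_pulse", "p_sine_given_pulse",
                  "p_quiet_given_sine", "p_pulse_given_sine")

## next-sample transition counts by reporting bin; labels use the raw
## classifier vocabulary with ambient as the quiet state
.transitionCounts <- function(tracks, stim, window, bin) {
  nBins <- ceiling((window[2] - window[1]) / bin - 1e-9)
  src <- c("ambient", "pulse", "sine")
  num <- array(0, c(6L, nBins))
  den <- matrix(0, 3L, nBins, dimnames = list(src, NULL))
  pair <- list(c("ambient", "pulse"), c("ambient", "sine"),
               c("pulse", "ambient"), c("pulse", "sine"),
               c("sine", "ambient"), c("sine", "pulse"))
  for (track in tracks) {
    labs <- as.character(trackLabels(track))
    t <- trackTimes(track)
    n <- length(labs)
    for (i in seq_len(nTrials(stim))) {
      rel <- t - trialOnsets(stim)[i]
      sel <- which(rel >= window[1] & rel < window[2] & seq_len(n) < n)
      if (!length(sel)) next
      g <- floor((rel[sel] - window[1]) / bin) + 1L
      ok <- g >= 1L & g <= nBins
      sel <- sel[ok]; g <- g[ok]
      a <- labs[sel]; b <- labs[sel + 1L]
      for (s in src) {
        den[s, ] <- den[s, ] + tabulate(g[a == s], nBins)
      }
      for (k in seq_along(pair)) {
        hit <- a == pair[[k]][1] & b == pair[[k]][2]
        num[k, ] <- num[k, ] + tabulate(g[hit], nBins)
      }
    }
  }
  list(num = num, den = den, nBins = nBins)
}

#' Conditional song-event probabilities over time
#'
#' Song initiation, termination and switch probabilities: for every sample
#' in a source state (quiet, pulse or sine), the probability that the next
#' label sample is each target state, estimated per stimulus-locked
#' reporting bin (150 ms by default) with data pooled across trials and
#' flies. Bins with no source-state samples are NA (flagged, not zero).
#'
#' @param tracks list of \code{LabelTrack}, one per fly
#' @param stim a \code{StimSchedule}
#' @param window stimulus-locked window (s relative to onset)
#' @param config an \code{\link{analysisConfig}}
#' @return a \code{BehaviorSummary} whose statistics are
#'   p_<target>_given_<source> and whose counts hold source-state samples
#' @export
eventTransitionProbabilities <- function(tracks, stim, window = NULL,
                                         config = analysisConfig()) {
  if (!length(tracks)) stop("at least one fly track is required")
  if (is.null(window))
    window <- c(-config@behaviorPreWindow,
                max(trialOffsets(stim) - trialOnsets(stim)) +
                  config@behaviorPreWindow)
  tc <- .transitionCounts(tracks, stim, window, config@behaviorBin)
  srcOf <- c(1L, 1L, 2L, 2L, 3L, 3L)
  stats <- matrix(NA_real_, 6L, tc$nBins,
                  dimnames = list(.EVENT_STATS, NULL))
  for (k in 1:6) {
    d <- tc$den[srcOf[k], ]
    stats[k, ] <- ifelse(d > 0, tc$num[k, ] / d, NA_real_)
  }
  centers <- window[1] + (seq_len(tc$nBins) - 0.5) * config@behaviorBin
  new("BehaviorSummary", time = centers, stats = stats,
      sem = matrix(NA_real_, 6L, tc$nBins), perFly = array(0, c(0, 0, 0)),
      counts = tc$den)
}

#' Per-fly optogenetic stimulation effects
#'
#' For each fly, the change in song statistics under stimulation: the value
#' computed from all samples during stimulation minus the value from the
#' pre-stimulation window (5 s by default). Reported for the pulse and
#' sine song fractions and the six conditional event probabilities. The
#' sign convention is during minus pre, so positive means stimulation
#' increased the statistic.
#'
#' @param tracks list of \code{LabelTrack}, one per fly
#' @param stim a \code{StimSchedule}
#' @param config an \code{\link{analysisConfig}}
#' @return data.frame, one row per fly, columns d_<statistic>
#' @export
stimulationEffect <- function(tracks, stim, config = analysisConfig()) {
  if (!length(tracks)) stop("at least one fly track is required")
  pre <- config@behaviorPreWindow
  dur <- max(trialOffsets(stim) - trialOnsets(stim))
  oneWindow <- function(track, window) {
    labs <- as.character(trackLabels(track))
    t <- trackTimes(track)
    n <- length(labs)
    idx <- integer(0)
    for (i in seq_len(nTrials(stim))) {
      rel <- t - trialOnsets(stim)[i]
      idx <- c(idx, which(rel >= window[1] & rel < window[2]))
    }
    if (!length(idx)) stop("missing samples in a required window")
    a <- labs[idx]
    hasNext <- idx < n
    b <- labs[pmin(idx + 1L, n)]
    ## pulse fraction uses pulse-train membership
    segs <- labelSegments(track, "pulse")
    train <- rep(FALSE, n)
    if (nrow(segs)) {
      merged <- mergePulseTrain(segs, config@maxIpi)
      for (m in seq_len(nrow(merged)))
        train <- train | (t >= merged$start[m] & t < merged$end[m])
    }
    cond <- function(s, s2) {
      sel <- a == s & hasNext
      if (!any(sel)) return(NA_real_)
      mean(b[sel] == s2)
    }
    c(p_pulse = mean(train[idx]), p_sine = mean(a == "sine"),
      p_pulse_given_quiet = cond("ambient", "pulse"),
      p_sine_given_quiet = cond("ambient", "sine"),
      p_quiet_given_pulse = cond("pulse", "ambient"),
      p_sine_given_pulse = cond("pulse", "sine"),
      p_quiet_given_sine = cond("sine", "ambient"),
      p_pulse_given_sine = cond("sine", "pulse"))
  }
  rows <- lapply(tracks, function(track) {
    during <- oneWindow(track, c(0, dur))
    before <- oneWindow(track, c(-pre, 0))
    during - before
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- paste0("d_", names(rows[[1]]))
  out$fly <- seq_along(tracks)
  out
}
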