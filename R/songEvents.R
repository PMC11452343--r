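#' Median-filter smoothing of classifier predictions
#'
#' Misclassifications in per-sample song labels tend to be short; they are
#' removed by median-filtering the per-class binary indicator of each class
#' that has a configured window (pulse 17.6 ms, sine 25.6 ms, flight 80 ms
#' by default). Window lengths are converted to the nearest odd sample
#' count (ties downward: 17.6 ms -> 11 samples, 25.6 -> 15, 80 -> 49) and
#' track ends are handled by edge replication. After filtering, one label
#' per sample is re-resolved by fixed priority
#' flight > pulse > sine > others > ambient; samples with no active
#' indicator fall back to ambient.
#'
#' @param track a \code{LabelTrack} or \code{ClassProbTrack} (argmax labels)
#' @param config an \code{\link{analysisConfig}}
#' @return a smoothed \code{LabelTrack}
#' @examples
#' tr <- labelTrack(c(rep("ambient", 20), "pulse", rep("ambient", 20)))
#' table(trackLabels(smoothPredictions(tr)))  # 1-sample spur removed
#' @export
smoothPredictions <- function(track, config = analysisConfig()) {
  if (is(track, "ClassProbTrack")) {
    lab <- factor(.SONG_CLASSES[max.col(track@probs, ties.method = "first")],
                  levels = .SONG_CLASSES)
    track <- new("LabelTrack", time = track@time, label = lab,
                 period = track@period)
  }
  stopifnot(is(track, "LabelTrack"))
  per <- track@period
  ind <- lapply(.SONG_CLASSES, function(cl) {
    x <- as.integer(track@label == cl)
    if (cl %in% names(config@medianWindows)) {
      k <- .oddWindow(config@medianWindows[[cl]], per)
      if (k < 3L) stop("median window shorter than 3 samples for ", cl)
      .binaryRunningMedian(x, k)
    } else x
  })
  names(ind) <- .SONG_CLASSES
  n <- length(track@time)
  lab <- rep("ambient", n)
  for (cl in c("ambient", "others", "sine", "pulse", "flight")) {
    lab[ind[[cl]] == 1L] <- cl
  }
  new("LabelTrack", time = track@time,
      label = factor(lab, levels = .SONG_CLASSES), period = per)
}

#' Merge pulse events into pulse trains
#'
#' Pulse song consists of discrete pulses separated by inter-pulse
#' intervals; merging pulses whose gaps are at most \code{maxIpi} (50 ms by
#' default) yields pulse trains comparable in extent to continuous sine
#' bouts.
#'
#' @param segments two-column matrix or data.frame of (start, end) times in
#'   seconds, sorted and non-overlapping
#' @param maxIpi maximum gap merged (s)
#' @return data.frame with columns start, end of merged trains
#' @examples
#' mergePulseTrain(rbind(c(0, 0.010), c(0.050, 0.060), c(0.120, 0.130)))
#' @export
mergePulseTrain <- function(segments, maxIpi = 0.050) {
  segments <- as.matrix(segments)
  if (length(segments) == 0L)
    return(data.frame(start = numeric(), end = numeric()))
  if (ncol(segments) != 2L) stop("segments must have two columns")
  if (any(segments[, 2] <= segments[, 1]))
    stop("each segment must have end > start")
  n <- nrow(segments)
  if (n > 1L) {
    if (is.unsorted(segments[, 1], strictly = FALSE) ||
        any(segments[-1L, 1] < segments[-n, 2]))
      stop("segments must be sorted and non-overlapping")
  }
  start <- segments[1, 1]; end <- segments[1, 2]
  outS <- numeric(); outE <- numeric()
  for (i in seq_len(n)[-1L]) {
    if (segments[i, 1] - end <= maxIpi) {
      end <- segments[i, 2]
    } else {
      outS <- c(outS, start); outE <- c(outE, end)
      start <- segments[i, 1]; end <- segments[i, 2]
    }
  }
  data.frame(start = c(outS, start), end = c(outE, end))
}

#' Extract (start, end) segments of one label from a track
#'
#' @param track a \code{LabelTrack}
#' @param label the label to extract
#' @return data.frame with columns start, end (seconds; end exclusive)
#' @export
labelSegments <- function(track, label = "pulse") {
  stopifnot(is(track, "LabelTrack"))
  r <- rle(as.character(track@label))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values == label
  if (!any(sel)) return(data.frame(start = numeric(), end = numeric()))
  data.frame(start = track@time[starts[sel]],
             end = track@time[ends[sel]] + track@period)
}

#' Bin classifier output to imaging frames
#'
#' Each label-grid sample is assigned to the frame interval
#' [t_k, t_(k+1)) containing it; the per-class mean occurrence probability
#' is computed per frame, and a class flag is raised iff that mean strictly
#' exceeds the class threshold (pulse 0.1, sine 0.6, ambient 0.9, flight
#' 0.01 by default). A single frame state is resolved by priority
#' flight > pulse > sine > quiet; frames with no flag, or outside the track
#' span, are "undefined".
#'
#' @param track a \code{LabelTrack} (indicator means) or
#'   \code{ClassProbTrack} (probability means)
#' @param frameTimes frame start times (s), strictly increasing; defaults
#'   to a nominal grid over the track at the configured frame period
#' @param config an \code{\link{analysisConfig}}
#' @return a \code{FrameBinTrack}
#' @export
binToFrames <- function(track, frameTimes = NULL,
                        config = analysisConfig()) {
  if (is(track, "LabelTrack")) {
    probs <- matrix(0, length(track@time), length(.SONG_CLASSES),
                    dimnames = list(NULL, .SONG_CLASSES))
    probs[cbind(seq_along(track@label), as.integer(track@label))] <- 1
    times <- track@time
  } else if (is(track, "ClassProbTrack")) {
    probs <- track@probs
    times <- track@time
  } else stop("track must be a LabelTrack or ClassProbTrack")
  if (is.null(frameTimes)) {
    frameTimes <- seq(times[1], times[length(times)],
                      by = config@framePeriod)
  }
  nf <- length(frameTimes)
  if (nf > 1L && is.unsorted(frameTimes, strictly = TRUE))
    stop("frameTimes must be strictly increasing")
  per <- if (nf > 1L) stats::median(diff(frameTimes)) else config@framePeriod
  edges <- c(frameTimes, frameTimes[nf] + per)
  idx <- findInterval(times, edges)
  inside <- idx >= 1L & idx <= nf
  counts <- tabulate(idx[inside], nbins = nf)
  means <- matrix(0, nf, ncol(probs), dimnames = list(NULL, colnames(probs)))
  for (cl in colnames(probs)) {
    s <- rep(0, nf)
    agg <- rowsum(probs[inside, cl], idx[inside], reorder = FALSE)
    s[as.integer(rownames(agg))] <- agg[, 1]
    means[, cl] <- ifelse(counts > 0, s / pmax(counts, 1L), NA_real_)
  }
  th <- config@frameThresholds
  flagCls <- c("pulse", "sine", "ambient", "flight")
  flags <- matrix(FALSE, nf, length(flagCls),
                  dimnames = list(NULL, flagCls))
  for (cl in flagCls) {
    flags[, cl] <- !is.na(means[, cl]) & means[, cl] > th[[cl]]
  }
  state <- rep("undefined", nf)
  state[flags[, "ambient"]] <- "quiet"
  state[flags[, "sine"]] <- "sine"
  state[flags[, "pulse"]] <- "pulse"
  state[flags[, "flight"]] <- "flight"
  state[counts == 0L] <- "undefined"
  new("FrameBinTrack", frameTimes = frameTimes, classMeans = means,
      flags = flags, state = factor(state, levels = .FRAME_STATES),
      masked = rep(FALSE, nf), framePeriod = per)
}

#' Mask frames around flight
#'
#' Flight contaminates both behavior and imaging; frames whose interval
#' intersects any flight frame padded by \code{flightPad} seconds on each
#' side (1 s by default) are masked and contribute to no downstream
#' statistic.
#'
#' @param binned a \code{FrameBinTrack}
#' @param config an \code{\link{analysisConfig}}
#' @return the \code{FrameBinTrack} with its mask updated
#' @export
applyFlightMask <- function(binned, config = analysisConfig()) {
  stopifnot(is(binned, "FrameBinTrack"))
  pad <- config@flightPad
  per <- binned@framePeriod
  ft <- binned@frameTimes
  masked <- binned@masked
  for (k in which(binned@state == "flight")) {
    lo <- ft[k] - pad
    hi <- ft[k] + per + pad
    masked <- masked | (ft < hi & (ft + per) > lo)
  }
  binned@masked <- masked
  binned
}

## run-length bookkeeping: for each frame, the length (frames) of the
## contiguous same-state run containing it
.runLengthPerFrame <- function(state) {
  r <- rle(as.character(state))
  rep(r$lengths, r$lengths)
}

#' Detect pulse/sine song-type transitions
#'
#' A pulse-to-sine (sine-to-pulse) event is recorded at every boundary
#' where frame k is pulse (sine) and frame k+1 is sine (pulse) with both
#' frames unmasked; no gap-bridging is performed. Bout lengths are the
#' durations of the contiguous same-state runs on either side.
#'
#' @param binned a \code{FrameBinTrack}
#' @return data.frame with columns kind ("pulse_to_sine"/"sine_to_pulse"),
#'   boundary (index of the first new-state frame), preBout, postBout (s)
#' @export
detectTypeTransitions <- function(binned) {
  stopifnot(is(binned, "FrameBinTrack"))
  st <- as.character(binned@state)
  ok <- !binned@masked
  n <- length(st)
  if (n < 2L)
    return(data.frame(kind = character(), boundary = integer(),
                      preBout = numeric(), postBout = numeric()))
  runLen <- .runLengthPerFrame(st)
  per <- binned@framePeriod
  a <- st[-n]; b <- st[-1L]
  okPair <- ok[-n] & ok[-1L]
  p2s <- which(okPair & a == "pulse" & b == "sine")
  s2p <- which(okPair & a == "sine" & b == "pulse")
  k <- c(p2s, s2p)
  out <- data.frame(
    kind = rep(c("pulse_to_sine", "sine_to_pulse"),
               c(length(p2s), length(s2p))),
    boundary = k + 1L,
    preBout = runLen[k] * per,
    postBout = runLen[k + 1L] * per,
    stringsAsFactors = FALSE)
  out[order(out$boundary), , drop = FALSE]
}

#' Detect quiet-to-pulse transitions
#'
#' Finds pulse frames preceded by at least \code{minQuietRun} seconds
#' (2 s by default) of uninterrupted quiet frames; the pulse frame and the
#' last quiet frame must be unmasked.
#'
#' @param binned a \code{FrameBinTrack}
#' @param config an \code{\link{analysisConfig}}
#' @return data.frame with columns kind ("quiet_to_pulse"), boundary,
#'   preBout, postBout (s)
#' @export
detectQuietToPulse <- function(binned, config = analysisConfig()) {
  stopifnot(is(binned, "FrameBinTrack"))
  st <- as.character(binned@state)
  ok <- !binned@masked
  per <- binned@framePeriod
  runLen <- .runLengthPerFrame(st)
  n <- length(st)
  boundary <- integer(); pre <- numeric(); post <- numeric()
  for (k in which(st == "pulse")) {
    if (k == 1L) next
    if (st[k - 1L] != "quiet") next
    if (!ok[k] || !ok[k - 1L]) next
    quietRun <- runLen[k - 1L]
    ## the run must be entirely unmasked quiet
    runStart <- k - quietRun
    if (any(!ok[seq.int(runStart, k - 1L)])) next
    if (quietRun * per < config@minQuietRun) next
    boundary <- c(boundary, k)
    pre <- c(pre, quietRun * per)
    post <- c(post, runLen[k] * per)
  }
  data.frame(kind = rep("quiet_to_pulse", length(boundary)),
             boundary = boundary, preBout = pre, postBout = post,
             stringsAsFactors = FALSE)
}

#' Tag transition bouts as short or long
#'
#' Each event's pre- and post-transition bouts are tagged against the
#' song-type-specific threshold (pulse 422 ms, sine 704 ms by default); a
#' bout is "long" only if strictly longer than the threshold.
#'
#' @param events data.frame from \code{\link{detectTypeTransitions}}
#' @param config an \code{\link{analysisConfig}}
#' @return the events with added preTag and postTag columns
#' @export
boutLengthPartition <- function(events, config = analysisConfig()) {
  if (!nrow(events)) {
    events$preTag <- character(0)
    events$postTag <- character(0)
    return(events)
  }
  split <- config@boutSplit
  preType <- ifelse(events$kind == "pulse_to_sine", "pulse",
                    ifelse(events$kind == "sine_to_pulse", "sine", NA))
  postType <- ifelse(events$kind == "pulse_to_sine", "sine", "pulse")
  events$preTag <- ifelse(events$preBout > split[preType], "long", "short")
  events$postTag <- ifelse(events$postBout > split[postType], "long", "short")
  events
}
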