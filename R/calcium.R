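#' Compute dF/F against per-trial pre-stimulation baselines
#'
#' For each stimulation trial the baseline F0 is the mean fluorescence over
#' the \code{dffBaselineWindow} seconds (10 s by default) preceding the
#' trial onset; dF/F = (F - F0)/F0 is computed per frame, using each
#' trial's F0 from the start of its baseline window up to the start of the
#' next trial's baseline window. Trials whose baseline window is not fully
#' covered by the recording are skipped with a warning.
#'
#' @param x a \code{FluorescenceTrace} or raw \code{VoxelMovie}
#' @param stim a \code{StimSchedule}
#' @param config an \code{\link{analysisConfig}}
#' @return the input object with dF/F filled in
#' @examples
#' st <- stimSchedule(nTrials = 1, firstOnset = 12)
#' tr <- labelTrack(rep("ambient", 18750))  # 30 s of quiet
#' tc <- simulateCalciumTrace(tr, tuningSpec(sigma = 0), stim = st)
#' range(dff(computeDff(tc, st)))  # identically 0
#' @export
setGeneric("computeDff", function(x, stim, config = analysisConfig())
  standardGeneric("computeDff"))

## per-trial baseline frame selections and per-frame trial epochs;
## shared between the trace and movie methods
.dffEpochs <- function(ft, stim, win) {
  on <- trialOnsets(stim)
  nT <- length(on)
  baseSel <- vector("list", nT)
  usable <- logical(nT)
  for (i in seq_len(nT)) {
    baseSel[[i]] <- which(ft >= on[i] - win & ft < on[i])
    usable[i] <- length(baseSel[[i]]) > 0L && ft[1] <= on[i] - win
  }
  epoch <- findInterval(ft, on - win)  # 0 before first baseline window
  list(baseSel = baseSel, usable = usable, epoch = epoch)
}

#' @rdname computeDff
setMethod("computeDff", "FluorescenceTrace", function(x, stim, config) {
  ep <- .dffEpochs(x@frameTimes, stim, config@dffBaselineWindow)
  nT <- nTrials(stim)
  f0 <- rep(NA_real_, nT)
  for (i in seq_len(nT)) {
    if (!ep$usable[i]) {
      warning("trial ", i, ": baseline window not covered; trial skipped")
      next
    }
    f0[i] <- mean(x@F[ep$baseSel[[i]]])
    if (is.finite(f0[i]) && f0[i] <= 0)
      stop("trial ", i, ": baseline F0 is not positive")
  }
  epoch <- ep$epoch
  epoch[epoch == 0L] <- match(TRUE, ep$usable)
  f0Frame <- f0[epoch]
  x@dff <- (x@F - f0Frame) / f0Frame
  x@f0 <- f0
  validObject(x)
  x
})

#' @rdname computeDff
setMethod("computeDff", "VoxelMovie", function(x, stim, config) {
  if (x@isDff) return(x)
  ep <- .dffEpochs(x@frameTimes, stim, config@dffBaselineWindow)
  d <- dim(x@F)
  M <- matrix(x@F, d[1L])
  nT <- nTrials(stim)
  f0 <- matrix(NA_real_, nT, ncol(M))
  for (i in seq_len(nT)) {
    if (!ep$usable[i]) {
      warning("trial ", i, ": baseline window not covered; trial skipped")
      next
    }
    f0[i, ] <- colMeans(M[ep$baseSel[[i]], , drop = FALSE])
    if (any(f0[i, ] <= 0)) stop("trial ", i, ": non-positive baseline F0")
  }
  epoch <- ep$epoch
  epoch[epoch == 0L] <- match(TRUE, ep$usable)
  M <- (M - f0[epoch, , drop = FALSE]) / f0[epoch, , drop = FALSE]
  x@F <- array(M, d)
  x@isDff <- TRUE
  x
})

#' 2x2 voxel binning
#'
#' Averages non-overlapping \code{factor} x \code{factor} blocks in the xy
#' planes to raise signal-to-noise; z-planes and frames are untouched and
#' trailing remainder rows/columns are dropped.
#'
#' @param movie a \code{VoxelMovie}
#' @param factor binning factor (2 by default)
#' @return the binned \code{VoxelMovie}
#' @export
binVoxels <- function(movie, factor = 2L) {
  stopifnot(is(movie, "VoxelMovie"))
  factor <- as.integer(factor)
  d <- dim(movie@F)
  ny <- d[3L] %/% factor
  nx <- d[4L] %/% factor
  if (ny < 1L || nx < 1L) stop("xy dimensions smaller than the bin factor")
  out <- array(0, c(d[1L], d[2L], ny, nx))
  for (by in seq_len(factor)) {
    for (bx in seq_len(factor)) {
      out <- out + movie@F[, , seq_len(ny) * factor - factor + by,
                           seq_len(nx) * factor - factor + bx, drop = FALSE]
    }
  }
  movie@F <- out / factor^2
  movie@binFactor <- movie@binFactor * factor
  movie
}

#' Responsiveness to optogenetic stimulation
#'
#' Per trial, the response is the mean dF/F during the stimulation period
#' minus the mean dF/F during the 10-s pre-stimulation window; responses
#' are pooled across the requested stimulation levels and tested against
#' zero with a two-sided one-sample t-test. A neuron is called responsive
#' when p < 0.05.
#'
#' @param trace a \code{FluorescenceTrace} with dF/F computed
#' @param stim a \code{StimSchedule}
#' @param levels subset of power levels to pool (default all)
#' @param config an \code{\link{analysisConfig}}
#' @return list with meanResponse, p, responsive, n (trials used)
#' @export
responsivenessTest <- function(trace, stim, levels = NULL,
                               config = analysisConfig()) {
  stopifnot(is(trace, "FluorescenceTrace"))
  d <- dff(trace)
  ft <- trace@frameTimes
  on <- trialOnsets(stim); off <- trialOffsets(stim)
  use <- if (is.null(levels)) seq_along(on) else
    which(trialPowers(stim) %in% levels)
  resp <- vapply(use, function(i) {
    stimSel <- ft >= on[i] & ft < off[i]
    preSel <- ft >= on[i] - config@dffBaselineWindow & ft < on[i]
    if (!any(stimSel) || !any(preSel)) return(NA_real_)
    mean(d[stimSel], na.rm = TRUE) - mean(d[preSel], na.rm = TRUE)
  }, 0)
  resp <- resp[is.finite(resp)]
  if (length(resp) < 2L)
    stop("at least two trials with usable windows are required")
  if (stats::sd(resp) == 0) {
    if (all(resp == 0))
      return(list(meanResponse = 0, p = 1, responsive = FALSE,
                  n = length(resp)))
    stop("degenerate test: responses have zero variance")
  }
  tt <- stats::t.test(resp, mu = 0)
  list(meanResponse = mean(resp), p = tt$p.value,
       responsive = tt$p.value < 0.05, n = length(resp))
}

#' Transition-triggered average
#'
#' Aligns dF/F segments on the boundary between the two transition frames
#' and averages across events with the standard error of the mean; song
#' occupancy (per-class flag means from a binned track) can be averaged
#' identically. Events whose window is truncated by the recording edge are
#' excluded.
#'
#' @param trace a \code{FluorescenceTrace} with dF/F
#' @param events transition events (data.frame with a boundary column)
#' @param window numeric length-2 window around the boundary (s)
#' @param binned optional \code{FrameBinTrack} for song occupancy
#' @return data.frame with timeRel, mean, sem, n; if \code{binned} is
#'   given, per-class occupancy columns occ_<class> are appended
#' @export
transitionTriggeredAverage <- function(trace, events, window = c(-1.5, 1.5),
                                       binned = NULL) {
  stopifnot(is(trace, "FluorescenceTrace"))
  if (!nrow(events)) stop("at least one event is required")
  d <- dff(trace)
  per <- stats::median(diff(trace@frameTimes))
  offs <- seq.int(floor(window[1] / per), ceiling(window[2] / per))
  n <- length(d)
  keep <- events$boundary + min(offs) >= 1L &
    events$boundary + max(offs) <= n
  b <- events$boundary[keep]
  if (!length(b)) stop("no event window fits inside the recording")
  seg <- vapply(b, function(k) d[k + offs], numeric(length(offs)))
  m <- rowMeans(seg)
  sem <- apply(seg, 1L, stats::sd) / sqrt(length(b))
  out <- data.frame(timeRel = offs * per, mean = m, sem = sem,
                    n = length(b))
  if (!is.null(binned)) {
    fl <- binned@flags
    for (cl in colnames(fl)) {
      occ <- vapply(b, function(k) as.numeric(fl[k + offs, cl]),
                    numeric(length(offs)))
      out[[paste0("occ_", cl)]] <- rowMeans(occ)
    }
  }
  out
}

#' Per-event transition response
#'
#' For each song-type transition, the response is the mean dF/F over the
#' compartment's post-transition window (soma: frames +3 and +4 after the
#' change, 282-564 ms; neurite: frames +2 and +3, 141-423 ms, reflecting
#' faster neurite kinetics) minus the mean dF/F over the two frames
#' straddling the transition (141 ms before to 141 ms after). Events with
#' masked or missing frames in either window are excluded.
#'
#' @param trace a \code{FluorescenceTrace} with dF/F
#' @param events data.frame of transition events
#' @param compartment "soma" or "neurite"; defaults to the trace's
#' @param binned optional \code{FrameBinTrack} supplying the frame mask
#' @param config an \code{\link{analysisConfig}}
#' @return data.frame of retained events with delta and baseMean columns;
#'   attribute nExcluded counts dropped events
#' @export
transitionDelta <- function(trace, events, compartment = NULL,
                            binned = NULL, config = analysisConfig()) {
  stopifnot(is(trace, "FluorescenceTrace"))
  if (is.null(compartment)) compartment <- trace@compartment
  offs <- switch(compartment,
                 soma = config@somaPostOffsets,
                 neurite = config@neuritePostOffsets,
                 stop("compartment must be 'soma' or 'neurite'"))
  d <- dff(trace)
  n <- length(d)
  masked <- if (is.null(binned)) rep(FALSE, n) else binned@masked
  delta <- baseMean <- rep(NA_real_, nrow(events))
  for (i in seq_len(nrow(events))) {
    b <- events$boundary[i]
    transIdx <- c(b - 1L, b)
    postIdx <- b + offs
    idx <- c(transIdx, postIdx)
    if (min(idx) < 1L || max(idx) > n) next
    if (any(masked[idx]) || anyNA(d[idx])) next
    baseMean[i] <- mean(d[transIdx])
    delta[i] <- mean(d[postIdx]) - baseMean[i]
  }
  keep <- !is.na(delta)
  out <- cbind(events[keep, , drop = FALSE],
               data.frame(delta = delta[keep], baseMean = baseMean[keep],
                          compartment = rep(compartment, sum(keep))))
  attr(out, "nExcluded") <- sum(!keep)
  out
}

#' Normalized mean transition change
#'
#' The mean per-event response delta divided by the mean transition-window
#' dF/F, computed per transition kind. Requires at least
#' \code{minEventsTransition} events (5 by default) and a mean
#' transition-window dF/F of at least \code{baselineFloor} (0.1), below
#' which the normalization is unreliable and the ROI is excluded.
#'
#' @param responses data.frame from \code{\link{transitionDelta}} for one
#'   ROI and one transition kind
#' @param config an \code{\link{analysisConfig}}
#' @return list with value, n, baseMean, excluded, reason
#' @export
normalizedTransitionChange <- function(responses,
                                       config = analysisConfig()) {
  n <- nrow(responses)
  if (n < config@minEventsTransition)
    return(list(value = NA_real_, n = n, baseMean = NA_real_,
                excluded = TRUE, reason = "too few events"))
  bm <- mean(responses$baseMean)
  if (bm < config@baselineFloor)
    return(list(value = NA_real_, n = n, baseMean = bm,
                excluded = TRUE, reason = "transition-window dF/F below floor"))
  list(value = mean(responses$delta) / bm, n = n, baseMean = bm,
       excluded = FALSE, reason = NA_character_)
}

#' Quiet-to-pulse dF/F change
#'
#' For each quiet-to-pulse transition: mean dF/F over the 2 s after the
#' transition minus mean dF/F over the 2 s before it. Events whose windows
#' fall outside the recording are excluded. At least
#' \code{minEventsQuietPulse} events (2 by default) are required for an
#' ROI-level summary.
#'
#' @param trace a \code{FluorescenceTrace} with dF/F
#' @param events data.frame from \code{\link{detectQuietToPulse}}
#' @param config an \code{\link{analysisConfig}}
#' @param frameTimesBinned frame times of the binned track the events were
#'   detected on (defaults to the trace's frame times)
#' @return numeric vector of per-event deltas (named by boundary frame)
#' @export
quietToPulseDelta <- function(trace, events, config = analysisConfig(),
                              frameTimesBinned = NULL) {
  stopifnot(is(trace, "FluorescenceTrace"))
  d <- dff(trace)
  ft <- trace@frameTimes
  bt <- if (is.null(frameTimesBinned)) ft else frameTimesBinned
  out <- numeric(0)
  for (i in seq_len(nrow(events))) {
    t0 <- bt[events$boundary[i]]
    preSel <- ft >= t0 - 2 & ft < t0
    postSel <- ft >= t0 & ft < t0 + 2
    if (t0 - 2 < ft[1] || t0 + 2 > ft[length(ft)] + 1e-9) next
    if (!any(preSel) || !any(postSel)) next
    v <- mean(d[postSel]) - mean(d[preSel])
    names(v) <- events$boundary[i]
    out <- c(out, v)
  }
  out
}

#' Fit a one-term exponential decay and its half-decay time
#'
#' Fits a * exp(-r t) by nonlinear least squares to the first
#' \code{decaySpan} seconds (845 ms, six frames at 141 ms) of a dF/F time
#' course, initializing the amplitude at the first point and the rate at
#' 1/s. The half-decay time is ln(2)/r. Non-decaying data (r <= 0) are
#' flagged and the half-decay left undefined.
#'
#' @param values dF/F time course (typically a transition-triggered mean)
#' @param times times of the values, relative to the fit origin (s)
#' @param config an \code{\link{analysisConfig}}
#' @param span fit span in seconds (defaults to the configured decaySpan)
#' @return a \code{DecayFit}
#' @examples
#' t <- (0:5) * 0.141
#' fit <- fitDecayHalftime(exp(-t / 0.5), t)
#' halfDecay(fit)  # ln(2) * 0.5
#' @export
fitDecayHalftime <- function(values, times, config = analysisConfig(),
                             span = NULL) {
  if (is.null(span)) span <- config@decaySpan
  sel <- times - times[1] <= span + 1e-9
  y <- values[sel]
  t <- times[sel] - times[1]
  if (length(y) < 3L) stop("at least three points are required in the span")
  if (y[1] <= 0) stop("the initial value must be positive")
  df <- data.frame(t = t, y = y)
  fit <- try(minpack.lm::nlsLM(y ~ a * exp(-r * t), data = df,
                               start = list(a = y[1], r = 1),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    ## fall back to a log-linear fit when all values are positive
    if (any(y <= 0)) stop("decay fit failed: ", attr(fit, "condition")$message)
    lf <- stats::lm(log(y) ~ t)
    a <- exp(stats::coef(lf)[[1]])
    r <- -stats::coef(lf)[[2]]
    res <- y - a * exp(-r * t)
  } else {
    a <- stats::coef(fit)[["a"]]
    r <- stats::coef(fit)[["r"]]
    res <- stats::residuals(fit)
  }
  flagged <- r <= 0
  new("DecayFit", amplitude = a, rate = r,
      halfDecay = if (flagged) NA_real_ else log(2) / r,
      span = span, residualNorm = sqrt(sum(res^2)), flagged = flagged)
}
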