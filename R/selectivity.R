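#' Song-type preference
#'
#' ROC-based selectivity index: the area under the ROC curve discriminating
#' the distribution of dF/F changes at sine-to-pulse transitions from that
#' at pulse-to-sine transitions, rescaled to S = 2 AUC - 1 in [-1, 1]. The
#' AUC is the pairwise win fraction (ties count 0.5), so S > 0 means larger
#' calcium changes around transitions into pulse song (pulse-preferring)
#' and S < 0 sine-preferring.
#'
#' @param deltasP2S numeric dF/F changes at pulse-to-sine transitions
#' @param deltasS2P numeric dF/F changes at sine-to-pulse transitions
#' @return the preference S
#' @examples
#' songTypePreference(c(-1, -2), c(1, 2))   # +1, perfect pulse preference
#' songTypePreference(c(0, 1), c(0, 2))     # 0.25
#' @export
songTypePreference <- function(deltasP2S, deltasS2P) {
  if (!length(deltasP2S) || !length(deltasS2P))
    stop("both transition kinds must have at least one event")
  2 * .rankAUC(deltasS2P, deltasP2S) - 1
}

#' Permutation test for the song-type preference
#'
#' Shuffles the transition-kind labels of the pooled dF/F changes
#' (preserving group sizes), recomputes S for each shuffle, and reports the
#' add-one two-sided p-value
#' p = (1 + #\{|S_null| >= |S_obs|\}) / (1 + nPerm).
#'
#' @param deltasP2S,deltasS2P per-event dF/F changes by transition kind
#' @param nPerm permutation count (10,000 by default)
#' @param seed integer seed for reproducibility
#' @return a \code{PreferenceResult}
#' @export
preferencePermutationTest <- function(deltasP2S, deltasS2P,
                                      nPerm = 10000L, seed = NULL) {
  if (!length(deltasP2S) || !length(deltasS2P))
    stop("both transition kinds must have at least one event")
  n1 <- length(deltasS2P); n2 <- length(deltasP2S)
  if (n1 + n2 < 2L) stop("at least two events are required")
  allv <- c(deltasS2P, deltasP2S)
  r <- rank(allv)
  sumAll <- sum(r)
  Sfrom <- function(rsumPos) 2 * ((rsumPos - n1 * (n1 + 1) / 2) /
                                    (n1 * n2)) - 1
  sObs <- Sfrom(sum(r[seq_len(n1)]))
  nPerm <- as.integer(nPerm)
  .withSeed(seed, {
    exceed <- 0L
    tol <- 1e-12
    for (i in seq_len(nPerm)) {
      idx <- sample.int(n1 + n2, n1)
      if (abs(Sfrom(sum(r[idx]))) >= abs(sObs) - tol) exceed <- exceed + 1L
    }
    new("PreferenceResult", S = sObs,
        p = (1 + exceed) / (1 + nPerm),
        nP2S = n2, nS2P = n1, nPerm = nPerm)
  })
}

## per-event, per-voxel transition responses on a dF/F movie, using the
## soma post-window (the voxel window choice); returns the response matrix
## (events x voxels) and the +/- sign per event (s2p = +1, p2s = -1)
.voxelEventResponses <- function(movie, events, config) {
  stopifnot(is(movie, "VoxelMovie"))
  if (!movie@isDff) stop("movie must hold dF/F; call computeDff() first")
  d <- dim(movie@F)
  M <- matrix(movie@F, d[1L])
  offs <- config@somaPostOffsets
  nEv <- nrow(events)
  V <- matrix(NA_real_, nEv, ncol(M))
  ok <- logical(nEv)
  for (i in seq_len(nEv)) {
    b <- events$boundary[i]
    transIdx <- c(b - 1L, b)
    postIdx <- b + offs
    if (min(transIdx) < 1L || max(postIdx) > d[1L]) next
    V[i, ] <- colMeans(M[postIdx, , drop = FALSE]) -
      colMeans(M[transIdx, , drop = FALSE])
    ok[i] <- TRUE
  }
  sign <- ifelse(events$kind == "sine_to_pulse", 1, -1)
  list(V = V[ok, , drop = FALSE], sign = sign[ok],
      events = events[ok, , drop = FALSE], dims = d[-1L])
}

#' Voxel-wise song-type preference map
#'
#' For every voxel of a dF/F movie, the mean transition response following
#' sine-to-pulse transitions minus the mean following pulse-to-sine
#' transitions (post-transition windows as in \code{transitionDelta}),
#' with per-voxel two-sided permutation significance at \code{voxelAlpha}
#' (0.001 by default). The null is formed either by shuffling whole
#' calcium trials relative to the song trials ("trial", the default; see
#' \code{\link{trialShuffleNull}}) or by shuffling transition-kind labels
#' ("label").
#'
#' @param movie a dF/F \code{VoxelMovie}
#' @param events transition events with kind, boundary and (for the trial
#'   null) trial columns
#' @param stim the \code{StimSchedule} (required for the trial null)
#' @param config an \code{\link{analysisConfig}}
#' @param nPerm number of shuffles
#' @param seed integer seed
#' @param null "trial" or "label"
#' @return a \code{VoxelPreferenceMap}
#' @export
voxelPreferenceMap <- function(movie, events, stim = NULL,
                               config = analysisConfig(),
                               nPerm = config@nPerm, seed = NULL,
                               null = c("trial", "label")) {
  null <- match.arg(null)
  if (nrow(events) < config@minEventsTransition)
    stop("fewer events than the configured minimum; map undefined")
  if (null == "trial") {
    nl <- trialShuffleNull(movie, events, stim, nShuffles = nPerm,
                           seed = seed, config = config)
    obs <- nl$observed
    nullMat <- nl$null
    dims <- nl$dims
    nEv <- nl$nEvents
  } else {
    er <- .voxelEventResponses(movie, events, config)
    s <- er$sign
    n1 <- sum(s > 0); n2 <- sum(s < 0)
    if (n1 == 0L || n2 == 0L) stop("both transition kinds are required")
    obs <- colMeans(er$V[s > 0, , drop = FALSE]) -
      colMeans(er$V[s < 0, , drop = FALSE])
    nEv <- length(s)
    nullMat <- .withSeed(seed, {
      t(vapply(seq_len(nPerm), function(i) {
        idx <- sample.int(nEv, n1)
        colMeans(er$V[idx, , drop = FALSE]) -
          colMeans(er$V[-idx, , drop = FALSE])
      }, numeric(ncol(er$V))))
    })
    dims <- er$dims
  }
  tol <- 1e-12
  exceed <- colSums(abs(nullMat) >= rep(abs(obs), each = nrow(nullMat)) - tol)
  p <- (1 + exceed) / (1 + nrow(nullMat))
  new("VoxelPreferenceMap",
      difference = array(obs, dims),
      pvalue = array(p, dims),
      mask = array(p < config@voxelAlpha, dims),
      alpha = config@voxelAlpha, nEvents = as.integer(nEv))
}

#' Trial-shuffle null for voxel transition responses
#'
#' Breaks the pairing between song-type transitions and calcium signals by
#' permuting whole calcium trials relative to the song trials: for each
#' shuffle, an event detected in song trial T reads its calcium windows at
#' the same within-trial position of calcium trial perm(T). The identity
#' permutation reproduces the observed statistic exactly. Only events whose
#' windows fit inside the common trial length are used.
#'
#' @param movie a dF/F \code{VoxelMovie}
#' @param events transition events with kind and boundary columns
#' @param stim the \code{StimSchedule} defining trial blocks
#' @param nShuffles number of random trial permutations
#' @param seed integer seed
#' @param config an \code{\link{analysisConfig}}
#' @return list with observed (per-voxel statistic), null (shuffles x
#'   voxels), dims (z, y, x), nEvents, nTrials
#' @export
trialShuffleNull <- function(movie, events, stim, nShuffles = 1000L,
                             seed = NULL, config = analysisConfig()) {
  stopifnot(is(movie, "VoxelMovie"), is(stim, "StimSchedule"))
  if (!movie@isDff) stop("movie must hold dF/F; call computeDff() first")
  nT <- nTrials(stim)
  if (nT < 2L) stop("at least two trials are required for trial shuffling")
  ft <- movie@frameTimes
  on <- trialOnsets(stim); off <- trialOffsets(stim)
  blockStart <- vapply(on, function(o) match(TRUE, ft >= o), 0L)
  blockEnd <- vapply(off, function(o) sum(ft < o), 0L)
  if (anyNA(blockStart)) stop("trials outside the recording span")
  L <- min(blockEnd - blockStart + 1L)
  ## event trial and within-block offset, from the boundary frame
  evTrial <- findInterval(ft[events$boundary], on)
  inTrial <- evTrial >= 1L &
    ft[events$boundary] < off[pmax(evTrial, 1L)]
  offs <- config@somaPostOffsets
  j <- events$boundary - blockStart[pmax(evTrial, 1L)]  # 0-based offset
  fits <- inTrial & (j - 1L >= 0L) & (j + max(offs) <= L - 1L)
  ev <- events[fits, , drop = FALSE]
  evTrial <- evTrial[fits]
  j <- j[fits]
  nEv <- nrow(ev)
  if (nEv < 1L) stop("no event windows fit inside the common trial length")
  d <- dim(movie@F)
  M <- matrix(movie@F, d[1L])
  nVox <- ncol(M)
  ## V[c, e, ] = response windows of event e applied to calcium trial c
  V <- array(NA_real_, c(nT, nEv, nVox))
  for (e in seq_len(nEv)) {
    for (cc in seq_len(nT)) {
      b <- blockStart[cc] + j[e]
      V[cc, e, ] <- colMeans(M[b + offs, , drop = FALSE]) -
        colMeans(M[c(b - 1L, b), , drop = FALSE])
    }
  }
  sgn <- ifelse(ev$kind == "sine_to_pulse", 1, -1)
  nPos <- sum(sgn > 0); nNeg <- sum(sgn < 0)
  if (nPos == 0L || nNeg == 0L) stop("both transition kinds are required")
  Vm <- matrix(V, nT * nEv, nVox)  # row index = c + (e-1) * nT
  statFor <- function(perm) {
    rows <- perm[evTrial] + (seq_len(nEv) - 1L) * nT
    W <- Vm[rows, , drop = FALSE]
    colMeans(W[sgn > 0, , drop = FALSE]) -
      colMeans(W[sgn < 0, , drop = FALSE])
  }
  observed <- statFor(seq_len(nT))
  nullMat <- .withSeed(seed, {
    t(vapply(seq_len(nShuffles), function(i) statFor(sample.int(nT)),
             numeric(nVox)))
  })
  list(observed = observed, null = nullMat, dims = d[-1L],
       nEvents = nEv, nTrials = nT, events = ev)
}
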