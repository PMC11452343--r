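#' Accessors
#'
#' Small accessor generics for the package's S4 classes.
#'
#' @param x an object
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trackTimes", function(x) standardGeneric("trackTimes"))
#' @rdname accessors
#' @export
setGeneric("trackLabels", function(x) standardGeneric("trackLabels"))
#' @rdname accessors
#' @export
setGeneric("samplePeriod", function(x) standardGeneric("samplePeriod"))
#' @rdname accessors
#' @export
setGeneric("classProbs", function(x) standardGeneric("classProbs"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("frameStates", function(x) standardGeneric("frameStates"))
#' @rdname accessors
#' @export
setGeneric("classFlags", function(x) standardGeneric("classFlags"))
#' @rdname accessors
#' @export
setGeneric("classMeans", function(x) standardGeneric("classMeans"))
#' @rdname accessors
#' @export
setGeneric("frameMask", function(x) standardGeneric("frameMask"))
#' @rdname accessors
#' @export
setGeneric("rawF", function(x) standardGeneric("rawF"))
#' @rdname accessors
#' @export
setGeneric("dff", function(x) standardGeneric("dff"))
#' @rdname accessors
#' @export
setGeneric("baselineF0", function(x) standardGeneric("baselineF0"))
#' @rdname accessors
#' @export
setGeneric("compartment", function(x) standardGeneric("compartment"))
#' @rdname accessors
#' @export
setGeneric("trialIndex", function(x) standardGeneric("trialIndex"))
#' @rdname accessors
#' @export
setGeneric("trialOnsets", function(x) standardGeneric("trialOnsets"))
#' @rdname accessors
#' @export
setGeneric("trialOffsets", function(x) standardGeneric("trialOffsets"))
#' @rdname accessors
#' @export
setGeneric("trialPowers", function(x) standardGeneric("trialPowers"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("movieData", function(x) standardGeneric("movieData"))
#' @rdname accessors
#' @export
setGeneric("preference", function(x) standardGeneric("preference"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("halfDecay", function(x) standardGeneric("halfDecay"))
#' @rdname accessors
#' @export
setGeneric("neuronIds", function(x) standardGeneric("neuronIds"))
#' @rdname accessors
#' @export
setGeneric("connCounts", function(x) standardGeneric("connCounts"))

setMethod("trackTimes", "LabelTrack", function(x) x@time)
setMethod("trackTimes", "ClassProbTrack", function(x) x@time)
setMethod("trackLabels", "LabelTrack", function(x) x@label)
setMethod("samplePeriod", "LabelTrack", function(x) x@period)
setMethod("samplePeriod", "ClassProbTrack", function(x) x@period)
setMethod("classProbs", "ClassProbTrack", function(x) x@probs)

setMethod("frameTimes", "FrameBinTrack", function(x) x@frameTimes)
setMethod("frameTimes", "FluorescenceTrace", function(x) x@frameTimes)
setMethod("frameTimes", "VoxelMovie", function(x) x@frameTimes)
setMethod("frameStates", "FrameBinTrack", function(x) x@state)
setMethod("classFlags", "FrameBinTrack", function(x) x@flags)
setMethod("classMeans", "FrameBinTrack", function(x) x@classMeans)
setMethod("frameMask", "FrameBinTrack", function(x) x@masked)

setMethod("rawF", "FluorescenceTrace", function(x) x@F)
setMethod("dff", "FluorescenceTrace", function(x) {
  if (!length(x@dff)) stop("dF/F not computed yet; call computeDff()")
  x@dff
})
setMethod("baselineF0", "FluorescenceTrace", function(x) x@f0)
setMethod("compartment", "FluorescenceTrace", function(x) x@compartment)
setMethod("trialIndex", "FluorescenceTrace", function(x) x@trial)

setMethod("trialOnsets", "StimSchedule", function(x) x@onsets)
setMethod("trialOffsets", "StimSchedule", function(x) x@offsets)
setMethod("trialPowers", "StimSchedule", function(x) x@power)
setMethod("nTrials", "StimSchedule", function(x) length(x@onsets))

setMethod("movieData", "VoxelMovie", function(x) x@F)
setMethod("preference", "PreferenceResult", function(x) x@S)
setMethod("pValue", "PreferenceResult", function(x) x@p)
setMethod("halfDecay", "DecayFit", function(x) x@halfDecay)
setMethod("neuronIds", "ConnectivityMatrix", function(x) x@ids)
setMethod("connCounts", "ConnectivityMatrix", function(x) x@counts)

setMethod("show", "LabelTrack", function(object) {
  cat("LabelTrack:", length(object@time), "samples @",
      format(object@period * 1000), "ms\n")
  tab <- table(object@label)
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

setMethod("show", "ClassProbTrack", function(object) {
  cat("ClassProbTrack:", length(object@time), "samples @",
      format(object@period * 1000), "ms,",
      ncol(object@probs), "classes\n")
})

setMethod("show", "FrameBinTrack", function(object) {
  cat("FrameBinTrack:", length(object@frameTimes), "frames @",
      format(object@framePeriod * 1000), "ms;",
      sum(object@masked), "masked\n")
  tab <- table(object@state)
  cat("  states:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

setMethod("show", "FluorescenceTrace", function(object) {
  cat("FluorescenceTrace", object@roi, "(", object@compartment, "):",
      length(object@frameTimes), "frames;",
      if (length(object@dff)) "dF/F computed" else "raw only", "\n")
})

setMethod("show", "VoxelMovie", function(object) {
  d <- dim(object@F)
  cat("VoxelMovie:", d[1], "frames x", d[2], "z x", d[3], "y x", d[4], "x;",
      if (object@isDff) "dF/F" else "raw F", "\n")
})

setMethod("show", "StimSchedule", function(object) {
  cat("StimSchedule:", length(object@onsets), "trials, powers {",
      paste(unique(object@power), collapse = ", "), "}\n")
})

setMethod("show", "PreferenceResult", function(object) {
  cat(sprintf("Song-type preference S = %+.3f (n = %d pulse->sine, %d sine->pulse)\n",
              object@S, object@nP2S, object@nS2P))
  if (!is.na(object@p))
    cat(sprintf("  two-sided permutation p = %.4g (%d permutations)\n",
                object@p, object@nPerm))
})

setMethod("show", "DecayFit", function(object) {
  if (object@flagged) {
    cat("DecayFit: non-decaying data (rate <= 0); half-decay undefined\n")
  } else {
    cat(sprintf("DecayFit: half-decay %.3f s (rate %.3f /s, amplitude %.3f)\n",
                object@halfDecay, object@rate, object@amplitude))
  }
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat("ConnectivityMatrix:", length(object@ids), "neurons,",
      sum(object@counts), "synapses\n")
})

setMethod("show", "VoxelPreferenceMap", function(object) {
  cat("VoxelPreferenceMap:", paste(dim(object@difference), collapse = " x "),
      "voxels;", sum(object@mask), "significant at alpha =",
      object@alpha, "\n")
})
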