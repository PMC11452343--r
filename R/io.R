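#' Read and write track and table CSV files
#'
#' Plain-text interchange for the package's objects. Label tracks are
#' written with columns time_s, label; probability tracks with time_s and
#' p_pulse, p_sine, p_ambient, p_others, p_flight; transition events with
#' kind, boundary_frame, pre_bout_s, post_bout_s and any tag columns;
#' synapse tables with pre_id, post_id, count.
#'
#' @param x object to write
#' @param path file path
#' @return readers return the reconstructed object; writers return
#'   \code{path} invisibly
#' @name track-io
NULL

#' @rdname track-io
#' @export
writeLabelTrack <- function(x, path) {
  stopifnot(is(x, "LabelTrack"))
  utils::write.csv(data.frame(time_s = x@time,
                              label = as.character(x@label)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname track-io
#' @export
readLabelTrack <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  per <- if (nrow(df) > 1L) stats::median(diff(df$time_s)) else 0.0016
  labelTrack(df$label, period = per, time = df$time_s)
}

#' @rdname track-io
#' @export
writeClassProbTrack <- function(x, path) {
  stopifnot(is(x, "ClassProbTrack"))
  df <- data.frame(time_s = x@time)
  for (cl in colnames(x@probs)) df[[paste0("p_", cl)]] <- x@probs[, cl]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname track-io
#' @export
readClassProbTrack <- function(path) {
  df <- utils::read.csv(path)
  probs <- as.matrix(df[, paste0("p_", .SONG_CLASSES)])
  colnames(probs) <- .SONG_CLASSES
  per <- if (nrow(df) > 1L) stats::median(diff(df$time_s)) else 0.0016
  new("ClassProbTrack", time = df$time_s, probs = probs, period = per)
}

#' @rdname track-io
#' @export
writeTransitions <- function(x, path) {
  out <- x
  names(out)[names(out) == "boundary"] <- "boundary_frame"
  names(out)[names(out) == "preBout"] <- "pre_bout_s"
  names(out)[names(out) == "postBout"] <- "post_bout_s"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname track-io
#' @export
readTransitions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "boundary_frame"] <- "boundary"
  names(df)[names(df) == "pre_bout_s"] <- "preBout"
  names(df)[names(df) == "post_bout_s"] <- "postBout"
  df
}

#' @rdname track-io
#' @export
writeSynapseTable <- function(x, path) {
  stopifnot(all(c("pre_id", "post_id", "count") %in% names(x)))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname track-io
#' @export
readSynapseTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(pre_id = "character",
                                 post_id = "character"))
}
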