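#' Filter connectome neurons
#'
#' Keeps neurons that have been traced and possess at least
#' \code{minTotal} presynapses or postsynapses (100 by default; the bound
#' is inclusive).
#'
#' @param meta data.frame with columns body_id, traced, pre, post
#' @param minTotal minimum presynapse or postsynapse count
#' @return character vector of retained body ids
#' @examples
#' meta <- data.frame(body_id = c("a", "b"), traced = c(TRUE, TRUE),
#'                    pre = c(100, 99), post = c(0, 99))
#' filterNeurons(meta)  # "a"
#' @export
filterNeurons <- function(meta, minTotal = 100) {
  stopifnot(all(c("body_id", "traced", "pre", "post") %in% names(meta)))
  keep <- meta$traced & (meta$pre >= minTotal | meta$post >= minTotal)
  as.character(meta$body_id[keep])
}

#' Build a synapse-count connectivity matrix
#'
#' Entry (i, j) is the total number of synapses from neuron i onto neuron
#' j, summed over duplicate table rows; pairs absent from the table are 0,
#' and rows whose ids are not in the neuron list are ignored (their count
#' is reported in a message).
#'
#' @param neurons ordered character vector of neuron ids (already filtered)
#' @param table data.frame with columns pre_id, post_id, count
#' @return a \code{ConnectivityMatrix}
#' @export
buildConnectivityMatrix <- function(neurons, table) {
  stopifnot(all(c("pre_id", "post_id", "count") %in% names(table)))
  neurons <- as.character(neurons)
  n <- length(neurons)
  counts <- matrix(0, n, n, dimnames = list(neurons, neurons))
  i <- match(as.character(table$pre_id), neurons)
  j <- match(as.character(table$post_id), neurons)
  keep <- !is.na(i) & !is.na(j)
  if (any(!keep))
    message(sum(!keep), " synapse rows referenced neurons outside the list",
            " and were ignored")
  if (any(keep)) {
    lin <- (j[keep] - 1L) * n + i[keep]
    agg <- rowsum(as.numeric(table$count[keep]), lin)
    counts[as.integer(rownames(agg))] <- agg[, 1L]
  }
  new("ConnectivityMatrix", ids = neurons, counts = counts)
}

#' Upstream partner table
#'
#' Upstream neurons with at least \code{minSyn} synapses (50 by default,
#' inclusive) onto the target, in descending synapse order.
#'
#' @param target target neuron id
#' @param table data.frame with columns pre_id, post_id, count
#' @param minSyn minimum synapse count onto the target
#' @return data.frame with columns pre_id, count, sorted descending
#' @export
upstreamPartnerTable <- function(target, table, minSyn = 50) {
  sel <- as.character(table$post_id) == as.character(target)
  if (!any(sel)) {
    warning("target ", target, " absent from the synapse table")
    return(data.frame(pre_id = character(), count = numeric()))
  }
  agg <- stats::aggregate(count ~ pre_id, data = table[sel, , drop = FALSE],
                          FUN = sum)
  agg <- agg[agg$count >= minSyn, , drop = FALSE]
  agg <- agg[order(-agg$count), , drop = FALSE]
  rownames(agg) <- NULL
  agg$pre_id <- as.character(agg$pre_id)
  agg
}

#' Connectivity feature vectors
#'
#' Per neuron, the concatenation of its input synapse counts (one per
#' neuron in the matrix) and its output counts to each of the other
#' neurons; self-synapse entries are zeroed. Raw counts are used — cosine
#' distance, the intended metric, is scale-invariant. Neurons whose vector
#' is all zero are flagged (cosine distance is undefined for them).
#'
#' @param cm a \code{ConnectivityMatrix}
#' @return numeric matrix (neurons x 2n features) with attribute
#'   \code{allZero}, a logical vector flagging undefined neurons
#' @examples
#' cm <- buildConnectivityMatrix(c("A", "B"),
#'   data.frame(pre_id = "A", post_id = "B", count = 5))
#' connectivityFeatureVectors(cm)
#' @export
connectivityFeatureVectors <- function(cm) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  C <- cm@counts
  Cz <- C
  diag(Cz) <- 0
  feats <- cbind(t(Cz), Cz)  # inputs (column of C), then outputs (row)
  colnames(feats) <- c(paste0("in_", cm@ids), paste0("out_", cm@ids))
  rownames(feats) <- cm@ids
  attr(feats, "allZero") <- rowSums(feats) == 0
  feats
}

#' Pairwise cosine distances between feature vectors
#'
#' @param feats matrix from \code{\link{connectivityFeatureVectors}}
#' @return symmetric matrix of cosine distances (NA for all-zero vectors)
#' @export
cosineDistanceMatrix <- function(feats) {
  n <- nrow(feats)
  D <- matrix(0, n, n, dimnames = list(rownames(feats), rownames(feats)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) next
      D[i, j] <- D[j, i] <- if (i == j) 0 else
        .cosineDist(feats[i, ], feats[j, ])
    }
  }
  D
}

#' Mean transmitter profile of a neuron
#'
#' Unweighted mean of per-synapse transmitter probability vectors; the
#' result sums to 1 when the inputs do.
#'
#' @param rows data.frame of per-synapse rows with p_<transmitter> columns
#'   (a neuron_id column, if present, must be constant)
#' @return named numeric vector of mean probabilities
#' @examples
#' rows <- data.frame(p_acetylcholine = c(0.8, 0.6),
#'                    p_gaba = c(0.2, 0.4))
#' meanTransmitterProfile(rows)  # 0.7, 0.3
#' @export
meanTransmitterProfile <- function(rows) {
  if (!nrow(rows)) {
    warning("no synapse rows; transmitter profile undefined")
    return(stats::setNames(numeric(0), character(0)))
  }
  if ("neuron_id" %in% names(rows) &&
      length(unique(rows$neuron_id)) > 1L)
    stop("rows must belong to a single neuron")
  pcols <- grep("^p_", names(rows), value = TRUE)
  if (!length(pcols)) stop("no p_<transmitter> columns found")
  colMeans(as.matrix(rows[, pcols, drop = FALSE]))
}
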