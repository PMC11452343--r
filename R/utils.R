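## Internal helpers.

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Sliding median of a binary vector with odd window k and edge replication.
.binaryRunningMedian <- function(x, k) {
  stopifnot(k %% 2L == 1L, k >= 1L)
  if (k == 1L || length(x) == 0L) return(x)
  h <- (k - 1L) %/% 2L
  n <- length(x)
  xp <- c(rep(x[1L], h), x, rep(x[n], h))
  cs <- c(0, cumsum(xp))
  counts <- cs[seq_len(n) + k] - cs[seq_len(n)]
  as.integer(counts >= (k + 1L) %/% 2L)
}

## Odd sample count nearest to w samples, ties resolved downward.
.oddWindow <- function(windowSec, period) {
  w <- windowSec / period
  k <- 2L * as.integer(ceiling(w / 2)) - 1L
  max(k, 1L)
}

## Cosine distance between two non-negative vectors; NA if either is zero.
.cosineDist <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(NA_real_)
  1 - sum(a * b) / (na * nb)
}

## Midrank AUC of `pos` versus `neg`: P(pos > neg) + 0.5 P(pos == neg).
.rankAUC <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
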