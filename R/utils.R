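# Internal helpers shared across the pipeline stages.

#' Derive a deterministic child seed from a master seed
#'
#' Stages that consume randomness (simulation, doublet scoring, GSEA
#' permutations) each get their own stream derived from one master seed, so
#' a whole pipeline run is reproducible from a single integer.
#'
#' @param master integer master seed.
#' @param stage character scalar naming the consumer.
#' @return an integer seed in [0, 2^31 - 1).
#' @keywords internal
child_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  # small multiplicative hash over the stage name, kept inside 32-bit range
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(master) %% 2147483647 * 2654435 + h) %% 2147483647)
}

#' Log-normalize a counts matrix to log1p counts-per-`scale` per cell
#' @param counts sparse gene x cell matrix.
#' @param scale target library size (default 1e4).
#' @keywords internal
log_normalize <- function(counts, scale = 1e4) {
  tot <- Matrix::colSums(counts)
  tot[tot == 0] <- 1
  sf <- scale / tot
  out <- counts %*% Matrix::Diagonal(x = sf)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  out
}

#' Midrank-based percentile ranks in [0, 1]
#'
#' Ties receive their midrank, so a large mass of equal values (e.g. genes
#' with zero ambient counts) sits in the middle of its own block instead of
#' all being pushed to the top.
#' @keywords internal
percentile_rank <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(0.5)
  (rank(x, ties.method = "average") - 0.5) / n
}

geometric_mean <- function(x) exp(mean(log(x)))

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Inverse of trigamma() by Newton iteration on 1/x scale (monotone, convex).
trigamma_inverse <- function(y) {
  stopifnot(y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}
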