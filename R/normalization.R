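#' Median-of-ratios size factors
#'
#' For each unit j, the size factor is the median over reference-positive
#' genes (genes with nonzero geometric mean across units, i.e. no zero
#' counts) of the ratio `counts[g, j] / geometric_mean_g`. When no
#' reference-positive gene exists the factors fall back to library-size
#' ratios, with a warning.
#'
#' @param counts gene x unit nonnegative matrix.
#' @return per-unit numeric factors (all > 0).
#' @export
size_factors_median_ratio <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 1, all(counts >= 0))
  ref_pos <- rowSums(counts == 0) == 0 & rowSums(counts) > 0
  if (!any(ref_pos)) {
    warning("no gene is positive in all units; ",
            "falling back to library-size ratios")
    libs <- colSums(counts)
    return(libs / geometric_mean(libs))
  }
  logc <- log(counts[ref_pos, , drop = FALSE])
  log_gm <- rowMeans(logc)
  apply(exp(logc - log_gm), 2, stats::median)
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Composition-correction factors relative to a reference unit, computed as
#' the inverse-variance-weighted mean of gene-wise log ratios (M-values)
#' after trimming the most extreme `trim_m` fraction by M and `trim_a`
#' fraction by average log expression (A). The reference unit is the one
#' whose upper-quartile count fraction is closest to the mean upper
#' quartile. Factors are normalized to geometric mean 1, so they carry no
#' depth information — library size is handled separately.
#'
#' @param counts gene x unit nonnegative matrix.
#' @param trim_m two-sided trim fraction on M-values (default 0.30).
#' @param trim_a two-sided trim fraction on A-values (default 0.05).
#' @return per-unit factors with geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 1, all(counts >= 0))
  libs <- colSums(counts)
  if (any(libs == 0)) stop("unit with all-zero counts")
  uq <- apply(counts, 2, function(x) stats::quantile(x[x > 0] / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    tmm_pair(counts[, j], counts[, ref], libs[j], libs[ref], trim_m, trim_a)
  }, numeric(1))
  f / geometric_mean(f)
}

# One TMM factor of column `obs` against column `ref`.
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) return(1)
  y_o <- obs[pos]; y_r <- ref[pos]
  m <- log2((y_o / n_obs) / (y_r / n_ref))
  a <- 0.5 * log2((y_o / n_obs) * (y_r / n_ref))
  w <- (n_obs - y_o) / (n_obs * y_o) + (n_ref - y_r) / (n_ref * y_r)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m, ties.method = "first")
  ra_ <- rank(a, ties.method = "first")
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep) || all(w[keep] == 0)) return(1)
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}
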