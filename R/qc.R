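#' Cell-level QC thresholds
#'
#' Defaults implement the droplet QC rules used throughout the pipeline:
#' cells with fewer than 500 UMIs or 200 detected genes are removed, the
#' per-sample mitochondrial cap is the 95th percentile of mitochondrial
#' content rounded up to the nearest value on a fixed grid (20/25/30/35%),
#' hemoglobin content above 0.1% flags contaminating erythrocytes, and the
#' doublet quota is 2% of cells per sample.
#'
#' @param min_umi minimum total UMI count (strict: `< min_umi` fails).
#' @param min_genes minimum number of detected genes (strict).
#' @param mito_cap_grid strictly increasing grid of admissible mito caps.
#' @param mito_percentile percentile of per-cell mito fractions the cap is
#'   derived from.
#' @param hemo_max maximum hemoglobin fraction (strict: `> hemo_max` fails).
#' @param expected_doublet_rate fraction of cells flagged as doublets.
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_umi = 500, min_genes = 200,
                          mito_cap_grid = c(0.20, 0.25, 0.30, 0.35),
                          mito_percentile = 0.95,
                          hemo_max = 0.001,
                          expected_doublet_rate = 0.02) {
  stopifnot(min_umi >= 0, min_genes >= 0,
            length(mito_cap_grid) >= 1, !is.unsorted(mito_cap_grid, strictly = TRUE),
            mito_percentile > 0, mito_percentile < 1,
            hemo_max >= 0, expected_doublet_rate >= 0, expected_doublet_rate < 1)
  structure(list(min_umi = min_umi, min_genes = min_genes,
                 mito_cap_grid = mito_cap_grid,
                 mito_percentile = mito_percentile, hemo_max = hemo_max,
                 expected_doublet_rate = expected_doublet_rate),
            class = "qc_thresholds")
}

#' Sample-adaptive mitochondrial threshold
#'
#' Returns the smallest grid value at or above the configured percentile
#' (default 95th, type-7 linear-interpolation quantile) of the per-cell
#' mitochondrial fractions. A percentile above the largest grid value is
#' capped at the largest grid value; sample-level exclusion is left to the
#' operator via the QC report.
#'
#' @param per_cell_mito_fractions numeric vector in [0, 1].
#' @param thresholds a [qc_thresholds()].
#' @return one grid value.
#' @export
mito_threshold <- function(per_cell_mito_fractions,
                           thresholds = qc_thresholds()) {
  x <- per_cell_mito_fractions
  if (!length(x)) stop("empty mitochondrial fraction vector")
  stopifnot(all(x >= 0 & x <= 1))
  q <- stats::quantile(x, thresholds$mito_percentile, type = 7, names = FALSE)
  grid <- thresholds$mito_cap_grid
  hit <- grid[grid >= q]
  if (length(hit)) hit[1] else grid[length(grid)]
}

#' Apply the cell-level count, gene, mitochondrial and hemoglobin filters
#'
#' A cell fails when `total_umi < min_umi`, OR `n_genes_detected < min_genes`,
#' OR its mitochondrial fraction exceeds its sample's [mito_threshold()], OR
#' its hemoglobin fraction exceeds `hemo_max`. All bounds are strict, so a
#' cell sitting exactly on a bound survives. The mitochondrial cap is
#' per-sample; the other filters are global.
#'
#' @param matrix a [cell_matrix()] (one or more samples).
#' @param thresholds a [qc_thresholds()].
#' @return list with `matrix` (restricted to passing cells) and `report`
#'   (one row per sample: input/fail/retained counts, threshold used, and an
#'   `excluded` flag for samples left with zero cells).
#' @export
apply_cell_filters <- function(matrix, thresholds = qc_thresholds()) {
  stopifnot(inherits(matrix, "cell_matrix"))
  bm <- matrix$barcode_meta
  fail_umi <- bm$total_umi < thresholds$min_umi
  fail_genes <- bm$n_genes_detected < thresholds$min_genes
  fail_hemo <- bm$hemo_fraction > thresholds$hemo_max
  samples <- unique(bm$sample_id)
  mito_cap <- vapply(samples, function(s)
    mito_threshold(bm$mito_fraction[bm$sample_id == s], thresholds),
    numeric(1))
  fail_mito <- bm$mito_fraction > mito_cap[bm$sample_id]
  pass <- !(fail_umi | fail_genes | fail_mito | fail_hemo)

  report <- data.frame(
    sample_id = samples,
    n_input = as.integer(table(factor(bm$sample_id, samples))),
    n_fail_umi = vapply(samples, function(s)
      sum(fail_umi[bm$sample_id == s]), integer(1)),
    n_fail_genes = vapply(samples, function(s)
      sum(fail_genes[bm$sample_id == s]), integer(1)),
    mito_threshold_used = unname(mito_cap),
    n_fail_mito = vapply(samples, function(s)
      sum(fail_mito[bm$sample_id == s]), integer(1)),
    n_fail_hemo = vapply(samples, function(s)
      sum(fail_hemo[bm$sample_id == s]), integer(1)),
    n_doublets = NA_integer_,
    n_retained = vapply(samples, function(s)
      sum(pass[bm$sample_id == s]), integer(1)),
    stringsAsFactors = FALSE)
  report$excluded <- report$n_retained == 0L
  if (any(report$excluded))
    warning("sample(s) with zero surviving cells: ",
            paste(report$sample_id[report$excluded], collapse = ", "))
  rownames(report) <- NULL
  out <- subset_barcodes(matrix, pass)
  out$barcode_meta$qc_pass <- TRUE
  list(matrix = out, report = report)
}

#' Score and flag within-sample doublets by artificial-doublet kNN
#'
#' A simplified single-pass artificial-nearest-neighbour scorer: artificial
#' doublets are averages of random pairs of log-normalised cell profiles;
#' real and artificial cells are embedded together by PCA; each real cell's
#' score is the proportion of artificial doublets among its k nearest
#' neighbours; the top `expected_rate` fraction of real cells by score is
#' flagged. No neighbourhood-size sweep is performed: the expected rate is
#' fixed by configuration.
#'
#' @param matrix a [cell_matrix()] containing a single sample.
#' @param expected_rate fraction of cells to flag (0 flags none).
#' @param k neighbourhood size; must be < number of cells.
#' @param n_artificial number of artificial doublets (default: one per cell).
#' @param n_pcs PCA dimensionality of the joint embedding.
#' @param seed integer seed (pair sampling).
#' @return the matrix with `doublet_score` and `is_doublet` filled in.
#' @export
doublet_scores <- function(matrix, expected_rate = 0.02, k = 20,
                           n_artificial = NULL, n_pcs = 10, seed = 1L) {
  stopifnot(inherits(matrix, "cell_matrix"))
  if (length(unique(matrix$barcode_meta$sample_id)) != 1L)
    stop("doublet_scores operates on one sample at a time")
  n <- ncol(matrix$counts)
  if (n < 2 * k) stop("need at least 2*k cells")
  if (k >= n) stop("k must be smaller than the number of cells")
  n_artificial <- n_artificial %||% n
  set.seed(seed)
  norm <- log_normalize(matrix$counts)
  p1 <- sample.int(n, n_artificial, replace = TRUE)
  p2 <- sample.int(n, n_artificial, replace = TRUE)
  art <- (norm[, p1, drop = FALSE] + norm[, p2, drop = FALSE]) / 2
  joint <- t(as.matrix(cbind(norm, art)))      # cells x genes
  n_pcs <- min(n_pcs, nrow(joint) - 1L, ncol(joint))
  emb <- stats::prcomp(joint, center = TRUE, scale. = FALSE,
                       rank. = n_pcs)$x
  real <- emb[seq_len(n), , drop = FALSE]
  d2 <- outer(rowSums(real^2), rowSums(emb^2), "+") - 2 * real %*% t(emb)
  is_art <- c(rep(FALSE, n), rep(TRUE, n_artificial))
  score <- numeric(n)
  for (i in seq_len(n)) {
    di <- d2[i, ]
    di[i] <- Inf                               # exclude self
    nb <- order(di)[seq_len(k)]
    score[i] <- mean(is_art[nb])
  }
  matrix$barcode_meta$doublet_score <- score
  n_flag <- floor(expected_rate * n)
  flag <- rep(FALSE, n)
  if (n_flag > 0) flag[order(-score, seq_len(n))[seq_len(n_flag)]] <- TRUE
  matrix$barcode_meta$is_doublet <- flag
  matrix
}
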