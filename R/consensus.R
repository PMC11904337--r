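#' Merge three engine results and apply the consensus significance rule
#'
#' A gene is consensus-significant in a cell type when its absolute log2
#' fold change exceeds `lfc_cut` AND it is significant at `p_cut_multi`
#' (BH-adjusted) in at least two engines, OR significant at `p_cut_single`
#' in at least one. The fold-change gate is applied to the cross-engine mean
#' log2FC by default (`lfc_source = "mean"`); `"any"` and `"all"` gate on
#' the per-engine fold changes instead. Genes missing from an engine are
#' treated as non-significant there and their mean log2FC uses the engines
#' that report them.
#'
#' @param results list of the three engine tables (see [run_de_engines()]).
#' @param lfc_cut strict absolute log2 fold-change cutoff (default 0.5).
#' @param p_cut_multi adjusted-p cutoff for the two-engine branch (0.05).
#' @param p_cut_single adjusted-p cutoff for the single-engine branch (0.01).
#' @param lfc_source which fold change the `lfc_cut` gate uses.
#' @return a `ConsensusTable` data.frame: per (cell type, gene) the three
#'   log2FCs and adjusted p-values, `mean_log2FC`, `n_engines_sig_05`,
#'   `min_adj_p`, `passes_lfc` and `consensus_sig`.
#' @export
consensus_call <- function(results, lfc_cut = 0.5, p_cut_multi = 0.05,
                           p_cut_single = 0.01,
                           lfc_source = c("mean", "any", "all")) {
  lfc_source <- match.arg(lfc_source)
  if (length(results) != 3) stop("exactly three engine tables are required")
  engines <- vapply(results, function(r) r$engine[1], "")
  keys <- unique(do.call(rbind, lapply(results, function(r)
    r[, c("cell_type", "gene")])))
  out <- keys
  for (i in 1:3) {
    r <- results[[i]]
    idx <- match(paste(keys$cell_type, keys$gene),
                 paste(r$cell_type, r$gene))
    out[[paste0("log2FC_", engines[i])]] <- r$log2FC[idx]
    out[[paste0("adj_p_", engines[i])]] <- r$adj_p[idx]
  }
  lfc_mat <- as.matrix(out[, paste0("log2FC_", engines)])
  p_mat <- as.matrix(out[, paste0("adj_p_", engines)])
  out$mean_log2FC <- rowMeans(lfc_mat, na.rm = TRUE)
  out$n_engines_sig_05 <- rowSums(p_mat < p_cut_multi, na.rm = TRUE)
  out$min_adj_p <- apply(p_mat, 1, function(x)
    if (all(is.na(x))) 1 else min(x, na.rm = TRUE))
  out$passes_lfc <- switch(lfc_source,
    mean = abs(out$mean_log2FC) > lfc_cut,
    any = apply(abs(lfc_mat) > lfc_cut, 1, any, na.rm = TRUE),
    all = apply(abs(lfc_mat) > lfc_cut, 1, all, na.rm = TRUE))
  out$passes_lfc[is.na(out$passes_lfc)] <- FALSE
  out$consensus_sig <- out$passes_lfc &
    (out$n_engines_sig_05 >= 2 | out$min_adj_p < p_cut_single)
  rownames(out) <- NULL
  class(out) <- c("consensus_table", "data.frame")
  out
}

#' Count unique consensus DEGs across cell types
#'
#' Number of distinct gene identifiers significant in at least one cell
#' type. Uses `final_sig` (i.e. after the ambient filter, see
#' [ambient_flag()]) when present, `consensus_sig` otherwise.
#'
#' @param table a consensus table covering one or more cell types.
#' @return integer count.
#' @export
unique_deg_count <- function(table) {
  stopifnot(is.data.frame(table))
  sig <- if ("final_sig" %in% names(table)) table$final_sig
         else table$consensus_sig
  length(unique(table$gene[sig]))
}

#' Fuse the three engines' fold changes into a PC1 rank score
#'
#' Per cell type, the genes x 3 matrix of engine log2 fold changes is
#' column-centred (not scaled: the columns share units) and projected onto
#' its first right singular vector. The sign of PC1 is oriented so that the
#' score correlates positively with the mean log2FC, making enrichment
#' directions interpretable. Genes missing a fold change in any engine are
#' excluded from the projection (score NA).
#'
#' @param table a consensus table (see [consensus_call()]).
#' @param scale_cols also scale columns to unit variance (default FALSE).
#' @return the table with a `pc1_score` column; the per-cell-type PC1
#'   explained-variance proportions are attached as attribute
#'   `pc1_explained`.
#' @export
pc1_rank <- function(table, scale_cols = FALSE) {
  stopifnot(inherits(table, "consensus_table") || is.data.frame(table))
  lfc_cols <- grep("^log2FC_", names(table), value = TRUE)
  stopifnot(length(lfc_cols) == 3)
  table$pc1_score <- NA_real_
  explained <- c()
  for (ct in unique(table$cell_type)) {
    rows <- which(table$cell_type == ct)
    m <- as.matrix(table[rows, lfc_cols])
    ok <- rowSums(!is.finite(m)) == 0
    if (sum(ok) < 3) next
    x <- scale(m[ok, , drop = FALSE], center = TRUE, scale = scale_cols)
    sv <- svd(x)
    if (sv$d[1] < 1e-12) {
      warning("degenerate fold-change matrix in ", ct,
              ": all PC1 scores equal")
      score <- rep(0, sum(ok))
      explained[ct] <- NA_real_
    } else {
      score <- drop(x %*% sv$v[, 1])
      mlfc <- rowMeans(m[ok, , drop = FALSE])
      if (stats::sd(mlfc) > 0 && stats::cor(score, mlfc) < 0) score <- -score
      explained[ct] <- sv$d[1]^2 / sum(sv$d^2)
    }
    table$pc1_score[rows[ok]] <- score
  }
  attr(table, "pc1_explained") <- explained
  table
}
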