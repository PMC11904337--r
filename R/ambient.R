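#' Batch-dependent ambient-RNA gene metric
#'
#' Ambient (cell-free) transcripts are estimated from non-viable barcodes:
#' for each batch, counts of every gene are aggregated over barcodes whose
#' total count is strictly below `max_total` (default 100), and the summed
#' counts are converted to within-batch percentile ranks. Ties — in
#' particular the large mass of genes with zero ambient counts — receive
#' their midrank, so the zero block is not pushed to the top of the ranking.
#'
#' @param raw_matrix the raw, pre-QC [cell_matrix()] including empty
#'   droplets.
#' @param max_total strict upper bound on barcode totals entering the
#'   aggregation.
#' @return data.frame of class `ambient_profile` with columns `batch_id`,
#'   `gene`, `ambient_count`, `percentile_rank`.
#' @export
ambient_metric <- function(raw_matrix, max_total = 100) {
  stopifnot(inherits(raw_matrix, "cell_matrix"), max_total > 0)
  bm <- raw_matrix$barcode_meta
  genes <- raw_matrix$gene_meta$gene_id
  batches <- unique(bm$batch_id)
  out <- lapply(batches, function(b) {
    sel <- bm$batch_id == b & bm$total_umi < max_total
    if (!any(sel)) {
      warning("batch ", b, " has no barcodes below ", max_total,
              " total counts; ambient profile is all zero")
      counts <- rep(0, length(genes))
    } else {
      counts <- as.numeric(Matrix::rowSums(
        raw_matrix$counts[, sel, drop = FALSE]))
    }
    data.frame(batch_id = b, gene = genes, ambient_count = counts,
               percentile_rank = percentile_rank(counts),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ambient_profile", "data.frame")
  res
}

#' Flag consensus DEGs attributable to ambient contamination
#'
#' A gene is flagged when its maximum ambient percentile rank across batches
#' strictly exceeds `percentile_cut` (default 0.75). Depending on `action`,
#' flagged genes are excluded from the final significant set (`final_sig`
#' column) or merely annotated; they are always retained in the table with
#' the flag so the call can be audited.
#'
#' @param degs a consensus table (see [consensus_call()]).
#' @param profile an [ambient_metric()] result.
#' @param percentile_cut strict percentile-rank cutoff.
#' @param action `"exclude"` (default) removes flagged genes from
#'   `final_sig`; `"annotate"` leaves `final_sig == consensus_sig`.
#' @return the consensus table with `ambient_flag` and `final_sig` columns.
#' @export
ambient_flag <- function(degs, profile, percentile_cut = 0.75,
                         action = c("exclude", "annotate")) {
  action <- match.arg(action)
  stopifnot(is.data.frame(degs), "gene" %in% names(degs),
            inherits(profile, "ambient_profile") || is.data.frame(profile))
  max_rank <- tapply(profile$percentile_rank, profile$gene, max)
  hit <- as.vector(max_rank[degs$gene])
  absent <- is.na(hit)
  if (any(absent)) {
    warning(sum(absent), " gene(s) absent from the ambient profile; ",
            "left unflagged")
    hit[absent] <- 0
  }
  degs$ambient_flag <- hit > percentile_cut
  base_sig <- if ("consensus_sig" %in% names(degs)) degs$consensus_sig
              else rep(TRUE, nrow(degs))
  degs$final_sig <- if (action == "exclude") base_sig & !degs$ambient_flag
                    else base_sig
  degs
}
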