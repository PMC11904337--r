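#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranking from top to bottom: hits (set members) increment the
#' running sum by `|score|^weight_exponent / sum(|score|^weight_exponent over
#' hits)`, misses decrement it by `1 / (N - Nh)`. The enrichment score is the
#' signed maximum deviation of the running sum from zero; core-enrichment
#' genes are the set members at or before the peak (at or after it for a
#' negative ES).
#'
#' @param ranked named numeric vector of gene scores; sorted into descending
#'   order internally (ties broken by gene id for determinism).
#' @param set character vector of member gene ids; must intersect the
#'   ranking and must not equal the whole universe.
#' @param weight_exponent score weighting exponent (default 1).
#' @return list with `es`, `running` (the full profile), `peak_index` and
#'   `core_genes`.
#' @export
enrichment_score <- function(ranked, set, weight_exponent = 1) {
  ord <- order(-ranked, names(ranked))
  scores <- ranked[ord]
  genes <- names(scores)
  hit <- genes %in% set
  nh <- sum(hit)
  n <- length(genes)
  if (nh == 0) stop("gene set does not intersect the ranking")
  if (nh == n) stop("gene set equals the whole universe")
  w <- abs(scores)^weight_exponent
  w[!hit] <- 0
  sw <- sum(w)
  inc <- if (sw > 0) w / sw else as.numeric(hit) / nh
  dec <- 1 / (n - nh)
  running <- cumsum(ifelse(hit, inc, -dec))
  peak <- which.max(abs(running))
  es <- running[peak]
  core <- if (es >= 0) genes[hit & seq_len(n) <= peak]
          else genes[hit & seq_len(n) >= peak]
  list(es = es, running = running, peak_index = peak, core_genes = core)
}

# ES from hit positions only (O(Nh)); used for the permutation null.
# pos: sorted hit positions; w: |score|^exponent at those positions.
es_from_positions <- function(pos, w, n) {
  nh <- length(pos)
  sw <- sum(w)
  cw <- if (sw > 0) cumsum(w) / sw else seq_len(nh) / nh
  d <- 1 / (n - nh)
  at_hit <- cw - (pos - seq_len(nh)) * d          # value just after each hit
  before_hit <- c(0, cw[-nh]) - (pos - seq_len(nh)) * d  # just before
  hi <- max(at_hit)
  lo <- min(before_hit)
  if (hi >= -lo) hi else lo
}

#' Pre-ranked gene set enrichment with a gene-sampling permutation null
#'
#' For every retained set, `n_perm` random same-size gene samples from the
#' ranked universe give a null ES distribution. NES is the observed ES
#' divided by the mean |null ES| of the matching sign (sign-stratified
#' normalisation); the permutation p-value is
#' `(1 + #{same-sign nulls at least as extreme}) / (1 + #same-sign nulls)`,
#' so it respects the `1/(n_perm+1)` floor. Adjusted p-values are BH across
#' the retained sets.
#'
#' @param ranked named numeric score vector (e.g. PC1 rank scores).
#' @param collection a [gene_set_collection()].
#' @param n_perm number of permutations (must be >= 1).
#' @param seed integer seed for the permutation draws.
#' @param min_size,max_size set-size bounds applied after intersection with
#'   the universe (defaults 10 and 500).
#' @param weight_exponent passed to [enrichment_score()].
#' @param cell_type optional label carried into the output.
#' @return an `enrichment_table` data.frame: set, size, ES, NES, p_value,
#'   adj_p, direction, core enrichment genes.
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 1000, seed = 1L,
                           min_size = 10, max_size = 500,
                           weight_exponent = 1, cell_type = NA_character_) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (n_perm < 1) stop("n_perm must be at least 1")
  ranked <- ranked[is.finite(ranked)]
  ord <- order(-ranked, names(ranked))
  scores <- ranked[ord]
  genes <- names(scores)
  n <- length(genes)
  w_all <- abs(scores)^weight_exponent

  sets <- lapply(collection$sets, intersect, genes)
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  dropped <- names(sets)[!keep]
  if (length(dropped))
    message(length(dropped), " set(s) outside size bounds dropped")
  sets <- sets[keep]
  if (!length(sets)) {
    out <- data.frame(cell_type = character(0), set = character(0),
                      size = integer(0), ES = numeric(0), NES = numeric(0),
                      p_value = numeric(0), adj_p = numeric(0),
                      direction = character(0),
                      core_enrichment = character(0))
    class(out) <- c("enrichment_table", "data.frame")
    return(out)
  }

  set.seed(seed)
  res <- lapply(names(sets), function(nm) {
    members <- sets[[nm]]
    k <- length(members)
    obs <- enrichment_score(scores, members, weight_exponent)
    null_es <- vapply(seq_len(n_perm), function(i) {
      pos <- sort(sample.int(n, k))
      es_from_positions(pos, w_all[pos], n)
    }, numeric(1))
    same <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    nes <- if (length(same) && mean(abs(same)) > 0)
      obs$es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    data.frame(cell_type = cell_type, set = nm, size = k, ES = obs$es,
               NES = nes, p_value = p,
               direction = if (obs$es >= 0) "positive" else "negative",
               core_enrichment = paste(obs$core_genes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- bh_adjust(out$p_value)
  out <- out[, c("cell_type", "set", "size", "ES", "NES", "p_value",
                 "adj_p", "direction", "core_enrichment")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Gene-set ratio: overlap of consensus DEGs with a pathway
#'
#' The fraction of a pathway's (universe-intersected) genes that are
#' consensus-significant DEGs of the cell type; the dot-size statistic of
#' the enrichment dot plots.
#'
#' @param consensus a consensus table (one or more cell types), after
#'   [consensus_call()] and optionally [ambient_flag()].
#' @param set character vector of pathway gene ids.
#' @param cell_type cell type to evaluate; defaults to the single cell type
#'   present.
#' @param universe gene universe; defaults to all genes of the cell type's
#'   consensus rows.
#' @return proportion in [0, 1].
#' @export
gene_set_ratio <- function(consensus, set, cell_type = NULL, universe = NULL) {
  stopifnot(is.data.frame(consensus))
  if (is.null(cell_type)) {
    cts <- unique(consensus$cell_type)
    if (length(cts) != 1) stop("specify cell_type")
    cell_type <- cts
  }
  rows <- consensus[consensus$cell_type == cell_type, , drop = FALSE]
  universe <- universe %||% rows$gene
  set_u <- intersect(set, universe)
  if (!length(set_u)) stop("gene set is empty after universe intersection")
  sig <- if ("final_sig" %in% names(rows)) rows$final_sig else rows$consensus_sig
  degs <- rows$gene[sig]
  length(intersect(degs, set_u)) / length(set_u)
}
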