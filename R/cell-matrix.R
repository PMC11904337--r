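#' Construct a CellMatrix, the pipeline's entry object
#'
#' A `cell_matrix` bundles a sparse gene x barcode raw count matrix with
#' per-gene flags (mitochondrial, hemoglobin) and per-barcode annotations.
#' Derived per-barcode quantities (total UMIs, genes detected, mitochondrial
#' and hemoglobin fractions) are computed here and kept consistent with the
#' counts; they are recomputed whenever barcodes are subset.
#'
#' @param counts sparse (or dense) nonnegative integer gene x barcode matrix
#'   with rownames (gene ids) and colnames (barcodes).
#' @param barcode_meta data.frame with one row per barcode, carrying at least
#'   `sample_id`; `batch_id`, `group_label` and `cell_type_label` are
#'   optional and default to `sample_id` / NA.
#' @param is_mito,is_hemo logical per-gene flags, or character vectors of
#'   gene ids.
#' @return an object of class `cell_matrix` with elements `counts`,
#'   `gene_meta` and `barcode_meta`.
#' @export
cell_matrix <- function(counts, barcode_meta, is_mito = NULL, is_hemo = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and barcode colnames")
  if (any(counts@x < 0)) stop("counts must be nonnegative")
  genes <- rownames(counts)
  flag <- function(x) {
    if (is.null(x)) rep(FALSE, length(genes))
    else if (is.character(x)) genes %in% x
    else { stopifnot(length(x) == length(genes)); as.logical(x) }
  }
  gene_meta <- data.frame(gene_id = genes, is_mito = flag(is_mito),
                          is_hemo = flag(is_hemo), stringsAsFactors = FALSE)
  stopifnot(is.data.frame(barcode_meta), nrow(barcode_meta) == ncol(counts),
            "sample_id" %in% names(barcode_meta))
  bm <- barcode_meta
  bm$barcode <- colnames(counts)
  if (is.null(bm$batch_id)) bm$batch_id <- bm$sample_id
  if (is.null(bm$group_label)) bm$group_label <- NA_character_
  if (is.null(bm$cell_type_label)) bm$cell_type_label <- NA_character_
  if (is.null(bm$qc_pass)) bm$qc_pass <- TRUE
  if (is.null(bm$doublet_score)) bm$doublet_score <- NA_real_
  if (is.null(bm$is_doublet)) bm$is_doublet <- FALSE
  obj <- structure(list(counts = counts, gene_meta = gene_meta,
                        barcode_meta = bm), class = "cell_matrix")
  refresh_barcode_stats(obj)
}

# Recompute the derived per-barcode columns from the counts.
refresh_barcode_stats <- function(x) {
  tot <- Matrix::colSums(x$counts)
  safe <- ifelse(tot == 0, 1, tot)
  x$barcode_meta$total_umi <- as.numeric(tot)
  x$barcode_meta$n_genes_detected <- Matrix::colSums(x$counts > 0)
  x$barcode_meta$mito_fraction <-
    as.numeric(Matrix::colSums(x$counts[x$gene_meta$is_mito, , drop = FALSE]) / safe)
  x$barcode_meta$hemo_fraction <-
    as.numeric(Matrix::colSums(x$counts[x$gene_meta$is_hemo, , drop = FALSE]) / safe)
  rownames(x$barcode_meta) <- NULL
  x
}

#' Subset a CellMatrix to a set of barcodes
#' @param x a `cell_matrix`.
#' @param keep logical or index vector over barcodes.
#' @export
subset_barcodes <- function(x, keep) {
  stopifnot(inherits(x, "cell_matrix"))
  obj <- structure(list(counts = x$counts[, keep, drop = FALSE],
                        gene_meta = x$gene_meta,
                        barcode_meta = x$barcode_meta[keep, , drop = FALSE]),
                   class = "cell_matrix")
  refresh_barcode_stats(obj)
}

#' Combine CellMatrix objects sharing one gene panel
#' @param ... `cell_matrix` objects with identical gene ids and flags.
#' @export
bind_cell_matrices <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "cell_matrix"))
    xs <- xs[[1]]
  stopifnot(length(xs) >= 1L, all(vapply(xs, inherits, TRUE, "cell_matrix")))
  g0 <- xs[[1]]$gene_meta
  for (x in xs) stopifnot(identical(x$gene_meta$gene_id, g0$gene_id))
  counts <- do.call(cbind, lapply(xs, `[[`, "counts"))
  meta_cols <- Reduce(intersect, lapply(xs, function(x) names(x$barcode_meta)))
  bm <- do.call(rbind, lapply(xs, function(x) x$barcode_meta[, meta_cols, drop = FALSE]))
  if (anyDuplicated(bm$barcode))
    bm$barcode <- colnames(counts) <- make.unique(bm$barcode, sep = "-")
  obj <- structure(list(counts = counts, gene_meta = g0, barcode_meta = bm),
                   class = "cell_matrix")
  refresh_barcode_stats(obj)
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d genes x %d barcodes, %d sample(s), %d batch(es)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$barcode_meta$sample_id)),
              length(unique(x$barcode_meta$batch_id))))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)
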