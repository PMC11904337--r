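#' Aggregate QC-passed cells into pseudobulk counts
#'
#' Sums raw counts per (sample, cell type) unit. The grand total of the
#' pseudobulk table equals the grand total of the input matrix, and the
#' aggregation is invariant to cell order. Per (gene, unit) the number of
#' expressing cells (count > 0) is recorded, which drives the downstream
#' gene filter.
#'
#' @param matrix a [cell_matrix()] whose cells all carry `sample_id` and
#'   `cell_type_label` and have passed QC.
#' @return a `pseudobulk` object: `counts` (gene x unit), `expressing`
#'   (gene x unit number of expressing cells) and `unit_meta`.
#' @export
pseudobulk_aggregate <- function(matrix) {
  stopifnot(inherits(matrix, "cell_matrix"))
  bm <- matrix$barcode_meta
  if (any(is.na(bm$cell_type_label)) || any(is.na(bm$sample_id)))
    stop("all cells must carry sample_id and cell_type_label")
  if (!all(bm$qc_pass)) stop("pseudobulk aggregation expects QC-passed cells")
  unit <- paste(bm$sample_id, bm$cell_type_label, sep = "|")
  levels_u <- sort(unique(unit))
  f <- factor(unit, levels = levels_u)
  ind <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                              dims = c(length(f), length(levels_u)))
  counts <- as.matrix(matrix$counts %*% ind)
  expressing <- as.matrix((matrix$counts > 0) %*% ind)
  dimnames(counts) <- dimnames(expressing) <-
    list(matrix$gene_meta$gene_id, levels_u)
  parts <- do.call(rbind, strsplit(levels_u, "|", fixed = TRUE))
  grp <- bm$group_label[match(parts[, 1], bm$sample_id)]
  unit_meta <- data.frame(
    unit = levels_u, sample_id = parts[, 1], cell_type = parts[, 2],
    group_label = grp,
    n_cells = as.integer(table(f)),
    total_count = colSums(counts),
    stringsAsFactors = FALSE)
  rownames(unit_meta) <- NULL
  structure(list(counts = counts, expressing = expressing,
                 unit_meta = unit_meta,
                 genes_by_celltype = NULL),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("pseudobulk: %d genes x %d units (%d samples, %d cell types)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$unit_meta$sample_id)),
              length(unique(x$unit_meta$cell_type))))
  invisible(x)
}

#' Filter pseudobulk units and genes
#'
#' Units with zero total counts are removed. Per cell type, a gene is
#' retained if at least one unit of that cell type has at least `min_cells`
#' cells expressing it; otherwise the gene is recorded as removed for that
#' cell type. Cell types left with fewer than two units in any represented
#' group are marked ineligible for differential expression (with a warning);
#' the units themselves are kept.
#'
#' @param table a [pseudobulk_aggregate()] result.
#' @param min_cells expressing-cell threshold (default 5); a gene with
#'   `>= min_cells` expressing cells in one unit of a cell type is retained
#'   for that cell type.
#' @return the filtered `pseudobulk`, with `genes_by_celltype` (named list of
#'   retained genes), `removed_genes_by_celltype`, and a `celltype_status`
#'   data.frame flagging cell types ineligible for DE.
#' @export
filter_units_and_genes <- function(table, min_cells = 5) {
  stopifnot(inherits(table, "pseudobulk"), min_cells >= 0)
  keep_units <- table$unit_meta$total_count > 0
  counts <- table$counts[, keep_units, drop = FALSE]
  expressing <- table$expressing[, keep_units, drop = FALSE]
  unit_meta <- table$unit_meta[keep_units, , drop = FALSE]
  rownames(unit_meta) <- NULL

  cts <- unique(unit_meta$cell_type)
  genes_by_ct <- removed_by_ct <- stats::setNames(vector("list", length(cts)), cts)
  for (ct in cts) {
    cols <- unit_meta$cell_type == ct
    n_max <- apply(expressing[, cols, drop = FALSE], 1, max)
    genes_by_ct[[ct]] <- rownames(counts)[n_max >= min_cells]
    removed_by_ct[[ct]] <- rownames(counts)[n_max < min_cells]
  }

  status <- do.call(rbind, lapply(cts, function(ct) {
    um <- unit_meta[unit_meta$cell_type == ct, , drop = FALSE]
    per_group <- table(um$group_label)
    data.frame(cell_type = ct,
               n_units = nrow(um),
               min_units_per_group = min(per_group),
               de_eligible = all(per_group >= 2),
               stringsAsFactors = FALSE)
  }))
  if (any(!status$de_eligible))
    warning("cell type(s) with < 2 units in a group, excluded from DE: ",
            paste(status$cell_type[!status$de_eligible], collapse = ", "))

  structure(list(counts = counts, expressing = expressing,
                 unit_meta = unit_meta,
                 genes_by_celltype = genes_by_ct,
                 removed_genes_by_celltype = removed_by_ct,
                 celltype_status = status,
                 min_cells = min_cells),
            class = "pseudobulk")
}

#' Construct a pseudobulk table from pre-aggregated counts
#'
#' For data that is already summed per (sample, cell type) — e.g. imported
#' from another pipeline — bypassing [pseudobulk_aggregate()].
#'
#' @param counts gene x unit nonnegative integer matrix with dimnames.
#' @param sample_id,cell_type,group_label per-unit annotation vectors.
#' @param n_cells optional per-unit cell counts (enables the expressing-cell
#'   filter only when `expressing` is also known; defaults to NA).
#' @return a `pseudobulk` object.
#' @export
pseudobulk_table <- function(counts, sample_id, cell_type, group_label,
                             n_cells = NA_integer_) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), ncol(counts) == length(sample_id),
            length(cell_type) %in% c(1, ncol(counts)),
            length(group_label) == ncol(counts), all(counts >= 0))
  unit <- paste(sample_id, cell_type, sep = "|")
  colnames(counts) <- unit
  unit_meta <- data.frame(unit = unit, sample_id = sample_id,
                          cell_type = cell_type, group_label = group_label,
                          n_cells = n_cells, total_count = colSums(counts),
                          stringsAsFactors = FALSE)
  structure(list(counts = counts, expressing = NULL, unit_meta = unit_meta,
                 genes_by_celltype = NULL),
            class = "pseudobulk")
}

# Subset a pseudobulk to one cell type's units (and its retained genes,
# when the gene filter has been applied) and to the two groups of a contrast.
pb_subset <- function(table, cell_type, contrast = NULL) {
  um <- table$unit_meta
  sel <- um$cell_type == cell_type
  if (!is.null(contrast)) sel <- sel & um$group_label %in% contrast
  genes <- if (!is.null(table$genes_by_celltype))
    table$genes_by_celltype[[cell_type]] else rownames(table$counts)
  list(counts = table$counts[genes, sel, drop = FALSE],
       unit_meta = um[sel, , drop = FALSE])
}
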