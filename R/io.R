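#' Write a CellMatrix as a 10x-style MTX triplet
#'
#' Writes `matrix.mtx` (MatrixMarket integer coordinate, 1-based indices),
#' `features.tsv` (gene id, gene name, feature type, mito flag, hemoglobin
#' flag) and `barcodes.tsv`, plus `cell_metadata.tsv` carrying the
#' per-barcode annotations, so the triplet round-trips losslessly through
#' [read_tenx_triplet()].
#'
#' @param matrix a [cell_matrix()].
#' @param directory output directory, created if absent.
#' @param force overwrite an existing triplet (default FALSE: error).
#' @return the directory, invisibly.
#' @export
write_tenx_triplet <- function(matrix, directory, force = FALSE) {
  stopifnot(inherits(matrix, "cell_matrix"), ncol(matrix$counts) > 0)
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  mtx_path <- file.path(directory, "matrix.mtx")
  if (file.exists(mtx_path) && !force)
    stop("triplet already present in ", directory, "; use force = TRUE")
  m <- methods::as(matrix$counts, "TsparseMatrix")
  con <- file(mtx_path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), con)
  if (length(m@x))
    writeLines(sprintf("%d %d %d", m@i + 1L, m@j + 1L, as.integer(m@x)), con)
  gm <- matrix$gene_meta
  utils::write.table(
    data.frame(gm$gene_id, gm$gene_id, "Gene Expression",
               gm$is_mito, gm$is_hemo),
    file.path(directory, "features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  writeLines(colnames(matrix$counts), file.path(directory, "barcodes.tsv"))
  utils::write.table(matrix$barcode_meta,
                     file.path(directory, "cell_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(directory)
}

#' Read a 10x-style MTX triplet into a CellMatrix
#'
#' Expects `matrix.mtx` (MatrixMarket coordinate, 1-based indices per the
#' standard), `features.tsv` and `barcodes.tsv` in `directory`. Mitochondrial
#' and hemoglobin flags are taken from columns 4 and 5 of `features.tsv` when
#' present, otherwise inferred from the `MT-` / `HB` gene-name prefixes.
#' Per-barcode annotations are read from `cell_metadata.tsv` when present.
#'
#' @param directory path holding the triplet.
#' @param sample_id sample label used when no metadata file is found.
#' @return a [cell_matrix()].
#' @export
read_tenx_triplet <- function(directory, sample_id = basename(directory)) {
  paths <- file.path(directory, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing triplet file(s): ", paste(basename(missing), collapse = ", "))
  header <- readLines(paths[1], n = 1L)
  if (!startsWith(header, "%%MatrixMarket matrix coordinate"))
    stop("malformed MatrixMarket header (line 1): ", header)
  m <- methods::as(Matrix::readMM(paths[1]), "CsparseMatrix")
  if (any(m@x != round(m@x))) stop("matrix.mtx contains non-integer values")
  feats <- utils::read.table(paths[2], sep = "\t", header = FALSE,
                             quote = "", stringsAsFactors = FALSE)
  barcodes <- readLines(paths[3])
  if (nrow(feats) != nrow(m))
    stop(sprintf("features.tsv has %d rows but matrix.mtx declares %d genes",
                 nrow(feats), nrow(m)))
  if (length(barcodes) != ncol(m))
    stop(sprintf("barcodes.tsv has %d rows but matrix.mtx declares %d barcodes",
                 length(barcodes), ncol(m)))
  rownames(m) <- feats[[1]]
  colnames(m) <- barcodes
  is_mito <- if (ncol(feats) >= 4) as.logical(feats[[4]])
             else startsWith(feats[[1]], "MT-")
  is_hemo <- if (ncol(feats) >= 5) as.logical(feats[[5]])
             else grepl("^HB[ABDEGMQZ]", feats[[1]])
  meta_path <- file.path(directory, "cell_metadata.tsv")
  bm <- if (file.exists(meta_path)) {
    mt <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                            quote = "", stringsAsFactors = FALSE)
    if (nrow(mt) != ncol(m)) stop("cell_metadata.tsv row count mismatch")
    mt
  } else data.frame(sample_id = rep(sample_id, ncol(m)),
                    stringsAsFactors = FALSE)
  cell_matrix(m, barcode_meta = bm, is_mito = is_mito, is_hemo = is_hemo)
}

#' Read a GMT gene set collection
#'
#' Each tab-separated line is: set name, description, member genes.
#' Duplicate members within a set are dropped with a warning.
#'
#' @param path GMT file.
#' @return a `gene_set_collection`: list with `sets` (named list of unique
#'   gene id vectors) and `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicated members within a gene set; deduplicated")
      members <- unique(members)
    }
    members
  })
  names(sets) <- nm
  gene_set_collection(sets, stats::setNames(desc, nm))
}

#' Construct a gene set collection
#' @param sets named list of gene id vectors.
#' @param descriptions optional named character vector.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets))
  sets <- lapply(sets, unique)
  structure(list(sets = sets,
                 descriptions = descriptions %||%
                   stats::setNames(rep("", length(sets)), names(sets))),
            class = "gene_set_collection")
}

#' Write a ranked gene list as a two-column RNK-style file
#' @param scores named numeric vector (names = gene ids).
#' @param path output file.
#' @export
write_rnk <- function(scores, path) {
  ord <- order(scores, decreasing = TRUE)
  utils::write.table(data.frame(gene = names(scores)[ord],
                                score = scores[ord]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
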