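#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Inputs are either a list of
#' in-memory [cell_matrix()] objects (`samples`) or a directory of 10x-style
#' triplet subdirectories (`input_dir`).
#'
#' @param samples named list of `cell_matrix` objects (one per sample), or
#'   NULL to read from `input_dir`.
#' @param input_dir directory whose subdirectories are MTX triplets.
#' @param output_dir where all result tables and the manifest are written.
#' @param gmt_path optional GMT file enabling the enrichment stage.
#' @param contrasts list of `c(test_group, reference_group)` pairs.
#' @param qc a [qc_thresholds()].
#' @param min_cells pseudobulk expressing-cell gene filter (default 5).
#' @param lfc_cut,p_cut_multi,p_cut_single consensus rule cuts
#'   (defaults 0.5, 0.05, 0.01).
#' @param lfc_source fold-change source for the consensus gate.
#' @param ambient_max_total strict barcode-total bound of the ambient metric
#'   (default 100).
#' @param ambient_percentile strict ambient percentile-rank cutoff (0.75).
#' @param ambient_action `"exclude"` or `"annotate"` flagged DEGs.
#' @param gsea list: `n_perm`, `min_size`, `max_size`, `weight_exponent`.
#' @param doublet list: `k`, `n_pcs`, `n_artificial`.
#' @param batch_map optional named vector mapping sample ids to batch ids
#'   (default: one batch per sample, i.e. the batches carried by the data).
#' @param engine_opts per-engine argument lists (see [run_de_engines()]).
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(samples = NULL, input_dir = NULL,
                            output_dir = tempfile("pbrun"),
                            gmt_path = NULL,
                            contrasts = list(),
                            qc = qc_thresholds(),
                            min_cells = 5,
                            lfc_cut = 0.5, p_cut_multi = 0.05,
                            p_cut_single = 0.01,
                            lfc_source = "mean",
                            ambient_max_total = 100,
                            ambient_percentile = 0.75,
                            ambient_action = "exclude",
                            gsea = list(n_perm = 1000, min_size = 10,
                                        max_size = 500, weight_exponent = 1),
                            doublet = list(k = 20, n_pcs = 10,
                                           n_artificial = NULL),
                            batch_map = NULL,
                            engine_opts = list(),
                            seed = 1L) {
  stopifnot(!is.null(samples) || !is.null(input_dir),
            lfc_cut >= 0, p_cut_multi > 0, p_cut_multi <= 1,
            p_cut_single > 0, p_cut_single <= 1,
            ambient_percentile > 0, ambient_percentile < 1,
            ambient_max_total > 0)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level YAML keys map to [pipeline_config()] arguments; `qc` maps to
#' [qc_thresholds()] arguments.
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$qc)) y$qc <- do.call(qc_thresholds, y$qc)
  if (!is.null(y$contrasts)) y$contrasts <- lapply(y$contrasts, unlist)
  do.call(pipeline_config, y)
}

safe_label <- function(x) gsub("[^A-Za-z0-9_.-]+", "-", x)

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes QC (count/gene/mito/hemoglobin filters, then per-sample doublet
#' scoring and removal), the ambient metric, pseudobulk aggregation and
#' filtering, the three DE engines, the consensus rule with ambient
#' filtering, PC1 rank fusion, and (when a GMT is configured) pre-ranked
#' GSEA, for every configured contrast. All result tables are written as
#' headered TSVs under `output_dir`, together with a machine-readable JSON
#' run manifest; a rerun with the same configuration and seed reproduces the
#' outputs byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the output directory and all in-memory
#'   result objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  samples <- run_stage("load", {
    if (!is.null(config$samples)) config$samples
    else {
      dirs <- list.dirs(config$input_dir, recursive = FALSE)
      if (!length(dirs)) stop("no triplet subdirectories in ", config$input_dir)
      stats::setNames(lapply(dirs, read_tenx_triplet), basename(dirs))
    }
  })
  raw <- run_stage("load", bind_cell_matrices(samples))
  if (!is.null(config$batch_map))
    raw$barcode_meta$batch_id <-
      unname(config$batch_map[raw$barcode_meta$sample_id])
  message("load: ", ncol(raw$counts), " barcodes, ", nrow(raw$counts),
          " genes, ", length(unique(raw$barcode_meta$sample_id)), " samples")

  ambient <- run_stage("ambient",
    ambient_metric(raw, max_total = config$ambient_max_total))
  write_tsv(ambient, file.path(out_dir, "ambient_metric.tsv"))

  qc_res <- run_stage("qc", apply_cell_filters(raw, config$qc))
  filtered <- qc_res$matrix
  report <- qc_res$report

  filtered <- run_stage("doublets", {
    parts <- lapply(unique(filtered$barcode_meta$sample_id), function(sid) {
      sm <- subset_barcodes(filtered, filtered$barcode_meta$sample_id == sid)
      sm <- do.call(doublet_scores, c(list(
        sm, expected_rate = config$qc$expected_doublet_rate,
        seed = child_seed(config$seed, paste0("doublets:", sid))),
        config$doublet))
      report$n_doublets[report$sample_id == sid] <<-
        sum(sm$barcode_meta$is_doublet)
      subset_barcodes(sm, !sm$barcode_meta$is_doublet)
    })
    bind_cell_matrices(parts)
  })
  report$n_retained <- report$n_retained - ifelse(is.na(report$n_doublets), 0,
                                                  report$n_doublets)
  write_tsv(report, file.path(out_dir, "qc_report.tsv"))
  message("qc: ", ncol(filtered$counts), " cells retained")

  pb <- run_stage("pseudobulk", {
    labeled <- subset_barcodes(filtered,
                               !is.na(filtered$barcode_meta$cell_type_label))
    filter_units_and_genes(pseudobulk_aggregate(labeled),
                           min_cells = config$min_cells)
  })
  write_tsv(pb$unit_meta, file.path(out_dir, "pseudobulk_units.tsv"))
  message("pseudobulk: ", ncol(pb$counts), " units, ",
          nrow(pb$counts), " genes")

  gmt <- if (!is.null(config$gmt_path)) read_gmt(config$gmt_path)
  results <- list()
  for (con in config$contrasts) {
    label <- paste0(safe_label(con[1]), "_vs_", safe_label(con[2]))
    cdir <- file.path(out_dir, label)
    if (!dir.exists(cdir)) dir.create(cdir)
    um <- pb$unit_meta
    eligible <- vapply(unique(um$cell_type), function(ct) {
      tab <- table(um$group_label[um$cell_type == ct])
      all(con %in% names(tab)) && all(tab[con] >= 2)
    }, logical(1))
    cts <- unique(um$cell_type)[eligible]
    if (!length(cts)) {
      message(label, ": no eligible cell type, skipped")
      next
    }
    engines_all <- list(); consensus_all <- list(); enrich_all <- list()
    for (ct in cts) {
      eng <- run_stage(paste0("de:", label),
        run_de_engines(pb, con, ct, config$engine_opts))
      cons <- run_stage(paste0("consensus:", label), {
        x <- consensus_call(eng, config$lfc_cut, config$p_cut_multi,
                            config$p_cut_single, config$lfc_source)
        x <- ambient_flag(x, ambient, config$ambient_percentile,
                          config$ambient_action)
        pc1_rank(x)
      })
      engines_all[[ct]] <- do.call(rbind, eng)
      consensus_all[[ct]] <- cons
      ranked <- stats::setNames(cons$pc1_score, cons$gene)
      ranked <- ranked[!is.na(ranked)]
      write_rnk(ranked, file.path(cdir, paste0(safe_label(ct), ".rnk")))
      if (!is.null(gmt) && length(ranked) >= 3) {
        et <- run_stage(paste0("gsea:", label), do.call(gsea_preranked,
          c(list(ranked, gmt,
                 seed = child_seed(config$seed, paste0("gsea:", label, ct)),
                 cell_type = ct), config$gsea)))
        if (nrow(et))
          et$gene_set_ratio <- vapply(et$set, function(s)
            gene_set_ratio(cons, gmt$sets[[s]], cell_type = ct,
                           universe = names(ranked)), numeric(1))
        enrich_all[[ct]] <- et
      }
      message(label, " / ", ct, ": ",
              sum(if ("final_sig" %in% names(cons)) cons$final_sig
                  else cons$consensus_sig), " consensus DEGs")
    }
    de_tab <- do.call(rbind, engines_all); rownames(de_tab) <- NULL
    cons_tab <- do.call(rbind, consensus_all); rownames(cons_tab) <- NULL
    write_tsv(de_tab, file.path(cdir, "de_results.tsv"))
    write_tsv(cons_tab, file.path(cdir, "consensus.tsv"))
    enr_tab <- NULL
    if (length(enrich_all)) {
      enr_tab <- do.call(rbind, enrich_all); rownames(enr_tab) <- NULL
      write_tsv(enr_tab, file.path(cdir, "enrichment.tsv"))
    }
    results[[label]] <- list(engines = de_tab, consensus = cons_tab,
                             enrichment = enr_tab,
                             unique_degs = unique_deg_count(cons_tab))
  }

  manifest <- list(
    package = "pbconsensus",
    version = as.character(utils::packageVersion("pbconsensus")),
    seed = config$seed,
    thresholds = list(
      qc = unclass(config$qc), min_cells = config$min_cells,
      lfc_cut = config$lfc_cut, p_cut_multi = config$p_cut_multi,
      p_cut_single = config$p_cut_single,
      ambient_max_total = config$ambient_max_total,
      ambient_percentile = config$ambient_percentile,
      gsea = config$gsea),
    contrasts = lapply(config$contrasts, as.list),
    counts = list(
      barcodes_in = ncol(raw$counts),
      cells_retained = ncol(filtered$counts),
      pseudobulk_units = ncol(pb$counts),
      genes = nrow(pb$counts),
      unique_degs = lapply(results, `[[`, "unique_degs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(output_dir = out_dir, qc_report = report, ambient = ambient,
                 pseudobulk = pb, results = results))
}
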