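#' Configuration for the synthetic multiplexed cohort generator
#'
#' The generator emulates a droplet scRNA-seq case-control cohort: three
#' groups (healthy controls and two patient phenotypes), several samples per
#' group, a panel of cell types separable in PCA space, negative-binomial
#' counts with planted per-cell-type group effects, empty droplets (total
#' counts < 100) drawn from the batch ambient profile, ambient contamination
#' shared by all samples of a batch, a configurable doublet rate, and
#' Beta-distributed per-cell mitochondrial and hemoglobin fractions.
#'
#' @param n_samples_per_group samples per group label.
#' @param groups ordered group labels; the first is treated as the control.
#' @param n_cell_types number of cell types.
#' @param cells_per_sample real barcodes (singlets + doublets) per sample.
#' @param n_genes total gene panel size including mito/hemo genes.
#' @param n_mito_genes,n_hemo_genes mitochondrial / hemoglobin gene counts.
#' @param planted_effects data.frame with columns `cell_type`, `gene`,
#'   `test_group`, `ref_group`, `log2fc`; expression of `gene` in
#'   `cell_type` is multiplied by `2^log2fc` in samples of `test_group`.
#' @param dispersion NB dispersion phi (variance = mu + phi * mu^2), scalar
#'   or per-gene vector.
#' @param ambient_fraction proportion of each barcode's counts replaced by
#'   draws from the batch ambient profile, in [0, 1).
#' @param n_empty_droplets empty droplets per sample.
#' @param doublet_rate proportion of real barcodes that are doublets, in [0, 1).
#' @param mito_beta,hemo_beta two-element shape vectors of the Beta laws for
#'   per-cell mitochondrial / hemoglobin count fractions.
#' @param median_umi target mean library size of a singlet.
#' @param marker_fraction fraction of genes boosted as markers per cell type.
#' @param marker_boost multiplicative marker boost.
#' @param samples_per_batch consecutive samples sharing one ambient pool.
#' @param seed integer master seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples_per_group = 4,
                       groups = c("HC", "PsA-only", "PsA-PsC"),
                       n_cell_types = 5,
                       cells_per_sample = 400,
                       n_genes = 1000,
                       n_mito_genes = 10,
                       n_hemo_genes = 5,
                       planted_effects = NULL,
                       dispersion = 0.4,
                       ambient_fraction = 0.10,
                       n_empty_droplets = 300,
                       doublet_rate = 0.05,
                       mito_beta = c(2.5, 30),
                       hemo_beta = c(1, 3000),
                       median_umi = 1500,
                       marker_fraction = 0.05,
                       marker_boost = 6,
                       samples_per_batch = 1,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_samples_per_group >= 1, length(groups) >= 2,
              n_cell_types >= 1, cells_per_sample >= 1, n_genes >= 10,
              n_mito_genes >= 1, n_hemo_genes >= 0,
              n_mito_genes + n_hemo_genes < n_genes,
              all(dispersion > 0),
              ambient_fraction >= 0, ambient_fraction < 1,
              n_empty_droplets >= 0,
              doublet_rate >= 0, doublet_rate < 1,
              length(mito_beta) == 2, all(mito_beta > 0),
              length(hemo_beta) == 2, all(hemo_beta > 0),
              median_umi > 0, samples_per_batch >= 1)
  })
  pe <- cfg$planted_effects
  if (!is.null(pe) && nrow(pe)) {
    req <- c("cell_type", "gene", "test_group", "ref_group", "log2fc")
    stopifnot(is.data.frame(pe), all(req %in% names(pe)),
              all(is.finite(pe$log2fc)))
    panel <- sim_gene_ids(cfg)
    bad <- setdiff(pe$gene, panel$expr)
    if (length(bad))
      stop("planted effect on gene(s) absent from the expressed panel: ",
           paste(bad, collapse = ", "))
    if (!all(pe$cell_type %in% sim_cell_type_ids(cfg)))
      stop("planted effect references unknown cell type")
    if (!all(c(pe$test_group, pe$ref_group) %in% cfg$groups))
      stop("planted effect references unknown group")
    if (anyDuplicated(pe[, c("cell_type", "gene", "test_group", "ref_group")]))
      stop("planted (cell_type, gene, contrast) combinations must be unique")
  }
  invisible(cfg)
}

sim_gene_ids <- function(cfg) {
  n_expr <- cfg$n_genes - cfg$n_mito_genes - cfg$n_hemo_genes
  list(expr = sprintf("GENE%04d", seq_len(n_expr)),
       mito = sprintf("MT-G%02d", seq_len(cfg$n_mito_genes)),
       hemo = if (cfg$n_hemo_genes > 0) sprintf("HB-G%02d", seq_len(cfg$n_hemo_genes))
              else character(0))
}

sim_cell_type_ids <- function(cfg) sprintf("CT%02d", seq_len(cfg$n_cell_types))

# Cohort-level cell type fractions: geometric decay, a few dominant types.
sim_cell_type_fractions <- function(cfg) {
  f <- 2^(-(seq_len(cfg$n_cell_types) - 1) / 1.5)
  f / sum(f)
}

# Per-cell-type per-gene NB mean vectors (expressed genes only), built from a
# shared log-normal baseline plus disjoint marker boosts so cell types
# separate in PCA space, scaled to the target library size.
sim_mean_vectors <- function(cfg) {
  ids <- sim_gene_ids(cfg)
  n_expr <- length(ids$expr)
  base <- stats::rlnorm(n_expr, meanlog = 0, sdlog = 1.2)
  n_marker <- max(1L, round(cfg$marker_fraction * n_expr))
  mu <- matrix(rep(base, cfg$n_cell_types), nrow = n_expr,
               dimnames = list(ids$expr, sim_cell_type_ids(cfg)))
  avail <- sample.int(n_expr)
  for (k in seq_len(cfg$n_cell_types)) {
    take <- avail[seq_len(min(n_marker, length(avail)))]
    avail <- avail[-seq_len(min(n_marker, length(avail)))]
    if (!length(avail)) avail <- sample.int(n_expr)
    mu[take, k] <- mu[take, k] * cfg$marker_boost
  }
  sweep(mu, 2, colSums(mu), "/") * cfg$median_umi
}

#' Simulate a multiplexed droplet scRNA-seq cohort with ground truth
#'
#' Draws, for every sample: singlet counts from per-cell-type NB mean
#' vectors with planted group effects applied as `2^log2fc` multipliers;
#' doublets as sums of two singlet draws (homotypic or heterotypic with
#' equal probability); Beta-distributed mitochondrial and hemoglobin count
#' fractions; ambient contamination as binomial thinning plus Poisson draws
#' from the batch ambient profile (the library-size-weighted mean expression
#' of the batch's singlets); and empty droplets with total counts strictly
#' below 100 drawn from the same ambient profile. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list with `samples` (one [cell_matrix()] per sample) and
#'   `ground_truth` (per-barcode truth table, planted-effect table, per-batch
#'   ambient profiles, per-cell-type mean vectors, sample table).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  ids <- sim_gene_ids(cfg)
  genes <- c(ids$expr, ids$mito, ids$hemo)
  ct_ids <- sim_cell_type_ids(cfg)
  fracs <- sim_cell_type_fractions(cfg)
  mu <- sim_mean_vectors(cfg)
  # fixed within-panel composition of the mito / hemo pools
  mito_w <- stats::runif(cfg$n_mito_genes); mito_w <- mito_w / sum(mito_w)
  hemo_w <- if (cfg$n_hemo_genes > 0) {
    w <- stats::runif(cfg$n_hemo_genes); w / sum(w)
  } else numeric(0)

  n_samp <- cfg$n_samples_per_group * length(cfg$groups)
  sample_tbl <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samp)),
    group_label = rep(cfg$groups, each = cfg$n_samples_per_group),
    stringsAsFactors = FALSE)
  # round-robin assignment over the group-ordered samples, so every batch
  # pools samples from the different groups (as multiplexed designs do)
  n_batch <- max(1L, floor(n_samp / cfg$samples_per_batch))
  sample_tbl$batch_id <- sprintf("B%02d",
    (seq_len(n_samp) - 1L) %% n_batch + 1L)

  phi <- if (length(cfg$dispersion) == 1L) rep(cfg$dispersion, length(ids$expr))
         else rep_len(cfg$dispersion, length(ids$expr))
  pe <- cfg$planted_effects

  # multiplier matrix per (gene, cell type) for one group
  effect_mult <- function(group) {
    m <- matrix(1, nrow(mu), ncol(mu), dimnames = dimnames(mu))
    if (!is.null(pe) && nrow(pe)) {
      hit <- pe[pe$test_group == group, , drop = FALSE]
      if (nrow(hit))
        m[cbind(match(hit$gene, rownames(mu)), match(hit$cell_type, ct_ids))] <-
          2^hit$log2fc
    }
    m
  }

  draw_singlet_block <- function(type_idx, n_cells, mult) {
    mu_vec <- mu[, type_idx] * mult[, type_idx]
    matrix(stats::rnbinom(length(mu_vec) * n_cells, mu = mu_vec, size = 1 / phi),
           nrow = length(mu_vec))
  }

  add_contaminant_pools <- function(block, beta_par, weights, ids_rows) {
    # append mito/hemo counts so the count fraction follows the Beta law
    if (!length(ids_rows)) return(block)
    tot <- colSums(block)
    f <- stats::rbeta(ncol(block), beta_par[1], beta_par[2])
    extra <- stats::rpois(ncol(block), tot * f / pmax(1 - f, 1e-6))
    add <- vapply(extra, function(n) stats::rmultinom(1, n, weights)[, 1],
                  numeric(length(weights)))
    out <- matrix(0L, length(ids_rows), ncol(block))
    out[] <- add
    out
  }

  truth_rows <- list(); samples <- list()
  ambient_profiles <- list()
  batches <- split(seq_len(n_samp), sample_tbl$batch_id)

  for (b in names(batches)) {
    bidx <- batches[[b]]
    raw <- list()   # per-sample true count matrices (genes x barcodes)
    meta <- list()
    for (i in bidx) {
      sid <- sample_tbl$sample_id[i]
      grp <- sample_tbl$group_label[i]
      mult <- effect_mult(grp)
      n_doub <- round(cfg$doublet_rate * cfg$cells_per_sample)
      n_sing <- cfg$cells_per_sample - n_doub
      types <- sample(seq_len(cfg$n_cell_types), n_sing, TRUE, prob = fracs)
      expr <- matrix(0L, length(ids$expr), n_sing)
      for (k in sort(unique(types))) {
        sel <- which(types == k)
        expr[, sel] <- draw_singlet_block(k, length(sel), mult)
      }
      # doublets: two independent singlet draws summed
      d_types <- NULL
      if (n_doub > 0) {
        homo <- stats::runif(n_doub) < 0.5
        t1 <- sample(seq_len(cfg$n_cell_types), n_doub, TRUE, prob = fracs)
        t2 <- ifelse(homo, t1,
                     vapply(t1, function(t) {
                       if (cfg$n_cell_types == 1L) return(t)
                       sample(setdiff(seq_len(cfg$n_cell_types), t), 1)
                     }, numeric(1)))
        d1 <- vapply(t1, function(k) draw_singlet_block(k, 1L, mult)[, 1],
                     numeric(length(ids$expr)))
        d2 <- vapply(t2, function(k) draw_singlet_block(k, 1L, mult)[, 1],
                     numeric(length(ids$expr)))
        expr <- cbind(expr, d1 + d2)
        d_types <- ct_ids[t1]
      }
      mito <- add_contaminant_pools(expr, cfg$mito_beta, mito_w,
                                    seq_along(ids$mito))
      hemo <- add_contaminant_pools(expr, cfg$hemo_beta, hemo_w,
                                    seq_along(ids$hemo))
      m <- rbind(expr, mito, if (cfg$n_hemo_genes > 0) hemo)
      rownames(m) <- genes
      colnames(m) <- sprintf("%s_bc%05d", sid, seq_len(ncol(m)))
      raw[[sid]] <- m
      meta[[sid]] <- data.frame(
        barcode = colnames(m), sample_id = sid,
        batch_id = b, group_label = grp,
        true_cell_type = c(ct_ids[types], d_types),
        true_doublet = c(rep(FALSE, n_sing), rep(TRUE, n_doub)),
        true_empty = FALSE, stringsAsFactors = FALSE)
    }
    # ambient profile: library-size-weighted mean of the batch's singlets
    singlet_sum <- Reduce(`+`, lapply(names(raw), function(sid) {
      keep <- !meta[[sid]]$true_doublet
      rowSums(raw[[sid]][, keep, drop = FALSE])
    }))
    profile <- singlet_sum / sum(singlet_sum)
    ambient_profiles[[b]] <- profile

    for (sid in names(raw)) {
      m <- raw[[sid]]
      if (cfg$ambient_fraction > 0) {
        tot <- colSums(m)
        kept <- matrix(stats::rbinom(length(m), as.vector(m),
                                     1 - cfg$ambient_fraction), nrow(m))
        amb_tot <- stats::rpois(ncol(m), cfg$ambient_fraction * tot)
        amb <- vapply(amb_tot, function(n) stats::rmultinom(1, n, profile)[, 1],
                      numeric(length(profile)))
        m <- kept + amb
        dimnames(m) <- dimnames(raw[[sid]])
      }
      me <- meta[[sid]]
      if (cfg$n_empty_droplets > 0) {
        tot_e <- pmin(99L, 1L + stats::rnbinom(cfg$n_empty_droplets,
                                               mu = 40, size = 2))
        emp <- vapply(tot_e, function(n) stats::rmultinom(1, n, profile)[, 1],
                      numeric(length(profile)))
        rownames(emp) <- genes
        colnames(emp) <- sprintf("%s_empty%05d", sid,
                                 seq_len(cfg$n_empty_droplets))
        m <- cbind(m, emp)
        me <- rbind(me, data.frame(
          barcode = colnames(emp), sample_id = sid, batch_id = b,
          group_label = me$group_label[1], true_cell_type = NA_character_,
          true_doublet = FALSE, true_empty = TRUE, stringsAsFactors = FALSE))
      }
      cm <- cell_matrix(Matrix::Matrix(m, sparse = TRUE),
                        barcode_meta = data.frame(
                          sample_id = me$sample_id, batch_id = me$batch_id,
                          group_label = me$group_label,
                          cell_type_label = me$true_cell_type,
                          stringsAsFactors = FALSE),
                        is_mito = ids$mito, is_hemo = ids$hemo)
      samples[[sid]] <- cm
      truth_rows[[sid]] <- me
    }
  }
  samples <- samples[sample_tbl$sample_id]
  truth <- do.call(rbind, truth_rows[sample_tbl$sample_id])
  rownames(truth) <- NULL
  amb <- do.call(cbind, ambient_profiles)
  list(samples = samples,
       ground_truth = list(
         barcodes = truth,
         planted_effects = if (is.null(pe)) pe_empty() else pe,
         ambient_profiles = amb,
         mean_vectors = mu,
         cell_type_fractions = stats::setNames(fracs, ct_ids),
         samples = sample_tbl))
}

#' Baseline per-cell-type mean vectors implied by a configuration
#'
#' Reproduces (from `config$seed`) the per-cell-type NB mean vectors that
#' [simulate_cohort()] will use, without generating counts. Useful for
#' planting effects on detectably expressed genes: an effect planted on a
#' gene whose expected count is near zero is removed by the expressing-cell
#' filter and can never be recovered.
#'
#' @param config a [sim_config()].
#' @return genes x cell-types matrix of expected counts per cell.
#' @export
sim_baseline_means <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  sim_mean_vectors(config)
}

pe_empty <- function() data.frame(cell_type = character(0), gene = character(0),
                                  test_group = character(0),
                                  ref_group = character(0),
                                  log2fc = numeric(0))

#' Build a planted-effect table
#' @param cell_type,gene,test_group,ref_group,log2fc vectors recycled to a
#'   common length.
#' @export
planted_effects <- function(cell_type, gene, test_group, ref_group, log2fc) {
  data.frame(cell_type = cell_type, gene = gene, test_group = test_group,
             ref_group = ref_group, log2fc = log2fc, stringsAsFactors = FALSE)
}
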