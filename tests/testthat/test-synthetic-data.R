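test_that("null configuration yields singlets with NB marginal means", {
  cfg <- sim_config(n_samples_per_group = 1, groups = c("A", "B"),
                    n_cell_types = 2, cells_per_sample = 600, n_genes = 300,
                    ambient_fraction = 0, doublet_rate = 0,
                    n_empty_droplets = 0, seed = 5)
  sim <- simulate_cohort(cfg)
  truth <- sim$ground_truth
  expect_false(any(truth$barcodes$true_doublet))
  expect_false(any(truth$barcodes$true_empty))

  m <- sim$samples[[1]]
  mu <- truth$mean_vectors
  bc <- truth$barcodes[truth$barcodes$sample_id == "S01", ]
  ct <- "CT01"
  cells <- bc$barcode[bc$true_cell_type == ct]
  obs <- as.matrix(m$counts[rownames(mu), cells])
  n <- length(cells)
  phi <- cfg$dispersion
  se <- sqrt((mu[, ct] + phi * mu[, ct]^2) / n)
  z <- (rowMeans(obs) - mu[, ct]) / pmax(se, 1e-9)
  expect_gt(mean(abs(z) <= 3), 0.97)
})

test_that("NB marginal variance follows mu + phi * mu^2", {
  phi <- 0.4
  cfg <- sim_config(n_samples_per_group = 1, groups = c("A", "B"),
                    n_cell_types = 1, cells_per_sample = 2000, n_genes = 200,
                    dispersion = phi, ambient_fraction = 0, doublet_rate = 0,
                    n_empty_droplets = 0, seed = 11)
  sim <- simulate_cohort(cfg)
  truth <- sim$ground_truth
  mu <- truth$mean_vectors[, "CT01"]
  bc <- truth$barcodes[truth$barcodes$sample_id == "S01", ]
  obs <- as.matrix(sim$samples[[1]]$counts[names(mu), bc$barcode])
  v_obs <- apply(obs, 1, var)
  v_theo <- mu + phi * mu^2
  keep <- mu > 1
  ratio <- v_obs[keep] / v_theo[keep]
  expect_gt(median(ratio), 0.85)
  expect_lt(median(ratio), 1.15)
})

test_that("planted log2FC of 2 gives a mean pseudobulk expression ratio near 4", {
  ratios <- vapply(1:20, function(s) {
    pe <- planted_effects("CT01", "GENE0010", "B", "A", 2)
    cfg <- sim_config(n_samples_per_group = 3, groups = c("A", "B"),
                      n_cell_types = 1, cells_per_sample = 150, n_genes = 200,
                      planted_effects = pe, ambient_fraction = 0,
                      doublet_rate = 0, n_empty_droplets = 0, seed = s)
    sim <- simulate_cohort(cfg)
    pb <- pseudobulk_aggregate(bind_cell_matrices(sim$samples))
    cpm <- sweep(pb$counts, 2, colSums(pb$counts) / 1e6, "/")
    grp <- pb$unit_meta$group_label
    mean(cpm["GENE0010", grp == "B"]) / mean(cpm["GENE0010", grp == "A"])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 4),
            max(0.4, 3 * sd(ratios) / sqrt(length(ratios))))
})

test_that("cohort simulation is deterministic in the seed", {
  cfg <- fixture_cohort_config(seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(lapply(a$samples, `[[`, "counts"),
                   lapply(b$samples, `[[`, "counts"))
  expect_identical(a$ground_truth$barcodes, b$ground_truth$barcodes)
})

test_that("doublets have higher totals and empty droplets stay below 100", {
  sim <- simulate_cohort(fixture_cohort_config(seed = 3))
  raw <- bind_cell_matrices(sim$samples)
  tr <- sim$ground_truth$barcodes
  tot <- raw$barcode_meta$total_umi[match(tr$barcode, raw$barcode_meta$barcode)]
  expect_gt(mean(tot[tr$true_doublet]), mean(tot[!tr$true_doublet & !tr$true_empty]))
  expect_true(all(tot[tr$true_empty] < 100))
  for (b in colnames(sim$ground_truth$ambient_profiles))
    expect_equal(sum(sim$ground_truth$ambient_profiles[, b]), 1)
})

test_that("planting an effect on an unknown gene is rejected", {
  expect_error(
    sim_config(planted_effects = planted_effects("CT01", "NOT_A_GENE",
                                                 "PsA-only", "HC", 1)),
    "absent from the expressed panel")
  expect_error(
    sim_config(planted_effects = planted_effects("CT99", "GENE0001",
                                                 "PsA-only", "HC", 1)),
    "unknown cell type")
})

test_that("MTX triplet writer round-trips, preserves zero rows, guards overwrite", {
  counts <- Matrix::Matrix(matrix(c(0, 0, 2, 3, 0, 5), nrow = 3, byrow = TRUE,
                                  dimnames = list(c("gA", "gB", "gC"),
                                                  c("bc1", "bc2"))),
                           sparse = TRUE)
  cm <- cell_matrix(counts, data.frame(sample_id = c("s1", "s1")),
                    is_mito = "gC")
  dir <- withr::local_tempdir()
  write_tenx_triplet(cm, dir)
  back <- read_tenx_triplet(dir)
  expect_equal(as.matrix(back$counts), as.matrix(cm$counts))
  expect_identical(back$gene_meta, cm$gene_meta)
  expect_identical(back$barcode_meta$sample_id, cm$barcode_meta$sample_id)
  expect_true(all(as.matrix(back$counts)["gA", ] == 0))
  expect_error(write_tenx_triplet(cm, dir), "force")
  expect_silent(write_tenx_triplet(cm, dir, force = TRUE))
})
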