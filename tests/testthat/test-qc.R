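# Helper: build a cell_matrix with exact per-cell totals, detected genes and
# mito/hemo counts. Panel: 300 ordinary genes + 1 mito + 1 hemo.
make_cells <- function(design) {
  n_genes <- 300
  genes <- c(sprintf("g%03d", seq_len(n_genes)), "MT-1", "HB-1")
  cols <- lapply(seq_len(nrow(design)), function(i) {
    v <- numeric(n_genes + 2)
    s <- design[i, ]
    body <- s$total - s$mito - s$hemo
    n_body_genes <- s$genes - (s$mito > 0) - (s$hemo > 0)
    base <- body %/% n_body_genes
    extra <- body %% n_body_genes
    v[seq_len(n_body_genes)] <- base + c(rep(1, extra), rep(0, n_body_genes - extra))
    v[n_genes + 1] <- s$mito
    v[n_genes + 2] <- s$hemo
    v
  })
  m <- do.call(cbind, cols)
  rownames(m) <- genes
  colnames(m) <- sprintf("cell%02d", seq_len(ncol(m)))
  cell_matrix(Matrix::Matrix(m, sparse = TRUE),
              data.frame(sample_id = design$sample),
              is_mito = "MT-1", is_hemo = "HB-1")
}

test_that("mito threshold maps the 95th percentile up to the grid and caps", {
  thr <- qc_thresholds()
  expect_equal(mito_threshold(rep(0.17, 50), thr), 0.20)
  expect_equal(mito_threshold(rep(0.25, 50), thr), 0.25)
  expect_equal(mito_threshold(rep(0.40, 50), thr), 0.35)
  expect_error(mito_threshold(numeric(0)), "empty")
  # monotone: raising every fraction never lowers the threshold
  set.seed(1)
  for (i in 1:20) {
    x <- runif(40, 0, 0.3)
    expect_gte(mito_threshold(pmin(x + runif(1, 0, 0.1), 1), thr),
               mito_threshold(x, thr))
  }
})

test_that("count, gene, mito and hemoglobin filters use strict bounds", {
  design <- data.frame(
    sample = "s1",
    total = c(1000, 499, 500, 1000, 1000, 1000, 1000,
              rep(1000, 35)),
    genes = c(250, 250, 250, 199, 250, 250, 250, rep(250, 35)),
    mito = c(100, 50, 50, 100, 200, 210, 100, rep(50, 35)),
    hemo = c(1, 0, 0, 0, 0, 0, 2, rep(0, 35)))
  # cells: pass / fail UMI(499) / pass at UMI boundary / fail genes(199) /
  #        mito 0.20 at threshold (pass) / mito 0.21 above (fail) /
  #        hemo 0.002 (fail); cell 1's hemoglobin sits exactly at 0.001
  #        (pass); 35 low-mito fillers pin the 95th percentile below 0.20
  cm <- make_cells(design)
  res <- apply_cell_filters(cm)
  kept <- res$matrix$barcode_meta$barcode
  expect_setequal(kept, c("cell01", "cell03", "cell05", sprintf("cell%02d", 8:42)))
  rep <- res$report
  expect_equal(rep$n_fail_umi, 1)
  expect_equal(rep$n_fail_genes, 1)
  expect_equal(rep$mito_threshold_used, 0.20)
  expect_equal(rep$n_fail_hemo, 1)
  expect_equal(rep$n_input, 42)
})

test_that("filtering is idempotent and counts are conserved per sample", {
  sim <- simulate_cohort(fixture_cohort_config(seed = 9, planted = FALSE))
  raw <- bind_cell_matrices(sim$samples)
  once <- apply_cell_filters(raw)
  twice <- apply_cell_filters(once$matrix)
  expect_equal(as.matrix(twice$matrix$counts), as.matrix(once$matrix$counts))
  rep <- once$report
  bm <- raw$barcode_meta
  for (i in seq_len(nrow(rep))) {
    s <- rep$sample_id[i]
    n_kept <- sum(once$matrix$barcode_meta$sample_id == s)
    expect_equal(rep$n_retained[i], n_kept)
    expect_equal(rep$n_input[i], sum(bm$sample_id == s))
  }
})

test_that("doublet quota, determinism and better-than-random recall", {
  cfg <- sim_config(n_samples_per_group = 1, groups = c("A", "B"),
                    n_cell_types = 4, cells_per_sample = 300, n_genes = 400,
                    doublet_rate = 0.05, ambient_fraction = 0,
                    n_empty_droplets = 0, seed = 1)
  sim <- simulate_cohort(cfg)
  m <- sim$samples[[1]]
  expect_false(any(doublet_scores(m, expected_rate = 0,
                                  seed = 1)$barcode_meta$is_doublet))
  a <- doublet_scores(m, expected_rate = 0.05, seed = 42)
  b <- doublet_scores(m, expected_rate = 0.05, seed = 42)
  expect_identical(a$barcode_meta$is_doublet, b$barcode_meta$is_doublet)
  expect_equal(sum(a$barcode_meta$is_doublet), floor(0.05 * ncol(m$counts)))
  expect_error(doublet_scores(m, k = ncol(m$counts)), "2\\*k|smaller")

  recalls <- vapply(1:10, function(s) {
    cfg_s <- sim_config(n_samples_per_group = 1, groups = c("A", "B"),
                        n_cell_types = 4, cells_per_sample = 300,
                        n_genes = 400, doublet_rate = 0.05,
                        ambient_fraction = 0, n_empty_droplets = 0, seed = s)
    sim_s <- simulate_cohort(cfg_s)
    ms <- doublet_scores(sim_s$samples[[1]], expected_rate = 0.05,
                         seed = s + 1000)
    tr <- sim_s$ground_truth$barcodes
    planted <- tr$barcode[tr$true_doublet]
    flagged <- ms$barcode_meta$barcode[ms$barcode_meta$is_doublet]
    length(intersect(flagged, planted)) / length(planted)
  }, numeric(1))
  expect_gt(mean(recalls), 0.05)   # clearly better than random flagging
})
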