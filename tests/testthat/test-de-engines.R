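test_that("BH adjustment reproduces the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(numeric(0)), "empty")
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
})

test_that("identical groups give zero log2FC and non-significant p", {
  m <- matrix(rpois(50 * 8, 30) + 1, 50)
  counts <- cbind(m, m)   # test group duplicates the reference exactly
  rownames(counts) <- sprintf("g%02d", 1:50)
  pb <- pseudobulk_table(counts, sprintf("u%02d", 1:16), "ct",
                         rep(c("ref", "test"), each = 8))
  for (fit in list(fit_nb_wald(pb, c("test", "ref"), "ct"),
                   fit_nb_exact(pb, c("test", "ref"), "ct"),
                   fit_wlm_modt(pb, c("test", "ref"), "ct"))) {
    expect_equal(fit$log2FC, rep(0, 50), tolerance = 1e-8)
    expect_true(all(fit$p_value > 0.5))
  }
})

test_that("exact NB test approaches the Poisson conditional test as phi -> 0", {
  poisson_oracle <- function(t1, t2, n1, n2) {
    t <- t1 + t2
    pr <- dbinom(0:t, t, n1 / (n1 + n2))
    sum(pr[pr <= pr[t1 + 1] * (1 + 1e-8)])
  }
  cases <- list(c(10, 30), c(55, 45), c(3, 20), c(140, 90))
  for (cs in cases) {
    ours <- pbconsensus:::nb_exact_test(cs[1], cs[2], n1 = 5, n2 = 7,
                                        phi = 1e-10)
    expect_equal(ours, poisson_oracle(cs[1], cs[2], 5, 7), tolerance = 1e-6)
  }
})

test_that("unweighted unmoderated engine reduces to the two-sample t-test", {
  pb <- nb_pseudobulk(31, n_genes = 80, n = 6)
  fit <- fit_wlm_modt(pb, c("test", "ref"), "ct",
                      use_weights = FALSE, moderate = FALSE)
  counts <- pb$counts
  eff <- colSums(counts) * tmm_factors(counts)
  y <- log2(sweep(counts + 0.5, 2, (eff + 1) / 1e6, "/"))
  grp <- pb$unit_meta$group_label
  p_oracle <- apply(y, 1, function(v)
    t.test(v[grp == "test"], v[grp == "ref"], var.equal = TRUE)$p.value)
  expect_equal(fit$p_value, unname(p_oracle), tolerance = 1e-8)
  lfc_oracle <- rowMeans(y[, grp == "test"]) - rowMeans(y[, grp == "ref"])
  expect_equal(fit$log2FC, unname(lfc_oracle), tolerance = 1e-8)
})

test_that("each engine recovers a planted log2FC of 2 within 0.3", {
  for (engine in c("fit_nb_wald", "fit_nb_exact", "fit_wlm_modt")) {
    est <- vapply(1:3, function(s) {
      pb <- nb_pseudobulk(400 + s, n_genes = 300, n = 8, n_de = 20, lfc = 2)
      fit <- get(engine)(pb, c("test", "ref"), "ct")
      mean(fit$log2FC[match(sprintf("g%04d", 1:20), fit$gene)])
    }, numeric(1))
    expect_lt(abs(mean(est) - 2), 0.3)
  }
})

test_that("engines agree on strong effects: Jaccard > 0.5 and coherent signs", {
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  signs_ok <- 0; signs_n <- 0
  for (s in 1:3) {
    pb <- nb_pseudobulk(600 + s, n_genes = 300, n = 8, n_de = 25, lfc = 2)
    fits <- run_de_engines(pb, c("test", "ref"), "ct")
    sig <- lapply(fits, function(f) f$gene[f$adj_p < 0.05])
    expect_gt(jac(sig$nb_wald, sig$nb_exact), 0.5)
    expect_gt(jac(sig$nb_wald, sig$wlm_modt), 0.5)
    expect_gt(jac(sig$nb_exact, sig$wlm_modt), 0.5)
    planted <- sprintf("g%04d", 1:25)
    sgn <- sapply(fits, function(f) sign(f$log2FC[match(planted, f$gene)]))
    signs_ok <- signs_ok + sum(apply(sgn, 1, function(x) all(x == x[1])))
    signs_n <- signs_n + length(planted)
  }
  expect_gte(signs_ok / signs_n, 0.95)
})

test_that("engines validate their design requirements", {
  pb <- nb_pseudobulk(7, n_genes = 20, n = 2)
  pb1 <- pb
  pb1$unit_meta$group_label <- c("ref", "ref", "ref", "test")
  expect_error(fit_nb_wald(pb1, c("test", "ref"), "ct"), ">= 2 units")
  expect_error(fit_nb_wald(pb, c("test", "nope"), "ct"), "absent")
  # an all-zero gene is reported as flat and non-significant
  pb$counts[1, ] <- 0
  fit <- fit_nb_wald(pb, c("test", "ref"), "ct")
  expect_equal(fit$log2FC[1], 0)
  expect_equal(fit$p_value[1], 1)
})
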