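make_results <- function(adj_p, lfc, genes = sprintf("g%02d", seq_along(lfc)),
                         ct = "ct") {
  engines <- c("nb_wald", "nb_exact", "wlm_modt")
  lapply(1:3, function(i) {
    data.frame(engine = engines[i], cell_type = ct, gene = genes,
               log2FC = lfc, p_value = adj_p[, i], adj_p = adj_p[, i],
               mean_expression = 10, stringsAsFactors = FALSE)
  })
}

test_that("the consensus rule reproduces its defining example rows", {
  adj_p <- rbind(c(0.03, 0.04, 0.50),   # two engines at 0.05 -> significant
                 c(0.005, 0.30, 0.40),  # one engine below 0.01 -> significant
                 c(0.001, 0.001, 0.001),# fails |log2FC| > 0.5
                 c(0.02, 0.20, 0.60))   # single 0.02 meets neither branch
  lfc <- c(0.6, 0.7, 0.4, 0.9)
  res <- make_results(adj_p, lfc)
  cons <- consensus_call(res)
  expect_identical(cons$consensus_sig, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(cons$n_engines_sig_05, c(2, 1, 3, 1))
})

test_that("consensus matches the brute-force rule over an exhaustive grid", {
  grid_p <- c(0.005, 0.02, 0.04, 0.2)
  grid_l <- c(0.4, 0.6)
  combos <- expand.grid(p1 = grid_p, p2 = grid_p, p3 = grid_p, l = grid_l)
  adj_p <- as.matrix(combos[, 1:3])
  lfc <- combos$l
  cons <- consensus_call(make_results(adj_p, lfc,
                                      genes = sprintf("g%03d", seq_len(nrow(combos)))))
  oracle <- vapply(seq_len(nrow(combos)), function(i)
    oracle_consensus(adj_p[i, ], lfc[i]), logical(1))
  expect_identical(cons$consensus_sig, oracle)
})

test_that("consensus invariants hold and evidence is monotone", {
  set.seed(12)
  adj_p <- matrix(runif(300), ncol = 3)
  lfc <- runif(100, -2, 2)
  cons <- consensus_call(make_results(adj_p, lfc,
                                      genes = sprintf("g%03d", 1:100)))
  expect_true(all(!cons$consensus_sig | cons$passes_lfc))
  expect_true(all(!cons$consensus_sig |
                  (cons$n_engines_sig_05 >= 2 | cons$min_adj_p < 0.01)))
  # lowering any engine's adj_p never turns significance off
  adj_p2 <- adj_p * 0.5
  cons2 <- consensus_call(make_results(adj_p2, lfc,
                                       genes = sprintf("g%03d", 1:100)))
  expect_true(all(cons2$consensus_sig[cons$consensus_sig]))
  expect_error(consensus_call(make_results(adj_p, lfc)[1:2]), "three")
})

test_that("unique DEG counting deduplicates genes across cell types", {
  tab <- data.frame(cell_type = c("a", "b", "c", "a"),
                    gene = c("g1", "g1", "g1", "g2"),
                    consensus_sig = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(unique_deg_count(tab), 1)
  tab$final_sig <- c(TRUE, TRUE, TRUE, TRUE)
  expect_equal(unique_deg_count(tab), 2)
  expect_equal(unique_deg_count(tab[0, ]), 0)
})

test_that("PC1 scores equal the covariance eigendecomposition oracle", {
  set.seed(5)
  for (rep in 1:5) {
    m <- matrix(rnorm(300), ncol = 3)
    res <- make_results(matrix(0.5, 100, 3), rep(0, 100),
                        genes = sprintf("g%03d", 1:100))
    for (i in 1:3) res[[i]]$log2FC <- m[, i]
    cons <- pc1_rank(consensus_call(res))
    xc <- scale(m, center = TRUE, scale = FALSE)
    ev <- eigen(cov(m))$vectors[, 1]
    oracle <- drop(xc %*% ev)
    if (cor(oracle, rowMeans(m)) < 0) oracle <- -oracle
    expect_equal(cons$pc1_score, oracle, tolerance = 1e-9)
    expl <- attr(cons, "pc1_explained")
    expect_gte(unname(expl["ct"]), 1 / 3)
  }
})

test_that("PC1 orientation and degenerate inputs behave as specified", {
  set.seed(6)
  shared <- rnorm(50)
  res <- make_results(matrix(0.5, 50, 3), shared,
                      genes = sprintf("g%02d", 1:50))
  cons <- pc1_rank(consensus_call(res))
  # identical columns: score proportional to the centred shared log2FC
  expect_equal(cor(cons$pc1_score, shared - mean(shared)), 1, tolerance = 1e-12)
  expect_gt(unname(attr(cons, "pc1_explained")["ct"]), 0.999)
  # negating one engine's column keeps the orientation rule intact
  res2 <- res
  res2[[2]]$log2FC <- -shared
  cons2 <- pc1_rank(consensus_call(res2))
  expect_gte(cor(cons2$pc1_score, cons2$mean_log2FC), 0)
  # all-identical rows: warning, equal scores
  res3 <- make_results(matrix(0.5, 10, 3), rep(1.5, 10),
                       genes = sprintf("g%02d", 1:10))
  expect_warning(cons3 <- pc1_rank(consensus_call(res3)), "degenerate")
  expect_true(all(cons3$pc1_score == 0))
  # gene order invariance
  perm <- sample(50)
  res4 <- lapply(res, function(r) r[perm, ])
  cons4 <- pc1_rank(consensus_call(res4))
  expect_equal(cons4$pc1_score[match(cons$gene, cons4$gene)], cons$pc1_score,
               tolerance = 1e-12)
})

test_that("genes missing from one engine are kept but not PCA-ranked", {
  res <- make_results(matrix(0.001, 20, 3), seq(0.6, 2, length.out = 20),
                      genes = sprintf("g%02d", 1:20))
  res[[2]] <- res[[2]][-1, ]  # engine 2 never reported g01
  cons <- pc1_rank(consensus_call(res))
  row <- cons[cons$gene == "g01", ]
  expect_true(is.na(row$adj_p_nb_exact))
  expect_true(is.na(row$pc1_score))
  expect_equal(row$n_engines_sig_05, 2)   # the two reporting engines
  expect_true(row$consensus_sig)
})
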