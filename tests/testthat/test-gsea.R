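test_that("enrichment score matches the hand-computed worked example", {
  ranked <- c(g1 = 3, g2 = 2, g3 = 1, g4 = 0.5)
  res <- enrichment_score(ranked, "g1")
  expect_equal(res$es, 1.0)
  expect_equal(res$peak_index, 1L)
  expect_identical(res$core_genes, "g1")
  expect_equal(res$running, c(1, 1 - 1/3, 1 - 2/3, 0))
  # a zero-scored member at the bottom of an otherwise positive ranking
  ranked2 <- c(g1 = 3, g2 = 2, g3 = 1, g4 = 0)
  expect_lt(enrichment_score(ranked2, "g4")$es, 0)
  expect_error(enrichment_score(ranked, c("gX")), "does not intersect")
  expect_error(enrichment_score(ranked, names(ranked)), "whole universe")
})

test_that("ES is bounded, symmetric, and 1 only for a perfect top block", {
  set.seed(10)
  for (i in 1:20) {
    scores <- sort(abs(rnorm(50)) + 0.01, decreasing = TRUE)
    names(scores) <- sprintf("g%02d", 1:50)
    set <- sample(names(scores), sample(3:20, 1))
    es <- enrichment_score(scores, set)$es
    expect_gte(es, -1); expect_lte(es, 1)
    # symmetry: negate scores and reverse the order
    rev_scores <- -scores
    expect_equal(enrichment_score(rev_scores, set)$es, -es, tolerance = 1e-12)
  }
  scores <- c(a = 5, b = 4, c = 3, d = 0.1, e = 0.1)
  expect_equal(enrichment_score(scores, c("a", "b", "c"))$es, 1)
  expect_lt(enrichment_score(scores, c("a", "b", "d"))$es, 1)
})

test_that("fast positional ES agrees with the full profile walk", {
  set.seed(14)
  scores <- sort(rnorm(200), decreasing = TRUE)
  names(scores) <- sprintf("g%03d", 1:200)
  w <- abs(scores)
  for (i in 1:50) {
    pos <- sort(sample(200, sample(3:30, 1)))
    full <- enrichment_score(scores, names(scores)[pos])$es
    fast <- pbconsensus:::es_from_positions(pos, w[pos], 200)
    expect_equal(fast, full, tolerance = 1e-12)
  }
})

test_that("preranked GSEA is reproducible, floored, and powered", {
  set.seed(20)
  scores <- setNames(rnorm(400), sprintf("g%03d", 1:400))
  coll <- gene_set_collection(list(
    planted = names(sort(scores, decreasing = TRUE))[1:20],
    random = sample(names(scores), 30),
    tiny = sample(names(scores), 3)))
  expect_message(et <- gsea_preranked(scores, coll, n_perm = 500, seed = 4),
                 "dropped")
  expect_false("tiny" %in% et$set)
  expect_true(all(et$p_value >= 1 / 501))
  expect_true(all(sign(et$NES) == sign(et$ES) | et$ES == 0))
  planted <- et[et$set == "planted", ]
  expect_lt(planted$adj_p, 0.05)
  expect_gt(planted$NES, 0)
  expect_identical(planted$direction, "positive")
  # core enrichment genes are planted members above the peak
  expect_true(all(strsplit(planted$core_enrichment, ",")[[1]] %in%
                  coll$sets$planted))
  et2 <- suppressMessages(gsea_preranked(scores, coll, n_perm = 500, seed = 4))
  expect_identical(et, et2)
  expect_error(gsea_preranked(scores, coll, n_perm = 0), "n_perm")
})

test_that("GMT parsing handles duplicates, short lines and empty files", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3",
               "setB\tdesc\tg2\tg4\tg4"), path)
  expect_warning(coll <- read_gmt(path), "duplicated")
  expect_named(coll$sets, c("setA", "setB"))
  expect_identical(coll$sets$setB, c("g2", "g4"))
  writeLines("setC\tonly-two-fields", path)
  expect_error(read_gmt(path), "fewer than 3")
  writeLines(character(0), path)
  expect_warning(empty <- read_gmt(path), "empty")
  expect_length(empty$sets, 0)
})

test_that("gene-set ratio counts the DEG overlap over the universe-clipped set", {
  cons <- data.frame(cell_type = "ct",
                     gene = sprintf("g%02d", 1:20),
                     consensus_sig = c(rep(TRUE, 4), rep(FALSE, 16)))
  set10 <- sprintf("g%02d", 1:10)
  expect_equal(gene_set_ratio(cons, set10), 0.4)
  expect_equal(gene_set_ratio(cons, sprintf("g%02d", 11:20)), 0)
  expect_equal(gene_set_ratio(cons, sprintf("g%02d", 1:4)), 1)
  # genes outside the universe do not count in the denominator
  expect_equal(gene_set_ratio(cons, c(set10, "gX", "gY")), 0.4)
  expect_error(gene_set_ratio(cons, c("gX")), "empty")
})
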