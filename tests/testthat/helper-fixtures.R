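# Shared fixtures: all synthetic, built in code at test time.

# Direct NB pseudobulk table: n_genes x 2n units, two groups ("ref", "test"),
# log-normal baseline means, optional planted log2 fold changes on the first
# n_de genes (applied to the test group).
nb_pseudobulk <- function(seed, n_genes = 500, n = 8, phi = 0.15,
                          n_de = 0, lfc = 2, cell_type = "ct") {
  set.seed(seed)
  mu <- rlnorm(n_genes, log(100), 1.3)
  depth <- runif(2 * n, 0.7, 1.4)
  m <- matrix(rnbinom(n_genes * 2 * n, mu = outer(mu, depth), size = 1 / phi),
              n_genes)
  if (n_de > 0) {
    idx <- seq_len(n_de)
    test_cols <- (n + 1):(2 * n)
    m[idx, test_cols] <- rnbinom(n_de * n,
                                 mu = outer(mu[idx] * 2^lfc, depth[test_cols]),
                                 size = 1 / phi)
  }
  rownames(m) <- sprintf("g%04d", seq_len(n_genes))
  pseudobulk_table(m,
                   sample_id = sprintf("u%02d", seq_len(2 * n)),
                   cell_type = cell_type,
                   group_label = rep(c("ref", "test"), each = n))
}

# Small cohort for pipeline-level tests: 3 groups x 4 samples, 3 cell types,
# 300 genes, with strong effects planted for the third group.
fixture_cohort_config <- function(seed = 2024L, planted = TRUE) {
  base <- sim_config(n_samples_per_group = 4,
                     groups = c("HC", "PsA-only", "PsA-PsC"),
                     n_cell_types = 3, cells_per_sample = 250, n_genes = 300,
                     n_empty_droplets = 150, samples_per_batch = 4,
                     seed = seed)
  if (!planted) return(base)
  # plant effects on mid-expression genes: detectable by the expressing-cell
  # filter yet below the ambient-exclusion band
  mu <- sim_baseline_means(base)
  r <- rank(rowMeans(mu)) / nrow(mu)
  band <- rownames(mu)[r >= 0.40 & r <= 0.60]
  genes <- band[round(seq(1, length(band), length.out = 8))]
  pe <- planted_effects("CT01", genes, "PsA-PsC", "HC",
                        c(rep(2.5, 6), rep(-2.5, 2)))
  sim_config(n_samples_per_group = 4, groups = c("HC", "PsA-only", "PsA-PsC"),
             n_cell_types = 3, cells_per_sample = 250, n_genes = 300,
             n_empty_droplets = 150, planted_effects = pe,
             samples_per_batch = 4, seed = seed)
}

# Brute-force BH step-up oracle, straight from the definition: sort p,
# compute p_(i) * m / i, enforce monotonicity from the largest rank down.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Brute-force consensus oracle implementing the rule verbatim: absolute
# log2FC > 0.5 AND (significant at 0.05 in >= 2 engines OR < 0.01 in one).
oracle_consensus <- function(adj_p, mean_lfc,
                             lfc_cut = 0.5, p2 = 0.05, p1 = 0.01) {
  abs(mean_lfc) > lfc_cut &
    (sum(adj_p < p2) >= 2 | any(adj_p < p1))
}

# Tiny GMT fixture written to a temp file.
write_fixture_gmt <- function(path, universe, n_sets = 5, set_size = 20,
                              seed = 7) {
  set.seed(seed)
  lines <- vapply(seq_len(n_sets), function(i) {
    paste(c(sprintf("SET%02d", i), sprintf("synthetic set %d", i),
            sample(universe, set_size)), collapse = "\t")
  }, "")
  writeLines(lines, path)
  path
}
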