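#' 2x2 chi-squared test with optional continuity correction
#'
#' Pearson chi-squared on a 2x2 contingency table. With
#' `continuity_correction = TRUE` (the default, matching the convention of
#' standard baseline-characteristics tables) each cell's |O - E| is reduced
#' by `min(0.5, |O - E|)` before squaring (Yates correction).
#'
#' @param table 2x2 nonnegative integer matrix.
#' @param continuity_correction apply the Yates correction (default TRUE).
#' @return list with `statistic` and `p_value` (chi-squared, df = 1).
#' @export
chisq_2x2 <- function(table, continuity_correction = TRUE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in contingency table")
  ct <- suppressWarnings(
    stats::chisq.test(table, correct = continuity_correction))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}

#' One-way ANOVA across two or more groups
#'
#' Classical equal-variance F test. A degenerate input (all values equal so
#' both sums of squares vanish) is guarded as p = 1.
#'
#' @param groups list of >= 2 numeric vectors.
#' @return list with `F` and `p_value`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(x) x[!is.na(x)])
  n <- lengths(groups)
  stopifnot(sum(n) > length(groups))
  y <- unlist(groups)
  if (stats::var(y) == 0) return(list(F = 0, p_value = 1))
  g <- factor(rep(seq_along(groups), n))
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p_value = unname(ft$p.value))
}

#' PCA of sample-level cell-type fractions
#'
#' Checks whether samples cluster by composition: PCA on the centred
#' samples x cell-types fraction matrix, returning sample scores and the
#' proportion of variance explained per component.
#'
#' @param fractions samples x cell-types matrix; rows must sum to 1.
#' @return list with `scores` and `explained_variance` (sums to 1).
#' @export
celltype_fraction_pca <- function(fractions) {
  fractions <- as.matrix(fractions)
  stopifnot(nrow(fractions) >= 3, all(fractions >= 0),
            all(abs(rowSums(fractions) - 1) < 1e-9))
  x <- scale(fractions, center = TRUE, scale = FALSE)
  if (all(abs(x) < 1e-12)) {
    return(list(scores = matrix(0, nrow(fractions), 1,
                                dimnames = list(rownames(fractions), "PC1")),
                explained_variance = NA_real_))
  }
  pc <- stats::prcomp(fractions, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, explained_variance = ev)
}

#' Baseline-characteristics summary table
#'
#' Categorical variables are reported as "n (%)" per group with a 2x2
#' chi-squared p-value (Yates-corrected, two groups and two levels only);
#' continuous variables as "median [q1, q3]" (type-7 quantiles) with a
#' one-way ANOVA p-value.
#'
#' @param data data.frame of per-sample variables.
#' @param group name of the grouping column in `data`.
#' @param categorical,continuous character vectors of column names.
#' @return data.frame with one row per (variable, level) and one column per
#'   group plus `p_value`.
#' @export
summarize_table1 <- function(data, group, categorical = character(0),
                             continuous = character(0)) {
  stopifnot(is.data.frame(data), group %in% names(data))
  g <- as.factor(data[[group]])
  if (any(table(g) == 0)) stop("empty group")
  rows <- list()
  for (v in categorical) {
    x <- data[[v]]
    if (all(is.na(x))) { warning("all-missing variable omitted: ", v); next }
    lv <- sort(unique(stats::na.omit(x)))
    tab <- table(factor(x, levels = lv), g)
    p <- if (length(lv) == 2 && nlevels(g) == 2)
      chisq_2x2(as.matrix(tab))$p_value else NA_real_
    for (l in lv) {
      cells <- vapply(levels(g), function(gr) {
        n <- sum(x == l & g == gr, na.rm = TRUE)
        sprintf("%d (%.1f)", n, 100 * n / sum(g == gr & !is.na(x)))
      }, "")
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = as.character(l), t(cells),
        p_value = if (l == lv[1]) p else NA_real_, check.names = FALSE)
    }
  }
  for (v in continuous) {
    x <- data[[v]]
    if (all(is.na(x))) { warning("all-missing variable omitted: ", v); next }
    cells <- vapply(levels(g), function(gr) {
      xs <- x[g == gr & !is.na(x)]
      q <- stats::quantile(xs, c(0.25, 0.5, 0.75), type = 7)
      sprintf("%.2f [%.2f, %.2f]", q[2], q[1], q[3])
    }, "")
    p <- anova_oneway(split(x[!is.na(x)], g[!is.na(x)]))$p_value
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = "", t(cells), p_value = p, check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
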