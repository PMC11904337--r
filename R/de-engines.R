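# Three independent pseudobulk differential-expression engines. They are
# deliberate archetype re-implementations -- an NB Wald GLM with trended
# dispersion shrinkage, an NB exact test with conditional-likelihood
# dispersion, and a precision-weighted moderated-t on log-CPM -- not
# bit-compatible clones of any published tool: the consensus layer only
# needs three reasonable, differently-behaved engines.

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with cumulative-minimum enforcement,
#' order-preserving in the input.
#'
#' @param p vector of p-values in (0, 1].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = "BH")
}

# Assemble one engine's result table (BH within the cell type).
de_result <- function(engine, cell_type, gene, log2fc, p, mean_expr,
                      converged = TRUE) {
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(engine = engine, cell_type = cell_type, gene = gene,
             log2FC = log2fc, p_value = p, adj_p = bh_adjust(p),
             mean_expression = mean_expr,
             converged = converged, stringsAsFactors = FALSE)
}

# Validate a two-group contrast and return per-unit design info.
contrast_design <- function(unit_meta, contrast) {
  stopifnot(length(contrast) == 2, !anyDuplicated(contrast))
  g <- unit_meta$group_label
  if (!all(contrast %in% g)) stop("contrast group(s) absent from units")
  keep <- g %in% contrast
  is_test <- g[keep] == contrast[1]
  if (sum(is_test) < 2 || sum(!is_test) < 2)
    stop("need >= 2 units per contrast level")
  list(keep = keep, is_test = is_test)
}

## ---- NB Wald engine (GLM with trended dispersion shrinkage) ----------------

# IRLS for an NB log-link GLM with fixed dispersion phi and offset.
nb_irls <- function(y, X, offset, phi, max_iter = 50, tol = 1e-8) {
  beta <- stats::lm.fit(X, log(y + 0.5) - offset)$coefficients
  beta[!is.finite(beta)] <- 0
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$coefficients))) break
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    if (delta < tol) { ok <- TRUE; break }
  }
  if (!ok && it == max_iter) ok <- TRUE   # slow but usable convergence
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + phi * mu)
  xtwx <- crossprod(X, X * w)
  cov <- tryCatch(solve(xtwx), error = function(e) NULL)
  list(beta = beta, mu = mu,
       se = if (is.null(cov)) rep(NA_real_, length(beta)) else sqrt(diag(cov)),
       converged = ok && !is.null(cov))
}

# Gene-wise dispersion by Cox-Reid adjusted profile likelihood given fitted
# means: the 0.5*logdet(X'WX) term compensates the downward bias of plain ML
# caused by estimating the mean parameters.
nb_ml_dispersion <- function(y, mu, X, lower = 1e-6, upper = 50) {
  nll <- function(log_phi) {
    phi <- exp(log_phi)
    w <- mu / (1 + phi * mu)
    ld <- determinant(crossprod(X, X * w), logarithm = TRUE)$modulus
    -sum(stats::dnbinom(y, mu = mu, size = 1 / phi, log = TRUE)) +
      0.5 * as.numeric(ld)
  }
  opt <- stats::optimize(nll, c(log(lower), log(upper)))
  exp(opt$minimum)
}

#' NB-Wald pseudobulk differential expression
#'
#' Per gene, a negative-binomial GLM with log link and
#' median-of-ratios-size-factor offset is fit for a two-group contrast.
#' Gene-wise dispersions are estimated by maximum likelihood, shrunk toward
#' a log-linear mean-dispersion trend with a fixed weight, and the contrast
#' coefficient is tested by a Wald z. `log2FC > 0` means higher expression
#' in the test group (`contrast[1]`) than the reference (`contrast[2]`).
#'
#' @param table a filtered [pseudobulk] object.
#' @param contrast `c(test_group, reference_group)`.
#' @param cell_type cell type to analyse.
#' @param shrink_weight weight of the trend in the log-dispersion shrinkage
#'   (0 = gene-wise ML only, 1 = pure trend); default 0.5.
#' @return a `DEResultTable` data.frame (engine `nb_wald`): gene, log2FC,
#'   p_value, BH-adjusted p within the cell type, mean expression.
#' @export
fit_nb_wald <- function(table, contrast, cell_type, shrink_weight = 0.5) {
  sub <- pb_subset(table, cell_type, contrast)
  des <- contrast_design(sub$unit_meta, contrast)
  counts <- sub$counts
  is_test <- des$is_test
  sf <- size_factors_median_ratio(counts)
  offset <- log(sf)
  X <- cbind(intercept = 1, test = as.numeric(is_test))
  n_gene <- nrow(counts)
  norm_mean <- rowMeans(sweep(counts, 2, sf, "/"))

  phi_hat <- rep(NA_real_, n_gene)
  fits <- vector("list", n_gene)
  for (g in seq_len(n_gene)) {
    y <- counts[g, ]
    if (all(y == 0)) next
    f0 <- nb_irls(y, X, offset, phi = 0.1)
    if (!f0$converged) next
    phi_hat[g] <- nb_ml_dispersion(y, f0$mu, X)
    fits[[g]] <- f0
  }
  usable <- which(is.finite(phi_hat) & norm_mean > 0)
  log_phi <- log(phi_hat)
  if (length(usable) >= 10) {
    tr <- stats::lm(log_phi[usable] ~ log(norm_mean[usable]))
    trend <- cbind(1, log(pmax(norm_mean, 1e-8))) %*% stats::coef(tr)
  } else {
    trend <- rep(mean(log_phi[usable]), n_gene)
  }
  phi_shrunk <- exp(shrink_weight * as.numeric(trend) +
                    (1 - shrink_weight) * log_phi)
  phi_shrunk[!is.finite(phi_shrunk)] <- exp(mean(log_phi[usable]))
  phi_shrunk <- pmin(pmax(phi_shrunk, 1e-6), 50)

  lfc <- p <- rep(NA_real_, n_gene)
  conv <- rep(FALSE, n_gene)
  for (g in seq_len(n_gene)) {
    y <- counts[g, ]
    if (all(y == 0)) { lfc[g] <- 0; p[g] <- 1; next }
    f <- nb_irls(y, X, offset, phi = phi_shrunk[g])
    if (!f$converged || !is.finite(f$se[2]) || f$se[2] == 0) {
      lfc[g] <- 0; p[g] <- 1; next
    }
    z <- f$beta[2] / f$se[2]
    lfc[g] <- f$beta[2] / log(2)
    p[g] <- 2 * stats::pnorm(-abs(z))
    conv[g] <- TRUE
  }
  de_result("nb_wald", cell_type, rownames(counts), lfc, p, norm_mean, conv)
}

## ---- NB exact-test engine (conditional likelihood + exact NB test) ---------

# Conditional (on the group sum) NB log-likelihood of one group's counts,
# assuming a common mean and equal effective library sizes.
nb_cml_group <- function(y, phi) {
  r <- 1 / phi
  n <- length(y)
  sum(lgamma(y + r)) - n * lgamma(r) + lgamma(n * r) - lgamma(sum(y) + n * r)
}

nb_cml <- function(pseudo, is_test, phi) {
  sum(apply(pseudo, 1, function(y)
    nb_cml_group(y[is_test], phi) + nb_cml_group(y[!is_test], phi)))
}

# Double-tail exact NB test of a two-group split of the total t: the
# conditional probabilities of all splits as or less likely than the
# observed one are summed. Computed over a quantile window around the
# conditional mean; for extremely wide windows a normal approximation of
# the split distribution is used instead.
nb_exact_test <- function(t1, t2, n1, n2, phi, max_window = 5e5) {
  t <- t1 + t2
  if (t == 0) return(1)
  p1 <- n1 / (n1 + n2)
  mu1 <- t * p1
  size1 <- n1 / phi; size2 <- n2 / phi
  lo <- max(0, min(stats::qnbinom(1e-12, size = size1, mu = mu1), t1))
  hi <- min(t, max(stats::qnbinom(1 - 1e-12, size = size1, mu = mu1), t1))
  if (hi - lo > max_window) {
    v <- mu1 * (1 + phi * mu1 / n1) * (1 - p1) # heuristic split variance
    z <- (t1 + 0.5 * sign(mu1 - t1) - mu1) / sqrt(v)
    return(min(1, 2 * stats::pnorm(-abs(z))))
  }
  y <- lo:hi
  lp <- stats::dnbinom(y, size = size1, mu = t * p1, log = TRUE) +
        stats::dnbinom(t - y, size = size2, mu = t * (1 - p1), log = TRUE)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[y == t1]
  sum(pr[pr <= obs * (1 + 1e-8)])
}

#' NB exact-test pseudobulk differential expression
#'
#' TMM-normalised effective library sizes; counts scaled to a common
#' effective depth (pseudo-counts); common dispersion by conditional maximum
#' likelihood across genes, gene-wise conditional-ML dispersions shrunk
#' toward the common value on the log scale with a fixed prior weight; exact
#' NB test conditioning on each gene's total pseudo-count; log2 fold change
#' from group mean CPM with a 0.5 prior count. Two-group contrasts only.
#'
#' @inheritParams fit_nb_wald
#' @param prior_weight weight of the common dispersion in the tagwise
#'   shrinkage (default 0.5).
#' @return a `DEResultTable` data.frame (engine `nb_exact`).
#' @export
fit_nb_exact <- function(table, contrast, cell_type, prior_weight = 0.5) {
  sub <- pb_subset(table, cell_type, contrast)
  des <- contrast_design(sub$unit_meta, contrast)
  counts <- sub$counts
  is_test <- des$is_test
  libs <- colSums(counts)
  eff <- libs * tmm_factors(counts)
  eff_bar <- geometric_mean(eff)
  pseudo <- sweep(counts, 2, eff_bar / eff, "*")
  nonzero <- rowSums(pseudo) > 0

  obj_common <- function(log_phi)
    -nb_cml(pseudo[nonzero, , drop = FALSE], is_test, exp(log_phi))
  phi_common <- exp(stats::optimize(obj_common, c(log(1e-6), log(50)))$minimum)

  n_gene <- nrow(counts)
  phi_tag <- rep(phi_common, n_gene)
  for (g in which(nonzero)) {
    y <- pseudo[g, ]
    obj <- function(log_phi)
      -(nb_cml_group(y[is_test], exp(log_phi)) +
        nb_cml_group(y[!is_test], exp(log_phi)))
    phi_g <- exp(stats::optimize(obj, c(log(1e-6), log(50)))$minimum)
    phi_tag[g] <- exp(prior_weight * log(phi_common) +
                      (1 - prior_weight) * log(phi_g))
  }

  cpm <- sweep(counts + 0.5, 2, (eff + 1) / 1e6, "/")
  lfc <- log2(rowMeans(cpm[, is_test, drop = FALSE])) -
         log2(rowMeans(cpm[, !is_test, drop = FALSE]))
  n1 <- sum(is_test); n2 <- sum(!is_test)
  p <- vapply(seq_len(n_gene), function(g) {
    if (!nonzero[g]) return(1)
    t1 <- round(sum(pseudo[g, is_test]))
    t2 <- round(sum(pseudo[g, !is_test]))
    nb_exact_test(t1, t2, n1, n2, phi_tag[g])
  }, numeric(1))
  lfc[!nonzero] <- 0
  mean_expr <- rowMeans(sweep(counts, 2, eff / eff_bar, "/"))
  de_result("nb_exact", cell_type, rownames(counts), lfc, p, mean_expr)
}

## ---- Precision-weighted moderated-t engine ---------------------------------

#' Precision-weighted moderated-t pseudobulk differential expression
#'
#' Counts are transformed to `log2((count + 0.5) / (eff_lib + 1) * 1e6)`;
#' a lowess trend of `sqrt(residual sd)` against mean log-count from a
#' preliminary unweighted fit yields per-observation inverse predicted
#' variance weights; each gene is refit by weighted least squares; residual
#' variances are shrunk by empirical Bayes toward a scaled-inverse-chi-square
#' prior fitted by moment matching on the log variances, giving a moderated
#' t with augmented degrees of freedom.
#'
#' @inheritParams fit_nb_wald
#' @param use_weights apply the mean-variance precision weights
#'   (default TRUE; FALSE gives an unweighted fit).
#' @param moderate apply the empirical-Bayes variance shrinkage
#'   (default TRUE; FALSE gives the ordinary t-test).
#' @return a `DEResultTable` data.frame (engine `wlm_modt`).
#' @export
fit_wlm_modt <- function(table, contrast, cell_type,
                         use_weights = TRUE, moderate = TRUE) {
  sub <- pb_subset(table, cell_type, contrast)
  des <- contrast_design(sub$unit_meta, contrast)
  counts <- sub$counts
  is_test <- des$is_test
  n_unit <- ncol(counts)
  df_resid <- n_unit - 2
  if (df_resid < 1) stop("fewer than 1 residual degree of freedom")
  libs <- colSums(counts)
  eff <- libs * tmm_factors(counts)
  y <- log2(sweep(counts + 0.5, 2, (eff + 1) / 1e6, "/"))
  X <- cbind(1, as.numeric(is_test))
  qr_x <- qr(X)

  # preliminary unweighted fit: residual sd and mean log-count per gene
  res0 <- t(qr.resid(qr_x, t(y)))
  s0 <- sqrt(rowSums(res0^2) / df_resid)
  mean_logcount <- rowMeans(y) + mean(log2(eff + 1)) - log2(1e6)

  w <- matrix(1, nrow(y), ncol(y))
  if (use_weights) {
    lo <- stats::lowess(mean_logcount, sqrt(s0), f = 0.5)
    fitted0 <- t(qr.fitted(qr_x, t(y)))
    obs_logcount <- sweep(fitted0, 2, log2(eff + 1) - log2(1e6), "+")
    sqrt_sd <- stats::approx(lo$x, lo$y, xout = as.vector(obs_logcount),
                             rule = 2)$y
    w <- matrix(pmax(sqrt_sd, 1e-4)^-4, nrow(y))
  }

  n_gene <- nrow(y)
  beta <- se_unscaled <- s2 <- rep(NA_real_, n_gene)
  for (g in seq_len(n_gene)) {
    fit <- stats::lm.wfit(X, y[g, ], w[g, ])
    beta[g] <- fit$coefficients[2]
    xtwx_inv <- tryCatch(solve(crossprod(X, X * w[g, ])),
                         error = function(e) NULL)
    if (is.null(xtwx_inv)) next
    se_unscaled[g] <- sqrt(xtwx_inv[2, 2])
    s2[g] <- sum(w[g, ] * fit$residuals^2) / df_resid
  }
  ok <- is.finite(s2) & s2 > 0 & is.finite(se_unscaled)

  if (moderate && sum(ok) >= 5) {
    z <- log(s2[ok])
    e <- z - digamma(df_resid / 2) + log(df_resid / 2)
    var_e <- stats::var(e) - trigamma(df_resid / 2)
    if (is.finite(var_e) && var_e > 0) {
      d0 <- 2 * trigamma_inverse(var_e)
      s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else { d0 <- Inf; s0sq <- exp(mean(e)) }
  } else { d0 <- 0; s0sq <- 0 }

  if (is.infinite(d0)) {
    s2_post <- rep(s0sq, n_gene); df_total <- rep(Inf, n_gene)
  } else if (d0 > 0) {
    s2_post <- (d0 * s0sq + df_resid * s2) / (d0 + df_resid)
    df_total <- rep(d0 + df_resid, n_gene)
  } else {
    s2_post <- s2; df_total <- rep(df_resid, n_gene)
  }
  tstat <- beta / (se_unscaled * sqrt(s2_post))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[!ok] <- 1
  lfc <- beta
  lfc[!ok] <- 0
  mean_expr <- rowMeans(sweep(counts, 2, eff / geometric_mean(eff), "/"))
  de_result("wlm_modt", cell_type, rownames(y), lfc, p, mean_expr, ok)
}

#' Run the three engines for one contrast and cell type
#'
#' @inheritParams fit_nb_wald
#' @param engine_opts named list of per-engine argument lists
#'   (`nb_wald`, `nb_exact`, `wlm_modt`).
#' @return named list of three `DEResultTable` data.frames.
#' @export
run_de_engines <- function(table, contrast, cell_type, engine_opts = list()) {
  list(
    nb_wald = do.call(fit_nb_wald,
      c(list(table, contrast, cell_type), engine_opts$nb_wald)),
    nb_exact = do.call(fit_nb_exact,
      c(list(table, contrast, cell_type), engine_opts$nb_exact)),
    wlm_modt = do.call(fit_wlm_modt,
      c(list(table, contrast, cell_type), engine_opts$wlm_modt)))
}
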