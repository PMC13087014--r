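#' Simple linear regression of atrophy on gene expression
#'
#' OLS of the mean w-score map on one gene's expression profile across
#' regions. With higher expression accompanying more negative w-scores
#' (more atrophy) the slope is negative. Expression enters on its
#' post-normalization [0, 1] scale by default; `standardize = TRUE`
#' z-scores both variables first.
#'
#' @param atrophy numeric vector / [region_map()] of mean w-scores.
#' @param gene numeric vector / [region_map()] of expression values.
#' @param standardize z-score both variables before fitting.
#' @return list: `beta`, `se`, `t`, `df` (= n - 2), `r2`, `intercept`, `n`.
#' @export
fit_gene_regression <- function(atrophy, gene, standardize = FALSE) {
  y <- as.numeric(atrophy)
  x <- as.numeric(gene)
  n <- length(y)
  if (length(x) != n) stop("atrophy and gene maps differ in length")
  if (n < 4) stop("need at least 4 regions")
  if (max(x) - min(x) == 0) stop("constant predictor")
  if (standardize) {
    x <- (x - mean(x)) / stats::sd(x)
    y <- (y - mean(y)) / stats::sd(y)
  }
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta <- sxy / sxx
  intercept <- mean(y) - beta * mean(x)
  resid <- y - intercept - beta * x
  df <- n - 2L
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 / sxx)
  syy <- sum((y - mean(y))^2)
  r2 <- if (syy == 0) 0 else 1 - sum(resid^2) / syy
  list(beta = beta, se = se, t = beta / se, df = df, r2 = r2,
       intercept = intercept, n = n)
}

# t statistics of y ~ each row of S (surrogate matrix), vectorized
regression_t_vector <- function(y, S) {
  n <- length(y)
  yc <- y - mean(y)
  Sc <- S - rowMeans(S)
  sxx <- rowSums(Sc^2)
  sxy <- as.vector(Sc %*% yc)
  r <- sxy / sqrt(sxx * sum(yc^2))
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  r * sqrt((n - 2) / (1 - r^2))
}

#' Spatial p-value for a gene-atrophy regression
#'
#' Refits the regression with the gene map replaced by each surrogate of the
#' gene's ensemble and returns the add-one empirical p-value of the observed
#' t statistic against the null t distribution (two-sided by default, as the
#' slope sign is not pre-specified).
#'
#' @param atrophy numeric vector / [region_map()].
#' @param gene numeric vector / [region_map()]; must be the ensemble source.
#' @param ensemble a `surrogate_ensemble` generated from `gene`.
#' @param sided `"two"` (default) or `"one"`.
#' @return list: `p_spatial`, `t_obs`, `t_null` (vector), `n_surrogates`.
#' @export
spatial_association_test <- function(atrophy, gene, ensemble,
                                     sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  x <- as.numeric(gene)
  if (length(x) != ncol(ensemble$values))
    stop("gene map and surrogate ensemble differ in region count")
  if (max(abs(sort(x) - sort(ensemble$source))) > 1e-8 && ensemble$resample)
    stop("ensemble was not generated from this gene map")
  fit <- fit_gene_regression(atrophy, x)
  t_null <- regression_t_vector(as.numeric(atrophy), ensemble$values)
  list(p_spatial = empirical_pvalue(fit$t, t_null, sided),
       t_obs = fit$t, t_null = t_null, n_surrogates = nrow(ensemble$values))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Standard step-up procedure: with ordered p-values \eqn{p_{(1)} \le \dots
#' \le p_{(m)}}, reject all hypotheses up to the largest i with
#' \eqn{p_{(i)} \le i q / m}. Adjusted p-values are the usual monotone
#' cumulative minima of \eqn{m p_{(i)} / i}.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param q target FDR (default 0.05).
#' @return data.frame: `p`, `p_adjusted`, `significant`, in input order.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) < 1) stop("empty p-value list")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  adj[o] <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  thresh <- p[o] <= seq_len(m) * q / m
  k <- if (any(thresh)) max(which(thresh)) else 0L
  sig <- logical(m)
  if (k > 0) sig[o[seq_len(k)]] <- TRUE
  data.frame(p = p, p_adjusted = adj, significant = sig)
}

#' Per-gene association suite with spatial nulls and FDR
#'
#' For each gene in the panel: fit the gene-atrophy regression, generate (or
#' reuse) that gene's variogram-matched surrogate ensemble, compute the
#' two-sided spatial p-value, then apply Benjamini-Hochberg across the panel.
#' Per-gene ensembles are deterministic functions of (`seed`, gene index) and
#' are returned for reuse (e.g. by the random-forest nulls).
#'
#' @param atrophy [region_map()] of mean patient w-scores.
#' @param expression an [expression_matrix()].
#' @param n_surrogates surrogates per gene (study default 10000).
#' @param seed master seed; gene g uses seed + g - 1.
#' @param q FDR level across the panel.
#' @param sided sidedness of the spatial test.
#' @param ensembles optional pre-built list of per-gene ensembles (named by
#'   gene) to reuse instead of generating.
#' @return An object of class `association_result`: data.frame with one row
#'   per gene (gene, beta, se, t, df, r2, p_spatial, p_bh, significant,
#'   n_surrogates); the ensembles are attached as attribute `"ensembles"`.
#' @export
run_association_suite <- function(atrophy, expression, n_surrogates = 10000,
                                  seed = 1L, q = 0.05,
                                  sided = c("two", "one"), ensembles = NULL) {
  sided <- match.arg(sided)
  stopifnot(inherits(expression, "expression_matrix"))
  genes <- expression$genes
  if (length(genes) < 1) stop("empty gene panel")
  atlas <- expression$atlas
  y <- as.numeric(atrophy)
  if (length(y) != n_regions(atlas))
    stop("atrophy map does not match the expression atlas")
  if (is.null(ensembles)) {
    ensembles <- lapply(seq_along(genes), function(g)
      generate_surrogates(expression$values[, g], atlas$distances,
                          n = n_surrogates, seed = seed + g - 1L))
    names(ensembles) <- genes
  }
  rows <- lapply(seq_along(genes), function(g) {
    x <- expression$values[, g]
    fit <- fit_gene_regression(y, x)
    st <- spatial_association_test(y, x, ensembles[[genes[g]]], sided)
    data.frame(gene = genes[g], beta = fit$beta, se = fit$se, t = fit$t,
               df = fit$df, r2 = fit$r2, p_spatial = st$p_spatial,
               n_surrogates = st$n_surrogates, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  fdr <- bh_fdr(out$p_spatial, q)
  out$p_bh <- fdr$p_adjusted
  out$significant <- fdr$significant
  out <- out[, c("gene", "beta", "se", "t", "df", "r2", "p_spatial",
                 "p_bh", "significant", "n_surrogates")]
  rownames(out) <- NULL
  attr(out, "ensembles") <- ensembles
  class(out) <- c("association_result", "data.frame")
  out
}
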