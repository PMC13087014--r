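#' Random-forest configuration
#'
#' Defaults follow the standard regression-forest conventions: 500 trees,
#' mtry = floor(p/3) predictors tried per split (4 for a 12-gene panel),
#' terminal nodes of at most 2 observations before splitting stops.
#'
#' @param ntree number of trees (>= 1).
#' @param mtry predictors sampled at each split; `NULL` means floor(p/3)
#'   (at least 1), resolved when the forest is fitted.
#' @param nodesize nodes with at most this many observations are not split.
#' @param seed integer seed; fits are deterministic given (data, config).
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(ntree = 500, mtry = NULL, nodesize = 2, seed = 1L) {
  stopifnot(ntree >= 1, nodesize >= 1, is.null(mtry) || mtry >= 1)
  structure(list(ntree = as.integer(ntree),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 nodesize = as.integer(nodesize), seed = as.integer(seed)),
            class = "forest_config")
}

resolve_mtry <- function(config, p) {
  mtry <- config$mtry
  if (is.null(mtry)) mtry <- max(1L, as.integer(floor(p / 3)))
  if (mtry > p) stop("mtry exceeds the number of predictors")
  mtry
}

#' Fit a regression random forest of atrophy on gene expression
#'
#' Bootstrap-aggregated regression trees predicting the mean w-score map
#' from the region x gene expression matrix. Performance is summarized
#' out-of-bag: `oob_mse` is the mean squared error of OOB predictions,
#' `pct_var` = 100 (1 - OOB MSE / Var(y)) with the population variance
#' (denominator n), and `r2_oob` is the squared Pearson correlation between
#' OOB predictions and the outcome. Importance is the raw mean increase in
#' OOB MSE when a predictor's OOB values are permuted (also reported as a
#' percentage of the OOB MSE).
#'
#' @param expression an [expression_matrix()] or plain regions x predictors
#'   numeric matrix.
#' @param atrophy numeric vector / [region_map()], one value per region.
#' @param config a [forest_config()].
#' @return An object of class `forest_result`: list with `oob_mse`,
#'   `pct_var`, `r2_oob`, `var_y`, `importance` (data.frame gene / inc_mse /
#'   inc_mse_pct), `oob_pred`, `config`.
#' @export
fit_forest <- function(expression, atrophy, config = forest_config()) {
  stopifnot(inherits(config, "forest_config"))
  X <- if (inherits(expression, "expression_matrix")) expression$values
       else as.matrix(expression)
  y <- as.numeric(atrophy)
  if (nrow(X) != length(y)) stop("expression and atrophy regions differ")
  if (nrow(X) < 10) stop("need at least 10 regions")
  if (nrow(X) <= config$nodesize)
    stop("fewer regions than the nodesize constraint allows")
  mtry <- resolve_mtry(config, ncol(X))
  fit <- withr_seed(config$seed,
                    .rf_fit_cpp(X, y, config$ntree, mtry, config$nodesize,
                                TRUE))
  var_y <- mean((y - mean(y))^2)          # population variance (denominator n)
  pct_var <- 100 * (1 - fit$oob_mse / var_y)
  ok <- is.finite(fit$oob_pred)
  r2_oob <- if (stats::sd(fit$oob_pred[ok]) == 0) 0 else
    stats::cor(fit$oob_pred[ok], y[ok])^2
  genes <- colnames(X)
  if (is.null(genes)) genes <- sprintf("x%d", seq_len(ncol(X)))
  structure(list(
    oob_mse = fit$oob_mse, pct_var = pct_var, r2_oob = r2_oob, var_y = var_y,
    importance = data.frame(gene = genes, inc_mse = as.numeric(fit$importance),
                            inc_mse_pct = 100 * as.numeric(fit$importance) /
                              fit$oob_mse,
                            stringsAsFactors = FALSE),
    oob_pred = as.numeric(fit$oob_pred),
    mtry = mtry, config = config), class = "forest_result")
}

#' @export
print.forest_result <- function(x, ...) {
  cat(sprintf(
    "<forest_result> ntree %d, mtry %d | OOB MSE %.4g, %%Var(y) %.2f\n",
    x$config$ntree, x$mtry, x$oob_mse, x$pct_var))
  if (!is.null(x$importance$p_spatial))
    cat(sprintf("  global p_spatial %.4g\n", x$p_spatial_global))
  invisible(x)
}

#' Surrogate-null distribution for the random forest
#'
#' For each null iteration, every gene's expression map is replaced by an
#' independently drawn surrogate from that gene's cached ensemble (the
#' atrophy outcome stays fixed), and the forest is refitted with a fresh
#' derived seed (`seed + iteration`). Records the global fit (%Var(y),
#' OOB MSE, r2_oob) and all per-gene importances per iteration.
#' `surrogate_outcome = TRUE` instead keeps the predictors and replaces the
#' outcome with surrogates of the atrophy map (sensitivity mode; `ensembles`
#' must then contain an ensemble named `".outcome"`).
#'
#' @param expression an [expression_matrix()].
#' @param atrophy numeric vector / [region_map()].
#' @param ensembles named list of `surrogate_ensemble` objects, one per gene
#'   (e.g. from [run_association_suite()]); each must hold at least `n_null`
#'   surrogates.
#' @param n_null number of null fits (study default 1000).
#' @param seed master seed; iteration i refits with seed + i.
#' @param config a [forest_config()] (its own seed is ignored here).
#' @param surrogate_outcome see above.
#' @return list of class `forest_null`: `pct_var`, `oob_mse`, `r2_oob`
#'   (vectors of length n_null), `importance` (n_null x genes matrix),
#'   `seed`.
#' @export
forest_null <- function(expression, atrophy, ensembles, n_null = 1000,
                        seed = 1L, config = forest_config(),
                        surrogate_outcome = FALSE) {
  stopifnot(inherits(expression, "expression_matrix"))
  genes <- expression$genes
  y <- as.numeric(atrophy)
  if (surrogate_outcome) {
    if (is.null(ensembles[[".outcome"]]))
      stop("surrogate_outcome mode needs an ensemble named '.outcome'")
    if (nrow(ensembles[[".outcome"]]$values) < n_null)
      stop("surrogate shortfall for the outcome map")
  } else {
    for (g in genes) {
      if (is.null(ensembles[[g]]))
        stop("no surrogate ensemble cached for gene ", g)
      if (nrow(ensembles[[g]]$values) < n_null)
        stop("surrogate shortfall for gene ", g, ": ",
             nrow(ensembles[[g]]$values), " < ", n_null)
    }
  }
  draw <- withr_seed(seed, {
    if (surrogate_outcome)
      matrix(sample.int(nrow(ensembles[[".outcome"]]$values), n_null,
                        replace = FALSE), ncol = 1)
    else
      vapply(genes, function(g)
        sample.int(nrow(ensembles[[g]]$values), n_null, replace = FALSE),
        integer(n_null))
  })
  pct_var <- oob_mse <- r2 <- numeric(n_null)
  imp <- matrix(NA_real_, n_null, length(genes),
                dimnames = list(NULL, genes))
  cfg <- config
  for (i in seq_len(n_null)) {
    cfg$seed <- as.integer(seed + i)
    if (surrogate_outcome) {
      Xi <- expression$values
      yi <- ensembles[[".outcome"]]$values[draw[i, 1], ]
    } else {
      Xi <- vapply(seq_along(genes), function(g)
        ensembles[[genes[g]]]$values[draw[i, g], ], numeric(length(y)))
      colnames(Xi) <- genes
      yi <- y
    }
    f <- fit_forest(Xi, yi, cfg)
    pct_var[i] <- f$pct_var
    oob_mse[i] <- f$oob_mse
    r2[i] <- f$r2_oob
    imp[i, ] <- f$importance$inc_mse
  }
  structure(list(pct_var = pct_var, oob_mse = oob_mse, r2_oob = r2,
                 importance = imp, seed = as.integer(seed),
                 n_null = n_null),
            class = "forest_null")
}

#' Attach surrogate-null p-values to a forest result
#'
#' One-sided add-one empirical p-values: the global p compares the empirical
#' %Var(y) against the null %Var(y) distribution; each gene's importance p
#' compares its raw increase-in-MSE against that gene's null importances.
#'
#' @param empirical a `forest_result` from [fit_forest()].
#' @param nulls a `forest_null` from [forest_null()].
#' @return the `forest_result` with `p_spatial_global`, a `p_spatial` column
#'   in `importance`, and `null_summary` added.
#' @export
forest_significance <- function(empirical, nulls) {
  stopifnot(inherits(empirical, "forest_result"),
            inherits(nulls, "forest_null"))
  genes <- empirical$importance$gene
  if (!identical(genes, colnames(nulls$importance)))
    stop("gene sets of empirical fit and null distributions differ")
  empirical$p_spatial_global <-
    empirical_pvalue(empirical$pct_var, nulls$pct_var, "one")
  empirical$importance$p_spatial <- vapply(seq_along(genes), function(g)
    empirical_pvalue(empirical$importance$inc_mse[g], nulls$importance[, g],
                     "one"), numeric(1))
  empirical$null_summary <- list(n_null = nulls$n_null, seed = nulls$seed)
  empirical
}
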