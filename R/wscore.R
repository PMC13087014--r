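#' Fit per-region normative models on controls
#'
#' Ordinary least squares of each region's volume on intercept + TIV + age +
#' sex in the control group, with the residual SD computed with denominator
#' n - 4 (one parameter per regressor plus intercept). These are the
#' "expected value" and "SD of residuals" entering the w-score.
#'
#' @param controls subject table rows with `group == "control"` (rows of
#'   other groups are dropped with a message). Columns: subject_id, group,
#'   age, sex (\"F\"/\"M\" or 0/1 with F = 1), tiv, then one volume column
#'   per region.
#' @param atlas a [region_atlas()] naming the volume columns.
#' @return An object of class `normative_model`: list with `coefficients`
#'   (regions x 4 matrix: intercept, tiv, age, sexF), `residual_sd` (per
#'   region), `n_controls`, and the atlas.
#' @export
fit_normative <- function(controls, atlas) {
  controls <- validate_subjects(controls, atlas)
  if (!all(controls$group == "control")) {
    message("dropping non-control rows for normative fitting")
    controls <- controls[controls$group == "control", , drop = FALSE]
  }
  n <- nrow(controls)
  if (n < 5) stop("need at least 5 controls")
  X <- cbind(intercept = 1, tiv = controls$tiv, age = controls$age,
             sexF = sex_indicator(controls$sex))
  for (j in 2:4) {
    if (stats::sd(X[, j]) == 0)
      stop("singular design: covariate '", colnames(X)[j], "' is constant")
  }
  qrX <- qr(X)
  if (qrX$rank < 4) {
    # name a covariate involved in the collinearity
    bad <- colnames(X)[setdiff(1:4, qrX$pivot[seq_len(qrX$rank)])]
    stop("singular design: covariate '", paste(bad, collapse = "', '"),
         "' is collinear with the others")
  }
  Y <- volumes_matrix(controls, atlas)
  beta <- qr.coef(qrX, Y)
  resid <- Y - X %*% beta
  rsd <- sqrt(colSums(resid^2) / (n - 4))
  if (any(rsd <= 0))
    rsd[rsd <= 0] <- .Machine$double.eps  # degenerate noise-free fits
  structure(list(coefficients = t(beta), residual_sd = rsd,
                 n_controls = n, atlas = atlas),
            class = "normative_model")
}

sex_indicator <- function(sex) {
  if (is.numeric(sex)) return(as.numeric(sex))
  as.numeric(sex %in% c("F", "f", "female"))
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model> %d regions, %d controls\n",
              nrow(x$coefficients), x$n_controls))
  invisible(x)
}

#' Compute regional w-scores for patients
#'
#' For each patient and region,
#' \deqn{w = (\mathrm{raw} - \mathrm{expected}(TIV, age, sex)) / SD_{resid},}
#' with expectation and residual SD taken from the control-fitted normative
#' model. A w-score of -1 means the volume lies one control residual SD
#' below the value expected for that patient's covariates.
#'
#' @param patients subject table rows to score (any group).
#' @param model a `normative_model` from [fit_normative()].
#' @return An object of class `wscore_panel`: list with `w` (patients x
#'   regions matrix), `subject_id`, `model`.
#' @export
compute_wscores <- function(patients, model) {
  stopifnot(inherits(model, "normative_model"))
  atlas <- model$atlas
  patients <- validate_subjects(patients, atlas)
  X <- cbind(1, patients$tiv, patients$age, sex_indicator(patients$sex))
  expected <- X %*% t(model$coefficients)
  Y <- volumes_matrix(patients, atlas)
  w <- sweep(Y - expected, 2, model$residual_sd, "/")
  rownames(w) <- patients$subject_id
  structure(list(w = w, subject_id = patients$subject_id, model = model),
            class = "wscore_panel")
}

#' @export
print.wscore_panel <- function(x, ...) {
  cat(sprintf("<wscore_panel> %d patients x %d regions; mean w = %.3f\n",
              nrow(x$w), ncol(x$w), mean(x$w)))
  invisible(x)
}

#' Average w-scores across patients
#'
#' @param panel a `wscore_panel`.
#' @return A [region_map()] of per-region mean w-scores, the group-level
#'   atrophy map.
#' @export
average_wscores <- function(panel) {
  stopifnot(inherits(panel, "wscore_panel"))
  if (nrow(panel$w) < 1) stop("empty w-score panel")
  region_map(panel$model$atlas, colMeans(panel$w))
}

#' Per-region atrophy tests
#'
#' One-sample two-tailed t-test of patient w-scores against 0 per region
#' (the expected control deviation is 0 by construction of the w-score).
#' For a two-sample test on raw volumes see
#' [region_atrophy_tests_volumes()].
#'
#' @param panel a `wscore_panel` with >= 3 patients.
#' @return data.frame: region_id, mean_w, t, df, p. Regions with zero
#'   variance are flagged with `NA` statistics and a warning.
#' @export
region_atrophy_tests <- function(panel) {
  stopifnot(inherits(panel, "wscore_panel"))
  w <- panel$w
  n <- nrow(w)
  if (n < 3) stop("need at least 3 patients")
  atlas <- panel$model$atlas
  m <- colMeans(w)
  s <- apply(w, 2, stats::sd)
  zero <- s == 0
  t <- ifelse(zero, NA_real_, m / (s / sqrt(n)))
  df <- rep(n - 1, ncol(w))
  p <- 2 * stats::pt(-abs(t), df)
  if (any(zero))
    warning("zero-variance region(s): ",
            paste(atlas$region_id[zero], collapse = ", "))
  data.frame(region_id = atlas$region_id, mean_w = m, t = t, df = df, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sample regional volume tests
#'
#' Welch two-sample t-test of raw regional volumes, patients vs controls,
#' the alternative to the default w-score-based one-sample test.
#'
#' @param patients,controls subject tables.
#' @param atlas a [region_atlas()].
#' @return data.frame: region_id, mean_diff, t, df, p.
#' @export
region_atrophy_tests_volumes <- function(patients, controls, atlas) {
  patients <- validate_subjects(patients, atlas)
  controls <- validate_subjects(controls, atlas)
  Yp <- volumes_matrix(patients, atlas)
  Yc <- volumes_matrix(controls, atlas)
  res <- lapply(seq_len(ncol(Yp)), function(j) {
    tt <- stats::t.test(Yp[, j], Yc[, j])
    data.frame(region_id = atlas$region_id[j],
               mean_diff = unname(diff(rev(tt$estimate))),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
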