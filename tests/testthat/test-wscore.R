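# exact synthetic controls: volumes are a known linear function of covariates
exact_controls <- function(atlas, n, coefs, noise_sd = 0, seed = 1) {
  set.seed(seed)
  age <- rnorm(n, 69, 8.6)
  tiv <- rnorm(n, 1550, 150)
  sexF <- rbinom(n, 1, 0.5)
  vols <- outer(rep(1, n), coefs$intercept) + outer(tiv, coefs$b_tiv) +
    outer(age, coefs$b_age) + outer(sexF, coefs$b_sex) +
    matrix(rnorm(n * n_regions(atlas), 0, noise_sd), n)
  df <- data.frame(subject_id = sprintf("c%03d", 1:n), group = "control",
                   age = age, sex = ifelse(sexF == 1, "F", "M"), tiv = tiv)
  df <- cbind(df, as.data.frame(vols))
  names(df)[-(1:5)] <- atlas$region_id
  df
}

test_that("normative fit recovers known coefficients exactly at zero noise", {
  atl <- tiny_atlas(8)
  cm <- default_covariate_model(atl, seed = 4)
  ctrl <- exact_controls(atl, 50, cm)
  m <- fit_normative(ctrl, atl)
  expect_equal(unname(m$coefficients[, "intercept"]), unname(cm$intercept),
               tolerance = 1e-8)
  expect_equal(unname(m$coefficients[, "tiv"]), unname(cm$b_tiv),
               tolerance = 1e-8)
  expect_equal(unname(m$coefficients[, "age"]), unname(cm$b_age),
               tolerance = 1e-8)
  expect_equal(unname(m$coefficients[, "sexF"]), unname(cm$b_sex),
               tolerance = 1e-8)
  expect_equal(m$n_controls, 50)
})

test_that("residual SD is estimated consistently (denominator n - 4)", {
  atl <- tiny_atlas(6)
  cm <- default_covariate_model(atl, seed = 4)
  hits <- 0L
  for (r in 1:200) {
    ctrl <- exact_controls(atl, 200, cm, noise_sd = 0.5, seed = 300 + r)
    m <- fit_normative(ctrl, atl)
    hits <- hits + (m$residual_sd[1] > 0.4 && m$residual_sd[1] < 0.6)
  }
  expect_gte(hits, 190)
  # explicit denominator check against lm's sigma (which also uses n - p)
  ctrl <- exact_controls(atl, 40, cm, noise_sd = 0.5, seed = 2)
  m <- fit_normative(ctrl, atl)
  l <- stats::lm(ctrl[[atl$region_id[3]]] ~ tiv + age + I(sex == "F"),
                 data = ctrl)
  expect_equal(unname(m$residual_sd[3]), summary(l)$sigma, tolerance = 1e-10)
})

test_that("controls scored under their own model have mean 0 and near-unit SD", {
  atl <- tiny_atlas(10)
  cm <- default_covariate_model(atl, seed = 4)
  ctrl <- exact_controls(atl, 150, cm, noise_sd = 0.5, seed = 5)
  m <- fit_normative(ctrl, atl)
  w <- compute_wscores(ctrl, m)$w
  expect_true(all(abs(colMeans(w)) < 1e-10))
  sds <- apply(w, 2, sd)
  expect_true(all(sds > 0.95 & sds < 1.05))
})

test_that("w-scores have the unit-deviation interpretation", {
  atl <- tiny_atlas(6)
  cm <- default_covariate_model(atl, seed = 4)
  ctrl <- exact_controls(atl, 80, cm, noise_sd = 0.5, seed = 6)
  m <- fit_normative(ctrl, atl)
  pat <- ctrl[1:2, ]
  pat$group <- "patient"
  X <- cbind(1, pat$tiv, pat$age, as.numeric(pat$sex == "F"))
  expected <- X %*% t(m$coefficients)
  pat[, atl$region_id] <- expected                      # exactly as expected
  pat[2, atl$region_id] <- expected[2, ] - m$residual_sd  # 1 SD below
  w <- compute_wscores(pat, m)$w
  expect_equal(unname(w[1, ]), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(w[2, ]), rep(-1, 6), tolerance = 1e-12)
})

test_that("singular designs are rejected with the offending covariate named", {
  atl <- tiny_atlas(6)
  cm <- default_covariate_model(atl, seed = 4)
  ctrl <- exact_controls(atl, 30, cm, noise_sd = 0.2, seed = 7)
  ctrl$age <- 70
  expect_error(fit_normative(ctrl, atl), "age")
  expect_error(fit_normative(exact_controls(atl, 4, cm), atl),
               "at least 5 controls")
})

test_that("w-scores are invariant to a joint affine volume rescaling", {
  atl <- tiny_atlas(8)
  expr <- simulate_expression(atl, c("A", "B"), seed = 8)
  coh <- simulate_cohort(atl, expr, zero_truth(c("A", "B"), seed = 9), 60, 40)
  g <- cohort_groups(coh)
  w1 <- compute_wscores(g$patients, fit_normative(g$controls, atl))$w
  scale_vols <- function(s) { s[, atl$region_id] <- 3.7 * s[, atl$region_id]; s }
  w2 <- compute_wscores(scale_vols(g$patients),
                        fit_normative(scale_vols(g$controls), atl))$w
  expect_equal(w1, w2, tolerance = 1e-9)
})

test_that("injected gene-linked atrophy is recovered in the mean w-score map", {
  atl <- default_atlas()
  genes <- default_gene_panel()
  expr <- simulate_expression(atl, genes, seed = 10)
  eff <- stats::setNames(rep(0, 12), genes)
  eff["GBA"] <- -0.5
  truth <- ground_truth(eff, seed = 11)
  atr <- simulated_atrophy(atl, expr, truth, 1000, 300)
  target <- as.numeric(expr$values %*% eff)
  dev <- abs(as.numeric(atr) - target)
  # +-0.15 per region; 58 simultaneous estimates, so 95% inside the band
  expect_gte(mean(dev <= 0.15), 0.95)
  expect_lt(sqrt(mean(dev^2)), 0.15)
  # downstream regression recovers the slope within 2 SE
  fit <- fit_gene_regression(atr, gene_map(expr, "GBA"))
  expect_lt(abs(fit$beta - (-0.5)), 2 * fit$se)
  expect_lt(fit$beta, 0)
})

test_that("average_wscores reduces the panel by the column mean", {
  atl <- tiny_atlas(6)
  w <- matrix(rnorm(60), 10, 6)
  panel <- manual_panel(w, atl)
  avg <- average_wscores(panel)
  for (j in 1:6) expect_equal(unname(avg[j]), mean(w[, j]))
  expect_equal(as.numeric(average_wscores(manual_panel(w[1, , drop = FALSE],
                                                       atl))),
               unname(w[1, ]))
  expect_equal(as.numeric(average_wscores(manual_panel(rbind(w[1, ], -w[1, ]),
                                                       atl))),
               rep(0, 6))
})

test_that("regional atrophy t-tests behave at the edges and under signal", {
  atl <- tiny_atlas(6)
  # hand panel: w-scores (-1, 0, 1) in every region -> t = 0, p = 1
  panel <- manual_panel(matrix(rep(c(-1, 0, 1), 6), 3), atl)
  res <- region_atrophy_tests(panel)
  expect_equal(res$t, rep(0, 6))
  expect_equal(res$p, rep(1, 6))
  expect_equal(res$df, rep(2, 6))
  # zero-variance region flagged
  wz <- matrix(rnorm(18), 3, 6); wz[, 2] <- 0
  expect_warning(rz <- region_atrophy_tests(manual_panel(wz, atl)),
                 atl$region_id[2])
  expect_true(is.na(rz$t[2]) && is.na(rz$p[2]))
  expect_error(region_atrophy_tests(manual_panel(wz[1:2, ], atl)),
               "at least 3")
  # power: N(-1, 1), n = 164 -> p < 0.001 in >= 99% of 200 replicates
  set.seed(13)
  sig <- 0L
  for (r in 1:200) {
    pn <- manual_panel(matrix(rnorm(164, -1, 1), ncol = 1),
                       make_atlas(1, 0, 0, 0))
    rr <- region_atrophy_tests(pn)
    sig <- sig + (rr$p < 0.001 && rr$t < 0)
  }
  expect_gte(sig, 198)
})

test_that("two-sample volume tests agree with t.test", {
  atl <- tiny_atlas(6)
  expr <- simulate_expression(atl, "G", seed = 14)
  coh <- simulate_cohort(atl, expr, zero_truth("G", seed = 15), 40, 40)
  g <- cohort_groups(coh)
  res <- region_atrophy_tests_volumes(g$patients, g$controls, atl)
  ref <- stats::t.test(g$patients[[atl$region_id[1]]],
                       g$controls[[atl$region_id[1]]])
  expect_equal(res$t[1], unname(ref$statistic))
  expect_equal(res$p[1], ref$p.value)
})
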