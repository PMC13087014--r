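probe_df <- function(ids, genes) {
  data.frame(probe_id = ids, gene = genes, stringsAsFactors = FALSE)
}

test_that("probe filtering applies the pooled >= 50% below-background rule", {
  atl <- tiny_atlas(6)
  pm <- probe_df(c("p_hi", "p_half", "p_low"), c("G1", "G1", "G2"))
  # 4 samples: p_hi always above, p_half below in exactly 2/4, p_low always below
  inten <- rbind(p_hi = c(5, 6, 7, 8),
                 p_half = c(3, 3, 7, 8),
                 p_low = c(1, 1, 1, 1))
  bg <- matrix(4, 3, 4, dimnames = list(rownames(inten), NULL))
  d <- manual_donor("d1", atl$centroids[1:4, ], inten, bg, pm)
  filt <- filter_probes_by_intensity(list(d))
  expect_equal(filt$below_fraction, c(0, 0.5, 1))
  expect_equal(filt$retained, c(TRUE, FALSE, FALSE))  # 50% exactly -> discarded
})

test_that("below-background fractions pool samples across donors and match a brute-force count", {
  atl <- tiny_atlas(8)
  set.seed(51)
  pm <- probe_df(sprintf("p%d", 1:5), c("A", "A", "B", "B", "C"))
  donors <- lapply(1:3, function(i) {
    ns <- 3 + i
    manual_donor(paste0("d", i), atl$centroids[seq_len(ns), ],
                 matrix(rnorm(5 * ns, 4, 2), 5), matrix(4, 5, ns), pm)
  })
  filt <- filter_probes_by_intensity(donors)
  # independent brute force
  for (k in 1:5) {
    below <- total <- 0
    for (d in donors) for (s in seq_len(ncol(d$intensities))) {
      below <- below + (d$intensities[k, s] < d$background[k, s])
      total <- total + 1
    }
    expect_equal(filt$below_fraction[k], unname(below / total))
    expect_equal(filt$retained[k], unname(below / total < 0.5))
  }
})

test_that("probe selection scores differential stability with Spearman and picks the winner", {
  atl <- tiny_atlas(8)
  pm <- probe_df(c("pA", "pB"), c("G", "G"))
  pattern <- seq(1, 8) + 4          # consistent regional profile
  wins <- 0L
  set.seed(61)
  for (r in 1:200) {
    donors <- lapply(1:2, function(i)
      manual_donor(paste0("d", i), atl$centroids,
                   rbind(pA = pattern, pB = rnorm(8, 8, 2)),
                   matrix(0, 2, 8), pm, atl$region_id))
    sel <- select_probe_per_gene(donors, c("pA", "pB"), atl)
    wins <- wins + (sel$probe_id == "pA")
  }
  expect_gte(wins, 190)            # >= 95% of 200 draws
})

test_that("probe selection score equals the hand-computed Spearman on 3-region profiles", {
  atl <- make_atlas(3, 0, 0, 0, seed = 5)
  pm <- probe_df(c("pX", "pY"), c("G", "G"))
  # pX: ranks (1,3,2) vs (1,2,3) -> Spearman 0.5
  # pY: perfectly anti-consistent -> Spearman -1, so pX wins with score 0.5
  donors <- list(
    manual_donor("d1", atl$centroids,
                 rbind(pX = c(1, 5, 3), pY = c(1, 2, 3)), matrix(0, 2, 3), pm),
    manual_donor("d2", atl$centroids,
                 rbind(pX = c(2, 4, 9), pY = c(3, 2, 1)), matrix(0, 2, 3), pm))
  sel <- select_probe_per_gene(donors, c("pX", "pY"), atl)
  expect_equal(sel$probe_id, "pX")
  expect_equal(sel$score, 0.5)
})

test_that("a gene with one retained probe keeps it unscored; zero-probe genes drop with warning", {
  atl <- tiny_atlas(6)
  pm <- probe_df(c("p1", "p2"), c("G1", "G2"))
  donors <- lapply(1:2, function(i)
    manual_donor(paste0("d", i), atl$centroids[1:4, ],
                 matrix(5 + seq_len(8), 2), matrix(0, 2, 4), pm))
  expect_warning(sel <- select_probe_per_gene(donors, "p1", atl),
                 "G2")
  expect_equal(sel$gene, "G1")
  expect_equal(sel$probe_id, "p1")
  expect_true(is.na(sel$score))
})

test_that("sample assignment is nearest-centroid with an inclusive 2 mm tolerance", {
  atl <- make_atlas(4, 0, 0, 0, seed = 3)
  pm <- probe_df("p", "G")
  coords <- rbind(atl$centroids[2, ],                    # exactly at centroid
                  atl$centroids[3, ] + c(2, 0, 0),       # exactly 2.0 mm
                  atl$centroids[1, ] + c(5, 0, 0))       # likely unassigned
  d <- manual_donor("d", coords, matrix(1, 1, 3), matrix(0, 1, 3), pm)
  asg <- assign_samples_to_regions(d, atl)
  expect_equal(asg[1], atl$region_id[2])
  expect_equal(asg[2], atl$region_id[3])
  dist3 <- sqrt(colSums((t(atl$centroids) - coords[3, ])^2))
  expect_equal(is.na(asg[3]), min(dist3) > 2)
  expect_error(assign_samples_to_regions(d, atl, -1), "non-negative")
})

test_that("interpolation fills empty regions from the donor's nearest sample", {
  atl <- tiny_atlas(8)
  vals <- matrix(seq(0.1, 0.6, length.out = 6), nrow = 2)  # 2 genes x 3 samples
  coords <- atl$centroids[c(1, 4, 6), ]
  partial <- matrix(NA_real_, 8, 2,
                    dimnames = list(atl$region_id, c("A", "B")))
  partial[c(1, 4, 6), ] <- t(vals)
  filled <- interpolate_empty_regions(partial, vals, coords, atl)
  expect_false(anyNA(filled))
  expect_equal(filled[c(1, 4, 6), ], partial[c(1, 4, 6), ])  # unchanged
  for (r in setdiff(1:8, c(1, 4, 6))) {
    nearest <- which.min(colSums((t(coords) - atl$centroids[r, ])^2))
    expect_equal(unname(filled[r, ]), unname(vals[, nearest]))
  }
  # no empty regions -> identity
  expect_identical(interpolate_empty_regions(filled, vals, coords, atl),
                   filled)
  # all samples at one location -> every empty region gets that sample
  one <- matrix(c(0.3, 0.9), 2, 1)
  partial2 <- matrix(NA_real_, 8, 2)
  partial2[1, ] <- c(0.3, 0.9)
  filled2 <- interpolate_empty_regions(partial2, one,
                                       atl$centroids[1, , drop = FALSE], atl)
  expect_true(all(filled2[, 1] == 0.3 & filled2[, 2] == 0.9))
  expect_error(
    interpolate_empty_regions(partial2, one[, 0, drop = FALSE],
                              atl$centroids[0, , drop = FALSE], atl, "dX"),
    "dX")
})

test_that("scaled robust sigmoid matches the direct formula and preserves order", {
  x <- c(1, 2, 3, 4, 5)
  got <- normalize_srs(matrix(x, ncol = 1), margin = 2)[, 1]
  # independent evaluation: median 3, linear-interpolation quartiles 2 and 4
  sig <- 1 / (1 + exp(-(x - 3) / ((4 - 2) / 1.35)))
  expected <- (sig - min(sig)) / (max(sig) - min(sig))
  expect_equal(got, expected, tolerance = 1e-12)
  expect_true(all(diff(got) > 0))
  expect_equal(range(got), c(0, 1))

  set.seed(71)
  m <- matrix(rnorm(60), 12, 5)
  nm <- normalize_srs(m, margin = 2)
  expect_true(all(nm >= 0 & nm <= 1))
  for (j in 1:5) expect_equal(order(nm[, j]), order(m[, j]))
  # margin = 1 normalizes rows
  nr <- normalize_srs(m, margin = 1)
  expect_equal(unname(apply(nr, 1, min)), rep(0, 12))
  expect_equal(unname(apply(nr, 1, max)), rep(1, 12))
})

test_that("zero-IQR slices fall back to rank scaling; constant slices error", {
  v <- c(1, 1, 1, 1, 1, 1, 1, 9)          # IQR 0, two distinct values
  expect_message(out <- normalize_srs(matrix(v, ncol = 1)), "rank")
  expect_equal(out[8, 1], 1)
  expect_true(all(out[1:7, 1] == 0))
  expect_error(normalize_srs(matrix(rep(2, 5), ncol = 1)), "distinct")
})

test_that("donor aggregation is the unweighted elementwise mean", {
  atl <- tiny_atlas(6)
  g <- c("A", "B")
  m1 <- matrix(runif(12), 6, 2, dimnames = list(atl$region_id, g))
  expect_equal(aggregate_donors(list(m1), atl)$values, m1)
  m2 <- 1 - m1
  expect_true(all(aggregate_donors(list(m1, m2), atl)$values == 0.5))
  m3 <- matrix(runif(12), 6, 2, dimnames = list(atl$region_id, g))
  agg <- aggregate_donors(list(m1, m2, m3), atl)$values
  for (i in 1:6) for (j in 1:2)
    expect_equal(agg[i, j], mean(c(m1[i, j], m2[i, j], m3[i, j])))
  expect_error(aggregate_donors(list(m1, m1[1:3, ]), atl), "mismatched")
})

test_that("gene correlation matrix is a valid correlation matrix with hand-checked entries", {
  atl <- make_atlas(4, 0, 0, 0, seed = 2)
  x <- c(0.1, 0.4, 0.5, 0.9)
  y <- c(0.2, 0.1, 0.8, 0.6)
  ex <- expression_matrix(atl, cbind(g1 = x, g2 = y, g3 = x))
  r <- gene_correlation_matrix(ex)
  expect_equal(unname(diag(r)), c(1, 1, 1))
  expect_equal(r, t(r))
  expect_equal(r["g1", "g3"], 1)
  # textbook Pearson by hand
  rxy <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r["g1", "g2"], rxy)
  const <- expression_matrix(atl, cbind(g1 = x, g2 = rep(0.5, 4)))
  expect_warning(rc <- gene_correlation_matrix(const), "constant")
  expect_true(is.na(rc["g1", "g2"]))
})

test_that("noise-free single-probe donors pass through as a monotone transform of the signal", {
  # single gene: only the across-sample normalization applies, which is a
  # monotone map, so the regional ranking is preserved exactly. (With a
  # multi-gene panel the per-sample cross-gene normalization legitimately
  # reshuffles values and exact rank preservation is not a property of the
  # processing chain.)
  atl <- tiny_atlas(12)
  donors <- simulate_donors(atl, n_donors = 2, genes = "A",
                            probes_per_gene = 1, noise_sd = 0,
                            background_sd = 0, p_region_sampled = 1,
                            far_fraction = 0, seed = 81)
  ex <- process_donor_expression(donors, atl)
  signal <- attr(donors, "signal")
  expect_equal(stats::cor(ex$values[, "A"], signal[, "A"],
                          method = "spearman"), 1)
  # and per donor the processed profile is in [0, 1] with full range
  expect_equal(range(ex$values), c(0, 1))
})

test_that("the full donor-processing pipeline yields a complete unit-interval matrix", {
  atl <- default_atlas()
  donors <- simulate_donors(atl, n_donors = 3, genes = sprintf("g%d", 1:6),
                            probes_per_gene = 2, weak_fraction = 0.2,
                            far_fraction = 0.1, seed = 91)
  filt <- filter_probes_by_intensity(donors)
  expect_lte(sum(filt$retained), nrow(filt))   # filtering never adds probes
  ex <- process_donor_expression(donors, atl)
  sel <- attr(ex, "probe_selection")
  expect_equal(anyDuplicated(sel$gene), 0)     # one probe per surviving gene
  expect_false(anyNA(ex$values))
  expect_true(all(ex$values >= 0 & ex$values <= 1))
  expect_equal(nrow(ex$values), 58)
})
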