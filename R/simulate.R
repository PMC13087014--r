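#' Simulate a spatially autocorrelated region map
#'
#' Draws one realization of a zero-mean, unit-variance Gaussian random field
#' over the atlas regions with exponential covariance
#' \eqn{Cov(x_i, x_j) = \exp(-d_{ij}/\ell)}, where \eqn{d_{ij}} is the
#' centroid distance and \eqn{\ell} the length scale in mm. A length scale of
#' 0 yields i.i.d. standard normal values.
#'
#' @param atlas a [region_atlas()].
#' @param length_scale spatial autocorrelation length scale, mm (>= 0).
#' @param seed integer seed; the draw is a pure function of its arguments.
#' @return A [region_map()].
#' @export
simulate_sa_map <- function(atlas, length_scale = 40, seed = 1L) {
  L <- sa_chol(atlas, length_scale)
  vals <- withr_seed(seed, as.vector(L %*% stats::rnorm(n_regions(atlas))))
  region_map(atlas, vals)
}

# lower-triangular factor of the exponential-covariance matrix
sa_chol <- function(atlas, length_scale) {
  stopifnot(inherits(atlas, "region_atlas"))
  if (!is.numeric(length_scale) || length(length_scale) != 1L ||
      !is.finite(length_scale) || length_scale < 0)
    stop("'length_scale' must be a single finite non-negative number")
  n <- n_regions(atlas)
  if (length_scale == 0) return(diag(n))
  C <- exp(-atlas$distances / length_scale)
  t(chol(C + diag(1e-10, n)))
}

# n independent SA maps as an n x regions matrix (shared covariance factor)
sa_map_matrix <- function(atlas, length_scale, n, seed) {
  L <- sa_chol(atlas, length_scale)
  z <- withr_seed(seed,
                  matrix(stats::rnorm(n * n_regions(atlas)), nrow = n))
  m <- z %*% t(L)
  colnames(m) <- atlas$region_id
  m
}

#' Ground truth for simulated cohorts
#'
#' Records the generative parameters of a synthetic cohort so that
#' downstream estimates can be checked against what was injected.
#'
#' @param effects named numeric vector: signed atrophy effect per gene, in
#'   w-score units per expression unit (negative = higher expression, more
#'   atrophy, matching the convention of reported gene-atrophy slopes).
#' @param noise_sd control residual SD of regional volumes, ml.
#' @param spatial_length_scale length scale of the spatially autocorrelated
#'   patient noise, mm.
#' @param sa_noise_sd SD of the per-patient spatially autocorrelated noise,
#'   in residual-SD (w-score) units.
#' @param seed integer master seed for the cohort draw.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(effects, noise_sd = 0.5, spatial_length_scale = 40,
                         sa_noise_sd = 0.2, seed = 1L) {
  effects <- unlist(effects)
  if (is.null(names(effects)) || any(names(effects) == ""))
    stop("'effects' must be a named numeric vector (one entry per gene)")
  stopifnot(is.numeric(effects), all(is.finite(effects)),
            noise_sd > 0, spatial_length_scale >= 0, sa_noise_sd >= 0)
  structure(list(effects = effects, noise_sd = noise_sd,
                 spatial_length_scale = spatial_length_scale,
                 sa_noise_sd = sa_noise_sd, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Default covariate model for simulated volumes
#'
#' Per-region generative coefficients for the control population: regional
#' baseline volumes between 6 and 12 ml, volumes scaling proportionally with
#' total intracranial volume, a mild age-related decline and a small sex
#' term. Coefficients are a pure function of the atlas and seed and are the
#' free parameters the normative model is later asked to recover.
#'
#' @param atlas a [region_atlas()].
#' @param seed integer seed.
#' @return list with per-region numeric vectors `intercept`, `b_tiv`
#'   (ml per ml), `b_age` (ml per year), `b_sex` (ml, for female = 1).
#' @export
default_covariate_model <- function(atlas, seed = 100L) {
  n <- n_regions(atlas)
  withr_seed(seed, {
    baseline <- stats::runif(n, 6, 12)
    b_tiv <- baseline / 1550          # proportional scaling with TIV
    b_age <- -0.002 * baseline        # ~ -1.4 ml per decade for a 7 ml region
    b_sex <- stats::rnorm(n, 0, 0.05)
    intercept <- baseline - b_tiv * 1550 - b_age * 69
    lapply(list(intercept = intercept, b_tiv = b_tiv, b_age = b_age,
                b_sex = b_sex), stats::setNames, atlas$region_id)
  })
}

#' Simulate a control/patient cohort with known gene-linked atrophy
#'
#' Control volumes follow the covariate model plus i.i.d. Gaussian noise of
#' SD `truth$noise_sd`. Patient volumes are additionally shifted by
#' \eqn{\sum_g \beta_g \, e_g(r) \, \sigma_r} — the ground-truth effect per
#' gene times that gene's expression in region r times the residual SD — plus
#' one independent spatially autocorrelated noise map per patient (SD
#' `truth$sa_noise_sd` in residual-SD units). Effects are therefore injected
#' on the w-score scale, so recovered gene-atrophy slopes are directly
#' comparable to `truth$effects`. Ages are drawn N(69, 8.6^2) years, TIV
#' N(1550, 150^2) ml, sex female with probability 0.274 (coded F = 1).
#'
#' @param atlas a [region_atlas()].
#' @param expression an [expression_matrix()] on the same atlas; the genes
#'   must match `names(truth$effects)`.
#' @param truth a [ground_truth()].
#' @param n_controls,n_patients group sizes (each >= 2).
#' @param covariate_model optional list as returned by
#'   [default_covariate_model()].
#' @return list with `subjects` (a subject table: data.frame with columns
#'   subject_id, group, age, sex, tiv, then one volume column per region, ml)
#'   and `truth` (the ground truth, with the covariate model attached).
#' @export
simulate_cohort <- function(atlas, expression, truth, n_controls = 164,
                            n_patients = 164, covariate_model = NULL) {
  stopifnot(inherits(atlas, "region_atlas"),
            inherits(expression, "expression_matrix"),
            inherits(truth, "ground_truth"))
  if (!identical(expression$atlas$region_id, atlas$region_id))
    stop("expression regions do not match the atlas")
  if (n_controls < 2 || n_patients < 2) stop("need >= 2 subjects per group")
  genes <- expression$genes
  if (length(truth$effects) != length(genes) ||
      !setequal(names(truth$effects), genes))
    stop("ground-truth effect vector must name exactly the expression genes")
  if (is.null(covariate_model)) covariate_model <- default_covariate_model(atlas)
  cm <- covariate_model
  n <- n_controls + n_patients
  nr <- n_regions(atlas)

  withr_seed(truth$seed, {
    age <- stats::rnorm(n, 69, 8.6)
    tiv <- stats::rnorm(n, 1550, 150)
    sex <- stats::rbinom(n, 1, 0.274)              # F = 1
    group <- rep(c("control", "patient"), c(n_controls, n_patients))
    expected <- outer(rep(1, n), cm$intercept) +
      outer(tiv, cm$b_tiv) + outer(age, cm$b_age) + outer(sex, cm$b_sex)
    vols <- expected + matrix(stats::rnorm(n * nr, 0, truth$noise_sd),
                              nrow = n)
    # gene-linked shift + per-patient spatially autocorrelated noise,
    # both in residual-SD units
    shift_w <- as.vector(expression$values %*% truth$effects[genes])
    pat <- which(group == "patient")
    vols[pat, ] <- vols[pat, ] +
      rep(shift_w * truth$noise_sd, each = n_patients)
    if (truth$sa_noise_sd > 0) {
      L <- sa_chol(atlas, truth$spatial_length_scale)
      z <- matrix(stats::rnorm(n_patients * nr), nrow = n_patients)
      vols[pat, ] <- vols[pat, ] +
        (z %*% t(L)) * truth$sa_noise_sd * truth$noise_sd
    }
    if (any(vols <= 0))
      warning("some simulated volumes are non-positive; ",
              "consider a smaller noise_sd")
    subjects <- data.frame(
      subject_id = sprintf("s%04d", seq_len(n)),
      group = group, age = age,
      sex = ifelse(sex == 1, "F", "M"), tiv = tiv,
      stringsAsFactors = FALSE
    )
    subjects <- cbind(subjects, as.data.frame(vols))
    names(subjects)[-(1:5)] <- atlas$region_id
    truth$covariate_model <- cm
    list(subjects = subjects, truth = truth)
  })
}

#' Simulate a synthetic normative expression matrix
#'
#' One spatially autocorrelated map per gene, min-max rescaled to [0, 1] to
#' mimic the unit-interval output of the donor-processing chain. Convenient
#' when the donor-level route is not being exercised.
#'
#' @param atlas a [region_atlas()].
#' @param genes character vector of gene symbols.
#' @param length_scale spatial autocorrelation length scale, mm.
#' @param seed integer seed.
#' @return An [expression_matrix()].
#' @export
simulate_expression <- function(atlas, genes = default_gene_panel(),
                                length_scale = 40, seed = 1L) {
  if (length(genes) < 1) stop("need at least one gene")
  m <- sa_map_matrix(atlas, length_scale, length(genes), seed)
  vals <- apply(m, 1, function(x) (x - min(x)) / (max(x) - min(x)))
  expression_matrix(atlas, vals, genes)
}

#' Simulate multi-donor microarray sample sets
#'
#' Emulates the structure of post-mortem donor data: each donor contributes
#' tissue samples scattered around region centroids (a configurable fraction
#' of regions receives no sample, and a fraction of samples is displaced
#' beyond the assignment tolerance, so the interpolation path is exercised),
#' with probe intensities equal to a shared regional gene signal plus a
#' per-probe offset and Gaussian noise, and per-sample background
#' intensities. A requested fraction of probes is generated as "weak"
#' (below background in most samples) to exercise intensity filtering.
#'
#' @param atlas a [region_atlas()].
#' @param n_donors number of donors (>= 1).
#' @param genes character vector of gene symbols (non-empty).
#' @param probes_per_gene probes indexing each gene (>= 1).
#' @param background_sd SD of the background intensities around their mean
#'   of 4 (log2-like units).
#' @param seed integer seed.
#' @param noise_sd SD of probe measurement noise.
#' @param weak_fraction fraction of probes generated below background.
#' @param p_region_sampled probability that a donor has a sample in a region.
#' @param far_fraction fraction of samples displaced 5-9 mm from their
#'   centroid (beyond the 2 mm assignment tolerance).
#' @param length_scale length scale of the underlying gene signal maps, mm.
#' @return list of `donor_sample_set` objects; the shared region x gene
#'   signal matrix is attached as attribute `"signal"`.
#' @export
simulate_donors <- function(atlas, n_donors = 6, genes = default_gene_panel(),
                            probes_per_gene = 3, background_sd = 0.5,
                            seed = 1L, noise_sd = 0.25, weak_fraction = 0,
                            p_region_sampled = 0.85, far_fraction = 0.05,
                            length_scale = 40) {
  stopifnot(inherits(atlas, "region_atlas"))
  if (length(genes) < 1) stop("gene list must be non-empty")
  if (n_donors < 1) stop("need at least one donor")
  if (probes_per_gene < 1) stop("need at least one probe per gene")
  if (weak_fraction < 0 || weak_fraction > 1)
    stop("'weak_fraction' must be in [0, 1]")
  ng <- length(genes)
  np <- ng * probes_per_gene
  nr <- n_regions(atlas)
  bg_mean <- 4

  withr_seed(seed, {
    # shared normative signal, log2-intensity-like: mean 7, SD 1
    signal <- t(sa_map_matrix(atlas, length_scale,
                              ng, stats::runif(1, 1, 1e6))) + 7
    colnames(signal) <- genes
    probe_map <- data.frame(
      probe_id = sprintf("%s_p%d", rep(genes, each = probes_per_gene),
                         rep(seq_len(probes_per_gene), ng)),
      gene = rep(genes, each = probes_per_gene),
      stringsAsFactors = FALSE
    )
    probe_offset <- stats::rnorm(np, 0, 0.5)
    weak <- rep(FALSE, np)
    if (weak_fraction > 0)
      weak[sample.int(np, round(weak_fraction * np))] <- TRUE

    donors <- lapply(seq_len(n_donors), function(d) {
      sampled <- if (nr == 1) 1L else
        which(stats::runif(nr) < p_region_sampled)
      if (length(sampled) == 0) sampled <- sample.int(nr, 1)
      src <- atlas$region_id[sampled]
      ns <- length(sampled)
      coords <- atlas$centroids[sampled, , drop = FALSE] +
        matrix(stats::rnorm(3 * ns, 0, 0.8), ncol = 3)
      far <- stats::runif(ns) < far_fraction
      if (any(far)) {
        dir <- matrix(stats::rnorm(3 * sum(far)), ncol = 3)
        dir <- dir / sqrt(rowSums(dir^2))
        coords[far, ] <- atlas$centroids[sampled[far], , drop = FALSE] +
          dir * stats::runif(sum(far), 5, 9)
      }
      base <- signal[sampled, , drop = FALSE]        # ns x genes
      inten <- t(base[, probe_map$gene, drop = FALSE]) + probe_offset +
        matrix(stats::rnorm(np * ns, 0, noise_sd), nrow = np)
      if (any(weak))
        inten[weak, ] <- bg_mean - abs(stats::rnorm(sum(weak) * ns, 1, 0.7))
      background <- matrix(stats::rnorm(np * ns, bg_mean, background_sd),
                           nrow = np)
      rownames(inten) <- rownames(background) <- probe_map$probe_id
      structure(list(donor_id = sprintf("donor%02d", d), coords = coords,
                     intensities = inten, background = background,
                     probe_map = probe_map, source_region = src),
                class = "donor_sample_set")
    })
    attr(donors, "signal") <- signal
    donors
  })
}

#' @export
print.donor_sample_set <- function(x, ...) {
  cat(sprintf("<donor_sample_set> %s: %d samples, %d probes, %d genes\n",
              x$donor_id, nrow(x$coords), nrow(x$intensities),
              length(unique(x$probe_map$gene))))
  invisible(x)
}
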