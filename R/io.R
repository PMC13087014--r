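#' Validate a subject table against an atlas
#'
#' Checks the covariate columns, the presence of one volume column per atlas
#' region, positivity of volumes and completeness, and returns the table with
#' volume columns in canonical atlas order.
#'
#' @param subjects data.frame with columns subject_id, group, age, sex, tiv
#'   and one numeric volume column per region.
#' @param atlas a [region_atlas()].
#' @return the validated, reordered data.frame.
#' @export
validate_subjects <- function(subjects, atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  need <- c("subject_id", "group", "age", "sex", "tiv")
  miss <- setdiff(need, names(subjects))
  if (length(miss))
    stop("subject table is missing column(s): ", paste(miss, collapse = ", "))
  missing_regions <- setdiff(atlas$region_id, names(subjects))
  if (length(missing_regions))
    stop("subject table is missing volume column(s): ",
         paste(missing_regions, collapse = ", "))
  covars <- subjects[, need]
  if (anyNA(covars)) stop("missing covariate values in subject table")
  vols <- as.matrix(subjects[, atlas$region_id, drop = FALSE])
  if (!is.numeric(vols) || anyNA(vols)) stop("missing or non-numeric volumes")
  if (any(vols <= 0)) stop("volumes must be strictly positive")
  cbind(covars, subjects[, atlas$region_id, drop = FALSE])
}

# patients x regions volume matrix in atlas order
volumes_matrix <- function(subjects, atlas) {
  as.matrix(subjects[, atlas$region_id, drop = FALSE])
}

#' Read / write the atlas as TSV
#'
#' Columns: region_id, label, lobe_class, x, y, z (mm). The distance matrix
#' is recomputed on read.
#'
#' @param atlas a [region_atlas()].
#' @param path file path.
#' @return `read_atlas` returns a [region_atlas()]; `write_atlas` the path,
#'   invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "region_atlas"))
  df <- data.frame(region_id = atlas$region_id, label = atlas$label,
                   lobe_class = atlas$lobe_class,
                   x = atlas$centroids[, 1], y = atlas$centroids[, 2],
                   z = atlas$centroids[, 3], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "label", "lobe_class", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("atlas file missing column(s): ", paste(miss, collapse = ", "))
  region_atlas(df$region_id, as.matrix(df[, c("x", "y", "z")]),
               lobe_class = df$lobe_class, label = df$label)
}

#' Read / write subject tables as CSV
#'
#' One row per subject; columns subject_id, group, age, sex, tiv, then one
#' volume column per region. On read the volume columns are restored to the
#' canonical atlas order and validated.
#'
#' @param subjects subject data.frame.
#' @param path file path.
#' @param atlas a [region_atlas()].
#' @return `read_subjects` returns the validated data.frame.
#' @export
write_subjects <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path, atlas) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_subjects(df, atlas)
}

#' Read / write expression matrices as CSV
#'
#' First column `region_id`, then one column per gene symbol. On read, rows
#' are restored to canonical atlas order.
#'
#' @param expression an [expression_matrix()].
#' @param path file path.
#' @param atlas a [region_atlas()].
#' @return `read_expression` returns an [expression_matrix()].
#' @export
write_expression <- function(expression, path) {
  stopifnot(inherits(expression, "expression_matrix"))
  df <- data.frame(region_id = expression$atlas$region_id,
                   expression$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path, atlas) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "region_id")
    stop("expression CSV must start with a 'region_id' column")
  if (!setequal(df$region_id, atlas$region_id))
    stop("expression regions do not match the atlas: missing ",
         paste(setdiff(atlas$region_id, df$region_id), collapse = ", "))
  df <- df[match(atlas$region_id, df$region_id), , drop = FALSE]
  expression_matrix(atlas, as.matrix(df[, -1, drop = FALSE]),
                    genes = names(df)[-1])
}

#' Write / read donor sample sets as a CSV bundle
#'
#' Per donor, a directory `<donor_id>/` with `samples.csv` (sample_id, x, y,
#' z, source_region), `probes.csv` (probe_id, gene) and `intensities.csv` /
#' `background.csv` (probe_id x sample columns).
#'
#' @param donors list of `donor_sample_set` objects.
#' @param dir bundle directory.
#' @return `read_donor_bundle` returns the donor list.
#' @export
write_donor_bundle <- function(donors, dir) {
  donors <- check_donors(donors)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in donors) {
    dd <- file.path(dir, d$donor_id)
    dir.create(dd, showWarnings = FALSE)
    ns <- nrow(d$coords)
    sample_id <- sprintf("s%03d", seq_len(ns))
    utils::write.csv(data.frame(sample_id = sample_id, x = d$coords[, 1],
                                y = d$coords[, 2], z = d$coords[, 3],
                                source_region = d$source_region),
                     file.path(dd, "samples.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(d$probe_map, file.path(dd, "probes.csv"),
                     row.names = FALSE, quote = FALSE)
    for (what in c("intensities", "background")) {
      m <- d[[what]]
      colnames(m) <- sample_id
      utils::write.csv(data.frame(probe_id = rownames(m), m,
                                  check.names = FALSE),
                       file.path(dd, paste0(what, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_donor_bundle
#' @export
read_donor_bundle <- function(dir) {
  dds <- list.dirs(dir, recursive = FALSE)
  if (!length(dds)) stop("no donor directories under ", dir)
  donors <- lapply(dds, function(dd) {
    smp <- utils::read.csv(file.path(dd, "samples.csv"),
                           stringsAsFactors = FALSE)
    pm <- utils::read.csv(file.path(dd, "probes.csv"),
                          stringsAsFactors = FALSE)
    rd <- function(f) {
      m <- utils::read.csv(file.path(dd, f), check.names = FALSE,
                           stringsAsFactors = FALSE)
      mm <- as.matrix(m[, -1, drop = FALSE])
      rownames(mm) <- m$probe_id
      mm[pm$probe_id, , drop = FALSE]
    }
    structure(list(donor_id = basename(dd),
                   coords = as.matrix(smp[, c("x", "y", "z")]),
                   intensities = rd("intensities.csv"),
                   background = rd("background.csv"),
                   probe_map = pm, source_region = smp$source_region),
              class = "donor_sample_set")
  })
  donors
}

#' Analysis configuration
#'
#' Bundles the knobs of the end-to-end run. The default gene panel is the
#' 12-gene alpha-synuclein / beta-amyloid / tau panel; the study defaults are
#' 10000 surrogates per gene for the regressions and 1000 for the forest
#' nulls, with FDR controlled at q = 0.05 across the panel.
#'
#' @param genes gene panel (non-empty character vector).
#' @param n_surrogates_regression surrogates per gene for the per-gene tests.
#' @param n_surrogates_forest null refits of the forest.
#' @param q FDR level.
#' @param seed master seed.
#' @param n_controls,n_patients synthetic cohort sizes.
#' @param effects named ground-truth effect vector for the synthetic cohort
#'   (`NULL` = all-zero effects).
#' @param forest a [forest_config()].
#' @param subgroup optional name of a patient subgroup selector recorded in
#'   the provenance log (subjects with `group == "patient"` whose
#'   `subject_id` is in `subgroup_ids` are kept).
#' @param subgroup_ids optional character vector of patient ids.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(genes = default_gene_panel(),
                            n_surrogates_regression = 10000,
                            n_surrogates_forest = 1000, q = 0.05, seed = 1L,
                            n_controls = 164, n_patients = 164,
                            effects = NULL, forest = forest_config(),
                            subgroup = NULL, subgroup_ids = NULL) {
  if (length(genes) < 1) stop("gene panel must be non-empty")
  if (anyDuplicated(genes)) stop("duplicate genes in panel")
  if (n_surrogates_regression < 1 || n_surrogates_forest < 1)
    stop("surrogate counts must be >= 1")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (!is.null(effects)) {
    unknown <- setdiff(names(effects), genes)
    if (length(unknown))
      stop("unknown gene symbol(s) in effects: ",
           paste(unknown, collapse = ", "))
  }
  structure(list(genes = as.character(genes),
                 n_surrogates_regression = as.integer(n_surrogates_regression),
                 n_surrogates_forest = as.integer(n_surrogates_forest),
                 q = q, seed = as.integer(seed),
                 n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients),
                 effects = effects, forest = forest,
                 subgroup = subgroup, subgroup_ids = subgroup_ids),
            class = "analysis_config")
}

#' Hash of a configuration
#'
#' MD5 of the deparsed configuration; embedded in every report so equal
#' hashes imply equal numeric outputs.
#'
#' @param config an `analysis_config`.
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[order(names(config))]), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis end to end
#'
#' Simulates (or loads) every input, processes expression, fits the
#' normative model on controls, scores patients, tests regional atrophy,
#' runs the per-gene association suite with spatial nulls and FDR, fits the
#' random forest with surrogate-null significance, and writes a report
#' bundle (TSV/CSV/JSON) with full provenance (config hash and seeds).
#'
#' @param config an [analysis_config()].
#' @param out_dir output directory (created); `NULL` skips writing.
#' @param atlas optional [region_atlas()]; default [make_atlas()].
#' @param expression optional [expression_matrix()]; default
#'   [simulate_expression()] under the config seed.
#' @param subjects optional subject table; default a synthetic cohort with
#'   the config's ground-truth effects.
#' @return list with components `atlas`, `expression`, `model`, `panel`,
#'   `atrophy` (region map), `atrophy_tests`, `gene_correlations`,
#'   `association`, `forest`, `config`, `provenance`.
#' @export
run_full_analysis <- function(config = analysis_config(), out_dir = NULL,
                              atlas = NULL, expression = NULL,
                              subjects = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(atlas)) atlas <- make_atlas(seed = config$seed)
  if (is.null(expression))
    expression <- simulate_expression(atlas, config$genes,
                                      seed = config$seed + 1L)
  if (!identical(expression$atlas$region_id, atlas$region_id))
    stop("inconsistent region sets: expression matrix vs atlas")
  if (!setequal(expression$genes, config$genes))
    stop("expression genes do not match the configured panel: ",
         paste(setdiff(config$genes, expression$genes), collapse = ", "))
  if (is.null(subjects)) {
    eff <- stats::setNames(rep(0, length(config$genes)), config$genes)
    if (!is.null(config$effects)) eff[names(config$effects)] <- config$effects
    truth <- ground_truth(eff, seed = config$seed + 2L)
    subjects <- simulate_cohort(atlas, expression, truth,
                                config$n_controls, config$n_patients)$subjects
  }
  subjects <- validate_subjects(subjects, atlas)

  controls <- subjects[subjects$group == "control", , drop = FALSE]
  patients <- subjects[subjects$group == "patient", , drop = FALSE]
  if (!is.null(config$subgroup_ids))
    patients <- patients[patients$subject_id %in% config$subgroup_ids, ,
                         drop = FALSE]
  if (nrow(patients) < 3) stop("fewer than 3 patients after subsetting")

  model <- fit_normative(controls, atlas)
  panel <- compute_wscores(patients, model)
  atrophy <- average_wscores(panel)
  tests <- region_atrophy_tests(panel)
  cors <- gene_correlation_matrix(expression)
  assoc <- run_association_suite(atrophy, expression,
                                 n_surrogates = config$n_surrogates_regression,
                                 seed = config$seed + 10L, q = config$q)
  forest_fit <- fit_forest(expression, atrophy, config$forest)
  nulls <- forest_null(expression, atrophy, attr(assoc, "ensembles"),
                       n_null = config$n_surrogates_forest,
                       seed = config$seed + 20L, config = config$forest)
  forest_fit <- forest_significance(forest_fit, nulls)

  prov <- list(config_hash = config_hash(config), seed = config$seed,
               seeds = list(expression = config$seed + 1L,
                            cohort = config$seed + 2L,
                            association = config$seed + 10L,
                            forest_null = config$seed + 20L),
               subgroup = config$subgroup,
               n_controls = nrow(controls), n_patients = nrow(patients),
               timestamp = format(Sys.time(), tz = "UTC"))

  res <- list(atlas = atlas, expression = expression, model = model,
              panel = panel, atrophy = atrophy, atrophy_tests = tests,
              gene_correlations = cors, association = assoc,
              forest = forest_fit, config = config, provenance = prov)
  if (!is.null(out_dir)) write_report_bundle(res, out_dir)
  res
}

write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_atlas(res$atlas, file.path(out_dir, "atlas.tsv"))
  write_expression(res$expression, file.path(out_dir, "expression.csv"))
  utils::write.csv(data.frame(subject_id = res$panel$subject_id, res$panel$w,
                              check.names = FALSE),
                   file.path(out_dir, "wscores.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.table(
    cbind(res$atrophy_tests[, "region_id", drop = FALSE],
          mean_w = res$atrophy_tests$mean_w,
          res$atrophy_tests[, c("t", "df", "p")]),
    file.path(out_dir, "atrophy_tests.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.csv(as.data.frame(res$gene_correlations),
                   file.path(out_dir, "gene_correlations.csv"),
                   row.names = TRUE, quote = FALSE)
  assoc <- as.data.frame(res$association)
  utils::write.table(assoc, file.path(out_dir, "association.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  fr <- res$forest
  jsonlite::write_json(
    list(config = unclass(fr$config), mtry = fr$mtry, oob_mse = fr$oob_mse,
         pct_var = fr$pct_var, r2_oob = fr$r2_oob,
         p_spatial_global = fr$p_spatial_global, importance = fr$importance,
         null_summary = fr$null_summary),
    file.path(out_dir, "forest.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
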