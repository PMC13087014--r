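#' The default 12-gene panel
#'
#' Genes implicated in alpha-synuclein synthesis/clearance and in
#' beta-amyloid and tau pathology, the default predictor panel throughout
#' the package.
#'
#' @return character vector of 12 gene symbols.
#' @export
default_gene_panel <- function() {
  c("APOE", "APP", "BIN1", "GBA", "LRP1", "MAPT",
    "PARK7", "PINK1", "PSEN1", "PSEN2", "SNCA", "TMEM175")
}

#' Region x gene normative expression matrix
#'
#' @param atlas a [region_atlas()].
#' @param values numeric matrix, regions x genes, unit-interval after the
#'   normalization chain (values outside [0, 1] are rejected).
#' @param genes character vector of gene symbols, one per column.
#' @return An object of class `expression_matrix` with components `atlas`,
#'   `genes`, `values`.
#' @export
expression_matrix <- function(atlas, values, genes = colnames(values)) {
  stopifnot(inherits(atlas, "region_atlas"))
  values <- as.matrix(values)
  if (is.null(genes)) stop("gene symbols required")
  genes <- as.character(genes)
  if (nrow(values) != n_regions(atlas))
    stop("expression matrix must have one row per atlas region")
  if (ncol(values) != length(genes))
    stop("one gene symbol per column required")
  if (anyDuplicated(genes)) stop("gene symbols must be unique")
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (any(values < -1e-9 | values > 1 + 1e-9))
    stop("expression values must lie in [0, 1]")
  values <- pmin(pmax(values, 0), 1)
  dim(values) <- c(n_regions(atlas), length(genes))
  dimnames(values) <- list(atlas$region_id, genes)
  structure(list(atlas = atlas, genes = genes, values = values),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d regions x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Extract one gene's expression profile as a region map
#' @param expression an [expression_matrix()].
#' @param gene gene symbol.
#' @return A [region_map()].
#' @export
gene_map <- function(expression, gene) {
  stopifnot(inherits(expression, "expression_matrix"))
  if (!gene %in% expression$genes) stop("unknown gene: ", gene)
  region_map(expression$atlas, expression$values[, gene])
}

#' Filter probes on intensity relative to background
#'
#' A probe is retained if its intensity exceeds the background in more than
#' half of the samples pooled across donors; probes at or below background in
#' at least 50% of samples are discarded.
#'
#' @param donors list of `donor_sample_set` objects sharing a probe set.
#' @return data.frame with columns `probe_id`, `gene`, `below_fraction`
#'   (fraction of pooled samples with intensity < background) and `retained`.
#' @export
filter_probes_by_intensity <- function(donors) {
  donors <- check_donors(donors)
  pm <- donors[[1]]$probe_map
  below <- total <- numeric(nrow(pm))
  for (d in donors) {
    if (!identical(d$probe_map$probe_id, pm$probe_id))
      stop("donor ", d$donor_id, " is missing probes present in other donors")
    below <- below + rowSums(d$intensities < d$background)
    total <- total + ncol(d$intensities)
  }
  frac <- below / total
  data.frame(probe_id = pm$probe_id, gene = pm$gene,
             below_fraction = frac, retained = frac < 0.5,
             stringsAsFactors = FALSE)
}

check_donors <- function(donors) {
  if (inherits(donors, "donor_sample_set")) donors <- list(donors)
  if (length(donors) < 1) stop("need at least one donor")
  if (!all(vapply(donors, inherits, TRUE, "donor_sample_set")))
    stop("'donors' must be a list of donor_sample_set objects")
  donors
}

#' Select one probe per gene by differential stability
#'
#' Each retained probe is scored by the mean pairwise Spearman correlation of
#' its region-averaged expression profile across donor pairs (regions present
#' in both donors of a pair); the most consistent probe wins. Genes with a
#' single retained probe keep it with an `NA` score; genes with no retained
#' probe are dropped with a warning.
#'
#' @param donors list of `donor_sample_set` objects (>= 2 for scoring).
#' @param retained character vector of retained probe ids (e.g. from
#'   [filter_probes_by_intensity()]), or the data.frame it returns.
#' @param atlas a [region_atlas()] used for sample-to-region assignment.
#' @param tolerance assignment tolerance passed to
#'   [assign_samples_to_regions()], mm.
#' @return data.frame with columns `gene`, `probe_id`, `score`.
#' @export
select_probe_per_gene <- function(donors, retained, atlas, tolerance = 2) {
  donors <- check_donors(donors)
  if (is.data.frame(retained)) retained <- retained$probe_id[retained$retained]
  pm <- donors[[1]]$probe_map
  keep <- pm[pm$probe_id %in% retained, , drop = FALSE]
  dropped <- setdiff(unique(pm$gene), unique(keep$gene))
  if (length(dropped))
    warning("genes dropped (no retained probe): ",
            paste(dropped, collapse = ", "))
  # region-averaged profile per donor per probe (regions x probes), NA where
  # the donor has no assigned sample
  profiles <- lapply(donors, function(d) {
    asg <- assign_samples_to_regions(d, atlas, tolerance)
    region_average_samples(d$intensities[keep$probe_id, , drop = FALSE],
                           asg, atlas)
  })
  out <- lapply(split(seq_len(nrow(keep)), keep$gene), function(idx) {
    probes <- keep$probe_id[idx]
    if (length(probes) == 1L || length(donors) < 2L)
      return(data.frame(gene = keep$gene[idx[1]], probe_id = probes[1],
                        score = NA_real_, stringsAsFactors = FALSE))
    score <- vapply(probes, function(p) {
      prof <- vapply(profiles, function(m) m[, p], numeric(n_regions(atlas)))
      pairs <- utils::combn(length(donors), 2)
      mean(apply(pairs, 2, function(ij) {
        ok <- stats::complete.cases(prof[, ij])
        if (sum(ok) < 3) return(NA_real_)
        stats::cor(prof[ok, ij[1]], prof[ok, ij[2]], method = "spearman")
      }), na.rm = TRUE)
    }, numeric(1))
    best <- if (all(is.na(score))) 1L else which.max(score)
    data.frame(gene = keep$gene[idx[1]], probe_id = probes[best],
               score = unname(score[best]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

# mean of sample columns per assigned region; regions x probes, NA when empty
region_average_samples <- function(intensities, assignment, atlas) {
  nr <- n_regions(atlas)
  m <- matrix(NA_real_, nr, nrow(intensities),
              dimnames = list(atlas$region_id, rownames(intensities)))
  ok <- !is.na(assignment)
  if (any(ok)) {
    grp <- assignment[ok]
    sums <- rowsum(t(intensities[, ok, drop = FALSE]), grp)
    cnt <- as.vector(table(grp)[rownames(sums)])
    m[rownames(sums), ] <- sums / cnt
  }
  m
}

#' Assign donor samples to atlas regions
#'
#' Each sample is assigned to the nearest region centroid if within
#' `tolerance` mm (inclusive), otherwise left unassigned. Exact ties go to
#' the lower region index.
#'
#' @param donor a `donor_sample_set`.
#' @param atlas a [region_atlas()].
#' @param tolerance assignment radius, mm (>= 0); default 2.
#' @return character vector of region ids, `NA` for unassigned samples.
#' @export
assign_samples_to_regions <- function(donor, atlas, tolerance = 2) {
  stopifnot(inherits(donor, "donor_sample_set"),
            inherits(atlas, "region_atlas"))
  if (!is.numeric(tolerance) || tolerance < 0)
    stop("'tolerance' must be non-negative")
  d2 <- outer(rowSums(donor$coords^2), rowSums(atlas$centroids^2), "+") -
    2 * donor$coords %*% t(atlas$centroids)
  d <- sqrt(pmax(d2, 0))
  nearest <- max.col(-d, ties.method = "first")
  dist <- d[cbind(seq_len(nrow(d)), nearest)]
  ifelse(dist <= tolerance, atlas$region_id[nearest], NA_character_)
}

#' Fill empty regions from the nearest tissue sample
#'
#' Regions without an assigned sample in a donor's partial region x gene
#' matrix are filled with the values of that donor's nearest sample
#' (Euclidean centroid-to-sample distance), so no empty cells remain.
#'
#' @param partial numeric matrix, regions x columns, with `NA` rows for
#'   regions lacking samples.
#' @param values numeric matrix, columns x samples: per-sample values on the
#'   same column set as `partial` (e.g. normalized probe or gene values).
#' @param coords numeric matrix, samples x 3: sample coordinates, mm.
#' @param atlas a [region_atlas()].
#' @param donor_id used in error messages.
#' @return `partial` with every empty row filled.
#' @export
interpolate_empty_regions <- function(partial, values, coords, atlas,
                                      donor_id = "donor") {
  stopifnot(inherits(atlas, "region_atlas"))
  if (ncol(values) != nrow(coords))
    stop("'values' must have one column per sample")
  if (nrow(coords) == 0)
    stop("donor ", donor_id, " has no samples to interpolate from")
  empty <- which(!stats::complete.cases(partial))
  if (!length(empty)) return(partial)
  d2 <- outer(rowSums(atlas$centroids[empty, , drop = FALSE]^2),
              rowSums(coords^2), "+") -
    2 * atlas$centroids[empty, , drop = FALSE] %*% t(coords)
  nearest <- max.col(-d2, ties.method = "first")
  partial[empty, ] <- t(values[, nearest, drop = FALSE])
  partial
}

#' Scaled robust sigmoid normalization
#'
#' Maps each slice along `margin` through the robust sigmoid
#' \eqn{1 / (1 + \exp(-(x - \mathrm{median}) / (\mathrm{IQR}/1.35)))} and
#' min-max rescales the result to [0, 1]. The IQR uses linear-interpolation
#' quartiles; division by 1.35 makes it a consistent estimator of the SD
#' under normality. Slices with zero IQR (but at least two distinct values)
#' fall back to rank-based scaling with a message.
#'
#' @param x numeric matrix.
#' @param margin 1 to normalize each row across columns (e.g. each sample
#'   across genes), 2 for each column across rows.
#' @return matrix of the same shape with values in [0, 1].
#' @export
normalize_srs <- function(x, margin = 2) {
  x <- as.matrix(x)
  stopifnot(margin %in% c(1, 2))
  if (margin == 1) return(t(normalize_srs(t(x), margin = 2)))
  out <- apply(x, 2, srs_vector)
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

srs_vector <- function(v) {
  if (length(unique(v)) < 2)
    stop("normalize_srs needs >= 2 distinct values per slice")
  iqr <- stats::IQR(v, type = 7)
  if (iqr == 0) {
    message("zero IQR in normalize_srs slice; using rank-based scaling")
    r <- rank(v, ties.method = "average")
    return((r - min(r)) / (max(r) - min(r)))
  }
  y <- 1 / (1 + exp(-(v - stats::median(v)) / (iqr / 1.35)))
  (y - min(y)) / (max(y) - min(y))
}

#' Average per-donor matrices into one expression matrix
#'
#' Unweighted elementwise mean across donors of per-donor normalized
#' region x gene matrices sharing the same region and gene sets.
#'
#' @param donor_matrices list of numeric matrices, regions x genes.
#' @param atlas a [region_atlas()].
#' @return An [expression_matrix()].
#' @export
aggregate_donors <- function(donor_matrices, atlas) {
  if (length(donor_matrices) < 1) stop("need at least one donor matrix")
  dims <- vapply(donor_matrices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("donor matrices have mismatched shapes")
  avg <- Reduce(`+`, donor_matrices) / length(donor_matrices)
  expression_matrix(atlas, avg, colnames(donor_matrices[[1]]))
}

#' Process donor sample sets into a normative expression matrix
#'
#' The full chain: (1) discard probes below background in >= 50% of samples
#' pooled across donors; (2) pick one probe per gene by differential
#' stability; (3) per donor, normalize the sample x gene values with the
#' scaled robust sigmoid, first each sample across genes, then each gene
#' across samples; (4) assign samples to regions within `tolerance` mm of the
#' nearest centroid and average samples within a region; (5) fill empty
#' regions from the donor's nearest sample; (6) average across donors.
#'
#' @param donors list of `donor_sample_set` objects.
#' @param atlas a [region_atlas()].
#' @param tolerance sample assignment radius, mm.
#' @return An [expression_matrix()]; the probe-selection table is attached
#'   as attribute `"probe_selection"`.
#' @export
process_donor_expression <- function(donors, atlas, tolerance = 2) {
  donors <- check_donors(donors)
  filt <- filter_probes_by_intensity(donors)
  if (!any(filt$retained)) stop("no probe survived intensity filtering")
  sel <- select_probe_per_gene(donors, filt, atlas, tolerance)
  per_donor <- lapply(donors, function(d) {
    g <- d$intensities[sel$probe_id, , drop = FALSE]   # genes x samples
    rownames(g) <- sel$gene
    if (ncol(g) < 2)
      stop("donor ", d$donor_id, " has fewer than 2 samples")
    if (nrow(g) >= 2)
      g <- normalize_srs(g, margin = 2)                # each sample across genes
    g <- normalize_srs(g, margin = 1)                  # each gene across samples
    asg <- assign_samples_to_regions(d, atlas, tolerance)
    if (all(is.na(asg)))
      stop("donor ", d$donor_id, " has no sample within ", tolerance,
           " mm of any region centroid")
    partial <- region_average_samples(g, asg, atlas)
    interpolate_empty_regions(partial, g, d$coords, atlas, d$donor_id)
  })
  out <- aggregate_donors(per_donor, atlas)
  attr(out, "probe_selection") <- sel
  out
}

#' Pairwise Pearson correlations between gene expression profiles
#'
#' @param expression an [expression_matrix()] with >= 3 regions.
#' @return symmetric gene x gene correlation matrix with unit diagonal;
#'   entries involving a constant gene are `NA` with a warning.
#' @export
gene_correlation_matrix <- function(expression) {
  stopifnot(inherits(expression, "expression_matrix"))
  v <- expression$values
  if (nrow(v) < 3) stop("need >= 3 regions for gene correlations")
  const <- apply(v, 2, function(x) max(x) - min(x) == 0)
  if (any(const))
    warning("constant gene column(s): ",
            paste(expression$genes[const], collapse = ", "),
            "; correlations undefined (NA)")
  r <- suppressWarnings(stats::cor(v))
  diag(r) <- 1
  r
}
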