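#' Region atlas objects
#'
#' A `region_atlas` is the spatial frame for every map in the package: a set
#' of uniquely identified grey-matter regions, each with a human-readable
#' label, a lobe class, and a 3-D centroid in millimetres, plus the full
#' pairwise Euclidean distance matrix between centroids.
#'
#' @param region_id character vector of unique region tokens.
#' @param label character vector of region labels (defaults to `region_id`).
#' @param lobe_class character vector of lobe classes, one per region.
#' @param centroids numeric matrix, regions x 3, centroid coordinates in mm.
#' @return An object of class `region_atlas` with components `region_id`,
#'   `label`, `lobe_class`, `centroids` (n x 3 matrix) and `distances`
#'   (n x n symmetric matrix, mm).
#' @seealso [make_atlas()] for the synthetic default geometry.
#' @export
region_atlas <- function(region_id, centroids, lobe_class = "cortical",
                         label = region_id) {
  region_id <- as.character(region_id)
  n <- length(region_id)
  if (n < 1L) stop("atlas must contain at least one region")
  if (anyDuplicated(region_id)) stop("region ids must be unique")
  centroids <- as.matrix(centroids)
  if (!is.numeric(centroids) || ncol(centroids) != 3L || nrow(centroids) != n)
    stop("'centroids' must be a numeric n x 3 matrix matching region_id")
  if (!all(is.finite(centroids))) stop("centroids must be finite")
  lobe_class <- rep_len(as.character(lobe_class), n)
  label <- rep_len(as.character(label), n)
  rownames(centroids) <- region_id
  colnames(centroids) <- c("x", "y", "z")
  d <- as.matrix(stats::dist(centroids))
  dimnames(d) <- list(region_id, region_id)
  structure(
    list(region_id = region_id, label = label, lobe_class = lobe_class,
         centroids = centroids, distances = d),
    class = "region_atlas"
  )
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("<region_atlas> %d regions (%s)\n", n_regions(x),
              paste(sprintf("%s: %d", names(table(x$lobe_class)),
                            as.integer(table(x$lobe_class))), collapse = ", ")))
  invisible(x)
}

#' Number of regions in an atlas
#' @param atlas a `region_atlas`.
#' @return integer count of regions.
#' @export
n_regions <- function(atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  length(atlas$region_id)
}

#' Construct a synthetic brain atlas
#'
#' Places region centroids in four spatially distinct clusters mimicking the
#' gross geometry of a left hemisphere: cortical regions on a hemispheric
#' shell of 70 mm radius, subcortical regions within 25 mm of the centre,
#' cerebellar regions in a posterior-inferior cluster, and brainstem regions
#' on the inferior midline. The default parcellation used throughout the
#' package has 41 cortical + 6 subcortical + 9 cerebellar + 2 brainstem = 58
#' regions.
#'
#' @param n_cortical,n_subcortical,n_cerebellar,n_brainstem region counts per
#'   lobe class (non-negative; total must be >= 1).
#' @param seed integer seed; the atlas is a pure function of its arguments.
#' @return A [region_atlas()].
#' @examples
#' atl <- make_atlas()
#' n_regions(atl) # 58
#' @export
make_atlas <- function(n_cortical = 41, n_subcortical = 6, n_cerebellar = 9,
                       n_brainstem = 2, seed = 1L) {
  counts <- c(n_cortical, n_subcortical, n_cerebellar, n_brainstem)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("region counts must be non-negative integers")
  if (sum(counts) < 1L) stop("atlas must contain at least one region")

  withr_seed(seed, {
    pieces <- list()
    if (n_cortical > 0) {
      # quasi-even shell coverage via a Fibonacci lattice on the hemisphere,
      # jittered so repeated builds with different seeds differ
      i <- seq_len(n_cortical) - 0.5
      phi <- acos(1 - i / n_cortical)          # polar angle, upper half
      theta <- pi * (1 + sqrt(5)) * i
      r <- 70
      xyz <- cbind(r * sin(phi) * cos(theta),
                   r * sin(phi) * sin(theta),
                   r * cos(phi))
      xyz <- xyz + matrix(stats::rnorm(3 * n_cortical, 0, 2), ncol = 3)
      xyz[, 1] <- -abs(xyz[, 1])               # left hemisphere: x <= 0
      # split the shell into the four cortical lobes by longitude/height
      lobe <- ifelse(xyz[, 2] > 15, "frontal",
              ifelse(xyz[, 2] < -45, "occipital",
              ifelse(xyz[, 3] < 20, "temporal", "parietal")))
      pieces$cortical <- list(xyz = xyz, lobe = lobe, prefix = "ctx")
    }
    if (n_subcortical > 0) {
      xyz <- matrix(stats::rnorm(3 * n_subcortical, 0, 10), ncol = 3)
      xyz <- xyz / pmax(1, sqrt(rowSums(xyz^2)) / 25)   # keep within 25 mm
      xyz[, 1] <- -abs(xyz[, 1]) - 5
      pieces$subcortical <- list(xyz = xyz, lobe = "subcortical",
                                 prefix = "sub")
    }
    if (n_cerebellar > 0) {
      ctr <- c(-15, -55, -40)                  # posterior-inferior
      xyz <- sweep(matrix(stats::rnorm(3 * n_cerebellar, 0, 9), ncol = 3),
                   2, ctr, "+")
      pieces$cerebellar <- list(xyz = xyz, lobe = "cerebellar",
                                prefix = "cbl")
    }
    if (n_brainstem > 0) {
      xyz <- cbind(stats::rnorm(n_brainstem, 0, 1.5),
                   stats::rnorm(n_brainstem, -30, 3),
                   seq(-35, -55, length.out = n_brainstem) +
                     stats::rnorm(n_brainstem, 0, 2))
      pieces$brainstem <- list(xyz = xyz, lobe = "brainstem",
                               prefix = "bst")
    }
    xyz <- do.call(rbind, lapply(pieces, `[[`, "xyz"))
    lobe <- unlist(lapply(pieces, function(p)
      rep_len(p$lobe, nrow(p$xyz))), use.names = FALSE)
    ids <- unlist(lapply(pieces, function(p)
      sprintf("%s_%02d", p$prefix, seq_len(nrow(p$xyz)))), use.names = FALSE)
    region_atlas(ids, xyz, lobe_class = lobe)
  })
}

#' Region maps: one value per atlas region
#'
#' Light wrapper pairing a numeric vector with the atlas it is defined on;
#' the carrier for averaged w-scores and per-gene expression profiles.
#'
#' @param atlas a `region_atlas`.
#' @param values numeric vector, one finite value per region. A named vector
#'   is reordered to the atlas region order.
#' @return An object of class `region_map` (numeric vector with `atlas`
#'   attribute, named by region id).
#' @export
region_map <- function(atlas, values) {
  stopifnot(inherits(atlas, "region_atlas"))
  n <- n_regions(atlas)
  if (!is.null(names(values))) {
    if (!setequal(names(values), atlas$region_id))
      stop("named values must cover exactly the atlas regions")
    values <- values[atlas$region_id]
  }
  values <- as.numeric(values)
  if (length(values) != n) stop("need exactly one value per atlas region")
  if (!all(is.finite(values))) stop("region map values must be finite")
  names(values) <- atlas$region_id
  structure(values, atlas = atlas, class = c("region_map", "numeric"))
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> %d regions; range [%.3g, %.3g]\n",
              length(x), min(x), max(x)))
  invisible(x)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
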