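# shared fixtures, all built in code

# small atlas for fast tests
tiny_atlas <- function(n = 12, seed = 11L) {
  make_atlas(n_cortical = n - 4, n_subcortical = 2, n_cerebellar = 1,
             n_brainstem = 1, seed = seed)
}

default_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_atlas()
    cache
  }
})

# hand-built donor sample set
manual_donor <- function(id, coords, intensities, background, probe_map,
                         source_region = rep(NA_character_, nrow(coords))) {
  rownames(intensities) <- rownames(background) <- probe_map$probe_id
  structure(list(donor_id = id, coords = as.matrix(coords),
                 intensities = intensities, background = background,
                 probe_map = probe_map, source_region = source_region),
            class = "donor_sample_set")
}

# minimal w-score panel wrapper around a bare matrix
manual_panel <- function(w, atlas) {
  colnames(w) <- atlas$region_id
  structure(list(w = w, subject_id = sprintf("p%d", seq_len(nrow(w))),
                 model = list(atlas = atlas)),
            class = "wscore_panel")
}

# split a simulated cohort into controls / patients
cohort_groups <- function(cohort) {
  s <- cohort$subjects
  list(controls = s[s$group == "control", , drop = FALSE],
       patients = s[s$group == "patient", , drop = FALSE])
}

# atrophy map of a freshly simulated cohort under `truth`
simulated_atrophy <- function(atlas, expression, truth,
                              n_controls = 100, n_patients = 100) {
  coh <- simulate_cohort(atlas, expression, truth, n_controls, n_patients)
  g <- cohort_groups(coh)
  model <- fit_normative(g$controls, atlas)
  average_wscores(compute_wscores(g$patients, model))
}

zero_truth <- function(genes, seed = 1L, ...) {
  ground_truth(stats::setNames(rep(0, length(genes)), genes), seed = seed, ...)
}
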