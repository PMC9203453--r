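# small fixtures built in code

# four regions at the corners of the unit square (z = 0), one lobe split
# and a two-hemisphere level: side pairs normalize to 0, diagonals to 1
unit_square_atlas <- function() {
  region_atlas(tibble::tibble(
    region_id = 1:4,
    name = c("A", "B", "C", "D"),
    cx = c(0, 1, 0, 1), cy = c(0, 0, 1, 1), cz = 0,
    level2_parent = c("low", "low", "high", "high"),
    level1_parent = c("all", "all", "all", "all")))
}

# wide lesion table from a plain degree matrix
lesion_table_from <- function(m, atlas) {
  colnames(m) <- atlas$regions$name
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%02d", seq_len(nrow(m)))),
    tibble::as_tibble(m))
}

# random lesion profiles on a small random atlas (for property sweeps)
random_profile <- function(n_regions, p_lesion = 0.3) {
  ifelse(stats::runif(n_regions) < p_lesion,
         stats::runif(n_regions, 0.1, 100), 0)
}

tiny_cohort <- function(seed = 1, n = c(8, 8, 8), n_regions = 12) {
  atlas <- generate_atlas(n_regions, seed = seed)
  spec <- cohort_spec(
    n_subjects = n,
    lesion_counts = list(c(1, 2), c(3, 5), c(6, 8)),
    single_lesion_fraction = c(0.3, 0, 0),
    sparsity_targets = list(c(0, 0.2), c(0.25, 0.45), c(0.55, 0.7)),
    seed = seed)
  cohort <- generate_cohort(spec, atlas)
  list(atlas = atlas, spec = spec, cohort = cohort)
}
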