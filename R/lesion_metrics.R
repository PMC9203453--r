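#' Lesion tables
#'
#' Throughout the package a lesion table is a wide tibble: one row per
#' subject, a `subject_id` column, and one column per atlas region holding
#' the lesion degree (percent of the region's voxels that are lesioned,
#' in `[0, 100]`). Columns are matched to the atlas by region name.
#'
#' @name lesion-table
#' @keywords internal
NULL

# wide lesion tibble -> subjects x regions matrix in atlas column order
lesion_matrix <- function(lesion_tbl, atlas = NULL) {
  stopifnot(is.data.frame(lesion_tbl), "subject_id" %in% names(lesion_tbl))
  if (is.null(atlas)) {
    cols <- setdiff(names(lesion_tbl), "subject_id")
  } else {
    cols <- atlas$regions$name
    missing <- setdiff(cols, names(lesion_tbl))
    if (length(missing) > 0) {
      rlang::abort(paste0("lesion table is missing region column(s): ",
                          paste(utils::head(missing, 5), collapse = ", ")))
    }
  }
  m <- as.matrix(lesion_tbl[, cols, drop = FALSE])
  if (any(!is.finite(m)) || any(m < 0) || any(m > 100)) {
    rlang::abort("lesion degrees must be finite and within [0, 100]")
  }
  rownames(m) <- lesion_tbl$subject_id
  m
}

#' Binarize lesion degrees into absence/presence
#'
#' A region counts as lesioned whenever its degree is strictly greater than
#' 0% -- any nonzero lesioned voxel fraction marks presence.
#'
#' @param lesion_tbl Wide lesion table (see [lesion-table]).
#' @return A tibble of the same shape with 0/1 entries.
#' @export
binarize_lesions <- function(lesion_tbl) {
  dplyr::mutate(lesion_tbl,
                dplyr::across(-dplyr::all_of("subject_id"), ~ as.integer(.x > 0)))
}

#' Lesion occurrence of a degree vector
#'
#' Fraction of atlas regions with lesion degree > 0%.
#'
#' @param degrees Numeric vector of per-region lesion degrees (percent).
#' @return A fraction in `[0, 1]`.
#' @export
occurrence_of <- function(degrees) {
  stopifnot(all(is.finite(degrees)), all(degrees >= 0))
  sum(degrees > 0) / length(degrees)
}

#' Lesion sparsity of a degree vector
#'
#' Averages the normalized inter-region distance over all unordered region
#' pairs in which *both* regions are lesioned (mutual occurrence, AND
#' logic); pairs where either region is intact are excluded from the
#' average. Subjects with fewer than two lesioned regions have no valid
#' pair and get sparsity 0. Larger values mean the lesioned regions sit
#' farther apart.
#'
#' @param degrees Numeric vector of per-region lesion degrees (percent).
#' @param dist Normalized distance matrix from [build_distance_matrix()].
#' @return A value in `[0, 1]`.
#' @export
sparsity_of <- function(degrees, dist) {
  if (length(degrees) != nrow(dist)) {
    rlang::abort("profile and distance matrix dimensions disagree")
  }
  idx <- which(degrees > 0)
  if (length(idx) < 2) return(0)
  sub <- dist[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Characterize subjects by lesion occurrence and sparsity
#'
#' @param lesion_tbl Wide lesion table (see [lesion-table]).
#' @param atlas A [region_atlas()].
#' @param dist Optional precomputed normalized distance matrix; defaults to
#'   [build_distance_matrix()] on `atlas`.
#' @return A tibble with columns `subject_id`, `n_lesioned`, `occurrence`,
#'   `sparsity`.
#' @examples
#' atlas <- generate_atlas(10, seed = 1)
#' coh <- generate_cohort(cohort_spec(n_subjects = c(5, 5, 5), seed = 1), atlas)
#' characterize_lesions(coh$lesions, atlas)
#' @export
characterize_lesions <- function(lesion_tbl, atlas,
                                 dist = build_distance_matrix(atlas)) {
  m <- lesion_matrix(lesion_tbl, atlas)
  tibble::tibble(
    subject_id = lesion_tbl$subject_id,
    n_lesioned = unname(apply(m, 1, function(d) sum(d > 0))),
    occurrence = unname(apply(m, 1, occurrence_of)),
    sparsity = unname(apply(m, 1, sparsity_of, dist = dist)))
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean. An all-zero vector (no
#' lesion ever observed in the region) is reported as CV 0, as is any
#' constant vector.
#'
#' @param x Numeric vector (at least 2 values).
#' @return A nonnegative value.
#' @export
coefficient_of_variation <- function(x) {
  stopifnot(length(x) >= 2, all(is.finite(x)))
  s <- stats::sd(x)
  if (s == 0) return(0)
  s / mean(x)
}

#' Per-region dispersion of lesion degrees across subjects
#'
#' @param lesion_tbl Wide lesion table.
#' @param atlas Optional [region_atlas()] to fix region order.
#' @return A tibble with columns `region`, `cv`.
#' @export
region_cv <- function(lesion_tbl, atlas = NULL) {
  m <- lesion_matrix(lesion_tbl, atlas)
  tibble::tibble(region = colnames(m),
                 cv = apply(m, 2, coefficient_of_variation))
}
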