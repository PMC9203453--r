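#' Categorize subjects on the (occurrence, sparsity) plane
#'
#' Runs k-means (k = 3 by default, 10 random restarts) on the raw
#' two-dimensional lesion characteristics. Both coordinates already live in
#' `[0, 1]`, so no standardization is applied. Cluster labels are relabeled
#' canonically so that subset 1 has the lowest mean occurrence centroid and
#' subset k the highest; the subset index is then reproducible across runs
#' and seeds.
#'
#' @param characteristics Tibble from [characterize_lesions()] (needs
#'   `subject_id`, `occurrence`, `sparsity`).
#' @param k Number of subsets (default 3).
#' @param seed Integer seed controlling the restarts.
#' @param nstart Number of random restarts (best within-cluster sum of
#'   squares kept).
#' @return The input tibble with an integer `subset` column appended;
#'   cluster centers (after relabeling) attached as attribute `centers`.
#' @examples
#' atlas <- generate_atlas(20, seed = 1)
#' coh <- generate_cohort(cohort_spec(n_subjects = c(10, 10, 10), seed = 1), atlas)
#' ch <- characterize_lesions(coh$lesions, atlas)
#' table(cluster_subjects(ch, seed = 1)$subset)
#' @export
cluster_subjects <- function(characteristics, k = 3, seed = 1, nstart = 10) {
  stopifnot(all(c("subject_id", "occurrence", "sparsity") %in%
                  names(characteristics)))
  pts <- as.matrix(characteristics[, c("occurrence", "sparsity")])
  if (any(!is.finite(pts))) rlang::abort("non-finite lesion characteristics")
  if (k > nrow(pts)) rlang::abort("k exceeds the number of subjects")
  if (k > 1 && nrow(unique(pts)) < k) {
    rlang::abort("degenerate clustering input: fewer distinct points than clusters")
  }
  if (k == 1) {
    out <- dplyr::mutate(characteristics, subset = 1L)
    attr(out, "centers") <- matrix(colMeans(pts), nrow = 1,
                                   dimnames = list(NULL, colnames(pts)))
    return(out)
  }
  km <- withr::with_seed(seed,
    stats::kmeans(pts, centers = k, nstart = nstart, iter.max = 100))
  # canonical order: subset index increases with centroid occurrence
  ord <- order(km$centers[, "occurrence"])
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  out <- dplyr::mutate(characteristics, subset = relabel[km$cluster])
  attr(out, "centers") <- km$centers[ord, , drop = FALSE]
  out
}
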