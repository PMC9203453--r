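#' Roll predictions (or truth) up to a coarser resolution
#'
#' A coarse region (lobe or hemispheric division) is marked lesioned for a
#' subject exactly when at least one of its constituent fine regions is
#' marked lesioned (OR logic). The same operation applied to binarized true
#' occurrences defines the coarse ground truth.
#'
#' @param pred_tbl Wide 0/1 tibble (`subject_id` + fine-region columns).
#' @param mapping Tibble from [rollup_map()] (`name`, `parent`).
#' @return A wide 0/1 tibble with one column per parent region.
#' @examples
#' atlas <- default_atlas()
#' coh <- generate_cohort(cohort_spec(n_subjects = c(3, 3, 3), seed = 1), atlas)
#' lobes <- rollup_predictions(binarize_lesions(coh$lesions),
#'                             rollup_map(atlas, "level2"))
#' @export
rollup_predictions <- function(pred_tbl, mapping) {
  stopifnot(all(c("name", "parent") %in% names(mapping)))
  regions <- setdiff(names(pred_tbl), "subject_id")
  missing <- setdiff(regions, mapping$name)
  if (length(missing) > 0) {
    rlang::abort(paste0("region(s) missing from mapping: ",
                        paste(utils::head(missing, 5), collapse = ", ")))
  }
  long <- tidyr::pivot_longer(pred_tbl, -dplyr::all_of("subject_id"),
                              names_to = "name", values_to = "pred")
  long <- dplyr::left_join(long, mapping[, c("name", "parent")], by = "name")
  coarse <- dplyr::summarise(
    dplyr::group_by(long, .data$subject_id, .data$parent),
    pred = as.integer(any(.data$pred > 0)), .groups = "drop")
  out <- tidyr::pivot_wider(coarse, names_from = "parent",
                            values_from = "pred")
  # preserve subject order and a stable parent column order
  parents <- unique(mapping$parent[mapping$name %in% regions])
  out <- out[match(pred_tbl$subject_id, out$subject_id),
             c("subject_id", parents)]
  tibble::as_tibble(out)
}

#' Fit lesion models directly at a coarser resolution
#'
#' Builds the coarse ground truth by OR roll-up of the binarized fine
#' lesion table, then runs the full region-modeling pipeline
#' ([fit_all_regions()]) with each coarse region as the outcome ("direct
#' estimation", as opposed to the "modified estimation" that rolls up
#' fine-level predictions).
#'
#' @param lesion_tbl Wide fine-resolution lesion table (degrees).
#' @param features Wide feature tibble.
#' @param mapping Tibble from [rollup_map()].
#' @param config A [fit_config()].
#' @return A list with `model_set` (a `region_model_set` over coarse
#'   regions) and `truth` (the coarse 0/1 table).
#' @export
direct_fit_at_level <- function(lesion_tbl, features, mapping,
                                config = fit_config()) {
  truth <- rollup_predictions(binarize_lesions(lesion_tbl), mapping)
  model_set <- fit_all_regions(truth, features, config)
  list(model_set = model_set, truth = truth)
}
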