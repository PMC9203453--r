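#' Configuration for an end-to-end pipeline run
#'
#' Bundles the inputs and tuning knobs of [run_full_pipeline()]. Data can
#' come from supplied wide tables (`lesion_table`, `feature_table`) or be
#' simulated from a [cohort_spec()]; in the simulated case the spec's seed
#' is overridden by the pipeline seed so one integer reproduces the whole
#' run.
#'
#' @param spec A [cohort_spec()] (used when no tables are supplied).
#' @param atlas A [region_atlas()]; defaults to the bundled registry.
#' @param lesion_table,feature_table Optional wide tibbles replacing
#'   simulation.
#' @param method Region-model method: `"none"`, `"l1"` or `"l2"`.
#' @param region_resamples Resampling repetitions per region model.
#' @param classifier_resamples Resampling repetitions for subset-classifier
#'   tuning.
#' @param classifier_grid Optional hyperparameter grid (see
#'   [fit_subset_classifier()]).
#' @param fit_subsets Also fit region models within each true subset
#'   (default `TRUE`).
#' @param direct_levels Coarse levels at which to run modified and direct
#'   estimation (default both).
#' @param seed Integer master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(spec = cohort_spec(seed = 1),
                            atlas = NULL,
                            lesion_table = NULL, feature_table = NULL,
                            method = c("none", "l1", "l2"),
                            region_resamples = 100,
                            classifier_resamples = 100,
                            classifier_grid = NULL,
                            fit_subsets = TRUE,
                            direct_levels = c("level2", "level1"),
                            seed = 1) {
  method <- rlang::arg_match(method)
  structure(list(spec = spec, atlas = atlas, lesion_table = lesion_table,
                 feature_table = feature_table, method = method,
                 region_resamples = region_resamples,
                 classifier_resamples = classifier_resamples,
                 classifier_grid = classifier_grid,
                 fit_subsets = fit_subsets, direct_levels = direct_levels,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end lesion-estimation pipeline
#'
#' Executes the full flow: characterize subjects by lesion occurrence and
#' sparsity, categorize them into three subsets by k-means, train the
#' non-imaging subset classifier, fit region-wise logistic lesion models
#' (complete cohort and per subset), predict lesion presence, roll
#' predictions up to the coarser resolutions (modified estimation) and fit
#' directly at those resolutions for comparison, and evaluate everything.
#' The run is fully reproducible from the configuration seed.
#'
#' @param config A [pipeline_config()].
#' @return A `lesion_report` list (JSON-serializable via [write_report()]).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  atlas <- config$atlas %||% default_atlas()

  if (is.null(config$lesion_table)) {
    spec <- config$spec
    spec$seed <- config$seed
    cohort <- generate_cohort(spec, atlas)
    feat <- generate_features(cohort, spec)
    lesions <- cohort$lesions
    features <- feat$features
    planted <- cohort$truth
  } else {
    lesions <- config$lesion_table
    features <- config$feature_table
    planted <- NULL
  }

  # stage 1: lesion characteristics and imaging-based categorization
  ch <- characterize_lesions(lesions, atlas)
  assign <- cluster_subjects(ch, k = 3, seed = config$seed)
  subset_block <- list(
    sizes = as.list(table(assign$subset)),
    planted_ari = if (!is.null(planted))
      adjusted_rand_index(planted$subset, assign$subset) else NULL)

  # stage 2: subset prediction from non-imaging features alone
  sm <- train_subset_model(features, assign, seed = config$seed,
                           grid = config$classifier_grid,
                           resamples = config$classifier_resamples)
  pred_subsets <- predict_subset(sm, features)
  cm <- table(truth = assign$subset, pred = pred_subsets$subset)
  classifier_block <- list(
    n_screened = length(sm$screened_features),
    n_components = sm$reduction$n_components,
    tuned = as.list(glance(sm$classifier)),
    training_accuracy = mean(assign$subset == pred_subsets$subset),
    training_mcc = multiclass_mcc(cm),
    predicted_sizes = as.list(table(pred_subsets$subset)))

  # stage 3: region-wise lesion models (on the missingness-filtered,
  # imputed feature table)
  features_c <- drop_sparse_features(features, 0.2)
  truth_bin <- binarize_lesions(lesions)
  fcfg <- function(seed_off) {
    fit_config(method = config$method, resamples = config$region_resamples,
               seed = config$seed + seed_off)
  }
  datasets <- list(complete = rep(TRUE, nrow(lesions)))
  if (config$fit_subsets) {
    for (s in sort(unique(assign$subset))) {
      datasets[[paste0("subset", s)]] <- assign$subset == s
    }
  }
  fits <- list()
  evals <- list()
  preds <- list()
  for (i in seq_along(datasets)) {
    nm <- names(datasets)[i]
    sel <- datasets[[i]]
    ms <- fit_all_regions(lesions[sel, ], features_c[sel, ], fcfg(i * 100))
    pr <- predict_regions(ms, features_c[sel, ])
    ev <- evaluate_pipeline(truth_bin[sel, names(pr)], pr)
    fits[[nm]] <- ms
    preds[[nm]] <- pr
    evals[[nm]] <- list(
      summary = ev$summary,
      n_modeled = length(ms$models),
      n_unmodellable = length(ms$unmodellable))
  }

  # estimation on the predicted subsets: each subject is scored by the
  # model set of the subset the classifier assigned it to
  predicted_eval <- NULL
  cv_corr <- NULL
  if (config$fit_subsets) {
    pred_rows <- purrr::map_dfr(sort(unique(pred_subsets$subset)),
                                function(s) {
      ids <- pred_subsets$subject_id[pred_subsets$subset == s]
      ms <- fits[[paste0("subset", s)]]
      if (is.null(ms) || length(ids) == 0) return(NULL)
      pr <- predict_regions(ms, features_c[features_c$subject_id %in% ids, ])
      pr
    })
    if (!is.null(pred_rows) && nrow(pred_rows) > 0) {
      pred_rows <- pred_rows[match(lesions$subject_id,
                                   pred_rows$subject_id), ]
      pred_rows <- pred_rows[!is.na(pred_rows$subject_id), ]
      # keep regions modeled in every subset's model set
      complete_cols <- names(pred_rows)[colSums(is.na(pred_rows)) == 0]
      shared <- intersect(complete_cols, names(truth_bin))
      tr <- truth_bin[truth_bin$subject_id %in% pred_rows$subject_id,
                      shared]
      ev <- evaluate_pipeline(tr, pred_rows[, shared],
                              lesion_tbl = lesions, subsets = assign,
                              predicted_subsets = pred_subsets)
      predicted_eval <- list(summary = ev$summary)
      cv_corr <- ev$cv_correlation
    }
  }

  # stage 4: resolution transfer on the complete cohort
  resolution <- list()
  for (lev in config$direct_levels) {
    mapping <- rollup_map(atlas, lev)
    pr_fine <- preds$complete
    map_sub <- mapping[mapping$name %in% names(pr_fine), ]
    modified_pred <- rollup_predictions(pr_fine, map_sub)
    coarse_truth <- rollup_predictions(truth_bin, mapping)
    direct <- direct_fit_at_level(lesions, features_c, mapping,
                                  fcfg(1000 + match(lev, config$direct_levels)))
    direct_pred <- predict_regions(direct$model_set, features_c)
    ev_mod <- evaluate_pipeline(coarse_truth[, names(modified_pred)],
                                modified_pred)
    ev_dir <- evaluate_pipeline(coarse_truth[, names(direct_pred)],
                                direct_pred)
    comp <- evaluate_pipeline(
      coarse_truth[, names(modified_pred)], modified_pred,
      modified = list(truth = coarse_truth[, names(modified_pred)],
                      pred = modified_pred),
      direct = list(truth = coarse_truth[, names(direct_pred)],
                    pred = direct_pred))
    resolution[[lev]] <- list(
      modified = ev_mod$summary, direct = ev_dir$summary,
      rank_sum = comp$modified_vs_direct)
  }

  structure(list(
    seed = config$seed,
    method = config$method,
    n_subjects = nrow(lesions),
    n_regions = atlas$n_regions,
    characteristics = ch,
    subsets = subset_block,
    classifier = classifier_block,
    regions = evals,
    predicted_subset_estimation = predicted_eval,
    cv_correlation = cv_corr,
    resolution = resolution),
    class = "lesion_report")
}

#' @export
print.lesion_report <- function(x, ...) {
  cat(sprintf("<lesion_report: %d subjects, %d regions, method %s>\n",
              x$n_subjects, x$n_regions, x$method))
  cat(sprintf("  subset sizes: %s; classifier accuracy %.3f (MCC %.3f)\n",
              paste(unlist(x$subsets$sizes), collapse = "/"),
              x$classifier$training_accuracy, x$classifier$training_mcc))
  invisible(x)
}

#' Read wide lesion and feature tables from CSV
#'
#' Lesion tables are wide CSVs: a `subject_id` column plus one
#' percent-degree column per region. Feature tables use the same layout
#' with empty cells for missing values.
#'
#' @param path CSV file path.
#' @return A wide tibble with a character `subject_id` column.
#' @export
read_lesion_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot("subject_id" %in% names(tbl))
  dplyr::mutate(tbl, subject_id = as.character(.data$subject_id))
}

#' @rdname read_lesion_table
#' @export
read_feature_table <- read_lesion_table

#' Serialize a pipeline report to JSON
#'
#' @param report A `lesion_report` (or any list of tibbles/values).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  report$characteristics <- NULL  # bulky per-subject table stays in R
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, na = "null")
  invisible(path)
}
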