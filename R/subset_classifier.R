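#' Drop features with excessive missingness and impute the rest
#'
#' Features whose missing fraction exceeds `max_missing` are removed;
#' remaining missing values are replaced by the feature median. The dropped
#' names and the imputation medians are attached as attributes
#' (`"dropped_features"`, `"imputation_values"`) so the same treatment can
#' be replayed on new data.
#'
#' @param features Wide feature tibble (`subject_id` plus numeric columns,
#'   `NA` allowed).
#' @param max_missing Maximum tolerated missing fraction per feature
#'   (default 0.2).
#' @return The filtered, imputed feature tibble.
#' @export
drop_sparse_features <- function(features, max_missing = 0.2) {
  m <- feature_matrix(features)
  frac <- colMeans(is.na(m))
  drop <- names(frac)[frac > max_missing]
  keep <- setdiff(colnames(m), drop)
  if (length(keep) == 0) rlang::abort("all features exceed the missingness threshold")
  m <- m[, keep, drop = FALSE]
  med <- apply(m, 2, stats::median, na.rm = TRUE)
  for (j in seq_along(keep)) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- med[j]
  }
  out <- dplyr::bind_cols(features[, intersect("subject_id", names(features)),
                                   drop = FALSE],
                          tibble::as_tibble(m))
  attr(out, "dropped_features") <- drop
  attr(out, "imputation_values") <- med
  out
}

#' Screen features for subset effects (Kruskal-Wallis)
#'
#' Keeps features whose Kruskal-Wallis test across the subsets is
#' significant at `alpha`. Constant features have H = 0, p = 1 and are
#' always dropped for `alpha < 1`.
#'
#' @param features Wide feature tibble (complete; run
#'   [drop_sparse_features()] first).
#' @param labels Integer subset labels, either a vector aligned with the
#'   rows or a tibble with `subject_id` and `subset` columns.
#' @param alpha Significance level (default 0.05).
#' @return The filtered feature tibble; the per-feature test results are
#'   attached as attribute `"kw_screen"` (tibble: feature, H, p, kept).
#' @export
screen_features_kw <- function(features, labels, alpha = 0.05) {
  g <- resolve_labels(features, labels)
  if (sum(table(g) >= 2) < 2) {
    rlang::abort("need at least 2 subsets with at least 2 members")
  }
  m <- feature_matrix(features)
  res <- purrr::map(colnames(m), function(f) {
    kw <- kruskal_wallis(split(m[, f], g))
    tibble::tibble(feature = f, H = kw$H, p = kw$p)
  })
  res <- dplyr::bind_rows(res)
  res$kept <- res$p < alpha
  keep <- res$feature[res$kept]
  out <- features[, c(intersect("subject_id", names(features)), keep),
                  drop = FALSE]
  attr(out, "kw_screen") <- res
  out
}

resolve_labels <- function(features, labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("subject_id", "subset") %in% names(labels)))
    idx <- match(features$subject_id, labels$subject_id)
    if (anyNA(idx)) rlang::abort("labels missing for some subjects")
    labels$subset[idx]
  } else {
    stopifnot(length(labels) == nrow(features))
    labels
  }
}

#' Reduce feature dimensionality by PCA
#'
#' Standardizes the features (z-score) and retains the smallest leading set
#' of principal components whose cumulative explained variance reaches
#' `variance_target`. Zero-variance features are removed before
#' standardization.
#'
#' @param features Wide feature tibble (complete).
#' @param variance_target Cumulative explained-variance target (default 0.95).
#' @return A `pca_reduction` object with elements `scores` (tibble:
#'   `subject_id` + `PC1..PCk`), `rotation`, `center`, `scale`,
#'   `n_components`, `explained`, `features`.
#' @export
reduce_dimensions <- function(features, variance_target = 0.95) {
  m <- feature_matrix(features)
  if (nrow(m) < 2 || ncol(m) < 2) {
    rlang::abort("need at least 2 subjects and 2 features")
  }
  sds <- apply(m, 2, stats::sd)
  keep <- colnames(m)[sds > 0]
  if (length(keep) == 0) rlang::abort("all features have zero variance")
  m <- m[, keep, drop = FALSE]
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- which(cumsum(explained) >= variance_target)[1]
  if (is.na(ncomp)) ncomp <- length(explained)
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]
  sc <- dplyr::bind_cols(
    features[, intersect("subject_id", names(features)), drop = FALSE],
    tibble::as_tibble(scores))
  structure(
    list(scores = sc, rotation = pc$rotation, center = pc$center,
         scale = pc$scale, n_components = ncomp, explained = explained,
         features = keep),
    class = "pca_reduction")
}

#' Project new data onto a fitted PCA reduction
#'
#' @param object A `pca_reduction`.
#' @param features New feature tibble holding at least the fitted features.
#' @param ... Unused.
#' @return A score tibble with the retained components.
#' @export
predict.pca_reduction <- function(object, features, ...) {
  missing <- setdiff(object$features, names(features))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing feature(s): ",
                        paste(utils::head(missing, 5), collapse = ", ")))
  }
  m <- as.matrix(features[, object$features, drop = FALSE])
  z <- scale(m, center = object$center, scale = object$scale)
  scores <- z %*% object$rotation[, seq_len(object$n_components), drop = FALSE]
  dplyr::bind_cols(
    features[, intersect("subject_id", names(features)), drop = FALSE],
    tibble::as_tibble(scores))
}

#' Generalized (multiclass) Matthews correlation coefficient
#'
#' Gorodkin's generalization of the MCC to a k-class confusion matrix
#' (rows = truth, columns = prediction). Degenerate marginals (e.g. all
#' predictions in one class) give 0 by convention.
#'
#' @param confusion Square matrix of nonnegative counts.
#' @return A value in `[-1, 1]`.
#' @export
multiclass_mcc <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (length(confusion) == 0) rlang::abort("empty confusion matrix")
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  s <- sum(confusion)
  c_ok <- sum(diag(confusion))
  t_k <- rowSums(confusion)
  p_k <- colSums(confusion)
  num <- c_ok * s - sum(t_k * p_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

default_forest_grid <- function() {
  tidyr::expand_grid(num_trees = c(100L, 300L),
                     max_depth = c(0L, 5L, 10L),
                     mtry_rule = c("sqrt", "all"))
}

#' Tune and fit the subset random forest
#'
#' For every hyperparameter candidate, the score data are resampled
#' `resamples` times into stratified 75/25 splits; on each training part a
#' stratified threefold cross-validation yields out-of-fold predictions from
#' which a multiclass MCC and a correct rate are computed. The candidate
#' with the highest mean MCC wins (ties broken by the higher correct rate),
#' and the final forest is refit on all data with the winning candidate.
#'
#' @param scores Score tibble (e.g. from [reduce_dimensions()]):
#'   `subject_id` plus numeric columns.
#' @param labels Subset labels (vector or tibble with `subject_id`, `subset`).
#' @param seed Integer seed for all resampling and forest randomness.
#' @param grid Hyperparameter candidates (tibble with `num_trees`,
#'   `max_depth`, `mtry_rule`); defaults to a small 12-candidate grid.
#' @param resamples Number of 75/25 resampling repetitions (default 100).
#' @param train_frac Training fraction per resample (default 0.75).
#' @param inner_folds Cross-validation folds on the training side (default 3).
#' @return A `subset_classifier` object.
#' @export
fit_subset_classifier <- function(scores, labels, seed = 1, grid = NULL,
                                  resamples = 100, train_frac = 0.75,
                                  inner_folds = 3) {
  y <- factor(resolve_labels(scores, labels))
  if (nlevels(y) < 3) rlang::abort("need at least 3 subset classes present")
  x <- feature_matrix(scores)
  if (is.null(grid)) grid <- default_forest_grid()
  grid <- tibble::as_tibble(grid)

  eval_candidate <- function(num_trees, max_depth, mtry_rule, plan) {
    mtry <- if (mtry_rule == "all") ncol(x) else max(1L, floor(sqrt(ncol(x))))
    per <- purrr::map(seq_len(resamples), function(r) {
      tr <- which(plan[[r]]$train)
      fold <- plan[[r]]$fold
      pred <- factor(rep(NA_character_, length(tr)), levels = levels(y))
      for (f in sort(unique(fold))) {
        fit <- ranger::ranger(
          x = x[tr[fold != f], , drop = FALSE], y = y[tr[fold != f]],
          num.trees = num_trees, mtry = mtry, max.depth = max_depth,
          seed = seed + 1000L * r + f, num.threads = 1)
        pred[fold == f] <- stats::predict(
          fit, data = x[tr[fold == f], , drop = FALSE],
          num.threads = 1, seed = seed + 1000L * r + f)$predictions
      }
      cm <- table(truth = y[tr], pred = pred)
      c(mcc = multiclass_mcc(cm), correct = mean(pred == y[tr]))
    })
    c(mcc = mean(purrr::map_dbl(per, "mcc")),
      correct = mean(purrr::map_dbl(per, "correct")))
  }

  tuning <- grid
  res <- withr::with_seed(seed, {
    plan <- purrr::map(seq_len(resamples), function(r) {
      train <- stratified_split(y, train_frac)
      list(train = train, fold = stratified_folds(y[train], inner_folds))
    })
    purrr::pmap(grid, eval_candidate, plan = plan)
  })
  tuning$mcc <- purrr::map_dbl(res, "mcc")
  tuning$correct_rate <- purrr::map_dbl(res, "correct")
  best_i <- order(-tuning$mcc, -tuning$correct_rate)[1]
  best <- tuning[best_i, ]
  mtry <- if (best$mtry_rule == "all") ncol(x) else max(1L, floor(sqrt(ncol(x))))
  fit <- withr::with_seed(seed,
    ranger::ranger(x = x, y = y, num.trees = best$num_trees,
                   mtry = mtry, max.depth = best$max_depth,
                   seed = seed, num.threads = 1,
                   importance = "impurity"))
  structure(
    list(fit = fit, tuning = tuning, best = best, levels = levels(y),
         score_columns = colnames(x), seed = seed, resamples = resamples),
    class = "subset_classifier")
}

#' @export
print.subset_classifier <- function(x, ...) {
  cat(sprintf("<subset_classifier: %d candidates tuned, best MCC %.3f (correct rate %.3f)>\n",
              nrow(x$tuning), x$best$mcc, x$best$correct_rate))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.subset_classifier <- function(x, ...) {
  dplyr::arrange(x$tuning, dplyr::desc(.data$mcc))
}

#' @export
glance.subset_classifier <- function(x, ...) {
  dplyr::bind_cols(x$best, tibble::tibble(n_candidates = nrow(x$tuning),
                                          resamples = x$resamples))
}

#' Train the full subset-prediction chain from raw features
#'
#' Convenience wrapper running missingness filtering, Kruskal-Wallis
#' screening, PCA reduction and random-forest tuning, and recording every
#' preprocessing parameter needed to predict the subset of a new subject
#' from non-imaging features alone.
#'
#' @inheritParams fit_subset_classifier
#' @param features Raw wide feature tibble (missing values allowed).
#' @param max_missing Missingness threshold for [drop_sparse_features()].
#' @param alpha Screening level for [screen_features_kw()].
#' @param variance_target PCA target for [reduce_dimensions()].
#' @return A `subset_model` object.
#' @export
train_subset_model <- function(features, labels, seed = 1,
                               max_missing = 0.2, alpha = 0.05,
                               variance_target = 0.95, grid = NULL,
                               resamples = 100) {
  filtered <- drop_sparse_features(features, max_missing)
  screened <- screen_features_kw(filtered, labels, alpha)
  if (ncol(screened) <= 1) rlang::abort("no feature passed the subset screen")
  red <- reduce_dimensions(screened, variance_target)
  clf <- fit_subset_classifier(red$scores, labels, seed = seed, grid = grid,
                               resamples = resamples)
  structure(
    list(classifier = clf, reduction = red,
         screened_features = setdiff(names(screened), "subject_id"),
         imputation_values = attr(filtered, "imputation_values"),
         dropped_features = attr(filtered, "dropped_features"),
         kw_screen = attr(screened, "kw_screen")),
    class = "subset_model")
}

#' @export
print.subset_model <- function(x, ...) {
  cat(sprintf("<subset_model: %d screened features -> %d components; tuned MCC %.3f>\n",
              length(x$screened_features), x$reduction$n_components,
              x$classifier$best$mcc))
  invisible(x)
}

#' Predict subset membership from non-imaging features
#'
#' Applies the stored preprocessing (median imputation, screened feature
#' subset, PCA projection) and the tuned forest; no imaging input is used.
#'
#' @param model A `subset_model` from [train_subset_model()], or a
#'   `subset_classifier` applied directly to score tibbles.
#' @param features Wide feature tibble for new subjects.
#' @return A tibble with `subject_id` and integer `subset`.
#' @export
predict_subset <- function(model, features) {
  UseMethod("predict_subset")
}

#' @export
predict_subset.subset_model <- function(model, features) {
  needed <- model$reduction$features
  missing <- setdiff(needed, names(features))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing retained feature(s): ",
                        paste(utils::head(missing, 5), collapse = ", ")))
  }
  m <- features[, c(intersect("subject_id", names(features)), needed),
                drop = FALSE]
  med <- model$imputation_values
  for (f in needed) {
    nas <- is.na(m[[f]])
    if (any(nas)) m[[f]][nas] <- med[[f]]
  }
  scores <- stats::predict(model$reduction, m)
  predict_subset(model$classifier, scores)
}

#' @export
predict_subset.subset_classifier <- function(model, features) {
  x <- as.matrix(features[, model$score_columns, drop = FALSE])
  pred <- stats::predict(model$fit, data = x, num.threads = 1,
                         seed = model$seed)$predictions
  tibble::tibble(
    subject_id = features$subject_id %||% as.character(seq_len(nrow(x))),
    subset = as.integer(as.character(pred)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
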