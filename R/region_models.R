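#' Fit configuration for region-wise lesion models
#'
#' @param method `"none"` (maximum-likelihood logistic regression with
#'   Kendall feature selection), `"l1"` (LASSO) or `"l2"` (Ridge).
#' @param outer_folds Outer cross-validation folds (default 4).
#' @param inner_folds Inner folds (default 3).
#' @param resamples Re-randomizations of the outer fold assignment
#'   (default 100), giving `outer_folds * resamples` candidate models.
#' @param min_presence Minimum number of presence subjects required to run
#'   cross-validation and resampling; below it a single model is fit on all
#'   data (default 4).
#' @param alpha Significance level of the Kendall tau screen (default 0.05).
#' @param lambda_grid Penalty grid for the regularized methods (default 20
#'   values log-spaced over `[1e-4, 1e2]`).
#' @param seed Integer seed for fold assignment.
#' @return A `fit_config` list.
#' @export
fit_config <- function(method = c("none", "l1", "l2"), outer_folds = 4,
                       inner_folds = 3, resamples = 100, min_presence = 4,
                       alpha = 0.05,
                       lambda_grid = 10^seq(-4, 2, length.out = 20),
                       seed = 1) {
  method <- rlang::arg_match(method)
  stopifnot(outer_folds >= 2, inner_folds >= 2, resamples >= 1,
            min_presence >= 1, alpha > 0, alpha <= 1)
  structure(list(method = method, outer_folds = outer_folds,
                 inner_folds = inner_folds, resamples = resamples,
                 min_presence = min_presence, alpha = alpha,
                 lambda_grid = sort(lambda_grid), seed = seed),
            class = "fit_config")
}

#' Select features by Kendall rank correlation with a binary outcome
#'
#' Keeps features whose tie-corrected Kendall tau-b correlation with the
#' 0/1 lesion indicator is significant at `alpha`. Constant features have
#' an undefined tau and are excluded. P-values come from
#' [stats::cor.test()] (exact for small untied samples, tie-corrected
#' normal approximation otherwise).
#'
#' @param features Wide feature tibble (complete).
#' @param y Binary 0/1 vector (both classes present).
#' @param alpha Significance level (default 0.05).
#' @return Character vector of selected feature names; the per-feature tau
#'   and p are attached as attribute `"kendall_screen"`.
#' @export
select_features_kendall <- function(features, y, alpha = 0.05) {
  if (length(unique(y)) < 2) rlang::abort("outcome has a single class")
  m <- feature_matrix(features)
  stopifnot(nrow(m) == length(y))
  res <- purrr::map(colnames(m), function(f) {
    x <- m[, f]
    if (stats::sd(x) == 0 || anyNA(x)) {
      return(tibble::tibble(feature = f, tau = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
    tibble::tibble(feature = f, tau = unname(ct$estimate), p = ct$p.value)
  })
  res <- dplyr::bind_rows(res)
  res$kept <- !is.na(res$p) & res$p < alpha
  out <- res$feature[res$kept]
  attr(out, "kendall_screen") <- res
  out
}

#' Min-max normalize features to the 0-1 range
#'
#' Scales each feature by its observed minimum and maximum. Constant
#' features cannot be scaled; they are flagged (attribute
#' `"constant_features"`) and excluded from the output so regularized fits
#' never see them. The scaling bounds are attached (attribute
#' `"normalization"`) so new data can be transformed with the training
#' bounds; values outside the training range are passed through (possibly
#' outside 0-1), not clipped.
#'
#' @param features Wide feature tibble.
#' @return The normalized feature tibble.
#' @export
normalize_features <- function(features) {
  m <- feature_matrix(features)
  rng <- apply(m, 2, range)
  constant <- colnames(m)[rng[1, ] == rng[2, ]]
  keep <- setdiff(colnames(m), constant)
  scaled <- purrr::map(keep, function(f) {
    unname((m[, f] - rng[1, f]) / (rng[2, f] - rng[1, f]))
  })
  out <- dplyr::bind_cols(
    features[, intersect("subject_id", names(features)), drop = FALSE],
    tibble::as_tibble(stats::setNames(scaled, keep)))
  attr(out, "normalization") <- tibble::tibble(
    feature = keep, min = rng[1, keep], max = rng[2, keep])
  attr(out, "constant_features") <- constant
  out
}

#' Apply stored min-max bounds to new data
#'
#' @param normalization Tibble attribute produced by [normalize_features()].
#' @param features New feature tibble.
#' @return The transformed tibble (values outside the training range are
#'   passed through un-clipped).
#' @export
apply_normalization <- function(normalization, features) {
  out <- features
  for (i in seq_len(nrow(normalization))) {
    f <- normalization$feature[i]
    out[[f]] <- (features[[f]] - normalization$min[i]) /
      (normalization$max[i] - normalization$min[i])
  }
  out[, c(intersect("subject_id", names(features)), normalization$feature),
      drop = FALSE]
}

# glmnet needs >= 2 columns; pad single-feature designs with a zero column
glmnet_pad <- function(x) {
  if (ncol(x) == 1) cbind(x, .pad = 0) else x
}

# binomial log-likelihood of probabilities p against 0/1 outcomes
binomial_loglik <- function(y, p) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

logistic_prob <- function(x, slopes, intercept) {
  z <- intercept + if (length(slopes) > 0) {
    as.vector(x[, names(slopes), drop = FALSE] %*% slopes)
  } else 0
  1 / (1 + exp(-z))
}

#' Fit a logistic lesion model
#'
#' Fits the probability of lesion presence as a logistic function of the
#' features: maximum likelihood for `method = "none"`, LASSO (`"l1"`) or
#' Ridge (`"l2"`) via glmnet at a fixed `lambda`. For the unpenalized fit,
#' perfect separation is handled deterministically: coefficients are capped
#' at absolute value 20 and the fit flagged, rather than being allowed to
#' diverge. Penalized fits report the *unpenalized* log-likelihood of the
#' fitted coefficients; their parameter count is the intercept plus the
#' nonzero slopes.
#'
#' @param x Numeric matrix (subjects x features); may have zero columns for
#'   an intercept-only model.
#' @param y Binary 0/1 outcome.
#' @param method `"none"`, `"l1"` or `"l2"`.
#' @param lambda Penalty strength (required for `"l1"`/`"l2"`).
#' @return A list with `slopes` (named), `intercept`, `log_lik`, `n_params`,
#'   `aic`, `method`, `lambda`, `separation`.
#' @export
fit_logistic <- function(x, y, method = c("none", "l1", "l2"),
                         lambda = NULL) {
  method <- rlang::arg_match(method)
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  separation <- FALSE
  if (method == "none") {
    xm <- cbind(`(Intercept)` = 1, x)
    fit <- suppressWarnings(
      stats::glm.fit(xm, y, family = stats::binomial()))
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    if (any(abs(coefs) > 20)) {
      separation <- TRUE
      coefs <- pmin(pmax(coefs, -20), 20)
    }
    intercept <- coefs[1]
    slopes <- coefs[-1]
  } else {
    if (is.null(lambda)) rlang::abort("lambda required for penalized fits")
    if (ncol(x) == 0) rlang::abort("penalized fit needs at least one feature")
    xg <- glmnet_pad(x)
    # small folds trip glmnet's small-class warning; degenerate classes are
    # guarded upstream
    fit <- suppressWarnings(
      glmnet::glmnet(xg, y, family = "binomial",
                     alpha = if (method == "l1") 1 else 0,
                     lambda = lambda, standardize = FALSE))
    beta <- as.vector(fit$beta)
    names(beta) <- rownames(fit$beta)
    beta <- beta[colnames(x)]
    intercept <- as.numeric(fit$a0)
    slopes <- beta
  }
  names(intercept) <- NULL
  p <- logistic_prob(x, slopes, intercept)
  ll <- binomial_loglik(y, p)
  n_params <- 1L + if (method == "none") length(slopes) else
    sum(slopes != 0)
  list(slopes = slopes, intercept = intercept, log_lik = ll,
       n_params = n_params, aic = aic(ll, n_params), method = method,
       lambda = lambda, separation = separation)
}

#' Akaike information criterion
#'
#' `2 * n_params - 2 * log_likelihood`. The parameter count includes the
#' intercept and the slopes (for penalized fits, nonzero slopes only).
#'
#' @param log_likelihood Model log-likelihood.
#' @param n_params Number of estimated parameters.
#' @return The AIC value.
#' @export
aic <- function(log_likelihood, n_params) {
  stopifnot(is.finite(log_likelihood), is.finite(n_params))
  2 * n_params - 2 * log_likelihood
}

new_region_model <- function(fit, region_id = NA, features = character(),
                             repeat_idx = NA_integer_, fold_idx = NA_integer_,
                             validation_sensitivity = NA_real_,
                             inner_sensitivity = NA_real_) {
  structure(
    list(region_id = region_id, method = fit$method,
         features = names(fit$slopes), slopes = fit$slopes,
         intercept = fit$intercept, lambda = fit$lambda,
         log_lik = fit$log_lik, n_params = fit$n_params, aic = fit$aic,
         separation = fit$separation, repeat_idx = repeat_idx,
         fold_idx = fold_idx,
         validation_sensitivity = validation_sensitivity,
         inner_sensitivity = inner_sensitivity),
    class = "region_model")
}

#' @export
print.region_model <- function(x, ...) {
  cat(sprintf("<region_model %s: method %s, %d feature(s), AIC %.2f>\n",
              as.character(x$region_id), x$method, length(x$slopes), x$aic))
  invisible(x)
}

#' Nested cross-validation with resampling for one region
#'
#' When the presence count reaches `config$min_presence`, the outer fold
#' assignment is re-randomized `config$resamples` times; each repetition
#' runs `outer_folds` outer folds with `inner_folds` stratified inner folds
#' on the outer-training part, yielding `outer_folds * resamples` candidate
#' models, each carrying its AIC (computed on the outer-training fit) and
#' its outer-validation sensitivity. For the unpenalized method the inner
#' loop fits one model per inner-training fold and records the best
#' inner-validation sensitivity before refitting on the full outer-training
#' fold; for the penalized methods it tunes `lambda` by mean
#' inner-validation sensitivity (ties resolved toward the stronger
#' penalty). Below `min_presence` a single model is fit on all data.
#'
#' @param x Numeric feature matrix (already screened/normalized as the
#'   method requires).
#' @param y Binary 0/1 outcome.
#' @param config A [fit_config()].
#' @return A list of `region_model` candidates.
#' @export
nested_cv_fit <- function(x, y, config) {
  stopifnot(inherits(config, "fit_config"))
  x <- as.matrix(x)
  presence <- sum(y == 1)
  if (presence < config$min_presence) {
    fit <- fit_single(x, y, config)
    return(list(new_region_model(fit)))
  }
  withr::with_seed(config$seed, {
    candidates <- vector("list", config$resamples * config$outer_folds)
    n <- 0L
    for (r in seq_len(config$resamples)) {
      outer <- stratified_folds(y, config$outer_folds)
      for (fo in seq_len(config$outer_folds)) {
        tr <- outer != fo
        cand <- fit_outer_fold(x[tr, , drop = FALSE], y[tr],
                               x[!tr, , drop = FALSE], y[!tr], config)
        cand$repeat_idx <- r
        cand$fold_idx <- fo
        n <- n + 1L
        candidates[[n]] <- cand
      }
    }
    candidates
  })
}

fit_single <- function(x, y, config) {
  if (config$method == "none") {
    fit_logistic(x, y, "none")
  } else if (length(unique(y)) < 2 || min(table(y)) < 2) {
    # too few members of a class for a penalized solver: intercept-only
    fit <- fit_logistic(x[, 0, drop = FALSE], y, "none")
    fit$method <- config$method
    fit$lambda <- min(config$lambda_grid)
    fit
  } else {
    # no inner data to tune on: take the weakest penalty on the grid
    fit_logistic(x, y, config$method, lambda = min(config$lambda_grid))
  }
}

fit_outer_fold <- function(x_tr, y_tr, x_val, y_val, config) {
  if (config$method != "none" &&
      (length(unique(y_tr)) < 2 || min(table(y_tr)) < 2)) {
    # outer-training fold too degenerate for the penalized solver
    fit <- fit_single(x_tr, y_tr, config)
    p_val <- logistic_prob(x_val, fit$slopes, fit$intercept)
    return(new_region_model(
      fit, validation_sensitivity = sensitivity_of(y_val,
                                                   as.integer(p_val >= 0.5))))
  }
  inner <- stratified_folds(y_tr, config$inner_folds)
  if (config$method == "none") {
    inner_sens <- purrr::map_dbl(seq_len(config$inner_folds), function(fi) {
      itr <- inner != fi
      if (length(unique(y_tr[itr])) < 2) return(NA_real_)
      f <- fit_logistic(x_tr[itr, , drop = FALSE], y_tr[itr], "none")
      p <- logistic_prob(x_tr[!itr, , drop = FALSE], f$slopes, f$intercept)
      sensitivity_of(y_tr[!itr], as.integer(p >= 0.5))
    })
    best_inner <- suppressWarnings(max(inner_sens, na.rm = TRUE))
    fit <- fit_logistic(x_tr, y_tr, "none")
  } else {
    galpha <- if (config$method == "l1") 1 else 0
    sens <- purrr::map(seq_len(config$inner_folds), function(fi) {
      itr <- inner != fi
      if (length(unique(y_tr[itr])) < 2 || min(table(y_tr[itr])) < 2) {
        return(rep(NA_real_, length(config$lambda_grid)))
      }
      fit <- suppressWarnings(
        glmnet::glmnet(glmnet_pad(x_tr[itr, , drop = FALSE]),
                       y_tr[itr], family = "binomial", alpha = galpha,
                       lambda = rev(config$lambda_grid),
                       standardize = FALSE))
      p <- stats::predict(fit, newx = glmnet_pad(x_tr[!itr, , drop = FALSE]),
                          s = config$lambda_grid, type = "response")
      apply(p, 2, function(pc) {
        sensitivity_of(y_tr[!itr], as.integer(pc >= 0.5))
      })
    })
    mean_sens <- colMeans(do.call(rbind, sens), na.rm = TRUE)
    mean_sens[is.nan(mean_sens)] <- -Inf
    # ties go to the largest (most parsimonious) lambda
    best_lam <- max(config$lambda_grid[mean_sens == max(mean_sens)])
    best_inner <- max(mean_sens)
    fit <- fit_logistic(x_tr, y_tr, config$method, lambda = best_lam)
  }
  p_val <- logistic_prob(x_val, fit$slopes, fit$intercept)
  val_sens <- sensitivity_of(y_val, as.integer(p_val >= 0.5))
  new_region_model(fit, validation_sensitivity = val_sens,
                   inner_sensitivity = best_inner)
}

#' Select the best candidate model by AIC
#'
#' Minimum AIC wins; ties are broken by the smaller parameter count, then
#' by the higher outer-validation sensitivity.
#'
#' @param candidates List of `region_model` candidates.
#' @return The selected `region_model`.
#' @export
select_best_model <- function(candidates) {
  if (length(candidates) == 0) rlang::abort("empty candidate list")
  aics <- purrr::map_dbl(candidates, "aic")
  np <- purrr::map_dbl(candidates, "n_params")
  vs <- purrr::map_dbl(candidates, ~ .x$validation_sensitivity %||% NA_real_)
  vs[is.na(vs)] <- -Inf
  candidates[[order(aics, np, -vs)[1]]]
}

#' Predict lesion presence for one region
#'
#' Evaluates the fitted logistic probability for each subject; the
#' presence class is predicted when P >= 0.5 (the boundary value counts as
#' presence, prioritizing sensitivity).
#'
#' @param model A `region_model`.
#' @param features Wide feature tibble holding the model's features.
#' @return A tibble with `subject_id`, `prob`, `pred`.
#' @export
predict_region <- function(model, features) {
  missing <- setdiff(model$features, names(features))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing required feature(s): ",
                        paste(utils::head(missing, 5), collapse = ", ")))
  }
  x <- as.matrix(features[, model$features, drop = FALSE])
  p <- logistic_prob(x, model$slopes, model$intercept)
  tibble::tibble(
    subject_id = features$subject_id %||% as.character(seq_len(nrow(x))),
    prob = p,
    pred = as.integer(p >= 0.5))
}

#' Fit lesion models for every region of a lesion table
#'
#' Binarizes each region's degrees, screens features (Kendall tau for the
#' unpenalized method; min-max normalization for the penalized ones), runs
#' [nested_cv_fit()] and [select_best_model()] per region, and records
#' regions that cannot be modeled (all-absent or all-present outcomes) as
#' unmodellable.
#'
#' @param lesion_tbl Wide lesion table (degrees or 0/1).
#' @param features Wide feature tibble (complete).
#' @param config A [fit_config()].
#' @param regions Optional subset of region column names to fit.
#' @return A `region_model_set`: list with `models` (named list of selected
#'   `region_model`s), `unmodellable` (character), `config`, and
#'   `candidate_counts`.
#' @export
fit_all_regions <- function(lesion_tbl, features, config = fit_config(),
                            regions = NULL) {
  stopifnot(identical(lesion_tbl$subject_id, features$subject_id))
  region_cols <- regions %||% setdiff(names(lesion_tbl), "subject_id")
  feats <- if (config$method == "none") features else
    normalize_features(features)
  models <- list()
  counts <- integer()
  unmodellable <- character()
  for (i in seq_along(region_cols)) {
    rg <- region_cols[i]
    y <- as.integer(lesion_tbl[[rg]] > 0)
    if (length(unique(y)) < 2) {
      unmodellable <- c(unmodellable, rg)
      next
    }
    cfg <- config
    cfg$seed <- config$seed + i
    if (config$method == "none") {
      sel <- select_features_kendall(feats, y, config$alpha)
      x <- as.matrix(feats[, sel, drop = FALSE])
    } else {
      x <- feature_matrix(feats)
    }
    cands <- nested_cv_fit(x, y, cfg)
    best <- select_best_model(cands)
    best$region_id <- rg
    models[[rg]] <- best
    counts[rg] <- length(cands)
  }
  structure(list(models = models, unmodellable = unmodellable,
                 config = config, candidate_counts = counts,
                 normalization = if (config$method == "none") NULL else
                   attr(feats, "normalization")),
            class = "region_model_set")
}

#' @export
print.region_model_set <- function(x, ...) {
  cat(sprintf("<region_model_set: %d modeled region(s), %d unmodellable, method %s>\n",
              length(x$models), length(x$unmodellable), x$config$method))
  invisible(x)
}

#' @export
tidy.region_model_set <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    tibble::tibble(region = as.character(m$region_id),
                   term = c("(Intercept)", m$features),
                   estimate = c(m$intercept, unname(m$slopes)))
  })
}

#' @export
glance.region_model_set <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    tibble::tibble(region = as.character(m$region_id), method = m$method,
                   n_features = length(m$features), aic = m$aic,
                   log_lik = m$log_lik,
                   validation_sensitivity = m$validation_sensitivity,
                   separation = m$separation)
  })
}

#' Predict lesion presence for every modeled region
#'
#' @param model_set A `region_model_set`.
#' @param features Wide feature tibble.
#' @return A wide 0/1 tibble (`subject_id` + one column per modeled region).
#' @export
predict_regions <- function(model_set, features) {
  stopifnot(inherits(model_set, "region_model_set"))
  feats <- if (is.null(model_set$normalization)) features else
    apply_normalization(model_set$normalization, features)
  preds <- purrr::map(model_set$models, function(m) {
    predict_region(m, feats)$pred
  })
  dplyr::bind_cols(tibble::tibble(subject_id = features$subject_id),
                   tibble::as_tibble(preds))
}
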