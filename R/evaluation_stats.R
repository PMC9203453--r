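#' Confusion-matrix performance of a binary prediction
#'
#' Accuracy counts both true absences and true presences; specificity is
#' the true-absence rate and sensitivity the true-presence rate. Ratios
#' with a zero denominator (e.g. sensitivity when a region has no true
#' presence) are reported as `NA`, never coerced to 0.
#'
#' @param truth,pred Equal-length binary 0/1 vectors.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `specificity`, `sensitivity`.
#' @export
confusion_metrics <- function(truth, pred) {
  if (length(truth) != length(pred)) rlang::abort("length mismatch")
  stopifnot(all(truth %in% c(0, 1)), all(pred %in% c(0, 1)))
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  tn <- sum(truth == 0 & pred == 0)
  fn <- sum(truth == 1 & pred == 0)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = ratio(tp + tn, tp + fp + tn + fn),
    specificity = ratio(tn, tn + fp),
    sensitivity = ratio(tp, tp + fn))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities of all
#' tables (with the observed margins) no more probable than the observed
#' one. A table with a zero margin carries no information and returns
#' p = 1 by convention.
#'
#' @param table A 2x2 matrix of nonnegative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' Kruskal-Wallis H test
#'
#' Tie-corrected H statistic with a chi-square p-value. Groups in which all
#' pooled values are identical are degenerate: H = 0, p = 1.
#'
#' @param groups List of numeric vectors (>= 2 groups, each nonempty).
#' @return A list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 1))
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Tukey-Kramer post-hoc comparisons on rank-transformed data
#'
#' Pairwise comparisons of group mean ranks using the studentized-range
#' distribution with Tukey-Kramer adjustment for unequal group sizes; the
#' usual follow-up to a significant Kruskal-Wallis test.
#'
#' @param groups Named (or unnamed) list of numeric vectors.
#' @param conf_level Family-wise confidence level (default 0.95).
#' @return A tibble with `group1`, `group2`, `mean_rank_diff`, `q`, `p`,
#'   `significant`.
#' @export
tukey_kramer_posthoc <- function(groups, conf_level = 0.95) {
  stopifnot(is.list(groups), length(groups) >= 2)
  k <- length(groups)
  nm <- names(groups) %||% as.character(seq_len(k))
  pooled <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  r <- rank(pooled)
  n_i <- lengths(groups)
  mean_r <- tapply(r, g, mean)
  big_n <- length(pooled)
  sse <- sum((r - mean_r[g])^2)
  df <- big_n - k
  s2 <- if (df > 0) sse / df else 0
  pairs <- utils::combn(k, 2)
  out <- purrr::map(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    diff <- mean_r[i1] - mean_r[i2]
    se <- sqrt(s2 / 2 * (1 / n_i[i1] + 1 / n_i[i2]))
    if (se == 0) {
      q <- 0; p <- 1
    } else {
      q <- abs(diff) / se
      p <- stats::ptukey(q, k, df, lower.tail = FALSE)
    }
    tibble::tibble(group1 = nm[i1], group2 = nm[i2],
                   mean_rank_diff = unname(diff), q = unname(q), p = p,
                   significant = p < 1 - conf_level)
  })
  dplyr::bind_rows(out)
}

#' Wilcoxon rank-sum test (normal approximation)
#'
#' Two-sided rank-sum test reporting the Mann-Whitney U statistic of the
#' first sample and a tie-corrected z score. No continuity correction is
#' applied, so the z score is exactly antisymmetric in the sample order.
#'
#' @param x,y Nonempty numeric vectors.
#' @return A list with `U`, `z`, `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  big_n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((big_n + 1) - tie_term / (big_n * (big_n - 1)))
  if (sigma2 <= 0) return(list(U = u, z = 0, p = 1))
  z <- (u - mu) / sqrt(sigma2)
  list(U = u, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Spearman rank correlation
#'
#' Rank correlation with tie handling (asymptotic p-value). A constant
#' vector makes the correlation undefined: both values are returned as
#' `NA`.
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return A list with `rho`, `p`.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

region_performance <- function(truth_tbl, pred_tbl, regions) {
  purrr::map_dfr(regions, function(rg) {
    cm <- confusion_metrics(truth_tbl[[rg]], pred_tbl[[rg]])
    cm$fisher_p <- fisher_exact_2x2(matrix(c(cm$tn, cm$fn, cm$fp, cm$tp), 2))
    dplyr::bind_cols(tibble::tibble(region = rg), cm)
  })
}

#' Evaluate lesion predictions against true occurrences
#'
#' Computes per-region confusion metrics and Fisher's exact association
#' p-values for the complete cohort and, when subset labels are supplied,
#' within each subset. When several methods' predictions are given (a named
#' list), their per-region metric distributions are compared by
#' Kruskal-Wallis with Tukey-Kramer post-hoc. Optionally compares
#' modified-estimation against direct-estimation sensitivities (rank-sum)
#' and correlates per-region dispersion (CV) between true and predicted
#' subsets (Spearman).
#'
#' @param truth_tbl Wide 0/1 table of true occurrences.
#' @param predictions Wide 0/1 prediction table, or a named list of them
#'   (one per method).
#' @param subsets Optional tibble with `subject_id`, `subset`.
#' @param lesion_tbl Optional wide degree table (for CV correlations).
#' @param predicted_subsets Optional tibble with `subject_id`, `subset`
#'   predicted from non-imaging data (for CV correlations).
#' @param modified,direct Optional named lists with elements `truth` and
#'   `pred` (coarse 0/1 tables) for the modified-vs-direct comparison.
#' @return A `lesion_evaluation` list with tibbles `per_region`, `summary`,
#'   and (when inputs allow) `method_comparison`, `modified_vs_direct`,
#'   `cv_correlation`.
#' @export
evaluate_pipeline <- function(truth_tbl, predictions, subsets = NULL,
                              lesion_tbl = NULL, predicted_subsets = NULL,
                              modified = NULL, direct = NULL) {
  if (is.data.frame(predictions)) predictions <- list(fit = predictions)
  regions <- setdiff(names(truth_tbl), "subject_id")
  per_region <- purrr::imap_dfr(predictions, function(pred_tbl, meth) {
    if (!identical(pred_tbl$subject_id, truth_tbl$subject_id)) {
      rlang::abort("misaligned subject ids between truth and predictions")
    }
    shared <- intersect(regions, names(pred_tbl))
    all_tbl <- dplyr::bind_cols(tibble::tibble(method = meth,
                                               subset = "all"),
                                region_performance(truth_tbl, pred_tbl,
                                                   shared))
    if (is.null(subsets)) return(all_tbl)
    sub_tbl <- purrr::map_dfr(sort(unique(subsets$subset)), function(s) {
      ids <- subsets$subject_id[subsets$subset == s]
      sel <- truth_tbl$subject_id %in% ids
      dplyr::bind_cols(
        tibble::tibble(method = meth, subset = as.character(s)),
        region_performance(truth_tbl[sel, ], pred_tbl[sel, ], shared))
    })
    dplyr::bind_rows(all_tbl, sub_tbl)
  })
  summary <- dplyr::summarise(
    dplyr::group_by(per_region, .data$method, .data$subset),
    dplyr::across(c("accuracy", "specificity", "sensitivity"),
                  ~ stats::median(.x, na.rm = TRUE), .names = "median_{.col}"),
    n_regions = dplyr::n(), .groups = "drop")

  method_comparison <- NULL
  if (length(predictions) > 1) {
    overall <- dplyr::filter(per_region, .data$subset == "all")
    method_comparison <- purrr::map_dfr(
      c("accuracy", "specificity", "sensitivity"), function(metric) {
        groups <- split(overall[[metric]], overall$method)
        groups <- purrr::map(groups, ~ .x[!is.na(.x)])
        kw <- kruskal_wallis(groups)
        tibble::tibble(metric = metric, H = kw$H, df = kw$df, p = kw$p,
                       posthoc = list(tukey_kramer_posthoc(groups)))
      })
  }

  modified_vs_direct <- NULL
  if (!is.null(modified) && !is.null(direct)) {
    perf_m <- region_performance(modified$truth, modified$pred,
                                 setdiff(names(modified$truth), "subject_id"))
    perf_d <- region_performance(direct$truth, direct$pred,
                                 setdiff(names(direct$truth), "subject_id"))
    modified_vs_direct <- purrr::map_dfr(
      c("accuracy", "specificity", "sensitivity"), function(metric) {
        a <- perf_m[[metric]][!is.na(perf_m[[metric]])]
        b <- perf_d[[metric]][!is.na(perf_d[[metric]])]
        if (length(a) == 0 || length(b) == 0) {
          return(tibble::tibble(metric = metric, z = NA_real_, p = NA_real_))
        }
        w <- wilcoxon_rank_sum(a, b)
        tibble::tibble(metric = metric, z = w$z, p = w$p)
      })
  }

  cv_correlation <- NULL
  if (!is.null(lesion_tbl) && !is.null(subsets) &&
      !is.null(predicted_subsets)) {
    cv_correlation <- purrr::map_dfr(sort(unique(subsets$subset)),
                                     function(s) {
      true_ids <- subsets$subject_id[subsets$subset == s]
      pred_ids <- predicted_subsets$subject_id[predicted_subsets$subset == s]
      if (length(true_ids) < 2 || length(pred_ids) < 2) {
        return(tibble::tibble(subset = as.character(s), rho = NA_real_,
                              p = NA_real_))
      }
      cv_t <- region_cv(lesion_tbl[lesion_tbl$subject_id %in% true_ids, ])
      cv_p <- region_cv(lesion_tbl[lesion_tbl$subject_id %in% pred_ids, ])
      sp <- spearman_corr(cv_t$cv, cv_p$cv)
      tibble::tibble(subset = as.character(s), rho = sp$rho, p = sp$p)
    })
  }

  structure(list(per_region = per_region, summary = summary,
                 method_comparison = method_comparison,
                 modified_vs_direct = modified_vs_direct,
                 cv_correlation = cv_correlation),
            class = "lesion_evaluation")
}

#' @export
print.lesion_evaluation <- function(x, ...) {
  cat("<lesion_evaluation>\n")
  print(x$summary)
  invisible(x)
}
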