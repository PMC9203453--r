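feature_tbl <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%02d", seq_len(nrow(m)))),
    tibble::as_tibble(m))
}

test_that("missingness filter drops by fraction and median-imputes the rest", {
  m <- matrix(stats::rnorm(200), 20, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  m[, "f1"] <- NA               # 100% missing
  m[1:3, "f2"] <- NA            # 3/20 = 0.15 missing
  tbl <- feature_tbl(m)
  out <- drop_sparse_features(tbl, max_missing = 0.2)
  expect_true("f1" %in% attr(out, "dropped_features"))
  expect_true("f2" %in% names(out))
  expect_false(anyNA(out))
  expect_equal(out$f2[1], stats::median(m[4:20, "f2"]))
  # 3 of 10 missing exceeds the threshold
  m2 <- m[1:10, c("f2", "f3")]
  m2[1:3, 1] <- NA
  out2 <- drop_sparse_features(feature_tbl(m2), max_missing = 0.2)
  expect_true("f2" %in% attr(out2, "dropped_features"))
  # clean table passes through unchanged
  clean <- feature_tbl(matrix(1:40 + 0, 10, 4,
                              dimnames = list(NULL, paste0("g", 1:4))))
  expect_equal(drop_sparse_features(clean, 0.2), clean,
               ignore_attr = TRUE)
})

test_that("Kruskal-Wallis screen keeps signal, drops constants, respects alpha bounds", {
  set.seed(21)
  g <- rep(1:3, each = 20)
  m <- cbind(signal = g + stats::rnorm(60, sd = 0.1),
             flat = rep(1, 60),
             noise = stats::rnorm(60))
  tbl <- feature_tbl(m)
  out <- screen_features_kw(tbl, g, alpha = 0.05)
  scr <- attr(out, "kw_screen")
  expect_true("signal" %in% names(out))
  expect_false("flat" %in% names(out))
  expect_equal(scr$H[scr$feature == "flat"], 0)
  expect_equal(scr$p[scr$feature == "flat"], 1)
  # alpha = 1 keeps everything with p < 1; alpha -> 0 keeps nothing
  all_kept <- screen_features_kw(tbl[, c("subject_id", "signal", "noise")],
                                 g, alpha = 1)
  expect_equal(setdiff(names(all_kept), "subject_id"), c("signal", "noise"))
  none <- screen_features_kw(tbl, g, alpha = 1e-300)
  expect_equal(setdiff(names(none), "subject_id"), character(0))
})

test_that("null features pass the screen at about the nominal rate", {
  set.seed(33)
  g <- rep(1:3, each = 15)
  n_rep <- 400
  hits <- 0
  for (i in seq_len(n_rep)) {
    x <- stats::rnorm(45)
    kw <- kruskal_wallis(split(x, g))
    if (kw$p < 0.05) hits <- hits + 1
  }
  rate <- hits / n_rep
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("PCA retains the minimal component set for the variance target", {
  set.seed(5)
  base <- stats::rnorm(50)
  two <- feature_tbl(cbind(a = base, b = 3 * base + 2))
  expect_equal(reduce_dimensions(two, 0.95)$n_components, 1)
  iso <- feature_tbl(matrix(stats::rnorm(5 * 500), 500, 5,
                            dimnames = list(NULL, paste0("v", 1:5))))
  expect_equal(reduce_dimensions(iso, 0.95)$n_components, 5)
  # component count is monotone in the variance target
  corr_m <- matrix(stats::rnorm(300), 100, 3) %*%
    matrix(stats::rnorm(18), 3, 6) +
    0.2 * matrix(stats::rnorm(600), 100, 6)
  colnames(corr_m) <- paste0("c", 1:6)
  corr <- feature_tbl(corr_m)
  ks <- vapply(c(0.5, 0.8, 0.95, 0.999), function(v) {
    reduce_dimensions(corr, v)$n_components
  }, 0L)
  expect_true(all(diff(ks) >= 0))
})

test_that("full-rank PCA reconstructs the standardized data", {
  set.seed(6)
  tbl <- feature_tbl(matrix(stats::rnorm(120), 20, 6,
                            dimnames = list(NULL, paste0("v", 1:6))))
  red <- reduce_dimensions(tbl, variance_target = 1)
  z <- scale(as.matrix(tbl[, -1]))
  recon <- as.matrix(red$scores[, -1]) %*% t(red$rotation)
  expect_equal(unname(recon), unname(z[, ]), tolerance = 1e-8)
  # projection of the training data reproduces the training scores
  again <- predict(red, tbl)
  expect_equal(as.matrix(again[, -1]), as.matrix(red$scores[, -1]),
               tolerance = 1e-10)
})

test_that("multiclass MCC matches the formula oracle and its conventions", {
  perfect <- diag(c(10, 20, 30))
  expect_equal(multiclass_mcc(perfect), 1)
  onecol <- matrix(c(10, 0, 0, 12, 0, 0, 8, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(multiclass_mcc(onecol), 0)
  cm <- matrix(c(50, 5, 5, 5, 50, 5, 5, 5, 50), 3, 3, byrow = TRUE)
  expect_equal(multiclass_mcc(cm), naive_mcc(cm))
  set.seed(12)
  for (i in 1:20) {
    cm <- matrix(stats::rpois(9, 8), 3, 3)
    expect_equal(multiclass_mcc(cm), naive_mcc(cm))
  }
  # invariant under simultaneous row/column permutation
  cm <- matrix(stats::rpois(9, 10), 3, 3)
  perm <- c(3, 1, 2)
  expect_equal(multiclass_mcc(cm[perm, perm]), multiclass_mcc(cm))
  expect_error(multiclass_mcc(matrix(numeric(0), 0, 0)), "empty")
})

sep_scores <- function(n_per = 30, seed = 4) {
  withr::with_seed(seed, {
    m <- rbind(
      cbind(stats::rnorm(n_per, -4), stats::rnorm(n_per, 0)),
      cbind(stats::rnorm(n_per, 4), stats::rnorm(n_per, -4)),
      cbind(stats::rnorm(n_per, 4), stats::rnorm(n_per, 4)))
    colnames(m) <- c("PC1", "PC2")
    list(scores = feature_tbl(m), labels = rep(1:3, each = n_per))
  })
}

test_that("tuned forest separates well-separated classes and is deterministic", {
  d <- sep_scores()
  grid <- tibble::tibble(num_trees = 100L, max_depth = c(0L, 5L),
                         mtry_rule = "sqrt")
  fit1 <- fit_subset_classifier(d$scores, d$labels, seed = 2, grid = grid,
                                resamples = 5)
  expect_gte(fit1$best$mcc, 0.9)
  pred <- predict_subset(fit1, d$scores)
  expect_equal(mean(pred$subset == d$labels), 1.0)
  fit2 <- fit_subset_classifier(d$scores, d$labels, seed = 2, grid = grid,
                                resamples = 5)
  expect_identical(fit2$best, fit1$best)
  expect_identical(predict_subset(fit2, d$scores)$subset, pred$subset)
  expect_equal(nrow(tidy(fit1)), 2)
  expect_true(all(c("mcc", "correct_rate") %in% names(glance(fit1))))
})

test_that("permuted labels give tuning MCC near zero", {
  d <- sep_scores(n_per = 25, seed = 10)
  perm <- withr::with_seed(31, sample(d$labels))
  grid <- tibble::tibble(num_trees = 100L, max_depth = 0L,
                         mtry_rule = "sqrt")
  fit <- fit_subset_classifier(d$scores, perm, seed = 3, grid = grid,
                               resamples = 25)
  expect_lt(abs(fit$best$mcc), 0.15)
})

test_that("end-to-end subset model beats the majority rate on signal cohorts", {
  tc <- tiny_cohort(seed = 12, n = c(15, 15, 15), n_regions = 14)
  spec <- tc$spec
  feat <- generate_features(tc$cohort, spec)
  ch <- characterize_lesions(tc$cohort$lesions, tc$atlas)
  cl <- cluster_subjects(ch, seed = 1)
  grid <- tibble::tibble(num_trees = 100L, max_depth = 0L,
                         mtry_rule = "sqrt")
  sm <- train_subset_model(feat$features, cl, seed = 1, grid = grid,
                           resamples = 5)
  pred <- predict_subset(sm, feat$features)
  majority <- max(table(cl$subset)) / nrow(cl)
  expect_gt(mean(pred$subset == cl$subset), majority)
})
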