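feat_tbl <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%03d", seq_len(nrow(m)))),
    tibble::as_tibble(m))
}

test_that("Kendall screen keeps concordant features and drops constants", {
  set.seed(14)
  y <- rep(c(0, 1), each = 20)
  tbl <- feat_tbl(cbind(same = y, flat = rep(2, 40),
                        noise = stats::rnorm(40)))
  sel <- select_features_kendall(tbl, y, alpha = 0.05)
  expect_true("same" %in% sel)
  expect_false("flat" %in% sel)
  scr <- attr(sel, "kendall_screen")
  expect_true(is.na(scr$tau[scr$feature == "flat"]))
  expect_error(select_features_kendall(tbl, rep(1, 40)), "single class")
})

test_that("Kendall tau-b matches pair-counting on printed toy rows", {
  x <- c(12, 2, 1, 12, 2, 9, 7, 4)
  y <- c(1, 4, 7, 1, 0, 8, 6, 3)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  expect_equal(unname(ct$estimate), naive_kendall_tau_b(x, y))
  set.seed(2)
  for (i in 1:15) {
    n <- sample(5:30, 1)
    a <- sample(0:6, n, replace = TRUE)       # heavy ties
    b <- sample(0:1, n, replace = TRUE)       # binary outcome side
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    ct <- suppressWarnings(stats::cor.test(a, b, method = "kendall"))
    expect_equal(unname(ct$estimate), naive_kendall_tau_b(a, b))
  }
})

test_that("min-max normalization maps to [0,1], flags constants, replays on new data", {
  tbl <- feat_tbl(cbind(a = c(2, 4, 6), b = c(0, 0.5, 1), k = c(3, 3, 3)))
  out <- normalize_features(tbl)
  expect_equal(out$a, c(0, 0.5, 1))
  expect_equal(out$b, c(0, 0.5, 1))
  expect_false("k" %in% names(out))
  expect_equal(attr(out, "constant_features"), "k")
  norm <- attr(out, "normalization")
  new <- feat_tbl(cbind(a = c(8, 1), b = c(0.25, 2), k = c(1, 1)))
  replay <- apply_normalization(norm, new)
  expect_equal(replay$a, c(1.5, -0.25))  # outside the training range, un-clipped
  expect_equal(replay$b, c(0.25, 2))
})

test_that("logistic probabilities follow the model formula", {
  # zero coefficients: P = 0.5 everywhere
  f0 <- fit_logistic(matrix(0, 10, 0), rep(c(0, 1), 5), "none")
  m0 <- lesioncast:::new_region_model(f0)
  p0 <- predict_region(m0, feat_tbl(matrix(stats::rnorm(10), 10, 1,
                                           dimnames = list(NULL, "x"))))
  expect_equal(p0$prob, rep(0.5, 10))
  expect_equal(p0$pred, rep(1L, 10))  # boundary P = 0.5 counts as presence
  # a = 1, b = 0, x = 1 -> 1/(1+e^-1)
  m <- lesioncast:::new_region_model(list(
    slopes = c(x = 1), intercept = 0, log_lik = 0, n_params = 2,
    aic = 4, method = "none", lambda = NULL, separation = FALSE))
  pr <- predict_region(m, feat_tbl(matrix(1, 1, 1,
                                          dimnames = list(NULL, "x"))))
  expect_equal(pr$prob, 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(pr$prob, naive_logistic_p(1, 1, 0))
})

test_that("logistic symmetry: z and -z give P and 1-P", {
  set.seed(3)
  x <- matrix(stats::rnorm(20), 20, 1, dimnames = list(NULL, "x"))
  mp <- lesioncast:::new_region_model(list(
    slopes = c(x = 1.3), intercept = 0.4, log_lik = 0, n_params = 2,
    aic = 4, method = "none", lambda = NULL, separation = FALSE))
  mn <- lesioncast:::new_region_model(list(
    slopes = c(x = -1.3), intercept = -0.4, log_lik = 0, n_params = 2,
    aic = 4, method = "none", lambda = NULL, separation = FALSE))
  pp <- predict_region(mp, feat_tbl(x))$prob
  pn <- predict_region(mn, feat_tbl(x))$prob
  expect_equal(pp + pn, rep(1, 20), tolerance = 1e-12)
})

test_that("maximum-likelihood fit agrees with glm and caps separation", {
  set.seed(4)
  x <- matrix(stats::rnorm(120), 60, 2, dimnames = list(NULL, c("u", "v")))
  y <- stats::rbinom(60, 1, plogis(0.8 * x[, 1] - 0.5))
  f <- fit_logistic(x, y, "none")
  ref <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(unname(f$intercept), unname(stats::coef(ref)[1]),
               tolerance = 1e-6)
  expect_equal(unname(f$slopes), unname(stats::coef(ref)[-1]),
               tolerance = 1e-6)
  expect_equal(f$log_lik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_equal(f$aic, stats::AIC(ref), tolerance = 1e-6)
  # perfectly separated outcome: capped, flagged, finite
  xs <- matrix(c(-(10:1), 1:10), 20, 1, dimnames = list(NULL, "s"))
  ys <- c(rep(0, 10), rep(1, 10))
  fs <- fit_logistic(xs, ys, "none")
  expect_true(fs$separation)
  expect_true(all(abs(c(fs$slopes, fs$intercept)) <= 20))
})

test_that("very large L1 penalty shrinks all slopes to zero", {
  set.seed(5)
  x <- matrix(stats::rnorm(150), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- stats::rbinom(50, 1, plogis(x[, 1]))
  f <- fit_logistic(x, y, "l1", lambda = 100)
  expect_equal(unname(f$slopes), c(0, 0, 0))
  expect_equal(f$n_params, 1L)
  # L1 nonzero count never increases with lambda
  nz <- vapply(c(0.001, 0.01, 0.1, 1), function(l) {
    sum(fit_logistic(x, y, "l1", lambda = l)$slopes != 0)
  }, 0L)
  expect_true(all(diff(nz) <= 0))
})

test_that("AIC follows 2k - 2lnL", {
  expect_equal(aic(0, 2), 4)
  expect_equal(aic(-10, 3), 26)
  expect_equal(aic(-5, 4) - aic(-5, 3), 2)
})

test_that("model selection minimizes AIC with parsimony tie-breaks", {
  mk <- function(a, k, vs = 0.5) lesioncast:::new_region_model(list(
    slopes = stats::setNames(rep(0.1, k - 1), paste0("f", seq_len(k - 1))),
    intercept = 0, log_lik = (2 * k - a) / 2, n_params = k, aic = a,
    method = "none", lambda = NULL, separation = FALSE),
    validation_sensitivity = vs)
  one <- mk(10, 2)
  expect_identical(select_best_model(list(one)), one)
  picked <- select_best_model(list(mk(10.2, 2), mk(9.8, 3), mk(11, 2)))
  expect_equal(picked$aic, 9.8)
  tie <- select_best_model(list(mk(7, 3), mk(7, 2)))
  expect_equal(tie$n_params, 2)
  tie2 <- select_best_model(list(mk(7, 2, vs = 0.2), mk(7, 2, vs = 0.9)))
  expect_equal(tie2$validation_sensitivity, 0.9)
  expect_error(select_best_model(list()), "empty")
})

sim_region <- function(n, n_pres, p = 4, seed = 6) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    y <- c(rep(1, n_pres), rep(0, n - n_pres))
    x[y == 1, 1] <- x[y == 1, 1] + 2
    list(x = x, y = y)
  })
}

test_that("candidate counts follow the resampling scheme", {
  d <- sim_region(67, 20)
  cfg <- fit_config(resamples = 5, seed = 2)
  cands <- nested_cv_fit(d$x, d$y, cfg)
  expect_length(cands, 5 * 4)
  expect_true(all(vapply(cands, function(m) is.finite(m$aic), TRUE)))
  # below the presence floor: one model, no CV
  d3 <- sim_region(50, 3)
  single <- nested_cv_fit(d3$x, d3$y, cfg)
  expect_length(single, 1)
  expect_true(is.na(single[[1]]$repeat_idx))
})

test_that("nested CV is deterministic under a fixed seed", {
  d <- sim_region(40, 12)
  cfg <- fit_config(resamples = 3, seed = 11)
  a <- nested_cv_fit(d$x, d$y, cfg)
  b <- nested_cv_fit(d$x, d$y, cfg)
  expect_equal(a, b)
  expect_identical(select_best_model(a), select_best_model(b))
})

test_that("penalized nested CV tunes lambda and yields candidates", {
  d <- sim_region(48, 16)
  cfg <- fit_config(method = "l1", resamples = 2, seed = 3,
                    lambda_grid = 10^seq(-3, 1, length.out = 8))
  cands <- nested_cv_fit(d$x, d$y, cfg)
  expect_length(cands, 8)
  expect_true(all(vapply(cands, function(m) m$lambda %in% cfg$lambda_grid,
                         TRUE)))
  best <- select_best_model(cands)
  expect_true(is.finite(best$aic))
})

test_that("coefficient bias shrinks as the sample grows", {
  truth <- c(1.5, -1)
  fit_at <- function(n, seed) {
    withr::with_seed(seed, {
      x <- matrix(stats::rnorm(n * 2), n, 2,
                  dimnames = list(NULL, c("a", "b")))
      y <- stats::rbinom(n, 1, stats::plogis(x %*% truth - 0.5))
      fit_logistic(x, y, "none")$slopes
    })
  }
  err <- function(n) {
    mean(vapply(1:8, function(s) {
      sum(abs(fit_at(n, s) - truth))
    }, 0))
  }
  expect_lt(err(1000), err(100))
})

test_that("fit_all_regions models every modellable region from screened features", {
  tc <- tiny_cohort(seed = 21, n = c(10, 10, 10), n_regions = 8)
  spec <- tc$spec
  feat <- generate_features(tc$cohort, spec)
  imp <- drop_sparse_features(feat$features, 0.2)
  cfg <- fit_config(resamples = 2, seed = 5)
  ms <- fit_all_regions(tc$cohort$lesions, imp, cfg)
  bin <- binarize_lesions(tc$cohort$lesions)
  modellable <- names(which(vapply(bin[, -1], function(v) {
    length(unique(v)) == 2
  }, TRUE)))
  expect_setequal(names(ms$models), modellable)
  expect_setequal(ms$unmodellable,
                  setdiff(names(bin)[-1], modellable))
  # method "none": selected features passed the Kendall screen per region
  for (rg in utils::head(names(ms$models), 3)) {
    y <- as.integer(tc$cohort$lesions[[rg]] > 0)
    sel <- select_features_kendall(imp, y, cfg$alpha)
    expect_true(all(ms$models[[rg]]$features %in% sel))
  }
  td <- tidy(ms)
  expect_true(all(c("region", "term", "estimate") %in% names(td)))
  gl <- glance(ms)
  expect_true(all(is.finite(gl$aic)))
})

test_that("predictions are consistent with the 0.5 threshold everywhere", {
  tc <- tiny_cohort(seed = 22, n = c(8, 8, 8), n_regions = 8)
  feat <- generate_features(tc$cohort, tc$spec)
  imp <- drop_sparse_features(feat$features, 0.2)
  ms <- fit_all_regions(tc$cohort$lesions, imp,
                        fit_config(resamples = 2, seed = 5))
  for (rg in names(ms$models)) {
    pr <- predict_region(ms$models[[rg]], imp)
    expect_true(all(pr$prob >= 0 & pr$prob <= 1))
    expect_identical(pr$pred, as.integer(pr$prob >= 0.5))
  }
})
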