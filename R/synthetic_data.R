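#' Specification of a synthetic stroke cohort
#'
#' Encodes the study conditions the generator emulates: three planted
#' subsets distinguished by lesion occurrence and spatial spread, lesion
#' degrees drawn from a right-skewed distribution, and a non-imaging
#' feature table in which a subset of features carries a logistic signal
#' about region-wise lesion presence.
#'
#' Defaults mirror the cohort the pipeline was designed around: subset
#' sizes 67/86/42, subset-1 subjects carrying 1-3 spatially adjacent
#' lesions (about a third with a single lesion), subset-2 moderate counts,
#' subset-3 high counts spread widely, and degrees conditional on presence
#' drawn from `100 * Beta(0.8, 5)`.
#'
#' @param n_subjects Integer vector of planted subset sizes.
#' @param lesion_counts List of `c(min, max)` lesioned-region counts per
#'   subset.
#' @param single_lesion_fraction Fraction of each subset's subjects forced
#'   to a single lesioned region.
#' @param sparsity_targets List of `c(lo, hi)` per subset: each subject's
#'   lesion set is grown so its mean normalized inter-lesion distance lands
#'   near a target drawn uniformly from this range. Low targets plant
#'   spatially compact lesions, high targets widely spread ones.
#' @param degree_shape `c(alpha, beta)` of the Beta distribution of
#'   degree/100 conditional on presence.
#' @param feature_counts Named integer vector: features per clinical test
#'   family.
#' @param n_informative Informative features per region.
#' @param effect_size Logistic shift (in baseline-SD units) separating
#'   presence from absence subjects on informative features.
#' @param nuisance_loading Loading of a shared severity factor on a random
#'   30% of features.
#' @param missing_rate Fraction of feature cells set missing at random.
#' @param seed Integer seed (mandatory).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = c(67, 86, 42),
                        lesion_counts = list(c(1, 3), c(4, 14), c(15, 37)),
                        single_lesion_fraction = c(23 / 67, 0, 0),
                        sparsity_targets = list(c(0, 0.15), c(0.18, 0.36),
                                                c(0.40, 0.50)),
                        degree_shape = c(0.8, 5),
                        feature_counts = default_feature_counts(),
                        n_informative = 2,
                        effect_size = 2,
                        nuisance_loading = 0.3,
                        missing_rate = 0.05,
                        seed = NULL) {
  if (is.null(seed)) rlang::abort("cohort_spec requires an explicit seed")
  stopifnot(length(n_subjects) == length(lesion_counts),
            length(n_subjects) == length(single_lesion_fraction),
            length(n_subjects) == length(sparsity_targets),
            all(n_subjects > 0), all(feature_counts > 0),
            is.finite(effect_size), missing_rate >= 0, missing_rate < 1)
  structure(list(n_subjects = n_subjects, lesion_counts = lesion_counts,
                 single_lesion_fraction = single_lesion_fraction,
                 sparsity_targets = sparsity_targets,
                 degree_shape = degree_shape,
                 feature_counts = feature_counts,
                 n_informative = n_informative, effect_size = effect_size,
                 nuisance_loading = nuisance_loading,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Per-test feature counts of the default non-imaging battery
#'
#' Feature families carry the names of the standard clinical batteries
#' (BIT, CAT, MMSE, RBMT, TMT, BRS, FIM, apathy, HADS, JPSS, medication,
#' metabolite panels, fundamental/demographic data) purely for realistic
#' I/O; all counts are configurable.
#'
#' @return A named integer vector.
#' @export
default_feature_counts <- function() {
  c(Fundamental = 10L, BIT = 30L, CAT = 65L, MMSE = 23L, RBMT = 26L,
    TMT = 4L, BRS = 3L, FIM = 23L, Apathy = 15L, HADS = 16L, JPSS = 15L,
    Medication = 7L, Metabolite = 13L)
}

#' Generate a random region atlas with a three-level hierarchy
#'
#' Samples region centroids in a brain-sized box and partitions them into
#' lobes and hemispheric divisions by k-means on the centroids, so the
#' hierarchy is total and spatially coherent. `preset = "aal-like"` returns
#' the bundled 116/18/5 registry instead.
#'
#' @param n_regions Number of regions (>= 4).
#' @param seed Integer seed.
#' @param n_level2,n_level1 Level sizes; defaults scale with `n_regions`.
#' @param preset `"aal-like"` for the bundled registry.
#' @return A [region_atlas()].
#' @export
generate_atlas <- function(n_regions, seed = 1, n_level2 = NULL,
                           n_level1 = NULL, preset = NULL) {
  if (!is.null(preset)) {
    preset <- rlang::arg_match(preset, "aal-like")
    return(default_atlas())
  }
  stopifnot(n_regions >= 4)
  n_level2 <- n_level2 %||% max(2L, round(n_regions / 6))
  n_level1 <- n_level1 %||% max(2L, min(5L, round(n_level2 / 3)))
  stopifnot(n_level2 <= n_regions, n_level1 <= n_level2)
  withr::with_seed(seed, {
    cents <- cbind(cx = stats::runif(n_regions, -70, 70),
                   cy = stats::runif(n_regions, -100, 70),
                   cz = stats::runif(n_regions, -60, 80))
    lobes <- stats::kmeans(cents, centers = n_level2, nstart = 5)
    hemis <- if (n_level1 == n_level2) seq_len(n_level2) else
      stats::kmeans(lobes$centers, centers = n_level1, nstart = 5)$cluster
    region_atlas(tibble::tibble(
      region_id = seq_len(n_regions),
      name = sprintf("R%03d", seq_len(n_regions)),
      cx = round(cents[, 1], 2), cy = round(cents[, 2], 2),
      cz = round(cents[, 3], 2),
      level2_parent = sprintf("L2_%02d", lobes$cluster),
      level1_parent = sprintf("L1_%02d", hemis[lobes$cluster])))
  })
}

# grow a lesioned set toward a target mean inter-lesion distance:
# seed one region, then repeatedly add a region chosen among the few whose
# inclusion keeps the running mean normalized distance closest to `target`
grow_lesion_set <- function(w, n_lesions, target) {
  n <- nrow(w)
  current <- sample.int(n, 1)
  pair_sum <- 0
  while (length(current) < n_lesions) {
    rest <- setdiff(seq_len(n), current)
    add_d <- colSums(w[current, rest, drop = FALSE])
    k <- length(current)
    new_mean <- (pair_sum + add_d) / choose(k + 1, 2)
    gap <- abs(new_mean - target)
    pick <- rest[order(gap)][sample.int(min(3L, length(rest)), 1)]
    pair_sum <- pair_sum + sum(w[pick, current])
    current <- c(current, pick)
  }
  current
}

#' Generate a synthetic lesion cohort
#'
#' Plants the subset structure of `spec` on `atlas`: per subject, a
#' lesioned-region count is drawn from the subset's range, the lesioned set
#' is grown around a random seed region with the subset's spatial spread,
#' and degrees conditional on presence are drawn from the right-skewed
#' Beta distribution. Achieved occurrence and sparsity are computed with
#' the same statistics the analysis uses and returned with the planted
#' labels.
#'
#' @param spec A [cohort_spec()].
#' @param atlas A [region_atlas()].
#' @return A list with `lesions` (wide degree table), `truth` (tibble:
#'   `subject_id`, `subset`, `n_lesioned`, `occurrence`, `sparsity`), and
#'   `dist` (the normalized distance matrix used).
#' @export
generate_cohort <- function(spec, atlas) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(atlas, "region_atlas"))
  nr <- atlas$n_regions
  if (max(purrr::map_dbl(spec$lesion_counts, max)) > nr) {
    rlang::abort("infeasible spec: lesion count range exceeds region count")
  }
  w <- build_distance_matrix(atlas)
  rows <- withr::with_seed(spec$seed, {
    purrr::imap(spec$n_subjects, function(ns, s) {
      n_single <- round(spec$single_lesion_fraction[s] * ns)
      purrr::map(seq_len(ns), function(i) {
        rng <- spec$lesion_counts[[s]]
        # forced single-lesion subjects are the only ones with one lesion
        lo <- max(rng[1], if (n_single > 0) 2 else 1)
        n_les <- if (i <= n_single) 1L else
          if (lo >= rng[2]) rng[2] else sample(lo:rng[2], 1)
        tgt <- stats::runif(1, spec$sparsity_targets[[s]][1],
                            spec$sparsity_targets[[s]][2])
        idx <- grow_lesion_set(w, n_les, tgt)
        deg <- numeric(nr)
        deg[idx] <- 100 * stats::rbeta(length(idx), spec$degree_shape[1],
                                       spec$degree_shape[2])
        list(subset = s, degrees = deg)
      })
    })
  })
  rows <- purrr::flatten(rows)
  deg_m <- do.call(rbind, purrr::map(rows, "degrees"))
  colnames(deg_m) <- atlas$regions$name
  ids <- sprintf("S%03d", seq_len(nrow(deg_m)))
  lesions <- dplyr::bind_cols(tibble::tibble(subject_id = ids),
                              tibble::as_tibble(deg_m))
  ch <- characterize_lesions(lesions, atlas, dist = w)
  truth <- dplyr::bind_cols(
    tibble::tibble(subject_id = ids,
                   subset = purrr::map_int(rows, ~ as.integer(.x$subset))),
    ch[, c("n_lesioned", "occurrence", "sparsity")])
  list(lesions = lesions, truth = truth, dist = w)
}

#' Generate a non-imaging feature table carrying lesion signal
#'
#' For each atlas region, `n_informative` features (drawn from the
#' non-metabolite families) are shifted by the planted logistic effect in
#' subjects where that region is lesioned; a shared severity factor loads
#' on a random 30% of features; the remaining variation is noise.
#' Missing values are injected completely at random. The ground-truth map
#' of which feature informs which region (and with what slope) is returned
#' so recovery can be scored without re-reading generator internals.
#'
#' @param cohort Output of [generate_cohort()] (or a wide lesion table).
#' @param spec The [cohort_spec()] used to build the cohort.
#' @return A list with `features` (wide tibble with `NA`s), `truth_map`
#'   (tibble: `region`, `feature`, `beta`), and `feature_info` (tibble:
#'   `feature`, `test`).
#' @export
generate_features <- function(cohort, spec) {
  lesions <- if (is.data.frame(cohort)) cohort else cohort$lesions
  pres <- as.matrix(
    dplyr::select(binarize_lesions(lesions), -dplyr::all_of("subject_id")))
  n <- nrow(pres)
  counts <- spec$feature_counts
  info <- tibble::tibble(
    test = rep(names(counts), counts),
    feature = unlist(purrr::imap(counts,
                                 ~ sprintf("%s_%02d", .y, seq_len(.x)))))
  p <- nrow(info)
  if (spec$n_informative > sum(info$test != "Metabolite")) {
    rlang::abort("more informative features requested than available")
  }
  withr::with_seed(spec$seed + 1L, {
    base_mean <- stats::rnorm(p, 0, 2)
    x <- matrix(stats::rnorm(n * p), n, p) +
      matrix(base_mean, n, p, byrow = TRUE)
    colnames(x) <- info$feature
    severity <- as.vector(scale(rowSums(pres)))
    loaded <- sample.int(p, round(0.3 * p))
    x[, loaded] <- x[, loaded] + spec$nuisance_loading *
      matrix(severity, n, length(loaded))
    pool <- which(info$test != "Metabolite")
    truth_map <- purrr::map_dfr(colnames(pres), function(rg) {
      fsel <- sample(pool, spec$n_informative)
      beta <- sample(c(-1, 1), spec$n_informative, replace = TRUE) *
        spec$effect_size
      tibble::tibble(region = rg, feature = info$feature[fsel], beta = beta)
    })
    for (i in seq_len(nrow(truth_map))) {
      f <- truth_map$feature[i]
      x[, f] <- x[, f] + truth_map$beta[i] * pres[, truth_map$region[i]]
    }
    if (spec$missing_rate > 0) {
      holes <- matrix(stats::runif(n * p) < spec$missing_rate, n, p)
      x[holes] <- NA_real_
    }
    features <- dplyr::bind_cols(
      tibble::tibble(subject_id = lesions$subject_id),
      tibble::as_tibble(x))
    list(features = features, truth_map = truth_map, feature_info = info)
  })
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Equal-length label vectors.
#' @return The adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
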