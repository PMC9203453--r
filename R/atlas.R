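#' Region atlas objects
#'
#' A `region_atlas` bundles an ordered region registry (id, name, centroid)
#' with a three-level spatial hierarchy: fine regions (AAL-style), their
#' level-2 parents (anatomical lobes) and level-1 parents (hemispheric
#' divisions). The bundled default registry mirrors the 116-region AAL
#' parcellation rolled up into 18 lobes and 5 hemispheric divisions.
#'
#' @param regions A data frame with columns `region_id`, `name`, `cx`, `cy`,
#'   `cz`, `level2_parent`, `level1_parent`.
#' @return A `region_atlas` object: a list with elements `regions` (tibble),
#'   `n_regions`, `n_level2`, `n_level1`.
#' @examples
#' atlas <- default_atlas()
#' atlas$n_regions
#' @export
region_atlas <- function(regions) {
  regions <- tibble::as_tibble(regions)
  required <- c("region_id", "name", "cx", "cy", "cz",
                "level2_parent", "level1_parent")
  missing <- setdiff(required, names(regions))
  if (length(missing) > 0) {
    rlang::abort(paste0("atlas registry is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(regions$region_id)) {
    rlang::abort("atlas region ids must be unique")
  }
  if (anyDuplicated(regions$name)) {
    rlang::abort("atlas region names must be unique")
  }
  # every level-2 parent must map to exactly one level-1 parent
  pairings <- dplyr::distinct(regions, .data$level2_parent, .data$level1_parent)
  if (anyDuplicated(pairings$level2_parent)) {
    rlang::abort("hierarchy inconsistent: a level-2 region has two level-1 parents")
  }
  structure(
    list(regions = regions,
         n_regions = nrow(regions),
         n_level2 = dplyr::n_distinct(regions$level2_parent),
         n_level1 = dplyr::n_distinct(regions$level1_parent)),
    class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("<region_atlas: %d regions, %d level-2, %d level-1>\n",
              x$n_regions, x$n_level2, x$n_level1))
  print(utils::head(x$regions, 4))
  invisible(x)
}

#' Read a region atlas registry from CSV
#'
#' Expected columns: `region_id,name,cx,cy,cz,level2_parent,level1_parent`.
#'
#' @param path Path to a registry CSV.
#' @return A [region_atlas()] object.
#' @export
read_atlas <- function(path) {
  region_atlas(readr::read_csv(path, show_col_types = FALSE))
}

#' The bundled AAL-like atlas registry
#'
#' Returns the shipped 116-region registry with AAL region names, a static
#' many-to-one mapping onto 18 lobes (level 2) and 5 hemispheric divisions
#' (level 1), and synthetic point centroids placed in anatomically plausible
#' zones. The centroids and hierarchy table are constructed stand-ins, not
#' template-derived coordinates; users with their own registry can load it
#' with [read_atlas()].
#'
#' @return A [region_atlas()] with 116/18/5 regions per level.
#' @export
default_atlas <- function() {
  path <- system.file("extdata", "aal116_registry_synthetic.csv",
                      package = "lesioncast", mustWork = TRUE)
  read_atlas(path)
}

#' Normalized inter-region distance matrix
#'
#' Computes Euclidean centroid-to-centroid distances between all region
#' pairs and min-max normalizes the off-diagonal entries to the 0-1 range
#' (the smallest pairwise distance maps to 0, the largest to 1). This matrix
#' is the weighting term of the lesion sparsity statistic.
#'
#' With exactly one distinct pair (two regions) normalization is degenerate;
#' the off-diagonal entries are set to 0 with a warning.
#'
#' @param atlas A [region_atlas()].
#' @return A symmetric `n x n` matrix with zero diagonal and off-diagonal
#'   entries in `[0, 1]`, dimnames set to region names.
#' @examples
#' w <- build_distance_matrix(default_atlas())
#' range(w[upper.tri(w)])
#' @export
build_distance_matrix <- function(atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  cents <- as.matrix(atlas$regions[, c("cx", "cy", "cz")])
  if (nrow(cents) < 2 || any(!is.finite(cents))) {
    rlang::abort("need at least 2 regions with finite centroids")
  }
  d <- as.matrix(stats::dist(cents))
  off <- d[upper.tri(d)]
  dmin <- min(off)
  dmax <- max(off)
  if (dmax == dmin) {
    if (length(off) == 1L) {
      rlang::warn("two-region atlas: single pair, normalized distance degenerates to 0")
      d[,] <- 0
    } else {
      rlang::abort("degenerate geometry: all pairwise distances equal")
    }
  } else {
    d <- (d - dmin) / (dmax - dmin)
    diag(d) <- 0
  }
  dimnames(d) <- list(atlas$regions$name, atlas$regions$name)
  d
}

#' Map fine regions onto a coarser resolution level
#'
#' @param atlas A [region_atlas()].
#' @param level `"level2"` (lobes) or `"level1"` (hemispheric divisions).
#' @return A tibble with columns `region_id`, `name`, `parent` covering every
#'   fine region exactly once.
#' @examples
#' dplyr::n_distinct(rollup_map(default_atlas(), "level1")$parent)
#' @export
rollup_map <- function(atlas, level = c("level2", "level1")) {
  stopifnot(inherits(atlas, "region_atlas"))
  level <- rlang::arg_match(level)
  col <- paste0(level, "_parent")
  tibble::tibble(region_id = atlas$regions$region_id,
                 name = atlas$regions$name,
                 parent = atlas$regions[[col]])
}

#' Extract per-region lesion degrees from a mask and label volume
#'
#' Given a binary lesion mask and an integer region-label volume of the same
#' shape, computes the lesion degree of each atlas region: 100 x (lesioned
#' voxels in the region) / (total voxels in the region). Regions absent from
#' the label volume get degree 0 with a warning. File paths to NIfTI volumes
#' are accepted when the RNifti package is available.
#'
#' @param mask Binary 3D array (or NIfTI path): 1 = lesioned voxel.
#' @param labels Integer 3D array (or NIfTI path) of region ids; 0 = background.
#' @param atlas A [region_atlas()].
#' @param subject_id Subject identifier for the returned row.
#' @return A one-row wide tibble: `subject_id` plus one percent-degree column
#'   per atlas region (columns named by region name, in atlas order).
#' @export
extract_region_degrees <- function(mask, labels, atlas,
                                   subject_id = "subject") {
  stopifnot(inherits(atlas, "region_atlas"))
  mask <- read_volume(mask)
  labels <- read_volume(labels)
  if (!identical(dim(mask), dim(labels))) {
    rlang::abort("mask and label volumes have different shapes")
  }
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1))) {
    rlang::abort("mask must be binary (0/1)")
  }
  extra <- setdiff(unique(as.vector(labels)), c(0, atlas$regions$region_id))
  if (length(extra) > 0) {
    rlang::abort("label volume contains ids not in the atlas")
  }
  ids <- atlas$regions$region_id
  lab <- as.vector(labels)
  msk <- as.vector(mask)
  total <- tabulate(match(lab, ids), nbins = length(ids))
  lesioned <- tabulate(match(lab[msk == 1], ids), nbins = length(ids))
  degree <- ifelse(total > 0, 100 * lesioned / total, 0)
  if (any(total == 0)) {
    rlang::warn(sprintf("%d atlas region(s) absent from label volume; degree set to 0",
                        sum(total == 0)))
  }
  out <- tibble::as_tibble(stats::setNames(as.list(degree), atlas$regions$name))
  dplyr::bind_cols(tibble::tibble(subject_id = subject_id), out)
}

# Accepts an array as-is; reads NIfTI from a path if RNifti is installed.
read_volume <- function(x) {
  if (is.character(x)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      rlang::abort("reading NIfTI paths requires the RNifti package")
    }
    x <- RNifti::readNifti(x)
  }
  array(as.numeric(x), dim = dim(x))
}
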