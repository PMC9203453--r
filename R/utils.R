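# internal helpers shared across modules

# feature tibble -> numeric matrix (subject_id column dropped)
feature_matrix <- function(features) {
  stopifnot(is.data.frame(features))
  cols <- setdiff(names(features), "subject_id")
  if (length(cols) == 0) rlang::abort("feature table has no feature columns")
  m <- as.matrix(features[, cols, drop = FALSE])
  if (!is.numeric(m)) rlang::abort("feature columns must be numeric")
  if (!is.null(features$subject_id)) rownames(m) <- features$subject_id
  m
}

# stratified fold assignment: each class spread as evenly as possible
# across k folds; random within class (uses the current RNG stream)
stratified_folds <- function(y, k) {
  y <- as.factor(y)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# stratified train indicator with roughly `frac` of each class in training
stratified_split <- function(y, frac) {
  y <- as.factor(y)
  train <- logical(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    n_tr <- max(1L, round(frac * length(idx)))
    if (length(idx) > 1 && n_tr >= length(idx)) n_tr <- length(idx) - 1L
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

# sensitivity (true presence rate); NA when no presences
sensitivity_of <- function(truth, pred) {
  pos <- truth == 1
  if (!any(pos)) return(NA_real_)
  mean(pred[pos] == 1)
}
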