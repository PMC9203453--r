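# Independent brute-force oracles used to validate the implementation.
# These are deliberately naive (loops, enumeration) and share no code with
# the package internals.

# sparsity: explicit double loop over all ordered region pairs
naive_sparsity <- function(degrees, w) {
  n <- length(degrees)
  vals <- c()
  for (m in seq_len(n)) {
    for (k in seq_len(n)) {
      if (m < k && degrees[m] > 0 && degrees[k] > 0) {
        vals <- c(vals, w[m, k])
      }
    }
  }
  if (length(vals) == 0) 0 else mean(vals)
}

# Fisher two-sided p by exhaustive hypergeometric enumeration over the
# feasible tables with the observed margins
naive_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Kendall tau-b by O(n^2) concordant/discordant pair counting with tie
# corrections
naive_kendall_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# Mann-Whitney U of x by explicit pair counting (ties count 1/2)
naive_wilcoxon_u <- function(x, y) {
  u <- 0
  for (xi in x) {
    for (yj in y) {
      if (xi > yj) u <- u + 1
      else if (xi == yj) u <- u + 0.5
    }
  }
  u
}

# Kruskal-Wallis H from the rank formula with explicit tie correction
naive_kw_h <- function(groups) {
  pooled <- unlist(groups)
  n <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(pooled)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Gorodkin multiclass MCC via the triple-sum form of the formula
naive_mcc <- function(cm) {
  k <- nrow(cm)
  num <- 0
  for (a in 1:k) for (l in 1:k) for (m in 1:k) {
    num <- num + cm[a, a] * cm[l, m] - cm[a, l] * cm[m, a]
  }
  d1 <- 0
  for (a in 1:k) {
    d1 <- d1 + sum(cm[a, ]) * sum(cm[setdiff(1:k, a), ])
  }
  d2 <- 0
  for (a in 1:k) {
    d2 <- d2 + sum(cm[, a]) * sum(cm[, setdiff(1:k, a)])
  }
  if (d1 == 0 || d2 == 0) return(0)
  num / sqrt(d1 * d2)
}

# logistic probability evaluated longhand
naive_logistic_p <- function(x, a, b) {
  1 / (1 + exp(-(sum(a * x) + b)))
}
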