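# Independent brute-force oracles, coded directly from the defining formulas
# (scalar loops, no shared code with the implementation they check).

# Benjamini-Hochberg step-up: sort, multiply by m/i, enforce monotonicity
# from the largest p downwards, cap at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# Quantile normalization by the definition: common reference distribution =
# per-rank means of the sorted columns (interpolated onto a shared grid when
# columns have different numbers of observed values); each observed value is
# mapped through its (interpolated) rank. Missing entries stay missing.
oracle_quantile_normalize <- function(mat) {
  n <- nrow(mat)
  grid <- (seq_len(n) - 1) / (n - 1)
  ref_cols <- sapply(seq_len(ncol(mat)), function(j) {
    v <- sort(mat[!is.na(mat[, j]), j])
    if (length(v) == n) v else
      stats::approx((seq_along(v) - 1) / (length(v) - 1), v, grid,
                    ties = "ordered")$y
  })
  ref <- rowMeans(ref_cols)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    obs <- which(!is.na(mat[, j]))
    r <- rank(mat[obs, j])
    out[obs, j] <- stats::approx(grid, ref, (r - 1) / (length(obs) - 1),
                                 ties = "ordered")$y
  }
  out
}

# Moderated t by the stated formulas, one feature at a time; the trigamma
# inverse is found by uniroot rather than Newton iteration.
oracle_moderated_t <- function(mat, groups, treatment, control) {
  groups <- as.character(groups)
  df1 <- ncol(mat) - length(unique(groups))
  s2 <- numeric(nrow(mat))
  lfc <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    res_i <- 0
    for (g in unique(groups)) {
      v <- mat[i, groups == g]
      res_i <- res_i + sum((v - mean(v))^2)
    }
    s2[i] <- res_i / df1
    lfc[i] <- mean(mat[i, groups == treatment]) - mean(mat[i, groups == control])
  }
  e <- log(s2) - digamma(df1 / 2) + log(df1 / 2)
  evar <- stats::var(e) - trigamma(df1 / 2)
  if (evar > 0) {
    tg_inv <- stats::uniroot(function(y) trigamma(y) - evar,
                             c(1e-8, 1e8), tol = 1e-14)$root
    d0 <- 2 * tg_inv
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- exp(mean(e))
  }
  s2_post <- if (is.infinite(d0)) rep(s0, length(s2)) else
    (d0 * s0 + df1 * s2) / (d0 + df1)
  lev <- 1 / sum(groups == treatment) + 1 / sum(groups == control)
  t_mod <- lfc / sqrt(s2_post * lev)
  list(t = t_mod, lfc = lfc, d0 = d0, s0_sq = s0,
       p = 2 * stats::pt(-abs(t_mod), df = d0 + df1))
}

# Hypergeometric upper tail by explicit summation of the point mass.
oracle_hyper_tail <- function(k, m, N, n) {
  kk <- k:min(m, n)
  sum(exp(lchoose(m, kk) + lchoose(N - m, n - kk) - lchoose(N, n)))
}

# Ordered enrichment: scan every prefix, take the minimum tail probability.
oracle_ordered_enrichment <- function(genes, term, background) {
  term <- intersect(term, background)
  N <- length(background)
  m <- length(term)
  best <- 1
  for (n in seq_along(genes)) {
    k <- length(intersect(genes[seq_len(n)], term))
    if (k > 0) best <- min(best, oracle_hyper_tail(k, m, N, n))
  }
  best
}
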