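# Independent brute-force reference implementations used as oracles.
# These follow the published formulas directly and share no code with the
# package internals.

# TMM factors, straight from the published definition: reference = sample
# whose upper-quartile count rate is closest to the mean; per sample,
# doubly trimmed precision-weighted mean of M values; geometric mean 1.
oracle_tmm <- function(values, lib = colSums(values),
                       trim_m = 0.30, trim_a = 0.05) {
  uq <- sapply(seq_len(ncol(values)),
               function(j) quantile(values[, j], 0.75) / lib[j])
  ref <- which.min(abs(uq - mean(uq)))
  f <- sapply(seq_len(ncol(values)), function(j) {
    o <- values[, j]; r <- values[, ref]
    keep <- o > 0 & r > 0
    o <- o[keep]; r <- r[keep]
    m <- log2((o / lib[j]) / (r / lib[ref]))
    a <- 0.5 * (log2(o / lib[j]) + log2(r / lib[ref]))
    w <- (lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r)
    if (max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    sel <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    2^(sum(m[sel] / w[sel]) / sum(1 / w[sel]))
  })
  f / exp(mean(log(f)))
}

# Textbook Benjamini-Hochberg: sort, multiply by n/rank, enforce
# monotonicity from the largest p down.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# Exact two-sided one-sample Wilcoxon signed-rank p by enumeration of all
# 2^n sign assignments (no ties, no zeros assumed).
oracle_signed_rank_p <- function(delta) {
  n <- length(delta)
  stopifnot(n <= 12, all(delta != 0))
  r <- rank(abs(delta))
  w_obs <- sum(r[delta > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_null <- signs %*% r
  mu <- n * (n + 1) / 4
  mean(abs(w_null - mu) >= abs(w_obs - mu))
}

# Ordinary equal-variance two-sample t-test on each row.
oracle_row_t <- function(x, g1, g2) {
  t(apply(x, 1, function(row) {
    tt <- t.test(row[g1], row[g2], var.equal = TRUE)
    c(t = unname(tt$statistic), p = tt$p.value,
      diff = unname(diff(rev(tt$estimate))))
  }))
}
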