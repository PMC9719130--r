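# Small in-code fixtures shared across test files.

# A three-window universe on chr1 plus one chrX window.
tiny_windows <- function() {
  window_set(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chrX"),
    start = c(0, 500, 1000, 0),
    end = c(500, 1000, 2000, 400),
    window_id = c("w1", "w2", "w3", "wx"),
    n_cpg = c(5L, 3L, 2L, 8L)
  ))
}

# Deterministic small count matrix with known library sizes.
tiny_counts <- function() {
  values <- matrix(c(10, 0, 5,
                     20, 4, 1,
                     0, 8, 2),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("w1", "w2", "w3"), c("s1", "s2", "s3")))
  count_matrix(values, library_sizes = c(s1 = 1e6, s2 = 5e5, s3 = 2e5))
}

# Random NB count matrix for oracle-equivalence checks.
random_counts <- function(n_windows = 200, n_samples = 4, seed = 1) {
  set.seed(seed)
  mu <- rexp(n_windows, 1 / 30)
  values <- sapply(seq_len(n_samples), function(j) {
    rnbinom(n_windows, mu = mu * runif(1, 0.5, 2), size = 5)
  })
  rownames(values) <- sprintf("w%03d", seq_len(n_windows))
  colnames(values) <- sprintf("s%d", seq_len(n_samples))
  values[rowSums(values) == 0, 1] <- 1L  # avoid all-zero windows
  count_matrix(values)
}
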