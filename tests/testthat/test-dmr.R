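test_that("low-count filter applies the presence-fraction rule with its boundary", {
  values <- rbind(
    w1 = c(rep(1, 1), rep(0, 9)),   # present in 1/10 -> dropped at 0.2
    w2 = c(rep(1, 2), rep(0, 8)),   # present in 2/10 -> kept (boundary)
    w3 = rep(0, 10),                # all-zero -> dropped at any fraction
    w4 = rep(3, 10))
  colnames(values) <- sprintf("s%d", 1:10)
  keep <- filter_low_count(count_matrix(values), 0.2)
  expect_equal(unname(keep), c(FALSE, TRUE, FALSE, TRUE))
  expect_false(filter_low_count(count_matrix(values), 0.05)[["w3"]])
  expect_error(filter_low_count(count_matrix(values), 0), "min_sample_frac")
})

test_that("TMM factors are 1 for identical or purely depth-scaled samples", {
  values <- matrix(rep(c(5, 10, 40, 2, 80), 3), ncol = 3,
                   dimnames = list(sprintf("w%d", 1:5), sprintf("s%d", 1:3)))
  f <- tmm_factors(count_matrix(values))
  expect_equal(unname(f), rep(1, 3))

  # doubling every count together with the library size is a pure
  # library-size effect: factor stays 1
  v2 <- cbind(values[, 1:2], s3 = values[, 1] * 2)
  f2 <- tmm_factors(count_matrix(v2))
  expect_equal(unname(f2), rep(1, 3), tolerance = 1e-12)
})

test_that("TMM factors match the brute-force oracle and edgeR", {
  skip_if_not_installed("edgeR")
  for (seed in 1:3) {
    cm <- random_counts(300, 5, seed = seed)
    f <- tmm_factors(cm)
    expect_equal(unname(f), unname(oracle_tmm(unclass(cm))), tolerance = 1e-8)
    f_edger <- edgeR::calcNormFactors(unclass(cm), method = "TMM")
    expect_equal(unname(f), unname(f_edger), tolerance = 1e-6)
  }
})

test_that("a sample sharing no window with the reference gets factor 1 with warning", {
  values <- cbind(s1 = c(10, 20, 30, 5, 0),
                  s2 = c(12, 18, 28, 6, 0),
                  s3 = c(0, 0, 0, 0, 7))
  rownames(values) <- sprintf("w%d", 1:5)
  expect_warning(f <- tmm_factors(count_matrix(values)), "no nonzero window")
  expect_equal(length(f), 3L)
})

test_that("log-CPM matches hand arithmetic and joint scaling invariance", {
  values <- matrix(c(4, 0, 16), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  lib <- c(s1 = 1000)
  lc <- log_cpm(count_matrix(values, lib), prior_count = 0.5)
  expect_equal(lc["a", "s1"], log2((4 + 0.5) / (1000 + 1) * 1e6), tolerance = 1e-12)
  expect_equal(lc["b", "s1"], log2(0.5 / 1001 * 1e6), tolerance = 1e-12)

  # all-zero column is constant
  z <- log_cpm(count_matrix(matrix(0, 3, 1, dimnames = list(letters[1:3], "s")),
                            c(s = 100)))
  expect_equal(length(unique(z)), 1L)

  # scaling counts and library jointly leaves the column unchanged up to
  # the (fixed) prior's vanishing influence
  big <- count_matrix(values * 1000, lib * 1000)
  expect_equal(log_cpm(big, prior_count = 0), log_cpm(count_matrix(values, lib),
                                                      prior_count = 0))
})

test_that("with d0 = 0 the moderated statistic is the ordinary two-sample t", {
  set.seed(7)
  x <- matrix(rnorm(40 * 9), 40, 9,
              dimnames = list(sprintf("w%d", 1:40), sprintf("s%d", 1:9)))
  group <- rep(c("case", "control"), c(4, 5))
  st <- moderated_two_group_test(x, group, d0_mode = "zero")
  ref <- oracle_row_t(x, group == "case", group == "control")
  expect_equal(st$t, unname(ref[, "t"]), tolerance = 1e-10)
  expect_equal(st$p_value, unname(ref[, "p"]), tolerance = 1e-10)
  expect_equal(st$log2fc, unname(ref[, "diff"]), tolerance = 1e-10)
})

test_that("moderated test agrees with limma on a toy matrix", {
  skip_if_not_installed("limma")
  set.seed(8)
  x <- matrix(rnorm(2000 * 10, sd = rep(sqrt(1 / rgamma(2000, 4, 4)), 10)),
              2000, 10, dimnames = list(sprintf("w%d", 1:2000), NULL))
  group <- rep(c("case", "control"), each = 5)
  st <- moderated_two_group_test(x, group)
  design <- cbind(1, group == "case")
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(attr(st, "d0"), fit$df.prior, tolerance = 0.05)
  expect_equal(st$t, fit$t[, 2], ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(st$p_value, fit$p.value[, 2], ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("equal group means give near-zero fold-change and large p", {
  x <- matrix(c(5, 5, 5, 5, 5, 5, 1, 2, 3, 1, 2, 3), nrow = 2, byrow = TRUE,
              dimnames = list(c("flat", "match"), sprintf("s%d", 1:6)))
  x <- x + matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0), 2)
  x <- rbind(x, noise = c(5.1, 4.9, 5.0, 5.05, 4.95, 5.0))
  st <- moderated_two_group_test(x, rep(c("case", "control"), each = 3))
  expect_equal(st$log2fc[st$window_id == "match"], 0)
  expect_gt(st$p_value[st$window_id == "match"], 0.95)
})

test_that("p-values are calibrated under the null", {
  set.seed(11)
  x <- matrix(rnorm(5000 * 12), 5000, 12,
              dimnames = list(sprintf("w%d", 1:5000), NULL))
  st <- moderated_two_group_test(x, rep(c("case", "control"), each = 6))
  ks <- suppressWarnings(ks.test(st$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment matches the textbook construction", {
  set.seed(12)
  for (i in 1:5) {
    p <- runif(200)^2
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  st <- data.frame(window_id = letters[1:4],
                   log2fc = c(2, -2, 0.5, 3),
                   adj_p = c(0.05, 0.05, 0.01, 0.2))
  dm <- call_dmrs(st, alpha = 0.1, min_abs_lfc = 1)
  expect_equal(dm$hyper, "a")   # significant and up
  expect_equal(dm$hypo, "b")    # significant and down
  # "c" fails the fold-change bar, "d" fails alpha
  expect_false(any(c("c", "d") %in% c(dm$hyper, dm$hypo)))
  expect_length(intersect(dm$hyper, dm$hypo), 0)
})

test_that("degenerate all-zero-variance input raises", {
  x <- matrix(5, 10, 6, dimnames = list(sprintf("w%d", 1:10), NULL))
  expect_error(moderated_two_group_test(x, rep(c("case", "control"), each = 3)),
               "degenerate")
})
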