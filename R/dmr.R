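#' Filter windows with low counts across samples
#'
#' A window is kept when it has a nonzero count in at least
#' `ceiling(min_sample_frac * n_samples)` samples; presence in exactly the
#' boundary fraction keeps the window. This presence-based reading is the
#' only depth-scale-free interpretation of a "low read counts across all
#' samples" rule.
#'
#' @param cm A [count_matrix()] (or plain matrix).
#' @param min_sample_frac Minimum fraction of samples with a nonzero count
#'   (default 0.2).
#' @return Named logical keep mask over windows.
#' @export
filter_low_count <- function(cm, min_sample_frac = 0.2) {
  if (min_sample_frac <= 0 || min_sample_frac > 1) {
    stop("min_sample_frac must lie in (0, 1]", call. = FALSE)
  }
  need <- ceiling(min_sample_frac * ncol(cm))
  keep <- rowSums(unclass(cm) > 0) >= need
  stats::setNames(keep, rownames(cm))
}

# Upper-quartile of the count rate per sample, used to pick the TMM
# reference sample.
.uq_rate <- function(values, lib) {
  vapply(seq_len(ncol(values)),
         function(j) stats::quantile(values[, j], 0.75) / lib[j],
         numeric(1))
}

# Pairwise TMM factor of sample `obs` against sample `ref` (counts and
# library sizes), doubly trimmed, precision-weighted.
.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  both <- obs > 0 & ref > 0
  if (!any(both)) return(NA_real_)
  obs <- obs[both]; ref <- ref[both]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep)) return(1)
  2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
}

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Composition normalization for count matrices. The reference sample is
#' the one whose upper-quartile count rate is closest to the cohort mean;
#' for every sample, log2 count-rate ratios (M) and average log2 abundances
#' (A) against the reference are computed over windows nonzero in both, the
#' most extreme `trim_m` of M and `trim_a` of A are discarded on each side,
#' and the factor is 2 to the precision-weighted mean of the retained M
#' values. Factors are rescaled to geometric mean 1.
#'
#' @param cm A [count_matrix()] (or matrix with nonzero column sums).
#' @param trim_m Two-sided trim fraction on M (default 0.30).
#' @param trim_a Two-sided trim fraction on A (default 0.05).
#' @param lib Library sizes; defaults to those recorded on `cm`, else
#'   column sums.
#' @return Named numeric factors, geometric mean 1.
#' @export
tmm_factors <- function(cm, trim_m = 0.30, trim_a = 0.05, lib = NULL) {
  values <- unclass(as.matrix(cm))
  if (is.null(lib)) {
    lib <- attr(cm, "library_sizes")
    if (is.null(lib)) lib <- colSums(values)
  }
  if (any(colSums(values) == 0)) stop("sample with no nonzero count", call. = FALSE)
  uq <- .uq_rate(values, lib)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(values)), function(j) {
    fj <- .tmm_pair(values[, j], values[, ref], lib[j], lib[ref],
                    trim_m, trim_a)
    if (is.na(fj)) {
      warning(sprintf("sample '%s' shares no nonzero window with the reference; factor set to 1",
                      colnames(values)[j]))
      fj <- 1
    }
    fj
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(values))
}

#' Log2 counts-per-million on TMM-effective library sizes
#'
#' `log2((c + prior) / (lib * factor + 2 * prior) * 1e6)`.
#'
#' @param cm A [count_matrix()] (or matrix).
#' @param factors Per-sample normalization factors (default all 1).
#' @param prior_count Pseudocount (default 0.5).
#' @param lib Library sizes; defaults to those recorded on `cm`.
#' @return Numeric matrix of log2-CPM values.
#' @export
log_cpm <- function(cm, factors = NULL, prior_count = 0.5, lib = NULL) {
  values <- unclass(as.matrix(cm))
  if (is.null(lib)) lib <- attr(cm, "library_sizes")
  attr(values, "library_sizes") <- NULL
  if (is.null(lib)) {
    lib <- attr(cm, "library_sizes")
    if (is.null(lib)) lib <- colSums(values)
  }
  if (is.null(factors)) factors <- rep(1, ncol(values))
  if (any(factors <= 0)) stop("factors must be > 0", call. = FALSE)
  eff <- lib * factors
  t(log2(t(values + prior_count) / (eff + 2 * prior_count) * 1e6))
}

# Newton inversion of the trigamma function (for the moments estimate of
# the prior degrees of freedom).
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

# Moments-method fit of the scaled inverse-chi-square prior for residual
# variances: returns d0 (prior df, possibly Inf) and s0^2.
.fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0
  if (!any(ok)) stop("all residual variances are zero (degenerate input)",
                     call. = FALSE)
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / max(1L, length(e) - 1L) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(emean)
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Empirical-Bayes moderated two-group test per window
#'
#' Per window, the ordinary least-squares group difference on log-CPM
#' (case minus control, log2 scale) and its residual variance `s^2` with
#' `d = n1 + n2 - 2` degrees of freedom are computed. A scaled
#' inverse-chi-square prior `(d0, s0^2)` is estimated from the distribution
#' of `log(s^2)` by the method of moments; the moderated variance is
#' `(d0*s0^2 + d*s^2) / (d0 + d)` and the moderated t-statistic is referred
#' to a t-distribution with `d0 + d` degrees of freedom. Benjamini-Hochberg
#' adjustment is applied over all tested windows.
#'
#' @param logcpm Matrix of log2-CPM values (windows x samples).
#' @param group Character/factor vector over columns with exactly two
#'   levels; the first level encountered in `levels` order is the control
#'   unless `case` is given.
#' @param case Label of the case group (default `"case"` when present,
#'   else the second factor level).
#' @param d0_mode `"estimate"` (default) or `"zero"`; with `"zero"` no
#'   moderation is applied and the statistic equals the ordinary
#'   equal-variance two-sample t.
#' @return Data frame: `window_id`, `log2fc`, `t`, `p_value`, `adj_p`,
#'   `mean_logcpm`, plus attributes `d0` and `s0_2`.
#' @export
moderated_two_group_test <- function(logcpm, group, case = NULL,
                                     d0_mode = c("estimate", "zero")) {
  d0_mode <- match.arg(d0_mode)
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) != 2L) stop("exactly two groups required", call. = FALSE)
  if (is.null(case)) case <- if ("case" %in% lev) "case" else lev[2]
  ctrl <- setdiff(lev, case)
  i1 <- group == case
  i2 <- group == ctrl
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop(">= 2 samples per group required", call. = FALSE)

  m1 <- rowMeans(logcpm[, i1, drop = FALSE])
  m2 <- rowMeans(logcpm[, i2, drop = FALSE])
  lfc <- m1 - m2
  ss1 <- rowSums((logcpm[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((logcpm[, i2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / df
  se_unscaled <- sqrt(1 / n1 + 1 / n2)

  if (d0_mode == "zero") {
    d0 <- 0; s2_post <- s2; df_total <- df
  } else {
    prior <- .fit_variance_prior(s2, df)
    d0 <- prior$d0
    s2_post <- if (is.infinite(d0)) rep(prior$s0_2, length(s2)) else {
      (d0 * prior$s0_2 + df * s2) / (d0 + df)
    }
    df_total <- d0 + df
  }
  tstat <- lfc / (sqrt(s2_post) * se_unscaled)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(window_id = rownames(logcpm),
                    log2fc = lfc,
                    t = tstat,
                    p_value = p,
                    adj_p = stats::p.adjust(p, method = "BH"),
                    mean_logcpm = rowMeans(logcpm),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- if (d0_mode == "zero") NA_real_ else prior$s0_2
  attr(out, "df_residual") <- df
  out
}

#' Call differentially methylated regions from a statistics table
#'
#' Hypermethylated: `adj_p < alpha` and `log2fc > min_abs_lfc`;
#' hypomethylated: `adj_p < alpha` and `log2fc < -min_abs_lfc`.
#'
#' @param stats Output of [moderated_two_group_test()].
#' @param alpha BH-adjusted p-value cutoff (default 0.1).
#' @param min_abs_lfc Minimum absolute log2 fold-change (default 1).
#' @return A `dmr_set`: list with `hyper` and `hypo` window-id vectors and
#'   the thresholds used.
#' @export
call_dmrs <- function(stats, alpha = 0.1, min_abs_lfc = 1) {
  sig <- stats$adj_p < alpha
  structure(list(hyper = stats$window_id[sig & stats$log2fc > min_abs_lfc],
                 hypo = stats$window_id[sig & stats$log2fc < -min_abs_lfc],
                 alpha = alpha, min_abs_lfc = min_abs_lfc),
            class = "dmr_set")
}

#' Differential methylation analysis, filters to calls
#'
#' Convenience wrapper chaining the background keep-mask, the low-count
#' filter, TMM normalization, log-CPM, the moderated test and DMR calling.
#' TMM factors and log-CPM use the library sizes recorded at full-universe
#' count time.
#'
#' @param cm A [count_matrix()] over the (CpG/chromosome-filtered) universe.
#' @param group Two-level group vector over columns (`"case"`/`"control"`).
#' @param keep_mask Optional named logical background mask over windows
#'   (from [apply_background_mask()]); `NULL` skips background depletion.
#' @param min_sample_frac Low-count presence fraction (default 0.2).
#' @param alpha,min_abs_lfc Calling thresholds (defaults 0.1 and 1).
#' @param trim_m,trim_a TMM trim fractions.
#' @return List with `stats`, `dmrs`, `tested_windows`, `factors`.
#' @export
run_dmr_analysis <- function(cm, group, keep_mask = NULL,
                             min_sample_frac = 0.2,
                             alpha = 0.1, min_abs_lfc = 1,
                             trim_m = 0.30, trim_a = 0.05) {
  if (!is.null(keep_mask)) {
    keep_ids <- names(keep_mask)[keep_mask]
    cm <- subset_windows(cm, intersect(rownames(cm), keep_ids))
  }
  lc <- filter_low_count(cm, min_sample_frac)
  cm <- subset_windows(cm, rownames(cm)[lc])
  f <- tmm_factors(cm, trim_m = trim_m, trim_a = trim_a)
  lcpm <- log_cpm(cm, f)
  st <- moderated_two_group_test(lcpm, group)
  list(stats = st,
       dmrs = call_dmrs(st, alpha = alpha, min_abs_lfc = min_abs_lfc),
       tested_windows = rownames(cm),
       factors = f)
}
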