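#' Tile chromosomes into fixed-width bins
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp (default 1 Mb); the last bin of each
#'   chromosome is truncated.
#' @return Data frame `chrom`, `start`, `end`, `bin_id` (sorted,
#'   non-overlapping, tiling).
#' @export
make_bins <- function(chrom_lengths, bin_size = 1e6) {
  stopifnot(length(names(chrom_lengths)) == length(chrom_lengths))
  rows <- lapply(names(chrom_lengths), function(chr) {
    len <- chrom_lengths[[chr]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, rows)
  bins$bin_id <- sprintf("%s:%d-%d", bins$chrom, bins$start, bins$end)
  bins
}

#' Count fragments into genomic bins (midpoint rule)
#'
#' @param fragments Fragment data frame (`chrom`, `start`, `end`).
#' @param bins Output of [make_bins()].
#' @return List `counts` (named by `bin_id`), `library_size`, `n_skipped`
#'   (as [count_fragments()]).
#' @export
bin_counts <- function(fragments, bins) {
  ws <- window_set(data.frame(chrom = bins$chrom, start = bins$start,
                              end = bins$end, window_id = bins$bin_id,
                              n_cpg = 0L, stringsAsFactors = FALSE),
                   provenance = "bins")
  res <- count_fragments(fragments, ws)
  res$counts <- res$counts[bins$bin_id]
  res
}

#' Normalize binned coverage against a copy-number-neutral panel
#'
#' Sample and panel count vectors are scaled to proportions of their
#' totals; the reference is the per-bin median panel proportion, and the
#' profile is `log2((sample_prop + eps) / (reference + eps))`. Bins in the
#' top `cv_quantile` of panel coefficient of variation, or with a zero
#' reference, are blacklisted (flagged unusable, no ratio).
#'
#' @param sample_counts Named count vector over bins (nonempty).
#' @param panel_counts Matrix of healthy bin counts (bins x >= 2 samples),
#'   same bin set.
#' @param eps Proportion-scale pseudocount (default 1e-6).
#' @param cv_quantile Panel-CV blacklist quantile (default 0.99, i.e. the
#'   top 1% most variable bins are dropped).
#' @return Data frame of class `log2ratio_profile`: `bin_id`, `log2r`,
#'   `usable`.
#' @export
normalize_to_panel <- function(sample_counts, panel_counts, eps = 1e-6,
                               cv_quantile = 0.99) {
  if (sum(sample_counts) == 0) stop("empty sample", call. = FALSE)
  if (ncol(panel_counts) < 2L) stop(">= 2 panel samples required", call. = FALSE)
  stopifnot(identical(names(sample_counts), rownames(panel_counts)))
  p_sample <- sample_counts / sum(sample_counts)
  p_panel <- sweep(panel_counts, 2L, colSums(panel_counts), "/")
  ref <- apply(p_panel, 1L, stats::median)
  cv <- apply(p_panel, 1L, stats::sd) / ifelse(ref > 0, ref, NA)
  usable <- ref > 0 & !is.na(cv) &
    cv <= stats::quantile(cv, cv_quantile, na.rm = TRUE)
  log2r <- ifelse(usable, log2((p_sample + eps) / (ref + eps)), NA_real_)
  structure(data.frame(bin_id = names(sample_counts), log2r = log2r,
                       usable = usable, row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("log2ratio_profile", "data.frame"))
}

#' Trimmed MAD-from-neutrality chromosomal instability score
#'
#' After dropping the `trim_frac` most extreme `|log2R|` bins, the score is
#' the median absolute log2 ratio over the remaining usable bins —
#' deviation is measured from 0 (copy-number neutrality), not from the
#' sample median.
#'
#' @param profile A `log2ratio_profile` (or numeric log2-ratio vector).
#' @param trim_frac Fraction of extreme bins removed (default 0.02).
#' @param min_bins Minimum usable bins required (default 100).
#' @return Non-negative scalar t-MAD score.
#' @export
tmad <- function(profile, trim_frac = 0.02, min_bins = 100L) {
  r <- if (is.data.frame(profile)) profile$log2r[profile$usable] else profile
  r <- r[!is.na(r)]
  if (length(r) < min_bins) {
    stop(sprintf("only %d usable bins (< %d required)", length(r), min_bins),
         call. = FALSE)
  }
  a <- abs(r)
  n_trim <- floor(trim_frac * length(a))
  if (n_trim > 0) a <- sort(a)[seq_len(length(a) - n_trim)]
  stats::median(a)
}

#' Cross-platform t-MAD concordance at a common depth
#'
#' Downsamples paired fragment sets from two platforms (e.g. shallow WGS
#' and cfMeDIP) to a common depth, normalizes each against its
#' platform-matched healthy panel, computes per-sample t-MAD scores and
#' their Pearson correlation across the cohort.
#'
#' @param fragments_a,fragments_b Named lists of fragment data frames;
#'   names identify samples, unpaired samples are excluded with a warning.
#' @param bins [make_bins()] output.
#' @param panel_a,panel_b Bin-count matrices of platform-matched healthy
#'   panels.
#' @param common_depth Fragments per sample after downsampling.
#' @param seed Optional integer seed.
#' @param trim_frac,min_bins Passed to [tmad()].
#' @return List: `tmad_a`, `tmad_b` (named vectors), `pearson_r`,
#'   `p_value`, `n`; a constant cohort yields `NA` correlation with a
#'   warning.
#' @export
dual_platform_concordance <- function(fragments_a, fragments_b, bins,
                                      panel_a, panel_b, common_depth,
                                      seed = NULL, trim_frac = 0.02,
                                      min_bins = 100L) {
  shared <- intersect(names(fragments_a), names(fragments_b))
  unpaired <- setdiff(union(names(fragments_a), names(fragments_b)), shared)
  if (length(unpaired)) {
    warning("excluding unpaired samples: ", paste(unpaired, collapse = ", "))
  }
  score_one <- function(fr, panel, k) {
    fr <- downsample_fragments(fr, common_depth, seed = child_seed(seed, k))
    prof <- normalize_to_panel(bin_counts(fr, bins)$counts, panel)
    tmad(prof, trim_frac = trim_frac, min_bins = min_bins)
  }
  # one downsampling stream per sample, shared by both platforms, so
  # identical inputs yield identical subsets
  ta <- vapply(seq_along(shared), function(i)
    score_one(fragments_a[[shared[i]]], panel_a, i), numeric(1))
  tb <- vapply(seq_along(shared), function(i)
    score_one(fragments_b[[shared[i]]], panel_b, i), numeric(1))
  names(ta) <- names(tb) <- shared
  if (stats::sd(ta) == 0 || stats::sd(tb) == 0) {
    warning("constant t-MAD cohort: correlation undefined")
    return(list(tmad_a = ta, tmad_b = tb, pearson_r = NA_real_,
                p_value = NA_real_, n = length(shared)))
  }
  ct <- stats::cor.test(ta, tb, method = "pearson")
  list(tmad_a = ta, tmad_b = tb, pearson_r = unname(ct$estimate),
       p_value = ct$p.value, n = length(shared))
}
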