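#' Build a pooled healthy reference baseline
#'
#' Healthy samples are each downsampled (uniformly, without replacement) to
#' a common per-sample depth so that the merged pool totals approximately
#' `target_depth` fragments; the pooled pseudo-sample is counted once and
#' its RPKM profile is the baseline against which per-sample 5-mC scores
#' are measured.
#'
#' @param healthy Either a named list of per-sample fragment data frames or
#'   a [count_matrix()] of healthy samples over the window universe.
#' @param ws The [window_set()].
#' @param target_depth Total fragments for the merged pool; when it exceeds
#'   the available total, everything is used with a warning.
#' @param seed Optional integer seed (downsampling).
#' @return List of class `baseline_profile`: `baseline_rpkm` (named
#'   vector), `target_depth`, `achieved_depth`, `samples`, `seed`.
#' @export
build_healthy_baseline <- function(healthy, ws, target_depth, seed = NULL) {
  if (inherits(healthy, "count_matrix") || is.matrix(healthy)) {
    counts_list <- lapply(stats::setNames(colnames(healthy), colnames(healthy)),
                          function(s) unclass(healthy)[, s])
  } else {
    if (!length(healthy)) stop(">= 1 healthy sample required", call. = FALSE)
    counts_list <- lapply(healthy, function(fr) count_fragments(fr, ws)$counts)
  }
  if (!length(counts_list)) stop(">= 1 healthy sample required", call. = FALSE)
  depths <- vapply(counts_list, sum, numeric(1))
  per_sample <- floor(target_depth / length(counts_list))
  if (any(depths < per_sample)) {
    warning("target depth exceeds available fragments; using all fragments of shallow samples")
  }
  pooled <- Reduce(`+`, lapply(seq_along(counts_list), function(i) {
    downsample_counts(counts_list[[i]], min(per_sample, depths[i]),
                      seed = child_seed(seed, i))
  }))
  lib <- sum(pooled)
  cm <- count_matrix(matrix(pooled, ncol = 1,
                            dimnames = list(names(pooled), "baseline")),
                     library_sizes = lib)
  rpkm <- compute_rpkm(cm, ws)[, 1]
  structure(list(baseline_rpkm = rpkm,
                 target_depth = target_depth,
                 achieved_depth = lib,
                 samples = names(counts_list),
                 seed = seed),
            class = "baseline_profile")
}

#' Per-sample 5-mC score
#'
#' The median absolute RPKM deviation from the healthy baseline over a
#' fixed set of hypermethylated DMR windows. The median of an even number
#' of deviations is the midpoint of the two central order statistics.
#'
#' @param sample_rpkm Named RPKM vector for one sample (full universe or at
#'   least the DMR windows).
#' @param baseline A `baseline_profile` (or named baseline RPKM vector).
#' @param dmr_windows Nonempty character vector of scoring window ids,
#'   present in both inputs.
#' @return Non-negative scalar score.
#' @export
five_mc_score <- function(sample_rpkm, baseline, dmr_windows) {
  if (!length(dmr_windows)) stop("dmr_windows must be nonempty", call. = FALSE)
  base <- if (inherits(baseline, "baseline_profile")) baseline$baseline_rpkm else baseline
  missing <- setdiff(dmr_windows, intersect(names(sample_rpkm), names(base)))
  if (length(missing)) {
    stop("scoring window absent from sample or baseline: ", missing[1],
         call. = FALSE)
  }
  stats::median(abs(sample_rpkm[dmr_windows] - base[dmr_windows]))
}

#' Detection threshold from a healthy cohort
#'
#' The threshold for tumor-DNA positivity is the maximum marker value
#' observed across the healthy cohort.
#'
#' @param healthy_scores Numeric vector (>= 1 value).
#' @return The maximum.
#' @export
detection_threshold <- function(healthy_scores) {
  if (!length(healthy_scores)) stop(">= 1 healthy score required", call. = FALSE)
  max(healthy_scores)
}

#' Classify a marker value against a detection threshold
#'
#' The 5-mC score uses a strict "exceeds the healthy maximum" rule by
#' default; t-MAD positivity uses `>=` by default. Missing values are not
#' evaluable (`NA`), never negative.
#'
#' @param value Numeric marker value(s); `NA` allowed.
#' @param threshold Non-negative detection threshold.
#' @param rule `"greater"` (strict, default) or `"greater_equal"`.
#' @return Logical vector (`NA` where not evaluable).
#' @export
classify_positive <- function(value, threshold,
                              rule = c("greater", "greater_equal")) {
  rule <- match.arg(rule)
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  if (rule == "greater") value > threshold else value >= threshold
}

#' Multi-marker detectability matrix
#'
#' Applies per-marker thresholds and comparison rules to a marker table and
#' summarizes positivity per marker and for the combination of all markers,
#' at sample and patient level. Samples missing a marker are not evaluable
#' for that marker and are excluded from its denominator; a sample counts
#' toward the any-marker combination when at least one marker is evaluable.
#'
#' @param marker_table Data frame with `sample_id`, `patient_id` and one
#'   numeric column per marker (missing = `NA`).
#' @param thresholds Named list/vector of per-marker thresholds (a marker
#'   column with no threshold raises an error).
#' @param rules Named character vector of per-marker rules
#'   (`"greater"`/`"greater_equal"`); default `"greater"`.
#' @return List of class `detection_matrix`: `calls` (logical samples x
#'   markers), `per_marker_fraction`, `any_marker_fraction`,
#'   `patient_any_fraction`, `n_evaluable`.
#' @export
build_detection_matrix <- function(marker_table, thresholds, rules = NULL) {
  markers <- setdiff(names(marker_table), c("sample_id", "patient_id", "date"))
  missing_thr <- setdiff(markers, names(thresholds))
  if (length(missing_thr)) {
    stop("no threshold for marker: ", missing_thr[1], call. = FALSE)
  }
  calls <- sapply(markers, function(m) {
    rule <- if (!is.null(rules) && m %in% names(rules)) rules[[m]] else "greater"
    classify_positive(marker_table[[m]], thresholds[[m]], rule)
  })
  calls <- matrix(calls, nrow = nrow(marker_table),
                  dimnames = list(marker_table$sample_id, markers))
  per_marker <- colMeans(calls, na.rm = TRUE)
  n_eval <- colSums(!is.na(calls))
  any_eval <- rowSums(!is.na(calls)) > 0
  any_pos <- rowSums(calls, na.rm = TRUE) > 0
  any_frac <- mean(any_pos[any_eval])
  patient_any <- tapply(any_pos[any_eval],
                        marker_table$patient_id[any_eval], any)
  structure(list(calls = calls,
                 per_marker_fraction = per_marker,
                 any_marker_fraction = any_frac,
                 patient_any_fraction = mean(unlist(patient_any)),
                 n_evaluable = n_eval),
            class = "detection_matrix")
}

#' Concordance between two marker score vectors
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs required).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `estimate`, `p_value`, `n`, `method`; a constant
#'   vector yields `NA` with a warning (flagged undefined).
#' @export
score_concordance <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3L) stop(">= 3 complete pairs required", call. = FALSE)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: correlation undefined")
    return(list(estimate = NA_real_, p_value = NA_real_, n = sum(ok),
                method = method))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
       method = method)
}
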