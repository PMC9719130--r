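#' Combine cell-type beta profiles into a cfDNA methylation background
#'
#' Most plasma cfDNA originates from hematopoietic cells, so windows that
#' are methylated in the weighted combination of contributing cell types
#' carry background rather than tumor signal. The combined background is
#' the abundance-weighted sum of per-cell-type beta values,
#' `combined_beta(w) = sum_c w_c * beta[w, c]`, with weights normalized to
#' sum to 1.
#'
#' @param beta Numeric matrix of beta values in `[0, 1]`, rows = window_id,
#'   columns = cell types.
#' @param weights Named non-negative vector of predicted cell-type
#'   abundances in healthy cfDNA; names must match `colnames(beta)`.
#' @return Named numeric vector of combined beta per window; windows with a
#'   missing beta in any cell type are `NA` (not evaluable, excluded from
#'   any downstream mask).
#' @export
combine_background <- function(beta, weights) {
  beta <- as.matrix(beta)
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(names(weights))) {
    if (length(weights) != ncol(beta)) {
      stop("weights must be named or match ncol(beta)", call. = FALSE)
    }
    names(weights) <- colnames(beta)
  }
  missing <- setdiff(colnames(beta), names(weights))
  if (length(missing)) {
    stop("no weight for cell type: ", missing[1], call. = FALSE)
  }
  w <- weights[colnames(beta)]
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  total <- sum(w)
  if (total <= 0) stop("weights sum to zero", call. = FALSE)
  w <- w / total
  combined <- drop(beta %*% w)
  combined[rowSums(is.na(beta)) > 0L] <- NA_real_
  stats::setNames(as.numeric(combined), rownames(beta))
}

#' Derive the background-exclusion keep mask
#'
#' Windows whose combined background beta exceeds the threshold `tau` are
#' excluded; the boundary `beta == tau` is kept (convention). Windows with
#' `NA` combined beta are not evaluable and never kept.
#'
#' @param combined_beta Output of [combine_background()].
#' @param tau Exclusion threshold in `[0, 1]` (default 0.15).
#' @return Named logical keep mask.
#' @export
apply_background_mask <- function(combined_beta, tau = 0.15) {
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]", call. = FALSE)
  keep <- !is.na(combined_beta) & combined_beta <= tau
  stats::setNames(keep, names(combined_beta))
}

#' Scan background-exclusion thresholds against tissue concordance
#'
#' For each candidate threshold, computes the Spearman correlation between
#' case-cfDNA and case-tissue log2 fold-changes over the kept windows. The
#' healthy reference cohort is split at random into two disjoint halves (an
#' odd sample is dropped): one half is the denominator for the cfDNA
#' fold-changes, the other for the tissue fold-changes, so the two axes
#' share no reference samples. The selected threshold maximizes the
#' correlation (ties broken toward the smallest threshold).
#'
#' @param case_cf_rpkm RPKM matrix of case cfDNA samples (windows x samples).
#' @param case_tissue_rpkm RPKM matrix of case tissue samples.
#' @param healthy_rpkm RPKM matrix of healthy cfDNA samples (>= 2 columns).
#' @param combined_beta Combined background beta per window (names must
#'   cover the rows of the RPKM matrices).
#' @param tau_grid Candidate thresholds in `[0, 1]`.
#' @param split_seed Seed for the healthy split.
#' @param eps Pseudocount (RPKM units) in fold-change ratios; default 0.5.
#' @param min_windows Thresholds keeping fewer windows than this have their
#'   correlation recorded as `NA` and are never selected (default 10).
#' @return List with `table` (data frame: `tau`, `n_kept`, `rho`),
#'   `selected_tau`, and the half assignments.
#' @export
scan_exclusion_threshold <- function(case_cf_rpkm, case_tissue_rpkm,
                                     healthy_rpkm, combined_beta,
                                     tau_grid = seq(0.05, 0.5, by = 0.05),
                                     split_seed = NULL, eps = 0.5,
                                     min_windows = 10L) {
  if (ncol(healthy_rpkm) < 2L) stop(">= 2 healthy samples required", call. = FALSE)
  if (any(tau_grid < 0 | tau_grid > 1)) stop("tau_grid must lie in [0, 1]", call. = FALSE)
  ids <- rownames(case_cf_rpkm)
  stopifnot(identical(ids, rownames(case_tissue_rpkm)),
            identical(ids, rownames(healthy_rpkm)))
  beta <- combined_beta[ids]

  nh <- ncol(healthy_rpkm)
  half_n <- nh %/% 2L
  perm <- with_seed(split_seed, sample.int(nh))
  half_a <- sort(perm[seq_len(half_n)])
  half_b <- sort(perm[half_n + seq_len(half_n)])

  lfc_cf <- log2((rowMeans(case_cf_rpkm) + eps) /
                 (rowMeans(healthy_rpkm[, half_a, drop = FALSE]) + eps))
  lfc_tissue <- log2((rowMeans(case_tissue_rpkm) + eps) /
                     (rowMeans(healthy_rpkm[, half_b, drop = FALSE]) + eps))

  evaluable <- !is.na(beta)
  res <- lapply(tau_grid, function(tau) {
    keep <- evaluable & beta <= tau
    n_kept <- sum(keep)
    rho <- if (n_kept >= min_windows) {
      suppressWarnings(stats::cor(lfc_cf[keep], lfc_tissue[keep],
                                  method = "spearman"))
    } else NA_real_
    c(n_kept = n_kept, rho = rho)
  })
  tab <- data.frame(tau = tau_grid,
                    n_kept = vapply(res, `[[`, numeric(1), "n_kept"),
                    rho = vapply(res, `[[`, numeric(1), "rho"))
  selected <- if (all(is.na(tab$rho))) NA_real_ else {
    tab$tau[which.max(replace(tab$rho, is.na(tab$rho), -Inf))]
  }
  list(table = tab, selected_tau = selected,
       healthy_half_cf = colnames(healthy_rpkm)[half_a],
       healthy_half_tissue = colnames(healthy_rpkm)[half_b])
}

#' Read a cell-type beta panel and weights from TSV files
#'
#' @param beta_path TSV with header: `window_id` column then one column per
#'   cell type.
#' @param weights_path Two-column TSV (`cell_type`, `weight`), no header
#'   required.
#' @return List with `beta` matrix and named `weights` vector.
#' @export
read_beta_panel <- function(beta_path, weights_path) {
  df <- utils::read.table(beta_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  beta <- as.matrix(df[, -1, drop = FALSE])
  rownames(beta) <- df[[1]]
  wdf <- utils::read.table(weights_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (is.character(wdf[[2]])) {  # tolerate a header row
    wdf <- utils::read.table(weights_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  }
  weights <- stats::setNames(as.numeric(wdf[[2]]), wdf[[1]])
  list(beta = beta, weights = weights)
}
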