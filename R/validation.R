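#' Directional intersection of two DMR sets
#'
#' @param cf,tissue `dmr_set` objects (see [call_dmrs()]) on the same
#'   window universe.
#' @param direction `"hyper"` or `"hypo"`; both sets are intersected in the
#'   same direction (cross-direction overlap is rejected by contract).
#' @param universe Optional vector of valid window ids; members of either
#'   set outside it raise an error.
#' @return Character vector of shared window ids.
#' @export
intersect_dmrs <- function(cf, tissue, direction = c("hyper", "hypo"),
                           universe = NULL) {
  direction <- match.arg(direction)
  a <- cf[[direction]]
  b <- tissue[[direction]]
  if (!is.null(universe)) {
    unknown <- setdiff(c(a, b), universe)
    if (length(unknown)) {
      stop("window id outside the declared universe: ", unknown[1],
           call. = FALSE)
    }
  }
  intersect(a, b)
}

#' Permutation test for window-set overlap
#'
#' Tests whether the observed overlap between a cfDNA DMR set and a tissue
#' DMR set exceeds chance, by drawing `|cf|` windows uniformly without
#' replacement from the tested universe `n_perm` times and recording the
#' overlap with the tissue set. The p-value is the fraction of null draws
#' with overlap greater than or equal to the observed overlap (no +1
#' correction); when no null draw reaches it the numeric p is 0 and the
#' display value floors at `1/n_perm`. The uniform-draw null is exactly
#' hypergeometric.
#'
#' @param cf Character vector of cfDNA DMR window ids (must lie in
#'   `universe`).
#' @param tissue Character vector of tissue DMR window ids (subset of
#'   `universe`).
#' @param universe The tested window universe (background-depleted,
#'   low-count-filtered ids).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return List of class `permutation_result`: `observed_overlap`,
#'   `null_overlaps`, `p_value`, `p_display`, `n_perm`, `seed`.
#' @export
permutation_overlap_test <- function(cf, tissue, universe,
                                     n_perm = 10000L, seed = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (length(setdiff(tissue, universe))) {
    stop("tissue set is not a subset of the universe", call. = FALSE)
  }
  if (length(setdiff(cf, universe))) {
    stop("cf set is not a subset of the universe", call. = FALSE)
  }
  cf_size <- length(cf)
  observed <- length(intersect(cf, tissue))
  n_u <- length(universe)
  in_tissue <- universe %in% tissue
  null_overlaps <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sum(in_tissue[sample.int(n_u, cf_size)]),
           integer(1))
  })
  p <- sum(null_overlaps >= observed) / n_perm
  structure(list(observed_overlap = observed,
                 null_overlaps = null_overlaps,
                 p_value = p,
                 p_display = if (p == 0) sprintf("< %g", 1 / n_perm) else
                   format(p),
                 n_perm = n_perm,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation overlap test: observed = %d, p %s (%d permutations)\n",
              x$observed_overlap,
              if (x$p_value == 0) x$p_display else paste("=", format(x$p_value)),
              x$n_perm))
  invisible(x)
}
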