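#' Construct a validated window set
#'
#' A window set is the fixed universe of non-overlapping genomic windows
#' (methylation blocks) on which every downstream stage operates. Coordinates
#' are 0-based half-open (BED convention).
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `window_id`,
#'   `n_cpg`.
#' @param provenance Character note recording source and filters applied.
#' @return A `window_set`: the sorted, validated data frame with a
#'   `provenance` attribute.
#' @export
window_set <- function(df, provenance = "constructed in memory") {
  required <- c("chrom", "start", "end", "window_id", "n_cpg")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("window set is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[required]
  df$chrom <- as.character(df$chrom)
  df$window_id <- as.character(df$window_id)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$n_cpg <- as.integer(df$n_cpg)
  if (nrow(df)) {
    bad <- which(!(df$end > df$start))
    if (length(bad)) {
      stop(sprintf("window '%s' has end <= start", df$window_id[bad[1]]),
           call. = FALSE)
    }
    if (any(df$n_cpg < 0, na.rm = TRUE)) stop("n_cpg must be >= 0", call. = FALSE)
    dup <- df$window_id[duplicated(df$window_id)]
    if (length(dup)) {
      stop("duplicate window_id: ", dup[1], call. = FALSE)
    }
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    same_chrom <- df$chrom[-1] == df$chrom[-nrow(df)]
    overlap <- same_chrom & df$start[-1] < df$end[-nrow(df)]
    if (any(overlap)) {
      i <- which(overlap)[1]
      stop(sprintf("windows '%s' and '%s' overlap",
                   df$window_id[i], df$window_id[i + 1L]), call. = FALSE)
    }
    rownames(df) <- NULL
  }
  structure(df, provenance = provenance, class = c("window_set", "data.frame"))
}

#' Read a window universe from a BED5-like file
#'
#' Expects tab-separated `chrom start end window_id n_cpg` with no header,
#' 0-based half-open coordinates. Gzip-compressed files are read
#' transparently.
#'
#' @param path Path to the window file.
#' @return A [window_set()].
#' @export
read_windows <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty window file: ", path)
    return(window_set(data.frame(chrom = character(), start = numeric(),
                                 end = numeric(), window_id = character(),
                                 n_cpg = integer()),
                      provenance = paste0("read from ", path)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    stop(sprintf("malformed window line %d: expected 5 tab-separated fields",
                 which(nf < 5L)[1]), call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:5))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  ncpg <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | is.na(ncpg))
  if (length(bad)) {
    stop(sprintf("malformed window line %d: non-numeric coordinate or CpG count",
                 bad[1]), call. = FALSE)
  }
  window_set(data.frame(chrom = m[, 1], start = start, end = end,
                        window_id = m[, 4], n_cpg = ncpg,
                        stringsAsFactors = FALSE),
             provenance = paste0("read from ", path))
}

#' Write a window set to a BED5-like file
#'
#' @param ws A [window_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows <- function(ws, path) {
  utils::write.table(as.data.frame(ws)[, c("chrom", "start", "end",
                                           "window_id", "n_cpg")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter windows by CpG content and chromosome
#'
#' Windows covering fewer than `min_cpg` CpG sites, or mapping to excluded
#' chromosomes (by default the sex chromosomes and the mitochondrial genome),
#' are removed from the universe before any differential analysis.
#'
#' @param ws A [window_set()].
#' @param min_cpg Minimum CpG count to retain a window (default 3; windows
#'   with fewer are dropped, `n_cpg == min_cpg` is kept).
#' @param exclude_chroms Chromosome names to drop entirely.
#' @return The filtered [window_set()]; warns when empty.
#' @export
filter_windows <- function(ws, min_cpg = 3L,
                           exclude_chroms = c("chrX", "chrY", "chrM")) {
  keep <- ws$n_cpg >= min_cpg & !(ws$chrom %in% exclude_chroms)
  out <- window_set(as.data.frame(ws)[keep, , drop = FALSE],
                    provenance = paste0(attr(ws, "provenance"),
                                        sprintf("; filtered min_cpg=%d, excluded {%s}",
                                                min_cpg,
                                                paste(exclude_chroms, collapse = ","))))
  if (!nrow(out)) warning("no windows left after filtering")
  out
}

windows_to_granges <- function(ws) {
  GenomicRanges::GRanges(
    seqnames = ws$chrom,
    ranges = IRanges::IRanges(start = ws$start + 1L, end = ws$end)
  )
}

#' Read fragment intervals from a BED-like file
#'
#' Expects `chrom start end` (a 4th column, if present, is taken as the
#' sample identifier). Gzip-compressed files are read transparently.
#'
#' @param path Path to the fragment file.
#' @param sample_id Sample name to attach when the file has no 4th column.
#' @return Data frame with columns `chrom`, `start`, `end`, `sample_id`.
#' @export
read_fragments <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  df <- utils::read.table(con, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  df[[1]] <- as.character(df[[1]])
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4] <- "sample_id" else {
    df$sample_id <- if (is.null(sample_id)) {
      sub("\\.bed(\\.gz)?$", "", basename(path))
    } else sample_id
  }
  if (any(df$end <= df$start)) stop("fragment with end <= start", call. = FALSE)
  df[c("chrom", "start", "end", "sample_id")]
}

#' Count fragments into windows by the midpoint rule
#'
#' Each fragment is assigned to the single window whose half-open interval
#' contains the fragment midpoint `floor((start + end) / 2)`, so no fragment
#' is ever double-counted across a non-overlapping universe. Fragments whose
#' midpoint falls outside every window (or on an unknown chromosome) are
#' skipped and tallied.
#'
#' @param fragments Data frame with `chrom`, `start`, `end` (0-based
#'   half-open) for one sample.
#' @param ws A [window_set()].
#' @return List with `counts` (named integer vector over `window_id`),
#'   `library_size` (number of window-assigned fragments) and `n_skipped`.
#' @export
count_fragments <- function(fragments, ws) {
  counts <- integer(nrow(ws))
  names(counts) <- ws$window_id
  n <- nrow(fragments)
  if (n == 0L || nrow(ws) == 0L) {
    return(list(counts = counts, library_size = 0L, n_skipped = n))
  }
  mid <- floor((fragments$start + fragments$end) / 2)
  gr_mid <- GenomicRanges::GRanges(
    seqnames = fragments$chrom,
    ranges = IRanges::IRanges(start = mid + 1, width = 1L)
  )
  gr_win <- windows_to_granges(ws)
  suppressWarnings({
    hits <- GenomicRanges::findOverlaps(gr_mid, gr_win)
  })
  idx <- S4Vectors::subjectHits(hits)
  tab <- tabulate(idx, nbins = nrow(ws))
  counts[] <- tab
  assigned <- length(idx)
  list(counts = counts, library_size = assigned, n_skipped = n - assigned)
}

#' Assemble a count matrix from per-sample fragment sets
#'
#' @param fragment_list Named list of per-sample fragment data frames.
#' @param ws A [window_set()].
#' @return A `count_matrix`: integer matrix (windows x samples) carrying a
#'   `library_sizes` attribute recorded at full-universe count time.
#' @export
count_matrix_from_fragments <- function(fragment_list, ws) {
  stopifnot(length(names(fragment_list)) == length(fragment_list))
  cols <- lapply(fragment_list, count_fragments, ws = ws)
  values <- vapply(cols, `[[`, numeric(nrow(ws)), "counts")
  if (nrow(ws) == 1L) values <- matrix(values, nrow = 1L,
                                       dimnames = list(ws$window_id, names(cols)))
  lib <- vapply(cols, `[[`, numeric(1), "library_size")
  count_matrix(values, lib)
}

#' Construct a count matrix with recorded library sizes
#'
#' Library sizes are recorded once, at full-universe count time, and are not
#' recomputed after window subsetting; RPKM denominators therefore survive
#' restriction to a DMR subset.
#'
#' @param values Non-negative matrix, rows = window_id, columns = sample_id.
#' @param library_sizes Per-sample totals of window-assigned fragments;
#'   defaults to column sums.
#' @return A `count_matrix`.
#' @export
count_matrix <- function(values, library_sizes = colSums(values)) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("count matrix needs window_id rownames and sample_id colnames",
         call. = FALSE)
  }
  library_sizes <- stats::setNames(as.numeric(library_sizes), colnames(values))
  structure(values, library_sizes = library_sizes,
            class = c("count_matrix", class(values)))
}

#' Library sizes recorded on a count matrix
#' @param cm A [count_matrix()].
#' @return Named numeric vector.
#' @export
library_sizes <- function(cm) attr(cm, "library_sizes")

#' Subset a count matrix by window, keeping recorded library sizes
#' @param cm A [count_matrix()].
#' @param window_ids Window ids to retain (order preserved).
#' @return A [count_matrix()] over the requested windows.
#' @export
subset_windows <- function(cm, window_ids) {
  missing <- setdiff(window_ids, rownames(cm))
  if (length(missing)) {
    stop("window ids absent from count matrix: ", missing[1], call. = FALSE)
  }
  count_matrix(unclass(cm)[window_ids, , drop = FALSE], library_sizes(cm))
}

#' Compute RPKM abundances
#'
#' `RPKM = count * 1e9 / (window_length_bp * library_size)`, with window
#' length `end - start` in bp and the library size recorded on the count
#' matrix (window-assigned fragments at full-universe count time).
#'
#' @param cm A [count_matrix()].
#' @param ws The [window_set()] providing window lengths; every row of `cm`
#'   must be present.
#' @return Numeric matrix of RPKM values, same dimnames as `cm`.
#' @export
compute_rpkm <- function(cm, ws) {
  lib <- library_sizes(cm)
  zero <- names(lib)[lib <= 0]
  if (length(zero)) {
    stop("library size is zero for sample: ", zero[1], call. = FALSE)
  }
  idx <- match(rownames(cm), ws$window_id)
  if (anyNA(idx)) {
    stop("window ids absent from window set: ",
         rownames(cm)[which(is.na(idx))[1]], call. = FALSE)
  }
  len <- ws$end[idx] - ws$start[idx]
  values <- unclass(cm)
  attr(values, "library_sizes") <- NULL
  sweep(values * 1e9 / len, 2L, lib, "/")
}

#' Downsample fragments uniformly without replacement
#'
#' @param fragments Fragment data frame.
#' @param target_n Number of fragments to retain; if `target_n >= nrow`, all
#'   are kept.
#' @param seed Optional integer seed for reproducibility.
#' @return The downsampled fragment data frame.
#' @export
downsample_fragments <- function(fragments, target_n, seed = NULL) {
  if (target_n < 0) stop("target_n must be >= 0", call. = FALSE)
  n <- nrow(fragments)
  if (target_n >= n) return(fragments)
  keep <- with_seed(seed, sort(sample.int(n, target_n)))
  fragments[keep, , drop = FALSE]
}

#' Downsample a count vector without replacement
#'
#' Equivalent to downsampling the underlying fragments and re-counting:
#' draws `target_n` of the `sum(counts)` assigned fragments uniformly
#' without replacement (multivariate hypergeometric over windows).
#'
#' @param counts Named non-negative integer vector.
#' @param target_n Fragments to retain; capped at `sum(counts)`.
#' @param seed Optional integer seed.
#' @return Downsampled counts vector, same names.
#' @export
downsample_counts <- function(counts, target_n, seed = NULL) {
  total <- sum(counts)
  if (target_n >= total) return(counts)
  picked <- with_seed(seed, sample.int(total, target_n))
  cum <- cumsum(counts)
  win <- findInterval(picked - 1L, c(0, cum), rightmost.closed = FALSE)
  out <- tabulate(win, nbins = length(counts))
  names(out) <- names(counts)
  out
}

#' Write a count matrix as TSV with a JSON sidecar
#'
#' The sidecar records library sizes and provenance so RPKM stays
#' reproducible after the matrix is re-read.
#'
#' @param cm A [count_matrix()].
#' @param path TSV path; the sidecar is written to `paste0(path, ".json")`.
#' @param provenance Free-text provenance note.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path, provenance = "") {
  df <- data.frame(window_id = rownames(cm), unclass(cm),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(library_sizes = as.list(library_sizes(cm)), provenance = provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#' @param path TSV path (sidecar expected at `paste0(path, ".json")`).
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$window_id
  sidecar <- paste0(path, ".json")
  lib <- if (file.exists(sidecar)) {
    unlist(jsonlite::read_json(sidecar)$library_sizes)[colnames(values)]
  } else colSums(values)
  count_matrix(values, lib)
}
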