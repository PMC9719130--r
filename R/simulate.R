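#' Simulation configuration
#'
#' Default parameters define the reference study conditions emulated by the
#' generator: a 20,000-window universe with CpG counts from a truncated
#' geometric distribution (mean 5), six hematopoietic/endothelial cell
#' types with bimodal beta profiles, 200 planted tumor hyper-DMRs (beta
#' effect +0.6) restricted to low-background windows, a 20-case / 13-control
#' cfDNA cohort (tumor fractions 0.15-0.35, giving planted log2
#' fold-changes near 2 under the enrichment model), 15 tumor / 10 normal
#' tissue samples, negative-binomial counts at 5e5 fragments per sample
#' with dispersion 0.2, longitudinal tumor-fraction trajectories
#' (exponential response decay, then exponential regrowth after resistance
#' onset, radiologic progression labeled when the fraction rebounds to 80%
#' of baseline), and segmental copy-number alterations on a 240 x 1-Mb bin
#' genome. Case samples additionally carry a shifted leukocyte composition
#' (neutrophilia with lymphopenia) so hematopoietic high-beta windows
#' contain genuine non-tumor case-control confounding — the signal the
#' background mask is designed to remove.
#'
#' @param ... Named overrides of any default.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    # window universe
    n_windows = 20000L,
    cpg_geom_p = 0.2,          # n_cpg = 1 + Geom(p)
    window_bp_per_cpg = 60,    # window length = 150 + 60 * n_cpg
    n_chroms = 22L,
    # cell-type panel
    cell_types = c("granulocyte", "megakaryocyte", "monocyte",
                   "lymphocyte", "erythroblast", "endothelial"),
    weights_healthy = c(0.25, 0.24, 0.12, 0.13, 0.06, 0.20),
    weights_case = c(0.62, 0.13, 0.07, 0.04, 0.04, 0.10),
    p_high = 0.25,             # per cell type, P(window in methylated mode)
    beta_high = c(20, 4),      # Beta shape of the methylated mode
    beta_low = c(2, 150),      # Beta shape of the unmethylated mode
    composition_concentration = 300,  # Dirichlet concentration of weights
    # planted tumor methylome
    n_true_dmrs = 200L,
    dmr_effect = 0.55,
    host_beta_max = 0.05,      # planted DMRs sit on fully unmethylated background
    host_min_cpg = 3L,         # and on windows surviving the CpG filter
    # cohorts
    n_cases = 20L,
    n_controls = 13L,
    n_tissue_tumor = 15L,
    n_tissue_normal = 10L,
    f_case_range = c(0.15, 0.35),
    f_tissue = 0.6,
    # enrichment / counting model
    depth = 5e5,
    dispersion = 0.2,
    capture_baseline = 0.2,    # nonspecific pulldown term `a`
    # longitudinal trajectories
    n_patients_longitudinal = 11L,
    sampling_interval_days = 42,
    f0_range = c(0.2, 0.5),
    r_resp_range = c(0.02, 0.05),   # per-day response decay rate
    t_onset_range = c(60, 240),     # days to resistance onset
    r_res_range = c(0.015, 0.03),   # per-day regrowth rate
    pd_rebound_frac = 1.0,          # radiologic PD once f regrows to baseline
    horizon_days = 540,
    start_date = as.Date("2020-01-01"),
    # copy-number simulation
    cna_chrom_lengths = stats::setNames(rep(60e6, 4),
                                        paste0("chr", 1:4)),
    cna_bin_size = 1e6,
    cna_depth = 150000L,
    cna_platform_bias_sd = 0.05,
    cna_n_panel = 16L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) stop("unknown config field: ", unknown[1], call. = FALSE)
  cfg[names(overrides)] <- overrides
  stopifnot(abs(sum(cfg$weights_healthy) - 1) < 1e-8,
            abs(sum(cfg$weights_case) - 1) < 1e-8,
            cfg$depth > 0, cfg$dispersion >= 0)
  structure(cfg, class = c("sim_config", "list"))
}

#' Simulate the window universe and cell-type beta panel
#'
#' CpG counts are 1 plus a geometric draw; window lengths grow with CpG
#' content; per-cell-type beta values come from a two-component Beta
#' mixture (unmethylated/methylated modes). The emitted healthy cell-type
#' weights are the ground truth consumed by [combine_background()].
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List: `windows` ([window_set()]), `beta` (windows x cell types),
#'   `weights` (healthy ground-truth weights), `config`.
#' @export
simulate_reference <- function(config = sim_config(), seed = 1L) {
  with_seed(seed, {
    n <- config$n_windows
    n_cpg <- 1L + stats::rgeom(n, config$cpg_geom_p)
    len <- 150 + config$window_bp_per_cpg * n_cpg
    chrom <- paste0("chr", rep_len(seq_len(config$n_chroms), n))
    ord <- order(chrom)
    start <- unlist(lapply(split(len[ord], chrom[ord]), function(l) {
      cumsum(c(0, l[-length(l)] + 500))
    }), use.names = FALSE)
    ws <- window_set(data.frame(chrom = chrom[ord], start = start,
                                end = start + len[ord],
                                window_id = sprintf("w%05d", seq_len(n)),
                                n_cpg = n_cpg[ord],
                                stringsAsFactors = FALSE),
                     provenance = sprintf("simulated (seed %s)", seed))
    k <- length(config$cell_types)
    high <- matrix(stats::rbinom(n * k, 1L, config$p_high) == 1L, n, k)
    beta <- matrix(NA_real_, n, k,
                   dimnames = list(ws$window_id, config$cell_types))
    beta[high] <- stats::rbeta(sum(high), config$beta_high[1], config$beta_high[2])
    beta[!high] <- stats::rbeta(sum(!high), config$beta_low[1], config$beta_low[2])
    weights <- stats::setNames(config$weights_healthy, config$cell_types)
    list(windows = ws, beta = beta, weights = weights, config = config)
  })
}

#' Plant a tumor methylome on top of the background
#'
#' The tumor methylome equals the combined healthy background except at
#' `n_true_dmrs` windows sampled from those with combined beta at or below
#' `host_beta_max`, where the beta effect is added (capped at 1).
#'
#' @param ref Output of [simulate_reference()].
#' @param seed Integer seed.
#' @return List: `beta_tumor` (named vector), `dmr_ids`, `combined_beta`.
#' @export
simulate_tumor_methylome <- function(ref, seed = 2L) {
  config <- ref$config
  combined <- combine_background(ref$beta, ref$weights)
  ncpg <- stats::setNames(ref$windows$n_cpg, ref$windows$window_id)[names(combined)]
  hosts <- names(combined)[!is.na(combined) &
                             combined <= config$host_beta_max &
                             ncpg >= config$host_min_cpg]
  if (length(hosts) < config$n_true_dmrs) {
    stop("not enough low-background windows to host the planted DMRs",
         call. = FALSE)
  }
  dmr_ids <- with_seed(seed, sort(sample(hosts, config$n_true_dmrs)))
  beta_tumor <- combined
  beta_tumor[dmr_ids] <- pmin(1, beta_tumor[dmr_ids] + config$dmr_effect)
  list(beta_tumor = beta_tumor, dmr_ids = dmr_ids, combined_beta = combined)
}

# Dirichlet draw around base weights.
.r_dirichlet <- function(base, concentration) {
  g <- stats::rgamma(length(base), shape = base * concentration)
  g / sum(g)
}

#' Simulate MeDIP-like counts for one sample
#'
#' Per window, the mixture methylation is
#' `m_w = (1 - f) * background_w + f * beta_tumor_w`, where the sample's
#' background combines the cell-type panel with its own (Dirichlet-jittered)
#' composition weights. The pulldown propensity is
#' `lambda_w = L_w * (a + m_w * n_cpg_w)` (baseline nonspecific capture `a`
#' plus capture linear in methylated-CpG content) and counts are negative
#' binomial with mean `depth * lambda_w / sum(lambda)`; dispersion 0 gives
#' the Poisson limit.
#'
#' @param f Tumor fraction in `[0, 1]`.
#' @param ref Output of [simulate_reference()].
#' @param tumor Output of [simulate_tumor_methylome()].
#' @param seed Integer seed.
#' @param group `"control"` (healthy composition) or `"case"` (shifted
#'   composition).
#' @param depth Expected fragments (default from config).
#' @param sample_weights Optional fixed composition weights (skips the
#'   Dirichlet draw; with fixed healthy weights the background reduces to
#'   the combined panel beta).
#' @return List: `counts` (named vector), `weights`, `f`.
#' @export
simulate_sample_counts <- function(f, ref, tumor, seed = NULL,
                                   group = c("control", "case"),
                                   depth = NULL, sample_weights = NULL) {
  group <- match.arg(group)
  config <- ref$config
  if (f < 0 || f > 1) stop("f must lie in [0, 1]", call. = FALSE)
  if (is.null(depth)) depth <- config$depth
  with_seed(seed, {
    if (is.null(sample_weights)) {
      base <- if (group == "case") config$weights_case else config$weights_healthy
      sample_weights <- stats::setNames(
        .r_dirichlet(base, config$composition_concentration),
        config$cell_types)
    }
    bg <- drop(ref$beta %*% (sample_weights / sum(sample_weights)))
    m <- (1 - f) * bg + f * tumor$beta_tumor[rownames(ref$beta)]
    ws <- ref$windows
    len <- ws$end - ws$start
    lambda <- len * (config$capture_baseline + m * ws$n_cpg)
    mu <- depth * lambda / sum(lambda)
    counts <- if (config$dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
    list(counts = stats::setNames(counts, ws$window_id),
         weights = sample_weights, f = f)
  })
}

#' Emit fragment intervals realizing a count vector
#'
#' Places, for each window, `counts[w]` fragments with midpoints uniform in
#' the window; fragment extent is symmetric about the midpoint (up to
#' `frag_len / 2` each side, shrunk at chromosome start), so re-counting by
#' the midpoint rule reproduces the counts exactly.
#'
#' @param counts Named count vector over `ws` windows.
#' @param ws The [window_set()].
#' @param seed Optional integer seed.
#' @param frag_len Nominal fragment length (default 160 bp).
#' @return Fragment data frame (`chrom`, `start`, `end`).
#' @export
simulate_fragments <- function(counts, ws, seed = NULL, frag_len = 160L) {
  stopifnot(identical(names(counts), ws$window_id))
  with_seed(seed, {
    idx <- rep.int(seq_len(nrow(ws)), counts)
    span <- ws$end[idx] - ws$start[idx]
    mid <- ws$start[idx] + floor(stats::runif(length(idx)) * span)
    d <- pmax(1L, pmin(frag_len %/% 2L, mid))
    data.frame(chrom = ws$chrom[idx], start = mid - d, end = mid + d,
               stringsAsFactors = FALSE)
  })
}

# Longitudinal latent tumor-fraction trajectory for one patient.
.simulate_trajectory <- function(config, seed) {
  with_seed(seed, {
    f0 <- stats::runif(1, config$f0_range[1], config$f0_range[2])
    r_resp <- stats::runif(1, config$r_resp_range[1], config$r_resp_range[2])
    t_on <- stats::runif(1, config$t_onset_range[1], config$t_onset_range[2])
    r_res <- stats::runif(1, config$r_res_range[1], config$r_res_range[2])
    f_nadir <- f0 * exp(-r_resp * t_on)
    times <- seq(0, config$horizon_days, by = config$sampling_interval_days)
    f_t <- ifelse(times < t_on,
                  f0 * exp(-r_resp * times),
                  pmin(0.9, f_nadir * exp(r_res * (times - t_on))))
    pd <- times > t_on & f_t >= config$pd_rebound_frac * f0
    radiology <- ifelse(pd, "PD", ifelse(f_t <= 0.5 * f0, "PR", "SD"))
    # truncate the line at the first radiologic PD (therapy switch)
    stop_at <- if (any(pd)) which(pd)[1] else length(times)
    keep <- seq_len(stop_at)
    list(times = times[keep], f = f_t[keep], radiology = radiology[keep],
         t_onset = t_on, f0 = f0,
         radiologic_pd_day = if (any(pd)) times[which(pd)[1]] else NA_real_)
  })
}

#' Simulate a complete study cohort with ground truth
#'
#' Generates the reference panel, the planted tumor methylome, count
#' matrices for the discovery cohort (cases at their drawn tumor fractions,
#' controls at 0) and the tissue cohort (tumor tissue at `f_tissue`, normal
#' tissue at 0), a dated longitudinal cohort following
#' decay-then-regrowth tumor-fraction trajectories with radiology labels
#' and co-measured genomic markers, and the ground truth needed for
#' parameter-recovery experiments.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; all internal streams derive from it.
#' @return List of class `sim_cohort`: `ref`, `tumor`, `counts_cf`,
#'   `counts_tissue`, `counts_longitudinal`, `sample_sheet`,
#'   `longitudinal_sheet`, `truth`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  ref <- simulate_reference(config, seed = child_seed(seed, 1L))
  tumor <- simulate_tumor_methylome(ref, seed = child_seed(seed, 2L))

  f_cases <- with_seed(child_seed(seed, 3L),
                       stats::runif(config$n_cases, config$f_case_range[1],
                                    config$f_case_range[2]))
  make_counts <- function(fs, groups, prefix, seed_base) {
    sims <- lapply(seq_along(fs), function(i) {
      simulate_sample_counts(fs[i], ref, tumor,
                             seed = child_seed(seed_base, i),
                             group = groups[i])
    })
    values <- vapply(sims, function(s) s$counts, numeric(config$n_windows))
    colnames(values) <- sprintf("%s%02d", prefix, seq_along(fs))
    list(cm = count_matrix(values), f = fs)
  }
  cf <- make_counts(c(f_cases, rep(0, config$n_controls)),
                    rep(c("case", "control"),
                        c(config$n_cases, config$n_controls)),
                    "cf", child_seed(seed, 4L))
  cf_groups <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  tis <- make_counts(c(rep(config$f_tissue, config$n_tissue_tumor),
                       rep(0, config$n_tissue_normal)),
                     rep("control", config$n_tissue_tumor + config$n_tissue_normal),
                     "t", child_seed(seed, 5L))
  tis_groups <- rep(c("case", "control"),
                    c(config$n_tissue_tumor, config$n_tissue_normal))

  sample_sheet <- data.frame(
    sample_id = c(colnames(cf$cm), colnames(tis$cm)),
    compartment = rep(c("cfDNA", "tissue"),
                      c(ncol(cf$cm), ncol(tis$cm))),
    group = c(cf_groups, tis_groups),
    tumor_fraction = c(cf$f, tis$f),
    stringsAsFactors = FALSE)

  # longitudinal cohort
  n_pat <- config$n_patients_longitudinal
  long_rows <- list()
  long_counts <- list()
  truth_traj <- list()
  for (p in seq_len(n_pat)) {
    traj <- .simulate_trajectory(config, seed = child_seed(seed, 100L + p))
    pid <- sprintf("P%03d", p)
    for (j in seq_along(traj$times)) {
      sid <- sprintf("%s_t%02d", pid, j)
      sim <- simulate_sample_counts(
        traj$f[j], ref, tumor,
        seed = child_seed(seed, 1000L + 20L * p + j),
        group = "case")
      long_counts[[sid]] <- sim$counts
      long_rows[[sid]] <- data.frame(
        patient_id = pid, sample_id = sid,
        date = config$start_date + traj$times[j],
        therapy_line = paste0(pid, "_L1"),
        radiology = traj$radiology[j],
        end_reason = "switch",
        tumor_fraction = traj$f[j],
        stringsAsFactors = FALSE)
    }
    truth_traj[[pid]] <- list(
      f0 = traj$f0, t_onset = traj$t_onset,
      molecular_onset_date = as.character(config$start_date + traj$t_onset),
      radiologic_pd_date = if (is.na(traj$radiologic_pd_day)) NA_character_ else
        as.character(config$start_date + traj$radiologic_pd_day))
  }
  longitudinal_sheet <- do.call(rbind, long_rows)
  rownames(longitudinal_sheet) <- NULL
  counts_long <- count_matrix(do.call(cbind, long_counts))
  colnames(counts_long) <- names(long_counts)

  genomic <- with_seed(child_seed(seed, 7L), {
    f <- longitudinal_sheet$tumor_fraction
    fus <- 100 * f * exp(stats::rnorm(length(f), 0, 0.4))
    tm <- 0.004 + 0.12 * f * exp(stats::rnorm(length(f), 0, 0.3))
    fus[stats::runif(length(f)) < 0.1] <- NA  # assay dropouts
    list(fusion_pct = fus, t_mad = tm)
  })
  longitudinal_sheet$fusion_pct <- genomic$fusion_pct
  longitudinal_sheet$t_mad <- genomic$t_mad

  structure(list(
    ref = ref, tumor = tumor,
    counts_cf = cf$cm, cf_groups = cf_groups,
    counts_tissue = tis$cm, tissue_groups = tis_groups,
    counts_longitudinal = counts_long,
    sample_sheet = sample_sheet,
    longitudinal_sheet = longitudinal_sheet,
    truth = list(dmr_ids = tumor$dmr_ids,
                 combined_beta = tumor$combined_beta,
                 tumor_fraction = stats::setNames(c(cf$f, tis$f),
                                                  sample_sheet$sample_id),
                 trajectories = truth_traj),
    seed = seed, config = config),
    class = "sim_cohort")
}

#' Simulate a paired two-platform copy-number cohort
#'
#' Each sample carries a latent tumor fraction and a segmental
#' copy-number-alteration map (whole-chromosome gains/losses); bin coverage
#' follows `(1 - f) + f * CN / 2` times a platform-specific fixed bin bias
#' (shared across samples of a platform, as enrichment bias would be, and
#' therefore absorbed by platform-matched panel normalization). Fragments
#' are emitted for both platforms from the same ground truth, alongside
#' platform-matched healthy panel count matrices.
#'
#' @param config A [sim_config()].
#' @param n_samples Cohort size (default 30).
#' @param seed Integer seed.
#' @return List: `bins`, `fragments_a` (sWGS-like), `fragments_b`
#'   (MeDIP-like), `panel_a`, `panel_b` (bin-count matrices), `truth`
#'   (per-sample `f`, segment maps).
#' @export
simulate_cna_cohort <- function(config = sim_config(), n_samples = 30L,
                                seed = 1L) {
  bins <- make_bins(config$cna_chrom_lengths, config$cna_bin_size)
  nb <- nrow(bins)
  bin_ws <- window_set(data.frame(chrom = bins$chrom, start = bins$start,
                                  end = bins$end, window_id = bins$bin_id,
                                  n_cpg = 0L), provenance = "cna bins")
  bias <- with_seed(child_seed(seed, 1L), list(
    a = exp(stats::rnorm(nb, 0, config$cna_platform_bias_sd)),
    b = exp(stats::rnorm(nb, 0, config$cna_platform_bias_sd))))
  chroms <- names(config$cna_chrom_lengths)

  draw_counts <- function(ratio, platform_bias, depth, s) {
    p <- ratio * platform_bias
    with_seed(s, stats::setNames(
      as.integer(stats::rmultinom(1, depth, p / sum(p))), bins$bin_id))
  }
  sample_truth <- with_seed(child_seed(seed, 2L), {
    lapply(seq_len(n_samples), function(i) {
      f <- stats::runif(1, 0.02, 0.4)
      altered <- sample(chroms, sample(1:3, 1))
      cn <- sample(c(1L, 3L, 4L), length(altered), replace = TRUE)
      list(f = f, altered = altered, cn = stats::setNames(cn, altered))
    })
  })
  ratio_of <- function(tr) {
    r <- rep(1, nb)
    for (chr in tr$altered) {
      sel <- bins$chrom == chr
      r[sel] <- (1 - tr$f) + tr$f * tr$cn[[chr]] / 2
    }
    r
  }
  frags <- function(platform_bias, tr, k) {
    counts <- draw_counts(ratio_of(tr), platform_bias, config$cna_depth,
                          child_seed(seed, 10L + k))
    simulate_fragments(counts, bin_ws, seed = child_seed(seed, 5000L + k))
  }
  ids <- sprintf("s%02d", seq_len(n_samples))
  fragments_a <- stats::setNames(lapply(seq_len(n_samples), function(i)
    frags(bias$a, sample_truth[[i]], 2L * i)), ids)
  fragments_b <- stats::setNames(lapply(seq_len(n_samples), function(i)
    frags(bias$b, sample_truth[[i]], 2L * i + 1L)), ids)
  panel <- function(platform_bias, n, base_k) {
    m <- vapply(seq_len(n), function(i)
      draw_counts(rep(1, nb), platform_bias, config$cna_depth,
                  child_seed(seed, base_k + i)), numeric(nb))
    rownames(m) <- bins$bin_id
    colnames(m) <- sprintf("h%02d", seq_len(n))
    m
  }
  list(bins = bins,
       fragments_a = fragments_a, fragments_b = fragments_b,
       panel_a = panel(bias$a, config$cna_n_panel, 20000L),
       panel_b = panel(bias$b, config$cna_n_panel, 30000L),
       truth = sample_truth)
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits the window BED, beta panel and weights TSVs, count matrices with
#' JSON sidecars, sample sheets, and the ground truth as JSON — exactly the
#' formats the package's readers consume.
#'
#' @param cohort A `sim_cohort` (see [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_windows(cohort$ref$windows, p("windows.bed"))
  beta_df <- data.frame(window_id = rownames(cohort$ref$beta),
                        cohort$ref$beta, check.names = FALSE)
  utils::write.table(beta_df, p("beta_panel.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(cell_type = names(cohort$ref$weights),
                                weight = as.numeric(cohort$ref$weights)),
                     p("cell_weights.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_count_matrix(cohort$counts_cf, p("counts_cf.tsv"),
                     provenance = "simulated cfDNA cohort")
  write_count_matrix(cohort$counts_tissue, p("counts_tissue.tsv"),
                     provenance = "simulated tissue cohort")
  write_count_matrix(cohort$counts_longitudinal, p("counts_longitudinal.tsv"),
                     provenance = "simulated longitudinal cohort")
  utils::write.table(cohort$sample_sheet, p("sample_sheet.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ls_out <- cohort$longitudinal_sheet
  ls_out$date <- as.character(ls_out$date)
  utils::write.table(ls_out, p("longitudinal_sheet.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(dmr_ids = cohort$truth$dmr_ids,
         tumor_fraction = as.list(cohort$truth$tumor_fraction),
         trajectories = cohort$truth$trajectories,
         seed = cohort$seed),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
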