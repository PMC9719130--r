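test_that("reference simulation has the declared shape and is seed-deterministic", {
  cfg <- sim_config(n_windows = 1000L)
  ref <- simulate_reference(cfg, seed = 1)
  expect_equal(nrow(ref$windows), 1000L)
  expect_true(all(ref$beta >= 0 & ref$beta <= 1))
  expect_equal(dim(ref$beta), c(1000L, length(cfg$cell_types)))
  expect_true(all(ref$windows$n_cpg >= 1))
  expect_equal(sum(ref$weights), 1)

  ref2 <- simulate_reference(cfg, seed = 1)
  expect_identical(ref$beta, ref2$beta)
  expect_identical(as.data.frame(ref$windows), as.data.frame(ref2$windows))
  expect_false(identical(ref$beta, simulate_reference(cfg, seed = 2)$beta))
})

test_that("low-background fraction matches a direct Monte-Carlo estimate", {
  cfg <- sim_config(n_windows = 8000L)
  ref <- simulate_reference(cfg, seed = 3)
  comb <- combine_background(ref$beta, ref$weights)
  observed <- mean(comb <= 0.15)
  # independent Monte-Carlo draw from the same mixture definition
  set.seed(99)
  n <- 40000
  k <- length(cfg$cell_types)
  hi <- matrix(rbinom(n * k, 1, cfg$p_high) == 1, n, k)
  b <- matrix(rbeta(n * k, cfg$beta_low[1], cfg$beta_low[2]), n, k)
  b[hi] <- rbeta(sum(hi), cfg$beta_high[1], cfg$beta_high[2])
  expected <- mean(drop(b %*% cfg$weights_healthy) <= 0.15)
  se <- sqrt(expected * (1 - expected) * (1 / 8000 + 1 / n))
  expect_lt(abs(observed - expected), 4 * se)
})

test_that("planted DMRs sit on low, evaluable background and shift the tumor beta", {
  cfg <- sim_config(n_windows = 3000L, n_true_dmrs = 50L)
  ref <- simulate_reference(cfg, seed = 4)
  tum <- simulate_tumor_methylome(ref, seed = 5)
  expect_length(tum$dmr_ids, 50L)
  expect_true(all(tum$combined_beta[tum$dmr_ids] <= 0.15))
  expect_true(all(tum$beta_tumor[tum$dmr_ids] -
                    tum$combined_beta[tum$dmr_ids] > 0))
  off <- setdiff(names(tum$beta_tumor), tum$dmr_ids)
  expect_equal(tum$beta_tumor[off], tum$combined_beta[off])

  # zero planted DMRs leaves the tumor methylome identical to background
  cfg0 <- sim_config(n_windows = 500L, n_true_dmrs = 0L)
  ref0 <- simulate_reference(cfg0, seed = 6)
  tum0 <- simulate_tumor_methylome(ref0, seed = 7)
  expect_equal(tum0$beta_tumor, tum0$combined_beta)
  expect_error(simulate_tumor_methylome(
    simulate_reference(sim_config(n_windows = 100L, n_true_dmrs = 90L), seed = 8),
    seed = 9), "not enough")
})

test_that("sample counts follow the enrichment model in expectation", {
  cfg <- sim_config(n_windows = 400L, dispersion = 0, depth = 3e5,
                    n_true_dmrs = 20L)
  ref <- simulate_reference(cfg, seed = 10)
  tum <- simulate_tumor_methylome(ref, seed = 11)
  reps <- sapply(1:40, function(i)
    simulate_sample_counts(0, ref, tum, seed = 200 + i,
                           sample_weights = ref$weights)$counts)
  mean_counts <- rowMeans(reps)
  ws <- ref$windows
  m <- tum$combined_beta
  lambda <- (ws$end - ws$start) * (cfg$capture_baseline + m * ws$n_cpg)
  mu <- cfg$depth * lambda / sum(lambda)
  # expected count ratios between windows track the lambda ratios
  expect_gt(cor(mean_counts, mu), 0.99)
  big <- mu > 20
  expect_lt(max(abs(mean_counts[big] - mu[big]) / (3 * sqrt(mu[big] / 40) + 1)), 1.5)

  # Poisson limit: variance ~ mean when dispersion is 0
  v <- apply(reps, 1, var)
  fit <- lm(v[big] ~ 0 + mu[big])
  expect_equal(unname(coef(fit)), 1, tolerance = 0.15)

  # a full tumor sample has elevated counts at planted DMRs
  f1 <- rowMeans(sapply(1:10, function(i)
    simulate_sample_counts(1, ref, tum, seed = 300 + i,
                           sample_weights = ref$weights)$counts))
  f0 <- rowMeans(reps)
  expect_gt(mean(f1[tum$dmr_ids]), mean(f0[tum$dmr_ids]) * 1.5)
})

test_that("cohort simulation is deterministic end-to-end and labels are coherent", {
  cfg <- sim_config(n_windows = 800L, depth = 5e4, n_true_dmrs = 40L,
                    n_patients_longitudinal = 4L)
  a <- simulate_cohort(cfg, seed = 12)
  b <- simulate_cohort(cfg, seed = 12)
  expect_identical(unclass(a$counts_cf), unclass(b$counts_cf))
  expect_identical(a$longitudinal_sheet, b$longitudinal_sheet)
  expect_identical(a$truth$dmr_ids, b$truth$dmr_ids)

  expect_equal(sum(a$cf_groups == "control"), cfg$n_controls)
  expect_true(all(a$truth$tumor_fraction[a$sample_sheet$group == "control"] == 0))

  # radiologic PD, when labeled, always follows the true molecular onset
  for (tr in a$truth$trajectories) {
    if (!is.na(tr$radiologic_pd_date)) {
      expect_gt(as.numeric(as.Date(tr$radiologic_pd_date) -
                             as.Date(tr$molecular_onset_date)), 0)
    }
  }
})

test_that("written cohorts round-trip through the package readers", {
  cfg <- sim_config(n_windows = 300L, depth = 2e4, n_true_dmrs = 15L,
                    n_patients_longitudinal = 2L)
  coh <- simulate_cohort(cfg, seed = 13)
  dir <- withr::local_tempdir()
  expect_no_warning(write_cohort(coh, dir))
  ws <- read_windows(file.path(dir, "windows.bed"))
  expect_equal(as.data.frame(ws), as.data.frame(coh$ref$windows),
               ignore_attr = TRUE)
  cm <- read_count_matrix(file.path(dir, "counts_cf.tsv"))
  expect_equal(unclass(cm), unclass(coh$counts_cf), ignore_attr = TRUE)
  expect_equal(library_sizes(cm), library_sizes(coh$counts_cf))
  panel <- read_beta_panel(file.path(dir, "beta_panel.tsv"),
                           file.path(dir, "cell_weights.tsv"))
  expect_equal(panel$beta, coh$ref$beta, tolerance = 1e-12)
  expect_equal(panel$weights, coh$ref$weights)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(unlist(truth$dmr_ids), coh$truth$dmr_ids, ignore_attr = TRUE)
})

test_that("DMR recall responds to effect size and depth", {
  grid <- expand.grid(effect = c(0.15, 0.55), depth = c(3e4, 3e5))
  recalls <- mapply(function(eff, dep) {
    cfg <- sim_config(n_windows = 4000L, n_true_dmrs = 60L,
                      dmr_effect = eff, depth = dep,
                      n_cases = 8L, n_controls = 8L)
    coh <- simulate_cohort(cfg, seed = 14)
    ws <- filter_windows(coh$ref$windows)
    cm <- subset_windows(coh$counts_cf, ws$window_id)
    mask <- apply_background_mask(coh$tumor$combined_beta[ws$window_id], 0.15)
    res <- run_dmr_analysis(cm, coh$cf_groups, keep_mask = mask)
    mean(coh$truth$dmr_ids %in% res$dmrs$hyper)
  }, grid$effect, grid$depth)
  # more effect helps at either depth; more depth helps at either effect
  expect_gt(recalls[2], recalls[1])
  expect_gt(recalls[4], recalls[3])
  expect_gte(recalls[3], recalls[1])
  expect_gte(recalls[4], recalls[2])
})
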