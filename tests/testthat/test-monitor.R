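mk_tp <- function(patient, line, dates, scores, radiology = NA,
                  end_reason = "switch") {
  data.frame(patient_id = patient, sample_id = paste0(patient, seq_along(dates)),
             date = as.Date(dates), therapy_line = line,
             radiology = rep_len(radiology, length(dates)),
             end_reason = end_reason, score_5mc = scores,
             stringsAsFactors = FALSE)
}

test_that("therapy-line segmentation groups, sorts, and rejects duplicates", {
  tp <- rbind(
    mk_tp("p1", "L1", c("2020-03-01", "2020-01-01", "2020-02-01"), c(2, 1, 3)),
    mk_tp("p1", "L2", c("2020-05-01", "2020-04-01"), c(1, 2)),
    mk_tp("p2", "L1", "2020-01-15", 5))
  lines <- segment_therapy_lines(tp)
  expect_length(lines, 3L)
  sizes <- vapply(lines, nrow, integer(1))
  expect_equal(unname(sizes), c(3L, 2L, 1L))
  expect_equal(lines[[1]]$score_5mc, c(1, 3, 2))  # date-sorted
  expect_error(segment_therapy_lines(rbind(tp, tp[1, ])), "duplicate")
})

test_that("the nadir rule reproduces the worked examples", {
  # [1.0, 0.6, 0.8]: nadir before t3 is 0.6; 0.8/0.6 = 1.33 >= 1.25 -> call
  line <- mk_tp("p1", "L1", c("2020-01-01", "2020-02-01", "2020-03-01"),
                c(1.0, 0.6, 0.8))
  call <- call_molecular_progression(segment_therapy_lines(line)[[1]])
  expect_true(call$called)
  expect_equal(call$call_date, as.Date("2020-03-01"))
  expect_equal(call$nadir, 0.6)
  expect_equal(call$pct_rise, 100 * (0.8 / 0.6 - 1), tolerance = 1e-12)

  # [1.0, 0.9, 1.0]: maximum rise 11% -> no call
  line2 <- mk_tp("p1", "L1", c("2020-01-01", "2020-02-01", "2020-03-01"),
                 c(1.0, 0.9, 1.0))
  expect_false(call_molecular_progression(segment_therapy_lines(line2)[[1]])$called)

  # monotone decreasing scores never trigger
  line3 <- mk_tp("p1", "L1", c("2020-01-01", "2020-02-01", "2020-03-01"),
                 c(1.0, 0.8, 0.5))
  expect_false(call_molecular_progression(segment_therapy_lines(line3)[[1]])$called)

  # a rise from a zero nadir counts as progression (infinite percent rise)
  line4 <- mk_tp("p1", "L1", c("2020-01-01", "2020-02-01", "2020-03-01"),
                 c(0.5, 0, 0.05))
  call4 <- call_molecular_progression(segment_therapy_lines(line4)[[1]])
  expect_true(call4$called)
  expect_equal(call4$pct_rise, Inf)
})

test_that("the nadir rule is prospective: calls replay identically on prefixes", {
  set.seed(5)
  for (i in 1:10) {
    n <- 8
    scores <- abs(cumsum(rnorm(n, 0, 0.3)) + 1)
    line <- mk_tp("p", "L", as.character(as.Date("2020-01-01") + 30 * (0:(n - 1))),
                  scores)
    full <- call_molecular_progression(line)
    if (full$called) {
      upto <- line[line$date <= full$call_date, ]
      replay <- call_molecular_progression(upto)
      expect_equal(replay$call_date, full$call_date)
      expect_equal(replay$nadir, full$nadir)
    }
  }
})

test_that("lead times follow calendar arithmetic with missed calls excluded", {
  expect_equal(lead_time(as.Date("2019-01-01"), as.Date("2019-04-01")), 90)
  expect_equal(lead_time(as.Date("2019-04-01"), as.Date("2019-04-01")), 0)
  expect_true(is.na(lead_time(as.Date("2019-05-01"), as.Date("2019-04-01"))))
  no_call <- structure(list(called = FALSE, call_date = as.Date(NA)),
                       class = "progression_call")
  expect_true(is.na(lead_time(no_call, as.Date("2019-04-01"))))
})

test_that("paired start-vs-PD test gives the exact p for 8 positive pairs", {
  lines <- lapply(1:8, function(i) {
    mk_tp(sprintf("p%d", i), "L1",
          c("2020-01-01", "2020-02-01", "2020-03-01"),
          c(1, 1.2, 1.5 + i / 10), radiology = c(NA, NA, "PD"))
  })
  tp <- do.call(rbind, lines)
  res <- paired_start_vs_pd(segment_therapy_lines(tp))
  expect_equal(res$n_pairs, 8L)
  expect_equal(res$n_increased, 8L)
  expect_equal(res$p_value, 2 / 2^8)  # exact enumeration: 0.0078125
  expect_equal(res$p_value, oracle_signed_rank_p(res$pairs$delta))
})

test_that("signed-rank p agrees with exhaustive enumeration for small n", {
  set.seed(9)
  for (n in c(5, 8, 10)) {
    delta <- round(rnorm(n, 0.2, 1), 3)
    delta[delta == 0] <- 0.1
    p_pkg <- suppressWarnings(
      wilcox.test(delta, exact = TRUE, alternative = "two.sided")$p.value)
    expect_equal(p_pkg, oracle_signed_rank_p(delta), tolerance = 1e-12)
  }
})

test_that("all-zero differences give p = 1 and lines without PD are skipped", {
  lines <- lapply(1:6, function(i) {
    mk_tp(sprintf("p%d", i), "L1", c("2020-01-01", "2020-03-01"),
          c(1, 1), radiology = c(NA, "PD"))
  })
  tp <- do.call(rbind, lines)
  res <- paired_start_vs_pd(segment_therapy_lines(tp))
  expect_equal(res$p_value, 1)
  expect_equal(res$n_increased, 0L)

  no_pd <- mk_tp("q1", "L1", c("2020-01-01", "2020-02-01"), c(1, 2))
  expect_error(paired_start_vs_pd(segment_therapy_lines(no_pd)), "no therapy line")
  # a line ending for another reason does not qualify
  censored <- mk_tp("q2", "L1", c("2020-01-01", "2020-02-01"), c(1, 2),
                    radiology = c(NA, "PD"), end_reason = "censored")
  expect_error(paired_start_vs_pd(segment_therapy_lines(censored)),
               "no therapy line")
})

test_that("molecular calls precede radiologic progression on resistant trajectories", {
  cfg <- sim_config(n_windows = 4000L, depth = 1e5,
                    n_patients_longitudinal = 12L)
  coh <- simulate_cohort(cfg, seed = 71)
  ctrl <- colnames(coh$counts_cf)[coh$cf_groups == "control"]
  base <- build_healthy_baseline(
    coh$counts_cf[, ctrl], coh$ref$windows,
    target_depth = length(ctrl) * min(library_sizes(coh$counts_cf)[ctrl]),
    seed = 3)
  rpkm <- compute_rpkm(coh$counts_longitudinal, coh$ref$windows)
  sheet <- coh$longitudinal_sheet
  sheet$score_5mc <- apply(rpkm[, sheet$sample_id], 2, five_mc_score,
                           baseline = base, dmr_windows = coh$truth$dmr_ids)
  mon <- monitor_cohort(sheet)
  expect_gte(mon$fraction_called_before_pd, 0.7)
  expect_true(all(mon$per_line$lead_days >= 0, na.rm = TRUE))
})
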