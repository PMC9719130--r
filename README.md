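# liquidmeth

Tumor-informative DNA methylation analysis of plasma cell-free DNA
(cfDNA) profiled by cfMeDIP-seq, for liquid-biopsy researchers who want to
discover tumor-derived hypermethylation markers, score them per sample,
and use them to detect tumor DNA and monitor therapy response — together
with a simplified chromosomal-instability readout (t-MAD) computable from
the same data.

## What it does

Most cfDNA originates from hematopoietic cells, so their methylation
dominates plasma methylomes and drowns tumor signal. `liquidmeth`
implements a discovery-to-monitoring pipeline built around suppressing
that background:

1. **Window counting** — fragments are counted by the midpoint rule into a
   fixed universe of non-overlapping methylation-block windows (≥ 3 CpGs,
   autosomes only), with abundance as
   RPKM = c·10⁹ / (L·N).
2. **Background depletion** — cell-type WGBS β profiles are combined with
   their predicted cfDNA abundances, β̄(w) = Σ_c w_c β_c(w), and windows
   with β̄ > τ (default 0.15) are excluded; τ can be tuned by scanning the
   rank correlation between case-cfDNA and case-tissue log2 fold-changes
   over split healthy references.
3. **DMR calling** — TMM-normalized log2-CPM, empirical-Bayes moderated
   t per window, BH-adjusted p < 0.1 and |log2FC| > 1, validated against
   tissue DMRs by a permutation overlap test (hypergeometric null).
4. **5-mC score** — per sample, the median absolute RPKM deviation from a
   pooled, depth-matched healthy baseline over the validated hyper-DMRs;
   tumor-DNA positivity when the score exceeds the healthy-cohort maximum.
5. **Monitoring** — therapy-line segmentation, paired start-vs-progression
   Wilcoxon tests, molecular progression at a ≥ 25% rise over the running
   line nadir, and lead times to radiologic progression.
6. **t-MAD** — trimmed median absolute deviation from neutrality of
   panel-normalized 1-Mb log2 coverage ratios, computable from sWGS-like
   or MeDIP-like fragments and comparable across platforms at a common
   depth.

A seeded synthetic-data generator (`simulate_cohort()`,
`simulate_cna_cohort()`) reproduces the statistical structure the analysis
assumes — planted DMRs on low-background windows, tumor-fraction-dependent
negative-binomial MeDIP counts, case leukocyte-composition shifts,
decay/regrowth tumor trajectories with radiology labels, segmental CNAs —
and exports the ground truth, so every stage is testable by parameter
recovery.

## A worked example

```r
library(liquidmeth)

coh  <- simulate_cohort(sim_config(), seed = 1)          # 20 cases vs 13 controls
ws   <- filter_windows(coh$ref$windows)                  # >= 3 CpGs, autosomes
cm   <- subset_windows(coh$counts_cf, ws$window_id)
mask <- apply_background_mask(coh$tumor$combined_beta[ws$window_id], 0.15)

res <- run_dmr_analysis(cm, coh$cf_groups, keep_mask = mask)
length(res$dmrs$hyper)
#> [1] 233
mean(coh$truth$dmr_ids %in% res$dmrs$hyper)   # recall of the 200 planted DMRs
#> [1] 0.985

ctrl <- colnames(cm)[coh$cf_groups == "control"]
bl   <- build_healthy_baseline(coh$counts_cf[, ctrl], coh$ref$windows,
                               target_depth = 13 * min(library_sizes(coh$counts_cf)[ctrl]),
                               seed = 2)
rpkm   <- compute_rpkm(coh$counts_cf, coh$ref$windows)
scores <- apply(rpkm, 2, five_mc_score, baseline = bl,
                dmr_windows = res$dmrs$hyper)
thr <- detection_threshold(scores[ctrl])                 # max of healthy
mean(classify_positive(scores[coh$cf_groups == "case"], thr))
#> [1] 1
```

233 hyper-DMRs are called of which 197/200 planted ones are recovered; the
detection threshold is the healthy-cohort maximum score, and every case
sample (tumor fractions 0.15–0.35) exceeds it while, by construction, no
healthy sample does.

A thin command-line wrapper over the same functions is in
`inst/scripts/liquidmeth-cli.R` (subcommands `count`, `background`, `dmr`,
`validate`, `score`, `tmad`, `simulate`).

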