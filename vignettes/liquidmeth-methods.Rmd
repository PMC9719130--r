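---
title: "Methods: tumor-informative cfDNA methylation analysis"
author: "liquidmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-informative cfDNA methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liquidmeth)
```

# Overview

`liquidmeth` implements an analysis strategy for detecting and monitoring
tumor-derived DNA in plasma through its methylation signal, as measured by
cfMeDIP-seq (immunoprecipitation of methylated cell-free DNA fragments
followed by sequencing). The pipeline has five stages:

1. **Counting.** Sequenced fragments are counted into a fixed universe of
   non-overlapping genomic windows (methylation blocks). Windows with fewer
   than 3 CpGs or on chrX/chrY/chrM are removed.
2. **Background depletion.** Most cfDNA comes from hematopoietic cells, so
   windows methylated in the weighted combination of blood cell types carry
   background rather than tumor information. Cell-type WGBS β values are
   combined as $\bar\beta_w = \sum_c w_c \beta_{c,w}$ and windows with
   $\bar\beta_w > \tau$ (default $\tau = 0.15$) are excluded.
3. **Differential methylation.** Patient versus healthy-donor cfDNA counts
   at the retained windows are TMM-normalized, converted to log2-CPM, and
   tested with an empirical-Bayes moderated t-statistic; DMRs are called at
   BH-adjusted $p < 0.1$ and $|\log_2 FC| > 1$. Hyper-DMRs are validated
   against tumor-vs-normal tissue DMRs by direct intersection and a
   permutation overlap test (uniform window resampling from the tested
   universe; the null is exactly hypergeometric).
4. **Scoring.** A pooled healthy baseline is built by downsampling healthy
   samples to a common depth and merging them; the per-sample **5-mC
   score** is the median absolute RPKM deviation from this baseline over
   the validated hyper-DMRs. The tumor-positivity threshold is the maximum
   score of the healthy cohort (strict `>` rule).
5. **Monitoring and chromosomal instability.** Longitudinal scores are
   segmented into therapy lines; molecular progression is called at the
   first timepoint rising ≥ 25% above the running line nadir, and lead
   times to radiologic progression are reported. Independently, a
   simplified chromosomal-instability score (t-MAD) is computed as the
   trimmed median absolute deviation of panel-normalized 1-Mb log2
   coverage ratios from neutrality.

# Statistical model

## Counting and abundance

Fragments are assigned to the window containing their midpoint
(`floor((start + end) / 2)`, half-open interval semantics), which
guarantees at most one count per fragment over a non-overlapping universe
and is deterministic. Library sizes are recorded at full-universe count
time, so subsetting to a DMR panel later never changes RPKM denominators:

$$\mathrm{RPKM}_{w,s} = \frac{c_{w,s} \cdot 10^9}{L_w \cdot N_s},$$

with $L_w = \mathrm{end} - \mathrm{start}$ in bp and $N_s$ the number of
window-assigned fragments.

## TMM and the moderated test

TMM follows the published construction: the reference sample is the one
whose upper-quartile count rate is closest to the cohort mean; per sample,
log-ratios (M) and average log-abundances (A) against the reference are
doubly trimmed (30% on M, 5% on A, two-sided) and the factor is 2 to the
precision-weighted mean of the retained M values, rescaled to geometric
mean 1. The unit tests verify equality with an independent brute-force
implementation (1e-8) and with `edgeR::calcNormFactors`.

The per-window two-group test is an OLS fit on log2-CPM (a weighted
least-squares fit reduces to OLS for an unweighted two-group design). The
residual variances $s^2_w$ with $d$ degrees of freedom are shrunk toward a
scaled inverse-chi-square prior $(d_0, s_0^2)$ estimated from the moments
of $\log s^2_w$ (trigamma inversion by Newton iteration); the moderated
statistic uses $\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ with
$d_0 + d$ degrees of freedom. With $d_0 = 0$ the statistic reduces exactly
to the ordinary equal-variance t (tested at 1e-10); with estimated $d_0$
it matches `limma::eBayes` on toy data. We use the *unweighted* moderated
t (no abundance trend, no voom precision weights): with a mean-variance
relationship in the counts this is mildly anti-conservative at
low-coverage windows, which is why the DMR-recovery acceptance check
budgets empirical FDR at twice the nominal α. A trend/voom layer is a
natural extension point.

The low-count rule keeps a window when it is nonzero in at least 20% of
samples (presence interpretation — the only reading that does not depend
on sequencing depth); the boundary is kept.

## Permutation overlap test

The null draws `|cfDNA DMR set|` windows uniformly without replacement
from the tested universe (background-depleted, low-count-filtered) and
counts the overlap with the tissue DMR set. The p-value is the fraction of
null overlaps greater than or equal to the observed overlap, with no +1
correction; a zero count is displayed as `< 1/n_perm`. Because windows are
the unit of testing, we resample window identities, not genomic
coordinates. The estimate is validated against the exact hypergeometric
tail on small instances, and the test's size at α = 0.05 is checked over
1,000 null replicates.

## Scores, thresholds, monitoring

The median of an even number of deviations is the midpoint of the two
central order statistics. The 5-mC positivity rule is strict (`>` the
healthy maximum); the t-MAD rule admits equality (`≥`), and per-marker
rules are configurable because the two conventions differ between markers.
Missing marker values are "not evaluable" and are excluded from
denominators rather than counted negative.

The therapy-line nadir is the running minimum over *strictly earlier*
timepoints, making the progression call prospective — replaying the line
up to the call date reproduces the call exactly (tested). A rise from a
zero nadir is treated as progression with infinite percent rise, since a
rise from undetectable is the strongest possible signal. For the paired
start-versus-progression comparison the pair is (first sample of the line,
first radiologic-PD sample of a line that ended in therapy switch or
death); the two-sided Wilcoxon signed-rank test is exact for small n.

## t-MAD

Bin counts (1-Mb default) are converted to proportions, the reference is
the per-bin median proportion of a platform-matched healthy panel, and the
profile is $\log_2((p_w + \varepsilon)/(r_w + \varepsilon))$ with
$\varepsilon = 10^{-6}$ on the proportion scale (small against typical bin
proportions; it only regularizes empty bins). Bins in the top 1% of panel
coefficient of variation or with a zero reference are blacklisted, the 2%
most extreme $|\log_2 R|$ bins are trimmed, and the score is the median
absolute deviation **from 0** (neutrality), not from the sample median —
so a flat profile scores exactly 0 and a minority of altered bins cannot
move it. This panel-proportion normalization intentionally replaces a full
HMM-based copy-number caller: the quantitative readout used downstream is
t-MAD, and a deterministic, dependency-light score suffices for it. GC
correction is out of scope for synthetic data.

# The synthetic-data generator

The study data this pipeline targets are controlled-access patient
samples, so the package ships a generator that reproduces the statistical
*structure* the analysis assumes, with ground truth for parameter
recovery. Defaults define the reference conditions used throughout the
tests; they were chosen once to realize the stated cohort design (a
20-case / 13-control discovery cohort at 5×10⁵ fragments per sample, 200
planted DMRs expressing a count-space log2 fold-change near 2) and are not
meant to be tuned per experiment.

* **Windows.** 20,000 windows across 22 autosomes; CpG counts
  $1 + \mathrm{Geom}(0.2)$ (mean 5); lengths $150 + 60 \cdot n_\mathrm{CpG}$ bp.
* **Cell-type panel.** Six types (granulocyte, megakaryocyte, monocyte,
  lymphocyte, erythroblast, endothelial) with healthy cfDNA weights
  (0.25, 0.24, 0.12, 0.13, 0.06, 0.20). Per-type β is bimodal:
  methylated mode Beta(20, 4), unmethylated mode Beta(2, 150) with mixing
  probability 0.25. The tight unmethylated mode reflects that truly
  unmethylated blocks show little between-cell-type spread; it also
  determines where composition confounding can act (below).
* **Composition confounding.** Case samples draw their cell-type weights
  around a shifted base (0.62, 0.13, 0.07, 0.04, 0.04, 0.10 — strong
  neutrophilia with lymphopenia, at the extreme of what advanced cancer
  inflammation produces), with Dirichlet concentration 300 for
  donor-to-donor variation. This places genuine non-tumor case–control
  differences at windows methylated in the shifted lineages — exactly the
  windows the background mask removes. Without this mechanism the mask
  would have nothing to do and its measured benefit would be vacuous.
* **Tumor methylome.** Equal to the combined background except at
  `n_true_dmrs = 200` windows drawn from those with combined β ≤ 0.05 and
  ≥ 3 CpGs, where β increases by 0.55 (capped at 1). Hosts are restricted
  to fully unmethylated, filter-surviving windows because a planted DMR on
  an already-methylated or filtered-out window cannot express the intended
  fold-change and would be unrecoverable by construction.
* **Counts.** Mixture methylation
  $m_w = (1 - f)\,\mathrm{bg}_{w,s} + f\,\beta^\mathrm{tum}_w$ with tumor
  fraction $f$; pulldown propensity
  $\lambda_w = L_w (a + m_w n_{\mathrm{CpG},w})$ with nonspecific capture
  $a = 0.2$ — the simplest monotone model of immunoprecipitation of
  methylated fragments (a modeling choice, not an empirical claim).
  Counts are negative binomial with mean $\mathrm{depth} \cdot
  \lambda_w / \sum \lambda$ and dispersion 0.2 (dispersion 0 gives the
  Poisson limit, tested). Case tumor fractions are Uniform(0.15, 0.35),
  tissue samples use $f = 0.6$.
* **Trajectories.** Longitudinal tumor fraction decays exponentially under
  therapy (rate 0.02–0.05/day), then regrows exponentially
  (0.015–0.03/day) from a resistance onset at 60–240 days; samples every
  42 days; radiologic PD is labeled at the first sampling where the
  fraction regrows to its pre-therapy baseline, and the line ends there
  (therapy switch). True molecular onset therefore always precedes
  radiologic PD, and the generator exports both dates.
* **Copy number.** A 240-bin (4 × 60 Mb, 1 Mb) genome; per sample 1–3
  whole-chromosome alterations with tumor copy number in {1, 3, 4};
  mixture coverage ratio $(1 - f) + f \cdot CN/2$; platform-specific fixed
  bin biases (log-normal, σ = 0.05) shared across samples of a platform,
  as enrichment bias would be, hence absorbed by platform-matched panel
  normalization.

**What the generator does not emulate:** fragment-length and end-motif
biology, GC/mappability bias, focal amplifications, subclonal copy-number
mixtures, germline CNVs, batch effects, and tumor-type-specific global
hypomethylation. Passing tests therefore demonstrate internal consistency
and statistical calibration of the method under its own assumptions — not
performance on real cfMeDIP-seq data.

# Numerical and design choices

* Fold-change pseudocount ε = 0.5 RPKM in the threshold scan (symmetric,
  avoids division by zero).
* The β = τ boundary is **kept** (the exclusion rule is "> τ"), and τ is
  exposed as configuration with default 0.15.
* The threshold scan splits the healthy cohort into two disjoint halves
  (seeded; an odd sample is dropped) so the cfDNA and tissue fold-change
  axes share no reference samples; thresholds keeping fewer than 10
  windows are recorded as undefined and never selected; ties select the
  smallest τ.
* log-CPM prior count 0.5; TMM trims 0.30/0.05; all configurable.
* The scoring DMR set defaults to the tissue-validated hyper set, with the
  full cfDNA hyper set as a configured alternative.
* Reported problem sizes: the acceptance checks use the default cohort
  (20,000 windows, 20 + 13 cfDNA and 15 + 10 tissue samples at 5×10⁵
  fragments), 20 replicate seeds for recovery/monotonicity statements,
  1,000 replicates for permutation-size calibration, 50 patients for
  monitoring, and 30 paired samples at a common depth of 10⁵ fragments
  for cross-platform concordance. These sizes were chosen as the smallest
  at which the binomial/Monte-Carlo error of each property is well below
  its assertion margin.

# Known limitations

* The moderated test has no abundance trend; heteroskedasticity across
  coverage strata costs some FDR control at very low counts (budgeted in
  the acceptance margins, see above).
* The permutation p-value is reported without the +1 correction, matching
  the published formula; it is therefore 0 (displayed as a floor) when the
  observed overlap exceeds every null draw.
* The t-MAD blacklist/trim parameters are this package's
  operationalization of "trimmed"; the original tooling's exact trimming
  set is not public.
* Real cohort effect sizes, thresholds (e.g. a healthy maximum of 0.6870),
  and DMR counts are functions of the underlying patient data and are not
  reproduced by the synthetic conditions; only the qualitative and
  calibration properties are.

# A worked example

```{r example, eval = FALSE}
library(liquidmeth)

coh <- simulate_cohort(sim_config(), seed = 1)
ws <- filter_windows(coh$ref$windows)
cm <- subset_windows(coh$counts_cf, ws$window_id)
mask <- apply_background_mask(coh$tumor$combined_beta[ws$window_id], 0.15)

res <- run_dmr_analysis(cm, coh$cf_groups, keep_mask = mask)
length(res$dmrs$hyper)                      # called hyper-DMRs
mean(coh$truth$dmr_ids %in% res$dmrs$hyper) # recall of planted DMRs

ctrl <- colnames(cm)[coh$cf_groups == "control"]
bl <- build_healthy_baseline(coh$counts_cf[, ctrl], coh$ref$windows,
                             target_depth = 13 * min(library_sizes(coh$counts_cf)[ctrl]),
                               seed = 2)
rpkm <- compute_rpkm(coh$counts_cf, coh$ref$windows)
scores <- apply(rpkm, 2, five_mc_score, baseline = bl,
                dmr_windows = res$dmrs$hyper)
thr <- detection_threshold(scores[ctrl])
mean(classify_positive(scores[coh$cf_groups == "case"], thr))
```
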