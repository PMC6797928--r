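---
title: "Models and methods behind methdelay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methdelay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdelay)
```

# Scope

`methdelay` analyses case/control DNA methylation on genome-wide CpG
arrays, with autism-spectrum postmortem brain studies as the motivating
design: beta-value matrices are filtered, differentially methylated loci
(DML) are called per age group with a moderated statistic under a
permutation null, DML are tested for enrichment in genomic region
categories and in bivalent chromatin domains, "epigenetically dynamic
regions" (EDRs) are defined as bivalent CpGs whose methylation changes
across fetal brain development, and group methylation profiles at EDR
CpGs are correlated against stage-binned fetal reference methylomes to
score *epigenetic delay* — the phenomenon of case profiles resembling
earlier developmental states than matched controls.

The package starts from normalized beta values; raw intensity (IDAT)
processing, normalization and batch correction are upstream concerns and
out of scope, as are read-level sequencing analyses.

# Differential methylation

## The moderated statistic

For a probe $g$ with case and control means $\bar\beta_{g1}, \bar\beta_{g2}$
(arm sizes $n_1, n_2$), the effect size is
$\Delta\beta_g = \bar\beta_{g1} - \bar\beta_{g2}$. The pooled two-group
variance $s_g^2$ (with $d = n_1 + n_2 - 2$ degrees of freedom) is shrunk
toward a common prior,

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},$$

and the statistic is
$t_g = \Delta\beta_g \big/ \sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}$.
The prior $(d_0, s_0^2)$ is estimated by method of moments on the log
sample variances, using the digamma/trigamma moments of the scaled
chi-square: this is the classical empirical-Bayes variance moderation of
microarray analysis, and on a shared fixture our estimates agree with
`limma::eBayes` to six decimals (the test suite checks this). When the
log-variance spread does not exceed chi-square sampling noise the prior
degrees of freedom are infinite and every probe is shrunk fully to the
common variance; we set that common value on the variance scale (the mean
of the $s_g^2$), which makes identical sample variances an exact fixed
point of the shrinkage.

## The permutation null

Significance comes from re-randomising the case/control labels and
recomputing the moderated statistic — including re-estimating the
variance prior — within every relabelling. Two modes:

* **Exhaustive**: when $\binom{n_1+n_2}{n_1} \le 2{,}000$ (true for the
  motivating design of 5–6 samples per arm), every distinct assignment is
  evaluated and $p_g$ is the exact fraction of assignments with
  $|t^*| \ge |t_g|$; the observed labelling is one of them, so $p > 0$.
* **Monte Carlo**: otherwise $B$ random relabellings with the add-one
  estimator $p_g = (1 + \#\{|t^*| \ge |t_g|\})/(B+1)$.

Comparisons use a relative tolerance of $10^{-8}$ on $|t|$: a permuted
statistic that recomputes the observed one through a different summation
order must count as a tie, otherwise the test would not be invariant to
swapping the arm labels.

A probe is a DML when $p < \alpha$ (default 0.05) **and**
$|\Delta\beta| \ge \delta$ (default 0.10). The boundary is inclusive on
the effect size: a probe at exactly 10% passes. No multiple-testing
correction is applied — the effect-size gate, not FDR control, is the
stringency mechanism here, and this mirrors how such DML lists are
defined in the motivating literature; users who need FDR control can
apply `p.adjust` to the returned `p_perm` column.

Which resampling scheme "the" empirical-Bayes permutation test should use
(residual vs label permutation, moderation of the variance vs of the
p-value distribution) is genuinely underdetermined; we chose label
permutation with per-permutation re-moderation because it is well defined,
exchangeable under the null, and calibration-testable. The suite verifies
type-I error at $\alpha = 0.05$ inside the 95% binomial interval and
Kolmogorov–Smirnov uniformity of the null p-values on 2,000 null probes.

## Clustering and distribution tests

Sample stratification uses agglomerative clustering with Manhattan
distance on beta vectors and complete linkage; samples are pre-sorted
lexicographically by id so ties break deterministically. Distributional
shifts between case and control DML betas use the two-sample
Kolmogorov–Smirnov test; global methylation measurements use Welch's
t-test (two constant equal samples return $t=0, p=1$ rather than an
error).

# Interval engine and enrichment

Peak tracks are BED-convention intervals (0-based, half-open). A CpG
probe at 1-based position $p$ occupies the dinucleotide interval
$[p-1, p+1)$ — two bases — and overlaps a domain when they share at least
one base. Track intersection emits one fragment per overlapping peak
pair (the semantics under which an intersected peak count is reported by
common tools); a `merge` option collapses fragments into maximal runs,
and overlap membership is identical either way. The engine is backed by
`GenomicRanges` and is property-tested against a per-base brute-force
oracle on random toy genomes.

Region-category and feature enrichments are ratios of fractions:
$\text{fold} = (k/m) / (K/M)$ for $k$ of $m$ subset members and $K$ of $M$
background probes inside the feature, with a 1-df chi-square
goodness-of-fit of the observed in/out split against the background rate.
Expected proportions are always computed from the *post-filter* manifest.
Overlap percentages are reported to one decimal using round-half-even;
note that a reported figure of 19.5% for 211/1,079 in the motivating
literature is not reproducible by standard rounding (the quotient is
19.56%), so the package reports 19.6 and does not replicate truncation.

# EDRs and the delay analysis

An EDR probe is in the intersection of the two histone-mark tracks
(bivalent) *and* in the list of developmentally dynamic CpGs; the
definition is a set intersection with provenance labels, and EDR
enrichment delegates to the same fold arithmetic as every other feature
(no second math path). For EDR counting, "DML" means the union of probe
ids across the age-group comparisons; the per-group counts are also
written by the pipeline so other denominators can be read off.

The fetal reference series is reduced to stage-bin means: each sample is
assigned to the prenatal window containing its days post conception
(23–76, 77–89, 90–108, 109–184 by default) and beta values are averaged
per CpG per bin. The quantities correlated are **per-CpG group means**
(diagnosis × age group), not per-sample values — the delay signature is a
property of group profiles. For each group and stage we report Pearson's
$r$ with a two-sided t-approximation p-value, and define

$$\text{delay}(g, s) = r_{\text{case}}(g, s) - r_{\text{control}}(g, s)$$

for the two earliest stages $s$. A positive score says the case profile
resembles early fetal methylation more than the matched control profile
does. The score is our formalization of an argument usually made by
inspecting the correlation matrix; it is antisymmetric under swapping the
arms and zero for identical profiles. Both per-age-group and pooled
(diagnosis-only) profiles are supported, since headline correlations are
sometimes quoted pooled across postnatal ages.

# The synthetic study generator

Every stage is testable offline against a seeded generator with planted
ground truth. Defaults define the simulated study conditions used by the
recovery tests:

| parameter | default | meaning |
|---|---|---|
| `n_probes` | 10,000 | array size (scaled down from ~485k for test runtimes) |
| `n_per_group` | 6 | samples per diagnosis × age group (young/middle/old) |
| `dml_fraction` | 0.05 | planted DML per age-group comparison |
| `dml_delta` | 0.15 | planted \|Δβ\|, straddling the 0.10 call threshold |
| `noise_sd` | 0.02 | per-sample truncated-Gaussian beta noise |
| `bivalent_probe_fraction` | 0.20 | probes inside the intersected tracks (~20% of DML fall in bivalent domains in the motivating data) |
| `dynamic_fraction` | 0.06 | developmentally dynamic probes (≈28.7k/485k on the real array) |
| `delayed_fraction` | 0.35 | EDR probes whose case mean is frozen at an earlier stage |
| `dml_edr_fold` | 4 | planted EDR enrichment of the pooled DML set |
| `n_fetal_per_stage` | 25 | fetal reference samples per stage bin (100 total) |

Construction, in order:

1. **Manifest** — probes on a 10-bp grid with strictly increasing
   positions, region categories drawn at configured proportions, SNP and
   CpG-island flags, transcript counts.
2. **Peak tracks** — around each planted bivalent probe a core domain is
   emitted in both tracks, extended asymmetrically per track so the
   pairwise intersection recovers the core exactly; extensions are capped
   at half the distance to the neighbouring probe so no peak reaches a
   probe it was not planted on. Decoy single-mark peaks occupy probe-free
   gaps. The planted bivalent fraction is therefore exact up to rounding,
   and the ground-truth set is recomputable through the interval engine.
3. **Fetal series** — baselines from a bimodal beta mixture (the two-hump
   array distribution); dynamic probes get a strictly monotone four-stage
   trajectory with total change 0.2–0.4 in a random direction; samples
   equal their bin's stage mean plus noise.
4. **Cohort** — control means sit at final-stage fetal values. Planted
   DML shift the case mean by a signed `dml_delta` (the sign flips rather
   than clipping hard at the [0, 1] boundary; any residual clipping is
   recorded as the effective delta). Delayed probes instead copy the
   earliest stage-bin mean into the case arm, in all age groups. DML
   planting oversamples EDR probes so the pooled DML set hits the target
   EDR fold exactly in expectation; per-group DML sets are disjoint
   except for the shared delayed probes, which keeps the planted
   union-level fold analytically exact.

Noise is truncated Gaussian on the beta scale rather than logit-normal —
simpler, and adequate for recovery testing; the generator is documented
so users can substitute their own error model. Planted effect sizes
(0.10–0.20) are chosen to straddle the call threshold, not to match any
particular dataset, whose effect-size distribution is unknown.
`delayed_fraction = 0.35` makes the planted delay signature unambiguous —
group-level delay scores around +0.2–0.5 at the earliest stage against a
between-seed spread an order of magnitude smaller — while keeping the
planted EDR fold constraint satisfiable; the real-data analogue (how many
EDR CpGs are delayed) is not identifiable from published summaries.

What the generator does **not** emulate: probe-type chemistry differences,
spatial autocorrelation of methylation, cell-composition heterogeneity,
batch structure, and covariate confounding (age, postmortem interval).
Passing recovery tests therefore demonstrate the correctness of the
statistical machinery under its own assumptions, not robustness to the
artefacts of real array data.

# The pipeline

`run_pipeline()` executes filter → per-group DML → region enrichment →
bivalent intersection and overlap → dynamic overlap → EDR definition and
enrichment → delay analysis, writing TSV/JSON artifacts and a summary.
The master seed fans out to per-stage child seeds through a stable string
hash (`child_seed`), so stages are independent of each other's randomness
and reruns are bit-identical. The delay analysis runs on DML ∩ EDR
probes when at least three exist (the motivating analyses correlate
exactly this set), falling back to all EDR probes otherwise.
Configuration is a plain list or YAML file; subcommand-style usage is
covered by calling the exported functions directly, which are each thin
and composable.

# Numerical choices and degenerate inputs

* Beta validation is strict: values outside [0, 1] name the offending
  probe and sample; duplicate ids are errors, not warnings.
* Probe filtering removes (never imputes) probes with any missing value,
  any SNP flag, or any detection p > 0.05 — "any sample" because the
  motivating description gives no quantifier and per-sample failure is
  the conservative array-QC reading.
* Zero-variance probes: shrinkage handles them through the prior; if no
  probe has positive variance the statistic falls back to an unmoderated
  t with a warning, and 0/0 cases are defined as $t = 0$.
* Empty probe subsets make overlap percentages undefined and error;
  empty peak sets intersect to empty sets silently.
* The ELISA standard curve is quadratic in log absorbance
  ($\%5\text{mC} = a + b\ln A + c\ln A^2$); with exactly three distinct
  standards the fit interpolates and residuals are zero. The alternative
  reading (log of a quadratic) is monotone-equivalent only locally and
  was not adopted.
* ΔΨ for splice events is oriented control − case, so "aberrantly
  down-regulated" (ΔΨ > 0.1) means reduced exon inclusion in cases; the
  orientation is a flag.

# Problem sizes used by the tests

The test suite and the acceptance script simulate at 10,000 probes, three
age groups of 6 + 6 samples, 100 fetal reference samples, and 999 Monte
Carlo (or ≤ 2,000 exhaustive) permutations; the delay-recovery property
is evaluated over 50 generator seeds. These sizes keep the full suite
within a few minutes on one CPU while leaving every statistical property
measurable with comfortable margins.

# Known limitations

* The permutation scheme is one concrete reading of a loosely specified
  family of resampling empirical-Bayes tests; published DML counts from
  any particular study are not expected to be reproduced exactly.
* No covariate adjustment (age, PMI, estimated cell composition) — the
  comparisons are marginal.
* Region-level (bump-style) detection is out of scope; the unit of
  inference is the probe.
* Cell-type concordance is correlation-based classification only, not
  proportion deconvolution.
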