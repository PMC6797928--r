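# methdelay

Differential methylation, bivalent-domain enrichment, and
developmental-delay trajectory analysis for CpG methylation arrays.

## The problem

Case/control methylome studies of postmortem brain — the motivating design
is autism spectrum disorder versus typically developing donors, sampled
from a neurogenic niche across three age groups — need a small set of
connected analyses:

1. **Differential methylation.** For each age-group comparison, call
   differentially methylated loci (DML) from beta values
   (β ∈ [0,1], methylated fraction per CpG). The test statistic is a
   moderated t: the per-probe pooled variance is shrunk toward a common
   prior, `s²_post = (d₀s₀² + d·s²)/(d₀ + d)`, with `(d₀, s₀²)` estimated
   by method of moments on the log sample variances. Significance comes
   from a case/control label-permutation null (exhaustive when the number
   of relabellings is small, Monte Carlo otherwise), and a probe is a DML
   when `p < 0.05` and `|Δβ| ≥ 0.10`.
2. **Where the DML fall.** Chi-square goodness-of-fit of DML counts per
   genomic region category against the array background, and fold
   enrichment of DML inside bivalent chromatin domains — regions carrying
   both the activating (H3K4me3) and repressive (H3K27me3) marks,
   computed as the exact interval intersection of two peak tracks.
3. **Epigenetically dynamic regions (EDRs).** CpGs that are bivalent
   *and* developmentally dynamic in fetal brain; DML enrichment in EDRs
   uses the same fold/chi-square machinery.
4. **Epigenetic delay.** Correlate per-group mean methylation at EDR CpGs
   against stage-binned fetal reference methylomes (23–76, 77–89, 90–108,
   109–184 days post conception) and score
   `delay = r_case − r_control` at the two earliest stages: positive
   scores mean case profiles resemble earlier developmental methylation
   states than their matched controls.

Because the motivating datasets are controlled-access and large, the
package ships a seeded synthetic-study generator with planted ground
truth (planted DML, planted bivalent fraction, planted monotone fetal
trajectories, planted delayed CpGs), so the whole pipeline is testable
offline, end to end, with known answers.

## Worked example

```r
library(methdelay)

cfg   <- sim_config(n_probes = 4000,
                    chrom_layout = c(chr1 = 4e6, chr2 = 2e6), seed = 42)
study <- simulate_study(cfg)

filt <- filter_probes(study$betas, study$manifest)
spec <- comparison_spec(
  study$samples$sample_id[study$samples$age_group == "young" &
                            study$samples$diagnosis == "autism"],
  study$samples$sample_id[study$samples$age_group == "young" &
                            study$samples$diagnosis == "control"],
  label = "young")
st  <- probe_stats(filt$betas, spec)
pv  <- permutation_pvalues(filt$betas, spec, seed = 7)
dml <- call_dml(st, pv)
dml
#> DML set 'young': 200 of 3920 probes (p < 0.05, |delta beta| >= 0.1)

biv <- intersect_tracks(study$peaks$mark_a, study$peaks$mark_b)
sub <- study$manifest[study$manifest$probe_id %in% dml$probe_ids, ]
ov  <- probes_in_peaks(sub, biv)
bg  <- probes_in_peaks(
  study$manifest[study$manifest$probe_id %in% rownames(filt$betas), ], biv)
fold_enrichment(ov$count, nrow(sub), bg$count, filt$report$n_retained)
#> enrichment: 55/200 in subset (27.50%) vs 784/3920 background (20.00%);
#>   fold 1.38, chi2 7.03, p 0.00801

fs   <- stage_bin_means(study$fetal$betas, study$fetal$samples$dpc)
edr  <- define_edr(study$truth$bivalent_probe_ids,
                   study$fetal$dynamic_probe_ids)
prof <- group_profiles(filt$betas, study$samples,
                       probe_subset = intersect(edr$probe_ids,
                                                rownames(filt$betas)))
delay_score(correlate_profiles(prof, fs))
#>  age_group    stage stage_index    r_case r_control delay_score delayed
#>      young dpc23_76           1 0.3519777 0.1111162  0.24086142    TRUE
#>      young dpc77_89           2 0.5389155 0.4675945  0.07132102    TRUE
#>  ...
```

Reading the output: of 3,920 retained probes, 200 pass both the
permutation p-value and the 10% effect-size gate in the young comparison
(the generator planted 200 per group at |Δβ| = 0.15). 27.5% of those DML
sit inside bivalent domains against a 20% background rate (fold 1.38).
At EDR CpGs, the autism arm correlates more strongly with the earliest
fetal stage than the control arm does (r 0.35 vs 0.11): a positive delay
score, reflecting the delayed CpGs the generator planted.

The whole flow is also available as one call:

```r
run_pipeline(list(simulate = list()), out_dir = "out", seed = 1)
```

which writes per-stage TSVs, a `summary.json`, and a log; reruns with the
same config and seed are bit-identical.

## Layout

- `R/` — generators (`sim_config`, `simulate_study`), IO and filtering,
  DML statistics, interval/enrichment engine, EDR and trajectory
  analyses, cell-type concordance, splice/ELISA utilities, pipeline.
- `tests/testthat/` — unit, property and end-to-end recovery tests, with
  brute-force oracles for the interval and permutation engines.
- `vignettes/methdelay-methods.Rmd` — the models, their assumptions, the
  generator's design, and known limitations.
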