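#' Simulation configuration for the synthetic methylome study
#'
#' Bundles every knob of the synthetic-data generators into a validated
#' object. The defaults describe the simulated study design used by the
#' package's recovery tests: a genome-wide array of 10,000 CpG probes, three
#' postnatal age groups with 6 cases and 6 matched controls each, planted
#' differential methylation of |delta beta| = 0.15 against per-sample noise
#' of SD 0.02, roughly 20% of probes inside bivalent chromatin domains, 6%
#' of probes developmentally dynamic in fetal brain, and a fetal reference
#' series of 25 samples per prenatal stage bin (100 in total, 23-184 days
#' post conception).
#'
#' @param n_probes Number of CpG probes on the simulated array.
#' @param chrom_layout Named numeric vector of chromosome lengths in bp.
#' @param n_per_group Samples per (diagnosis x age group) cell; at least 2.
#' @param age_groups Age-group labels, ordered young to old.
#' @param dml_fraction Fraction of probes planted as differentially
#'   methylated loci (DML) in each age-group comparison.
#' @param dml_delta Target |delta beta| planted at DML (fraction).
#' @param noise_sd Per-sample Gaussian noise SD on the beta scale; values
#'   are clipped back into `[0,1]`.
#' @param region_props Named proportions of probes per genomic region
#'   category (`promoter`, `gene_body`, `three_utr`, `intergenic`).
#' @param snp_fraction Fraction of probes flagged as SNP-overlapping;
#'   flagged probes are excluded from DML planting because the analysis
#'   filters them before testing.
#' @param bivalent_probe_fraction Target fraction of probes whose CpG
#'   interval lies inside the intersection of the two histone-mark tracks.
#' @param dynamic_fraction Fraction of probes with a monotone fetal
#'   methylation trajectory (total change at least 0.2 beta units).
#' @param delayed_fraction Fraction of epigenetically dynamic region (EDR)
#'   probes planted as "delayed" in cases: the case group mean equals an
#'   earlier fetal stage mean instead of the final one.
#' @param dml_edr_fold Planted fold enrichment of the pooled DML set inside
#'   EDRs relative to the array background.
#' @param delay_stage Stage-bin index (1 = earliest) whose fetal mean the
#'   delayed probes adopt in cases.
#' @param stage_bins Data.frame of four prenatal stage bins
#'   (see [default_stage_bins()]).
#' @param n_fetal_per_stage Fetal reference samples per stage bin.
#' @param seed Integer master seed; all generators derive stage-specific
#'   child seeds from it with [child_seed()].
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_probes = 500, seed = 7)
#' cfg$dml_delta
#' @export
sim_config <- function(n_probes = 10000,
                       chrom_layout = c(chr1 = 8e6, chr2 = 6e6,
                                        chr3 = 4e6, chr4 = 2e6),
                       n_per_group = 6,
                       age_groups = c("young", "middle", "old"),
                       dml_fraction = 0.05,
                       dml_delta = 0.15,
                       noise_sd = 0.02,
                       region_props = c(promoter = 0.25, gene_body = 0.35,
                                        three_utr = 0.10, intergenic = 0.30),
                       snp_fraction = 0.02,
                       bivalent_probe_fraction = 0.20,
                       dynamic_fraction = 0.06,
                       delayed_fraction = 0.35,
                       dml_edr_fold = 4,
                       delay_stage = 1,
                       stage_bins = default_stage_bins(),
                       n_fetal_per_stage = 25,
                       seed = 1) {
  ## tolerate YAML-style lists and stringy numerics
  cl <- unlist(chrom_layout)
  chrom_layout <- stats::setNames(as.numeric(cl), names(cl))
  rp <- unlist(region_props)
  region_props <- stats::setNames(as.numeric(rp), names(rp))
  if (is.list(stage_bins)) stage_bins <- as.data.frame(stage_bins)
  cfg <- list(
    n_probes = as.integer(n_probes), chrom_layout = chrom_layout,
    n_per_group = as.integer(n_per_group), age_groups = age_groups,
    dml_fraction = dml_fraction, dml_delta = dml_delta, noise_sd = noise_sd,
    region_props = region_props, snp_fraction = snp_fraction,
    bivalent_probe_fraction = bivalent_probe_fraction,
    dynamic_fraction = dynamic_fraction, delayed_fraction = delayed_fraction,
    dml_edr_fold = dml_edr_fold, delay_stage = as.integer(delay_stage),
    stage_bins = stage_bins,
    n_fetal_per_stage = as.integer(n_fetal_per_stage),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fracs <- c(cfg$dml_fraction, cfg$snp_fraction, cfg$bivalent_probe_fraction,
             cfg$dynamic_fraction, cfg$delayed_fraction, cfg$dml_delta)
  if (any(fracs < 0 | fracs > 1)) fail("all fractions must lie in [0,1]")
  if (cfg$n_probes < 0) fail("n_probes must be non-negative")
  if (length(cfg$chrom_layout) == 0 || is.null(names(cfg$chrom_layout)))
    fail("chrom_layout must be a named, non-empty vector of lengths")
  if (any(cfg$chrom_layout <= 0)) fail("chromosome lengths must be positive")
  if (cfg$n_per_group < 2) fail("n_per_group must be at least 2")
  if (cfg$noise_sd < 0) fail("noise_sd must be non-negative")
  if (abs(sum(cfg$region_props) - 1) > 1e-9)
    fail("region_props must sum to 1")
  if (!setequal(names(cfg$region_props), REGION_CATEGORIES))
    fail("region_props must name exactly: %s",
         paste(REGION_CATEGORIES, collapse = ", "))
  check_stage_bins(cfg$stage_bins)
  if (nrow(cfg$stage_bins) != 4) fail("exactly four stage bins are required")
  if (cfg$delay_stage < 1 || cfg$delay_stage > nrow(cfg$stage_bins))
    fail("delay_stage out of range")
  if (cfg$n_fetal_per_stage < 1)
    fail("n_fetal_per_stage must be at least 1")
  cfg
}
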