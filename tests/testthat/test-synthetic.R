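small_cfg <- function(...) {
  sim_config(n_probes = 1500, chrom_layout = c(chr1 = 2e6, chr2 = 1e6),
             n_fetal_per_stage = 10, seed = 101, ...)
}

test_that("generators are deterministic under a fixed config and seed", {
  s1 <- simulate_study(small_cfg())
  s2 <- simulate_study(small_cfg())
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$fetal$betas, s2$fetal$betas)
  expect_identical(s1$betas, s2$betas)
  expect_identical(s1$truth, s2$truth)
})

test_that("manifest respects size, ordering and category proportions", {
  cfg <- sim_config(n_probes = 4000, chrom_layout = c(chr1 = 3e6, chr2 = 3e6),
                    region_props = c(promoter = 0.25, gene_body = 0.25,
                                     three_utr = 0.25, intergenic = 0.25),
                    seed = 3)
  m <- generate_manifest(cfg)
  expect_equal(nrow(m), 4000)
  expect_false(anyDuplicated(m$probe_id) > 0)
  for (chr in unique(m$chromosome))
    expect_true(!is.unsorted(m$position[m$chromosome == chr],
                             strictly = TRUE))
  ## each category within 3 binomial SDs of 1000: sd = sqrt(n p (1-p))
  sd3 <- 3 * sqrt(4000 * 0.25 * 0.75)
  counts <- table(m$region_category)
  expect_true(all(abs(counts - 1000) < sd3))
  expect_true(all(m$transcript_count >= 1))
})

test_that("empty and over-capacity manifests behave as specified", {
  empty <- generate_manifest(sim_config(n_probes = 0, seed = 1))
  expect_equal(nrow(empty), 0)
  expect_error(
    generate_manifest(sim_config(n_probes = 1000,
                                 chrom_layout = c(chr1 = 500), seed = 1)),
    "capacity")
})

test_that("peak tracks plant the bivalent fraction and match the interval engine", {
  cfg <- sim_config(n_probes = 5000, chrom_layout = c(chr1 = 4e6, chr2 = 4e6),
                    bivalent_probe_fraction = 0.2, seed = 17)
  m <- generate_manifest(cfg)
  pk <- generate_peak_tracks(m, cfg)
  biv <- intersect_tracks(pk$mark_a, pk$mark_b)
  ov <- probes_in_peaks(m, biv)
  frac <- ov$count / nrow(m)
  expect_gte(frac, 0.17)
  expect_lte(frac, 0.23)
  ## ground truth equals the probe set recomputed through the engine
  expect_setequal(ov$probe_ids, pk$bivalent_probe_ids)
  expect_true(all(biv$start < biv$end))
})

test_that("zero bivalent fraction yields an intersection covering no probe", {
  cfg <- small_cfg(bivalent_probe_fraction = 0)
  m <- generate_manifest(cfg)
  pk <- generate_peak_tracks(m, cfg)
  biv <- intersect_tracks(pk$mark_a, pk$mark_b)
  if (nrow(biv) > 0) {
    ov <- probes_in_peaks(m, biv)
    expect_equal(ov$count, 0)
  } else {
    succeed()
  }
})

test_that("fetal series plants monotone trajectories and exact zero-noise means", {
  cfg <- small_cfg(noise_sd = 0)
  m <- generate_manifest(cfg)
  fe <- generate_fetal_series(m, cfg)
  fs <- stage_bin_means(fe$betas, fe$samples$dpc, cfg$stage_bins)
  expect_equal(fs$means, fe$stage_means)
  dyn <- fe$dynamic_probe_ids
  stopifnot(length(dyn) > 0)
  diffs <- t(apply(fe$stage_means[dyn, , drop = FALSE], 1, diff))
  expect_true(all(diffs > 0 | diffs < 0))
  expect_true(all(rowSums(abs(diffs)) >= 0.2 - 1e-12))
  static <- setdiff(rownames(fe$betas), dyn)
  expect_true(all(apply(fe$stage_means[static, ], 1,
                        function(x) max(x) - min(x)) == 0))
})

test_that("static probes stay flat under noise and boundary fractions work", {
  cfg <- sim_config(n_probes = 400, chrom_layout = c(chr1 = 1e6),
                    noise_sd = 0.02, n_fetal_per_stage = 25, seed = 9,
                    dynamic_fraction = 0.1)
  m <- generate_manifest(cfg)
  fe <- generate_fetal_series(m, cfg)
  fs <- stage_bin_means(fe$betas, fe$samples$dpc, cfg$stage_bins)
  static <- setdiff(rownames(fe$betas), fe$dynamic_probe_ids)
  ## stage means of static probes vary only by noise of SD 0.02/sqrt(25)
  spread <- apply(fs$means[static, ], 1, function(x) max(x) - min(x))
  expect_lt(mean(spread >= 0.02), 0.05)

  cfg_all <- small_cfg(dynamic_fraction = 1)
  fe_all <- generate_fetal_series(generate_manifest(cfg_all), cfg_all)
  expect_equal(length(fe_all$dynamic_probe_ids), cfg_all$n_probes)

  expect_error(sim_config(n_fetal_per_stage = 0), "n_fetal_per_stage")
})

test_that("cohort plants exact deltas at zero noise and delayed probes by construction", {
  cfg <- small_cfg(noise_sd = 0)
  m <- generate_manifest(cfg)
  pk <- generate_peak_tracks(m, cfg)
  fe <- generate_fetal_series(m, cfg)
  co <- generate_cohort(m, fe, pk$bivalent_probe_ids, cfg)
  tr <- co$truth
  grp <- cfg$age_groups[1]
  case <- co$samples$sample_id[co$samples$age_group == grp &
                                 co$samples$diagnosis == "autism"]
  ctrl <- co$samples$sample_id[co$samples$age_group == grp &
                                 co$samples$diagnosis == "control"]
  emp_delta <- rowMeans(co$betas[, case]) - rowMeans(co$betas[, ctrl])
  planted <- tr$planted_deltas[[grp]]
  expect_equal(unname(emp_delta[names(planted)]), unname(planted),
               tolerance = 1e-12)
  ## non-planted probes have zero delta at zero noise
  others <- setdiff(rownames(co$betas), names(planted))
  expect_true(all(abs(emp_delta[others]) < 1e-12))
  ## delayed probes: case mean at the earliest stage, control at the last
  expect_true(length(tr$delayed_probe_ids) > 0)
  d <- tr$delayed_probe_ids
  expect_equal(rowMeans(co$betas[d, case, drop = FALSE]),
               fe$stage_means[d, 1], tolerance = 1e-12)
  expect_equal(rowMeans(co$betas[d, ctrl, drop = FALSE]),
               fe$stage_means[d, 4], tolerance = 1e-12)
})

test_that("planted deltas survive realistic noise in most probes", {
  cfg <- small_cfg()   # noise_sd 0.02, n = 6 per arm
  m <- generate_manifest(cfg)
  pk <- generate_peak_tracks(m, cfg)
  fe <- generate_fetal_series(m, cfg)
  co <- generate_cohort(m, fe, pk$bivalent_probe_ids, cfg)
  grp <- "young"
  case <- co$samples$sample_id[co$samples$age_group == grp &
                                 co$samples$diagnosis == "autism"]
  ctrl <- co$samples$sample_id[co$samples$age_group == grp &
                                 co$samples$diagnosis == "control"]
  emp <- rowMeans(co$betas[, case]) - rowMeans(co$betas[, ctrl])
  planted <- co$truth$planted_deltas[[grp]]
  err <- abs(emp[names(planted)] - planted)
  expect_gte(mean(err < 0.05), 0.95)
})

test_that("ground-truth sets are internally consistent", {
  st <- simulate_study(small_cfg())
  tr <- st$truth
  expect_true(all(tr$delayed_probe_ids %in% tr$edr_probe_ids))
  expect_setequal(tr$edr_probe_ids,
                  intersect(tr$bivalent_probe_ids, tr$dynamic_probe_ids))
  for (grp in names(tr$dml_probe_ids))
    expect_true(all(tr$dml_probe_ids[[grp]] %in% st$manifest$probe_id))
  expect_true(all(st$betas >= 0 & st$betas <= 1))
  expect_true(all(st$fetal$betas >= 0 & st$fetal$betas <= 1))
  for (trk in list(st$peaks$mark_a, st$peaks$mark_b))
    expect_true(all(trk$start >= 0 & trk$start < trk$end))
})
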