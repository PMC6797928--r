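#' Run the full methylome analysis pipeline
#'
#' Orchestrates: probe filtering, per-age-group DML calling (moderated t
#' with a permutation null), genomic-region category enrichment, bivalent
#' domain intersection and overlap enrichment, developmental-dynamic
#' overlap, EDR definition and enrichment, and the fetal-trajectory delay
#' analysis. Every stage draws its randomness from a child seed of the
#' master seed, so reruns with the same config and seed are bit-identical
#' and adding a stage never perturbs the others.
#'
#' The configuration is either a list or the path of a YAML file. It
#' must contain either a `simulate` block (arguments for [sim_config()])
#' or a `paths` block with `betas`, `samples`, `manifest`, `bed_a`,
#' `bed_b`, `fetal_betas`, `fetal_samples` and `dynamic_probes` (a text
#' file of probe ids, one per line). Optional `cutoffs`: `alpha`
#' (default 0.05), `delta_beta` (0.10), `n_perm` (999).
#'
#' @param config List or YAML path.
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; overrides `config$seed` when given.
#' @return The summary list, invisibly. Files written: `filter_report.json`,
#'   `dml_<group>.tsv`, `region_enrichment.tsv`, `bivalent_enrichment.tsv`,
#'   `dynamic_enrichment.tsv`, `edr_probes.txt`, `edr_enrichment.tsv`,
#'   `delay_correlations.tsv`, `delay_scores.tsv`, `summary.json`,
#'   `log.txt`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) fail("config must be a list or a YAML path")
  if (is.null(seed)) seed <- if (!is.null(config$seed)) config$seed else 1
  seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "log.txt")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                sprintf(fmt, ...)), file = logfile, append = TRUE)
  }
  cat("", file = logfile)
  stage <- "setup"
  on.exit(logf("aborted during stage: %s", stage), add = TRUE)

  cut <- config$cutoffs
  alpha <- if (!is.null(cut$alpha)) cut$alpha else 0.05
  delta <- if (!is.null(cut$delta_beta)) cut$delta_beta else 0.10
  n_perm <- if (!is.null(cut$n_perm)) cut$n_perm else 999
  if (alpha <= 0 || delta <= 0 || n_perm <= 0)
    fail("cutoffs must be positive")
  logf("seed %d; cutoffs alpha=%g delta=%g n_perm=%d", seed, alpha, delta,
       n_perm)

  ## ---- inputs -----------------------------------------------------------
  stage <- "input"
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    study <- simulate_study(cfg)
    manifest <- study$manifest
    betas <- study$betas
    samples <- study$samples
    mark_a <- study$peaks$mark_a
    mark_b <- study$peaks$mark_b
    fetal_betas <- study$fetal$betas
    fetal_samples <- study$fetal$samples
    dynamic_ids <- study$fetal$dynamic_probe_ids
    stage_bins <- cfg$stage_bins
    truth <- study$truth
    logf("simulated study: %d probes, %d samples", nrow(betas), ncol(betas))
  } else if (!is.null(config$paths)) {
    p <- config$paths
    need <- c("betas", "samples", "manifest", "bed_a", "bed_b",
              "fetal_betas", "fetal_samples", "dynamic_probes")
    miss <- setdiff(need, names(p))
    if (length(miss) > 0)
      fail("paths block missing: %s", paste(miss, collapse = ", "))
    manifest <- read_manifest(p$manifest)
    betas <- read_beta_matrix(p$betas)
    samples <- read_sample_sheet(p$samples)
    mark_a <- read_bed(p$bed_a)
    mark_b <- read_bed(p$bed_b)
    fetal_betas <- read_beta_matrix(p$fetal_betas)
    fetal_samples <- utils::read.delim(p$fetal_samples,
                                       stringsAsFactors = FALSE)
    dynamic_ids <- readLines(p$dynamic_probes)
    stage_bins <- if (!is.null(config$stage_bins))
      as.data.frame(config$stage_bins) else default_stage_bins()
    logf("loaded inputs: %d probes, %d samples", nrow(betas), ncol(betas))
  } else {
    fail("config needs either a 'simulate' block or a 'paths' block")
  }

  ## ---- filtering --------------------------------------------------------
  stage <- "filter"
  filt <- filter_probes(betas, manifest)
  betas <- filt$betas
  retained <- rownames(betas)
  manifest_kept <- manifest[manifest$probe_id %in% retained, , drop = FALSE]
  jsonlite::write_json(filt$report, file.path(out_dir, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("filter: %d of %d probes retained", filt$report$n_retained,
       filt$report$n_input)

  ## ---- DML per age group ------------------------------------------------
  stage <- "dml"
  age_groups <- unique(samples$age_group)
  dml_sets <- list()
  for (grp in age_groups) {
    spec <- comparison_spec(
      samples$sample_id[samples$age_group == grp &
                          samples$diagnosis == "autism"],
      samples$sample_id[samples$age_group == grp &
                          samples$diagnosis == "control"],
      label = grp)
    st <- probe_stats(betas, spec)
    pv <- permutation_pvalues(betas, spec, n_perm = n_perm,
                              seed = child_seed(seed, paste0("perm_", grp)))
    dml <- call_dml(st, pv, alpha = alpha, delta = delta)
    dml_sets[[grp]] <- dml
    ann <- manifest_kept[match(dml$table$probe_id, manifest_kept$probe_id),
                         c("chromosome", "position", "gene_symbol",
                           "region_category")]
    out_tab <- cbind(dml$table["probe_id"], ann,
                     dml$table[c("mean_case", "mean_control", "delta_beta",
                                 "t_mod", "p_perm", "passes")])
    utils::write.table(out_tab, file.path(out_dir,
                                          sprintf("dml_%s.tsv", grp)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("dml %s: %d calls (%s permutation mode)", grp,
         length(dml$probe_ids), attr(pv, "mode"))
  }
  dml_union <- sort(unique(unlist(lapply(dml_sets, `[[`, "probe_ids"))))

  ## ---- region-category enrichment ---------------------------------------
  stage <- "region_enrichment"
  region_rows <- list()
  for (grp in age_groups) {
    cc <- categorize_dml(dml_sets[[grp]], manifest_kept)
    gof <- if (cc$total > 0) chisq_gof(cc$observed, cc$expected_prop)
           else list(chi2 = NA_real_, df = NA_real_, p_value = NA_real_)
    region_rows[[grp]] <- data.frame(
      age_group = grp, category = names(cc$fold),
      observed = as.integer(cc$observed),
      expected_prop = as.numeric(cc$expected_prop),
      fold = as.numeric(cc$fold), chi2 = gof$chi2, p_value = gof$p_value,
      stringsAsFactors = FALSE)
  }
  region_tab <- do.call(rbind, region_rows)
  rownames(region_tab) <- NULL
  utils::write.table(region_tab, file.path(out_dir, "region_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- bivalent domains --------------------------------------------------
  stage <- "bivalent"
  bivalent <- intersect_tracks(mark_a, mark_b)
  bg_overlap <- probes_in_peaks(manifest_kept, bivalent)
  biv_rows <- list(); biv_results <- list()
  for (grp in age_groups) {
    ids <- dml_sets[[grp]]$probe_ids
    if (length(ids) == 0) next
    sub <- manifest_kept[manifest_kept$probe_id %in% ids, , drop = FALSE]
    ov <- probes_in_peaks(sub, bivalent)
    enr <- fold_enrichment(ov$count, nrow(sub), bg_overlap$count,
                           nrow(manifest_kept))
    biv_results[[grp]] <- enr
    biv_rows[[grp]] <- data.frame(
      age_group = grp, n_dml = nrow(sub), n_in_bivalent = ov$count,
      percent = ov$percent, fold = enr$fold, chi2 = enr$chi2,
      p_value = enr$p_value, stringsAsFactors = FALSE)
  }
  biv_tab <- do.call(rbind, biv_rows)
  utils::write.table(biv_tab, file.path(out_dir, "bivalent_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("bivalent: %d intersected peaks cover %d/%d retained probes",
       nrow(bivalent), bg_overlap$count, nrow(manifest_kept))

  ## ---- dynamic overlap and EDR -------------------------------------------
  stage <- "dynamic"
  dynamic_kept <- intersect(dynamic_ids, retained)
  dyn_enr <- if (length(dml_union) > 0)
    dynamic_overlap(dml_union, dynamic_kept, retained) else NULL
  if (!is.null(dyn_enr))
    utils::write.table(
      as.data.frame(unclass(dyn_enr)[c("n_in_subset", "n_subset",
                                       "n_in_background", "n_background",
                                       "fold", "chi2", "p_value")]),
      file.path(out_dir, "dynamic_enrichment.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)

  stage <- "edr"
  edr <- define_edr(bg_overlap$probe_ids, dynamic_kept,
                    bivalent_source = "intersected peak tracks",
                    dynamic_source = "dynamic CpG list")
  writeLines(edr$probe_ids, file.path(out_dir, "edr_probes.txt"))
  edr_enr <- if (length(dml_union) > 0 && length(edr$probe_ids) > 0)
    edr_enrichment(dml_union, edr, retained) else NULL
  if (!is.null(edr_enr))
    utils::write.table(
      as.data.frame(unclass(edr_enr)[c("n_in_subset", "n_subset",
                                       "n_in_background", "n_background",
                                       "fold", "chi2", "p_value")]),
      file.path(out_dir, "edr_enrichment.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  logf("edr: %d probes; %d DML inside",
       length(edr$probe_ids),
       if (is.null(edr_enr)) 0L else edr_enr$n_in_subset)

  ## ---- delay analysis -----------------------------------------------------
  stage <- "delay"
  delay_corr <- NULL; delay_tab <- NULL
  edr_dml <- intersect(dml_union, edr$probe_ids)
  delay_probes <- if (length(edr_dml) >= 3) edr_dml else edr$probe_ids
  if (length(delay_probes) >= 3) {
    fetal_stages <- stage_bin_means(fetal_betas, fetal_samples$dpc,
                                    stage_bins)
    prof <- group_profiles(betas, samples, probe_subset = delay_probes)
    delay_corr <- correlate_profiles(prof, fetal_stages)
    delay_tab <- delay_score(delay_corr)
    utils::write.table(delay_corr,
                       file.path(out_dir, "delay_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(delay_tab, file.path(out_dir, "delay_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## ---- summary ------------------------------------------------------------
  stage <- "summary"
  enr_summary <- function(e) if (is.null(e)) NULL else
    unclass(e)[c("n_in_subset", "n_subset", "n_in_background",
                 "n_background", "fold", "chi2", "p_value")]
  summary <- list(
    filter = filt$report,
    dml = lapply(dml_sets, function(d)
      list(n = length(d$probe_ids), cutoffs = as.list(d$cutoffs))),
    region_enrichment = region_tab,
    bivalent = list(n_intersected_peaks = nrow(bivalent),
                    background_percent = bg_overlap$percent,
                    per_group = biv_tab),
    dynamic = enr_summary(dyn_enr),
    edr = c(list(n_edr = length(edr$probe_ids),
                 n_dml_union = length(dml_union),
                 n_dml_in_edr = length(edr_dml)),
            enr_summary(edr_enr)),
    delay = list(correlations = delay_corr, scores = delay_tab),
    seed = seed,
    cutoffs = list(alpha = alpha, delta_beta = delta, n_perm = n_perm),
    versions = list(package = as.character(utils::packageVersion("methdelay")))
  )
  if (!is.null(truth)) {
    recov <- lapply(names(dml_sets), function(grp) {
      planted <- truth$dml_probe_ids[[grp]]
      called <- dml_sets[[grp]]$probe_ids
      nulls <- setdiff(retained, planted)
      list(age_group = grp,
           sensitivity = if (length(planted))
             length(intersect(called, planted)) / length(planted) else NA,
           fpr = length(setdiff(called, planted)) / length(nulls))
    })
    summary$recovery <- recov
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "columns")
  logf("done")
  on.exit()
  invisible(summary)
}
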