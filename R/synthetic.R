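#' Generate a synthetic probe manifest
#'
#' Places `n_probes` CpG probes on the configured chromosomes at strictly
#' increasing positions (10-bp grid, so probe intervals never touch), draws
#' a genomic region category per probe with the configured proportions, and
#' attaches gene symbols, strand, CpG-island and SNP flags, and transcript
#' counts. Deterministic for a given config and seed.
#'
#' @param config A [sim_config()] object.
#' @return A manifest data.frame with columns `probe_id`, `chromosome`,
#'   `position` (1-based bp of the CpG cytosine), `strand`, `gene_symbol`,
#'   `region_category`, `cpg_island`, `snp_flag`, `transcript_count`.
#' @export
generate_manifest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "manifest"))
  n <- config$n_probes
  cols <- c("probe_id", "chromosome", "position", "strand", "gene_symbol",
            "region_category", "cpg_island", "snp_flag", "transcript_count")
  if (n == 0) {
    out <- data.frame(probe_id = character(), chromosome = character(),
                      position = integer(), strand = character(),
                      gene_symbol = character(), region_category = character(),
                      cpg_island = logical(), snp_flag = logical(),
                      transcript_count = integer(), stringsAsFactors = FALSE)
    return(out[cols])
  }
  ## 10-bp grid per chromosome; leave one slot of margin at each end
  slots <- pmax(0, floor(config$chrom_layout / 10) - 2)
  if (sum(slots) < n)
    fail("capacity error: %d probes requested but only %d grid positions",
         n, sum(slots))
  ## allocate probes proportionally to chromosome capacity
  alloc <- floor(slots / sum(slots) * n)
  rem <- n - sum(alloc)
  if (rem > 0) {
    ord <- order(slots - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }
  alloc <- pmin(alloc, slots)
  short <- n - sum(alloc)
  if (short > 0) { # spill any overflow into chromosomes with room
    for (i in order(slots - alloc, decreasing = TRUE)) {
      take <- min(short, slots[i] - alloc[i]); alloc[i] <- alloc[i] + take
      short <- short - take; if (short == 0) break
    }
  }
  chrom <- rep(names(config$chrom_layout), alloc)
  position <- unlist(lapply(seq_along(alloc), function(i) {
    if (alloc[i] == 0) return(integer())
    sort(sample.int(slots[i], alloc[i])) * 10L
  }), use.names = FALSE)
  region <- sample(REGION_CATEGORIES, n, replace = TRUE,
                   prob = config$region_props[REGION_CATEGORIES])
  genes <- sprintf("GENE%04d", 1 + (seq_len(n) - 1L) %/% 10L)
  genes[region == "intergenic"] <- ""
  out <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(n)),
    chromosome = chrom,
    position = position,
    strand = sample(c("+", "-"), n, replace = TRUE),
    gene_symbol = genes,
    region_category = region,
    cpg_island = stats::runif(n) < 0.30,
    snp_flag = stats::runif(n) < config$snp_fraction,
    transcript_count = 1L + stats::rpois(n, 2),
    stringsAsFactors = FALSE
  )
  out[cols]
}

#' Generate two histone-mark peak tracks with a planted bivalent set
#'
#' Builds mark-A and mark-B peak tracks whose pairwise intersection covers
#' exactly a chosen subset of probes (the planted "bivalent" probes, a
#' fraction `bivalent_probe_fraction` of the manifest). Around each chosen
#' probe a shared core domain is emitted in both tracks; the two tracks
#' extend the core asymmetrically so that their intersection recovers the
#' core exactly. Extensions are bounded by half the distance to the
#' neighbouring probe, so no peak ever reaches a probe it was not planted
#' on. A handful of single-mark decoy peaks is placed in probe-free gaps.
#'
#' @param manifest A probe manifest (see [generate_manifest()]).
#' @param config A [sim_config()] object.
#' @return A list with elements `mark_a`, `mark_b` (peak sets, 0-based
#'   half-open), and `bivalent_probe_ids` (character).
#' @export
generate_peak_tracks <- function(manifest, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(manifest) == 0) fail("manifest is empty")
  set.seed(child_seed(config$seed, "peaks"))
  n <- nrow(manifest)
  k <- round(config$bivalent_probe_fraction * n)
  chosen <- sort(sample.int(n, k))
  chosen_ids <- manifest$probe_id[chosen]

  a_rows <- list(); b_rows <- list()
  for (chr in names(config$chrom_layout)) {
    idx <- which(manifest$chromosome == chr)
    if (length(idx) == 0) next
    pos <- manifest$position[idx]              # sorted by construction
    len <- config$chrom_layout[[chr]]
    sel <- which(idx %in% chosen)
    if (length(sel) > 0) {
      p <- pos[sel]
      ## reach budget: half the gap to the adjacent probe, minus margin
      prev_i <- match(p, pos) - 1L
      next_i <- match(p, pos) + 1L
      gl <- ifelse(prev_i >= 1, p - pos[pmax(prev_i, 1L)], Inf)
      gr <- ifelse(next_i <= length(pos), pos[pmin(next_i, length(pos))] - p, Inf)
      budget_l <- pmax(0, floor(gl / 2) - 3)
      budget_r <- pmax(0, floor(gr / 2) - 3)
      core_l <- pmin(floor(stats::runif(length(p), 20, 200)), budget_l)
      core_r <- pmin(floor(stats::runif(length(p), 20, 200)), budget_r)
      ext_a  <- pmin(floor(stats::runif(length(p), 10, 150)), budget_r - core_r)
      ext_b  <- pmin(floor(stats::runif(length(p), 10, 150)), budget_l - core_l)
      d_start <- pmax(0, p - 1 - core_l)
      d_end   <- pmin(len, p + 1 + core_r)
      a_rows[[chr]] <- data.frame(chrom = chr, start = d_start,
                                  end = pmin(len, d_end + pmax(0, ext_a)))
      b_rows[[chr]] <- data.frame(chrom = chr,
                                  start = pmax(0, d_start - pmax(0, ext_b)),
                                  end = d_end)
    }
    ## decoy single-mark peaks in the largest probe-free gaps
    bounds <- c(0, pos, len)
    gaps <- diff(bounds)
    big <- order(gaps, decreasing = TRUE)
    big <- big[gaps[big] > 2000][seq_len(min(6, sum(gaps > 2000)))]
    di <- 0L
    for (g in big) {
      di <- di + 1L
      lo <- bounds[g] + floor(gaps[g] * 0.4)
      hi <- bounds[g] + floor(gaps[g] * 0.6)
      row <- data.frame(chrom = chr, start = lo, end = hi)
      key <- paste0(chr, "_decoy", di)
      if (di %% 2 == 0) a_rows[[key]] <- row else b_rows[[key]] <- row
    }
  }
  mk <- function(rows, label) {
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), start = numeric(), end = numeric())
    rownames(df) <- NULL
    peak_set(df, label = label)
  }
  list(mark_a = mk(a_rows, "mark_a"), mark_b = mk(b_rows, "mark_b"),
       bivalent_probe_ids = chosen_ids)
}

#' Generate a staged fetal reference methylome series
#'
#' Draws a baseline methylation level per probe from a bimodal beta mixture
#' (the typical two-hump array distribution), plants a strictly monotone
#' four-stage trajectory (total change 0.2-0.4 beta units, random
#' direction) at a `dynamic_fraction` of probes, and emits
#' `n_fetal_per_stage` samples per prenatal stage bin, each equal to its
#' bin's planted stage mean plus truncated Gaussian noise.
#'
#' @param manifest A probe manifest.
#' @param config A [sim_config()] object.
#' @return A list with `betas` (probe x fetal-sample matrix), `samples`
#'   (data.frame `sample_id`, `dpc`), `stage_means` (probe x 4 matrix of
#'   planted stage means), `bins`, and `dynamic_probe_ids`.
#' @export
generate_fetal_series <- function(manifest, config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(child_seed(config$seed, "fetal"))
  n <- nrow(manifest)
  bins <- config$stage_bins
  ## bimodal baseline typical of array beta distributions
  comp <- sample.int(3, n, replace = TRUE, prob = c(0.45, 0.45, 0.10))
  base <- numeric(n)
  base[comp == 1] <- stats::rbeta(sum(comp == 1), 2, 8)
  base[comp == 2] <- stats::rbeta(sum(comp == 2), 8, 2)
  base[comp == 3] <- stats::rbeta(sum(comp == 3), 5, 5)

  stage_means <- matrix(rep(base, 4), nrow = n,
                        dimnames = list(manifest$probe_id, bins$label))
  n_dyn <- round(config$dynamic_fraction * n)
  dyn <- sort(sample.int(n, n_dyn))
  if (n_dyn > 0) {
    dtot <- stats::runif(n_dyn, 0.2, 0.4)
    dir <- sample(c(-1, 1), n_dyn, replace = TRUE)
    start <- ifelse(dir > 0,
                    stats::runif(n_dyn, 0.05, 0.95 - dtot),
                    stats::runif(n_dyn, 0.05 + dtot, 0.95))
    u2 <- stats::runif(n_dyn, 0.20, 0.45)
    u3 <- stats::runif(n_dyn, 0.55, 0.80)
    traj <- cbind(0, u2, u3, 1)
    stage_means[dyn, ] <- start + dir * dtot * traj
  }
  stage_means <- clip01(stage_means)

  per <- config$n_fetal_per_stage
  dpc <- unlist(lapply(seq_len(nrow(bins)), function(i)
    sort(sample(seq(bins$dpc_min[i], bins$dpc_max[i]), per, replace = TRUE))))
  stage_of <- rep(seq_len(nrow(bins)), each = per)
  sample_id <- sprintf("F%03d", seq_along(dpc))
  betas <- stage_means[, stage_of, drop = FALSE]
  if (config$noise_sd > 0)
    betas <- betas + stats::rnorm(length(betas), 0, config$noise_sd)
  betas <- clip01(betas)
  dimnames(betas) <- list(manifest$probe_id, sample_id)
  list(betas = betas,
       samples = data.frame(sample_id = sample_id, dpc = dpc,
                            stringsAsFactors = FALSE),
       stage_means = stage_means, bins = bins,
       dynamic_probe_ids = manifest$probe_id[dyn])
}

#' Generate a case/control postnatal cohort with planted ground truth
#'
#' Control group means sit at the final-stage fetal values for every probe.
#' Per age group, a set of planted DML shifts the case mean by a signed
#' `dml_delta` (sign random, flipped when the shift would leave
#' `[0.02, 0.98]`; residual clipping is recorded as the effective delta).
#' "Delayed" probes -- a `delayed_fraction` of EDR probes, shared across
#' age groups -- instead set the case mean to the `delay_stage` fetal stage
#' mean, emulating a methylation state frozen at an earlier developmental
#' stage. DML planting oversamples EDR probes so that the pooled DML set is
#' enriched in EDRs by `dml_edr_fold` relative to the array background.
#' Per-sample truncated Gaussian noise is added on top.
#'
#' @param manifest A probe manifest.
#' @param fetal Output of [generate_fetal_series()].
#' @param bivalent_probe_ids Probe ids inside the intersected peak tracks
#'   (from [generate_peak_tracks()]).
#' @param config A [sim_config()] object.
#' @return A list with `betas` (probe x sample), `samples` (sample sheet),
#'   and `truth`: per-age-group DML id sets and signed planted deltas,
#'   plus `bivalent_probe_ids`, `dynamic_probe_ids`, `edr_probe_ids`,
#'   `delayed_probe_ids`.
#' @export
generate_cohort <- function(manifest, fetal, bivalent_probe_ids, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "cohort"))
  n <- nrow(manifest)
  ids <- manifest$probe_id
  base <- fetal$stage_means[, ncol(fetal$stage_means)]   # final stage
  eligible <- ids[!manifest$snp_flag]                    # survives filtering

  edr <- intersect(bivalent_probe_ids, fetal$dynamic_probe_ids)
  edr_eligible <- intersect(edr, eligible)
  delayed <- sort(sample(edr_eligible,
                         round(config$delayed_fraction * length(edr_eligible))))
  d <- length(delayed)
  m <- round(config$dml_fraction * n)          # planted DML per age group
  q <- length(edr_eligible) / length(eligible) # background EDR rate
  n_groups <- length(config$age_groups)

  ## Solve for per-group extra EDR DML so that the pooled (union) DML set
  ## hits the target EDR fold: (d + G*e) / (G*m - (G-1)*d) = fold * q.
  union_size <- n_groups * m - (n_groups - 1) * d
  e <- max(0, round((config$dml_edr_fold * q * union_size - d) / n_groups))
  e <- min(e, floor((length(edr_eligible) - d) / n_groups), m - d)

  edr_pool <- sort(setdiff(edr_eligible, delayed))
  non_edr_pool <- sort(setdiff(eligible, edr_eligible))
  extra_edr <- if (e > 0) sample(edr_pool, n_groups * e) else character()
  n_plain <- m - d - e
  plain <- if (n_plain > 0) sample(non_edr_pool, n_groups * n_plain)
           else character()

  group_means <- list(); truth_dml <- list(); truth_delta <- list()
  delay_mean <- fetal$stage_means[, config$delay_stage]
  for (g in seq_len(n_groups)) {
    grp <- config$age_groups[g]
    picked <- c(if (e > 0) extra_edr[seq((g - 1) * e + 1, g * e)],
                if (n_plain > 0) plain[seq((g - 1) * n_plain + 1, g * n_plain)])
    ## signed shifts at ordinary DML; flip sign rather than clip hard
    sgn <- sample(c(-1, 1), length(picked), replace = TRUE)
    b <- base[picked]
    shifted <- b + sgn * config$dml_delta
    flip <- shifted < 0.02 | shifted > 0.98
    sgn[flip] <- -sgn[flip]
    target <- clip01(b + sgn * config$dml_delta)
    eff <- target - b

    case_mean <- base
    case_mean[picked] <- target
    case_mean[delayed] <- delay_mean[delayed]
    group_means[[grp]] <- list(control = base, autism = case_mean)
    all_ids <- c(picked, delayed)
    deltas <- c(eff, (delay_mean - base)[delayed])
    ord <- order(all_ids)
    truth_dml[[grp]] <- all_ids[ord]
    truth_delta[[grp]] <- stats::setNames(deltas[ord], all_ids[ord])
  }

  ## emit samples: diagnosis x age group x replicate
  age_centre <- stats::setNames(c(7.3, 22.0, 53.3)[seq_len(n_groups)],
                                config$age_groups)
  cols <- list(); meta <- list(); si <- 0L
  for (grp in config$age_groups) for (dx in c("control", "autism")) {
    mu <- group_means[[grp]][[dx]]
    for (r in seq_len(config$n_per_group)) {
      si <- si + 1L
      v <- mu
      if (config$noise_sd > 0)
        v <- clip01(v + stats::rnorm(n, 0, config$noise_sd))
      cols[[si]] <- v
      meta[[si]] <- data.frame(
        sample_id = sprintf("S%03d", si), diagnosis = dx, age_group = grp,
        age_years = round(max(0.5, age_centre[[grp]] + stats::rnorm(1, 0, 2)), 1),
        pmi_hours = round(stats::runif(1, 10, 30), 1),
        stringsAsFactors = FALSE)
    }
  }
  betas <- do.call(cbind, cols)
  samples <- do.call(rbind, meta)
  dimnames(betas) <- list(ids, samples$sample_id)
  truth <- list(
    dml_probe_ids = truth_dml, planted_deltas = truth_delta,
    bivalent_probe_ids = sort(bivalent_probe_ids),
    dynamic_probe_ids = sort(fetal$dynamic_probe_ids),
    edr_probe_ids = sort(edr), delayed_probe_ids = delayed,
    eligible_probe_ids = sort(eligible))
  list(betas = betas, samples = samples, truth = truth)
}

#' Run every synthetic generator and return the full study
#'
#' Convenience wrapper: manifest, peak tracks, fetal series and cohort from
#' one config, with the merged ground truth. Optionally writes all pieces
#' to `out_dir` in their plain-text interchange formats.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Optional directory; when given, writes manifest TSV, beta
#'   matrix TSV, sample sheet TSV, two BED files, fetal beta TSV + fetal
#'   sample TSV, and a ground-truth JSON.
#' @return A list: `manifest`, `peaks`, `fetal`, `betas`, `samples`,
#'   `truth`, `config`.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  manifest <- generate_manifest(config)
  peaks <- generate_peak_tracks(manifest, config)
  fetal <- generate_fetal_series(manifest, config)
  cohort <- generate_cohort(manifest, fetal, peaks$bivalent_probe_ids, config)
  study <- list(manifest = manifest, peaks = peaks, fetal = fetal,
                betas = cohort$betas, samples = cohort$samples,
                truth = cohort$truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
    write_beta_matrix(cohort$betas, file.path(out_dir, "betas.tsv"))
    write_sample_sheet(cohort$samples, file.path(out_dir, "samples.tsv"))
    write_bed(peaks$mark_a, file.path(out_dir, "mark_a.bed"))
    write_bed(peaks$mark_b, file.path(out_dir, "mark_b.bed"))
    write_beta_matrix(fetal$betas, file.path(out_dir, "fetal_betas.tsv"))
    utils::write.table(fetal$samples, file.path(out_dir, "fetal_samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(cohort$truth, file.path(out_dir, "ground_truth.json"))
  }
  study
}
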