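#' Stage-binned mean methylation of a fetal reference series
#'
#' Assigns each fetal sample to the prenatal stage bin containing its days
#' post conception (dpc) and averages beta values per CpG per bin.
#'
#' @param betas Probe x fetal-sample beta matrix.
#' @param dpc Named (or positionally aligned) numeric vector of days post
#'   conception, one per sample.
#' @param bins Stage-bin data.frame (see [default_stage_bins()]).
#' @return A `fetal_stages` list: `means` (probe x bin matrix), `n` (bin
#'   sample counts), `bins`.
#' @export
stage_bin_means <- function(betas, dpc, bins = default_stage_bins()) {
  check_stage_bins(bins)
  if (length(dpc) != ncol(betas))
    fail("dpc length (%d) != number of samples (%d)", length(dpc),
         ncol(betas))
  bin_of <- rep(NA_integer_, length(dpc))
  for (i in seq_len(nrow(bins)))
    bin_of[dpc >= bins$dpc_min[i] & dpc <= bins$dpc_max[i]] <- i
  if (anyNA(bin_of)) {
    bad <- colnames(betas)[is.na(bin_of)]
    if (is.null(bad)) bad <- which(is.na(bin_of))
    fail("samples with dpc outside all stage bins: %s",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  counts <- tabulate(bin_of, nbins = nrow(bins))
  if (any(counts == 0))
    fail("empty stage bin: %s", bins$label[which(counts == 0)[1]])
  means <- matrix(NA_real_, nrow(betas), nrow(bins),
                  dimnames = list(rownames(betas), bins$label))
  for (i in seq_len(nrow(bins)))
    means[, i] <- rowMeans(betas[, bin_of == i, drop = FALSE])
  structure(list(means = means, n = stats::setNames(counts, bins$label),
                 bins = bins), class = "fetal_stages")
}

#' Per-group methylation profiles (mean and SEM)
#'
#' Splits samples by the grouping columns and returns per-CpG mean and
#' standard error of the mean for every group.
#'
#' @param betas Probe x sample beta matrix.
#' @param samples Sample sheet covering every column of `betas`.
#' @param probe_subset Optional probe ids to restrict to.
#' @param by Grouping columns of the sample sheet; default diagnosis and
#'   age group, set to `"diagnosis"` to pool age groups per arm.
#' @return A `group_profiles` list of entries, each with the group key
#'   values, `n`, `mean` (named vector) and `sem`.
#' @export
group_profiles <- function(betas, samples,
                           probe_subset = NULL,
                           by = c("diagnosis", "age_group")) {
  miss <- setdiff(colnames(betas), samples$sample_id)
  if (length(miss) > 0) fail("sample not in sheet: %s", miss[1])
  if (!all(by %in% names(samples)))
    fail("grouping column absent from sample sheet")
  if (!is.null(probe_subset)) {
    absent <- setdiff(probe_subset, rownames(betas))
    if (length(absent) > 0) fail("probe not in matrix: %s", absent[1])
    betas <- betas[probe_subset, , drop = FALSE]
  }
  meta <- samples[match(colnames(betas), samples$sample_id), , drop = FALSE]
  key <- interaction(meta[by], drop = TRUE, lex.order = TRUE, sep = ".")
  out <- lapply(levels(key), function(k) {
    idx <- which(key == k)
    if (length(idx) < 2) fail("group %s has fewer than 2 samples", k)
    X <- betas[, idx, drop = FALSE]
    mu <- rowMeans(X)
    sdv <- apply(X, 1, stats::sd)
    entry <- as.list(meta[idx[1], by, drop = FALSE])
    entry$n <- length(idx)
    entry$mean <- mu
    entry$sem <- sdv / sqrt(length(idx))
    entry
  })
  names(out) <- levels(key)
  structure(out, class = "group_profiles", by = by)
}

#' Correlate group methylation profiles with fetal stage means
#'
#' Pearson correlation (two-sided t-approximation p) between each group's
#' per-CpG mean profile and each fetal stage's per-CpG mean, over a shared
#' probe subset. This is the group x stage correlation matrix that the
#' delay analysis reads.
#'
#' @param profiles A [group_profiles()] object.
#' @param fetal A [stage_bin_means()] object.
#' @param probe_subset Optional probe ids (default: all probes shared by
#'   profiles and fetal means).
#' @return A `delay_report` data.frame with one row per (group, stage):
#'   grouping columns, `stage`, `stage_index`, `r`, `p_value`, `n_cpg`.
#' @export
correlate_profiles <- function(profiles, fetal, probe_subset = NULL) {
  stopifnot(inherits(profiles, "group_profiles"),
            inherits(fetal, "fetal_stages"))
  by <- attr(profiles, "by")
  shared <- intersect(names(profiles[[1]]$mean), rownames(fetal$means))
  if (!is.null(probe_subset)) shared <- intersect(shared, probe_subset)
  if (length(shared) < 3) fail("fewer than 3 shared CpGs")
  rows <- list()
  for (g in names(profiles)) {
    gv <- profiles[[g]]$mean[shared]
    if (stats::sd(gv) == 0) fail("constant profile vector for group %s", g)
    for (s in seq_len(ncol(fetal$means))) {
      fv <- fetal$means[shared, s]
      if (stats::sd(fv) == 0)
        fail("constant fetal stage vector: %s", colnames(fetal$means)[s])
      ct <- stats::cor.test(gv, fv)
      row <- as.data.frame(profiles[[g]][by], stringsAsFactors = FALSE)
      row$stage <- colnames(fetal$means)[s]
      row$stage_index <- s
      row$r <- unname(ct$estimate)
      row$p_value <- ct$p.value
      row$n_cpg <- length(shared)
      rows[[paste(g, s)]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("delay_report", "data.frame")
  out
}

#' Score epigenetic delay from a correlation report
#'
#' For every age group with both diagnosis arms, the delay score at a
#' stage is `r(case) - r(control)`; it is reported for the two earliest
#' prenatal stages. A positive score means the case profile resembles
#' early fetal methylation more than the matched control profile does --
#' the signature read as epigenetic delay.
#'
#' @param report A [correlate_profiles()] result containing a `diagnosis`
#'   column with both `autism` and `control`, and an `age_group` column
#'   (or pooled profiles with diagnosis only).
#' @param stages Stage indices to score (default the earliest two).
#' @return A data.frame with `age_group` (or `"pooled"`), `stage`,
#'   `stage_index`, `r_case`, `r_control`, `delay_score`, `delayed` flag.
#' @export
delay_score <- function(report, stages = c(1L, 2L)) {
  if (!"diagnosis" %in% names(report)) fail("report lacks a diagnosis column")
  has_age <- "age_group" %in% names(report)
  groups <- if (has_age) unique(report$age_group) else "pooled"
  rows <- list()
  for (g in groups) {
    sub <- if (has_age) report[report$age_group == g, ] else report
    for (s in stages) {
      rc <- sub$r[sub$diagnosis == "autism" & sub$stage_index == s]
      rt <- sub$r[sub$diagnosis == "control" & sub$stage_index == s]
      if (length(rc) != 1 || length(rt) != 1)
        fail("missing diagnosis arm for group %s at stage %d", g, s)
      rows[[paste(g, s)]] <- data.frame(
        age_group = g, stage = sub$stage[sub$stage_index == s][1],
        stage_index = s, r_case = rc, r_control = rt,
        delay_score = rc - rt, delayed = rc > rt,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trajectory table for a single CpG
#'
#' One row per fetal stage (planted/observed stage mean) followed by one
#' row per postnatal group (mean and SEM), ready for plotting a locus
#' trajectory.
#'
#' @param probe_id A single probe id present in both inputs.
#' @param profiles A [group_profiles()] object.
#' @param fetal A [stage_bin_means()] object.
#' @return A data.frame with columns `source`, `label`, `mean`, `sem`,
#'   `n`; fetal rows first in stage order.
#' @export
locus_report <- function(probe_id, profiles, fetal) {
  if (!probe_id %in% rownames(fetal$means))
    fail("probe %s not in fetal dataset", probe_id)
  if (!probe_id %in% names(profiles[[1]]$mean))
    fail("probe %s not in group profiles", probe_id)
  fet <- data.frame(source = "fetal", label = colnames(fetal$means),
                    mean = fetal$means[probe_id, ],
                    sem = NA_real_, n = as.integer(fetal$n),
                    stringsAsFactors = FALSE)
  post <- do.call(rbind, lapply(names(profiles), function(g) {
    data.frame(source = "postnatal", label = g,
               mean = unname(profiles[[g]]$mean[probe_id]),
               sem = unname(profiles[[g]]$sem[probe_id]),
               n = profiles[[g]]$n, stringsAsFactors = FALSE)
  }))
  out <- rbind(fet, post)
  rownames(out) <- NULL
  out
}
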