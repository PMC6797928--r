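#' Tabulate DML counts by genomic region category
#'
#' Counts called DML per region category and computes the expected
#' proportions from the background manifest (all retained probes), the
#' basis of the region-distribution comparison and its chi-square
#' goodness-of-fit test.
#'
#' @param dml A `dml_set` (or a character vector of probe ids).
#' @param manifest Background probe manifest (post-filter).
#' @return A `category_counts` list: `observed` (named counts), `total`,
#'   `expected_prop` (background proportions), `fold` (observed over
#'   expected proportion per category; `NA` for an empty DML set).
#' @export
categorize_dml <- function(dml, manifest) {
  ids <- if (inherits(dml, "dml_set")) dml$probe_ids else as.character(dml)
  bad_cat <- setdiff(unique(manifest$region_category), REGION_CATEGORIES)
  if (length(bad_cat) > 0)
    fail("unknown region category in manifest: %s", bad_cat[1])
  missing <- setdiff(ids, manifest$probe_id)
  if (length(missing) > 0) fail("DML probe not in manifest: %s", missing[1])
  cat_f <- factor(manifest$region_category, levels = REGION_CATEGORIES)
  expected_prop <- prop.table(table(cat_f))
  obs <- table(factor(manifest$region_category[match(ids, manifest$probe_id)],
                      levels = REGION_CATEGORIES))
  total <- length(ids)
  fold <- if (total > 0) as.numeric(obs / total) / as.numeric(expected_prop)
          else rep(NA_real_, length(expected_prop))
  structure(list(observed = obs, total = total,
                 expected_prop = expected_prop,
                 fold = stats::setNames(fold, names(expected_prop))),
            class = "category_counts")
}

#' Chi-square goodness-of-fit test
#'
#' Pearson `chi2 = sum((O - E)^2 / E)` against expected proportions, with
#' `df = k - 1` and an upper-tail p-value.
#'
#' @param observed Named or plain vector of category counts (>= 2 cells).
#' @param expected_prop Expected proportions, summing to 1.
#' @return List with `chi2`, `df`, `p_value`, `expected` counts.
#' @export
chisq_gof <- function(observed, expected_prop) {
  observed <- as.numeric(observed)
  expected_prop <- as.numeric(expected_prop)
  if (length(observed) < 2) fail("need at least 2 categories")
  if (length(observed) != length(expected_prop))
    fail("observed and expected lengths differ")
  if (abs(sum(expected_prop) - 1) > 1e-9)
    fail("expected proportions must sum to 1")
  expected <- sum(observed) * expected_prop
  if (any(expected <= 0)) fail("expected count of 0 in some category")
  res <- suppressWarnings(stats::chisq.test(observed, p = expected_prop))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value), expected = expected)
}

#' Fold enrichment of a subset relative to a background
#'
#' `fold = (n_in_subset / n_subset) / (n_in_background / n_background)`,
#' with a 1-df chi-square goodness-of-fit of the observed in/out split of
#' the subset against the background rate.
#'
#' @param n_in_subset Members of the subset inside the feature.
#' @param n_subset Subset size (> 0).
#' @param n_in_background Background elements inside the feature.
#' @param n_background Background size (> 0).
#' @return An `enrichment_result` list with the four counts, both
#'   fractions, `fold`, `expected` count, `chi2` and `p_value`.
#' @export
fold_enrichment <- function(n_in_subset, n_subset,
                            n_in_background, n_background) {
  if (n_subset <= 0 || n_background <= 0)
    fail("subset and background sizes must be positive")
  if (n_in_subset > n_subset || n_in_background > n_background)
    fail("feature count exceeds set size")
  bg_frac <- n_in_background / n_background
  if (bg_frac == 0) fail("background fraction is 0: fold undefined")
  sub_frac <- n_in_subset / n_subset
  fold <- sub_frac / bg_frac
  ct <- NULL
  if (bg_frac < 1) {
    ct <- suppressWarnings(
      stats::chisq.test(c(n_in_subset, n_subset - n_in_subset),
                        p = c(bg_frac, 1 - bg_frac)))
  }
  structure(list(
    n_in_subset = n_in_subset, n_subset = n_subset,
    n_in_background = n_in_background, n_background = n_background,
    subset_fraction = sub_frac, background_fraction = bg_frac,
    fold = fold, expected = n_subset * bg_frac,
    chi2 = if (is.null(ct)) NA_real_ else unname(ct$statistic),
    p_value = if (is.null(ct)) NA_real_ else unname(ct$p.value)),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: %d/%d in subset (%.2f%%) vs %d/%d background (%.2f%%); fold %.3g, chi2 %.3g, p %.3g\n",
    x$n_in_subset, x$n_subset, 100 * x$subset_fraction,
    x$n_in_background, x$n_background, 100 * x$background_fraction,
    x$fold, x$chi2, x$p_value))
  invisible(x)
}
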