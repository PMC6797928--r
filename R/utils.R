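#' Derive a reproducible child seed for a named pipeline stage
#'
#' A single user-supplied seed fans out to per-stage seeds through a stable
#' string hash, so adding or reordering stages never perturbs the random
#' stream of another stage.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name.
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

## Percent of a count over a total, to one decimal (round half to even).
percent_1dp <- function(count, total) {
  stopifnot(total > 0)
  round(100 * count / total, 1)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)  # x first: keeps dim attributes

## stop() with a sprintf-style message, no call in the condition
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
assert_beta_matrix <- function(betas) {
  if (!is.matrix(betas) || !is.numeric(betas))
    fail("beta matrix must be a numeric matrix (probes x samples)")
  if (is.null(rownames(betas)) || is.null(colnames(betas)))
    fail("beta matrix must carry probe rownames and sample colnames")
  if (anyDuplicated(rownames(betas)))
    fail("duplicate probe ids in beta matrix")
  rng <- range(betas, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    fail("beta values outside [0,1] (range %.4g..%.4g)", rng[1], rng[2])
  invisible(betas)
}

REGION_CATEGORIES <- c("promoter", "gene_body", "three_utr", "intergenic")

#' Default fetal stage bins (days post conception)
#'
#' The four prenatal windows used throughout the trajectory analysis:
#' 23-76, 77-89, 90-108 and 109-184 days post conception.
#'
#' @return A data.frame with columns `label`, `dpc_min`, `dpc_max`.
#' @export
default_stage_bins <- function() {
  data.frame(
    label   = c("dpc23_76", "dpc77_89", "dpc90_108", "dpc109_184"),
    dpc_min = c(23, 77, 90, 109),
    dpc_max = c(76, 89, 108, 184),
    stringsAsFactors = FALSE
  )
}

check_stage_bins <- function(bins) {
  need <- c("label", "dpc_min", "dpc_max")
  if (!is.data.frame(bins) || !all(need %in% names(bins)))
    fail("stage bins must be a data.frame with columns label, dpc_min, dpc_max")
  if (any(bins$dpc_min > bins$dpc_max)) fail("stage bin with dpc_min > dpc_max")
  if (nrow(bins) > 1) {
    if (is.unsorted(bins$dpc_min, strictly = TRUE))
      fail("stage bins must be ordered by dpc_min")
    if (any(bins$dpc_min[-1] <= bins$dpc_max[-nrow(bins)]))
      fail("stage bins overlap")
  }
  invisible(bins)
}
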