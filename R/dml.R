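#' Define a two-group comparison
#'
#' @param case_sample_ids,control_sample_ids Disjoint sample-id sets, each
#'   with at least 2 members.
#' @param label Comparison label (e.g. the age group).
#' @return A `comparison_spec` object.
#' @export
comparison_spec <- function(case_sample_ids, control_sample_ids, label = "") {
  case_sample_ids <- as.character(case_sample_ids)
  control_sample_ids <- as.character(control_sample_ids)
  if (length(intersect(case_sample_ids, control_sample_ids)) > 0)
    fail("case and control sample sets overlap")
  if (length(case_sample_ids) < 2 || length(control_sample_ids) < 2)
    fail("each arm needs at least 2 samples")
  structure(list(case = case_sample_ids, control = control_sample_ids,
                 label = label), class = "comparison_spec")
}

## Newton inversion of the trigamma function (for the variance-prior
## degrees of freedom). Solves trigamma(y) = x for y > 0.
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(60)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

## Method-of-moments fit of a scaled inverse-chi-square prior to per-probe
## sample variances: returns prior df d0 and prior variance s02. Uses the
## log-variance moments (digamma/trigamma identities for chi-square).
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(d0 = 0, s02 = NA_real_))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    ## no excess spread in the log variances beyond chi-square sampling
    ## noise: infinitely strong prior at the common variance, so equal
    ## sample variances are an exact fixed point of the shrinkage
    d0 <- Inf
    s02 <- mean(s2[ok])
  }
  list(d0 = d0, s02 = s02)
}

## Moderated two-sample t statistics for one or many label assignments.
## X: probe x sample matrix; case_ind: logical matrix (samples x B), one
## column per assignment of samples to the case arm. Every assignment must
## place the same number of samples in the case arm (label permutation),
## so arm sizes are scalars and everything vectorises over columns.
## Returns delta (probe x B), tmod (probe x B), the per-assignment prior.
moderated_t_matrix <- function(X, case_ind) {
  n <- ncol(X)
  n1 <- sum(case_ind[, 1])
  if (any(colSums(case_ind) != n1)) fail("unbalanced label assignment")
  n2 <- n - n1
  df <- n - 2
  p <- nrow(X)
  B <- ncol(case_ind)
  X2 <- X * X
  S1 <- X %*% case_ind          # probe x B case sums
  Q1 <- X2 %*% case_ind
  S2 <- rowSums(X) - S1
  Q2 <- rowSums(X2) - Q1
  M1 <- S1 / n1
  M2 <- S2 / n2
  s2 <- (Q1 - n1 * M1 * M1 + Q2 - n2 * M2 * M2)
  s2 <- pmax(s2, 0) / df
  delta <- M1 - M2

  ## per-column method-of-moments prior on the log variances
  z <- log(s2)
  z[!is.finite(z)] <- NA
  npos <- colSums(!is.na(z))
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- colMeans(e, na.rm = TRUE)
  evar <- (colMeans(e * e, na.rm = TRUE) - emean^2) * npos / pmax(npos - 1, 1)
  evar <- evar - trigamma(df / 2)
  d0s <- vapply(evar, function(v)
    if (is.finite(v) && v > 0) 2 * trigamma_inverse(v) else Inf, numeric(1))
  ## infinite d0: no excess spread beyond chi-square noise; shrink fully
  ## to the common variance (variance-scale mean), making equal sample
  ## variances an exact fixed point
  s2_zeroed <- s2
  s2_zeroed[is.na(z)] <- 0
  s02s <- ifelse(is.finite(d0s),
                 exp(emean + digamma(d0s / 2) - log(d0s / 2)),
                 colSums(s2_zeroed) / pmax(npos, 1))
  moderated <- npos >= 2 & is.finite(s02s)
  ## shrinkage s2_post = wA + wB * s2 per column; unmoderated fallback
  ## (wA = 0, wB = 1) where the prior is not estimable
  wA <- ifelse(moderated,
               ifelse(is.finite(d0s), d0s * s02s / (d0s + df), s02s), 0)
  wB <- ifelse(moderated, ifelse(is.finite(d0s), df / (d0s + df), 0), 1)
  s2post <- s2 * rep(wB, each = p) + rep(wA, each = p)
  se <- sqrt(s2post * (1 / n1 + 1 / n2))
  tmod <- delta / se
  tmod[delta == 0 & se == 0] <- 0
  d0s[!moderated] <- 0
  list(delta = delta, tmod = tmod, s2 = s2, d0 = d0s, s02 = s02s,
       moderated = moderated, df = df)
}

#' Per-probe differential-methylation statistics
#'
#' Computes group means, the signed methylation difference
#' `delta_beta = mean(case) - mean(control)`, and a moderated t-statistic
#' in which the per-probe pooled variance is shrunk toward a common prior:
#' `s2_post = (d0 * s02 + d * s2) / (d0 + d)`, with the prior `(d0, s02)`
#' estimated by method of moments on the log sample variances across all
#' probes. `t_mod = delta_beta / sqrt(s2_post * (1/n1 + 1/n2))`.
#'
#' When fewer than two probes have positive variance the prior cannot be
#' estimated; an ordinary (unmoderated) t is returned with a warning.
#'
#' @param betas Probe x sample beta matrix without missing values.
#' @param spec A [comparison_spec()].
#' @return A data.frame with columns `probe_id`, `mean_case`,
#'   `mean_control`, `delta_beta`, `s2_pooled`, `t_mod`; attributes `d0`,
#'   `s02`, `df` carry the shrinkage parameters.
#' @export
probe_stats <- function(betas, spec) {
  stopifnot(inherits(spec, "comparison_spec"))
  assert_beta_matrix(betas)
  miss <- setdiff(c(spec$case, spec$control), colnames(betas))
  if (length(miss) > 0) fail("sample not in beta matrix: %s", miss[1])
  if (anyNA(betas[, c(spec$case, spec$control)]))
    fail("beta matrix contains missing values; filter first")
  X <- betas[, c(spec$case, spec$control), drop = FALSE]
  ind <- matrix(c(rep(TRUE, length(spec$case)),
                  rep(FALSE, length(spec$control))), ncol = 1)
  res <- moderated_t_matrix(X, ind)
  if (!res$moderated[1])
    warning("variance prior not estimable; returning unmoderated t",
            call. = FALSE)
  n1 <- length(spec$case)
  out <- data.frame(
    probe_id = rownames(betas),
    mean_case = res$delta[, 1] + (rowSums(X[, -seq_len(n1), drop = FALSE]) /
                                    (ncol(X) - n1)),
    mean_control = rowSums(X[, -seq_len(n1), drop = FALSE]) / (ncol(X) - n1),
    delta_beta = res$delta[, 1],
    s2_pooled = res$s2[, 1],
    t_mod = res$tmod[, 1],
    stringsAsFactors = FALSE
  )
  attr(out, "d0") <- res$d0[1]
  attr(out, "s02") <- res$s02[1]
  attr(out, "df") <- res$df
  attr(out, "label") <- spec$label
  out
}

#' Permutation p-values for the moderated t-statistic
#'
#' Builds the null by permuting the case/control labels and recomputing
#' the moderated t for every probe under every permutation, re-estimating
#' the variance prior within each permutation. Two modes:
#'
#' * exhaustive: when the number of distinct label assignments
#'   `choose(n1 + n2, n1)` is at most `exhaustive_limit`, every assignment
#'   is evaluated and the p-value is the exact fraction of assignments
#'   (including the observed one) with `|t*| >= |t_obs|`.
#' * Monte Carlo: `n_perm` random label permutations with the add-one
#'   estimator `p = (1 + #{|t*| >= |t_obs|}) / (n_perm + 1)`.
#'
#' @param betas Probe x sample beta matrix.
#' @param spec A [comparison_spec()].
#' @param n_perm Number of random permutations in Monte-Carlo mode.
#' @param seed Integer seed for Monte-Carlo permutations.
#' @param mode `"auto"` (default), `"exhaustive"` or `"monte_carlo"`.
#' @param exhaustive_limit Assignment-count threshold for auto mode.
#' @return Named numeric vector of p-values in `(0, 1]`, one per probe;
#'   attribute `mode` records which mode ran, `n_assignments` its size.
#' @export
permutation_pvalues <- function(betas, spec, n_perm = 999, seed = 1,
                                mode = c("auto", "exhaustive", "monte_carlo"),
                                exhaustive_limit = 2000) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "comparison_spec"))
  X <- betas[, c(spec$case, spec$control), drop = FALSE]
  if (anyNA(X)) fail("beta matrix contains missing values; filter first")
  n1 <- length(spec$case)
  n <- ncol(X)
  n_assign <- choose(n, n1)
  if (mode == "auto")
    mode <- if (n_assign <= exhaustive_limit) "exhaustive" else "monte_carlo"

  obs <- moderated_t_matrix(X, matrix(c(rep(TRUE, n1),
                                        rep(FALSE, n - n1)), ncol = 1))
  t_obs <- abs(obs$tmod[, 1])
  ## tolerance for |t*| >= |t_obs| ties: permuted statistics recompute the
  ## same value through a different summation order, so exact equality is
  ## broken by float noise; without this, label-swap symmetry fails
  t_ref <- t_obs - 1e-8 * (1 + ifelse(is.finite(t_obs), t_obs, 0))

  if (mode == "exhaustive") {
    combos <- utils::combn(n, n1)
    ind <- matrix(FALSE, n, ncol(combos))
    ind[cbind(as.vector(combos),
              rep(seq_len(ncol(combos)), each = n1))] <- TRUE
    null <- moderated_t_matrix(X, ind)
    ge <- abs(null$tmod) >= t_ref   # column-wise recycling over probes
    p <- rowMeans(ge)
    n_used <- ncol(combos)
  } else {
    if (n_perm < 1) fail("at least one permutation required")
    if (n_perm < 100)
      warning("fewer than 100 permutations: p-values will be coarse",
              call. = FALSE)
    set.seed(seed)
    ind <- matrix(FALSE, n, n_perm)
    for (b in seq_len(n_perm)) ind[sample.int(n, n1), b] <- TRUE
    null <- moderated_t_matrix(X, ind)
    ge <- abs(null$tmod) >= t_ref
    p <- (1 + rowSums(ge)) / (n_perm + 1)
    n_used <- n_perm
  }
  names(p) <- rownames(betas)
  attr(p, "mode") <- mode
  attr(p, "n_assignments") <- n_used
  p
}

#' Call differentially methylated loci
#'
#' A probe is a DML when its permutation p-value is below `alpha` and its
#' absolute group difference `|delta_beta|` is at least `delta`.
#'
#' @param stats Output of [probe_stats()].
#' @param pvals Output of [permutation_pvalues()] (aligned by probe id).
#' @param alpha Significance cutoff (default 0.05, `p < alpha`).
#' @param delta Effect-size cutoff on the beta scale (default 0.10,
#'   `|delta_beta| >= delta`).
#' @return A `dml_set`: list with `label`, `table` (the full stats table
#'   with `p_perm` and logical `passes`), `probe_ids` (the calls, sorted),
#'   and `cutoffs`.
#' @export
call_dml <- function(stats, pvals, alpha = 0.05, delta = 0.10) {
  if (!all(stats$probe_id %in% names(pvals)))
    fail("p-values missing for some probes")
  tab <- stats
  tab$p_perm <- unname(pvals[tab$probe_id])
  tab$passes <- tab$p_perm < alpha & abs(tab$delta_beta) >= delta
  structure(list(label = attr(stats, "label"),
                 table = tab,
                 probe_ids = sort(tab$probe_id[tab$passes]),
                 cutoffs = c(alpha = alpha, delta = delta)),
            class = "dml_set")
}

#' @export
print.dml_set <- function(x, ...) {
  cat(sprintf("DML set '%s': %d of %d probes (p < %g, |delta beta| >= %g)\n",
              x$label, length(x$probe_ids), nrow(x$table),
              x$cutoffs["alpha"], x$cutoffs["delta"]))
  invisible(x)
}

#' Hierarchical clustering of samples on their beta profiles
#'
#' Agglomerative clustering with Manhattan distance between sample beta
#' vectors and complete linkage. Samples are ordered lexicographically by
#' id before clustering, which fixes the tie-break deterministically.
#'
#' @param betas Probe x sample beta matrix (typically restricted to a DML
#'   set's probes).
#' @return An [stats::hclust] object (single sample: a one-leaf stub list
#'   of class `hclust` with no merges).
#' @export
cluster_samples <- function(betas) {
  if (ncol(betas) < 1) fail("no samples to cluster")
  ord <- order(colnames(betas))
  X <- betas[, ord, drop = FALSE]
  if (ncol(X) == 1) {
    return(structure(list(merge = matrix(numeric(), 0, 2), height = numeric(),
                          order = 1L, labels = colnames(X),
                          method = "complete", dist.method = "manhattan"),
                     class = "hclust"))
  }
  d <- stats::dist(t(X), method = "manhattan")
  stats::hclust(d, method = "complete")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided KS test of `sup |ECDF_a - ECDF_b|` with the asymptotic
#' p-value.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) fail("empty sample")
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Welch two-sample t-test
#'
#' Two-sided Welch t-test. The degenerate case of two constant samples
#' with equal means returns `t = 0, p = 1` instead of erroring.
#'
#' @param a,b Numeric samples with at least 2 values each.
#' @return List with `statistic` (t), `p_value`, `df`.
#' @export
ttest_two_sample <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) fail("each sample needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, p_value = 1, df = length(a) + length(b) - 2))
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0,
                df = length(a) + length(b) - 2))
  }
  res <- stats::t.test(a, b)
  list(statistic = unname(res$statistic), p_value = unname(res$p.value),
       df = unname(res$parameter))
}
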