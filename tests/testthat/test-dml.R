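make_spec <- function(n1 = 2, n2 = 2) {
  comparison_spec(sprintf("case%d", seq_len(n1)),
                  sprintf("ctrl%d", seq_len(n2)), "toy")
}

test_that("group means and delta beta are computed exactly", {
  m <- beta_matrix(c(0.9, 0.2, 0.9, 0.3, 0.1, 0.25, 0.1, 0.35),
                   c("cgA", "cgB"),
                   c("case1", "case2", "ctrl1", "ctrl2"))
  st <- probe_stats(m, make_spec())
  expect_equal(st$delta_beta[st$probe_id == "cgA"], 0.8)
  expect_equal(st$mean_case[st$probe_id == "cgA"], 0.9)
  expect_equal(st$mean_control[st$probe_id == "cgA"], 0.1)
  expect_equal(st$delta_beta[st$probe_id == "cgB"], -0.05)
})

test_that("shrinkage is a no-op when all probes share the same variance", {
  ## per-probe constant offsets: means differ, sample variances identical
  base <- c(0.40, 0.44, 0.42, 0.46, 0.41, 0.45)
  offsets <- seq(-0.1, 0.1, length.out = 30)
  rows <- t(vapply(offsets, function(o) base + o, numeric(6)))
  dimnames(rows) <- list(sprintf("p%02d", 1:30),
                         c(sprintf("case%d", 1:3), sprintf("ctrl%d", 1:3)))
  st <- probe_stats(rows, make_spec(3, 3))
  s2post_implied <- (st$delta_beta / st$t_mod)^2 / (1 / 3 + 1 / 3)
  ok <- is.finite(s2post_implied)
  expect_equal(s2post_implied[ok], st$s2_pooled[ok], tolerance = 1e-9)
})

test_that("moderated variances interpolate between raw and prior", {
  set.seed(11)
  n <- 50
  sds <- sqrt(1 / stats::rgamma(n, 4, rate = 4)) * 0.03
  X <- t(vapply(seq_len(n), function(i) 0.5 + rnorm(8, 0, sds[i]),
                numeric(8)))
  X <- pmin(pmax(X, 0), 1)
  dimnames(X) <- list(sprintf("p%02d", 1:n),
                      c(sprintf("case%d", 1:4), sprintf("ctrl%d", 1:4)))
  st <- probe_stats(X, make_spec(4, 4))
  d0 <- attr(st, "d0"); s02 <- attr(st, "s02"); df <- attr(st, "df")
  expect_true(is.finite(d0) && d0 > 0)
  s2post <- (d0 * s02 + df * st$s2_pooled) / (d0 + df)
  lo <- pmin(st$s2_pooled, s02); hi <- pmax(st$s2_pooled, s02)
  expect_true(all(s2post >= lo - 1e-15 & s2post <= hi + 1e-15))
  strict <- abs(st$s2_pooled - s02) > 1e-12
  expect_true(all(s2post[strict] > lo[strict] & s2post[strict] < hi[strict]))
})

test_that("moderated t agrees with an independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(21)
  X <- matrix(pmin(pmax(rnorm(200 * 10, 0.5, 0.05), 0), 1), 200, 10,
              dimnames = list(sprintf("p%03d", 1:200),
                              c(sprintf("case%d", 1:5),
                                sprintf("ctrl%d", 1:5))))
  st <- probe_stats(X, make_spec(5, 5))
  design <- cbind(intercept = 1, case = c(rep(1, 5), rep(0, 5)))
  fit <- limma::eBayes(limma::lmFit(X, design))
  expect_equal(st$t_mod, unname(fit$t[, "case"]), tolerance = 1e-6)
  expect_equal(attr(st, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(st, "s02"), fit$s2.prior, tolerance = 1e-6)
})

test_that("exhaustive permutation p matches hand enumeration", {
  ## one probe, 2 vs 2: six balanced assignments, the two extreme ones
  ## (original and its mirror) share the maximal |t| -> p = 2/6
  m <- beta_matrix(c(0.9, 0.9, 0.1, 0.1), "cgA",
                   c("case1", "case2", "ctrl1", "ctrl2"))
  p <- permutation_pvalues(m, make_spec(), mode = "exhaustive")
  expect_equal(unname(p["cgA"]), 2 / 6)
  expect_equal(attr(p, "n_assignments"), 6)

  flat <- beta_matrix(rep(0.4, 4), "cgA",
                      c("case1", "case2", "ctrl1", "ctrl2"))
  pf <- permutation_pvalues(flat, make_spec(), mode = "exhaustive")
  expect_equal(unname(pf["cgA"]), 1)
})

test_that("exhaustive p matches an independent per-assignment oracle", {
  skip_if_not_installed("limma")
  set.seed(33)
  n1 <- 3; n2 <- 3
  X <- matrix(pmin(pmax(rnorm(40 * 6, 0.5, 0.06), 0), 1), 40, 6,
              dimnames = list(sprintf("p%02d", 1:40),
                              c(sprintf("case%d", 1:n1),
                                sprintf("ctrl%d", 1:n2))))
  p_pkg <- permutation_pvalues(X, make_spec(n1, n2), mode = "exhaustive")
  ## oracle: limma moderated t recomputed for every label assignment
  combos <- combn(6, n1)
  tmat <- sapply(seq_len(ncol(combos)), function(j) {
    lab <- rep(0, 6); lab[combos[, j]] <- 1
    fit <- limma::eBayes(limma::lmFit(X, cbind(1, lab)))
    fit$t[, 2]
  })
  t_obs <- abs(tmat[, 1])  # first assignment is the observed labelling
  ## same float-tie tolerance as the engine, so near-equal |t| count alike
  p_oracle <- rowMeans(abs(tmat) >= t_obs - 1e-8 * (1 + t_obs))
  expect_equal(as.numeric(p_pkg), unname(p_oracle), tolerance = 1e-10)
})

test_that("label swap negates effects and preserves permutation p", {
  set.seed(5)
  X <- matrix(pmin(pmax(rnorm(60 * 8, 0.5, 0.05), 0), 1), 60, 8,
              dimnames = list(sprintf("p%02d", 1:60),
                              c(sprintf("a%d", 1:4), sprintf("b%d", 1:4))))
  spec_f <- comparison_spec(sprintf("a%d", 1:4), sprintf("b%d", 1:4), "f")
  spec_r <- comparison_spec(sprintf("b%d", 1:4), sprintf("a%d", 1:4), "r")
  sf <- probe_stats(X, spec_f); sr <- probe_stats(X, spec_r)
  expect_equal(sf$delta_beta, -sr$delta_beta)
  expect_equal(sf$t_mod, -sr$t_mod)
  pf <- permutation_pvalues(X, spec_f, mode = "exhaustive")
  pr <- permutation_pvalues(X, spec_r, mode = "exhaustive")
  expect_equal(pf, pr)
})

test_that("DML calling applies both cutoffs and is order-invariant", {
  st <- data.frame(
    probe_id = c("cgA", "cgB", "cgC"),
    mean_case = c(0.59, 0.65, 0.70), mean_control = c(0.50, 0.50, 0.50),
    delta_beta = c(0.09, 0.15, 0.20), s2_pooled = 1e-4,
    t_mod = c(5, 5, 5), stringsAsFactors = FALSE)
  attr(st, "label") <- "toy"
  pv <- c(cgA = 0.001, cgB = 0.20, cgC = 0.01)
  dml <- call_dml(st, pv)
  expect_equal(dml$probe_ids, "cgC")       # cgA fails delta, cgB fails p
  perm <- c(3, 1, 2)
  dml_perm <- call_dml(st[perm, ], pv[c("cgB", "cgA", "cgC")])
  expect_equal(dml_perm$probe_ids, dml$probe_ids)
  ## boundary: |delta| exactly 0.10 is kept
  st$delta_beta[1] <- 0.10
  expect_true("cgA" %in% call_dml(st, pv)$probe_ids)
})

test_that("Monte-Carlo mode warns when coarse and errors without permutations", {
  m <- beta_matrix(runif(40, 0.3, 0.7), sprintf("p%02d", 1:10),
                   c("case1", "case2", "ctrl1", "ctrl2"))
  expect_warning(
    permutation_pvalues(m, make_spec(), n_perm = 50, seed = 1,
                        mode = "monte_carlo"),
    "fewer than 100")
  expect_error(
    permutation_pvalues(m, make_spec(), n_perm = 0, mode = "monte_carlo"),
    "at least one permutation")
})

test_that("complete-linkage Manhattan clustering matches hand computation", {
  ## 1-D toy {0, 1, 10}: merge {0},{1} at height 1, then with {10} at 10
  m <- matrix(c(0, 1, 10), nrow = 1,
              dimnames = list("p1", c("s1", "s2", "s3")))
  hc <- cluster_samples(m)
  expect_equal(hc$height, c(1, 10))

  dup <- matrix(c(0.4, 0.4, 0.9), nrow = 1,
                dimnames = list("p1", c("s1", "s2", "s3")))
  expect_equal(cluster_samples(dup)$height[1], 0)

  single <- matrix(0.5, 1, 1, dimnames = list("p1", "s1"))
  expect_equal(length(cluster_samples(single)$height), 0)
})

test_that("clustering on planted DML separates the diagnoses", {
  cfg <- sim_config(n_probes = 1500, chrom_layout = c(chr1 = 2e6),
                    n_fetal_per_stage = 5, seed = 77)
  st <- simulate_study(cfg)
  grp <- "young"
  ids <- st$truth$dml_probe_ids[[grp]]
  cols <- st$samples$sample_id[st$samples$age_group == grp]
  hc <- cluster_samples(st$betas[ids, cols])
  cl <- stats::cutree(hc, k = 2)
  dx <- st$samples$diagnosis[match(names(cl), st$samples$sample_id)]
  expect_equal(length(unique(cl[dx == "autism"])), 1)
  expect_equal(length(unique(cl[dx == "control"])), 1)
  expect_false(cl[dx == "autism"][1] == cl[dx == "control"][1])
})

test_that("KS and t-test wrappers reproduce known values", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(c(0.1, 0.2), c(0.8, 0.9))$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2, 3, 4), c(2, 3, 4, 5))$statistic, 0.25)
  expect_error(ks_two_sample(numeric(), 1:3), "empty")

  eq <- ttest_two_sample(c(2, 2, 2), c(2, 2, 2))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(ttest_two_sample(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(8)
  sep <- ttest_two_sample(rnorm(4, 0, 1e-4), 1 + rnorm(4, 0, 1e-4))
  expect_lt(sep$p_value, 0.001)
})
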