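#' Threshold classification of exon-skipping splice events
#'
#' Classifies events by their control inclusion level Psi and by the
#' case/control inclusion change. `inclusion_class` is `included` when
#' control Psi >= 0.9, `excluded` when <= 0.1, otherwise `intermediate`.
#' `delta_psi` is oriented `control - case` by default, so a positive
#' change (> 0.1) means reduced inclusion in cases and is labelled
#' `down`; `< -0.1` is `up`; otherwise `unchanged`.
#'
#' @param psi Data.frame with columns `event_id`, `psi_control`,
#'   `psi_case`, all Psi in `[0,1]`.
#' @param orientation `"control_minus_case"` (default) or
#'   `"case_minus_control"` for the opposite sign convention.
#' @return The input with `delta_psi`, `inclusion_class` and `aberrance`
#'   columns appended.
#' @export
classify_splice_events <- function(psi,
                                   orientation = c("control_minus_case",
                                                   "case_minus_control")) {
  orientation <- match.arg(orientation)
  need <- c("event_id", "psi_control", "psi_case")
  if (!all(need %in% names(psi)))
    fail("psi table needs columns: %s", paste(need, collapse = ", "))
  vals <- c(psi$psi_control, psi$psi_case)
  if (any(vals < 0 | vals > 1, na.rm = TRUE))
    fail("Psi values outside [0,1]")
  d <- psi$psi_control - psi$psi_case
  if (orientation == "case_minus_control") d <- -d
  psi$delta_psi <- d
  psi$inclusion_class <- ifelse(psi$psi_control >= 0.9, "included",
                         ifelse(psi$psi_control <= 0.1, "excluded",
                                "intermediate"))
  psi$aberrance <- ifelse(d > 0.1, "down", ifelse(d < -0.1, "up",
                                                  "unchanged"))
  psi
}

#' Percent 5-methylcytosine from an ELISA standard curve
#'
#' Fits the standard curve as a second-order polynomial in the log of the
#' 405-nm absorbance, `percent = a + b*ln(A) + c*ln(A)^2`, by least
#' squares, and evaluates it at each sample's mean absorbance (replicates
#' are averaged per sample).
#'
#' @param standards Data.frame with columns `percent_5mc` and
#'   `absorbance` (> 0); at least 3 standards with distinct absorbances.
#' @param samples Data.frame with columns `sample_id` and `absorbance`
#'   (one row per replicate; replicates are averaged).
#' @return List with `coefficients` (a, b, c), `residuals` of the
#'   standard fit, and `samples`: per-sample mean absorbance and fitted
#'   `percent_5mc`.
#' @export
elisa_percent_5mc <- function(standards, samples) {
  if (!all(c("percent_5mc", "absorbance") %in% names(standards)))
    fail("standards need columns percent_5mc and absorbance")
  if (nrow(standards) < 3) fail("need at least 3 standards")
  if (any(standards$absorbance <= 0) ||
      any(samples$absorbance <= 0))
    fail("absorbance must be positive")
  if (length(unique(standards$absorbance)) < 3)
    fail("need at least 3 distinct standard absorbances")
  la <- log(standards$absorbance)
  fit <- stats::lm(percent_5mc ~ la + I(la^2),
                   data = data.frame(percent_5mc = standards$percent_5mc,
                                     la = la))
  mean_abs <- tapply(samples$absorbance, samples$sample_id, mean)
  lam <- log(as.numeric(mean_abs))
  pred <- stats::predict(fit, newdata = data.frame(la = lam))
  list(
    coefficients = stats::setNames(unname(stats::coef(fit)),
                                   c("a", "b", "c")),
    residuals = unname(stats::residuals(fit)),
    samples = data.frame(sample_id = names(mean_abs),
                         mean_absorbance = as.numeric(mean_abs),
                         percent_5mc = as.numeric(pred),
                         stringsAsFactors = FALSE))
}
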