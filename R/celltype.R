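#' Correlate samples against reference cell-type methylation profiles
#'
#' Pearson correlation of each sample's beta vector with each reference
#' cell-type profile over the shared marker CpGs, with a two-sided
#' p-value; each sample is labelled with the best-correlated cell type.
#' Typical references are mean methylation profiles of sorted neurons and
#' glia at their most discriminating CpGs.
#'
#' @param betas Probe x sample beta matrix.
#' @param refs Marker-CpG x cell-type matrix of reference mean betas
#'   (rownames are CpG ids, >= 2 cell types).
#' @return A data.frame with one row per sample: `sample_id`, one `r_*`
#'   and `p_*` column pair per cell type, and `label` (argmax r).
#' @export
correlate_to_reference <- function(betas, refs) {
  if (is.data.frame(refs)) refs <- as.matrix(refs)
  if (ncol(refs) < 2) fail("need at least 2 reference cell types")
  shared <- intersect(rownames(betas), rownames(refs))
  if (length(shared) < 3) fail("fewer than 3 shared marker CpGs")
  B <- betas[shared, , drop = FALSE]
  R <- refs[shared, , drop = FALSE]
  out <- data.frame(sample_id = colnames(B), stringsAsFactors = FALSE)
  rmat <- matrix(NA_real_, ncol(B), ncol(R),
                 dimnames = list(colnames(B), colnames(R)))
  for (ct in colnames(R)) {
    rs <- numeric(ncol(B)); ps <- numeric(ncol(B))
    for (j in seq_len(ncol(B))) {
      tst <- stats::cor.test(B[, j], R[, ct])
      rs[j] <- unname(tst$estimate); ps[j] <- tst$p.value
    }
    rmat[, ct] <- rs
    out[[paste0("r_", ct)]] <- rs
    out[[paste0("p_", ct)]] <- ps
  }
  out$label <- colnames(R)[max.col(rmat, ties.method = "first")]
  out
}
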