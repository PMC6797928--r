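# Shared fixtures and independent oracles for the suite.

# Minimal manifest: n probes on one chromosome, evenly spaced.
toy_manifest <- function(n, spacing = 100, chrom = "chr1",
                         region = "gene_body") {
  data.frame(
    probe_id = sprintf("cg%05d", seq_len(n)),
    chromosome = chrom,
    position = seq_len(n) * spacing,
    strand = "+",
    gene_symbol = "",
    region_category = rep_len(region, n),
    cpg_island = FALSE,
    snp_flag = FALSE,
    transcript_count = 1L,
    stringsAsFactors = FALSE
  )
}

beta_matrix <- function(values, probe_ids, sample_ids) {
  matrix(values, nrow = length(probe_ids),
         dimnames = list(probe_ids, sample_ids))
}

# Per-base oracle: coverage vector of a peak set on a toy genome,
# computed base by base (1-based positions 1..len cover 0-based [i-1, i)).
oracle_coverage <- function(peaks, chrom, len) {
  cov <- logical(len)
  sub <- peaks[peaks$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    lo <- max(0, sub$start[i]); hi <- min(len, sub$end[i])
    if (hi > lo) cov[(lo + 1):hi] <- TRUE
  }
  cov
}

# Per-base bivalent membership of probes: a base is bivalent iff covered
# by both tracks; a probe (2-bp interval [pos-1, pos+1)) overlaps iff any
# of its bases is bivalent.
oracle_bivalent_probes <- function(manifest, track_a, track_b, chrom_len) {
  hits <- character()
  for (chrom in unique(manifest$chromosome)) {
    both <- oracle_coverage(track_a, chrom, chrom_len) &
      oracle_coverage(track_b, chrom, chrom_len)
    sub <- manifest[manifest$chromosome == chrom, ]
    for (i in seq_len(nrow(sub))) {
      p <- sub$position[i]
      if (any(both[p:min(p + 1, chrom_len)])) hits <- c(hits, sub$probe_id[i])
    }
  }
  hits
}

# Contiguous runs of jointly covered bases, as 0-based half-open intervals.
oracle_bivalent_runs <- function(track_a, track_b, chrom, len) {
  both <- oracle_coverage(track_a, chrom, len) &
    oracle_coverage(track_b, chrom, len)
  r <- rle(both)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(chrom = rep(chrom, sum(keep)), start = starts[keep],
             end = ends[keep])
}

random_peaks <- function(n, len, max_width = 800) {
  start <- sample.int(len - 10, n)
  width <- sample.int(max_width, n)
  data.frame(chrom = "chr1", start = start,
             end = pmin(len, start + width), stringsAsFactors = FALSE)
}
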