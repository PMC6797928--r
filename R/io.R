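#' Read a beta-value matrix from TSV
#'
#' Expects a header row of sample ids and a first column of probe ids.
#' Empty cells and `NA` become missing values. Values are validated to lie
#' in `[0,1]`; the first offending cell is named in the error.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix, probes in rows, samples in columns.
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) fail("no such file: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) fail("beta matrix needs a probe-id column and >=1 sample")
  probe_ids <- as.character(df[[1]])
  if (anyDuplicated(probe_ids))
    fail("duplicate probe id: %s", probe_ids[duplicated(probe_ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    fail("beta value %.4g outside [0,1] at probe %s, sample %s",
         m[bad[1, 1], bad[1, 2]], probe_ids[bad[1, 1]],
         colnames(m)[bad[1, 2]])
  rownames(m) <- probe_ids
  m
}

#' Write a beta-value matrix to TSV
#'
#' @param betas Numeric matrix with probe rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(betas, path) {
  df <- data.frame(probe_id = rownames(betas), betas,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a peak set
#'
#' A peak set is a sorted data.frame of genomic intervals in 0-based
#' half-open coordinates, the convention of BED files.
#'
#' @param df Data.frame with columns `chrom`, `start`, `end`.
#' @param label Track label.
#' @return A `peak_set` data.frame sorted by (chrom, start, end).
#' @export
peak_set <- function(df, label = "") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) fail("peak set needs columns chrom/start/end")
  df <- df[need]
  if (nrow(df) > 0) {
    if (any(df$start < 0)) fail("negative interval start")
    bad <- which(df$start >= df$end)
    if (length(bad) > 0)
      fail("interval with start >= end at row %d (%s:%g-%g)", bad[1],
           df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]])
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "label") <- label
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Read a BED3 file as a peak set
#'
#' @param path Path to a tab-separated BED file (3+ columns).
#' @param label Track label to attach.
#' @return A sorted [peak_set()].
#' @export
read_bed <- function(path, label = basename(path)) {
  if (!file.exists(path)) fail("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (length(lines) == 0)
    return(peak_set(data.frame(chrom = character(), start = numeric(),
                               end = numeric()), label = label))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc < 3)) fail("BED line %d has fewer than 3 columns",
                        which(nc < 3)[1])
  chrom <- vapply(parts, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end))
    fail("non-numeric coordinate at BED line %d",
         which(is.na(start) | is.na(end))[1])
  bad <- which(start >= end)
  if (length(bad) > 0) fail("start >= end at BED line %d", bad[1])
  peak_set(data.frame(chrom = chrom, start = start, end = end,
                      stringsAsFactors = FALSE), label = label)
}

#' Write a peak set as BED3
#'
#' @param peaks A [peak_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  df <- as.data.frame(peaks)[c("chrom", "start", "end")]
  ## integer-format coordinates so read/write round-trips exactly
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a probe manifest TSV
#' @param path File path.
#' @return A manifest data.frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chromosome", "position", "region_category")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    fail("manifest missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id)) fail("duplicate probe ids in manifest")
  if (any(df$position < 1)) fail("manifest positions must be >= 1")
  df
}

#' @rdname read_manifest
#' @param manifest A manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet TSV
#' @param path File path.
#' @return A sample-sheet data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "diagnosis", "age_group")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    fail("sample sheet missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) fail("duplicate sample ids")
  df
}

#' @rdname read_sample_sheet
#' @param samples A sample-sheet data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter probes by missingness, SNP overlap and detection quality
#'
#' Removes any probe that (i) has a missing beta value in any sample,
#' (ii) is SNP-flagged in the manifest, or (iii) exceeds a detection
#' p-value of `detp_threshold` in any sample. Surviving values are passed
#' through untouched.
#'
#' @param betas Probe x sample beta matrix.
#' @param manifest Probe manifest covering every probe in `betas`.
#' @param detp Optional probe x sample matrix of detection p-values,
#'   aligned with `betas` by dimnames.
#' @param detp_threshold Detection p-value cutoff (default 0.05; probes
#'   with any p above it are dropped).
#' @return A list with `betas` (the retained matrix) and `report`: counts
#'   of removals by reason (`missing`, `snp`, `detection`; a probe can
#'   count toward several reasons), the number of distinct probes removed
#'   (`total_removed`), `n_input` and `n_retained`.
#' @export
filter_probes <- function(betas, manifest, detp = NULL,
                          detp_threshold = 0.05) {
  assert_beta_matrix(betas)
  ids <- rownames(betas)
  miss_manifest <- setdiff(ids, manifest$probe_id)
  if (length(miss_manifest) > 0)
    fail("probe absent from manifest: %s", miss_manifest[1])
  has_missing <- rowSums(is.na(betas)) > 0
  snp <- manifest$snp_flag[match(ids, manifest$probe_id)]
  snp[is.na(snp)] <- FALSE
  det_fail <- rep(FALSE, length(ids))
  if (!is.null(detp)) {
    if (!all(ids %in% rownames(detp)))
      fail("detection p matrix does not cover all probes")
    dp <- detp[ids, colnames(betas), drop = FALSE]
    det_fail <- rowSums(dp > detp_threshold, na.rm = TRUE) > 0
  }
  drop <- has_missing | snp | det_fail
  report <- list(
    n_input = length(ids),
    removed_missing = sum(has_missing),
    removed_snp = sum(snp),
    removed_detection = sum(det_fail),
    total_removed = sum(drop),
    n_retained = sum(!drop),
    detp_threshold = detp_threshold
  )
  list(betas = betas[!drop, , drop = FALSE], report = report)
}
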