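## Interval engine. Peak sets are 0-based half-open (BED convention);
## GRanges is 1-based closed, so conversion is start+1 on the way in and
## start-1 on the way out.

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
}

granges_to_peaks <- function(gr, label = "") {
  peak_set(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE), label = label)
}

## A CpG probe at 1-based position p occupies the dinucleotide interval
## [p-1, p+1) in 0-based half-open coordinates, i.e. 1-based [p, p+1].
probe_granges <- function(manifest) {
  GenomicRanges::GRanges(
    seqnames = manifest$chromosome,
    ranges = IRanges::IRanges(start = manifest$position,
                              end = manifest$position + 1))
}

#' Intersect two peak tracks
#'
#' Emits one output interval per overlapping pair of input intervals,
#' equal to their coordinate intersection (the per-pair semantics of
#' common intersect tools). Use `merge = TRUE` to collapse the result into
#' maximal non-overlapping runs; overlap membership of any locus is
#' identical either way.
#'
#' @param a,b Sorted [peak_set()] objects.
#' @param merge Collapse overlapping output fragments into merged runs.
#' @return A sorted [peak_set()] of intersections.
#' @export
intersect_tracks <- function(a, b, merge = FALSE) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(peak_set(data.frame(chrom = character(), start = numeric(),
                               end = numeric()), label = "intersection"))
  ga <- peaks_to_granges(a)
  gb <- peaks_to_granges(b)
  hits <- GenomicRanges::findOverlaps(ga, gb)
  frag <- GenomicRanges::pintersect(ga[S4Vectors::queryHits(hits)],
                                    gb[S4Vectors::subjectHits(hits)])
  if (merge) frag <- GenomicRanges::reduce(frag)
  granges_to_peaks(frag, label = "intersection")
}

#' Merge overlapping or touching intervals of a peak set
#'
#' @param peaks A [peak_set()].
#' @return A [peak_set()] of maximal disjoint runs.
#' @export
merge_peaks <- function(peaks) {
  if (nrow(peaks) == 0) return(peaks)
  granges_to_peaks(GenomicRanges::reduce(peaks_to_granges(peaks)),
                   label = attr(peaks, "label"))
}

#' Count probes overlapping a peak set
#'
#' A probe counts as overlapping when its 2-bp CpG interval
#' `[position - 1, position + 1)` shares at least one base with any peak.
#' The percent is reported to one decimal (round half to even).
#'
#' @param probes Subset of a probe manifest (non-empty).
#' @param peaks A [peak_set()].
#' @return List with `probe_ids` (overlapping ids), `count`, and
#'   `percent` of the subset.
#' @export
probes_in_peaks <- function(probes, peaks) {
  if (nrow(probes) == 0) fail("empty probe subset: percent undefined")
  if (nrow(peaks) == 0)
    return(list(probe_ids = character(), count = 0L,
                percent = percent_1dp(0, nrow(probes))))
  gp <- probe_granges(probes)
  ## suppress the benign "no sequence levels in common" note when the
  ## peak set lives on other chromosomes entirely
  hit <- suppressWarnings(
    GenomicRanges::countOverlaps(gp, peaks_to_granges(peaks))) > 0
  list(probe_ids = probes$probe_id[hit], count = sum(hit),
       percent = percent_1dp(sum(hit), nrow(probes)))
}
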