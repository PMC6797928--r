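#' Enrichment of DML among developmentally dynamic CpGs
#'
#' Fold enrichment of a DML set in the set of CpGs whose methylation
#' changes during fetal brain development, relative to all retained array
#' probes.
#'
#' @param dml_ids Character vector of DML probe ids (typically the union
#'   across age-group comparisons).
#' @param dynamic_ids Ids of developmentally dynamic CpGs.
#' @param background_ids All retained probe ids.
#' @return An `enrichment_result` (see [fold_enrichment()]).
#' @export
dynamic_overlap <- function(dml_ids, dynamic_ids, background_ids) {
  if (length(background_ids) == 0) fail("empty background")
  fold_enrichment(
    n_in_subset = length(intersect(dml_ids, dynamic_ids)),
    n_subset = length(dml_ids),
    n_in_background = length(intersect(background_ids, dynamic_ids)),
    n_background = length(background_ids))
}

#' Define epigenetically dynamic regions (EDRs)
#'
#' An EDR probe lies inside a bivalent chromatin domain (both activating
#' and repressive histone marks) and is developmentally dynamic in fetal
#' brain. The definition is a plain set intersection, with provenance
#' labels retained.
#'
#' @param bivalent_probe_ids Ids inside the intersected peak tracks.
#' @param dynamic_probe_ids Ids of developmentally dynamic CpGs.
#' @param bivalent_source,dynamic_source Free-text provenance labels.
#' @return An `edr_set`: list with sorted `probe_ids` and `provenance`.
#' @export
define_edr <- function(bivalent_probe_ids, dynamic_probe_ids,
                       bivalent_source = "", dynamic_source = "") {
  structure(list(
    probe_ids = sort(intersect(unique(bivalent_probe_ids),
                               unique(dynamic_probe_ids))),
    provenance = list(bivalent = bivalent_source, dynamic = dynamic_source)),
    class = "edr_set")
}

#' Enrichment of DML inside EDRs
#'
#' Fold of DML-in-EDR over the background EDR rate, delegating the
#' arithmetic to [fold_enrichment()] (observed and expected counts are
#' reported in the result).
#'
#' @param dml_ids DML probe ids (union across comparisons by default in
#'   the pipeline; any id set is accepted).
#' @param edr An `edr_set` from [define_edr()].
#' @param background_ids All retained probe ids.
#' @return An `enrichment_result`.
#' @export
edr_enrichment <- function(dml_ids, edr, background_ids) {
  stopifnot(inherits(edr, "edr_set"))
  if (length(edr$probe_ids) == 0)
    fail("empty EDR set: background fraction undefined")
  fold_enrichment(
    n_in_subset = length(intersect(dml_ids, edr$probe_ids)),
    n_subset = length(dml_ids),
    n_in_background = length(intersect(background_ids, edr$probe_ids)),
    n_background = length(background_ids))
}
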