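# Reference tables for the October 2009 GOA corpora: the published corpus
# sizes and power-law fit results for five species (Hs, Mm, Dr, Sc, Rn)
# across the three sub-ontologies, and for the human/mouse corpora split by
# evidence-code class. Reproducing these fits needs the 2009 GOA/GO
# snapshot, which is not redistributable here; the tables serve as inputs
# for the cross-corpus comparison operations and as regression anchors.

#' Corpus sizes of the October 2009 GOA datasets
#'
#' Total annotation counts and distinct GO id counts per species and
#' sub-ontology, as reported for the October 2009 GOA release.
#'
#' @return A tibble: `source` (species code), `aspect`, `total_annotations`,
#'   `distinct_go_ids`.
#' @export
goa_oct2009_summary <- function() {
  tibble::tribble(
    ~source, ~aspect, ~total_annotations, ~distinct_go_ids,
    "Hs", "CC", 51640L,  889L,
    "Hs", "MF", 55781L, 2844L,
    "Hs", "BP", 58320L, 5259L,
    "Mm", "CC", 45933L,  641L,
    "Mm", "MF", 60919L, 2318L,
    "Mm", "BP", 59133L, 4239L,
    "Dr", "CC", 23179L,  304L,
    "Dr", "MF", 47651L, 1187L,
    "Dr", "BP", 34158L, 1513L,
    "Sc", "CC", 29563L,  626L,
    "Sc", "MF", 26292L, 1611L,
    "Sc", "BP", 31797L, 1963L,
    "Rn", "CC", 53342L,   50L,
    "Rn", "MF", 63050L, 2776L,
    "Rn", "BP", 74943L, 5411L
  )
}

#' Corpus sizes of the evidence-stratified 2009 GOA datasets
#'
#' Human and mouse corpora split into high-confidence (HC) and
#' low-confidence (LC, electronic-only) evidence classes.
#'
#' @return A tibble: `source`, `aspect`, `evidence_class`,
#'   `total_annotations`, `distinct_go_ids`.
#' @export
goa_oct2009_evidence_summary <- function() {
  tibble::tribble(
    ~source, ~aspect, ~evidence_class, ~total_annotations, ~distinct_go_ids,
    "Hs", "CC", "HC", 16744L,  642L,
    "Hs", "MF", "HC", 20250L, 1974L,
    "Hs", "BP", "HC", 18594L, 3172L,
    "Mm", "CC", "HC", 11784L,  487L,
    "Mm", "MF", "HC", 10467L, 1364L,
    "Mm", "BP", "HC", 26478L, 3846L,
    "Hs", "CC", "LC", 31164L,  572L,
    "Hs", "MF", "LC", 31709L, 1735L,
    "Hs", "BP", "LC", 33820L, 3642L,
    "Mm", "CC", "LC", 28918L,  232L,
    "Mm", "MF", "LC", 45185L, 1320L,
    "Mm", "BP", "LC", 26473L,  731L
  )
}

#' Power-law exponents fitted to the 2009 GOA corpora
#'
#' The exponent `beta` and bootstrap goodness-of-fit p-value reported for
#' each species and sub-ontology of the October 2009 GOA release.
#'
#' @return A tibble: `source`, `aspect`, `beta`, `p_value`.
#' @examples
#' group_mean_beta(goa_oct2009_fits(), "BP")
#' @export
goa_oct2009_fits <- function() {
  tibble::tribble(
    ~source, ~aspect, ~beta, ~p_value,
    "Hs", "CC", 1.73, 0.63,
    "Hs", "MF", 1.83, 0.55,
    "Hs", "BP", 2.04, 0.65,
    "Mm", "CC", 1.69, 0.74,
    "Mm", "MF", 1.76, 0.36,
    "Mm", "BP", 2.08, 0.97,
    "Dr", "CC", 1.62, 0.74,
    "Dr", "MF", 1.69, 0.91,
    "Dr", "BP", 1.88, 0.11,
    "Sc", "CC", 1.86, 0.29,
    "Sc", "MF", 1.88, 0.78,
    "Sc", "BP", 2.27, 0.42,
    "Rn", "CC", 1.68, 0.24,
    "Rn", "MF", 1.91, 0.85,
    "Rn", "BP", 2.38, 0.76
  )
}

#' Power-law exponents for the evidence-stratified 2009 GOA corpora
#'
#' Fitted exponents and p-values for the human and mouse corpora split by
#' evidence class. Within every species and sub-ontology the HC exponent
#' exceeds the LC one.
#'
#' @return A tibble: `source`, `aspect`, `evidence_class`, `beta`,
#'   `p_value`.
#' @export
goa_oct2009_evidence_fits <- function() {
  tibble::tribble(
    ~source, ~aspect, ~evidence_class, ~beta, ~p_value,
    "Hs", "CC", "HC", 1.88, 0.37,
    "Hs", "MF", "HC", 2.05, 0.18,
    "Hs", "BP", "HC", 2.12, 0.37,
    "Mm", "CC", "HC", 1.90, 0.43,
    "Mm", "MF", "HC", 2.15, 0.65,
    "Mm", "BP", "HC", 2.60, 0.61,
    "Hs", "CC", "LC", 1.62, 0.11,
    "Hs", "MF", "LC", 1.75, 0.16,
    "Hs", "BP", "LC", 2.04, 0.62,
    "Mm", "CC", "LC", 1.50, 0.71,
    "Mm", "MF", "LC", 1.67, 0.03,
    "Mm", "BP", "LC", 1.62, 0.00
  )
}
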