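hc_codes <- c("IDA", "IPI", "IMP", "TAS", "EXP", "IC", "IEP", "IGI")
lc_codes <- "IEA"

aspect_labels <- c(F = "MF", P = "BP", C = "CC",
                   MF = "MF", BP = "BP", CC = "CC")

normalize_aspect <- function(aspect) {
  aspect <- toupper(aspect)
  if (length(aspect) != 1 || !aspect %in% names(aspect_labels)) {
    stop_gozipf("`aspect` must be one of F/P/C (or MF/BP/CC).",
                "gozipf_error_domain")
  }
  unname(aspect_labels[aspect])
}

#' Evidence-code classes
#'
#' The evidence-code sets used to stratify corpora by annotation support:
#' `"HC"` (high confidence — experimentally or curator supported: IDA, IPI,
#' IMP, TAS, EXP, IC, IEP, IGI), `"LC"` (low confidence — electronic only:
#' IEA), and `"ALL"` (no filter). A custom class is any character vector of
#' evidence codes.
#'
#' @param class `"ALL"`, `"HC"`, `"LC"`, or a character vector of evidence
#'   codes (treated as a custom class).
#'
#' @return A character vector of evidence codes, with attribute `label`;
#'   `"ALL"` returns `NULL` (meaning: keep everything), also labelled.
#' @examples
#' evidence_codes("HC")
#' @export
evidence_codes <- function(class = c("ALL", "HC", "LC")) {
  if (identical(class, c("ALL", "HC", "LC"))) class <- "ALL"
  if (length(class) == 1 && toupper(class) %in% c("ALL", "HC", "LC")) {
    return(switch(toupper(class),
      ALL = NULL,
      HC = structure(hc_codes, label = "HC"),
      LC = structure(lc_codes, label = "LC")
    ))
  }
  structure(toupper(class), label = "CUSTOM")
}

evidence_label <- function(evidence) {
  if (is.character(evidence) && length(evidence) == 1 &&
      evidence %in% c("ALL", "HC", "LC")) {
    return(evidence)
  }
  attr(evidence, "label") %||% "CUSTOM"
}

#' Build a stratified annotation corpus
#'
#' Filters an annotation tibble to one sub-ontology and one evidence-code
#' class, and returns the surviving annotations as a token corpus: one row
#' (token) per annotation line, the token being the GO id. This is the
#' "text" whose term-frequency statistics the rest of the package analyses.
#'
#' @param annotations Annotation tibble from [read_gaf()] or
#'   [generate_corpus()].
#' @param aspect Sub-ontology: `"F"`/`"MF"`, `"P"`/`"BP"` or `"C"`/`"CC"`.
#' @param evidence `"ALL"`, `"HC"`, `"LC"`, or a character vector of
#'   evidence codes ([evidence_codes()]).
#' @param exclude_negated Drop annotations whose qualifier contains `NOT`
#'   (default `TRUE`).
#' @param dedupe Collapse repeated (gene product, GO term) pairs to a single
#'   token after filtering (default `FALSE`: each annotation line is one
#'   token, so a pair supported by two evidence codes counts twice, matching
#'   how annotation totals are usually reported).
#' @param ontology Optional `go_ontology`; when given, alternate GO ids are
#'   resolved to primary ids before counting.
#' @param source_label Label carried into summaries (e.g. a species code).
#'
#' @return A `go_corpus`: a tibble with column `term` (one row per token)
#'   and attributes `aspect` (`"MF"`/`"BP"`/`"CC"`), `evidence_class` and
#'   `source_label`.
#' @export
build_corpus <- function(annotations, aspect, evidence = "ALL",
                         exclude_negated = TRUE, dedupe = FALSE,
                         ontology = NULL, source_label = "corpus") {
  asp <- normalize_aspect(aspect)
  codes <- if (is.character(evidence) && length(evidence) == 1 &&
               evidence %in% c("ALL", "HC", "LC")) {
    evidence_codes(evidence)
  } else {
    evidence
  }
  label <- evidence_label(codes %||% evidence)
  keep <- aspect_labels[annotations$aspect] == asp
  if (!is.null(codes)) keep <- keep & annotations$evidence_code %in% codes
  if (exclude_negated && "negated" %in% names(annotations)) {
    keep <- keep & !annotations$negated
  }
  surv <- annotations[keep, , drop = FALSE]
  if (dedupe) {
    surv <- dplyr::distinct(surv, .data$db_object_id, .data$go_id,
                            .keep_all = TRUE)
  }
  if (nrow(surv) == 0) {
    stop_gozipf(
      sprintf("No annotations survive the %s/%s filter; fitting is undefined on an empty corpus.",
              asp, label),
      "gozipf_error_empty_corpus"
    )
  }
  term <- surv$go_id
  if (!is.null(ontology)) term <- resolve_go_ids(ontology, term)
  structure(
    tibble(term = term),
    aspect = asp, evidence_class = label, source_label = source_label,
    class = c("go_corpus", class(tibble())))
}

#' Term-frequency table of a corpus
#'
#' Counts each distinct term and ranks terms by descending frequency, ties
#' broken by lexicographic term id so ranks are deterministic.
#'
#' @param corpus A `go_corpus` from [build_corpus()], or any tibble with a
#'   `term` column.
#'
#' @return A tibble with columns `term`, `freq` and `rank` (1 = most
#'   frequent); frequencies sum to the corpus token count.
#' @examples
#' corp <- tibble::tibble(term = c("A", "A", "A", "B", "B", "C"))
#' term_frequencies(corp)
#' @export
term_frequencies <- function(corpus) {
  stopifnot("term" %in% names(corpus))
  if (nrow(corpus) == 0) {
    stop_gozipf("Corpus is empty.", "gozipf_error_empty_corpus")
  }
  out <- corpus |>
    dplyr::count(.data$term, name = "freq") |>
    dplyr::arrange(dplyr::desc(.data$freq), .data$term) |>
    dplyr::mutate(rank = dplyr::row_number())
  for (a in c("aspect", "evidence_class", "source_label")) {
    attr(out, a) <- attr(corpus, a)
  }
  out
}

#' Summarise corpora: totals and distinct-term counts
#'
#' One row per corpus, the shape in which annotation corpora are
#' conventionally characterised (total annotations and distinct GO ids per
#' species, sub-ontology and evidence class).
#'
#' @param corpora A `go_corpus` or a list of them.
#'
#' @return A tibble with columns `source`, `aspect`, `evidence_class`,
#'   `total_annotations`, `distinct_go_ids`.
#' @export
corpus_summary <- function(corpora) {
  if (inherits(corpora, "go_corpus")) corpora <- list(corpora)
  purrr::map_dfr(corpora, function(corp) {
    tibble(
      source = attr(corp, "source_label") %||% "corpus",
      aspect = attr(corp, "aspect") %||% NA_character_,
      evidence_class = attr(corp, "evidence_class") %||% NA_character_,
      total_annotations = nrow(corp),
      distinct_go_ids = dplyr::n_distinct(corp$term)
    )
  })
}

#' Write a corpus summary as TSV
#'
#' @param summary A tibble from [corpus_summary()].
#' @param file Output path.
#' @return Invisibly, `summary`.
#' @export
write_summary_tsv <- function(summary, file) {
  cols <- c("source", "aspect", "evidence_class", "total_annotations",
            "distinct_go_ids")
  readr::write_tsv(summary[, cols], file)
  invisible(summary)
}
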