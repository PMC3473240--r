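#' Depth of terms in the ontology
#'
#' Depth is the length of the shortest `is_a` path from a term to the root
#' of its namespace (the root itself has depth 0). Shallow terms are
#' generic ("cell"), deep terms specific ("integrin complex"); the depth of
#' the terms an annotation corpus uses is therefore a proxy for how specific
#' the annotation is.
#'
#' @param ontology A `go_ontology` from [read_obo()].
#' @param terms Character vector of GO ids (alternate ids are resolved).
#'
#' @return A non-negative integer vector of depths, same length as `terms`.
#' @export
term_depth <- function(ontology, terms) {
  stopifnot(inherits(ontology, "go_ontology"))
  terms <- resolve_go_ids(ontology, terms)
  if (any(terms %in% ontology$obsolete)) {
    stop_gozipf(
      sprintf("Obsolete term(s): %s.",
              paste(head(intersect(terms, ontology$obsolete), 3), collapse = ", ")),
      "gozipf_error_obsolete_term"
    )
  }
  unknown <- setdiff(terms, ontology$terms)
  if (length(unknown)) {
    stop_gozipf(
      sprintf("Unknown term(s): %s.", paste(head(unknown, 3), collapse = ", ")),
      "gozipf_error_unknown_term"
    )
  }
  d <- ontology$depth[terms]
  if (any(is.na(d))) {
    stop_gozipf(
      "Some terms have no namespace (or are unreachable from their root) and are excluded from depth queries.",
      "gozipf_error_no_depth"
    )
  }
  unname(d)
}

#' Compare ontology depth of frequent versus rare terms
#'
#' Splits the distinct terms of a frequency table into the top and bottom
#' quartiles by usage frequency (quartile size `floor(n/4)` distinct terms;
#' frequency ties resolved by the table's deterministic rank order) and
#' reports the mean ontology depth of each. If commonly used terms are more
#' generic, the top-quartile mean is the smaller.
#'
#' @param freq_table Frequency table from [term_frequencies()].
#' @param ontology A `go_ontology` from [read_obo()].
#' @param corpus_label Label for reporting; defaults to the table's source
#'   label.
#'
#' @return A one-row tibble: `corpus_label`, `n_top`, `mean_depth_top`,
#'   `n_bottom`, `mean_depth_bottom`.
#' @export
quartile_depth_comparison <- function(freq_table, ontology,
                                      corpus_label = NULL) {
  n <- nrow(freq_table)
  if (n < 4) {
    stop_gozipf("Need at least 4 distinct terms for a quartile split.",
                "gozipf_error_too_few_terms")
  }
  corpus_label <- corpus_label %||% attr(freq_table, "source_label") %||% "corpus"
  ord <- dplyr::arrange(freq_table, .data$rank)
  k <- floor(n / 4)
  top <- ord$term[seq_len(k)]
  bottom <- ord$term[seq.int(n - k + 1, n)]
  tibble(
    corpus_label = corpus_label,
    n_top = k,
    mean_depth_top = mean(term_depth(ontology, top)),
    n_bottom = k,
    mean_depth_bottom = mean(term_depth(ontology, bottom))
  )
}

#' Paired test for the depth difference across corpora
#'
#' Takes one (top-quartile, bottom-quartile) mean-depth pair per corpus and
#' runs a paired t-test on the pairs, asking whether frequently used terms
#' sit systematically shallower than rarely used ones across corpora.
#'
#' @param comparisons A tibble of rows from [quartile_depth_comparison()]
#'   (at least 2).
#' @param alternative `"two.sided"` (default), `"less"` (top shallower) or
#'   `"greater"`.
#'
#' @return A one-row tibble: `t`, `df`, `p_value`, `mean_difference`
#'   (top minus bottom), `alternative`.
#' @export
depth_significance <- function(comparisons, alternative = "two.sided") {
  if (nrow(comparisons) < 2) {
    stop_gozipf("Need at least 2 corpora.", "gozipf_error_too_few_pairs")
  }
  paired_t_test(comparisons$mean_depth_top, comparisons$mean_depth_bottom,
                alternative = alternative)
}

#' Write depth comparisons as TSV
#'
#' @param comparisons Tibble of [quartile_depth_comparison()] rows.
#' @param file Output path.
#' @return Invisibly, `comparisons`.
#' @export
write_depth_tsv <- function(comparisons, file) {
  cols <- c("corpus_label", "n_top", "mean_depth_top", "n_bottom",
            "mean_depth_bottom")
  readr::write_tsv(comparisons[, cols], file)
  invisible(comparisons)
}
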