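#' Mean fitted exponent for one sub-ontology
#'
#' Arithmetic mean of `beta` over the exponent records matching `aspect`.
#'
#' @param records Tibble of exponent records: columns `aspect` and `beta`
#'   (e.g. [goa_oct2009_fits()] or rows assembled from [glance()]d fits).
#' @param aspect `"MF"`, `"BP"` or `"CC"` (GAF letters accepted).
#'
#' @return A single number.
#' @examples
#' group_mean_beta(goa_oct2009_fits(), "BP")
#' @export
group_mean_beta <- function(records, aspect) {
  asp <- normalize_aspect(aspect)
  beta <- records$beta[aspect_labels[records$aspect] == asp]
  if (length(beta) == 0) {
    stop_gozipf(sprintf("No records for aspect %s.", asp),
                "gozipf_error_empty_input")
  }
  mean(beta)
}

#' Paired t-test on matched exponent (or depth) pairs
#'
#' The standard paired t statistic \eqn{t = \bar d / (s_d / \sqrt n)} on the
#' differences `x - y`, with `n - 1` degrees of freedom. Used to compare
#' high- against low-confidence exponents across matched corpora, and
#' top- against bottom-quartile depths.
#'
#' @param x,y Numeric vectors of equal length (>= 2), matched by position.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#'
#' @return A one-row tibble: `t`, `df`, `p_value`, `mean_difference`,
#'   `alternative`.
#' @examples
#' t4 <- goa_oct2009_evidence_fits()
#' paired_t_test(t4$beta[t4$evidence_class == "HC"],
#'               t4$beta[t4$evidence_class == "LC"],
#'               alternative = "greater")
#' @export
paired_t_test <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  if (length(x) < 2) {
    stop_gozipf("Need at least 2 pairs.", "gozipf_error_too_few_pairs")
  }
  d <- x - y
  if (stats::sd(d) == 0) {
    stop_gozipf(
      "Differences have zero variance; the paired t statistic is undefined.",
      "gozipf_error_degenerate"
    )
  }
  ht <- t.test(x, y, paired = TRUE, alternative = alternative)
  tibble(
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_difference = unname(ht$estimate),
    alternative = alternative
  )
}

#' Association between corpus size and fitted exponent
#'
#' Spearman rank correlations of `beta` with the number of distinct terms
#' and with the total annotation count, plus the scatter data behind them.
#' A near-zero correlation says the exponent is not an artefact of corpus
#' size. If `beta` is constant the correlation is reported as 0 (no
#' association).
#'
#' @param records Tibble with columns `beta`, `n_distinct`, `n_total`
#'   (>= 3 rows).
#'
#' @return A list with `correlations` (tibble: `measure`, `rho`) and `data`
#'   (the scatter tibble).
#' @export
size_exponent_association <- function(records) {
  if (nrow(records) < 3) {
    stop_gozipf("Need at least 3 records.", "gozipf_error_too_few_records")
  }
  rho_of <- function(size) {
    if (stats::sd(records$beta) == 0 || stats::sd(size) == 0) return(0)
    cor(records$beta, size, method = "spearman")
  }
  list(
    correlations = tibble(
      measure = c("n_distinct", "n_total"),
      rho = c(rho_of(records$n_distinct), rho_of(records$n_total))
    ),
    data = tibble(
      beta = records$beta,
      n_distinct = records$n_distinct,
      n_total = records$n_total
    )
  )
}
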