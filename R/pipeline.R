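#' Configuration for a full corpus analysis run
#'
#' @param gaf Path to a GAF file (or a character vector of GAF lines), or
#'   `NULL` when `spec` is given.
#' @param obo Optional path to an OBO file (or lines); required for the
#'   depth analysis stage.
#' @param spec A [corpus_spec()] (or list of them) to analyse a synthetic
#'   corpus instead of files.
#' @param aspects Sub-ontologies to analyse (GAF letters).
#' @param evidence Evidence classes to analyse (subset of
#'   `c("ALL", "HC", "LC")`).
#' @param n_bootstrap Bootstrap replicates for each goodness-of-fit test
#'   (0 skips the test).
#' @param min_tail Minimum tail size for cutoff candidates.
#' @param exclude_negated Drop NOT-qualified annotations (default `TRUE`).
#' @param seed Integer seed recorded in, and governing, every output.
#' @param source_label Label for file-based corpora.
#' @param out_dir Optional directory; when set, [run_pipeline()] writes all
#'   result tables there via [render_tables()].
#'
#' @return A `run_config` object (a validated list).
#' @export
run_config <- function(gaf = NULL, obo = NULL, spec = NULL,
                       aspects = c("P", "F", "C"), evidence = "ALL",
                       n_bootstrap = 200, min_tail = 10,
                       exclude_negated = TRUE, seed = 1L,
                       source_label = "corpus", out_dir = NULL) {
  if (is.null(gaf) && is.null(spec)) {
    stop_gozipf("Provide `gaf` input or a synthetic `spec`.",
                "gozipf_error_config")
  }
  if (inherits(spec, "corpus_spec")) spec <- list(spec)
  structure(
    list(gaf = gaf, obo = obo, spec = spec,
         aspects = vapply(aspects, normalize_aspect, character(1)),
         evidence = evidence, n_bootstrap = n_bootstrap, min_tail = min_tail,
         exclude_negated = exclude_negated, seed = as.integer(seed),
         source_label = source_label, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full Zipf's-law analysis pipeline
#'
#' Builds the requested corpora (from GAF input or synthetic specs), fits a
#' discrete power law with bootstrap goodness-of-fit to each, summarises
#' corpus sizes, runs the depth analysis when an ontology is available, and
#' aggregates exponents across corpora (sub-ontology means, HC-vs-LC paired
#' test when both classes were fitted, size association when three or more
#' fits exist). Corpora that come out empty after filtering are reported
#' and skipped; the run continues. Deterministic given the config.
#'
#' @param config A [run_config()].
#'
#' @return A `zipf_run` list: `summary` (corpus sizes), `fits` (tibble, one
#'   row per fitted corpus), `ccdf` (named list of CCDF tibbles), `depth`
#'   (quartile depth comparisons, or `NULL`), `depth_test`, `comparison`
#'   (list: `aspect_means`, `hc_lc`, `size_association`), `skipped`
#'   (character vector), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ontology <- NULL
  if (!is.null(config$obo)) ontology <- read_obo(config$obo)
  sources <- list()
  if (!is.null(config$spec)) {
    for (sp in config$spec) {
      sim <- generate_corpus(sp)
      lab <- sprintf("synthetic_beta%.2f_seed%d", sp$beta_true, sp$seed)
      sources[[lab]] <- list(annotations = sim$annotations,
                             ontology = sim$ontology %||% ontology)
    }
  }
  if (!is.null(config$gaf)) {
    sources[[config$source_label]] <- list(annotations = read_gaf(config$gaf),
                                           ontology = ontology)
  }
  corpora <- list()
  skipped <- character(0)
  for (lab in names(sources)) {
    for (asp in config$aspects) {
      for (ev in config$evidence) {
        key <- paste(lab, asp, ev, sep = "/")
        corp <- tryCatch(
          build_corpus(sources[[lab]]$annotations, asp, ev,
                       exclude_negated = config$exclude_negated,
                       ontology = sources[[lab]]$ontology,
                       source_label = lab),
          gozipf_error_empty_corpus = function(e) NULL
        )
        if (is.null(corp)) skipped <- c(skipped, key) else corpora[[key]] <- corp
      }
    }
  }
  if (length(corpora) == 0) {
    stop_gozipf("Every requested corpus is empty after filtering.",
                "gozipf_error_empty_corpus")
  }
  summary_tbl <- corpus_summary(corpora)
  fits <- list()
  ccdfs <- list()
  depth_rows <- list()
  for (key in names(corpora)) {
    corp <- corpora[[key]]
    ft <- term_frequencies(corp)
    ccdfs[[key]] <- ccdf(ft$freq)
    fit <- tryCatch(
      fit_power_law(ft$freq, min_tail = config$min_tail,
                    n_bootstrap = config$n_bootstrap,
                    seed = config$seed),
      gozipf_error = function(e) NULL
    )
    if (is.null(fit)) { # too few distinct frequencies to fit a tail
      skipped <- c(skipped, key)
      next
    }
    fits[[key]] <- dplyr::bind_cols(
      tibble(corpus = key,
             source = attr(corp, "source_label"),
             aspect = attr(corp, "aspect"),
             evidence_class = attr(corp, "evidence_class"),
             total_annotations = nrow(corp),
             distinct_terms = nrow(ft)),
      glance(fit)
    )
    ont <- sources[[attr(corp, "source_label")]]$ontology
    if (!is.null(ont) && nrow(ft) >= 4 &&
        all(resolve_go_ids(ont, ft$term) %in% ont$terms)) {
      depth_rows[[key]] <- quartile_depth_comparison(ft, ont,
                                                     corpus_label = key)
    }
  }
  fits <- dplyr::bind_rows(fits)
  if (nrow(fits) == 0) {
    stop_gozipf("No corpus had enough distinct frequencies to fit.",
                "gozipf_error_no_candidates")
  }
  depth_tbl <- if (length(depth_rows)) dplyr::bind_rows(depth_rows) else NULL
  depth_test <- if (!is.null(depth_tbl) && nrow(depth_tbl) >= 2 &&
                    stats::sd(depth_tbl$mean_depth_top -
                              depth_tbl$mean_depth_bottom) > 0) {
    depth_significance(depth_tbl)
  }
  comparison <- list(
    aspect_means = fits |>
      dplyr::group_by(.data$aspect) |>
      dplyr::summarise(mean_beta = mean(.data$beta), n_corpora = dplyr::n()),
    hc_lc = NULL,
    size_association = NULL
  )
  hc <- fits[fits$evidence_class == "HC", ]
  lc <- fits[fits$evidence_class == "LC", ]
  if (nrow(hc) >= 2 && nrow(lc) >= 2) {
    key_of <- function(d) paste(d$source, d$aspect)
    common <- intersect(key_of(hc), key_of(lc))
    if (length(common) >= 2) {
      x <- hc$beta[match(common, key_of(hc))]
      y <- lc$beta[match(common, key_of(lc))]
      if (stats::sd(x - y) > 0) comparison$hc_lc <- paired_t_test(x, y)
    }
  }
  if (nrow(fits) >= 3) {
    comparison$size_association <- size_exponent_association(
      tibble(beta = fits$beta, n_distinct = fits$distinct_terms,
             n_total = fits$total_annotations)
    )
  }
  result <- structure(
    list(summary = summary_tbl, fits = fits, ccdf = ccdfs,
         depth = depth_tbl, depth_test = depth_test,
         comparison = comparison, skipped = skipped, config = config),
    class = "zipf_run"
  )
  if (!is.null(config$out_dir)) render_tables(result, config$out_dir)
  result
}

#' Write a pipeline result bundle to disk
#'
#' Emits the corpus summary (TSV), the fit table (TSV with `beta` and
#' `p_value` rounded to 2 decimals, plus a JSON report at full precision),
#' the depth table (TSV), the comparison summary (JSON) and one two-column
#' CCDF TSV per corpus for log-log plotting. The seed is recorded in every
#' JSON artifact.
#'
#' @param results A `zipf_run` from [run_pipeline()].
#' @param out_dir Directory to write into (created if missing).
#'
#' @return Invisibly, the vector of files written.
#' @export
render_tables <- function(results, out_dir) {
  stopifnot(inherits(results, "zipf_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  path <- function(name) file.path(out_dir, name)
  write_summary_tsv(results$summary, path("summary.tsv"))
  files <- c(files, path("summary.tsv"))
  fit_tsv <- results$fits |>
    dplyr::transmute(.data$corpus, .data$source, .data$aspect,
                     .data$evidence_class,
                     beta = sprintf("%.2f", .data$beta),
                     p_value = ifelse(is.na(.data$p_value), "NA",
                                      sprintf("%.2f", .data$p_value)))
  readr::write_tsv(fit_tsv, path("fits.tsv"))
  files <- c(files, path("fits.tsv"))
  jsonlite::write_json(
    c(list(seed = results$config$seed), list(fits = results$fits)),
    path("fits.json"), auto_unbox = TRUE, digits = NA, null = "null"
  )
  files <- c(files, path("fits.json"))
  if (!is.null(results$depth)) {
    write_depth_tsv(results$depth, path("depth.tsv"))
    files <- c(files, path("depth.tsv"))
  }
  comparison <- list(
    seed = results$config$seed,
    aspect_means = results$comparison$aspect_means,
    hc_lc = results$comparison$hc_lc,
    size_association = results$comparison$size_association$correlations,
    depth_test = results$depth_test
  )
  jsonlite::write_json(comparison, path("comparison.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, path("comparison.json"))
  for (key in names(results$ccdf)) {
    f <- path(paste0("ccdf_", gsub("[^A-Za-z0-9._-]", "_", key), ".tsv"))
    readr::write_tsv(results$ccdf[[key]], f)
    files <- c(files, f)
  }
  invisible(files)
}

#' @export
print.zipf_run <- function(x, ...) {
  cat(sprintf("Zipf's-law analysis run (seed %d): %d corpora fitted, %d skipped\n",
              x$config$seed, nrow(x$fits), length(x$skipped)))
  print(x$fits[, c("corpus", "n", "n_tail", "xmin", "beta", "ks_distance",
                   "p_value", "plausible")])
  invisible(x)
}
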