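go_id_pattern <- "^GO:\\d{7}$"
gaf_aspects <- c("F", "P", "C")

#' Read a GAF 2.x gene-association file
#'
#' Parses tab-delimited GAF text into one annotation row per association.
#' Comment lines (starting with `!`) and blank lines are skipped. Lines with
#' fewer than 15 columns, a malformed GO identifier, an unknown aspect
#' letter, or an empty evidence code are skipped with a single summary
#' warning — annotation corpora are dirty and a bad line should not abort a
#' run.
#'
#' @param file Path to a GAF file, or a character vector of GAF lines.
#'
#' @return A tibble of annotations with columns `db`, `db_object_id`,
#'   `go_id`, `qualifier` (list column of character vectors), `negated`
#'   (logical: qualifier contains `NOT`), `aspect` (`"F"`, `"P"` or `"C"`),
#'   `evidence_code` and `taxon`. The number of skipped lines is attached as
#'   attribute `n_skipped`.
#' @examples
#' lines <- c("!gaf-version: 2.0",
#'            paste("UniProtKB", "P05556", "ITGB1", "", "GO:0008305",
#'                  "PMID:1", "IDA", "", "C", "", "", "protein",
#'                  "taxon:9606", "20090101", "UniProt", "", "",
#'                  sep = "\t"))
#' read_gaf(lines)
#' @export
read_gaf <- function(file) {
  is_path <- length(file) == 1 && !grepl("[\t\n!]", file)
  if (is_path && !file.exists(file)) {
    stop_gozipf(sprintf("File not found: %s", file), "gozipf_error_io")
  }
  lines <- if (is_path) readLines(file) else file
  lines <- lines[!startsWith(lines, "!") & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_cols <- lengths(fields)
  short <- n_cols < 15
  n_short <- sum(short)
  fields <- fields[!short]
  if (length(fields) == 0) {
    stop_gozipf("No parseable annotation lines in input.",
                "gozipf_error_empty_input")
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  go_id <- col(5)
  aspect <- col(9)
  evidence <- toupper(trimws(col(7)))
  qualifier_raw <- col(4)
  ok_go <- grepl(go_id_pattern, go_id)
  ok_aspect <- aspect %in% gaf_aspects
  ok_ev <- nzchar(evidence)
  ok <- ok_go & ok_aspect & ok_ev
  n_bad <- sum(!ok)
  if (n_short + n_bad > 0) {
    warn_gozipf(
      sprintf(
        "Skipped %d malformed line(s): %d with < 15 columns, %d with a bad GO id, unknown aspect or empty evidence code.",
        n_short + n_bad, n_short, n_bad
      ),
      "gozipf_warning_malformed_lines"
    )
  }
  if (!any(ok)) {
    stop_gozipf("No parseable annotation lines in input.",
                "gozipf_error_empty_input")
  }
  qualifier <- ifelse(nzchar(qualifier_raw), qualifier_raw, NA_character_)
  out <- tibble(
    db = col(1)[ok],
    db_object_id = col(2)[ok],
    go_id = go_id[ok],
    qualifier = lapply(qualifier[ok], function(q) {
      if (is.na(q)) character(0) else strsplit(q, "|", fixed = TRUE)[[1]]
    }),
    aspect = aspect[ok],
    evidence_code = evidence[ok],
    taxon = col(13)[ok]
  )
  out$negated <- vapply(out$qualifier, function(q) "NOT" %in% q, logical(1))
  out <- out[, c("db", "db_object_id", "go_id", "qualifier", "negated",
                 "aspect", "evidence_code", "taxon")]
  attr(out, "n_skipped") <- n_short + n_bad
  out
}

#' Write annotations as GAF 2.0 text
#'
#' Serialises an annotation tibble (the shape produced by [read_gaf()]) back
#' to GAF 2.0. Fields the tibble does not hold are left empty except the
#' required object symbol (copied from `db_object_id`), date and assigned-by
#' columns, which get placeholders. The output re-parses to the same held
#' fields: `read_gaf(write_gaf(x))` restores `db`, `db_object_id`, `go_id`,
#' `qualifier`, `aspect`, `evidence_code` and `taxon`.
#'
#' @param annotations Annotation tibble (columns as from [read_gaf()]).
#' @param file Path to write, or `NULL` to return the lines invisibly.
#'
#' @return Invisibly, the character vector of GAF lines.
#' @export
write_gaf <- function(annotations, file = NULL) {
  header <- "!gaf-version: 2.0"
  if (nrow(annotations) == 0) {
    out <- header
  } else {
    qual <- vapply(annotations$qualifier, paste, character(1), collapse = "|")
    taxon <- annotations$taxon
    taxon[is.na(taxon)] <- ""
    body <- paste(
      annotations$db, annotations$db_object_id, annotations$db_object_id,
      qual, annotations$go_id, "GO_REF:0000000", annotations$evidence_code,
      "", annotations$aspect, "", "", "protein", taxon, "20091001",
      "GOA", "", "",
      sep = "\t"
    )
    out <- c(header, body)
  }
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
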