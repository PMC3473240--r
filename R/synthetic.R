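#' Specification for a synthetic annotation corpus
#'
#' Describes a corpus whose term-frequency distribution has a power-law
#' tail with known exponent, with evidence codes drawn from a configurable
#' profile — the controlled stand-in for a real GOA corpus that makes every
#' pipeline stage testable offline.
#'
#' @param n_annotations Number of annotation lines to emit.
#' @param n_terms Number of distinct synthetic GO terms (>= 4). Synthetic
#'   ids use the reserved pattern `GO:9xxxxxx` so they cannot collide with
#'   real GO ids.
#' @param beta_true True frequency power-law exponent (> 1).
#' @param xmin Lower cutoff of the sampled frequency distribution
#'   (default 1).
#' @param aspect Sub-ontology letter for the emitted records (`"F"`, `"P"`
#'   or `"C"`).
#' @param evidence_profile Named numeric vector of evidence-code
#'   probabilities, summing to 1.
#' @param shallow_frequent_coupling When `TRUE`, a toy ontology is built and
#'   larger target frequencies are steered (noisily) towards shallower
#'   terms, emulating the observation that heavily used terms are generic.
#' @param seed Integer seed; generation is deterministic given the spec.
#'
#' @return A `corpus_spec` object (a validated list).
#' @export
corpus_spec <- function(n_annotations, n_terms, beta_true, xmin = 1,
                        aspect = "P",
                        evidence_profile = c(IDA = 0.3, IEA = 0.7),
                        shallow_frequent_coupling = FALSE, seed = 1L) {
  if (n_terms < 4) {
    stop_gozipf("`n_terms` must be at least 4.", "gozipf_error_domain")
  }
  if (beta_true <= 1) {
    stop_gozipf("`beta_true` must exceed 1.", "gozipf_error_domain")
  }
  if (is.null(names(evidence_profile)) ||
      abs(sum(evidence_profile) - 1) > 1e-9 || any(evidence_profile < 0)) {
    stop_gozipf("`evidence_profile` must be named probabilities summing to 1.",
                "gozipf_error_domain")
  }
  structure(
    list(n_annotations = as.integer(n_annotations),
         n_terms = as.integer(n_terms), beta_true = beta_true,
         xmin = xmin, aspect = normalize_aspect(aspect),
         evidence_profile = evidence_profile,
         shallow_frequent_coupling = isTRUE(shallow_frequent_coupling),
         seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

aspect_letter <- c(MF = "F", BP = "P", CC = "C")
ns_long <- c(MF = "molecular_function", BP = "biological_process",
             CC = "cellular_component")

#' Generate a synthetic annotation corpus with known structure
#'
#' Draws one target frequency per term from the discrete power law at
#' `(beta_true, xmin)`, then emits `n_annotations` GAF-style records by
#' sampling terms with probability proportional to those frequencies.
#' Evidence codes are i.i.d. from the spec's profile. With
#' `shallow_frequent_coupling` a balanced toy ontology is generated and
#' larger frequencies are assigned to shallower terms (through a noisy
#' depth score), so depth analyses have a known signal to find.
#'
#' @param spec A [corpus_spec()].
#'
#' @return A list with elements `annotations` (tibble in [read_gaf()]
#'   shape), `truth` (list: `beta_true`, `frequencies` — tibble of `term`,
#'   `target_freq`, and `depth` when coupled — plus the spec), and
#'   `ontology` (a `go_ontology`, only when coupling is on).
#' @examples
#' sim <- generate_corpus(corpus_spec(2000, 200, beta_true = 2, seed = 5))
#' head(sim$truth$frequencies)
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  if (spec$n_annotations < spec$n_terms) {
    warn_gozipf("Fewer annotations than terms: some terms will be unused.",
                "gozipf_warning_sparse_corpus")
  }
  withr::with_seed(spec$seed, {
    target <- sample_discrete_power_law(spec$n_terms, spec$beta_true,
                                        xmin = spec$xmin)
    term_ids <- sprintf("GO:9%06d", seq_len(spec$n_terms))
    ontology <- NULL
    depth <- NULL
    if (spec$shallow_frequent_coupling) {
      levels_needed <- ceiling(log2(spec$n_terms + 1))
      toy <- generate_toy_obo(n_levels = max(3, levels_needed), branching = 2,
                              namespace = ns_long[[spec$aspect]])
      ontology <- read_obo(toy$lines)
      # take the n_terms shallowest toy terms; couple big frequencies to
      # shallow terms via a jittered depth score
      ord_terms <- toy$depths$term[order(toy$depths$depth)][seq_len(spec$n_terms)]
      term_ids <- ord_terms
      depth <- toy$depths$depth[match(term_ids, toy$depths$term)]
      score <- depth + rnorm(spec$n_terms, sd = 0.75)
      target <- sort(target, decreasing = TRUE)[rank(score, ties.method = "first")]
    }
    tokens <- term_ids[sample.int(spec$n_terms, spec$n_annotations,
                                  replace = TRUE, prob = target)]
    evidence <- sample(names(spec$evidence_profile), spec$n_annotations,
                       replace = TRUE, prob = spec$evidence_profile)
    n_genes <- max(20L, spec$n_terms %/% 2L)
    gene <- sprintf("SYN%05d", sample.int(n_genes, spec$n_annotations,
                                          replace = TRUE))
    annotations <- tibble(
      db = "SYNTH",
      db_object_id = gene,
      go_id = tokens,
      qualifier = rep(list(character(0)), spec$n_annotations),
      negated = FALSE,
      aspect = unname(aspect_letter[spec$aspect]),
      evidence_code = evidence,
      taxon = "taxon:0000"
    )
    truth <- list(
      beta_true = spec$beta_true,
      frequencies = tibble(term = term_ids, target_freq = target,
                           depth = if (is.null(depth)) NA_integer_ else depth),
      spec = spec
    )
    list(annotations = annotations, truth = truth, ontology = ontology)
  })
}

#' Generate a balanced toy ontology in OBO 1.2 format
#'
#' Builds a complete `branching`-ary `is_a` tree of `n_levels` levels in one
#' namespace, optionally adding cross-edges (an extra parent one level up)
#' that keep the graph a DAG without changing any shortest-path depth. The
#' returned depth map is exact ground truth for depth queries.
#'
#' @param n_levels Number of levels including the root (>= 1).
#' @param branching Children per internal node (>= 1; 1 gives a chain).
#' @param n_cross Number of extra `is_a` edges to sprinkle in (each from a
#'   node at depth d to a second parent at depth d - 1).
#' @param namespace OBO namespace string for every term.
#' @param seed Optional integer seed (only the cross-edge choice is random).
#'
#' @return A list with `lines` (character vector of OBO text) and `depths`
#'   (tibble: `term`, `depth`).
#' @examples
#' toy <- generate_toy_obo(3, 2)
#' toy$depths
#' @export
generate_toy_obo <- function(n_levels, branching, n_cross = 0,
                             namespace = "biological_process", seed = NULL) {
  stopifnot(n_levels >= 1, branching >= 1)
  run <- function() {
    n_per_level <- branching^(0:(n_levels - 1))
    n_total <- sum(n_per_level)
    ids <- sprintf("GO:9%06d", seq_len(n_total))
    depth <- rep(0:(n_levels - 1), n_per_level)
    # node i > 1 in a complete b-ary tree has parent (i - 2) %/% b + 1
    parent_of <- function(i) if (branching == 1) i - 1 else (i - 2) %/% branching + 1
    parents <- lapply(seq_len(n_total), function(i) {
      if (i == 1) integer(0) else parent_of(i)
    })
    if (n_cross > 0) {
      eligible <- which(depth >= 1)
      extra <- sample(eligible, min(n_cross, length(eligible)))
      for (i in extra) {
        up <- which(depth == depth[i] - 1)
        cand <- setdiff(up, parents[[i]])
        if (length(cand)) {
          parents[[i]] <- c(parents[[i]], cand[sample.int(length(cand), 1)])
        }
      }
    }
    stanzas <- unlist(lapply(seq_len(n_total), function(i) {
      c("[Term]",
        paste0("id: ", ids[i]),
        paste0("name: synthetic term ", i),
        paste0("namespace: ", namespace),
        paste0("is_a: ", ids[parents[[i]]], " ! synthetic parent"),
        "")
    }))
    lines <- c("format-version: 1.2", "ontology: synthetic-go", "", stanzas)
    list(lines = lines, depths = tibble(term = ids, depth = depth))
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}
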