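obo_namespace_map <- c(
  molecular_function = "MF",
  biological_process = "BP",
  cellular_component = "CC"
)

#' Read an OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas (fields `id`, `name`, `namespace`, `is_a`,
#' `alt_id`, `is_obsolete`) into a DAG of terms connected by `is_a` edges
#' only — the relation conventional term-depth analysis walks. Obsolete
#' terms are excluded from the graph but remembered; alternate ids map to
#' their primary id. Terms without a namespace are kept but flagged, and
#' depth queries refuse them.
#'
#' @param file Path to an OBO file, or a character vector of OBO lines.
#'
#' @return An object of class `go_ontology`: a list with elements `terms`
#'   (character vector of primary ids), `name` / `namespace` (named
#'   character vectors; namespace one of `"MF"`, `"BP"`, `"CC"` or `NA`),
#'   `parents` (named list of `is_a` parent ids), `alt_id` (named character
#'   vector mapping alternate to primary ids), `obsolete` (character
#'   vector), and `depth` (named integer vector of shortest `is_a` distances
#'   to the namespace root).
#' @export
read_obo <- function(file) {
  lines <- if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    readLines(file)
  } else {
    file
  }
  lines <- trimws(lines)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0) {
    stop_gozipf("No [Term] stanzas in input.", "gozipf_error_empty_input")
  }
  boundaries <- c(stanza_starts, length(lines) + 1L)
  other_stanzas <- which(grepl("^\\[", lines) & lines != "[Term]")
  terms <- list()
  for (i in seq_along(stanza_starts)) {
    beg <- stanza_starts[i] + 1L
    end <- boundaries[i + 1L] - 1L
    # stop at the next non-Term stanza if one intervenes
    cut <- other_stanzas[other_stanzas > stanza_starts[i] & other_stanzas <= end]
    if (length(cut)) end <- min(cut) - 1L
    if (end < beg) next
    block <- lines[beg:end]
    get_all <- function(key) {
      vals <- block[startsWith(block, paste0(key, ":"))]
      sub("\\s*!.*$", "", sub(paste0("^", key, ":\\s*"), "", vals))
    }
    id <- get_all("id")
    if (length(id) == 0) next
    terms[[i]] <- list(
      id = id[1],
      name = get_all("name")[1] %||% NA_character_,
      namespace = get_all("namespace")[1] %||% NA_character_,
      is_a = get_all("is_a"),
      alt_id = get_all("alt_id"),
      obsolete = any(grepl("^true", get_all("is_obsolete")))
    )
  }
  terms <- purrr::compact(terms)
  obsolete <- purrr::map_chr(purrr::keep(terms, "obsolete"), "id")
  live <- purrr::discard(terms, "obsolete")
  if (length(live) == 0) {
    stop_gozipf("All terms are obsolete.", "gozipf_error_empty_input")
  }
  ids <- purrr::map_chr(live, "id")
  name <- purrr::set_names(purrr::map_chr(live, "name"), ids)
  ns_raw <- purrr::set_names(purrr::map_chr(live, "namespace"), ids)
  namespace <- purrr::set_names(unname(obo_namespace_map[ns_raw]), ids)
  if (any(is.na(namespace))) {
    warn_gozipf(
      sprintf("%d term(s) lack a recognised namespace and are excluded from depth queries.",
              sum(is.na(namespace))),
      "gozipf_warning_no_namespace"
    )
  }
  parents <- purrr::set_names(
    purrr::map(live, function(t) intersect(t$is_a, ids)),
    ids
  )
  alt_pairs <- purrr::map(live, function(t) {
    if (length(t$alt_id)) purrr::set_names(rep(t$id, length(t$alt_id)), t$alt_id)
  })
  alt_id <- unlist(purrr::compact(alt_pairs)) %||% character(0)
  ont <- structure(
    list(terms = ids, name = name, namespace = namespace, parents = parents,
         alt_id = alt_id, obsolete = obsolete),
    class = "go_ontology"
  )
  check_acyclic(ont)
  ont$depth <- compute_depths(ont)
  ont
}

# Kahn topological check on the is_a DAG; names a cycle member on failure.
check_acyclic <- function(ont) {
  indeg <- purrr::map_int(ont$parents, length) # edges term -> parent
  children <- split(
    rep(names(ont$parents), lengths(ont$parents)),
    unlist(ont$parents)
  )
  queue <- names(indeg)[indeg == 0]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (ch in children[[v]] %||% character(0)) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ont$terms)) {
    member <- names(indeg)[indeg > 0][1]
    stop_gozipf(
      sprintf("is_a relation contains a cycle (involving %s).", member),
      "gozipf_error_cycle"
    )
  }
  invisible(TRUE)
}

# BFS down from each namespace root: depth = shortest is_a path to the root.
compute_depths <- function(ont) {
  depth <- purrr::set_names(rep(NA_integer_, length(ont$terms)), ont$terms)
  children <- split(
    rep(names(ont$parents), lengths(ont$parents)),
    unlist(ont$parents)
  )
  for (ns in unique(stats::na.omit(ont$namespace))) {
    in_ns <- names(ont$namespace)[!is.na(ont$namespace) & ont$namespace == ns]
    roots <- in_ns[purrr::map_int(ont$parents[in_ns],
                                  ~ length(intersect(.x, in_ns))) == 0]
    if (length(roots) != 1) {
      warn_gozipf(
        sprintf("Namespace %s has %d roots; depths measured from the nearest.",
                ns, length(roots)),
        "gozipf_warning_multiple_roots"
      )
    }
    frontier <- roots
    depth[frontier] <- 0L
    d <- 0L
    while (length(frontier)) {
      d <- d + 1L
      nxt <- setdiff(
        intersect(unique(unlist(children[frontier], use.names = FALSE)), in_ns),
        names(depth)[!is.na(depth)]
      )
      depth[nxt] <- d
      frontier <- nxt
    }
  }
  depth
}

#' Resolve GO ids to primary, current ids
#'
#' Maps alternate ids to their primary id and leaves unknown ids untouched.
#'
#' @param ontology A `go_ontology` from [read_obo()].
#' @param go_ids Character vector of GO ids.
#' @return Character vector of the same length with alternate ids replaced.
#' @export
resolve_go_ids <- function(ontology, go_ids) {
  stopifnot(inherits(ontology, "go_ontology"))
  hit <- go_ids %in% names(ontology$alt_id)
  go_ids[hit] <- unname(ontology$alt_id[go_ids[hit]])
  go_ids
}

#' @export
print.go_ontology <- function(x, ...) {
  ns <- table(x$namespace, useNA = "ifany")
  cat(sprintf("GO ontology graph: %d terms (%s), %d obsolete, %d alt ids\n",
              length(x$terms),
              paste(sprintf("%s %d", names(ns), ns), collapse = ", "),
              length(x$obsolete), length(x$alt_id)))
  invisible(x)
}
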