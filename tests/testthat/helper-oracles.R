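# Independent brute-force oracles used to cross-check the statistical core.
# These deliberately avoid the package's own numerical routines.

# Hurwitz zeta by direct partial summation with an integral tail bound;
# accurate to ~1e-10 for s >= 1.5, plenty for 1e-6 comparisons.
oracle_zeta <- function(s, q, terms = 3000) {
  k <- 0:(terms - 1)
  m <- q + terms
  sum((q + k)^(-s)) + m^(1 - s) / (s - 1) + 0.5 * m^(-s) +
    s * m^(-s - 1) / 12
}

# Exhaustive grid maximiser of the discrete power-law log-likelihood.
oracle_mle_grid <- function(values, xmin, betas = seq(1.01, 6, by = 1e-4)) {
  tail_vals <- values[values >= xmin]
  n <- length(tail_vals)
  s_log <- sum(log(tail_vals))
  ll_at <- function(b) -n * log(oracle_zeta(b, xmin)) - b * s_log
  ll <- vapply(betas, ll_at, numeric(1))
  betas[which.max(ll)]
}

# Staged exhaustive grid: global scan at 1e-3, then local scans at 1e-5 and
# 1e-7 around the running maximiser (the likelihood is unimodal in beta).
oracle_mle_grid_fine <- function(values, xmin) {
  b <- oracle_mle_grid(values, xmin, betas = seq(1.01, 6, by = 1e-3))
  b <- oracle_mle_grid(values, xmin, betas = seq(b - 2e-3, b + 2e-3, by = 1e-5))
  oracle_mle_grid(values, xmin, betas = seq(b - 2e-5, b + 2e-5, by = 1e-7))
}

# KS distance by explicit enumeration over every distinct tail value.
oracle_ks <- function(values, beta, xmin) {
  tail_vals <- values[values >= xmin]
  z_min <- oracle_zeta(beta, xmin)
  max(vapply(sort(unique(tail_vals)), function(x) {
    abs(mean(tail_vals >= x) - oracle_zeta(beta, x) / z_min)
  }, numeric(1)))
}

# Exhaustive cutoff scan mirroring the selection rule from first principles.
oracle_select <- function(values, min_tail = 10) {
  cands <- sort(unique(values))
  best <- NULL
  for (xm in cands) {
    tail_vals <- values[values >= xm]
    if (length(tail_vals) < min_tail || length(unique(tail_vals)) < 2) next
    b <- oracle_mle_grid_fine(values, xm)
    d <- oracle_ks(values, b, xm)
    if (is.null(best) || d < best$d) best <- list(xmin = xm, beta = b, d = d)
  }
  best
}

# Shortest is_a path to a namespace root by exhaustive path enumeration.
oracle_depth <- function(ontology, term) {
  walk <- function(t, len) {
    ps <- ontology$parents[[t]]
    ps <- ps[!is.na(ontology$namespace[ps]) &
             ontology$namespace[ps] == ontology$namespace[[term]]]
    if (length(ps) == 0) return(len)
    min(vapply(ps, function(p) walk(p, len + 1L), integer(1)))
  }
  walk(term, 0L)
}

oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t = t_stat, df = n - 1,
       p_two = 2 * pt(-abs(t_stat), n - 1),
       p_greater = pt(t_stat, n - 1, lower.tail = FALSE))
}

# A small well-formed GAF fixture: 20 lines over two aspects with a known
# HC/LC/other evidence mix and one NOT-qualified line.
make_gaf_line <- function(go, evidence, aspect, qualifier = "", obj = "P00001",
                          db = "UniProtKB") {
  paste(db, obj, "SYM", qualifier, go, "PMID:1", evidence, "", aspect,
        "", "", "protein", "taxon:9606", "20091001", "GOA", "", "",
        sep = "\t")
}

fixture_gaf <- function() {
  c("!gaf-version: 2.0",
    make_gaf_line("GO:0000001", "IDA", "P"),
    make_gaf_line("GO:0000001", "IDA", "P", obj = "P00002"),
    make_gaf_line("GO:0000001", "IEA", "P"),
    make_gaf_line("GO:0000002", "IEA", "P"),
    make_gaf_line("GO:0000002", "IEA", "P", obj = "P00003"),
    make_gaf_line("GO:0000002", "ISS", "P"),
    make_gaf_line("GO:0000003", "TAS", "P"),
    make_gaf_line("GO:0000003", "IMP", "P", qualifier = "NOT"),
    make_gaf_line("GO:0000004", "IEA", "P"),
    make_gaf_line("GO:0000004", "ISS", "P"),
    make_gaf_line("GO:0008305", "IDA", "C"),
    make_gaf_line("GO:0008305", "IDA", "C", obj = "P00004"),
    make_gaf_line("GO:0008305", "IPI", "C"),
    make_gaf_line("GO:0005737", "IEA", "C"),
    make_gaf_line("GO:0005737", "IEA", "C", obj = "P00005"),
    make_gaf_line("GO:0005737", "TAS", "C"),
    make_gaf_line("GO:0005856", "ISS", "C"),
    make_gaf_line("GO:0005856", "IC", "C"),
    make_gaf_line("GO:0005856", "IEA", "C", qualifier = "NOT|colocalizes_with"),
    make_gaf_line("GO:0016020", "EXP", "C"))
}

# Diamond DAG: the leaf has a 2-edge route to the root (via GO:9000002) and
# a 4-edge route (via the GO:9000003 chain); shortest-path depth is 2.
fixture_diamond_obo <- function() {
  stanza <- function(id, is_a = character(0)) {
    c("[Term]", paste0("id: ", id), paste0("name: n", id),
      "namespace: molecular_function",
      if (length(is_a)) paste0("is_a: ", is_a), "")
  }
  c("format-version: 1.2", "",
    stanza("GO:9000001"),
    stanza("GO:9000002", "GO:9000001"),
    stanza("GO:9000003", "GO:9000001"),
    stanza("GO:9000004", "GO:9000003"),
    stanza("GO:9000005", "GO:9000004"),
    stanza("GO:9000006", c("GO:9000002", "GO:9000005")))
}

# Random DAG on n nodes: node i may attach to any subset of earlier nodes,
# guaranteeing acyclicity; node 1 is the root.
fixture_random_dag <- function(n, seed) {
  withr::with_seed(seed, {
    stanza <- function(id, is_a) {
      c("[Term]", paste0("id: ", id), paste0("name: x"),
        "namespace: biological_process",
        if (length(is_a)) paste0("is_a: ", is_a), "")
    }
    ids <- sprintf("GO:9%06d", 1:n)
    lines <- c("format-version: 1.2", "", stanza(ids[1], character(0)))
    for (i in 2:n) {
      k <- sample(1:min(3, i - 1), 1)
      parents <- ids[sample(i - 1, k)]
      lines <- c(lines, stanza(ids[i], parents))
    }
    lines
  })
}
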