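test_that("term_depth walks the shortest is_a path to the root", {
  chain <- read_obo(c(
    "[Term]", "id: GO:9000001", "name: root", "namespace: molecular_function", "",
    "[Term]", "id: GO:9000002", "name: a", "namespace: molecular_function",
    "is_a: GO:9000001", "",
    "[Term]", "id: GO:9000003", "name: b", "namespace: molecular_function",
    "is_a: GO:9000002", ""
  ))
  expect_equal(term_depth(chain, "GO:9000001"), 0L)
  expect_equal(term_depth(chain, "GO:9000003"), 2L)
  # diamond: routes of length 2 and 4 from the leaf to the root
  diamond <- read_obo(fixture_diamond_obo())
  expect_equal(term_depth(diamond, "GO:9000006"), 2L)
  expect_equal(term_depth(diamond, "GO:9000006"),
               oracle_depth(diamond, "GO:9000006"))
  expect_error(term_depth(chain, "GO:1234567"),
               class = "gozipf_error_unknown_term")
})

test_that("term_depth equals brute-force path enumeration on random DAGs", {
  for (seed in 1:6) {
    n <- c(10, 20, 35, 50, 15, 42)[seed]
    ont <- read_obo(fixture_random_dag(n, seed))
    got <- term_depth(ont, ont$terms)
    want <- vapply(ont$terms, function(t) oracle_depth(ont, t), integer(1))
    expect_equal(got, unname(want))
  }
})

test_that("quartile split compares mean depths of frequent vs rare terms", {
  # 4 terms, depths 1..4, frequencies 4..1: top quartile = depth 1, bottom = 4
  ont <- read_obo(c(
    "[Term]", "id: GO:9000001", "name: r", "namespace: biological_process", "",
    "[Term]", "id: GO:9000002", "name: d1", "namespace: biological_process",
    "is_a: GO:9000001", "",
    "[Term]", "id: GO:9000003", "name: d2", "namespace: biological_process",
    "is_a: GO:9000002", "",
    "[Term]", "id: GO:9000004", "name: d3", "namespace: biological_process",
    "is_a: GO:9000003", "",
    "[Term]", "id: GO:9000005", "name: d4", "namespace: biological_process",
    "is_a: GO:9000004", ""
  ))
  corp <- tibble::tibble(term = rep(sprintf("GO:900000%d", 2:5), times = 4:1))
  cmp <- quartile_depth_comparison(term_frequencies(corp), ont)
  expect_equal(cmp$n_top, 1)
  expect_equal(cmp$mean_depth_top, 1)
  expect_equal(cmp$mean_depth_bottom, 4)
  # all terms at one depth: both means equal that depth
  flat_terms <- sprintf("GO:900000%d", 2:5)
  flat <- tibble::tibble(term = rep(flat_terms[c(1, 1, 2, 3, 4)], 1))
  ont_flat <- read_obo(c(
    "[Term]", "id: GO:9000001", "name: r", "namespace: biological_process", "",
    unlist(lapply(flat_terms, function(id) {
      c("[Term]", paste0("id: ", id), "name: x",
        "namespace: biological_process", "is_a: GO:9000001", "")
    }))
  ))
  cmp_flat <- quartile_depth_comparison(term_frequencies(flat), ont_flat)
  expect_equal(cmp_flat$mean_depth_top, cmp_flat$mean_depth_bottom)
  expect_error(
    quartile_depth_comparison(term_frequencies(tibble::tibble(term = c("a", "b"))),
                              ont),
    class = "gozipf_error_too_few_terms"
  )
})

test_that("generated shallow-frequent corpora show the depth gradient", {
  for (seed in 1:5) {
    sim <- generate_corpus(corpus_spec(3000, 150, beta_true = 2, seed = seed,
                                       shallow_frequent_coupling = TRUE))
    ft <- term_frequencies(build_corpus(sim$annotations, "P"))
    cmp <- quartile_depth_comparison(ft, sim$ontology)
    expect_lt(cmp$mean_depth_top, cmp$mean_depth_bottom)
  }
})

test_that("depth_significance runs a paired t-test and rejects degenerate input", {
  cmps <- tibble::tibble(
    corpus_label = letters[1:3],
    n_top = 5, n_bottom = 5,
    mean_depth_top = c(4.1, 4.5, 4.3),
    mean_depth_bottom = c(6.0, 6.5, 6.2)
  )
  res <- depth_significance(cmps)
  ora <- oracle_paired_t(cmps$mean_depth_top, cmps$mean_depth_bottom)
  expect_equal(res$t, ora$t, tolerance = 1e-12)
  expect_equal(res$df, ora$df)
  expect_equal(res$p_value, ora$p_two, tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)
  same <- dplyr::mutate(cmps, mean_depth_bottom = mean_depth_top + 1)
  expect_error(depth_significance(same), class = "gozipf_error_degenerate")
  expect_error(depth_significance(cmps[1, ]),
               class = "gozipf_error_too_few_pairs")
})
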