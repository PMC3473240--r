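test_that("evidence classes hold the standard code sets", {
  expect_setequal(evidence_codes("HC"),
                  c("IDA", "IPI", "IMP", "TAS", "EXP", "IC", "IEP", "IGI"))
  expect_equal(unclass(evidence_codes("LC")), "IEA", ignore_attr = TRUE)
  expect_null(evidence_codes("ALL"))
})

test_that("build_corpus filters by aspect and evidence class", {
  ann <- read_gaf(fixture_gaf())
  hc_p <- build_corpus(ann, "P", "HC")
  expect_equal(nrow(hc_p), 3) # two IDA + one TAS; the NOT-qualified IMP drops
  expect_true(all(hc_p$term %in% c("GO:0000001", "GO:0000003")))
  lc_p <- build_corpus(ann, "P", "LC")
  expect_equal(nrow(lc_p), 4)
  all_c <- build_corpus(ann, "C", "ALL")
  expect_equal(nrow(all_c), 9) # one NOT-qualified line excluded
  expect_equal(attr(all_c, "aspect"), "CC")
  # including negated restores the NOT lines
  expect_equal(nrow(build_corpus(ann, "P", "ALL", exclude_negated = FALSE)), 10)
  # custom class
  iss <- build_corpus(ann, "P", c("ISS"))
  expect_equal(nrow(iss), 2)
  expect_equal(attr(iss, "evidence_class"), "CUSTOM")
  # empty corpus errors
  expect_error(build_corpus(ann, "F", "HC"),
               class = "gozipf_error_empty_corpus")
})

test_that("HC, LC and remainder partition the ALL corpus", {
  ann <- read_gaf(fixture_gaf())
  other <- setdiff(unique(ann$evidence_code),
                   c(evidence_codes("HC"), evidence_codes("LC")))
  for (asp in c("P", "C")) {
    n_all <- nrow(build_corpus(ann, asp, "ALL"))
    n_hc <- nrow(build_corpus(ann, asp, "HC"))
    n_lc <- nrow(build_corpus(ann, asp, "LC"))
    n_other <- nrow(build_corpus(ann, asp, other))
    expect_equal(n_hc + n_lc + n_other, n_all)
  }
})

test_that("dedupe collapses repeated gene-term pairs", {
  ann <- read_gaf(fixture_gaf())
  # GO:0000001 IDA appears for P00001 and P00002, plus IEA for P00001
  all_p <- build_corpus(ann, "P", "ALL", dedupe = TRUE)
  counts <- table(all_p$term)
  expect_equal(unname(counts[["GO:0000001"]]), 2) # two distinct objects
})

test_that("term_frequencies counts, ranks, and breaks ties lexicographically", {
  ft <- term_frequencies(tibble::tibble(term = c("A", "A", "A", "B", "B", "C")))
  expect_equal(ft$term, c("A", "B", "C"))
  expect_equal(ft$freq, c(3, 2, 1))
  expect_equal(ft$rank, 1:3)
  tied <- term_frequencies(tibble::tibble(term = c("B", "A", "B", "A")))
  expect_equal(tied$term, c("A", "B"))
  expect_equal(tied$rank, 1:2)
})

test_that("frequencies are conserved and order-invariant", {
  sim <- generate_corpus(corpus_spec(1500, 60, beta_true = 2, seed = 4))
  corp <- build_corpus(sim$annotations, "P", "ALL", source_label = "syn")
  ft <- term_frequencies(corp)
  expect_equal(sum(ft$freq), nrow(corp))
  shuffled <- corp[withr::with_seed(1, sample(nrow(corp))), ]
  expect_equal(term_frequencies(shuffled)[, c("term", "freq", "rank")],
               ft[, c("term", "freq", "rank")])
})

test_that("corpus_summary reports one row per corpus with exact counts", {
  ann <- read_gaf(fixture_gaf())
  corpora <- list(build_corpus(ann, "P", "ALL", source_label = "toy"),
                  build_corpus(ann, "C", "HC", source_label = "toy"))
  s <- corpus_summary(corpora)
  expect_equal(nrow(s), 2)
  expect_equal(s$total_annotations, c(9, 6))
  expect_equal(s$distinct_go_ids, c(4, 4))
  expect_equal(s$evidence_class, c("ALL", "HC"))
  # generator bookkeeping: totals match the spec that produced them
  sim <- generate_corpus(corpus_spec(800, 50, beta_true = 2.2, seed = 9))
  corp <- build_corpus(sim$annotations, "P", "ALL", source_label = "syn")
  s2 <- corpus_summary(corp)
  expect_equal(s2$total_annotations, 800)
  expect_lte(s2$distinct_go_ids, 50)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_summary_tsv(s, tmp)
  expect_equal(as.data.frame(readr::read_tsv(tmp, show_col_types = FALSE)),
               as.data.frame(s))
})
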