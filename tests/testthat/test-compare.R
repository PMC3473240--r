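test_that("sub-ontology mean exponents reproduce the reference survey values", {
  fits <- goa_oct2009_fits()
  expect_equal(group_mean_beta(fits, "BP"), 2.13, tolerance = 1e-10)
  expect_equal(group_mean_beta(fits, "MF"), 1.814, tolerance = 1e-10)
  expect_equal(round(group_mean_beta(fits, "MF"), 2), 1.81)
  # the CC column averages 1.716; the survey printed the truncated 1.71
  expect_equal(group_mean_beta(fits, "CC"), 1.716, tolerance = 1e-10)
  expect_error(group_mean_beta(fits[fits$aspect == "BP", ], "MF"),
               class = "gozipf_error_empty_input")
  # permutation invariant, bounded by the column range
  withr::with_seed(3, shuffled <- fits[sample(nrow(fits)), ])
  expect_equal(group_mean_beta(shuffled, "BP"), group_mean_beta(fits, "BP"))
  expect_gte(group_mean_beta(fits, "BP"), min(fits$beta))
  expect_lte(group_mean_beta(fits, "BP"), max(fits$beta))
})

test_that("paired_t_test matches the textbook formula on reference data", {
  t4 <- goa_oct2009_evidence_fits()
  hc <- t4$beta[t4$evidence_class == "HC"]
  lc <- t4$beta[t4$evidence_class == "LC"]
  res <- paired_t_test(hc, lc)
  ora <- oracle_paired_t(hc, lc)
  expect_equal(res$t, ora$t, tolerance = 1e-12)
  expect_equal(res$t, 3.32, tolerance = 0.005)
  expect_equal(res$df, 5)
  expect_equal(res$p_value, ora$p_two, tolerance = 1e-12)
  one <- paired_t_test(hc, lc, alternative = "greater")
  expect_equal(one$p_value, ora$p_greater, tolerance = 1e-12)
  expect_equal(round(one$p_value, 2), 0.01)
})

test_that("paired_t_test matches the closed form on random pairs", {
  for (seed in 1:4) {
    withr::with_seed(seed, {
      x <- rnorm(4 + seed, mean = 2, sd = 0.3)
      y <- x - rnorm(4 + seed, mean = 0.2, sd = 0.15)
    })
    res <- paired_t_test(x, y)
    ora <- oracle_paired_t(x, y)
    expect_equal(res$t, ora$t, tolerance = 1e-12)
    expect_equal(res$p_value, ora$p_two, tolerance = 1e-12)
  }
})

test_that("paired_t_test rejects degenerate or tiny inputs", {
  expect_error(paired_t_test(c(1, 2, 3), c(0, 1, 2)),
               class = "gozipf_error_degenerate")
  expect_error(paired_t_test(1, 0), class = "gozipf_error_too_few_pairs")
})

test_that("size_exponent_association reports rank correlations and scatter data", {
  recs <- tibble::tibble(beta = c(1.7, 1.9, 2.1, 2.3),
                         n_distinct = c(100, 500, 2000, 4000),
                         n_total = c(1e3, 5e3, 2e4, 4e4))
  assoc <- size_exponent_association(recs)
  expect_equal(assoc$correlations$rho, c(1, 1))
  flat <- dplyr::mutate(recs, beta = 2)
  expect_equal(size_exponent_association(flat)$correlations$rho, c(0, 0))
  expect_equal(nrow(assoc$data), 4)
  expect_error(size_exponent_association(recs[1:2, ]),
               class = "gozipf_error_too_few_records")
  expect_s3_class(plot_size_exponent(assoc), "ggplot")
})

test_that("exponents fitted at varying corpus size show no size association", {
  rows <- purrr::map_dfr(seq_along(sizes <- c(800, 1500, 3000, 6000, 12000)),
    function(i) {
      x <- sample_discrete_power_law(sizes[i], 2, seed = 100 + i)
      sel <- select_xmin(x)
      tibble::tibble(beta = sel$beta_hat, n_distinct = length(unique(x)),
                     n_total = sizes[i])
    })
  assoc <- size_exponent_association(rows)
  expect_lt(abs(assoc$correlations$rho[1]), 0.95)
})
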