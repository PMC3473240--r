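test_that("ccdf matches hand counts and is non-increasing", {
  tab <- ccdf(c(1, 1, 2, 3))
  expect_equal(tab$x, c(1, 2, 3))
  expect_equal(tab$p, c(1, 0.5, 0.25))
  expect_equal(ccdf(5)$p, 1)
  for (seed in 1:5) {
    x <- sample_discrete_power_law(300, 1.8, seed = seed)
    p <- ccdf(x)$p
    expect_equal(p[1], 1)
    expect_true(all(diff(p) < 0))
  }
  expect_error(ccdf(numeric(0)), class = "gozipf_error_empty_input")
})

test_that("mle_beta agrees with a brute-force likelihood grid", {
  x <- sample_discrete_power_law(200, 2.2, seed = 21)
  expect_equal(mle_beta(x, 1), oracle_mle_grid(x, 1), tolerance = 1e-4)
  x2 <- sample_discrete_power_law(150, 1.7, seed = 22)
  expect_equal(mle_beta(x2, 2), oracle_mle_grid(x2, 2), tolerance = 1e-4)
})

test_that("mle_beta recovers the exponent of a large simulated sample", {
  x <- sample_discrete_power_law(50000, 2.5, seed = 17)
  beta_hat <- mle_beta(x, 1)
  se <- (beta_hat - 1) / sqrt(length(x))
  expect_lt(abs(beta_hat - 2.5), 3 * se)
})

test_that("mle_beta approaches the continuous closed form for large xmin", {
  xmin <- 40
  x <- sample_discrete_power_law(5000, 2.5, xmin = xmin, seed = 99)
  continuous <- 1 + length(x) / sum(log(x / (xmin - 0.5)))
  expect_equal(mle_beta(x, xmin), continuous, tolerance = 0.02)
})

test_that("mle_beta rejects degenerate tails", {
  expect_error(mle_beta(rep(3, 20), 1), class = "gozipf_error_divergence")
  expect_error(mle_beta(c(1, 2, 3), 10), class = "gozipf_error_empty_tail")
})

test_that("ks_distance equals explicit enumeration and shrinks with n", {
  x <- sample_discrete_power_law(20, 2, seed = 5)
  expect_equal(ks_distance(x, 2.1, 1), oracle_ks(x, 2.1, 1), tolerance = 1e-8)
  x2 <- sample_discrete_power_law(30, 2.4, xmin = 3, seed = 6)
  expect_equal(ks_distance(x2, 2.2, 3), oracle_ks(x2, 2.2, 3), tolerance = 1e-8)
  big <- sample_discrete_power_law(10000, 2.5, seed = 3)
  expect_lt(ks_distance(big, 2.5, 1), 0.05)
  single <- rep(4, 15)
  d <- ks_distance(single, 2, 4)
  expect_gte(d, 0)
  expect_lte(d, 1)
  expect_error(ks_distance(x, 0.9, 1), class = "gozipf_error_domain")
})

test_that("select_xmin equals an exhaustive candidate scan", {
  x <- sample_discrete_power_law(100, 2.3, seed = 31)
  sel <- select_xmin(x)
  ora <- oracle_select(x)
  expect_equal(sel$xmin, ora$xmin)
  expect_equal(sel$beta_hat, ora$beta, tolerance = 1e-4)
  expect_equal(sel$ks_distance, ora$d, tolerance = 1e-6)
})

test_that("select_xmin finds the true cutoff of a spliced sample", {
  hits <- 0
  low <- 0
  for (seed in 1:20) {
    set.seed(seed)
    noise <- sample(1:3, 2000, replace = TRUE)
    tail_part <- sample_discrete_power_law(2000, 2.5, xmin = 4)
    if (select_xmin(c(noise, tail_part))$xmin %in% 3:5) hits <- hits + 1
    pure <- sample_discrete_power_law(1000, 2.5)
    if (select_xmin(pure)$xmin <= 3) low <- low + 1
  }
  expect_gte(hits / 20, 0.9)
  expect_gt(low / 20, 0.5)
})

test_that("select_xmin errors when no tail is big enough", {
  expect_error(select_xmin(c(1, 2, 3), min_tail = 10),
               class = "gozipf_error_no_candidates")
})

test_that("rank_frequency extracts monotone plot points", {
  ft <- term_frequencies(tibble::tibble(term = c("A", "A", "A", "B", "B", "C")))
  rf <- rank_frequency(ft)
  expect_equal(rf$rank, 1:3)
  expect_equal(rf$frequency, c(3, 2, 1))
  sim <- generate_corpus(corpus_spec(1000, 40, beta_true = 2, seed = 8))
  ft2 <- term_frequencies(build_corpus(sim$annotations, "P"))
  rf2 <- rank_frequency(ft2)
  expect_true(all(diff(rf2$frequency) <= 0))
  expect_equal(sum(rf2$frequency), 1000)
})
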