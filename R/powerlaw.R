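#' Empirical complementary cumulative distribution (Pareto form)
#'
#' Tabulates, for each distinct value `x` in the input, the proportion of
#' observations with value at least `x`. Term-frequency data whose upper tail
#' follows \eqn{P(f) \propto f^{-\beta}} show a straight line of slope
#' \eqn{-k = -(\beta - 1)} on the log-log CCDF plot, which is the stable
#' representation used for exponent estimation (rank-frequency plots are
#' noisy at high rank).
#'
#' @param values Positive integer observations (e.g. term frequencies).
#'
#' @return A tibble with columns `x` (distinct values, ascending) and `p`
#'   (proportion of observations `>= x`); `p` starts at 1 and is
#'   non-increasing.
#' @examples
#' ccdf(c(1, 1, 2, 3))
#' @export
ccdf <- function(values) {
  values <- assert_count_values(values)
  n <- length(values)
  tab <- table(values)
  x <- as.numeric(names(tab))
  counts <- as.numeric(tab)
  # observations >= x[i]: everything not in the strictly smaller classes
  at_least <- n - cumsum(counts) + counts
  tibble(x = x, p = at_least / n)
}

# sum of log(x) over the tail, the sufficient statistic of the discrete MLE
tail_stats <- function(values, xmin) {
  tail_vals <- values[values >= xmin]
  list(values = tail_vals, n = length(tail_vals), sum_log = sum(log(tail_vals)))
}

# run-length view of a sorted sample: distinct values, their counts, and the
# number of observations at or above each distinct value
value_counts <- function(sorted) {
  r <- rle(sorted)
  list(x = r$values, counts = r$lengths,
       at_least = rev(cumsum(rev(r$lengths))))
}

# KS distance for one candidate cutoff, on the run-length view (index i)
ks_at <- function(vc, beta, i) {
  m <- length(vc$x)
  xs <- vc$x[i:m]
  emp <- vc$at_least[i:m] / vc$at_least[i]
  hz <- hurwitz_zeta(beta, xs)
  max(abs(emp - hz / hz[1]))
}

# cutoff selection on a pre-sorted sample; plain-list return for hot loops
select_xmin_impl <- function(sorted, min_tail) {
  vc <- value_counts(sorted)
  m <- length(vc$x)
  sum_log <- rev(cumsum(rev(vc$counts * log(vc$x))))
  n_distinct_tail <- m - seq_len(m) + 1L
  keep <- which(vc$at_least >= min_tail & n_distinct_tail >= 2L)
  if (length(keep) == 0) return(NULL)
  best <- NULL
  for (i in keep) {
    opt <- optimize(pl_negloglik, interval = c(1 + 1e-6, 10),
                    n = vc$at_least[i], sum_log = sum_log[i], xmin = vc$x[i],
                    tol = 1e-6)
    d <- ks_at(vc, opt$minimum, i)
    if (is.null(best) || d < best$ks_distance) {
      best <- list(xmin = vc$x[i], beta_hat = opt$minimum, ks_distance = d,
                   n_tail = vc$at_least[i])
    }
  }
  best
}

pl_negloglik <- function(beta, n, sum_log, xmin) {
  n * log(hurwitz_zeta(beta, xmin)) + beta * sum_log
}

#' Discrete power-law exponent by maximum likelihood
#'
#' Fits \eqn{P(X = x) = x^{-\beta} / \zeta(\beta, x_{min})} to the tail of
#' `values` at or above `xmin`, maximising the log-likelihood
#' \eqn{\ell(\beta) = -n \ln \zeta(\beta, x_{min}) - \beta \sum \ln x_i}
#' by bounded scalar search over \eqn{\beta \in (1, 10]}.
#'
#' @param values Positive integer observations.
#' @param xmin Lower cutoff; only values `>= xmin` enter the fit.
#'
#' @return The estimate `beta_hat` (a single number greater than 1),
#'   located to better than 1e-4.
#' @examples
#' x <- sample_discrete_power_law(500, beta = 2, seed = 1)
#' mle_beta(x, xmin = 1)
#' @export
mle_beta <- function(values, xmin) {
  values <- assert_count_values(values)
  stopifnot(length(xmin) == 1, xmin >= 1)
  ts <- tail_stats(values, xmin)
  if (ts$n == 0) {
    stop_gozipf("No observations at or above `xmin`.", "gozipf_error_empty_tail")
  }
  if (length(unique(ts$values)) < 2) {
    stop_gozipf(
      "All tail observations are equal; the likelihood diverges (beta -> Inf).",
      "gozipf_error_divergence"
    )
  }
  opt <- optimize(pl_negloglik, interval = c(1 + 1e-6, 10),
                  n = ts$n, sum_log = ts$sum_log, xmin = xmin, tol = 1e-6)
  opt$minimum
}

#' Kolmogorov-Smirnov distance between tail data and a fitted power law
#'
#' The maximum absolute difference, over the distinct observed tail values,
#' between the empirical CCDF of the tail and the model CCDF
#' \eqn{\zeta(\beta, x) / \zeta(\beta, x_{min})}, both conditioned on
#' \eqn{x \ge x_{min}}.
#'
#' @inheritParams mle_beta
#' @param beta Power-law exponent, greater than 1.
#'
#' @return The KS distance, a number in `[0, 1]`.
#' @export
ks_distance <- function(values, beta, xmin) {
  values <- assert_count_values(values)
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 1) {
    stop_gozipf("`beta` must be a single number > 1.", "gozipf_error_domain")
  }
  tail_vals <- values[values >= xmin]
  if (length(tail_vals) == 0) {
    stop_gozipf("No observations at or above `xmin`.", "gozipf_error_empty_tail")
  }
  vc <- value_counts(sort(tail_vals))
  emp <- vc$at_least / vc$at_least[1]
  model <- hurwitz_zeta(beta, vc$x) / hurwitz_zeta(beta, xmin)
  max(abs(emp - model))
}

#' Select the power-law lower cutoff by KS minimisation
#'
#' Every distinct observed value whose tail holds at least `min_tail` points
#' (and at least two distinct values, so the MLE exists) is a candidate
#' cutoff. Each candidate is fitted by [mle_beta()] and scored by
#' [ks_distance()]; the candidate with the smallest KS distance wins, ties
#' going to the smaller cutoff (the larger tail).
#'
#' @inheritParams mle_beta
#' @param min_tail Minimum number of tail observations a candidate cutoff
#'   must retain (default 10).
#'
#' @return A one-row tibble with columns `xmin`, `beta_hat`, `ks_distance`
#'   and `n_tail`.
#' @examples
#' x <- sample_discrete_power_law(1000, beta = 2, seed = 1)
#' select_xmin(x)
#' @export
select_xmin <- function(values, min_tail = 10) {
  values <- assert_count_values(values)
  best <- select_xmin_impl(sort(values), min_tail)
  if (is.null(best)) {
    stop_gozipf(
      sprintf("No candidate cutoff keeps a tail of >= %d points.", min_tail),
      "gozipf_error_no_candidates"
    )
  }
  tibble(xmin = best$xmin, beta_hat = best$beta_hat,
         ks_distance = best$ks_distance, n_tail = best$n_tail)
}

#' Fit a discrete power law with cutoff selection and optional bootstrap
#'
#' The full fitting procedure applied to a vector of term frequencies:
#' KS-based cutoff selection ([select_xmin()]), maximum-likelihood exponent
#' ([mle_beta()]), and — when `n_bootstrap > 0` — the semi-parametric
#' bootstrap goodness-of-fit p-value ([gof_pvalue()]). A fit with
#' `p_value > 0.1` is flagged plausible: the power law cannot be rejected as
#' a model of the tail.
#'
#' @inheritParams select_xmin
#' @param n_bootstrap Number of bootstrap replicates for the goodness-of-fit
#'   test; 0 skips the test and leaves `p_value` as `NA`.
#' @param seed Integer seed making the bootstrap reproducible.
#'
#' @return An object of class `pl_fit`: a list with elements `xmin`,
#'   `beta_hat`, `n_tail`, `ks_distance`, `p_value`, `plausible`,
#'   `n_bootstrap`, `seed`, `min_tail`, `n` and `values`. Methods:
#'   [tidy()], [glance()], `print()`, [ggplot2::autoplot()].
#' @examples
#' x <- sample_discrete_power_law(2000, beta = 2, seed = 7)
#' fit <- fit_power_law(x, n_bootstrap = 50, seed = 7)
#' glance(fit)
#' @export
fit_power_law <- function(values, min_tail = 10, n_bootstrap = 0, seed = 1L) {
  values <- assert_count_values(values)
  sel <- select_xmin(values, min_tail = min_tail)
  fit <- structure(
    list(xmin = sel$xmin, beta_hat = sel$beta_hat, n_tail = sel$n_tail,
         ks_distance = sel$ks_distance, p_value = NA_real_,
         plausible = NA, n_bootstrap = 0L, seed = as.integer(seed),
         min_tail = min_tail, n = length(values), values = values),
    class = "pl_fit"
  )
  if (n_bootstrap > 0) {
    fit$p_value <- gof_pvalue(values, fit, n_bootstrap = n_bootstrap, seed = seed)
    fit$plausible <- fit$p_value > 0.1
    fit$n_bootstrap <- as.integer(n_bootstrap)
  }
  fit
}

#' Bootstrap goodness-of-fit p-value for a power-law fit
#'
#' Semi-parametric bootstrap: each replicate dataset of size `n` draws every
#' point, with probability `n_below / n`, uniformly from the observed values
#' below the fitted cutoff, and otherwise from the fitted discrete power law
#' at `(beta_hat, xmin)`. Each replicate is refitted with the same cutoff
#' search, and the p-value is the fraction of replicates whose refitted KS
#' distance is at least the observed one. Large p-values mean the observed
#' departure from a power law is unremarkable; `p > 0.1` is taken as
#' "plausible".
#'
#' @inheritParams mle_beta
#' @param fit A `pl_fit` produced by [fit_power_law()] (or a list with the
#'   same fields) for these `values`.
#' @param n_bootstrap Number of replicates (at least 1).
#' @param seed Integer seed; the same seed always yields the same p-value.
#'
#' @return The p-value, a number in `[0, 1]`.
#' @export
gof_pvalue <- function(values, fit, n_bootstrap = 1000, seed = 1L) {
  values <- assert_count_values(values)
  if (!is.numeric(n_bootstrap) || n_bootstrap < 1) {
    stop_gozipf("`n_bootstrap` must be at least 1.", "gozipf_error_domain")
  }
  n <- length(values)
  body_vals <- values[values < fit$xmin]
  p_body <- length(body_vals) / n
  draw_tail <- pl_sampler(fit$beta_hat, fit$xmin)
  min_tail <- fit$min_tail %||% 10
  withr::with_seed(as.integer(seed), {
    d_boot <- vapply(seq_len(n_bootstrap), function(b) {
      m <- rbinom(1, n, p_body)
      synth <- c(
        body_vals[sample.int(length(body_vals), m, replace = TRUE)],
        draw_tail(n - m)
      )
      sel <- select_xmin_impl(sort(synth), min_tail)
      if (is.null(sel)) return(NA_real_)
      sel$ks_distance
    }, numeric(1))
  })
  mean(d_boot >= fit$ks_distance, na.rm = TRUE)
}

#' Convert between the three equivalent heavy-tail exponents
#'
#' The rank-frequency (Zipf) exponent \eqn{\alpha}, the frequency-distribution
#' exponent \eqn{\beta} and the Pareto CCDF shape \eqn{k} describe the same
#' power law and are linked by \eqn{\beta = 1 + 1/\alpha}, \eqn{\alpha = 1/k}
#' and \eqn{\beta = 1 + k}. Supply exactly one of them; the other two are
#' derived.
#'
#' @param alpha Zipf rank exponent (> 0), or `NULL`.
#' @param beta Frequency power-law exponent (> 1), or `NULL`.
#' @param k Pareto CCDF shape (> 0), or `NULL`.
#'
#' @return A one-row tibble with columns `alpha`, `beta`, `k`.
#' @examples
#' convert_exponents(k = 1)        # alpha 1, beta 2
#' convert_exponents(beta = 2.04)
#' @export
convert_exponents <- function(alpha = NULL, beta = NULL, k = NULL) {
  given <- !c(alpha = is.null(alpha), beta = is.null(beta), k = is.null(k))
  if (sum(given) != 1) {
    stop_gozipf("Supply exactly one of `alpha`, `beta`, `k`.",
                "gozipf_error_domain")
  }
  if (!is.null(beta)) {
    if (beta <= 1) stop_gozipf("`beta` must exceed 1.", "gozipf_error_domain")
    k <- beta - 1
    alpha <- 1 / k
  } else if (!is.null(alpha)) {
    if (alpha <= 0) stop_gozipf("`alpha` must be positive.", "gozipf_error_domain")
    k <- 1 / alpha
    beta <- 1 + k
  } else {
    if (k <= 0) stop_gozipf("`k` must be positive.", "gozipf_error_domain")
    alpha <- 1 / k
    beta <- 1 + k
  }
  tibble(alpha = alpha, beta = beta, k = k)
}

#' Rank-frequency points for Zipf plots
#'
#' Extracts the classical Zipf representation (log frequency against log
#' rank) from a frequency table. No fitting is done on this representation —
#' the Pareto/CCDF form is used for estimation — but the plot is the
#' traditional way to eyeball the law.
#'
#' @param freq_table A frequency table from [term_frequencies()] (columns
#'   `term`, `freq`, `rank`).
#'
#' @return A tibble with columns `rank` and `frequency`, frequency
#'   non-increasing in rank.
#' @export
rank_frequency <- function(freq_table) {
  stopifnot(all(c("freq", "rank") %in% names(freq_table)))
  if (nrow(freq_table) == 0) {
    stop_gozipf("Frequency table is empty.", "gozipf_error_empty_input")
  }
  freq_table |>
    dplyr::arrange(.data$rank) |>
    dplyr::transmute(rank = .data$rank, frequency = .data$freq)
}

# methods -------------------------------------------------------------------

#' @export
print.pl_fit <- function(x, ...) {
  cat("Discrete power-law fit\n")
  cat(sprintf("  n = %d observations, tail n = %d (xmin = %d)\n",
              x$n, x$n_tail, as.integer(x$xmin)))
  cat(sprintf("  beta_hat = %.4f, KS distance = %.4f\n",
              x$beta_hat, x$ks_distance))
  if (!is.na(x$p_value)) {
    cat(sprintf("  bootstrap p = %.3f (%d reps, seed %d): power law %s\n",
                x$p_value, x$n_bootstrap, x$seed,
                if (isTRUE(x$plausible)) "plausible" else "rejected"))
  } else {
    cat("  goodness-of-fit not run (n_bootstrap = 0)\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pl_fit <- function(x, ...) {
  se <- (x$beta_hat - 1) / sqrt(x$n_tail)
  tibble(
    term = c("beta", "xmin"),
    estimate = c(x$beta_hat, x$xmin),
    std.error = c(se, NA_real_)
  )
}

#' @exportS3Method generics::glance
glance.pl_fit <- function(x, ...) {
  tibble(
    xmin = x$xmin, beta = x$beta_hat, n = x$n, n_tail = x$n_tail,
    ks_distance = x$ks_distance, p_value = x$p_value,
    plausible = x$plausible, n_bootstrap = x$n_bootstrap, seed = x$seed
  )
}
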