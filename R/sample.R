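# Inverse-CDF sampler for the discrete power law (zeta distribution).
# The pmf x^-beta / zeta(beta, xmin) is tabulated from xmin up to `cap`
# (stopping early once the residual tail mass drops below ~1e-12); whatever
# mass remains beyond the table is lumped onto the last entry. With the
# default cap of 1e6 the lumped mass is below ~5e-5 even at beta = 1.7.
pl_sampler <- function(beta, xmin, cap = 1e6) {
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 1) {
    stop_gozipf("`beta` must be a single number > 1.", "gozipf_error_domain")
  }
  xmin <- as.numeric(xmin)
  stopifnot(length(xmin) == 1, xmin >= 1, cap >= xmin)
  z <- hurwitz_zeta(beta, xmin)
  block <- 65536L
  support <- numeric(0)
  cum <- numeric(0)
  total <- 0
  lo <- xmin
  while (lo <= cap) {
    hi <- min(lo + block - 1, cap)
    xs <- lo:hi
    cs <- total + cumsum(xs^(-beta) / z)
    support <- c(support, xs)
    cum <- c(cum, cs)
    total <- cs[length(cs)]
    if (1 - total < 1e-12) break
    lo <- hi + 1
  }
  cum[length(cum)] <- 1 # lump residual tail mass at the cap
  function(n) {
    if (n == 0) return(numeric(0))
    support[findInterval(runif(n), cum) + 1L]
  }
}

#' Sample from the discrete power law
#'
#' Draws i.i.d. integers with \eqn{P(X = x) = x^{-\beta} / \zeta(\beta,
#' x_{min})} for \eqn{x \ge x_{min}}, by inverse-CDF lookup on a precomputed
#' cumulative table.
#'
#' @param n Number of draws.
#' @param beta Exponent, greater than 1.
#' @param xmin Smallest attainable value (default 1).
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @param cap Largest tabulated value; the tiny tail mass beyond it is
#'   lumped onto `cap` itself.
#'
#' @return An integer-valued numeric vector of length `n`, all `>= xmin`.
#' @examples
#' x <- sample_discrete_power_law(1000, beta = 2, seed = 42)
#' mean(x == 1) # close to 1/zeta(2) = 6/pi^2
#' @export
sample_discrete_power_law <- function(n, beta, xmin = 1, seed = NULL,
                                      cap = 1e6) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop_gozipf("`n` must be a positive count.", "gozipf_error_domain")
  }
  draw <- pl_sampler(beta, xmin, cap)
  if (is.null(seed)) draw(n) else withr::with_seed(as.integer(seed), draw(n))
}
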