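---
title: "Zipf's law in Gene Ontology annotation corpora: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zipf's law in Gene Ontology annotation corpora: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gozipf)
```

## The model

A collection of GO annotations can be read as a text written in a vocabulary
of GO identifiers: each annotation line contributes one token, and a corpus
is the multiset of tokens for one species, one sub-ontology (molecular
function, biological process or cellular component) and one evidence-code
class. Natural-language corpora famously obey Zipf's law,
$N(r) \propto r^{-\alpha}$: the frequency of the $r$-th most common
word falls off as a power of its rank. Equivalently, the proportion of
vocabulary items used with frequency $f$ follows
$P(f) \propto f^{-\beta}$, and the complementary cumulative distribution
is a Pareto law $P(X \ge x) \propto x^{-k}$. The three exponents are one
parameter seen three ways:

$$\beta = 1 + \frac{1}{\alpha}, \qquad \alpha = \frac{1}{k}, \qquad
\beta = 1 + k,$$

implemented in `convert_exponents()` and held to 1e-9 in the test suite.
Estimation works on the Pareto (CCDF) form because the rank-frequency curve
is noisy exactly where the information is — in the long tail of rarely used
terms — whereas the CCDF is monotone and well defined at every observed
frequency.

## Fitting procedure

The term-frequency values of a corpus are positive integers, so the package
fits the discrete power law
$P(X = x) = x^{-\beta} / \zeta(\beta, x_{min})$, where
$\zeta(\beta, x_{min})$ is the Hurwitz zeta normaliser (`hurwitz_zeta()`,
computed by Euler–Maclaurin summation to near machine precision; the
continuous MLE appears in the tests only, as an independent oracle). Three
steps, following the now-standard maximum-likelihood recipe for heavy-tailed
data:

1. **Exponent.** For a given lower cutoff `xmin`, `mle_beta()` maximises
   $\ell(\beta) = -n \ln \zeta(\beta, x_{min}) - \beta \sum \ln x_i$ over
   the tail by bounded scalar search on $\beta \in (1, 10]$, locating the
   maximiser to better than 1e-4.
2. **Cutoff.** Real term-frequency data are power-law only in the tail.
   `select_xmin()` tries every distinct observed value that keeps at least
   `min_tail` tail points (default 10, and at least two distinct values so
   the MLE exists) and keeps the cutoff whose fitted model minimises the
   Kolmogorov–Smirnov distance between empirical and model CCDF over the
   tail. KS ties break toward the smaller cutoff, i.e. the larger tail.
3. **Goodness of fit.** `gof_pvalue()` runs a semi-parametric bootstrap:
   each replicate draws, with probability `n_below / n`, from the observed
   sub-cutoff values and otherwise from the fitted power law, is refitted
   with the same cutoff search, and contributes its KS distance. The p-value
   is the fraction of replicates fitting at least as badly as the data;
   `p > 0.1` flags the power law as a plausible model. The default is 1000
   replicates; the suite's calibration checks use 250, which bounds the
   Monte-Carlo error of a p-value near 0.1 at about ±0.02.

`fit_power_law()` wraps the three steps and returns an object with
`tidy()`/`glance()` methods and a log-log `autoplot()`.

### Numerical choices

- The likelihood search interval (1, 10] covers every exponent seen in
  annotation or language data (empirically 1.5–2.6) with a wide margin;
  values at the upper boundary would indicate a degenerate tail, which is
  caught earlier (an all-equal tail raises a divergence error).
- The KS statistic is evaluated at the distinct observed tail values, with
  both distributions conditioned on $x \ge x_{min}$.
- Frequency ties in ranking break lexicographically by term id, making
  ranks, quartiles and therefore every downstream number deterministic.
- The bootstrap refit can, on rare degenerate replicates, have no admissible
  cutoff; such replicates are dropped from the p-value denominator rather
  than counted on either side.

## Evidence stratification and corpus accounting

Corpora are stratified with the standard evidence-code classes: high
confidence (IDA, IPI, IMP, TAS, EXP, IC, IEP, IGI — direct experimental or
curator support) and low confidence (IEA, electronic annotation only). Each
GAF line is one token, so a gene–term pair supported by two evidence codes
contributes two tokens; this matches how annotation totals are convention-
ally reported and makes per-line evidence filtering well defined. A
`dedupe` switch collapses repeated (gene product, term) pairs for users who
prefer type counts. NOT-qualified annotations assert what a gene product
does *not* do, so they are excluded by default (`exclude_negated = TRUE`).

## Depth analysis

Term depth is the length of the shortest `is_a` path from a term to the
root of its namespace (root depth 0). Shortest path on `is_a` only is the
conventional reading of "levels down from the root"; longest-path and
`part_of`-inclusive variants exist in the literature but change absolute
depths more than comparisons, and only `is_a` is guaranteed to stay within
a namespace. `quartile_depth_comparison()` takes the top and bottom
quartiles of distinct terms by usage frequency (quartile size
`floor(n/4)`, boundary ties resolved by the deterministic rank order) and
compares mean depths; `depth_significance()` runs a paired t-test across
corpora with the (top, bottom) means as the matched pair.

## Cross-corpus comparisons

`group_mean_beta()` averages fitted exponents within a sub-ontology;
`paired_t_test()` compares matched high- and low-confidence exponents
(two-sided by default; the one-sided value is exposed because the
directional hypothesis — stronger evidence, larger exponent — is usually
what is being asked); `size_exponent_association()` reports Spearman rank
correlations of the exponent with corpus size, where no association is the
interesting outcome. The packaged reference tables
(`goa_oct2009_fits()` and friends) carry the corpus sizes and published
fit results for the October 2009 GOA release across five species; the
underlying annotation snapshot is not redistributable, so those fits serve
as comparison inputs and regression anchors rather than as something the
package re-derives.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` draws one target frequency per term from the discrete
power law at `(beta_true, xmin)` — sampling the frequency distribution
directly, i.e. the Pareto-of-frequencies formulation the fitter assumes,
not a rank model — then emits annotation lines by sampling terms with
probability proportional to those frequencies, with evidence codes i.i.d.
from a configurable profile. Synthetic ids use the reserved pattern
`GO:9xxxxxx` so they cannot collide with real terms. With
`shallow_frequent_coupling` a balanced binary toy ontology is built and
larger frequencies are steered to shallower terms through a jittered depth
score (depth plus N(0, 0.75) noise), giving depth analyses a known but not
deterministic signal.

The sampler inverts a tabulated CDF capped at 1e6 (configurable); the
residual tail mass beyond the cap — about 4e-5 at $\beta = 1.7$, far
less at larger exponents — is lumped onto the cap itself.

Real GOA corpora differ from these simulations in ways that matter for
interpretation: annotation events are not independent draws (curation
proceeds gene by gene and paper by paper), evidence codes correlate with
terms rather than being i.i.d., the true frequency distribution is
power-law only in its tail, and the real GO DAG is neither balanced nor
binary. Passing the closed-loop tests therefore shows the estimator chain
is correct and calibrated, not that any particular real corpus follows a
power law — that question is what the goodness-of-fit machinery is for.

## Study conditions used by the test suite

The suite exercises the pipeline at sizes chosen to give the properties
sharp expectations: parameter recovery uses 20,000-point frequency samples
at $\beta_{true} \in \{1.7, 2.0, 2.4\}$ over 20 seeds (median absolute
error at most 0.05; 3-standard-error coverage at least 95%); bootstrap
calibration uses 200 null datasets of 100 points at 250 replicates each
(the fraction of p-values below 0.1 must lie in [0.04, 0.18]); the spliced
cutoff-recovery check mixes 2000 uniform noise points on {1..3} with a
2000-point tail from $x_{min} = 4$; depth coupling uses 20 corpora of
3000 annotations over 150 terms. Full-corpus recovery (annotation lines
rather than frequency values) is asserted at 3 standard errors because
multinomial token sampling adds noise on top of the frequency draw.

## Known limitations

- Only `is_a` edges are read from OBO input; `part_of` and regulatory
  relations are ignored throughout.
- No alternative heavy-tail models (lognormal, stretched exponential) are
  fitted, so "plausible" means "not rejected", never "best".
- Annotation propagation up the ontology (the true-path rule) is out of
  scope; tokens are the asserted terms as written.
- The multiple comparisons across sub-ontologies and evidence classes are
  reported unadjusted.
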