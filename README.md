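# gozipf

Gene Ontology (GO) annotation corpora read like texts written in a
vocabulary of GO identifiers: every annotation line is a token, and each
species × sub-ontology × evidence-class slice of an annotation set is a
corpus. `gozipf` analyses the term-usage statistics of such corpora the way
quantitative linguistics analyses word frequencies — via Zipf's law — and is
aimed at anyone studying annotation practice: ontology engineers, curators
of GOA-style resources, and bioinformaticians who want a calibrated
heavy-tail fit rather than a straight line through a log-log plot.

## The statistics at the core

If `N(r)` is the number of uses of the `r`-th most common term, Zipf's law
says `N(r) ∝ r^(−α)`. Equivalently the proportion of terms used with
frequency `f` follows `P(f) ∝ f^(−β)`, and the complementary cumulative
distribution is Pareto, `P(X ≥ x) ∝ x^(−k)`, with

```
β = 1 + 1/α,    α = 1/k,    β = 1 + k.
```

The package fits the discrete power law
`P(X = x) = x^(−β) / ζ(β, xmin)` (Hurwitz-zeta normalised) to the term
frequencies of a corpus by maximum likelihood, selects the lower cutoff
`xmin` by minimising the Kolmogorov–Smirnov distance between the empirical
and fitted tail CCDF, and attaches a semi-parametric bootstrap
goodness-of-fit p-value (`p > 0.1` ⇒ the power law is a plausible model).
Around that core sit GAF 2.x / OBO 1.2 readers, evidence-code
stratification (high-confidence experimental codes vs electronic-only IEA),
ontology term-depth analysis of frequent vs rare terms, cross-corpus
exponent comparisons, and a synthetic-corpus generator with known exponent
for end-to-end validation.

## Worked example

```r
library(gozipf)

# a synthetic corpus with known exponent beta = 2
sim  <- generate_corpus(corpus_spec(20000, 2000, beta_true = 2, seed = 42))
corp <- build_corpus(sim$annotations, aspect = "P", evidence = "ALL",
                     source_label = "sim")
ft   <- term_frequencies(corp)
fit  <- fit_power_law(ft$freq, n_bootstrap = 200, seed = 42)
fit
#> Discrete power-law fit
#>   n = 1736 observations, tail n = 872 (xmin = 3)
#>   beta_hat = 2.0875, KS distance = 0.0170
#>   bootstrap p = 0.425 (200 reps, seed 42): power law plausible
```

The fitter works on the 1736 distinct term frequencies, trims the noisy
sub-tail (`xmin = 3` keeps 872 of them) and recovers the generating
exponent (2.09, within sampling error of 2.0 given a standard error of
`(β̂−1)/√n_tail ≈ 0.037`); the bootstrap p-value 0.425 > 0.1 says a power
law is a plausible model, as it should be for data drawn from one.
`glance(fit)` returns the same numbers as a one-row tibble,
`autoplot(fit)` draws the log-log CCDF with the fitted line, and

```r
convert_exponents(beta = fit$beta_hat)
#> # A tibble: 1 × 3
#>   alpha  beta     k
#>   <dbl> <dbl> <dbl>
#> 1 0.920  2.09  1.09
```

gives the equivalent Zipf (α) and Pareto (k) exponents.

Cross-corpus comparison on the packaged October-2009 GOA survey tables —
high-confidence exponents against electronic-only ones, paired within
species × sub-ontology:

```r
t4 <- goa_oct2009_evidence_fits()
paired_t_test(t4$beta[t4$evidence_class == "HC"],
              t4$beta[t4$evidence_class == "LC"], alternative = "greater")
#> # A tibble: 1 × 5
#>       t    df p_value mean_difference alternative
#>   <dbl> <dbl>   <dbl>           <dbl> <chr>
#> 1  3.32     5  0.0105           0.417 greater
```

Evidence-filtered corpora differ systematically: high-confidence
annotation carries a larger exponent than electronic annotation
(mean difference 0.42, one-sided p ≈ 0.01).

`run_pipeline(run_config(...))` chains all stages (corpus building,
fitting, depth analysis, comparisons) over GAF/OBO files or synthetic
specs and `render_tables()` writes the TSV/JSON result bundle.

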