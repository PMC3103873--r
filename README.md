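# cenpois

Bayesian censored random-effects Poisson regression for administratively
censored disease counts.

## The problem

Agencies that release health or special-education counts by small geographic
unit routinely suppress low counts to protect privacy: a school district with
1–4 students in a category is released with a sentinel code (`-999`) instead
of its count, while exact zeros and counts of five or more are released as
is. In one much-analyzed setting — district autism counts regressed on
county mercury emissions — about a third of all districts are suppressed
this way. Substituting a fixed value for the sentinel rows, or deleting
them, biases the estimated exposure association and understates its
uncertainty; the defensible treatment is to give each suppressed record its
exact interval probability in the likelihood.

`cenpois` is for epidemiologists and biostatisticians who need that
treatment for count regressions with an offset and a grouping level. It
fits, by MCMC,

```
Pr(Y_i = y_i)   = exp(-λ_i) λ_i^y / y!          for y_i = 0 or y_i > 4
Pr(0 < Y_i ≤ 4) = Σ_{y=1..4} exp(-λ_i) λ_i^y/y!  for sentinel-coded records
log λ_i = log(size_i) + μ + b_{j(i)} + β₁ mercury_i + ... + β₇ other_i
b_j ~ N(0, σ₀²)
```

with priors `μ ~ N(-6, 10)`, `β_k ~ N(0, 100)` (mean/variance
parameterization) and `σ₀² ~ Uniform(0, 50)`. The reported quantity is the
relative risk `RR = exp(β₁)` per 1000 lbs of emissions, summarized from the
pooled post-burn-in draws with an equal-tailed 95% credible interval. The
naive substitution (c = 0…4) and exclusion treatments are implemented with
the same machinery for side-by-side comparison, and a calibrated synthetic
data generator emulates the released Texas-like data structure (≈1029
districts in 254 counties, ≈44% zeros, ≈35% suppressed, zero-inflated
right-skewed county exposure, censoring negatively associated with
exposure) with known ground truth for recovery studies.

## Worked example

```r
library(cenpois)

cfg <- texas_like_config(seed = 42, rr_mercury = 1.4)  # true RR = 1.4
d   <- generate_dataset(cfg)$data
summarize_counts(d)[c("total", "zero_fraction", "censored_fraction")]
#> $total
#> [1] 1009
#>
#> $zero_fraction
#> [1] 0.4222002
#>
#> $censored_fraction
#> [1] 0.3785927

fit <- cenpois(d, control = mcmc_control(n_iter = 6000, n_chains = 2, seed = 7))
fit
#> Hierarchical Poisson regression for censored counts
#>   method: censored likelihood;  1009 districts, 254 counties
#>   mercury RR (per 1000 lbs): 1.33  (95% CI: 1.04, 1.69)
#>   convergence: PASS (max R-hat 1.010)

run_comparison(d, control = mcmc_control(n_iter = 6000, n_chains = 2, seed = 7),
               methods = c("censored_likelihood", "substitute_0",
                           "substitute_3", "exclusion"))
#> Mercury RR per 1000 lbs, by censored-data treatment
#>  method              RR   95% CI      converged
#>  censored_likelihood 1.33 1.04, 1.69  yes
#>  substitute_0        6.32 2.90, 12.22 yes
#>  substitute_3        0.96 0.75, 1.23  yes
#>  exclusion           2.10 1.45, 3.02  yes
```

The censored-likelihood fit recovers the generative RR of 1.4 within its
interval. Zero substitution — treating every suppressed district as having
no cases — inflates the estimate more than four-fold, because the
suppressed districts concentrate in low-emission counties; substituting a
mid-interval value lands near the truth but with an interval that ignores
the suppression uncertainty; exclusion discards a third of the data and is
biased upward by the same selection. `summary(fit)` gives the full
parameter table with R-hat per parameter, `check_convergence(fit)` applies
the dual thresholds (1.01 for the mercury coefficient, 1.05 elsewhere),
`prior_sensitivity()` refits with the exposure prior recentered, and
`simulation_study()` replicates the whole contrast against ground truth.

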