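---
title: "Interval-censored disease counts: model, sampler and study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval-censored disease counts: model, sampler and study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

State education agencies release special-education counts by school district,
but suppress small counts to protect student privacy: a district with 1--4
students in a category is released with a sentinel code (here `-999`) instead
of its count, while exact zeros and counts of 5 or more are released as is.
Ecological regressions of such counts on environmental exposures — the
motivating case is district autism counts versus county mercury releases from
the Toxic Release Inventory — have commonly handled the sentinel rows by
substituting a fixed value (often zero) or deleting them. Both treatments
discard the one thing actually known about a suppressed district, namely that
its count lies in the interval $(0, 4]$, and both can bias the estimated
exposure association and understate its uncertainty.

`cenpois` implements the likelihood-based alternative: each suppressed record
contributes its exact interval probability to a hierarchical Poisson
regression, fitted by MCMC, alongside the naive substitution and exclusion
treatments so the three can be compared on equal terms.

## Model

For district $i$ in county $j(i)$, with released count $y_i$,

$$
\Pr(Y_i = y_i) = \frac{e^{-\lambda_i}\lambda_i^{y_i}}{y_i!}
  \quad\text{for } y_i = 0 \text{ or } y_i > 4,
$$
$$
\Pr(0 < Y_i \le 4) = \sum_{y=1}^{4}\frac{e^{-\lambda_i}\lambda_i^{y}}{y!}
  \quad\text{for sentinel-coded records},
$$
$$
\log\lambda_i = \log(\text{size}_i) + \mu + b_{j(i)}
  + \beta_1\,\text{mercury}_i + \beta_2\,\text{white}_i
  + \beta_3\,\text{taxbase}_i + \beta_4\,\text{econ}_i
  + \beta_5\,\text{urban}_i + \beta_6\,\text{suburban}_i
  + \beta_7\,\text{other}_i,
$$

with $b_j \sim N(0, \sigma_0^2)$ county random intercepts and log enrollment
as an offset, so the regression describes prevalence. Rural is the reference
urbanicity level. The quantity of interest is the relative risk
$\mathrm{RR} = e^{\beta_1}$ per 1000 lbs of reported mercury release.

Priors are weakly informative: $\mu \sim N(-6, 10)$,
$\beta_k \sim N(0, 100)$, $\sigma_0^2 \sim \mathrm{Uniform}(0, 50)$. Two
parameterization choices deserve comment, because common MCMC environments
use precision rather than variance:

* All normal priors here are mean/**variance**. Read as precisions these
  densities would be sharply informative, contradicting their intent, so the
  variance reading is used throughout.
* The uniform prior is placed on the variance $\sigma_0^2$ itself, not on
  $\sigma_0$, matching the model statement literally.

A prior mean of $-6$ for the intercept corresponds to a baseline prevalence
of $e^{-6} \approx 1/400$, the right order of magnitude for autism
special-education counts in the study period; with variance 10 it is only a
soft anchor.

## Sampler

The posterior is explored by adaptive random-walk Metropolis-within-Gibbs
(in C++ via Rcpp) over blocks: the intercept, each coefficient, each county
intercept, and $\sigma_0^2$. Numerical and design choices:

* **Centering.** All covariate columns are centered before sampling and the
  intercept is mapped back afterwards; this removes most intercept--slope
  correlation and changes nothing about the model or the reported draws.
* **Translation moves.** The exposure is a county-level covariate, so
  $\beta_1$ and the county intercepts are strongly confounded: adding $d$ to
  $\beta_1$ while subtracting $d\,\text{mercury}_j$ from every $b_j$ leaves
  every $\lambda_i$ unchanged. The sampler exploits this with two
  likelihood-invariant translation moves ($\mu$ against all $b_j$, and
  $\beta_1$ against $b_j$ whenever mercury is constant within county), whose
  acceptance ratio involves only the priors. Without them the mercury
  coefficient is the slowest-mixing parameter by an order of magnitude.
* **Adaptation.** Proposal scales follow a Robbins--Monro recursion toward
  44% acceptance during burn-in only; retained draws come from a fixed
  kernel, so the invariant distribution of the recorded chain is exactly the
  posterior.
* **Support handling.** $\sigma_0^2$ proposals outside $(0, 50)$ are
  rejected through the prior (no reflection). $\lambda_i = 0$ cannot occur:
  the offset is at least $\log 1$ and the predictor is finite.
* **Stability.** All likelihood terms are computed in log space; the
  censored interval term is a log-sum-exp over the four interval masses, and
  linear predictors are clamped at $\pm 700$ so no intermediate `exp`
  overflows even under wild early proposals.
* **Initialization.** Chain 1 starts at the reference point ($\mu$ at its
  prior mean, $\beta = 0$, $b = 0$, $\sigma_0^2 = 1$). Later chains start at
  small seeded perturbations of that point: the Gelman--Rubin diagnostic
  compares between- to within-chain variance and is more informative when
  chains do not share one starting point exactly. The perturbations are part
  of the seeded stream, so runs remain bit-reproducible.

Defaults mirror standard practice for this model class: 3 chains of 100,000
iterations, the first half discarded, convergence declared only when R-hat
is below 1.01 for the mercury coefficient and below 1.05 for every other
parameter (`check_convergence()`). Summaries pool chains after burn-in, and
the RR is summarized by applying $\exp$ to each $\beta_1$ draw, never to the
summaries; intervals are equal-tailed 2.5/97.5% posterior quantiles. These
are credible intervals; the term "confidence interval" in applied reports of
this model family refers to the same posterior quantities. Highest-density
intervals are not implemented.

Package tests and the bundled acceptance study run at reduced scale —
typically 1,500--8,000 iterations and 2 chains for the replicated studies,
with about 1,000 districts per dataset and 50 replications — which the
translation moves make sufficient: at 6,000 iterations the full-size model
already passes both R-hat thresholds.

## Synthetic data

No public accession exists for the original district-level dataset, so the
package ships a generator (`texas_like_config()`, `generate_dataset()`)
that emulates its released structure and provides ground truth for recovery
studies. One latent county score $u_j \sim N(0,1)$ ("industrial/urban
character") couples everything:

* counties have $1 + \mathrm{Poisson}$ districts (mean 4.05, tilted by
  $u_j$, about 254 counties and 1029 districts in total);
* county exposure is zero with probability 0.25 and otherwise a capped
  Gamma draw whose propensity is correlated with $u_j$ (emitting-county
  mean 0.288, maximum 1.579, in 1000-lbs units);
* district enrollment is log-normal with both its location and its spread
  increasing in $u_j$: rural counties have mid-sized districts of similar
  size, urbanized counties mix very small and very large districts.

The spread link is what reproduces the released data's signature: about 44%
exact zeros, about 35% suppressed counts, and a *negative* rank correlation
between a district's censoring indicator and county mercury. Suppressed
counts (1--4) come mostly from mid-sized districts, which dominate
low-emission counties, while high-emission counties contribute both the
large exactly-observed districts and many small zero-count ones. No explicit
censoring-given-exposure rule exists; the association is an emergent
property of the joint size/exposure calibration, as in the administrative
data it mimics. True parameters default to $\mathrm{RR} = 1.4$ per 1000 lbs
(the order of the published air-mercury estimate), modest covariate effects,
and $\sigma_0^2 = 0.2$; the intercept $-6.8$ was calibrated once, jointly
with the size distribution, to the released zero/censored fractions.

What the generator does *not* emulate: spatial correlation between
neighboring counties, temporal lags between emission and diagnosis, covariate
measurement error, and any non-Poisson overdispersion beyond the county
intercept. Recovery results on these data therefore validate the estimator
under its own assumptions; they do not certify the substantive published
estimates.

A consequence worth stating plainly: the generator's censoring--exposure
coupling is strong, so the naive treatments fail more dramatically here than
in the published real-data tables. Zero substitution converts a third of all
districts — concentrated in low-exposure counties — into fake zeros, which
both inflates the RR several-fold and inflates the random-effect variance;
its posterior intervals on the RR scale can then be *wide* as well as badly
mis-centered (coverage near zero), whereas the published real-data contrast
showed inflated-but-precise naive estimates. Mid-interval substitutions
(c = 2, 3, 4) reproduce the published pattern: nearly right central value,
artificially narrow interval. The simulation study reports all of this
per method (bias, RMSE, coverage with binomial Monte Carlo error, median
interval width) rather than asserting one story.

## Comparators and pipeline

`substitute_censored()` and `exclude_censored()` implement the naive
treatments; both leave uncensored records untouched and attach a provenance
label that every downstream report carries, so a transformed dataset can
never masquerade as source data. `fit_naive()` and `run_comparison()` fit
the naive treatments with the *same* Bayesian machinery as the censored
likelihood — a deliberate deviation from the frequentist mixed-model fits
used historically for the comparators, chosen so that differences between
rows of the comparison table isolate the censoring treatment rather than
mixing it with estimation-algorithm differences, which are known to be
material for these rare-count models. All seven fits in a comparison share
one base seed for the same reason.

`prior_sensitivity()` refits with the mercury prior recentered on
$\log(\text{RR}_0)$ for a user-chosen $\text{RR}_0$ (e.g. the naive
zero-substitution estimate) and reports both summaries; a small shift
relative to the interval width indicates the prior is not driving the
estimate. `simulation_study()` wraps the replicated recovery loop.

## Degenerate inputs and edge cases

* An empty dataset is legal everywhere: the likelihood is 0, so MCMC on it
  samples the prior — used as a correctness check (prior moments are known
  in closed form).
* Chains with zero variance make the classic R-hat formula 0/0; the
  diagnostic returns 1 (chains agree) or `Inf` (constant chains at distinct
  values) with a `degenerate` attribute instead of `NaN`.
* A dataset whose censoring has been resolved by substitution relaxes the
  validation rule that exact counts cannot lie in the suppressed interval;
  unresolved data with such counts are rejected as self-contradictory.
* Counties unseen during fitting predict with the population-mean intercept
  (zero).

## Reproducibility

Every stochastic path is seeded: `generate_dataset()` from its config seed,
`run_mcmc()` from the control seed (chains drawn sequentially from one
stream), and `simulation_study()` derives per-replicate seeds from the
config seed. Identical inputs give byte-identical outputs, including written
CSV/JSON files.
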