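---
title: "Compositional spike-and-slab regression: model, sampler and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional spike-and-slab regression: model, sampler and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bracod)
```

## The problem

Sequencing-based community profiles are compositional: per-sample read
counts only carry information about *relative* abundances, which sum to one.
Regressing a continuous physiological outcome (a short-chain fatty acid
concentration, an immune readout) on relative abundances with off-the-shelf
tools produces spurious associations, because an increase in one taxon
mechanically depresses all others. `bracod` addresses this with a fully
Bayesian linear regression in which the outcome depends on *absolute* log
abundances and the unobserved per-sample total is a latent variable that is
integrated out of the likelihood analytically, rather than removed by a
pre-transformation.

## Model

For sample $i$ with relative abundances $c_{ij}$ and outcome $y_i$:

$$y_i = \alpha + \sum_j \beta_j \log x_{ij} + \varepsilon_i, \qquad
  \log x_{ij} = \log c_{ij} + \log T_i,$$

with $\varepsilon_i \sim \mathrm{N}(0, \sigma^2)$ and latent log total
$\log T_i \sim \mathrm{N}(\mu_t, \sigma^2_t)$. Integrating $\log T_i$ out
gives an independent Gaussian likelihood per sample with mean
$\alpha + \beta^\top \log c_i + (\sum_j \beta_j)\,\mu_t$ and variance
$\sigma^2 + (\sum_j \beta_j)^2 \sigma^2_t$ (`log_marginal_likelihood()`).
Two consequences are used as correctness checks throughout the test suite:
when $\sum_j \beta_j = 0$ the total drops out entirely, and as
$\sigma^2_t \to 0$ the likelihood reduces to a fixed-total regression. The
closed form is verified against one-dimensional quadrature over the latent
total at every suite run.

Taxon selection uses stochastic search variable selection (SSVS). Each
taxon carries two coefficient copies and a binary indicator:

$$\beta_j = p_j\,\beta_{\mathrm{inc},j} + (1 - p_j)\,\beta_{\mathrm{exc},j},
 \qquad p_j \sim \mathrm{Bernoulli}(\pi),$$
$$\beta_{\mathrm{exc},j} \sim \mathrm{N}(0, \tau^2), \qquad
  \beta_{\mathrm{inc},j} \sim \mathrm{N}(0, g\,\tau^2),$$

with $\pi = 0.25$, $g = 500$ and a HalfNormal(0, 1) prior on the spike
scale. The posterior mean of $p_j$ is the inclusion probability
$\hat p_j$; the posterior mean of $\beta_{\mathrm{inc},j}$ is the reported
association strength $\hat\beta_{\mathrm{included},j}$.

### Priors and parameterization decisions

Several details are deliberate choices where more than one reading is
defensible; they are all configurable through `prior_config()`:

* **HalfNormal on $\tau$, not $\tau^2$.** The positive scale is sampled on
  the log scale with the Jacobian included, which keeps the support
  unconstrained without boundary pathologies.
* **$\mu_t = 0$, $\sigma^2_t = 1$** for the latent log total. The
  composition-cancellation property means results depend on these only
  through $\sum_j \beta_j$; sensitivity can be probed by re-running with
  other values.
* **Response standardization** (`standardize = TRUE` by default). The
  intercept prior N(0, 10²) and the HalfNormal(1) priors on $\sigma$ and
  $\tau$ are calibrated for a unit-variance response; coefficient summaries
  are rescaled back to the original units. Fitting unstandardized data with
  these priors is supported but only sensible when the response is already
  of order one.
* **$\hat\beta_{\mathrm{included}}$ averages all slab draws**, including
  draws in which the taxon was excluded (where the slab copy is a prior
  draw). This matches the estimator reported alongside $\hat p$ in the
  method's original description; a conditional-on-inclusion mean is
  available via `summarize_trace(conditional = TRUE)`.
* **Zero relative abundances** are replaced multiplicatively (half the
  smallest nonzero relative abundance in the table, then re-closure) before
  the log transform. Deterministic, configurable via `zero_policy`.

## Sampler

`run_chain()` uses a compiled Metropolis-within-Gibbs scheme:

* intercept: exact Gibbs (conditionally Gaussian);
* $\log\sigma^2$, $\log\tau$: adaptive random-walk Metropolis, with
  Robbins–Monro adaptation frozen at the end of burn-in so the retained
  chain has a fixed kernel;
* whichever coefficient copy is likelihood-active: independence
  Metropolis–Hastings from the conditional Gaussian obtained by holding the
  sample variance at its current value (the acceptance ratio corrects for
  the dependence of the variance on the coefficient sum);
* the inactive copy: exact Gibbs from its prior;
* indicators: Metropolised Gibbs flips in random sweep order, proposing the
  newly active coefficient jointly from the same conditional Gaussian (an
  add/delete move with a matched reverse-proposal density).

The data-informed flip proposal matters: naive flips that propose slab
values from the prior almost never accept once the spike scale has
concentrated, freezing the indicators. With the conditional proposal, flip
acceptance is typically 5–10% on community-scale problems and the sampled
inclusion probabilities match brute-force enumeration within 0.02 on small
problems (see the acceptance tests).

All randomness flows through R's RNG, so a fixed `seed` in
`sampler_config()` reproduces a trace bit for bit.

### Chain length

Defaults are 1000 burn-in and 1000 retained draws. A gradient-based sampler
would typically be well mixed at that length; the random-walk-plus-flips
kernel used here benefits from more, and the package's own burn-in
sensitivity diagnostic (`burn_in_sensitivity()`) and replicate-concordance
regression (`replicate_concordance()`) are the tools to judge it. The
benchmark experiments in the acceptance script run at 3000/3000 (and the
concordance check with more retained draws), sizes at which the selection
metrics plateau on 120-taxon problems; per-fit cost is a few seconds.

## Summarization and the cut point

`summarize_trace()` reports $\hat p$, $\hat\beta_{\mathrm{included}}$ (and
its posterior SD), mean relative abundance and a selection flag at the cut
point, default $\hat p \ge 0.3$ — the start of the broad performance
optimum on simulated communities (high accuracy, low false positive rate,
slowly declining sensitivity). The cut point is a user decision, not a
hypothesis test: `cutoff = 0` returns the complete ranked list, and
`autoplot()` of the summary reproduces the
$\hat\beta_{\mathrm{included}}$-versus-$\hat p$ diagnostic scatter on which
non-contributors cluster tightly around a near-zero coefficient.

## The community simulator

`make_dataset()` generates ground-truth-annotated communities in three
steps: lognormal absolute abundances (per-taxon means and SDs of log
abundance, optional pairwise log-scale correlations between designated
contributor/non-contributor pairs), a linear response with contributor
coefficients drawn Uniform(−5, 5) and non-contributors exactly zero, and
multinomial read counts at fixed depth after closure. Defaults are the
benchmark conditions used throughout: 119 samples, 20 contributors, 100
non-contributors.

Where the generating conditions were open, the package fixes them once:

* **Per-taxon lognormal parameters**, when not estimated from a real table
  with `estimate_lognormal_params()`, are drawn as
  $\mu_j \sim \mathrm{N}(0, 1.5^2)$ and
  $\sigma_j \sim \mathrm{U}(0.5, 2)$ — spreads typical of filtered 16S
  communities — and redrawn for any taxon whose expected relative abundance
  falls at or below the 0.1% abundance floor, mirroring the filter applied
  before estimating parameters from real data.
* **Sequencing depth** defaults to 100 000 reads per sample, the order of
  magnitude of the motivating rat dataset.
* **Response noise** defaults to 10% of the variance of the linear signal.
* **Response scale**: the default generates the outcome linearly in *log*
  absolute abundance so that the generative model matches the fitted model;
  `response_scale = "linear"` retains the literal linear-in-abundance
  variant for robustness experiments; under it the fitted model is
  misspecified, so benchmark numbers from the two regimes are not
  comparable.

What the simulator does *not* emulate: taxon-taxon interaction networks
beyond designated pairwise correlations, overdispersion beyond the
lognormal-multinomial composition, longitudinal structure, and real
taxonomies. Passing benchmarks on these communities therefore demonstrates
correct behaviour of the selection machinery under the stated generative
assumptions, not performance guarantees on arbitrary real datasets.

## Comparators and benchmarking

`clr_transform()` + `fit_clr_lasso()` implement the common
centred-log-ratio LASSO baseline (glmnet, $\lambda$ by cross-validation,
selection = nonzero coefficients). `fit_clr_ss()` is a standard Gaussian
spike-and-slab regression on column-standardized clr predictors — the same
SSVS machinery with the total-abundance marginalization switched off. Note
that published comparisons of this kind often use BoomSpikeSlab with its
own defaults (notably a much sparser expected model size); our clr-SS
shares the BRACoD priors instead, which makes it a stronger ranker than
that configuration, so its ROC numbers are not directly comparable to
published BoomSpikeSlab results even though its selection behaviour at the
0.3 cut (conservative: lower FPR and TPR than the compositional model)
reproduces the qualitative pattern.

`confusion_metrics()`, `roc_from_scores()`, `performance_sweep()`,
`correlated_discrimination_experiment()` and `benchmark_roc()` provide the
evaluation harness: exact integer confusion counting, threshold sweeps
(over $\hat p$ for the Bayesian methods, over $\lambda$ for the LASSO),
vertical ROC averaging across simulations, and the correlated-taxon
confusion experiment.

## Numerical choices and degenerate inputs

* The likelihood is evaluated in a single pass per proposal with
  incremental updates of the linear predictor; an exact recomputation every
  200 iterations prevents drift.
* Precision of selection summaries is limited by Monte-Carlo error of order
  $\sqrt{\hat p(1-\hat p)/\mathrm{ESS}}$; the replicate-concordance
  regression makes this visible.
* Fewer than 3 samples, zero-variance responses, all-zero sample rows,
  negative abundances, and non-finite log abundances are refused with
  errors naming the offending component. Ties at the cut point are
  included (selection uses $\ge$).
* `cutoff = 0` selects everything by design; raising the cutoff can only
  shrink the selection (a property-tested invariant).

## Known limitations

* The model is Gaussian in the response; heavy-tailed or bounded outcomes
  should be transformed first.
* With many taxa and weak data the Bernoulli(0.25) prior dominates: on a
  469-taxon community the prior alone expects ~117 inclusions, so selected
  sets at the 0.3 cut are larger than on 120-taxon communities. Lowering
  `inclusion_prob_prior` is advisable for very wide tables.
* The adaptive random-walk kernel needs longer chains than gradient-based
  samplers; budget 3000+ iterations for 100+ taxa.
* Correlated contributors with opposite signs can trade places between
  chains; the concordance diagnostic flags this.
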