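---
title: "Modelling non-response in black-box error-rate studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling non-response in black-box error-rate studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbmiss)
```

## The problem

Black-box studies present forensic examiners (latent print, firearms,
footwear, ...) with comparison items of known ground truth and estimate
error rates from their decisions.  In practice the resulting
examiner-by-item panels are riddled with missingness: enrolled examiners
who answer nothing (unit non-response), examiners who skip items (item
non-response), "no value" determinations, and "inconclusive" decisions.
Published error rates are usually computed on the answered items only,
with inconclusives counted as correct.  If the probability of answering an
item depends on whether the answer would have been an error — a plausible
selection effect when examiners can decline difficult comparisons — that
practice can understate the error rate by an order of magnitude.

bbmiss implements a family of beta-binomial hierarchical models that make
the missingness assumption explicit and quantify its consequences, using
nothing beyond per-examiner response and error counts.

## Data reduction

The unit of data is a decision record: one (examiner, item) pair with a
ground-truth label and a decision among *identification*, *exclusion*,
*inconclusive*, *no value*.  Within one ground-truth stratum
(different-source items for false positives; the machinery is symmetric
for same-source / false negatives), `build_panel()` reduces records to
per-examiner sufficient statistics

* `J` — items assigned,
* `R` — items with an observed binary decision,
* `E_obs` — observed errors,

under an explicit inconclusive policy: `as_correct_observed` counts an
inconclusive as an observed correct decision (the prevailing practice);
`as_missing` treats it as a non-response.  "No value" is missing under
both.  All models consume only `(J, R, E_obs)`; the likelihoods below
depend on the data through nothing else, which is why published count
tables are sufficient input when record-level data are withheld.

```{r panel}
study <- palmar_print_fixture(seed = 1)
panel <- build_panel(study$records, study$assignments,
                     policy = "as_correct_observed",
                     include_unit_nonrespondents = TRUE)
panel
```

## The models

Let $y_{ij}$ indicate an error by examiner $i$ on item $j$ and $r_{ij}$
indicate a response.  All probability parameters get Beta population
distributions in the mean/concentration parameterization
$\mathrm{Beta}(\mu\tau, (1-\mu)\tau)$.

**Naive** (complete-data comparator): $y_{ij} \sim \mathrm{Bern}(p_i)$ on
answered items only, $p_i \sim \mathrm{Beta}(\mu_p\tau_p,(1-\mu_p)\tau_p)$.

**Ignorable**: adds $r_{ij} \sim \mathrm{Bern}(\pi_i)$ with its own beta
population, independent of the $y$ process.  Point inference on error
rates barely moves relative to the naive model; uncertainty shrinks.

**Non-ignorable** (selection model): the response probability depends on
the would-be outcome,
$r_{ij}\,|\,y_{ij}=0 \sim \mathrm{Bern}(\pi_{1i})$ and
$r_{ij}\,|\,y_{ij}=1 \sim \mathrm{Bern}(\pi_{2i})$.
The observed-data likelihood marginalizes the unanswered items:
$$
\prod_i \binom{J_i}{R_i}\binom{R_i}{E_i}
  (p_i\pi_{2i})^{E_i}\,((1-p_i)\pi_{1i})^{R_i-E_i}\,
  \bigl[p_i(1-\pi_{2i})+(1-p_i)(1-\pi_{1i})\bigr]^{J_i-R_i}.
$$

Fully Bayesian fitting of the non-ignorable model with flat priors is
fragile — the hyperparameters are weakly identified and mix poorly when
non-response is heavy and correlated with errors — so the supported route
is empirical Bayes: `fit_eb_mle()` maximizes the marginal likelihood of
the observed data (all $p_i$, $\pi_{1i}$, $\pi_{2i}$ integrated out; each
examiner contributes a finite sum over the unknown number $z_i$ of errors
among unanswered items), and `fit_nonignorable_eb()` samples the
examiner-level probabilities conditional on the fixed estimates.

## Samplers and numerical choices

The samplers are bespoke conjugate Gibbs / data-augmentation schemes
rather than a generic slice-sampling engine: every full conditional in the
non-ignorable model is an exact Beta or Binomial draw, which avoids the
numerical fragility that motivates truncated priors in off-the-shelf
engines and makes each conditional testable against enumeration oracles.
Specifics worth knowing:

* **Hyperparameter updates** (naive/ignorable models) are joint
  random-walk Metropolis moves of $(\mu, \tau)$ on the (logit, log) scale
  with the appropriate Jacobian.  The proposal scale adapts toward a
  0.2–0.45 acceptance rate during burn-in only and is frozen afterwards,
  preserving detailed balance for retained draws.
* **Priors** default to $\mathrm{Beta}(1,1)$ on means and
  $\Gamma(\mathrm{shape}=2, \mathrm{rate}=0.5)$ on concentrations, with
  support truncated to $\mu \in (0.001, 0.999)$, $\tau > 0.001$.
* **Marginal likelihood**: the inner $z$-sum is always computed exactly
  (at most $J_i - R_i + 1 \le 23$ terms per examiner in the motivating
  design) via log-sum-exp, with Beta functions through `lgamma`.
  Examiners are first aggregated to unique $(J, R, E)$ triples, which
  makes each evaluation effectively free even at thousands of examiners.
* **Optimization** runs on unconstrained (logit $\mu$, log $\tau$)
  coordinates, Nelder–Mead from 20 dispersed starts by default,
  stratified so that $\mu_{\pi_2}$ begins both near 0 and near
  $\mu_{\pi_1}$: the surface is multimodal when response and error rates
  are correlated, and sparse-error panels push $\mu_{\pi_2}$ (and
  sometimes $\mu_p$) toward the truncation boundary.  Estimates within
  $10^{-3}$ of a bound are reported with a boundary flag rather than
  silently clamped.
* **Probability draws** are clamped to $[10^{-12}, 1-10^{-12}]$ so log
  densities stay finite when a concentration is tiny.
* **Degenerate inputs**: an examiner with $J = R = E = 0$ contributes
  exactly zero to every likelihood; `empirical_error_rate()` refuses
  examiners with $R = 0$ rather than returning 0/0.
* Reports round percentages half-to-even to one decimal, and machine
  outputs always retain full-precision fractions alongside.

Chain defaults mirror the published analysis protocol: 2 chains,
15 000 iterations / 5 000 burn-in for the naive and ignorable models, and
40 000/10 000 (inconclusives observed) or 60 000/10 000 (inconclusives
missing) for the non-ignorable model.  Convergence is assessed by
nonoverlapping batch-means Monte Carlo standard errors (threshold 0.01 on
every monitored probability) and the Brooks–Gelman multivariate potential
scale reduction factor (threshold 1.1, relaxed to 1.2 for the
non-ignorable model); when the pooled covariance is singular the
diagnostic falls back, flagged, to the maximum univariate PSRF.

## Error-rate inference

The quantity reported to courts is a study-level error proportion.
`pe_predictive()` simulates, per posterior draw, the error counts of a new
study with the same assignment/response pattern:

* naive: $E_i \sim \mathrm{Bin}(R_i, p_i)$, denominator $\sum R_i$;
* ignorable: $E_i^{obs} \sim \mathrm{Bin}(R_i, p_i\pi_i)$ plus
  $E_i^{mis} \sim \mathrm{Bin}(J_i - R_i, p_i(1-\pi_i))$, denominator
  $\sum J_i$;
* non-ignorable: the same with $\pi_{2i}$ in both roles.

One predictive replicate per posterior draw keeps the draw count
interpretable, and the error counts are re-drawn rather than conditioned
on their observed values: the predictive describes a replicate study, not
the realized one.  Intervals are equal-tailed.  `clopper_pearson()`
provides the exact frequentist baseline that published studies report.

```{r fit, eval = FALSE}
eb <- fit_eb_mle(panel)
draws <- fit_nonignorable_eb(panel, eb$hyper,
                             default_chain_config("nonignorable",
                                                  "as_correct_observed"))
pe_predictive(draws)
```

## The synthetic generator

`generate_study()` simulates the full generative process — examiner-level
probabilities from their Beta populations, latent error indicators,
response indicators under an `mcar`, `ignorable`, or `nonignorable`
mechanism — and returns records, assignments, and the latent truth.  A
relabelling layer turns a configurable fraction of responded items into
inconclusive / no-value decisions, independent of the latent error status
by default, with an optional ratio knob that concentrates inconclusives
on error items for sensitivity studies.  Randomness flows through
per-examiner substreams, so enlarging a study extends it without
perturbing earlier examiners.

`palmar_print_fixture()` emulates the dimensions and missingness regime of
the motivating palmar-print study (226 examiners, 22 different-source
items each) with non-ignorable truth near the hyperparameter estimates
reported for that study.  It is a synthetic stand-in: the real
record-level data are not redistributable, so study-specific model
outputs (the 8.4% / 28.4% predictive error proportions, the exact MLEs)
are *not* reproduced by the fixture — only the study's structure,
sparse-error regime, and roughly half-missing response pattern.

What the generator deliberately does not emulate: the crossed design in
which the same physical items circulate among examiners (no shared
item-difficulty structure), correlated same-source/different-source
skill, and examiner covariates.  Tests passing on synthetic panels
therefore validate the estimators under the models' own assumptions; they
cannot validate those assumptions against real examiner behaviour.

## Validation regimes and problem sizes

Two generative regimes matter in the test suite and are worth recording
as deliberate choices:

* **Recovery regime** (`mu_p = 0.3, tau_p = 2, mu_pi1 = 0.8, tau_pi1 = 8,
  mu_pi2 = 0.2, tau_pi2 = 8`, $I = 2000$, $J = 22$): dispersed examiner
  error rates with moderately separated, well-concentrated response
  blocks.  Here the marginal likelihood identifies the hyperparameters,
  and the empirical-Bayes MLE recovers $\mu_p$ and $\mu_{\pi_1}$ to
  within 15% relative error while ordering $\mu_{\pi_2} < \mu_{\pi_1}$.
  Regimes with tightly concentrated error probabilities reproduce instead
  the weak $p$/$\pi_2$ identifiability that the motivating analysis
  reports (observed errors constrain mainly the product $p\,\pi_2$);
  recovery there is not expected and not asserted.
* **Fixture regime** (above): used for end-to-end and reproducibility
  checks, not for parameter recovery.

Validation runs are scaled to stay exact where exactness is cheap and
Monte Carlo where it is not: oracle comparisons for the marginal
likelihood use panels with $J \le 6$ against completion-enumeration and
quadrature integration; sampler checks use 2–3 examiner toys with
20 000–30 000 iterations (Monte Carlo error well under the 0.01
tolerance); recovery uses 20 replicate studies at $I = 2000$ with 6
optimization starts each; demonstration fits in scripts use 6 000
iteration chains on the 226-examiner fixture.

## Limitations

* The empirical-Bayes route propagates no uncertainty from the
  hyperparameter estimates into the posterior; with boundary-flagged
  MLEs the examiner-level posteriors should be read as conditional
  sensitivity analyses, not calibrated inference.
* Inconclusives are handled by policy, not modelled; the two policies
  bracket rather than resolve their contribution.
* Unit and item non-response are pooled, as in the analyses the package
  mirrors; modelling them separately needs auxiliary data the models
  deliberately avoid requiring.
* A fully Bayesian non-ignorable fit (sampling all six hyperparameters)
  is intentionally not part of the supported surface; with flat priors it
  is known to fail exactly where this package is most useful.
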