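---
title: "Evaluating a graded-response item bank with grmbank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a graded-response item bank with grmbank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grmbank)
```

## The measurement model

`grmbank` evaluates banks of ordered-category items under Samejima's
graded response model (GRM). Each item $j$ has a discrimination $a_j > 0$
and strictly increasing thresholds $b_{j1} < \dots < b_{j,K-1}$ on the
latent-trait ($\theta$) metric. The probability of responding above
category $k$ is logistic,

$$P^*_{jk}(\theta) = \frac{1}{1 + \exp\{-a_j(\theta - b_{jk})\}},$$

with scaling constant $D = 1$ — a deliberate, verifiable convention: for
an isolated threshold the maximum item information equals $a^2/4$ under
$D = 1$, and the packaged bank's published information maxima match that
identity (e.g. $5.47^2/4 = 7.48$ for `EDANX05` against a reported peak of
7.49), which rules out the $D = 1.7$ normal-ogive approximation. Category
probabilities are adjacent differences of the $P^*$ curves; they are
nonnegative and sum to one for any valid item at any $\theta$, and both
facts are asserted as invariant tests.

The trait is identified by fixing the population distribution to
N(0, 1); item parameters are then expressed in population-SD units.

## Pipeline stages and their decision rules

`run_pipeline()` chains the stages a bank evaluation conventionally
reports, each exposed as a standalone function with its decision rule as
an explicit, overridable argument:

* **Classical reliability** — Cronbach's α (raw covariance form,
  n−1 denominators, listwise deletion with the dropped count logged;
  criterion α > 0.70), α-if-item-deleted, and corrected item-rest
  correlations (criterion r > 0.40). The *rest* score is the default
  because the uncorrected item-total correlation is inflated by
  self-correlation; the uncorrected variant sits behind
  `corrected = FALSE`.
* **Unidimensionality** — KMO (anti-image formula from the inverse
  correlation matrix), Bartlett's sphericity test, and the ratio of the
  first two principal-component roots of the Pearson correlation matrix
  of the raw ordinal codes, with pass rule $\lambda_1/\lambda_2 > 3$.
  Pearson-on-raw-codes is the default deliberately — it reproduces the
  arithmetic general-purpose statistics software performs — rather than a
  polychoric analysis that would model the ordinality more faithfully but
  answer a different question.
* **Local independence** — Yen's Q3: residuals of the observed score
  against the model-expected score at each person's EAP $\theta$,
  correlated across item pairs; pass when all |Q3| < 0.70. The rule is
  applied to absolute values, and the known small negative bias of Q3
  under local independence (mean ≈ −1/(J−1)) is itself a test. Q3 is one
  of several constructions that could sit behind the phrase "residual
  correlations"; the choice is recorded in the report metadata.
* **Monotonicity** — mean item score conditional on quantile-binned rest
  scores (bins merged to hold at least 30 persons); a bin-to-bin decrease
  larger than 0.05 score units flags the item. The 0.05 tolerance absorbs
  binomial noise at the minimum bin size where a visual inspection rule
  offers no numeric criterion.
* **Calibration and screening** — MML-EM estimation (below), then the
  three bank-quality rules: a > 0.50, all |b| < 10, and
  adjacent-threshold intervals within [0.81, 5].
* **Model fit** — a limited-information $M_2$-type statistic on the
  univariate means and bivariate product moments of the responses, with
  RMSEA, and CFI/TLI computed against the zero-association model on the
  same moment set (conventional cutoffs: RMSEA < 0.06, CFI/TLI > 0.95).
  The moment-based variant is used because the full contingency-table
  statistic for 23 five-category items would require a moment vector in
  the thousands; on this moment set the zero-association model is
  identified through the item means only, which fixes its degrees of
  freedom at (number of moments − J).
* **DIF** — per item, three nested proportional-odds models (matching;
  + group; + matching × group). Uniform DIF is the LR test of the group
  main effect, non-uniform of the interaction, each on 1 df. Flags use
  p < 0.05 without multiplicity correction, and *practical* salience uses
  McFadden ΔR² ≥ 0.02 (both changes and their sum), mirroring the
  two-tier logic in which statistically detectable DIF can still be
  negligible in magnitude. The default matching variable is the
  standardized rest score — it needs no calibration and avoids
  circularity from the studied item; EAP matching is a flag. No iterative
  purification is run by default (single pass, the simplest auditable
  choice); both choices are arguments.

## Estimation details

The marginal likelihood integrates $\theta$ over a fixed N(0,1) prior on
a rectangular grid of 61 equally spaced nodes on [−6, 6] with
renormalized normal weights. A dense rectangular grid is robust to the
spiky, occasionally multimodal posteriors that high-discrimination items
produce, and the same grid serves EAP scoring and curve tables.

EM cycles alternate an E-step (posterior node weights per person,
missing responses skipped — never imputed) with per-item M-steps in
slope/intercept form $a\theta + d_k$ ($d_k = -a b_k$): Newton updates
with a finite-difference Hessian of the analytic gradient, step-halving,
and rejection of any step that breaks threshold ordering or takes
$a \le 0$ (at most 25 inner iterations). Starting values are $a = 1$ and
$d_k$ from the inverse logit of the marginal cumulative category
proportions, which are monotone by construction. The EM stops when the
largest absolute change in any reported parameter falls below 1e-4 or at
500 cycles; the per-cycle marginal log-likelihood trace is stored and its
monotone non-decrease is asserted in the tests. Guards: samples below 100
persons are refused; discriminations diverging past 50 are capped and
flagged; categories never observed for an item are collapsed with their
neighbour before fitting, with the remap logged (thresholds of empty
categories are unidentified). Optional standard errors come from the
empirical cross-product of per-person analytic score contributions.

Probability floors (1e-300 in likelihoods, 1e-10 in M-step ratios) keep
all arithmetic finite without perturbing any quantity above rounding
level.

## Information reporting and near-tied peaks

Item information is $I(\theta) = \sum_k P_k'^2/P_k$; the summary table
reports each item's maximum, its location, and $I(0)$ (a medium trait
level). The maximum is located by exhaustive evaluation on a 0.1-step
grid over [−4, 4] — peak locations are conventionally printed to one
decimal, which is exactly a 0.1-grid output, and gradient methods are
unreliable on the multimodal information curves of high-discrimination
graded items. Exact ties break toward the smaller $\theta$.

One subtlety is handled explicitly: an information curve can have two
local peaks whose heights differ by less than what two-decimal rounding
of $a$ and $b$ can resolve (for `EDANX53`, 6.6458 at $\theta = -1.1$
versus 6.6350 at $\theta = -2.3$). For such curves the *location* of the
global maximum is not identifiable from rounded parameters — a
sub-rounding perturbation can move it by more than a full $\theta$ unit —
so `max_information()` also returns the set of near-tied local peaks
(heights within `tie_tol = 0.02`, i.e. two print units, of the maximum),
and comparisons of peak locations against published tables should be
made against that set. Peak *heights* are unaffected and are compared
directly.

Test information is the plain sum of item informations with no prior
term — the convention under which the packaged bank's information-at-zero
column sums to its published test-information maximum — and the
"highly informative range" is reported as the explicit numeric rule
$T(\theta) \ge 10$ (conditional SE ≤ 0.316) rather than a visual band.

## The synthetic-data generator

`simulate_responses()` draws $\theta_i$ from N(mean, sd²) and each
response from the item's category probabilities at $\theta_i$; a single
mandatory seed drives the whole simulation through a local RNG scope, so
identical seeds give identical data and the caller's RNG state is never
touched. True traits are returned as an attribute, never written into
response files, so they cannot leak into pipeline tests.
`simulate_study()` produces the canonical study-shaped dataset: 1075
persons, the 23 packaged items, $\theta \sim$ N(0,1), and three
dichotomized covariates drawn independently of $\theta$ at the study
proportions (age 64.5/35.5, gender 38.0/62.0, education 47.0/53.0).

DIF is injected by answering selected items from a modified focal-group
bank: a uniform shift adds a constant to all thresholds, non-uniform DIF
scales the discrimination. Covariates are independent of $\theta$ by
default ("no impact"); a group mean-shift knob exists separately so that
simulation studies can distinguish impact from DIF.

What the generator does *not* emulate: real response styles (extreme or
midpoint responding), missing-data mechanisms, minor secondary
dimensions, or a non-normal trait distribution in the sampled clinic
population. Passing pipeline tests on simulated data therefore
demonstrates that the software computes its statistics correctly under
the model's own assumptions — not that any particular real dataset
satisfies those assumptions.

## Problem sizes used in the test suite

The suite calibrates one full study-shaped dataset (1075 × 23) and
checks parameter recovery against the generating bank (discriminations
within 15% relative RMSE, central thresholds |b| < 2 within 0.15
absolute RMSE). DIF operating characteristics use 200 null replicates at
n = 1000 (ΔR² ≥ 0.02 in fewer than 1% of item tests; anchor-item LR
p-values uniform by a Kolmogorov–Smirnov check at α = 0.01) and 50 power
replicates with a 0.75-unit uniform shift at roughly 1000 persons per
group (detection in at least 90%). Fit-index behaviour is checked on
12-item sub-banks: RMSEA near zero for correctly specified data and
clearly larger when two independent traits are forced into one GRM.

## Known limitations

* No linking or equating to an external reporting metric (T-scores), and
  no computerized-adaptive-testing engine; the package evaluates and
  calibrates banks that such systems consume.
* The unidimensionality check is a principal-component heuristic, not a
  confirmatory factor model; polychoric-based analysis is available as an
  option but is not the default.
* The proportional-odds DIF models use the rest score as an observed
  matching proxy for $\theta$; with very short banks this proxy is noisy
  and EAP matching is preferable.
* Wording text in the packaged bank is stored verbatim as published,
  including one apparent typo ("I felt fearly.", `EDANX01`).
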