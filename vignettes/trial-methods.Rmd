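---
title: "Methods: randomised-block biocontrol trial statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: randomised-block biocontrol trial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blisstrial)
```

This vignette documents the statistical models behind `blisstrial`, the
assumptions they make, the choices taken where the methodology was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## The trial design

The package targets randomised-block field trials against the large pine
weevil *Hylobius abietis*: each block contains one stump per treatment
(untreated control, full-dose entomopathogenic fungus, full-dose
entomopathogenic nematode, and a combined half-dose mix, "halfmix"), and
three data streams are collected per trial — per-stump season totals of
emerging adults (emergence traps), record-level destructive-sampling data
(one row per weevil found under the bark: developmental stage, infection
outcome, depth, distance to the bole), and trap-by-taxon counts of
non-target invertebrates.

## Contingency analysis

Associations between infection outcome and treatment (or developmental
stage) are tested with the uncorrected Pearson chi-square on the
cross-tabulated counts. Per-cell departures are reported as standardized
residuals $Z_{ij} = (O_{ij} - E_{ij})/\sqrt{E_{ij}}$, flagged against
$\pm 1.96$; their squares sum to the chi-square statistic, an identity
the test suite asserts on random tables. The effect size is Cramér's V,
$\sqrt{\chi^2 / (n \cdot \min(r-1, c-1))}$.

Choices worth stating:

* **Pearson rather than margin-adjusted residuals.** Both are in common
  use under the name "standardized residual". The Pearson form is the
  default here (it reproduces the published Z matrices of the motivating
  trial); the margin-adjusted form
  $(O-E)/\sqrt{E(1-p_{r})(1-p_{c})}$ is available via
  `residual_type = "adjusted"`.
* **No Yates correction**, matching standard practice for r×c tables.
* **Zero margins are an error, not a silent drop.** Removing an empty
  category changes the degrees of freedom; the caller must opt in with
  `drop_empty = TRUE`.

## Bliss independence synergy testing

For a combined treatment of two agents, Bliss independence is the null
model in which the agents kill independent fractions, so survival
probabilities multiply:

$$I_{Bliss} = I_{EPF} + I_{EPN} - I_{EPF} \cdot I_{EPN}.$$

The observed combined-arm infection rate $I_{NF}$ is compared with this
expectation through
$\chi^2_{Bliss} = (I_{NF} - I_{Bliss})^2 / I_{Bliss}$ on 1 df, and the
synergy score $S = I_{NF} - I_{Bliss}$ is classified by sign (strictly by
default; `tolerance` widens the additive band).

Two aspects of the procedure are conventions rather than consequences of
the data, and both are exposed as options:

* **Half-dose rates.** Trials of this design usually have no
  half-dose-alone arms, yet the Bliss formula wants half-dose agent
  rates. The default convention scales linearly — half the full-dose
  any-death rate — which is the convention under which the motivating
  trial's published expectation reproduces exactly. `"full"` (use the
  full-dose rates unchanged) gives a deliberately conservative
  sensitivity analysis.
* **Mortality definition.** `any_death` counts every non-alive outcome,
  including indeterminate deaths, in the numerator (again the
  reproducing definition); `agent_specific` restricts to the matching
  agent's kills.

A property of this statistic that users should understand: it divides a
squared difference of *proportions* by a proportion and never sees the
sample size, so under a true Bliss null it is far smaller than a
$\chi^2(1)$ variate and its p-values concentrate near 1 rather than
being uniform. The package's null simulations assert what does hold —
the synergy score is centred on zero — and treat the test as what it is:
a very conservative deviation screen, not a calibrated hypothesis test.
Degenerate input $I_{Bliss} = 0$ with $I_{NF} > 0$ is a defined failure
(the statistic is unbounded) rather than an infinity.

Block-level runs estimate all rates within each block and skip — with a
warning, never silently — blocks missing any of the three required arms.

## Emergence modelling

Per-stump season counts are modelled as NB2 negative binomial with log
link: $y \sim \mathrm{NB}(\mu, \theta)$,
$\mathrm{Var}(y) = \mu + \mu^2/\theta$, with
$\log \mu = \beta_0 + \beta_{treatment} + b_{block}$. Treatment is coded
against the control, so $e^{\beta_t}$ is the relative emergence ratio.
Two block modes:

* `block_mode = "fixed"` (default): block indicators, exact ML via
  `MASS::glm.nb`. Fully deterministic and transparent — but note that
  with one nuisance coefficient per block the likelihood-ratio test of
  the treatment effect is anti-conservative at trial-scale designs
  (tens of blocks, four observations per block).
* `block_mode = "random"`: Gaussian random block intercept integrated
  out by the Laplace approximation (`glmmTMB`, NB2 family). This mirrors
  the GLMM formulation used in field-trial practice and is the mode
  whose LRT holds its nominal size in the package's simulations; it is
  therefore what the calibration tests use.

The treatment effect is tested by the likelihood ratio
$\chi^2 = 2(\ell_{full} - \ell_{null})$ on the difference in parameter
count; a statistic materially below zero is treated as an optimiser
failure, not truncated silently. Estimated marginal means are
response-scale predictions per treatment — averaged over the observed
blocks in fixed mode, evaluated at a block effect of zero in random mode
(a median-block, not population-average, prediction; the distinction is
deliberate and documented on the function) — with delta-method standard
errors, cross-checked in the test suite against a parametric bootstrap
and against `emmeans`.

Dunnett-style many-to-one contrasts use the classical max-|Z|
adjustment: the adjusted p-value is
$P(\max_j |Z_j| \ge |z_i|)$ for a zero-mean multivariate normal with the
contrasts' estimated correlation. This probability is evaluated by
seeded Monte Carlo (default $10^4$ draws, add-one estimator) rather than
closed-form equicoordinate quantiles: the Monte Carlo route is
dimension-agnostic and directly testable against the Šidák closed form
at identity correlation. Monte Carlo noise could leave an adjusted
p-value a hair below its unadjusted value, so adjusted values are
floored at the unadjusted ones.

Groups with all-zero counts warn: their coefficients diverge toward
$-\infty$ and standard errors are unreliable; nothing is clipped.

## Non-target community analysis

Distances between traps default to **Sørensen** (Bray–Curtis on
presence/absence), the documented default of the analysis software
traditionally used for MRPP; Bray–Curtis on counts and Euclidean are
selectable. A pair of all-zero traps has an undefined Bray–Curtis
distance; it is defined as 0 with a warning.

**PCoA** double-centres $-\tfrac12 D^2$ and eigendecomposes;
co-ordinates are eigenvectors scaled by $\sqrt{\lambda}$ for positive
eigenvalues. Negative eigenvalues (expected for Sørensen) are reported,
their axes dropped, and no Cailliez/Lingoes correction is applied — for
ordination plots of the first few axes the uncorrected embedding is the
conventional choice. On a Euclidean distance matrix the embedding is
exact: the test suite asserts the round trip to $10^{-9}$.

**MRPP** compares the weighted mean within-group distance
$\delta = \sum_g (n_g/N)\, \bar d_g$ with its permutation null (random
relabelling preserving group sizes; default 9,999 permutations, seeded).
The chance-corrected within-group agreement is
$A = 1 - \delta_{obs}/\delta_{exp}$ — 0 in expectation under random
grouping, 1 for identical within-group units — and the p-value uses the
add-one estimator $(1 + \#\{\delta^* \le \delta_{obs}\})/(1 + B)$, which
can never be exactly zero. Group weights $n_g/N$ are the default, with
$(n_g-1)$ weighting behind a flag. The implementation is validated three
ways: against exhaustive enumeration of all label splits on 6-item
instances, against an independent implementation (`vegan::mrpp`), and
against the null property $\mathrm{E}[A] \approx 0$.

Abundance/richness comparisons use the classical one-way ANOVA F test.

## The synthetic-data generator

Because raw data from such trials are typically unpublished, the
generator produces datasets with exactly the statistical structure the
analyses assume — and only that:

* **Destructive records**: a complete block × treatment layout with
  Poisson per-stump weevil totals; stage and outcome drawn from
  configured multinomials (outcome per treatment); depth from a
  per-outcome normal location model (below-ground means, so a small
  positive tail remains possible, matching field records of weevils
  above ground level); distance to bole as a zero-inflated exponential
  (field medians sit at 0).
* **Emergence counts**: NB2 draws around
  $\mu = e^{\beta_0 + b_{block} + \log RR_t}$, block effects shared
  across treatments within a block.
* **Community matrices**: independent Poisson counts with per-taxon
  means times a per-treatment multiplier (1 = null, no compositional
  signal).

Default parameter values live in a versioned JSON file
(`inst/extdata/sim-defaults.json`). The outcome and stage probabilities
are the exact count fractions of the motivating trial's published
cross-tabulations (the printed percentages round-trip to 1.001 and would
violate the simplex invariant; the counts are their source). Emergence
rate ratios (0.468, 0.393, 0.322) are the trial's fitted relative
emergence ratios. Values no trial report states were chosen once, on
field-realism grounds, and are not tuned: 10 blocks (the
destructive-sampling design), 10 weevils per stump (≈ 400 weevils over
40 stumps), control emergence mean $e^{\beta_0} = 10$ adults per trap
per season, block SD 0.3 on the log scale (block-to-block emergence
varying roughly ±35%), NB dispersion $\theta = 2$ (strong
overdispersion typical of insect counts), depth SD 8 cm, distance
zero-inflation 0.6, and 12 broad taxa with mean abundances between 2
and 30 per trap.

Reproducibility: one root seed; each dataset draws from its own derived
substream (fixed dataset index), so generating or skipping one dataset
never perturbs another. Identical configurations give identical outputs,
a property asserted at byte level for the whole pipeline.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: spatial structure among stumps, seasonal
phenology, within-stump correlation of infection outcomes,
non-independence between taxa in community samples, trap failures, and
any dose–response mechanism linking the infection-rate and emergence
streams. Tests validate the statistical machinery, not the biology.

## Problem sizes and numerical choices

The validation suite chooses sizes that make Monte Carlo error small
relative to the tolerance being asserted while keeping the suite quick:
frequency convergence at $10^5$ records, rate-ratio recovery at 500
blocks (±0.05), LRT size at 1,000 null replicates of 20 blocks
(nominal 0.05, accepted in 0.03–0.08), MRPP null behaviour over 200
simulated communities (mean A within ±0.02 of 0), Šidák cross-checks at
$2\text{–}4 \times 10^5$ Monte Carlo draws. Probability vectors are
validated to $10^{-9}$; chi-square identities to $10^{-12}$ (relative);
the perfect-separation MRPP example uses two clusters of eight traps so
that the chance of a permutation tying $\delta^* = 0$ is negligible and
the add-one p floor $1/(1+B)$ is attained exactly.

## Known limitations

* The Bliss deviation statistic's p-value is conservative by
  construction (see above); a calibrated alternative (e.g. a binomial
  test of the combined arm against $I_{Bliss}$) is out of scope because
  the goal is the field's published procedure.
* Outlier-exclusion reruns of emergence models are not reproduced: no
  exclusion rule is published.
* Fixed-block LRTs at small block counts are anti-conservative; use
  `block_mode = "random"` for calibrated tests.
* The mark–recapture stream of such trials is purely descriptive
  (recaptures too sparse to test) and is not modelled.
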