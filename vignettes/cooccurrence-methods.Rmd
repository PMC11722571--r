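---
title: "Methods: co-occurrence of epiphytes and lianas on host trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence of epiphytes and lianas on host trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lianepi)
```

## The problem

Lianas (woody climbers) and vascular epiphytes both depend on trees for
structural support, yet they are usually surveyed and analysed
separately. `lianepi` implements a complete co-occurrence analysis for
census data in which every tree at or above the 10 cm dbh threshold is
recorded together with the liana stems (diameter ≥ 1 cm at 130 cm from
the rooting point) and epiphyte species (Braun-Blanquet cover classes
1–5, where 1 = 1–5 % up to 5 = 76–100 %) it carries, across forest
patches of ten 20 × 20 m plots classified as successional or mature.
The analysis asks four questions at four scales:

1. **Tree zone, tree and patch scale** — do the two guilds occupy the
   same trunks/crowns, the same trees within diameter classes, and the
   same patches?
2. **Host models** — do forest type and tree size explain richness,
   liana basal area and epiphyte cover, once host-tree species
   heterogeneity is absorbed?
3. **Interaction networks** — which species pairs actually meet?
4. **Spatial association** — are liana-host and epiphyte-host trees
   spatially attracted or repelled once tree size and species are
   accounted for?

## Scale summaries and tests

"Host" always means carrying at least one record of the guild,
regardless of zone. At the tree scale, `contingency_by_class()` builds
a 2 × 2 presence/absence table per dbh class (default breakpoints
13.15, 19.75, 33.76 cm — near-quartiles of the kind of stand the
package targets) and applies the continuity-corrected (Yates)
chi-square, \(\sum (\max(|O-E|-0.5,\,0))^2/E\), with 1 df. The
correction is clamped at zero so perfectly proportional tables give a
statistic of exactly 0. A flag disables the correction. Exact dbh ties
at a breakpoint go to the upper class so the classes partition
\([10, \infty)\).

Shared-host percentages use the *union* denominator,
\(100\,s/(l+e-s)\): the share of trees hosting either guild that host
both. Zone-scale counts treat each liana record as one occurrence in
its single recorded zone, and each epiphyte record as one occurrence in
*each* zone it occupies.

Patch- and zone-scale comparisons use a negative-binomial (NB2)
log-link GLM on per-plot counts (`nb_group_contrast()`), with the
dispersion estimated by maximum likelihood. Under NB2 the group-mean
MLEs equal the sample means, so the contrast estimate is always the log
ratio of group means — a property the tests exploit as a closed-form
oracle; z and p are Wald statistics and depend on the dispersion. On
severely underdispersed fixtures the theta iteration may fail; the fit
then falls back to the Poisson limit (theta = ∞), which leaves the
estimate unchanged and is flagged in the output. P-values are
two-sided and unadjusted, matching per-patch reporting practice.

## Host models

Four Bayesian mixed models relate per-tree responses to forest type and
dbh with a host-tree-species random intercept:

| response | family |
|---|---|
| liana species richness | hurdle-Poisson |
| epiphyte species richness | hurdle-Poisson |
| total liana basal area (m²) | hurdle-lognormal |
| epiphyte cover class (1–5) | cumulative logit |

The hurdle is a logistic model for Pr(zero) with the same covariates;
the positive part is a zero-truncated Poisson (renormalised by
\(1-e^{-\lambda}\)) or a lognormal, which needs no truncation. The
cover model is fitted on colonized trees only — the cover scale is
undefined for trees without epiphytes — with the per-tree response
taken as the maximum recorded class; its cutpoints absorb the
intercept. dbh is z-scored before fitting for sampler stability, and
`tidy()` reports the slope on both the standardised and per-cm scales.
The hurdle sub-model carries fixed effects only; because the two hurdle
parts factor in the likelihood, this does not affect the positive-part
estimates.

Priors are weakly informative: normal(0, 2.5) on coefficients on the
standardised scale, normal(0, 5) on cutpoints, half-normal(0, 1) on the
species-intercept scale and half-normal(0, 2.5) on the lognormal scale.

Sampling uses an adaptive random-walk Metropolis-within-Gibbs scheme
written for exactly these likelihoods: scalar updates touch only the
likelihood factor they affect (hurdle vs positive part, one species'
rows for its intercept), proposal scales adapt toward 44 % acceptance
during warmup only, the species scale uses a multiplicative proposal,
and an exact Gibbs "recentering" step resolves the intercept /
random-intercept (or cutpoint / random-intercept) ridge by sampling the
likelihood-invariant shift from its Gaussian full conditional. Defaults
are 4 chains × 8000 iterations (half warmup); convergence is declared
when every parameter has split-Rhat < 1.01 and ESS > 1000 (summed over
chains), and a failing fit is flagged with a warning rather than an
error. The exposed `host_loglik()` is the same code path the sampler
uses, so the test suite can pin it against numeric-summation oracles.

## Interaction networks

Three weighted bipartite matrices: liana × tree weighted by total basal
area; epiphyte × tree weighted by occupied zones (1 or 2 per record —
only trunk and crown are recorded, with a config hook for finer
schemes); epiphyte × liana weighted by the number of trees hosting both
species, computed over doubly-colonized trees only (summed occurrences
are available as an option, since either reading is defensible).
Rankings break ties by weight descending, then name ascending, for
determinism. Totals are conserved by construction — matrix sums equal
record-level sums — and the tests verify this on simulated stands. No
network-level indices (nestedness, modularity) are computed.

## Spatial association

Within a fully mapped contiguous block (0.36 ha of nine 20 m plots in
the emulated design), trees are a marked point pattern: locations fixed,
liana-host and epiphyte-host status as marks. `ring_k()` computes the
translation-corrected Ripley K (exact for rectangular windows, mirrored
by the brute-force test oracle) and returns *ring-differenced* values
\(K(r) - K(r-w)\) with 2 m rings, which remove the cumulative
autocorrelation of K; under complete spatial randomness each ring has
expectation \(\pi(r^2-(r-w)^2)\). Cross-type versions take one guild's
hosts as foci and the other's as targets; trees hosting both guilds
belong to both sets but are never paired with themselves. The default
radii run 1 m steps from 2 to 14 m — the interesting structure sits
below ~7 m and the maximum is bounded by half the window side.

The null model is covariate-adjusted random labelling: a logistic model
`presence ~ dbh + species` is fitted for the reshuffled mark (falling
back to dbh-only if a species separates the mark perfectly), and each
of the 10 000 simulations reassigns the mark by weighted sampling
*without* replacement with the fitted probabilities as weights. This
conditions on the observed number of hosts, as random-labelling
practice does; independent Bernoulli draws are available as an option.
Envelopes are pointwise alpha/2 and 1 − alpha/2 quantiles per radius
(alpha = 0.05 by default) with an exceedance flag. The two cross
directions (epiphytes around lianas, lianas around epiphytes) are run
as two independent analyses, each reshuffling one guild. Point
intensity is never resimulated.

## The synthetic stand generator

`generate_stand()` emulates the survey design so every stage is
testable without field data: 12 patches (8 successional, 4 mature) of
ten 20 × 20 m plots; per-plot tree locations from a Poisson (or Thomas
cluster) process at 0.044 trees/m² (≈ 2100 trees per stand); dbh from a
lognormal truncated to [10, 120] cm (meanlog 2.85/3.05, sdlog 0.70/0.75
by forest type — the upper bound keeps giant-tree artefacts out of the
response models and matches real census ranges); guild colonization
from per-tree logistic probabilities with a per-cm dbh slope, a mature
offset and a tree-species offset. Colonization intercepts are
calibrated numerically (quadrature over the dbh distribution, species
pool and patch mix) so the expected host fractions are 34 % for lianas
and 52 % for epiphytes — the survey-level rates this design emulates.

Conditional on colonization, the positive responses are drawn from the
same families the host models fit, which makes parameter recovery
well-posed: richness from a *zero-truncated* Poisson (we deliberately
use the truncated form rather than 1 + Poisson: with a shifted Poisson
the fitted truncated-Poisson slope estimand differs from the generating
slope and recovery checks would test a misspecified model); total liana
basal area from a lognormal, split across stems by resampled Gamma
shares so that every stem stays above the 1 cm threshold without
perturbing the drawn total (clamping instead would bias the abundance
model upward at small totals); cover classes from a latent-logistic
variable cut at fixed cutpoints. Defaults reproduce the survey's
headline descriptives: per-host median liana richness 1, epiphyte
richness 2, mean per-tree liana basal area ≈ 0.0025 m², modal cover
class 1.

Species-level heterogeneity enters through a `quality` offset shared by
all positive-part responses. Its values are deliberately uncorrelated
with the species' successional affinity: if canopy dominants of mature
stands were also the highest-quality hosts, the forest-type effect
would be partially confounded with species composition and a 12-species
random intercept cannot fully separate the two — a generator for
recovery testing must keep the estimands clean. Liana climbing
mechanism is a species attribute, and specialized climbers get a
dbh-dependent bonus when species are assigned to colonized trees, so
the "specialized lianas co-occur with epiphytes on big trees" pattern
is reproducible. Epiphyte zones are crown-biased (25 % trunk-only,
45 % crown-only, 30 % both); within-tree vertical structure beyond
trunk/crown is not modelled because the census records only those two
zones.

What the generator does *not* emulate: real species lists, spatial
autocorrelation of colonization beyond covariates, multi-stem merging
rules (each record is one stem), temporal dynamics, or observation
error in ground-based cover estimates. Passing recovery tests therefore
show the estimators work when the model is true; they do not validate
the model against real forests.

## Numerical choices and problem sizes

- The ring-K machinery precomputes the pair structure (distances,
  translation weights, annulus bins) once per pattern, so a
  10 000-simulation envelope on a 120-tree block runs in seconds.
- Recovery tests use six-patch stands (~1000 trees) and 4 chains × 2000
  iterations per fit — enough for stable central 95 % intervals, which
  is what the recovery criterion uses; full-length 4 × 8000 runs are
  the analysis default.
- The chi-square wraps `stats::chisq.test` (whose clamped-Yates formula
  is identical); the test suite pins it against an explicit formula.
- Degenerate inputs have defined behaviour: empty dbh classes give zero
  tables and NA tests, an all-zero count group is a separation error,
  fewer than two marked points an error, a zero-margin 2 × 2 table a
  degenerate-table error, and an envelope under deterministic (0/1)
  fitted probabilities collapses to zero width.
- One irreconcilable reporting artefact in the kind of published table
  this pipeline mirrors: a text statement of "exclusive" liana hosts
  can conflict with the per-patch shared counts; the patch summaries
  therefore report exclusive counts exactly as computed from the data
  and make no attempt to match such statements.

## Known limitations

- The sampler is a random-walk scheme: for very small effective sample
  sizes per parameter it flags non-convergence rather than switching to
  gradient-based methods; extremely unbalanced designs (one forest
  type) drop the forest effect with a warning.
- The translation edge correction is exact only for rectangular
  windows; irregular plot unions are approximated by their bounding
  rectangle.
- Cover is modelled per tree (maximum class); per-species covers on the
  same tree are not modelled separately.
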