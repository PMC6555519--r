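---
title: "Allometric models of bee mouthpart length: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allometric models of bee mouthpart length: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeallometry)
```

## The scientific problem

A bee's functional tongue length — the proboscis, defined as the summed
lengths of the glossa and the prementum — governs which flowers it can
drink from, and its body size governs how far it can forage. Both traits
are laborious to measure: the proboscis must be dissected out of fresh
specimens, and foraging distance can only be observed in the field. Body
size, by contrast, is cheap: the intertegular distance (IT, the span
between the wing tegulae, in mm) can be measured on any pinned museum
specimen and is a standard proxy for dry body mass.

`beeallometry` implements the interspecific allometric machinery that
connects the cheap trait to the expensive ones: it fits and AIC-selects
log–log regressions of species-mean mouthpart length on species-mean IT
across bee families, converts the winning regression into an allometric
power function

$$L = e^{a_f} \cdot \mathrm{IT}^{\,b},$$

with a family-specific intercept $a_f$ and scaling exponent $b$ (all logs
natural), and applies that function — together with separately published
log10–log10 body-size regressions for foraging distance — to museum
species tables. A phylogenetic comparative layer then asks whether body
size is structured by an environmental factor (here, rainfall-seasonality
regions) while controlling for shared ancestry.

## The candidate model set and its selection

For each response (proboscis, glossa, prementum) seven ordinary
least-squares models of $\ln L$ on $\ln \mathrm{IT}$ are fitted to
species-level means:

| grouping | IT term |
|---|---|
| family | common slope (additive) |
| family | family-specific slopes (interaction) |
| family | none |
| tongue group (short/long) | common slope |
| tongue group | group slopes |
| tongue group | none |
| none | slope only |

Species means (not specimens) are the regression units; each specimen
enters its species mean with equal weight. The sexes are pooled by
default: a specimen-level F test (`test_common_slope_by_sex()`) comparing
`ln L ~ species + sex * ln IT` with the additive model checks the pooling
assumption, and a `sex_filter` is retained for single-sex reanalysis.
Listwise deletion is applied before fitting so that all seven candidates
see the identical species set — AIC values are only comparable on a fixed
dataset.

The log-likelihood is the Gaussian ML value with the error variance
profiled out, $\ell = -\tfrac{n}{2}(\ln 2\pi + \ln(\mathrm{RSS}/n) + 1)$,
and $\mathrm{AIC} = -2\ell + 2(k+1)$, counting the residual variance as a
parameter. This is the convention under which `stats::AIC` evaluates
linear models, and the convention required to reproduce published
selection tables from this line of work. Exact AIC ties are broken toward
the smaller model, then by the fixed candidate order above. A numerically
perfect fit (RSS at machine zero, which zero-noise synthetic data
produces by design) is reported as an explicit $-\infty$ AIC sentinel
with a warning rather than as a fragile large negative number.

Grouping factors are treatment-coded against a fixed alphabetical
reference (Andrenidae; "long" for tongue group). The published tables in
this literature report *absolute* per-family coefficients, so
`parameterize()` always emits reference-plus-offset sums, with the common
slope replicated across families for additive winners and per-family
slopes for interaction winners.

### A note on AIC's selection rate

When the generating model is the additive family model, the interaction
model contains it and AIC prefers the superset whenever
$n\ln(\mathrm{RSS}_{add}/\mathrm{RSS}_{int}) > 2\,\Delta k$. With six
families ($\Delta k = 5$) and roughly 110 species this is the event
$F_{5,\,n-12} > 1.87$, which has probability $\approx 0.11$ *regardless
of the noise level*. A simulation study should therefore expect the true
additive structure to win in roughly 89% of replicates, not more — the
residual 11% is an intrinsic property of AIC, not an estimation failure;
the recovered coefficients remain consistent either way, which is why
coefficient recovery is tested on the parameterized best model whichever
candidate wins.

## Trait and foraging-distance prediction

`predict_length()` evaluates the power function exactly
($\ln$-linear in $\ln \mathrm{IT}$, multiplicative in IT:
$L(c\cdot\mathrm{IT}) = c^b L(\mathrm{IT})$). The package bundles the
published six-family coefficient table (`published_coefficients()`):
proboscis and glossa scale with common exponents 0.96 and 1.04, the
prementum with family-specific exponents (0.45 for Melittidae).

Foraging (homing) distance follows the published form
$\log_{10}(\mathrm{km}) = c_0 + c_1 \log_{10}(\mathrm{IT})$ for a
"typical" and a "maximum" distance. Those regression constants are *not*
bundled: the source publication distinguishes several distance
categories, the primary text this package accompanies does not reprint
the constants, and shipping guessed values would be worse than shipping
none. `foraging_coefficients()` therefore requires the user to transcribe
$c_0$, $c_1$ and the IT unit (the literature mixes mm and cm, so the unit
is an explicit config field with conversion handled internally). All
package tests use clearly synthetic configurations.

Region summaries use multi-membership counting: a species contributes to
every rainfall region its records fall in, so per-region species counts
may sum to more than the species total (e.g. 89 memberships over 56
species in the motivating dataset).

## The phylogenetic comparative layer

The working phylogeny starts from a genus-level backbone. Pruning keeps
the induced subtree and carries any dropped root-to-MRCA path as a root
edge, so root-to-tip distances are preserved exactly. Species are then
attached to their genus tip as a polytomy: a genus terminal edge of
length $\ell$ becomes a stem of $\ell/2$ ending in a fan of species tips
of length $\ell/2$. The published description of this construction
("equal branch lengths relative to the genus branch") is ambiguous about
where the split falls; the midpoint is the choice that preserves both
ultrametricity and tip depths, which any defensible reading requires, so
it is adopted here. A single-species genus is renamed rather than split —
the two trees are indistinguishable in every path length.

Under Brownian motion the expected trait covariance of two tips is
$\sigma^2 V_{ij}$ with $V_{ij}$ the shared root-to-MRCA path length.
`pgls_fit()` computes the GLS estimate
$\hat\beta = (X^\top V^{-1}X)^{-1}X^\top V^{-1}y$ by whitening with the
Cholesky factor of $V$ and running OLS on the transformed problem; a
numerically singular $V$ receives a documented diagonal jitter of
$10^{-10}$ (logged, never silent). On a star phylogeny $V \propto I$ and
the entire PGLS/ANOVA stack collapses to ordinary OLS and classical
one-way ANOVA — a property the tests assert exactly. The region effect is
tested by an F statistic on whitened residual sums of squares with
conventional degrees of freedom $(g-1,\, n-k)$ for a $g$-level factor.
(The motivating study prints $F_{(1,3)}$ for a four-level factor over 56
species; that df pair is not reproducible under any standard ANOVA
convention, so the conventional df are reported instead.)

Species spanning several regions need a single label for modeling: the
region holding the majority of the species' records wins, ties resolved
by the fixed order winter < aseasonal < early summer < late summer.

Because the grafted polytomies carry no real branch-length information
below the genus level, a second, phylogeny-free approach complements
PGLS: a linear mixed model of $\ln \mathrm{IT}$ with random intercepts
for genus nested in tribe nested in subfamily, fitted by *maximum
likelihood* (not REML) so the region model and its intercept-only null
are comparable by AIC and likelihood-ratio test. Boundary (zero) variance
components are reported, not treated as failures; at the boundary the LMM
log-likelihood equals the OLS log-likelihood exactly, which is used as a
correctness check.

## The synthetic-data generator

Every stage is testable without external downloads because the generator
reproduces the statistical structure the analysis assumes, at the study's
own conditions:

* **Specimens** — species-mean IT drawn log-uniformly on 0.99–4.42 mm
  (the observed museum range; log-uniform keeps the slope estimate
  well-conditioned across the range), mouthpart lengths
  $\ln L = a_f + b_f \ln \mathrm{IT} + \varepsilon$ with independent
  Gaussian noise (sd 0.1 on the ln scale, consistent with species-mean
  models explaining $\sim$98% of proboscis variance) on glossa and
  prementum, and the proboscis re-derived as their sum *after* noise —
  matching the measurement definition rather than noising the sum.
  Within-species body-size spread is not modelled: all specimens of a
  species share its IT. Defaults: ~110 species across the six families,
  up to 10 specimens per species (the unit-tray sampling cap used in
  museum series), generating coefficients equal to the published table.
* **Museum table** — 56 Melittidae species over the real seven-genus,
  five-tribe, three-subfamily taxonomy, with a deterministic multi-region
  membership pattern hitting the observed per-region counts
  (44/13/12/20); for other table sizes the counts are rescaled by
  largest-remainder apportionment.
* **Trees** — Yule (pure-birth) trees conditioned on tip count,
  ultrametric by construction; default backbone: 7 genera, birth rate 1.
* **Traits** — Brownian tip values with rate $\sigma^2 = 0.1$ around a
  root state of $\ln 2.58$ (the museum mean IT), plus optional additive
  region shifts; the default shift is zero everywhere, i.e. the null the
  field data supported.

All generators are pure functions of (config, seed) and restore the
caller's RNG state.

What the generator deliberately does *not* emulate: within-species IT
variation, measurement error correlated between glossa and prementum,
unbalanced and taxonomically clustered sampling, museum digitization
artifacts, and non-Brownian trait evolution. Passing tests therefore
demonstrate correctness of the estimators under the assumed model, not
robustness of the scientific conclusions to violations of it.

## Numerical choices and problem sizes

* OLS via QR (`lm.fit`); rank deficiency and $n \le k$ are hard errors.
* Perfect fits: RSS below $10^{-12}\times$ the response's total sum of
  squares triggers the $-\infty$ AIC sentinel.
* PGLS whitening via Cholesky; $\log|V|$ from the factor's diagonal.
* Simulation-based checks use sizes chosen to estimate the tested rates
  to adequate precision in seconds-to-minutes on one core: 200 random
  designs for the OLS oracle, 100 replicates of the 108-species
  end-to-end recovery, 500 Brownian-null replicates on a 40-tip tree for
  the PGLS type-I rate, 100 random backbones for the tree-surgery
  properties, and 25 replicates of a 496-observation nested design
  (62 subfamilies × 2 tribes × 2 genera × 2 species) for LMM
  variance-component recovery. The LMM recovery is asserted on the
  standard-deviation scale (components 1.0/0.5/0.25): at this design size
  the top-level *variance* estimate has a relative sampling sd of
  $\sqrt{2/62} \approx 18\%$, so a 25% variance-scale band could not be
  met reliably by any correct estimator, while the sd-scale band halves
  the relative error and yields a sharp, achievable check.

## Known limitations

* The seven-model candidate set is fixed; no measurement-error or
  reduced-major-axis alternatives (deliberately out of scope — the
  downstream power-function usage assumes OLS coefficients).
* PGLS supports only the Brownian error structure; no Pagel's λ or OU.
* The polytomy graft assumes the backbone's genus terminal edges are
  meaningful; if they are not, the LMM route is the appropriate one.
* Foraging-distance predictions are only as good as the transcribed
  regression constants and extrapolate outside the IT range those
  regressions were built on.
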