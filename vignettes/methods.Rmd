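---
title: "Methods: farmland bird communities along an intensity gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: farmland bird communities along an intensity gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(farmbird)
```

## The scientific setting

Farmland birds respond to agricultural intensity, and the shape of that
response — convex (losses concentrated at low intensities) versus concave —
decides where conservation effort buys the most. `farmbird` implements a
complete analysis chain for this question: a continuous intensity indicator at
the level of small agricultural regions (SARs), species- and community-level
trait indices computed from standardised breeding-bird point counts, a
neighbourhood aggregation statistic for intensity, and regression models that
estimate the response shape and an intensity-by-aggregation interaction.

Because the underlying national survey and farm-accounting data are not
redistributable, the package ships a synthetic generator that emulates their
statistical structure; every stage is exercised and tested end to end on
generated data.

## Species and community indices

Three species-level indices summarise a species' ecology:

* **SSI** (habitat specialisation): the coefficient of variation of the
  species' density across the seven survey habitat classes (forest,
  heath/scrub, marshland, farmland, urban, wetland/aquatic, rocks). A
  generalist scores 0; a species confined to one class scores $\sqrt 7$.
* **STI** (trophic index): diet proportions of seeds/plants, invertebrates and
  vertebrates weighted 1, 2, 3; range $[1, 3]$.
* **SSIg** (grassland specialisation): abundance-weighted mean over the four
  farmland sub-habitats with weights 4 (unimproved grassland), 3 (improved
  grassland), 2 (mixed), 1 (arable); range $[1, 4]$.

The packaged 22-species community table (`farmland_species()`) is the
reference for all community computations. Community descriptors are
abundance-weighted means, e.g.

$$\mathrm{CSIg} = \sum_i \frac{N_i}{N_\mathrm{tot}}\, \mathrm{SSIg}_i,$$

over the 22 species; richness counts the species present. The SSI standard
deviation uses the sample ($n-1$) denominator by default — the usual CV
convention in this literature — with a population-sd variant behind a flag.
When computing SSI from survey records, per-point densities are averaged
within each habitat class first and the CV is taken across the seven class
means; species absent from a class contribute density 0, not a missing value.

## Survey aggregation rules

The point-count protocol drives several fixed rules, each implemented as its
own function so it can be tested in isolation:

1. sites need at least five farmland point counts; sites with more get five
   selected uniformly at random, **once per site** (the same points in all
   years, for comparability across years);
2. per point, species and year, the maximum of the two spring visits is kept
   (a missing visit counts 0);
3. the five per-point maxima are summed within the year;
4. yearly abundances are averaged over the years the site was actually
   surveyed, so sites surveyed fewer times are not down-weighted. A species
   unrecorded in a surveyed year contributes zero to its average.

A site in which no community bird was recorded keeps richness 0 and flagged,
undefined composition indices. Distance bands are accepted on input but
summed; no detectability correction is applied.

## The intensity indicator and its aggregation

**IC/ha** sums seven input-cost categories (fertilizers, feedstuff,
pesticides, seeds, fuel, veterinary products, irrigation water; Euros) over
the farms of a region and divides by their summed utilised area (ha). Only
five production types enter (industrial crops, cereals, bovine dairy, bovine
meat, mixed); vegetables, granivore livestock, wine and orchards are excluded
before any computation. The regional ratio is computed per year as a
ratio-of-sums (area-weighted — robust to many small farms; a mean-of-ratios
variant is selectable) and then averaged over the three accounting years to
damp price and stock fluctuations. Regions qualify only when the five types'
area strictly exceeds two thirds of the total agricultural area; the
comparison is done as `3 * area > 2 * total` so the boundary is exact in
floating point.

The **aggregation index** of region $i$ is
$$AI_i = X_i - \frac{\sum_j w_{ij} X_j}{\sum_j w_{ij}},$$
with $w$ the binary contiguity matrix: the gap between a region's intensity
and its neighbours' mean. Small $|AI|$ means the region sits in a block of
similar intensity. The published verbal rule for calling a region
"aggregated" is ambiguous, so the default — $|AI_i| < \overline{|AI|}$, strict
at the boundary — is stated explicitly and a signed-mean variant
(`rule = "signed_mean"`) is provided rather than guessing further.

Weights are binary and not row-standardised throughout, matching the explicit
$\sum_j w_{ij}$ normalisation above; Moran's I is invariant to the difference
on constant-degree graphs, which is what the cross-check test uses.

## Spatial statistics

`morans_i()` implements the classic statistic
$I = \frac{n}{\sum w_{ij}}\frac{\sum w_{ij} z_i z_j}{\sum z_i^2}$;
`moran_correlogram()` evaluates it over distance classes (half-open intervals
`(lower, upper]` on centroid distances) to identify the scale of strongest
autocorrelation, and `morans_i_test()` assesses significance by random
relabelling — the standard permutation ("bootstrap") procedure, two-sided on
$|I|$ by default, with the $(1+k)/(1+n_\mathrm{perm})$ p-value convention.
Distance-class edges are configurable since no canonical set exists.

## Models

The response models are Gaussian identity-link least-squares fits built by
`icm(formula, data)`. The intensity term enters as `s(ic_ha, 2)`: an
**unpenalised natural cubic regression spline with exactly 2 degrees of
freedom** (interior knot at the median, columns centred). Fixing the df
removes any smoothing-parameter estimation, so the "GAM" is an ordinary
linear model on an expanded design — a deliberate simplification that keeps
AIC, F-tests, stepwise selection and leave-one-out predictions exact. With
`df = 1` the smooth collapses to a linear term; the basis is affine-invariant
in the covariate, and prediction re-evaluates the training knots and centring.

Reported tests mirror conventional practice: t-tests for linear and
interaction coefficients, and for each smooth a block F-test comparing the
fits with and without its whole basis.

**Backward stepwise AIC** (`backward_select()`) repeatedly removes the single
term block whose removal lowers AIC most, until no removal lowers AIC. Blocks
are dropped whole; the focal intensity term is placed in the always-keep set
(it is reported in every final model of this analysis style), and marginality
is enforced — a main effect is never dropped while its interaction remains.
The selection loop is written explicitly (rather than delegating to a generic
stepper) so block structure, keep-sets and the recorded selection path are
under the package's control; on separable designs it attains the exhaustive
best-subset AIC, which the test suite verifies on 50 random datasets.

**LOO-CV error** (`loo_cv_error()`) refits the coefficients once per held-out
observation and reports the mean absolute prediction error as a percentage of
the mean observed value (a per-observation-percentage variant is available;
the "percentage of the observed value" phrase admits both readings). The
design — spline knots and centring — is held fixed across folds; this is what
makes the linear-model identity $e_i/(1-h_{ii})$ hold exactly, and it is the
standard convention for model-level (not basis-level) cross-validation.

The **interaction model** (`fit_interaction_model()`) is the same machinery
with `ic_ha * aggregated`: with the class coded 0/1, the model estimates the
non-aggregated baseline slope plus the intercept and slope differences in
aggregated regions. Because the sample is split by the binary factor,
intensity enters linearly here (a spline per subgroup would overfit).

**Residual diagnostics** (`residual_diagnostics()`) are report-only:
Shapiro–Wilk for normality, studentised Breusch–Pagan for homoscedasticity
(two standard named tests chosen as defaults), and the Moran permutation test
on per-region *mean* residuals over the contiguity matrix — averaging within
regions first, because intensity is constant within a region and that is the
level at which spatial leakage would bias the tests.

## The synthetic generator

`scenario_config()` fixes the study conditions; its defaults are the scale of
the emulated study: an 8 × 19 lattice (152 regions), 332 sites, 22 species,
three survey years, 10 points per site, intensity mean 405.1 Euros/ha — the
national mean of the emulated indicator — with sd 150 Euros/ha (which places
the low-input quintile near 300 Euros/ha, matching the published shape of the
gradient), smoothing 0.6, farmland share 0.8 and detection probability 0.7
per visit (a realistic single-visit detection level for farmland passerines).

* **Landscape**: white noise neighbour-averaged `round(10*smoothing)` times,
  rescaled to the target mean/sd — smoothing 0 gives Moran's I ≈ 0,
  smoothing 0.8 gives I > 0.3 on a 20 × 20 lattice. Farm records are written
  so the ratio-of-sums IC/ha recovers the field *exactly*, making the
  intensity stage verifiable to machine precision; a small excluded-type farm
  per region exercises the production-type filter.
* **Counts**: species' expected site abundance is
  $\lambda_{is} = \exp(a_s + f_s(X_i) + g_s \tilde X^{(n)}_i)$ with $f_s$
  convex-declining (scaled negative exponential) for grassland-specialist
  losers, concave-increasing (saturating) for arable winners, flat otherwise.
  Sensitivity scales with the species' grassland specialisation — the most
  specialised species decline hardest — because a community whose members all
  responded identically would never change composition, and composition
  change is the phenomenon under study. The neighbourhood term acts on the
  losers (default $g_s = -0.3$ per sd of neighbourhood-mean intensity), which
  plants the intensity-by-aggregation interaction on CSIg: in aggregated
  regions the neighbourhood reinforces the local intensity. Counts are
  Poisson at point level, binomially thinned per visit by the detection
  probability.
* **Covariates**: the regional arable/grassland gradient is linear in a
  latent variable correlated with intensity at the configured level (default
  0.6, emulating the documented intensity/land-use correlation); climate and
  altitude are independent. Site land-cover areas follow the regional
  gradient with local noise.

What the generator does *not* emulate: observer heterogeneity, detectability
differences along the gradient, overdispersed counts (a Poisson-binomial
scheme is the default), real region polygons and sizes, and any correlation
of climate with intensity. Passing tests therefore demonstrate the
correctness and calibration of the machinery under the stated data model, not
the field validity of the original ecological conclusions.

`simulate_interaction_data()` plants interaction effects at the descriptor
level directly (default magnitudes: baseline slope −1.165·10⁻³, intercept
difference −0.297, slope difference +7.602·10⁻⁴, the magnitudes this design
is meant to detect). Its residual sd of 0.25 follows from the design: with
intensity sd 150 Euros/ha and n = 332, it reproduces a slope standard error
near 9·10⁻⁵, the reported precision scale of such fits.

## Numerical choices and degenerate inputs

* Undefined quantities are explicit: SSI/SSIg with all-zero inputs, Moran's I
  on constant fields, community indices of empty communities (NA + flag),
  AI of isolated regions (NA), arable ratio with no arable or grassland area.
* Permutation p-values never go below $1/(n_\mathrm{perm}+1)$.
* The stepwise loop uses a $10^{-10}$ AIC slack so exact ties do not cycle.
* All randomised routines take a mandatory seed, run in a local RNG scope and
  restore the caller's RNG stream.
* Eligibility and classification boundaries use strict inequalities,
  implemented in integer-exact arithmetic where possible.

## Problem sizes in the test suite

The suite verifies oracle equivalence on 100 random instances per statistic;
parameter recovery on 200 replicates of the 152-region / 332-site scenario;
test-size calibration on 1000 null replicates each for the smooth F-test, the
interaction t-test and the Moran permutation test (lattice of 30 units,
99 permutations); and stepwise optimality against exhaustive best-subset
search on 50 random datasets with 6 candidate blocks. These sizes give
binomial standard errors well inside the asserted bands while keeping the
default test run quick.

## Known limitations

* Gaussian identity-link models are used for all four descriptors including
  richness (consistent with the t/F reporting style this analysis follows); a
  count-model variant is out of scope.
* Only binary factors are supported in model formulas; multi-level factors
  would need dummy blocks.
* The correlogram uses user-supplied distance-class edges; no automatic
  choice is attempted.
* Backward selection is greedy; its optimality is verified empirically on
  separable designs, not guaranteed in pathological collinear ones.

## A worked run

```{r, eval = FALSE}
sim <- simulate_scenario(scenario_config(seed = 1))
tabs <- list(survey = sim$records, farms = sim$landscape$farms,
             edges = sim$landscape$edges,
             total_area = sim$landscape$total_area,
             clc_areas = sim$covariates$clc_areas,
             altitude = sim$covariates$altitude,
             climate = sim$covariates$climate,
             site_sar = sim$covariates$site_sar,
             sar_landuse = sim$covariates$sar_landuse)
res <- run_pipeline(tabs, seed = 2)
summary(res$fits$csig)
summary(res$interaction_fit)
res$cv_error
plot(res$fits$csig)   # partial effect of intensity on CSIg
```
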