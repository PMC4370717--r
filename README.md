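# farmbird

Analysis of farmland breeding-bird communities along a continuous
agricultural-intensity gradient, for community ecologists working with
point-count monitoring data and regional farm statistics.

Agricultural intensity is summarised as **IC/ha** — the sum of seven
input-cost categories (fertilizers, feedstuff, pesticides, seeds, fuel,
veterinary products, irrigation water) over the utilised agricultural area of
a small agricultural region (SAR), in Euros per hectare, averaged over three
accounting years. Its **spatial aggregation** is measured per region as

```
AI_i = X_i − (Σ_j w_ij X_j) / (Σ_j w_ij)
```

the gap between a region's intensity `X_i` and the mean of its contiguous
neighbours (`w` the binary contiguity matrix); regions with `|AI|` below the
average magnitude sit in blocks of similar intensity ("aggregated").

The bird community is summarised per 2 × 2 km survey site by species richness
and three abundance-weighted composition indices over a fixed 22-species
farmland community:

```
CSI  = Σ_i (N_i / N_tot) · SSI_i     (habitat specialisation)
CTI  = Σ_i (N_i / N_tot) · STI_i     (trophic position, 1–3)
CSIg = Σ_i (N_i / N_tot) · SSIg_i    (grassland specialisation, 1–4)
```

where SSI is the coefficient of variation of a species' density across seven
habitat classes, STI weights diet proportions (seeds/plants, invertebrates,
vertebrates) by 1/2/3, and SSIg weights use of four farmland sub-habitats by
4 (unimproved grassland) … 1 (arable).

Responses are modelled with Gaussian least-squares fits in which intensity
enters as a fixed 2-df natural-cubic regression spline,

```
descriptor ~ s(IC/ha, 2) + altitude + land-use + climate
```

with backward stepwise AIC selection, leave-one-out cross-validation error,
and residual diagnostics including a Moran's I permutation test on
per-region mean residuals. The interaction of intensity with its aggregation
is tested by `descriptor ~ IC/ha * aggregated + …` with the aggregation class
coded 0/1, so the coefficients read as the non-aggregated baseline slope plus
the aggregated-region intercept and slope differences.

A synthetic generator emulates the survey structure (152-region lattice,
332 sites of 10 point counts with two spring visits, three years, 22 species
with winner/loser response shapes, farm records that reproduce the intensity
field exactly), so the entire pipeline is testable without access to the
original monitoring data.

## Worked example

```r
library(farmbird)

sim <- simulate_scenario(scenario_config(seed = 1))   # study-scale scenario
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
#> Intensity-community model
#>
#>         term estimate       se statistic test p_value
#>  (Intercept)    1.903 0.002648     718.6    t < 1e-16
#>  s(ic_ha, 2)       NA       NA     114.1    F < 1e-16
#>
#> n = 327, residual sd = 0.04788, R^2 = 0.413, AIC = -1054.52
```

The backward-selected model for the grassland specialisation index retains
the intensity spline (F = 114.1 on the 2-df block: the planted decline is
recovered decisively); the independent climate and land-use covariates were
dropped by AIC. `plot(res$fits$csig)` shows the convex-declining partial
effect — steep below the intensity mean, attenuated above it.

```r
summary(res$interaction_fit)
#>              term   estimate        se statistic test   p_value
#>       (Intercept)  2.046e+00 3.687e-02    55.510    t   < 1e-16
#>             ic_ha -2.035e-04 2.748e-05    -7.407    t 1.145e-12
#>        aggregated  3.715e-02 1.728e-02     2.149    t   0.03236
#>            precip -7.867e-05 4.250e-05    -1.851    t   0.06505
#>  ic_ha:aggregated -9.072e-05 3.952e-05    -2.296    t   0.02233
```

`ic_ha` is the intensity slope in non-aggregated regions; `aggregated` and
`ic_ha:aggregated` are the intercept and slope differences where intensity is
spatially aggregated — here the decline steepens by −9.1·10⁻⁵ CSIg units per
Euro/ha (p = 0.022), i.e. aggregation strengthens the intensity effect, the
scenario's planted neighbourhood structure.

```r
res$cv_error
#> richness      csi      cti     csig
#>      2.8      3.4      2.7      2.0
res$diagnostics$csig
#> Residual diagnostics
#>   Shapiro-Wilk normality: W = 0.9924, p = 0.09564
#>   Breusch-Pagan homoscedasticity: BP = 0.5507, p = 0.7593
#>   Moran's I on per-region mean residuals (137 regions): I = -0.0429, p = 0.44
```

Leave-one-out errors are a few percent of the mean descriptor value, and the
residuals show no spatial autocorrelation between adjacent regions — the
models have absorbed the spatially structured intensity field.

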