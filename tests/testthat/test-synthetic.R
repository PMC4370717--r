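test_that("the generator is deterministic given the seed", {
  cfg <- scenario_config(rows = 3, cols = 4, n_sites = 10, seed = 7)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$landscape$intensity, s2$landscape$intensity)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$covariates, s2$covariates)
  # and the RNG stream of the caller is untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_scenario(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("smoothing controls the spatial autocorrelation of intensity", {
  l0 <- generate_landscape(scenario_config(rows = 20, cols = 20, n_sites = 10,
                                           smoothing = 0, seed = 2))
  expect_lt(abs(morans_i(l0$intensity, l0$w)), 0.1)
  l8 <- generate_landscape(scenario_config(rows = 20, cols = 20, n_sites = 10,
                                           smoothing = 0.8, seed = 2))
  expect_gt(morans_i(l8$intensity, l8$w), 0.3)
})

test_that("farm records reproduce the intensity field through IC/ha", {
  l <- generate_landscape(scenario_config(rows = 4, cols = 6, n_sites = 10,
                                          seed = 3))
  got <- ic_per_ha(l$farms)
  expect_equal(setNames(got$ic_per_ha, got$sar_id),
               l$intensity[got$sar_id], tolerance = 1e-10)
  # every region passes the production-type dominance rule by construction
  expect_setequal(sar_eligibility(l$farms, l$total_area), l$sars)
})

test_that("null effect sizes leave abundances unrelated to intensity", {
  sim <- simulate_scenario(scenario_config(rows = 10, cols = 10, n_sites = 300,
                                           effect_size = 0, neigh_effect = 0,
                                           seed = 11))
  x <- sim$landscape$intensity[sim$landscape$sites$sar_id]
  # observed per-site totals per species vs intensity: |r| stays at noise level
  desc <- site_descriptors(sim$records, seed = 1)
  lam <- attr(sim$records, "lambda")
  tot <- matrix(0, nrow(sim$landscape$sites), 22,
                dimnames = dimnames(lam))
  agg <- aggregate(count ~ site_id + species_id, sim$records, sum)
  tot[cbind(agg$site_id, agg$species_id)] <- agg$count
  rs <- apply(tot, 2, function(v) suppressWarnings(cor(v, x)))
  expect_lt(mean(abs(rs), na.rm = TRUE), 0.1)
})

test_that("perfect detection makes the two visits identical", {
  sim <- simulate_scenario(scenario_config(rows = 3, cols = 3, n_sites = 20,
                                           detection_prob = 1, seed = 13))
  r <- sim$records
  v1 <- r[r$visit == 1, ]; v2 <- r[r$visit == 2, ]
  key <- function(d) paste(d$site_id, d$point_id, d$year, d$species_id)
  m <- merge(setNames(v1[c("site_id", "point_id", "year", "species_id",
                           "count")], c("site_id", "point_id", "year",
                                        "species_id", "c1")),
             setNames(v2[c("site_id", "point_id", "year", "species_id",
                           "count")], c("site_id", "point_id", "year",
                                        "species_id", "c2")))
  expect_gt(nrow(m), 0)
  expect_equal(m$c1, m$c2)
})

test_that("a loser-dominated community declines in CSIg along intensity", {
  cfg <- scenario_config(rows = 8, cols = 10, n_sites = 200,
                         loser_ssig = 1.2, effect_size = 1.2, seed = 17)
  expect_true(all(cfg$shapes == "convex_decline"))
  sim <- simulate_scenario(cfg)
  desc <- site_descriptors(sim$records, seed = 1)
  x <- sim$landscape$intensity[
    sim$landscape$sites$sar_id[match(desc$site_id,
                                     sim$landscape$sites$site_id)]]
  ok <- desc$flag == "ok"
  expect_lt(cor(desc$csig[ok], x[ok]), -0.2)
})

test_that("the arable gradient correlates with intensity as configured", {
  frac_of <- function(cv) {
    with(cv$sar_landuse, arable_area / (arable_area + grassland_area))
  }
  c0 <- scenario_config(rows = 15, cols = 20, n_sites = 10,
                        arable_intensity_cor = 0, seed = 19)
  l0 <- generate_landscape(c0)
  g0 <- generate_covariates(c0, l0)
  expect_lt(abs(cor(l0$intensity, frac_of(g0))), 0.15)
  c6 <- scenario_config(rows = 15, cols = 20, n_sites = 10,
                        arable_intensity_cor = 0.6, seed = 19)
  l6 <- generate_landscape(c6)
  g6 <- generate_covariates(c6, l6)
  expect_lt(abs(cor(l6$intensity, frac_of(g6)) - 0.6), 0.15)
})

test_that("generated tables pass the consuming validators", {
  sim <- simulate_scenario(scenario_config(rows = 4, cols = 5, n_sites = 25,
                                           seed = 23))
  v <- validate_tables(list(survey = sim$records,
                            farms = sim$landscape$farms,
                            edges = sim$landscape$edges,
                            centroids = sim$landscape$centroids,
                            total_area = sim$landscape$total_area,
                            clc_areas = sim$covariates$clc_areas,
                            altitude = sim$covariates$altitude,
                            climate = sim$covariates$climate,
                            site_sar = sim$covariates$site_sar,
                            sar_landuse = sim$covariates$sar_landuse))
  expect_equal(nrow(v), 0)
})

test_that("a planted interaction is detected and an absent one is not", {
  # power at the study scale
  sig <- logical(30)
  for (r in 1:30) {
    l <- generate_landscape(scenario_config(seed = 100 + r))
    d <- simulate_interaction_data(l, seed = 200 + r)
    s <- summary(fit_interaction_model(y ~ ic_ha * aggregated, d))$table
    sig[r] <- s$p_value[s$term == "ic_ha:aggregated"] < 0.05
  }
  expect_gte(mean(sig), 0.8)
  # type-I error when the interaction is programmed absent
  l <- generate_landscape(scenario_config(seed = 1))
  null_sig <- logical(200)
  for (r in 1:200) {
    d <- simulate_interaction_data(l, slope_diff = 0, agg_diff = 0,
                                   seed = 300 + r)
    s <- summary(fit_interaction_model(y ~ ic_ha * aggregated, d))$table
    null_sig[r] <- s$p_value[s$term == "ic_ha:aggregated"] < 0.05
  }
  expect_lte(mean(null_sig), 0.09)
})
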