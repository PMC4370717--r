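# Synthetic data emulating the structure of the national breeding-bird survey
# and the farm accounting data: a lattice of Small Agricultural Regions with a
# spatially autocorrelated intensity field, farm records that reproduce it,
# 2x2 km survey sites of 10 point counts with two spring visits, and per-site
# covariate tables. Every stage of the analysis can be exercised end to end on
# these tables without any external data.

#' Scenario configuration for the synthetic survey generator
#'
#' Defaults mirror the scale of the national study the package emulates:
#' an 8 x 19 lattice of 152 regions, 332 survey sites, the packaged 22-species
#' community, intensity mean 405.1 Euros/ha (the national mean) with sd
#' 150 Euros/ha, three survey years, 10 points per site of which about 80% are
#' farmland, and detection probability 0.7 per visit.
#'
#' Species response shapes follow the winner/loser structure of farmland bird
#' communities: grassland specialists (high SSIg) decline with intensity along
#' a convex (negative-exponential) curve, arable specialists (low SSIg)
#' increase along a concave (saturating) curve, intermediate species are flat.
#' A neighbourhood term (`neigh_effect`) couples abundance to the mean
#' intensity of contiguous regions, which is what makes an
#' intensity-by-aggregation interaction plantable.
#'
#' @param rows,cols Lattice dimensions (rows * cols regions).
#' @param n_sites Number of survey sites, assigned to regions at random.
#' @param icha_mean,icha_sd Target mean and sd of the intensity field
#'   (Euros/ha).
#' @param smoothing Spatial smoothing strength in `[0, 1)`: the white-noise
#'   field is neighbour-averaged `round(10 * smoothing)` times.
#' @param years Survey years.
#' @param n_points Point counts per site.
#' @param farmland_share Probability a point is farmland.
#' @param detection_prob Detection probability per visit in `(0, 1]`.
#' @param baseline_log_abundance Per-species log site abundance at reference
#'   intensity (single value recycled or named vector).
#' @param effect_size Magnitude of the intensity effect on loser/winner
#'   species (log scale).
#' @param neigh_effect Effect of standardised neighbourhood-mean intensity on
#'   grassland specialists (log scale). The default -0.3 plants the
#'   intensity-by-aggregation interaction on the grassland specialisation
#'   index: losers are further depressed where the surrounding regions are
#'   also intensive. Set 0 to disable.
#' @param loser_ssig,winner_ssig SSIg thresholds classifying species as
#'   grassland-specialist losers (ssig >= `loser_ssig`) or arable winners
#'   (ssig <= `winner_ssig`); the rest respond flat.
#' @param arable_intensity_cor Correlation between regional intensity and the
#'   arable/grassland land-use gradient in the covariate tables.
#' @param farms_per_sar Eligible farms per region and year.
#' @param traits Species trait table (default the packaged community).
#' @param seed Integer seed; mandatory.
#' @return A `"scenario_config"` list.
#' @export
scenario_config <- function(rows = 8, cols = 19, n_sites = 332,
                            icha_mean = 405.1, icha_sd = 150,
                            smoothing = 0.6, years = 2006:2008,
                            n_points = 10, farmland_share = 0.8,
                            detection_prob = 0.7,
                            baseline_log_abundance = log(3),
                            effect_size = 0.8, neigh_effect = -0.3,
                            loser_ssig = 2.1, winner_ssig = 1.7,
                            arable_intensity_cor = 0.6,
                            farms_per_sar = 3,
                            traits = farmland_species(), seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(rows >= 1, cols >= 1, n_sites >= 1, icha_sd > 0,
            smoothing >= 0, smoothing < 1,
            detection_prob > 0, detection_prob <= 1,
            farmland_share >= 0, farmland_share <= 1,
            length(years) >= 1, farms_per_sar >= 1)
  shape <- ifelse(traits$ssig >= loser_ssig, "convex_decline",
                  ifelse(traits$ssig <= winner_ssig, "concave_increase",
                         "flat"))
  structure(list(rows = rows, cols = cols, n_sites = n_sites,
                 icha_mean = icha_mean, icha_sd = icha_sd,
                 smoothing = smoothing, years = years, n_points = n_points,
                 farmland_share = farmland_share,
                 detection_prob = detection_prob,
                 baseline_log_abundance = baseline_log_abundance,
                 effect_size = effect_size, neigh_effect = neigh_effect,
                 shapes = stats::setNames(shape, traits$species_id),
                 arable_intensity_cor = arable_intensity_cor,
                 farms_per_sar = farms_per_sar, traits = traits,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# Rook-contiguity edge list of a rows x cols lattice with ids "SAR###".
lattice_edges <- function(rows, cols) {
  id <- function(r, c) sprintf("SAR%03d", (r - 1) * cols + c)
  e <- list()
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) e[[length(e) + 1]] <- c(id(r, c), id(r, c + 1))
    if (r < rows) e[[length(e) + 1]] <- c(id(r, c), id(r + 1, c))
  }
  as.data.frame(do.call(rbind, e), stringsAsFactors = FALSE) |>
    stats::setNames(c("unit_a", "unit_b"))
}

#' Generate the regional landscape: intensity field, adjacency, farm records
#'
#' White noise on the lattice is smoothed by iterated neighbour averaging
#' (`round(10 * smoothing)` passes of half-self, half-neighbour-mean), then
#' rescaled to the target mean and sd, giving a spatially autocorrelated
#' intensity field. Farm records are drawn per region so that [ic_per_ha()]
#' recovers the field exactly; one small ineligible-type farm per region
#' exercises the production-type filter without tipping the two-thirds rule.
#'
#' @param cfg A [scenario_config()].
#' @return A list: `sars` (ids), `edges`, `w` (contiguity matrix), `centroids`
#'   (data.frame `sar_id`, `x_km`, `y_km`; 30 km spacing), `intensity` (named
#'   vector, Euros/ha), `neigh_mean` (named vector: mean intensity of
#'   contiguous neighbours), `farms` (farm record table, years 2004:2006),
#'   `total_area` (per-region total agricultural area), `sites` (data.frame
#'   `site_id`, `sar_id`).
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  rng <- local_rng(cfg$seed)
  on.exit(rng())
  n <- cfg$rows * cfg$cols
  sars <- sprintf("SAR%03d", seq_len(n))
  edges <- lattice_edges(cfg$rows, cfg$cols)
  w <- contiguity_matrix(edges, sars)
  deg <- rowSums(w)
  z <- stats::rnorm(n)
  for (k in seq_len(round(10 * cfg$smoothing)))
    z <- 0.5 * z + 0.5 * as.numeric(w %*% z) / pmax(deg, 1)
  z <- (z - mean(z)) / stats::sd(z)
  x <- pmax(cfg$icha_mean + cfg$icha_sd * z, 1)   # intensity cannot go negative
  names(x) <- sars

  centroids <- data.frame(
    sar_id = sars,
    x_km = 30 * ((seq_len(n) - 1) %% cfg$cols),
    y_km = 30 * ((seq_len(n) - 1) %/% cfg$cols))

  years <- 2004:2006
  nf <- cfg$farms_per_sar
  grid <- expand.grid(sar = seq_len(n), farm = seq_len(nf), year = years)
  area <- stats::runif(nrow(grid), 50, 150)
  cost_total <- x[grid$sar] * area
  split <- c(0.25, 0.2, 0.15, 0.12, 0.13, 0.1, 0.05)  # category shares
  costs <- outer(cost_total, split)
  colnames(costs) <- input_cost_categories
  farms <- data.frame(
    farm_id = sprintf("F%03d_%d", grid$sar, grid$farm),
    sar_id = sars[grid$sar],
    production_type = sample(eligible_production_types, nrow(grid),
                             replace = TRUE),
    year = grid$year, costs, utilised_area = area,
    stringsAsFactors = FALSE)
  # one small excluded-type farm per region and year (filter exercise)
  excl <- data.frame(
    farm_id = sprintf("F%03d_X", rep(seq_len(n), length(years))),
    sar_id = rep(sars, length(years)),
    production_type = "wine",
    year = rep(years, each = n),
    matrix(5, n * length(years), 7,
           dimnames = list(NULL, input_cost_categories)),
    utilised_area = stats::runif(n * length(years), 5, 15),
    stringsAsFactors = FALSE)
  farms <- rbind(farms, excl)

  elig_area <- tapply(area, grid$sar, sum) / length(years)
  total_area <- data.frame(sar_id = sars,
                           total_area = as.numeric(elig_area) * 1.2)

  sites <- data.frame(
    site_id = sprintf("S%04d", seq_len(cfg$n_sites)),
    sar_id = sars[sample.int(n, cfg$n_sites, replace = TRUE)],
    stringsAsFactors = FALSE)

  neigh <- as.numeric(w %*% x) / pmax(deg, 1)
  neigh[deg == 0] <- NA_real_
  list(sars = sars, edges = edges, w = w, centroids = centroids,
       intensity = x, neigh_mean = stats::setNames(neigh, sars),
       farms = farms, total_area = total_area, sites = sites)
}

# Species response to intensity on the log-abundance scale.
response_curve <- function(shape, x, x0, scale, effect) {
  switch(shape,
         convex_decline = effect * exp(-(x - x0) / scale) - effect / 2,
         concave_increase = effect * (1 - exp(-(x - x0) / scale)) - effect / 2,
         flat = rep(0, length(x)),
         stop("unknown response shape '", shape, "'"))
}

#' Generate point-count records for a landscape
#'
#' True site abundance of species s at site i is
#' `lambda = exp(a_s + f_s(X_i) + g_s * Xn_i)` with `X_i` the regional
#' intensity, `f_s` the species' response curve (convex-declining for losers,
#' concave-increasing for winners) and `Xn_i` the standardised
#' neighbourhood-mean intensity (losers only, strength `neigh_effect`).
#' Per point and year the latent bird number is Poisson with mean
#' `lambda / n_points`; each of the two visits records a binomial thinning of
#' it with the configured detection probability. Habitat classes are fixed
#' per point across years; farmland points carry a sub-habitat label.
#'
#' @param cfg A [scenario_config()].
#' @param landscape Output of [generate_landscape()].
#' @return Data frame of point-count records (`site_id`, `point_id`, `visit`,
#'   `year`, `species_id`, `count`, `habitat_class`, `subhabitat`); zero
#'   counts are not stored. The per-site expected abundances are attached as
#'   attribute `"lambda"` (sites x species matrix).
#' @export
generate_counts <- function(cfg, landscape) {
  stopifnot(inherits(cfg, "scenario_config"))
  rng <- local_rng(cfg$seed + 1L)
  on.exit(rng())
  tr <- cfg$traits
  nsp <- nrow(tr)
  sites <- landscape$sites
  x <- landscape$intensity[sites$sar_id]
  xn <- landscape$neigh_mean[sites$sar_id]
  xn[is.na(xn)] <- mean(landscape$intensity)
  xn_std <- (xn - mean(landscape$intensity)) / cfg$icha_sd
  x0 <- min(landscape$intensity)

  a <- rep(cfg$baseline_log_abundance, length.out = nsp)
  # sensitivity grows with grassland specialisation: the most specialised
  # grassland species decline hardest, the most arable species gain most,
  # which is what shifts community composition along the gradient
  sg <- (tr$ssig - min(tr$ssig)) / diff(range(tr$ssig))
  lambda <- matrix(0, nrow(sites), nsp,
                   dimnames = list(sites$site_id, tr$species_id))
  for (s in seq_len(nsp)) {
    eff <- cfg$effect_size *
      switch(cfg$shapes[s], convex_decline = sg[s],
             concave_increase = 1 - sg[s], flat = 0)
    f <- response_curve(cfg$shapes[s], x, x0, cfg$icha_sd, eff)
    g <- if (cfg$shapes[s] == "convex_decline") cfg$neigh_effect else 0
    lambda[, s] <- exp(a[s] + f + g * xn_std)
  }

  # fixed point layout per site
  hab <- matrix("farmland", nrow(sites), cfg$n_points)
  other <- setdiff(habitat_classes, "farmland")
  nonfarm <- matrix(stats::runif(length(hab)) > cfg$farmland_share,
                    nrow(sites), cfg$n_points)
  hab[nonfarm] <- sample(other, sum(nonfarm), replace = TRUE)
  subh <- matrix(sample(farmland_subhabitats, length(hab), replace = TRUE),
                 nrow(sites), cfg$n_points)
  subh[hab != "farmland"] <- NA_character_

  out <- vector("list", length(cfg$years))
  for (yi in seq_along(cfg$years)) {
    yr <- cfg$years[yi]
    # latent birds per site x point x species
    lam_pt <- lambda / cfg$n_points
    n_lat <- array(stats::rpois(nrow(sites) * cfg$n_points * nsp,
                                rep(lam_pt, cfg$n_points)),
                   dim = c(nrow(sites), nsp, cfg$n_points))
    recs <- list()
    for (v in 1:2) {
      cnt <- array(stats::rbinom(length(n_lat), n_lat, cfg$detection_prob),
                   dim = dim(n_lat))
      idx <- which(cnt > 0, arr.ind = TRUE)
      if (nrow(idx)) {
        recs[[v]] <- data.frame(
          site_id = sites$site_id[idx[, 1]],
          point_id = idx[, 3],
          visit = v, year = yr,
          species_id = tr$species_id[idx[, 2]],
          count = cnt[idx],
          habitat_class = hab[cbind(idx[, 1], idx[, 3])],
          subhabitat = subh[cbind(idx[, 1], idx[, 3])],
          stringsAsFactors = FALSE)
      }
    }
    out[[yi]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "lambda") <- lambda
  attr(res, "habitat") <- hab
  res
}

#' Generate covariate tables for a landscape
#'
#' Land-cover areas per site are drawn so the arable share follows the
#' regional arable/grassland gradient, which itself correlates with intensity
#' at the configured level (`arable_intensity_cor`); climate and altitude are
#' independent fields. All tables match the input layouts of
#' [assemble_covariates()].
#'
#' @param cfg A [scenario_config()].
#' @param landscape Output of [generate_landscape()].
#' @return A list of data.frames: `clc_areas`, `altitude`, `climate`,
#'   `site_sar`, `sar_landuse`.
#' @export
generate_covariates <- function(cfg, landscape) {
  stopifnot(inherits(cfg, "scenario_config"))
  rng <- local_rng(cfg$seed + 2L)
  on.exit(rng())
  x <- landscape$intensity
  n <- length(x)
  r <- cfg$arable_intensity_cor
  xs <- (x - mean(x)) / stats::sd(x)
  u <- r * xs + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
  # regional arable fraction of the arable+grassland area, linear in the
  # latent gradient so the configured correlation carries through
  arable_frac <- pmin(pmax(0.5 + 0.18 * u, 0.02), 0.98)
  ag_area <- stats::runif(n, 2000, 6000)
  sar_landuse <- data.frame(sar_id = landscape$sars,
                            arable_area = ag_area * arable_frac,
                            grassland_area = ag_area * (1 - arable_frac))

  sites <- landscape$sites
  ns <- nrow(sites)
  frac_site <- pmin(pmax(arable_frac[match(sites$sar_id, landscape$sars)] +
                           stats::rnorm(ns, 0, 0.05), 0.01), 0.99)
  agri <- stats::runif(ns, 2.2, 3.4)   # of the 4 km^2 site
  cshare <- stats::runif(ns, 0.08, 0.25)
  arable <- agri * frac_site * (1 - cshare)
  pasture <- agri * (1 - frac_site) * (1 - cshare)
  complex_c <- agri * cshare
  rest <- 4 - agri
  other_cats <- c("broad_leaved_forest", "mixed_forest", "natural_grasslands",
                  "moors_heathland", "artificial_surfaces", "water_bodies")
  shares <- matrix(stats::rgamma(ns * length(other_cats), 1), ns)
  shares <- shares / rowSums(shares) * rest
  clc <- data.frame(site_id = rep(sites$site_id, 3 + length(other_cats)),
                    category = rep(c("non_irrigated_arable", "pastures",
                                     "complex_cultivation", other_cats),
                                   each = ns),
                    area_km2 = c(arable, pasture, complex_c, as.vector(shares)),
                    stringsAsFactors = FALSE)
  clc <- clc[clc$area_km2 > 1e-9, ]

  altitude <- data.frame(site_id = sites$site_id,
                         altitude_m = stats::rlnorm(ns, log(250), 0.6))
  climate <- expand.grid(sar_id = landscape$sars, year = cfg$years,
                         stringsAsFactors = FALSE)
  climate$temp_c <- stats::rnorm(nrow(climate), 11.5, 1.5)
  climate$precip_mm <- stats::rnorm(nrow(climate), 800, 120)

  list(clc_areas = clc, altitude = altitude, climate = climate,
       site_sar = sites, sar_landuse = sar_landuse)
}

#' Generate a complete synthetic scenario
#'
#' Convenience wrapper: landscape, point counts and covariates, plus the truth
#' (expected abundances, intensity field, configuration) needed by recovery
#' tests.
#'
#' @param cfg A [scenario_config()], or arguments passed to it via `...`.
#' @param ... If `cfg` is missing, arguments for [scenario_config()].
#' @return A list: `cfg`, `landscape`, `records`, `covariates`.
#' @export
simulate_scenario <- function(cfg, ...) {
  if (missing(cfg)) cfg <- scenario_config(...)
  landscape <- generate_landscape(cfg)
  records <- generate_counts(cfg, landscape)
  covariates <- generate_covariates(cfg, landscape)
  list(cfg = cfg, landscape = landscape, records = records,
       covariates = covariates)
}

#' Simulate descriptor-level interaction data on a generated landscape
#'
#' Draws a community descriptor directly from the intensity-by-aggregation
#' linear model on a generated landscape: regions get an aggregation class
#' from their realised aggregation index, sites are assigned to regions, and
#' \deqn{y = \beta_0 + \beta_x X + \beta_a A + \beta_{xa} X A + \varepsilon}
#' with i.i.d. Gaussian noise. Used for parameter-recovery and power studies
#' of [fit_interaction_model()] at the study scale.
#'
#' @param landscape Output of [generate_landscape()].
#' @param intercept,slope Baseline intercept and intensity slope
#'   (non-aggregated regions).
#' @param agg_diff,slope_diff Intercept and slope differences in aggregated
#'   regions.
#' @param sigma Residual sd of the descriptor.
#' @param seed Integer seed.
#' @return Data frame `site_id`, `sar_id`, `ic_ha`, `aggregated`, `y`.
#' @export
simulate_interaction_data <- function(landscape, intercept = 1.779,
                                      slope = -1.165e-3, agg_diff = -0.297,
                                      slope_diff = 7.602e-4, sigma = 0.25,
                                      seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  rng <- local_rng(seed)
  on.exit(rng())
  ai <- aggregation_index(landscape$intensity, landscape$w)
  agg <- classify_aggregated(ai)
  sites <- landscape$sites
  x <- as.numeric(landscape$intensity[sites$sar_id])
  a <- as.integer(agg[sites$sar_id])
  keepr <- !is.na(a)
  sites <- sites[keepr, ]; x <- x[keepr]; a <- a[keepr]
  y <- intercept + slope * x + agg_diff * a + slope_diff * x * a +
    stats::rnorm(length(x), 0, sigma)
  data.frame(site_id = sites$site_id, sar_id = sites$sar_id,
             ic_ha = x, aggregated = a, y = y, stringsAsFactors = FALSE)
}
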