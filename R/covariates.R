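# Land-use, climate and altitude covariates per survey site.

#' The 15 CORINE land-cover categories used as site covariates
#' @format Character vector of length 15.
#' @export
clc_categories <- c(
  "non_irrigated_arable", "vineyards", "fruit_trees", "pastures",
  "complex_cultivation", "agriculture_natural_vegetation",
  "broad_leaved_forest", "coniferous_forest", "mixed_forest",
  "natural_grasslands", "moors_heathland", "transitional_woodland_shrub",
  "artificial_surfaces", "wetlands", "water_bodies")

#' Land-cover proportions of a site
#'
#' Converts per-category areas into proportions of the site area; categories
#' absent from the input get 0.
#'
#' @param areas Named numeric vector (or data.frame `category`, `area`) of
#'   category areas within the site (any common unit).
#' @param total_area Site area in the same unit; defaults to the summed input
#'   areas (i.e. the categories are taken as exhaustive).
#' @param categories Category universe (default [clc_categories]).
#' @return Named numeric vector of proportions over `categories`.
#' @export
clc_proportions <- function(areas, total_area = NULL,
                            categories = clc_categories) {
  if (is.data.frame(areas))
    areas <- stats::setNames(areas$area, areas$category)
  stopifnot(is.numeric(areas), !is.null(names(areas)))
  if (any(areas < 0)) stop("areas must be non-negative")
  bad <- setdiff(names(areas), categories)
  if (length(bad)) stop("unknown land-cover categories: ",
                        paste(bad, collapse = ", "))
  if (is.null(total_area)) total_area <- sum(areas)
  if (total_area <= 0) stop("total site area must be positive")
  if (sum(areas) > total_area * (1 + 1e-8))
    stop("category areas exceed the site area")
  out <- stats::setNames(numeric(length(categories)), categories)
  out[names(areas)] <- areas / total_area
  out
}

#' Shannon diversity of a landscape composition
#'
#' \eqn{H = -\sum_{p>0} p \log p} over the present categories, with proportions
#' renormalised to sum to 1. Maximal (`log(k)`) for k equally frequent
#' categories, 0 for a single category.
#'
#' @param p Numeric vector of non-negative proportions/areas.
#' @param base Logarithm base (natural log by default).
#' @return A non-negative number.
#' @examples
#' shannon_diversity(rep(1, 4))  # log(4)
#' @export
shannon_diversity <- function(p, base = exp(1)) {
  stopifnot(is.numeric(p))
  if (any(p < 0)) stop("proportions must be non-negative")
  s <- sum(p)
  if (s == 0) stop("Shannon diversity undefined: all proportions zero")
  p <- p[p > 0] / s
  -sum(p * log(p, base = base))
}

#' Arable-to-grassland land-use ratio
#'
#' Arable area divided by the sum of arable and grassland areas: 0 for pure
#' grassland, 1 for pure arable regions.
#'
#' @param arable,grassland Non-negative areas (same unit).
#' @return Number in `[0, 1]`, or `NA_real_` (with a warning) if both are zero.
#' @export
arable_grassland_ratio <- function(arable, grassland) {
  stopifnot(arable >= 0, grassland >= 0)
  if (arable + grassland == 0) {
    warning("arable + grassland area is zero; ratio undefined")
    return(NA_real_)
  }
  arable / (arable + grassland)
}

#' Assemble the per-site covariate table
#'
#' Joins site-level variables (land-cover proportions, their Shannon
#' diversity, altitude) with region-level variables (climate averaged over the
#' survey years, the arable/grassland ratio, and optionally IC/ha intensity
#' and its aggregation class) through the site-to-region mapping.
#'
#' @param clc_areas Data frame `site_id`, `category`, `area_km2`.
#' @param altitude Data frame `site_id`, `altitude_m`.
#' @param climate Data frame `sar_id`, `year`, `temp_c`, `precip_mm`; rows
#'   with `year` in `climate_years` are averaged per region.
#' @param site_sar Data frame `site_id`, `sar_id`.
#' @param sar_landuse Data frame `sar_id`, `arable_area`, `grassland_area`
#'   (region-level areas behind the arable/grassland ratio).
#' @param sar_intensity Optional data frame `sar_id`, `ic_per_ha`, `ai`,
#'   `aggregated` (see [sar_intensity()]).
#' @param site_area_km2 Site area (2 x 2 km squares by default).
#' @param climate_years Years of climate data to average (default 2006:2008).
#' @param standardise_precip If `TRUE`, precipitation enters in metres
#'   (mm / 1000); default keeps the input unit.
#' @return Data frame, one row per site: the 15 land-cover proportion columns,
#'   `shannon`, `altitude`, `temp`, `precip`, `arable_grassland`, optional
#'   intensity columns, and a logical `complete` flag (FALSE where a join
#'   failed; such rows carry NAs rather than being dropped).
#' @export
assemble_covariates <- function(clc_areas, altitude, climate, site_sar,
                                sar_landuse, sar_intensity = NULL,
                                site_area_km2 = 4, climate_years = 2006:2008,
                                standardise_precip = FALSE) {
  stopifnot(is.data.frame(clc_areas), is.data.frame(altitude),
            is.data.frame(climate), is.data.frame(site_sar),
            is.data.frame(sar_landuse))
  sites <- sort(unique(clc_areas$site_id))
  miss_map <- setdiff(sites, site_sar$site_id)
  if (length(miss_map))
    stop("sites without a region mapping: ", paste(miss_map, collapse = ", "))

  prop <- matrix(0, length(sites), length(clc_categories),
                 dimnames = list(sites, clc_categories))
  shan <- numeric(length(sites))
  for (i in seq_along(sites)) {
    a <- clc_areas[clc_areas$site_id == sites[i], ]
    pr <- clc_proportions(stats::setNames(a$area_km2, a$category),
                          total_area = site_area_km2)
    prop[i, ] <- pr
    shan[i] <- shannon_diversity(pr)
  }

  cl <- climate[climate$year %in% climate_years, ]
  temp <- tapply(cl$temp_c, cl$sar_id, mean)
  prec <- tapply(cl$precip_mm, cl$sar_id, mean)

  sar <- site_sar$sar_id[match(sites, site_sar$site_id)]
  out <- data.frame(site_id = sites, sar_id = sar, prop, shannon = shan,
                    altitude = altitude$altitude_m[match(sites, altitude$site_id)],
                    temp = as.numeric(temp[sar]),
                    precip = as.numeric(prec[sar]),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (standardise_precip) out$precip <- out$precip / 1000
  ar <- sar_landuse$arable_area[match(sar, sar_landuse$sar_id)]
  gr <- sar_landuse$grassland_area[match(sar, sar_landuse$sar_id)]
  out$arable_grassland <- ifelse(is.na(ar) | is.na(gr), NA_real_,
                                 mapply(function(a, g)
                                   if (a + g == 0) NA_real_ else a / (a + g),
                                   ar, gr))
  if (!is.null(sar_intensity)) {
    j <- match(sar, sar_intensity$sar_id)
    out$ic_ha <- sar_intensity$ic_per_ha[j]
    out$ai <- sar_intensity$ai[j]
    out$aggregated <- sar_intensity$aggregated[j]
  }
  out$complete <- stats::complete.cases(
    out[setdiff(names(out), c("site_id", "sar_id", "complete"))])
  out[order(out$site_id), , drop = FALSE]
}
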