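# Point-count aggregation rules of the national breeding-bird survey, and the
# four community descriptors (richness, CSI, CTI, CSIg) per 2x2 km site.
#
# The chain is: keep sites with >= 5 farmland points, pick 5 at random where
# there are more, take the maximum of the two spring visits per point and
# species, sum over the 5 points within a year, average over surveyed years,
# then form abundance-weighted community indices.

#' Select five farmland point counts per site
#'
#' Sites need at least five farmland point counts to enter the analysis; sites
#' with more than five get five drawn uniformly at random (once per site, the
#' same points in every year). A point's farmland status is taken from its
#' habitat class in the first year the site was surveyed.
#'
#' @param records Point-count record table with columns `site_id`, `point_id`,
#'   `year`, `habitat_class` (other columns ignored here).
#' @param n_select Number of points to retain per site (survey convention: 5).
#' @param seed Integer seed governing the random draw; mandatory so repeated
#'   runs select the same points.
#' @return A named list, one element per retained site, each an integer/character
#'   vector of the selected `point_id`s, sorted. Excluded sites (fewer than
#'   `n_select` farmland points) are reported in the `"excluded"` attribute.
#' @export
select_survey_points <- function(records, n_select = 5, seed) {
  stopifnot(is.data.frame(records))
  if (missing(seed)) stop("'seed' is required for reproducible point selection")
  rng <- local_rng(seed)
  on.exit(rng())
  sites <- sort(unique(records$site_id))
  sel <- list()
  excluded <- character(0)
  for (s in sites) {
    rs <- records[records$site_id == s, ]
    y0 <- min(rs$year)
    pts <- unique(rs[rs$year == y0, c("point_id", "habitat_class")])
    farm <- sort(unique(pts$point_id[pts$habitat_class == "farmland"]))
    if (length(farm) < n_select) {
      excluded <- c(excluded, s)
    } else if (length(farm) == n_select) {
      sel[[as.character(s)]] <- farm
    } else {
      sel[[as.character(s)]] <- sort(sample(farm, n_select))
    }
  }
  attr(sel, "excluded") <- excluded
  sel
}

#' Between-visit maximum count
#'
#' Each point is surveyed twice each spring; the count retained per point,
#' species and year is the maximum of the two visits. A missing visit counts 0.
#'
#' @param visit1,visit2 Non-negative integer count vectors (recycled); `NA`
#'   means the visit was not recorded and is treated as 0.
#' @return Elementwise maximum.
#' @examples
#' visit_max(3, 5)        # 5
#' visit_max(7, NA)       # 7
#' @export
visit_max <- function(visit1, visit2) {
  visit1[is.na(visit1)] <- 0
  visit2[is.na(visit2)] <- 0
  if (any(visit1 < 0) || any(visit2 < 0)) stop("counts must be non-negative")
  pmax(visit1, visit2)
}

# Per-point visit maxima for one site restricted to its selected points.
# Returns data.frame point_id, year, species_id, max_count.
point_maxima <- function(records) {
  agg <- stats::aggregate(count ~ point_id + year + species_id + visit,
                          data = records, FUN = sum)
  stats::aggregate(count ~ point_id + year + species_id, data = agg, FUN = max)
}

#' Yearly site abundance from per-point maxima
#'
#' Sums the between-visit maxima of the five selected points within a site and
#' year, per species: the yearly local relative abundance of the species on
#' that site.
#'
#' @param maxima Data frame with columns `point_id`, `year`, `species_id`,
#'   `count` (the per-point visit maxima).
#' @param selected_points The point ids selected for this site.
#' @return Data frame `year`, `species_id`, `abundance`.
#' @export
site_year_abundance <- function(maxima, selected_points) {
  stopifnot(is.data.frame(maxima))
  if (!all(maxima$point_id %in% selected_points))
    stop("maxima contain points outside the selected set")
  out <- stats::aggregate(count ~ year + species_id, data = maxima, FUN = sum)
  names(out)[names(out) == "count"] <- "abundance"
  out
}

#' Multi-year mean abundance
#'
#' Averages yearly abundances over the years a site was actually surveyed (a
#' species absent in a surveyed year contributes 0 to its mean), so that sites
#' surveyed in fewer years do not weigh less per year.
#'
#' @param yearly Data frame `year`, `species_id`, `abundance` for one site.
#' @param surveyed_years The years the site was surveyed (defaults to the years
#'   present in `yearly`).
#' @param species The species universe over which to report (defaults to those
#'   present).
#' @return Named numeric vector of mean abundance per species.
#' @export
multi_year_mean <- function(yearly, surveyed_years = unique(yearly$year),
                            species = unique(yearly$species_id)) {
  if (length(surveyed_years) == 0) stop("site has no surveyed years")
  out <- stats::setNames(numeric(length(species)), species)
  for (sp in species) {
    a <- yearly$abundance[yearly$species_id == sp &
                            yearly$year %in% surveyed_years]
    out[sp] <- sum(a) / length(surveyed_years)
  }
  out
}

#' Species richness of a site
#'
#' Number of community species with positive mean abundance.
#'
#' @param abundance Named numeric vector of per-species abundance.
#' @return Integer count.
#' @export
species_richness <- function(abundance) {
  stopifnot(is.numeric(abundance), all(abundance >= 0, na.rm = TRUE))
  sum(abundance > 0, na.rm = TRUE)
}

#' Abundance-weighted community index (CSI, CTI, CSIg)
#'
#' The community counterpart of a species trait is its abundance-weighted mean
#' over the 22-species community:
#' \deqn{C = \sum_i (N_i / N_{tot})\, t_i}
#' where \eqn{N_i} is the species' site abundance and \eqn{t_i} its trait value
#' (SSI for CSI, STI for CTI, SSIg for CSIg). Undefined (NA) when the total
#' abundance is zero.
#'
#' @param abundance Named numeric vector of per-species abundance; names must
#'   match `traits$species_id`. Species missing from `abundance` count 0.
#' @param traits Species trait table, default the packaged community
#'   ([farmland_species()]).
#' @param trait Which trait column to average: `"ssi"`, `"sti"` or `"ssig"`.
#' @return A single number, or `NA_real_` if the community is empty.
#' @examples
#' tr <- farmland_species()
#' ab <- c("Alauda arvensis" = 4, "Lullula arborea" = 4)
#' community_index(ab, tr, "sti")
#' @export
community_index <- function(abundance, traits = farmland_species(),
                            trait = c("ssi", "sti", "ssig")) {
  trait <- match.arg(trait)
  stopifnot(is.numeric(abundance), !is.null(names(abundance)))
  if (any(abundance < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  unknown <- setdiff(names(abundance), traits$species_id)
  if (length(unknown))
    warning("ignoring non-community species: ", paste(unknown, collapse = ", "))
  ab <- abundance[names(abundance) %in% traits$species_id]
  ntot <- sum(ab)
  if (length(ab) == 0 || ntot == 0) return(NA_real_)
  tv <- traits[[trait]][match(names(ab), traits$species_id)]
  sum(ab * tv) / ntot
}

#' Site-level community descriptors from raw point-count records
#'
#' Runs the whole survey aggregation chain (farmland-point filter and
#' selection, visit maxima, within-year point sums, multi-year averaging) and
#' computes the four community descriptors per site.
#'
#' @inheritParams select_survey_points
#' @param traits Species trait table ([farmland_species()] by default);
#'   records of species not in this table are ignored with a warning.
#' @param n_select Points retained per site.
#' @return A data.frame with one row per retained site: `site_id`, `n_years`,
#'   `richness`, `csi`, `cti`, `csig`, `flag` (`"ok"` or `"empty"` when no
#'   community bird was recorded, in which case the indices are NA). Excluded
#'   sites are listed in the `"excluded"` attribute.
#' @export
site_descriptors <- function(records, traits = farmland_species(),
                             n_select = 5, seed) {
  stopifnot(is.data.frame(records))
  unknown <- setdiff(unique(records$species_id), traits$species_id)
  if (length(unknown))
    warning("ignoring records of non-community species: ",
            paste(sort(unknown), collapse = ", "))
  records <- records[records$species_id %in% traits$species_id, , drop = FALSE]
  sel <- select_survey_points(records, n_select = n_select, seed = seed)
  rows <- vector("list", length(sel))
  for (i in seq_along(sel)) {
    s <- names(sel)[i]
    rs <- records[records$site_id == s, ]
    years <- sort(unique(rs$year))
    rs <- rs[rs$point_id %in% sel[[i]], ]
    if (nrow(rs)) {
      ab <- multi_year_mean(site_year_abundance(point_maxima(rs), sel[[i]]),
                            surveyed_years = years,
                            species = traits$species_id)
    } else {
      ab <- stats::setNames(numeric(nrow(traits)), traits$species_id)
    }
    empty <- sum(ab) == 0
    rows[[i]] <- data.frame(
      site_id = s, n_years = length(years),
      richness = species_richness(ab),
      csi = if (empty) NA_real_ else community_index(ab, traits, "ssi"),
      cti = if (empty) NA_real_ else community_index(ab, traits, "sti"),
      csig = if (empty) NA_real_ else community_index(ab, traits, "ssig"),
      flag = if (empty) "empty" else "ok",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site_id = character(), n_years = integer(),
                      richness = integer(), csi = numeric(), cti = numeric(),
                      csig = numeric(), flag = character())
  attr(out, "excluded") <- attr(sel, "excluded")
  out
}

# Run `expr`-style seeded draws without clobbering the caller's RNG stream:
# returns a restore function for on.exit().
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
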