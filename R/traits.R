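# Species-level indices: habitat specialisation (SSI), trophic position (STI),
# grassland specialisation (SSIg), and the packaged 22-species farmland community.

#' The seven habitat classes of the breeding-bird survey
#'
#' Habitat classes recorded alongside point counts, in the conventional order.
#' Farmland is the class whose points qualify a site for the farmland-community
#' analysis; the remaining six classes enter only the SSI computation.
#'
#' @format Character vector of length 7.
#' @export
habitat_classes <- c("forest", "heath_scrub", "marshland", "farmland",
                     "urban", "wetland_aquatic", "rocks")

#' The four farmland sub-habitats, from most grassland to most arable
#'
#' Order matters: the grassland specialisation index weights these 4, 3, 2, 1.
#'
#' @format Character vector of length 4.
#' @export
farmland_subhabitats <- c("unimproved_grassland", "improved_grassland",
                          "mixed_grassland_arable", "arable")

#' Species specialisation index (SSI)
#'
#' The SSI of a species is the coefficient of variation (standard deviation
#' divided by the mean) of its density across the seven habitat classes.
#' A habitat generalist, equally dense everywhere, scores 0; a species confined
#' to a single class scores \eqn{\sqrt{7}} (sample sd). Classes where the
#' species was never recorded contribute density 0, not missing.
#'
#' @param densities Numeric vector of length 7: mean density (birds per point
#'   count) in each habitat class, in the order of [habitat_classes].
#' @param sd_type `"sample"` (default, n-1 denominator) or `"population"`
#'   (n denominator) standard deviation.
#' @return A single non-negative number.
#' @examples
#' species_ssi(c(0.4, 0, 0, 1.6, 0.1, 0, 0))
#' species_ssi(rep(0.3, 7))  # perfect generalist: 0
#' @seealso [species_sti()], [species_ssig()], [community_index()]
#' @export
species_ssi <- function(densities, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.numeric(densities))
  if (length(densities) != length(habitat_classes))
    stop("'densities' must have exactly ", length(habitat_classes),
         " entries, one per habitat class")
  if (any(is.na(densities)) || any(densities < 0))
    stop("'densities' must be non-negative and complete")
  m <- mean(densities)
  if (m == 0) stop("SSI undefined: species has zero density in every habitat class")
  s <- stats::sd(densities)
  if (sd_type == "population")
    s <- s * sqrt((length(densities) - 1) / length(densities))
  s / m
}

#' Species trophic index (STI)
#'
#' Diet-weighted score: proportions of seeds/plants, invertebrates and
#' vertebrates in the diet weighted by 1, 2 and 3. Ranges from 1 (pure
#' granivore/herbivore) to 3 (pure vertebrate diet).
#'
#' @param diet Numeric vector of length 3 `(seeds_plants, invertebrates,
#'   vertebrates)`, non-negative, summing to 1.
#' @param tol Tolerance on the sum-to-one constraint.
#' @return A number in `[1, 3]`.
#' @examples
#' species_sti(c(1, 0, 0))        # 1: granivore
#' species_sti(c(0.5, 0.5, 0))    # 1.5
#' @export
species_sti <- function(diet, tol = 1e-9) {
  stopifnot(is.numeric(diet))
  if (length(diet) != 3 || any(is.na(diet)) || any(diet < 0))
    stop("'diet' must be 3 non-negative proportions (seeds/plants, invertebrates, vertebrates)")
  if (abs(sum(diet) - 1) > tol)
    stop("diet proportions must sum to 1 (got ", format(sum(diet)), ")")
  sum(c(1, 2, 3) * diet)
}

#' Species grassland specialisation index (SSIg)
#'
#' Abundance-weighted mean over the four farmland sub-habitats with weights
#' 4 (unimproved grassland), 3 (improved grassland), 2 (mixed), 1 (arable).
#' High values mark grassland specialists, low values arable specialists.
#'
#' @param abundance Numeric vector of length 4: the species' abundance in each
#'   sub-habitat, in the order of [farmland_subhabitats].
#' @return A number in `[1, 4]`.
#' @examples
#' species_ssig(c(0, 0, 0, 10))  # strict arable species: 1
#' species_ssig(rep(5, 4))       # even use: 2.5
#' @export
species_ssig <- function(abundance) {
  stopifnot(is.numeric(abundance))
  if (length(abundance) != length(farmland_subhabitats) ||
      any(is.na(abundance)) || any(abundance < 0))
    stop("'abundance' must be 4 non-negative values, one per farmland sub-habitat")
  tot <- sum(abundance)
  if (tot == 0) stop("SSIg undefined: zero abundance in all farmland sub-habitats")
  sum(c(4, 3, 2, 1) * abundance / tot)
}

#' The 22-species farmland bird community and its trait indices
#'
#' Returns the packaged table of the 22 European farmland bird species used
#' throughout the package, with their habitat specialisation (`ssi`), trophic
#' (`sti`) and grassland specialisation (`ssig`) indices.
#'
#' @return A data.frame with columns `species_id`, `ssi`, `sti`, `ssig`
#'   (22 rows, ordered by increasing `ssig`).
#' @examples
#' tr <- farmland_species()
#' tr[tr$species_id == "Alauda arvensis", ]
#' @export
farmland_species <- function() {
  path <- system.file("extdata", "farmland_species.tsv", package = "farmbird")
  if (!nzchar(path) || !file.exists(path))
    stop("packaged species trait table not found; reinstall the package")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species_id", "ssi", "sti", "ssig")
  if (!identical(names(tab), need))
    stop("species trait table is corrupt: expected columns ",
         paste(need, collapse = ", "))
  if (anyNA(tab) || any(tab$ssi < 0) ||
      any(tab$sti < 1 | tab$sti > 3) || any(tab$ssig < 1 | tab$ssig > 4))
    stop("species trait table is corrupt: values out of range")
  tab
}

#' Mean density per habitat class from point-count records
#'
#' Helper for computing SSI from survey data: averages a species' per-point
#' count over all points of each habitat class (points where the species was
#' absent count 0), returning one mean density per class.
#'
#' @param records Point-count records, see [simulate_scenario()] for the layout
#'   (`site_id`, `point_id`, `visit`, `year`, `species_id`, `count`,
#'   `habitat_class`).
#' @param species Species to profile (single id).
#' @return Named numeric vector over [habitat_classes].
#' @export
habitat_mean_density <- function(records, species) {
  stopifnot(is.data.frame(records))
  pts <- unique(records[c("site_id", "point_id", "year", "habitat_class")])
  sp <- records[records$species_id == species, ]
  key <- function(d) paste(d$site_id, d$point_id, d$year)
  # per point-year: sum within visit, then the between-visit maximum
  vk <- paste(key(sp), sp$visit)
  per_visit <- tapply(sp$count, vk, sum)
  cnt <- tapply(per_visit, sub(" [^ ]+$", "", names(per_visit)), max)
  pts$count <- ifelse(key(pts) %in% names(cnt), cnt[key(pts)], 0)
  out <- stats::setNames(numeric(length(habitat_classes)), habitat_classes)
  got <- tapply(pts$count, factor(pts$habitat_class, habitat_classes), mean)
  out[!is.na(got)] <- got[!is.na(got)]
  out
}
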