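make_records <- function(n_farm_points, site = "s1", year = 2006) {
  pts <- seq_len(10)
  hab <- rep("forest", 10)
  hab[seq_len(n_farm_points)] <- "farmland"
  data.frame(site_id = site, point_id = pts, visit = 1, year = year,
             species_id = "Alauda arvensis", count = 1, habitat_class = hab,
             stringsAsFactors = FALSE)
}

test_that("farmland point selection filters, keeps and samples correctly", {
  # too few farmland points: site excluded
  sel <- select_survey_points(make_records(3), seed = 1)
  expect_length(sel, 0)
  expect_equal(attr(sel, "excluded"), "s1")
  # exactly five: kept whatever the seed
  s5a <- select_survey_points(make_records(5), seed = 1)
  s5b <- select_survey_points(make_records(5), seed = 999)
  expect_equal(s5a$s1, 1:5)
  expect_equal(s5a$s1, s5b$s1)
  # eight farmland points: five drawn, reproducibly, from the farmland set
  r8 <- make_records(8)
  s8a <- select_survey_points(r8, seed = 7)
  s8b <- select_survey_points(r8, seed = 7)
  expect_length(s8a$s1, 5)
  expect_true(all(s8a$s1 %in% 1:8))
  expect_identical(s8a$s1, s8b$s1)
  # farmland status from the first surveyed year governs selection
  r2 <- make_records(8)
  later <- make_records(2, year = 2007)
  sel2 <- select_survey_points(rbind(r2, later), seed = 7)
  expect_identical(sel2$s1, s8a$s1)
})

test_that("visit maxima treat a missing visit as zero", {
  expect_equal(visit_max(3, 5), 5)
  expect_equal(visit_max(0, 0), 0)
  expect_equal(visit_max(7, NA), 7)
  expect_equal(visit_max(c(1, 4, NA), c(2, 2, 3)), c(2, 4, 3))
  expect_error(visit_max(-1, 2), "non-negative")
})

test_that("site-year abundance is the sum of per-point maxima over 5 points", {
  mx <- data.frame(point_id = 1:5, year = 2006, species_id = "sp",
                   count = c(1, 0, 2, 0, 1))
  ab <- site_year_abundance(mx, 1:5)
  expect_equal(ab$abundance, 4)
  expect_error(site_year_abundance(mx, 2:6), "outside")
  # random table equals a brute-force nested-loop sum
  set.seed(5)
  big <- expand.grid(point_id = 1:5, year = 2006:2007, species_id = c("a", "b"))
  big$count <- rpois(nrow(big), 3)
  got <- site_year_abundance(big, 1:5)
  for (i in seq_len(nrow(got))) {
    tot <- 0
    for (j in seq_len(nrow(big)))
      if (big$year[j] == got$year[i] && big$species_id[j] == got$species_id[i])
        tot <- tot + big$count[j]
    expect_equal(got$abundance[i], tot)
  }
})

test_that("multi-year averaging uses surveyed years only", {
  y <- data.frame(year = c(2006, 2007), species_id = "sp",
                  abundance = c(4, 6))
  expect_equal(unname(multi_year_mean(y)), 5)
  y1 <- data.frame(year = 2006, species_id = "sp", abundance = 3)
  expect_equal(unname(multi_year_mean(y1)), 3)
  y3 <- data.frame(year = 2006:2008, species_id = "sp", abundance = c(1, 2, 6))
  expect_equal(unname(multi_year_mean(y3)), 3)
  # a species missing in a surveyed year contributes zero for that year
  expect_equal(unname(multi_year_mean(y1, surveyed_years = 2006:2007)), 1.5)
})

test_that("richness counts strictly positive mean abundances", {
  expect_equal(species_richness(setNames(rep(1, 22), paste0("s", 1:22))), 22)
  expect_equal(species_richness(setNames(numeric(3), c("a", "b", "c"))), 0)
  ab <- c(a = 0.5, b = 0, c = 1.2, d = 0)
  expect_equal(species_richness(ab), 2)
})

test_that("community indices are abundance-weighted trait means", {
  tr <- farmland_species()
  # a single species present: the community index is its trait value
  ab1 <- setNames(3.2, "Perdix perdix")
  expect_equal(community_index(ab1, tr, "ssi"), 1.31)
  expect_equal(community_index(ab1, tr, "ssig"), 1.25)
  # two species, equal abundance, STI 1 and 3 -> CTI 2
  toy <- data.frame(species_id = c("g", "v"), ssi = c(1, 1),
                    sti = c(1, 3), ssig = c(1, 4))
  expect_equal(community_index(c(g = 2, v = 2), toy, "sti"), 2)
  # random abundances against the brute-force oracle, all three indices
  set.seed(11)
  for (i in 1:20) {
    ab <- setNames(rgamma(22, 1), tr$species_id)
    for (trait in c("ssi", "sti", "ssig")) {
      got <- community_index(ab, tr, trait)
      expect_equal(got, oracle_community_index(ab, tr[[trait]]),
                   tolerance = 1e-12)
      # bounded by the trait range, invariant to abundance scaling
      expect_gte(got, min(tr[[trait]])); expect_lte(got, max(tr[[trait]]))
      expect_equal(community_index(ab * 5.5, tr, trait), got,
                   tolerance = 1e-12)
    }
    # adding a species with zero abundance changes nothing
    ab0 <- ab; ab0[sample(22, 1)] <- 0
    expect_equal(community_index(ab0, tr, "sti"),
                 oracle_community_index(ab0, tr$sti), tolerance = 1e-12)
  }
  # empty community: undefined
  expect_true(is.na(community_index(setNames(0, "Perdix perdix"), tr, "ssi")))
  expect_warning(community_index(c("Tyto alba" = 1, "Perdix perdix" = 1), tr,
                                 "ssi"), "non-community")
})

test_that("the survey chain is deterministic given the seed", {
  sim <- simulate_scenario(scenario_config(rows = 3, cols = 4, n_sites = 15,
                                           seed = 21))
  d1 <- site_descriptors(sim$records, seed = 9)
  d2 <- site_descriptors(sim$records, seed = 9)
  expect_identical(d1, d2)
  expect_true(all(d1$richness <= 22))
  ok <- d1$flag == "ok"
  expect_true(all(d1$cti[ok] >= 1 & d1$cti[ok] <= 3))
  expect_true(all(d1$csig[ok] >= 1 & d1$csig[ok] <= 4))
})
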