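one_farm <- function(sar = "s1", year = 2004, area = 100, cost_each = NULL,
                     type = "cereals", id = "f1") {
  costs <- if (is.null(cost_each)) rep(40000 / 7, 7) else cost_each
  df <- data.frame(farm_id = id, sar_id = sar, production_type = type,
                   year = year, t(costs), utilised_area = area,
                   stringsAsFactors = FALSE)
  names(df)[5:11] <- input_cost_categories
  df
}

test_that("IC/ha is total cost over total area, averaged over years", {
  # one farm, 40,000 EUR over 100 ha -> 400 EUR/ha
  f <- one_farm()
  expect_equal(ic_per_ha(f, years = 2004)$ic_per_ha, 400)
  # yearly ratios 300, 400, 500 -> three-year mean 400
  f3 <- rbind(one_farm(year = 2004, cost_each = rep(30000 / 7, 7)),
              one_farm(year = 2005, cost_each = rep(40000 / 7, 7)),
              one_farm(year = 2006, cost_each = rep(50000 / 7, 7)))
  expect_equal(ic_per_ha(f3)$ic_per_ha, 400)
  # multi-farm random table against the brute-force oracle
  set.seed(31)
  for (i in 1:10) {
    farms <- random_farms()
    suppressWarnings({
      got <- ic_per_ha(farms)
      want <- oracle_ic_per_ha(farms, 2004:2006, eligible_production_types)
    })
    expect_equal(setNames(got$ic_per_ha, got$sar_id), want[got$sar_id],
                 tolerance = 1e-12)
  }
})

test_that("IC/ha is invariant to splitting a farm and honours the cost identity", {
  f <- one_farm(cost_each = c(10, 20, 30, 40, 50, 60, 70) * 100)
  half <- f; half$utilised_area <- 50
  half[input_cost_categories] <- half[input_cost_categories] / 2
  half2 <- half; half2$farm_id <- "f2"
  expect_equal(ic_per_ha(rbind(half, half2), years = 2004)$ic_per_ha,
               ic_per_ha(f, years = 2004)$ic_per_ha)
  # no category silently dropped: IC equals the sum of the seven categories
  expect_equal(ic_per_ha(f, years = 2004)$ic_per_ha * 100,
               sum(f[input_cost_categories]))
})

test_that("excluded production types never enter the indicator", {
  f <- one_farm()
  wine <- one_farm(type = "wine", id = "f9",
                   cost_each = rep(1e6, 7), area = 10)
  expect_equal(ic_per_ha(rbind(f, wine), years = 2004)$ic_per_ha, 400)
  # mean-of-ratios variant
  f2 <- rbind(one_farm(), one_farm(id = "f2", area = 200))
  expect_equal(ic_per_ha(f2, years = 2004, method = "mean_of_ratios")$ic_per_ha,
               mean(c(400, 200)))
})

test_that("the two-thirds area rule is strict at the boundary", {
  mk <- function(area) one_farm(area = area)
  tot <- data.frame(sar_id = "s1", total_area = 100)
  expect_equal(sar_eligibility(mk(70), tot, years = 2004), "s1")
  expect_length(sar_eligibility(mk(60), tot, years = 2004), 0)
  # exactly two-thirds: excluded under the strict inequality
  tot3 <- data.frame(sar_id = "s1", total_area = 3)
  expect_length(sar_eligibility(mk(2), tot3, years = 2004), 0)
  expect_error(sar_eligibility(mk(70), data.frame(sar_id = "zz",
                                                  total_area = 1),
                               years = 2004), "missing")
})

test_that("the aggregation index is the gap to the neighbourhood mean", {
  units <- c("a", "b", "c", "d")
  w <- contiguity_matrix(data.frame(u = c("a", "a", "a"),
                                    v = c("b", "c", "d")), units)
  # a sits at 500 among neighbours 300, 500, 400 -> AI = 100
  x <- c(a = 500, b = 300, c = 500, d = 400)
  expect_equal(unname(aggregation_index(x, w)["a"]), 100)
  # constant field: identically zero
  expect_equal(unname(aggregation_index(c(a = 7, b = 7, c = 7, d = 7), w)),
               rep(0, 4))
  # translation invariance
  set.seed(13)
  for (i in 1:10) {
    ww <- random_weights(8)
    xx <- setNames(runif(8, 100, 900), rownames(ww))
    ai <- aggregation_index(xx, ww)
    expect_equal(aggregation_index(xx + 123.4, ww), ai, tolerance = 1e-9)
    expect_equal(ai, oracle_aggregation_index(xx, ww), tolerance = 1e-12)
  }
  # isolated unit: AI undefined
  w0 <- contiguity_matrix(data.frame(u = "a", v = "b"), units)
  expect_true(is.na(aggregation_index(x, w0)["c"]))
})

test_that("aggregation classification follows the |AI| < mean|AI| rule", {
  ai <- c(a = 0, b = 0, c = 200, d = 200)
  expect_equal(unname(classify_aggregated(ai)), c(1L, 1L, 0L, 0L))
  # single region at AI 0: mean |AI| is 0, strict < fails -> non-aggregated
  expect_equal(unname(classify_aggregated(c(a = 0))), 0L)
  # sign symmetry of the default rule
  ai2 <- c(a = -50, b = 120, c = 10, d = -200)
  expect_equal(classify_aggregated(ai2), classify_aggregated(-ai2))
  # signed variant
  expect_equal(unname(classify_aggregated(c(a = -1, b = 1),
                                          rule = "signed_mean")), c(1L, 0L))
  expect_error(classify_aggregated(c(a = NA_real_)), "no defined")
})
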