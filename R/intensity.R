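# The input-cost-per-hectare (IC/ha) agricultural intensity indicator at the
# Small Agricultural Region (SAR) level, and its spatial aggregation index.

#' Production types entering the IC/ha indicator
#'
#' The indicator is computed over the five production types that jointly cover
#' the bulk of agricultural land; vegetables, granivore livestock (poultry,
#' pigs), wine and orchards are excluded.
#'
#' @format Character vector of length 5.
#' @export
eligible_production_types <- c("industrial crops", "cereals", "bovine dairy",
                               "bovine meat", "mixed")

#' Input-cost categories of the intensity indicator
#' @format Character vector of length 7.
#' @export
input_cost_categories <- c("fertilizers", "feedstuff", "pesticides", "seeds",
                           "fuel", "veterinary", "irrigation")

#' IC/ha agricultural intensity per region
#'
#' For each Small Agricultural Region (SAR) and year, sums the seven input-cost
#' categories over the eligible farms and divides by their summed utilised
#' agricultural area; the per-year ratios are then averaged over `years`
#' (a 3-year average irons out input price and stock fluctuations).
#'
#' @param farms Farm record table: one row per farm and year, columns
#'   `farm_id`, `sar_id`, `production_type`, `year`, `utilised_area` (ha, > 0)
#'   and the seven cost columns of [input_cost_categories] (Euros).
#' @param years Years to average over (default 2004:2006, the window behind
#'   the reference 2006 value).
#' @param method `"ratio_of_sums"` (default; SAR totals, i.e. area-weighted) or
#'   `"mean_of_ratios"` (unweighted mean of per-farm IC/ha).
#' @return Data frame `sar_id`, `ic_per_ha` (Euros/ha), one row per SAR with
#'   eligible farm area in at least one of `years`. SARs with no eligible area
#'   are dropped with a warning.
#' @export
ic_per_ha <- function(farms, years = 2004:2006,
                      method = c("ratio_of_sums", "mean_of_ratios")) {
  method <- match.arg(method)
  check_farm_table(farms)
  f <- farms[farms$production_type %in% eligible_production_types &
               farms$year %in% years, , drop = FALSE]
  all_sars <- sort(unique(farms$sar_id))
  if (nrow(f) == 0) stop("no eligible farm records in the requested years")
  f$total_cost <- rowSums(f[input_cost_categories])
  key <- interaction(f$sar_id, f$year, drop = TRUE)
  if (method == "ratio_of_sums") {
    ratio <- tapply(f$total_cost, key, sum) / tapply(f$utilised_area, key, sum)
  } else {
    ratio <- tapply(f$total_cost / f$utilised_area, key, mean)
  }
  sar_of <- sub("\\.[^.]+$", "", names(ratio))
  out <- data.frame(sar_id = sort(unique(sar_of)))
  out$ic_per_ha <- as.numeric(tapply(ratio, sar_of, mean)[out$sar_id])
  dropped <- setdiff(all_sars, out$sar_id)
  if (length(dropped))
    warning("SARs with no eligible farm area excluded: ",
            paste(dropped, collapse = ", "))
  out
}

check_farm_table <- function(farms) {
  stopifnot(is.data.frame(farms))
  need <- c("farm_id", "sar_id", "production_type", "year", "utilised_area",
            input_cost_categories)
  miss <- setdiff(need, names(farms))
  if (length(miss))
    stop("farm table lacks columns: ", paste(miss, collapse = ", "))
  if (any(farms$utilised_area <= 0)) stop("utilised_area must be > 0")
  if (any(as.matrix(farms[input_cost_categories]) < 0))
    stop("input costs must be non-negative")
  invisible(farms)
}

#' Regions dominated by the five eligible production types
#'
#' A SAR enters the analysis only if the area of the five eligible production
#' types strictly exceeds two-thirds of its total agricultural area.
#'
#' @param farms Farm record table (see [ic_per_ha()]).
#' @param total_area Data frame `sar_id`, `total_area` (ha): total agricultural
#'   area per SAR, all production types included.
#' @param years Years over which eligible area is averaged before the test.
#' @return Character vector of eligible `sar_id`s.
#' @export
sar_eligibility <- function(farms, total_area, years = 2004:2006) {
  check_farm_table(farms)
  stopifnot(is.data.frame(total_area),
            all(c("sar_id", "total_area") %in% names(total_area)))
  f <- farms[farms$production_type %in% eligible_production_types &
               farms$year %in% years, , drop = FALSE]
  key <- interaction(f$sar_id, f$year, drop = TRUE)
  per_year <- tapply(f$utilised_area, key, sum)
  sar_of <- sub("\\.[^.]+$", "", names(per_year))
  elig_area <- tapply(per_year, sar_of, mean)
  sars <- sort(unique(farms$sar_id))
  tot <- total_area$total_area[match(sars, total_area$sar_id)]
  if (anyNA(tot))
    stop("total agricultural area missing for SARs: ",
         paste(sars[is.na(tot)], collapse = ", "))
  ea <- ifelse(sars %in% names(elig_area), elig_area[sars], 0)
  sars[3 * ea > 2 * tot]   # strict inequality, exact at the boundary
}

#' Spatial aggregation index of agricultural intensity
#'
#' For each region, the difference between its IC/ha and the mean IC/ha of its
#' contiguous neighbours:
#' \deqn{AI_i = X_i - \frac{\sum_j w_{ij} X_j}{\sum_j w_{ij}}}
#' where `w` is the binary contiguity matrix. A small magnitude means the
#' region sits among neighbours of similar intensity (spatially aggregated
#' intensity); regions with no neighbour get `NA`.
#'
#' @param x Named numeric vector of per-region IC/ha; names must match the
#'   row/column names of `w`.
#' @param w Binary symmetric contiguity matrix (see [contiguity_matrix()]).
#' @return Named numeric vector of AI values (Euros/ha, signed), `NA` for
#'   isolated regions.
#' @export
aggregation_index <- function(x, w) {
  check_weights(w)
  if (is.null(names(x)) || !identical(sort(names(x)), sort(rownames(w))))
    stop("'x' must be named and match the units of 'w'")
  x <- x[rownames(w)]
  deg <- rowSums(w)
  ai <- x - as.numeric(w %*% x) / deg
  ai[deg == 0] <- NA_real_
  stats::setNames(ai, rownames(w))
}

#' Classify regions as intensity-aggregated or not
#'
#' Default rule: a region is aggregated (1) when the magnitude of its
#' aggregation index is strictly below the mean magnitude over all scored
#' regions — i.e. its intensity resembles its neighbours' more than average.
#' The published wording ("AI lower than the average value") is ambiguous, so
#' a signed-mean variant is selectable.
#'
#' @param ai Named numeric AI vector (NA allowed for isolated regions).
#' @param rule `"abs_mean"` (default): `|AI_i| < mean(|AI|)`;
#'   `"signed_mean"`: `AI_i < mean(AI)`.
#' @return Named integer vector: 1 aggregated, 0 non-aggregated, NA where AI
#'   is undefined.
#' @export
classify_aggregated <- function(ai, rule = c("abs_mean", "signed_mean")) {
  rule <- match.arg(rule)
  if (all(is.na(ai))) stop("no defined AI values to classify")
  flag <- rep(NA_integer_, length(ai))
  ok <- !is.na(ai)
  if (rule == "abs_mean") {
    flag[ok] <- as.integer(abs(ai[ok]) < mean(abs(ai[ok])))
  } else {
    flag[ok] <- as.integer(ai[ok] < mean(ai[ok]))
  }
  stats::setNames(flag, names(ai))
}

#' SAR intensity table: IC/ha, aggregation index and class
#'
#' Convenience wrapper chaining [ic_per_ha()], [aggregation_index()] and
#' [classify_aggregated()].
#'
#' @inheritParams ic_per_ha
#' @inheritParams aggregation_index
#' @inheritParams classify_aggregated
#' @return Data frame `sar_id`, `ic_per_ha`, `ai`, `aggregated`.
#' @export
sar_intensity <- function(farms, w, years = 2004:2006,
                          rule = c("abs_mean", "signed_mean")) {
  ic <- ic_per_ha(farms, years = years)
  if (!all(rownames(w) %in% ic$sar_id))
    stop("intensity missing for SARs: ",
         paste(setdiff(rownames(w), ic$sar_id), collapse = ", "))
  x <- stats::setNames(ic$ic_per_ha, ic$sar_id)[rownames(w)]
  ai <- aggregation_index(x, w)
  data.frame(sar_id = rownames(w), ic_per_ha = as.numeric(x),
             ai = as.numeric(ai),
             aggregated = as.integer(classify_aggregated(ai, rule)),
             stringsAsFactors = FALSE)
}
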