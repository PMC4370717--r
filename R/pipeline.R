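# Table validation, scenario serialisation, and the end-to-end pipeline:
# intensity -> spatial -> survey -> covariates -> models, from delimited text
# tables to descriptor tables, fit reports and diagnostics.

table_schemas <- list(
  survey = list(cols = c("site_id", "point_id", "visit", "year", "species_id",
                         "count", "habitat_class", "subhabitat")),
  farms = list(cols = c("farm_id", "sar_id", "production_type", "year",
                        input_cost_categories, "utilised_area")),
  edges = list(cols = c("unit_a", "unit_b")),
  centroids = list(cols = c("sar_id", "x_km", "y_km")),
  clc_areas = list(cols = c("site_id", "category", "area_km2")),
  altitude = list(cols = c("site_id", "altitude_m")),
  climate = list(cols = c("sar_id", "year", "temp_c", "precip_mm")),
  site_sar = list(cols = c("site_id", "sar_id")),
  sar_landuse = list(cols = c("sar_id", "arable_area", "grassland_area")),
  total_area = list(cols = c("sar_id", "total_area")))

#' Validate the pipeline's input tables
#'
#' Checks each table against its expected schema and row-level invariants
#' (non-negative integer counts, valid habitat classes, positive areas,
#' sub-habitat only on farmland points, ...). Nothing is modified; the return
#' value lists every violation found.
#'
#' @param tables Named list of data.frames and/or file paths (tab-delimited
#'   with headers). Recognised names: `survey`, `farms`, `edges`, `centroids`,
#'   `clc_areas`, `altitude`, `climate`, `site_sar`, `sar_landuse`,
#'   `total_area`.
#' @return Data frame `table`, `row`, `rule` — empty when everything is valid.
#' @export
validate_tables <- function(tables) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  bad_names <- setdiff(names(tables), names(table_schemas))
  if (length(bad_names))
    stop("unknown table names: ", paste(bad_names, collapse = ", "))
  v <- list()
  note <- function(tab, row, rule)
    v[[length(v) + 1]] <<- data.frame(table = tab, row = row, rule = rule,
                                      stringsAsFactors = FALSE)
  for (nm in names(tables)) {
    d <- tables[[nm]]
    if (is.character(d)) {
      if (!file.exists(d)) stop("cannot read file: ", d)
      d <- utils::read.delim(d, stringsAsFactors = FALSE)
    }
    want <- table_schemas[[nm]]$cols
    miss <- setdiff(want, names(d))
    if (length(miss)) {
      note(nm, NA_integer_, paste("missing columns:", paste(miss, collapse = ", ")))
      next
    }
    bad <- function(cond, rule) {
      i <- which(cond)
      for (j in i) note(nm, j, rule)
    }
    if (nm == "survey") {
      bad(d$count < 0 | d$count != round(d$count), "count must be a non-negative integer")
      bad(!d$habitat_class %in% habitat_classes, "invalid habitat_class")
      bad(!d$visit %in% c(1, 2), "visit must be 1 or 2")
      bad(d$habitat_class == "farmland" &
            !(d$subhabitat %in% farmland_subhabitats),
          "farmland point lacks a valid subhabitat")
      bad(d$habitat_class != "farmland" & !is.na(d$subhabitat),
          "subhabitat on a non-farmland point")
    } else if (nm == "farms") {
      bad(d$utilised_area <= 0, "utilised_area must be > 0")
      for (cc in input_cost_categories)
        bad(d[[cc]] < 0, paste(cc, "cost must be non-negative"))
    } else if (nm == "edges") {
      bad(d$unit_a == d$unit_b, "self-edge")
    } else if (nm == "clc_areas") {
      bad(d$area_km2 < 0, "area_km2 must be non-negative")
      bad(!d$category %in% clc_categories, "unknown land-cover category")
    } else if (nm == "altitude") {
      bad(is.na(d$altitude_m), "missing altitude")
    } else if (nm == "climate") {
      bad(d$precip_mm < 0, "precipitation must be non-negative")
    } else if (nm == "sar_landuse") {
      bad(d$arable_area < 0 | d$grassland_area < 0, "areas must be non-negative")
    } else if (nm == "total_area") {
      bad(d$total_area <= 0, "total_area must be > 0")
    }
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(table = character(), row = integer(), rule = character())
}

#' Write a synthetic scenario to delimited text tables
#'
#' Serialises the output of [simulate_scenario()] as the tab-delimited input
#' files consumed by [run_pipeline()], plus a `truth.tsv` with the generating
#' intensity field (for recovery checks).
#'
#' @param sim Output of [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) {
    p <- file.path(dir, f)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    survey = wt(sim$records, "survey.tsv"),
    farms = wt(sim$landscape$farms, "farms.tsv"),
    edges = wt(sim$landscape$edges, "edges.tsv"),
    centroids = wt(sim$landscape$centroids, "centroids.tsv"),
    total_area = wt(sim$landscape$total_area, "total_area.tsv"),
    clc_areas = wt(sim$covariates$clc_areas, "clc_areas.tsv"),
    altitude = wt(sim$covariates$altitude, "altitude.tsv"),
    climate = wt(sim$covariates$climate, "climate.tsv"),
    site_sar = wt(sim$covariates$site_sar, "site_sar.tsv"),
    sar_landuse = wt(sim$covariates$sar_landuse, "sar_landuse.tsv"),
    truth = wt(data.frame(sar_id = names(sim$landscape$intensity),
                          intensity = as.numeric(sim$landscape$intensity)),
               "truth.tsv"))
  invisible(paths)
}

read_input <- function(x) {
  if (is.character(x)) utils::read.delim(x, stringsAsFactors = FALSE) else x
}

#' Run the full analysis pipeline
#'
#' Sequences the whole analysis: IC/ha intensity and aggregation per region,
#' survey aggregation to the four community descriptors per site, covariate
#' assembly, fixed-df spline models with backward AIC selection and LOO-CV
#' error for each descriptor, the intensity-by-aggregation interaction model
#' for the grassland specialisation index, and residual diagnostics including
#' the Moran permutation test. Optionally writes all result tables and a
#' reproducibility manifest.
#'
#' @param tables Named list of input tables or file paths (see
#'   [validate_tables()]); `survey`, `farms`, `edges`, `clc_areas`,
#'   `altitude`, `climate`, `site_sar`, `sar_landuse` are required.
#' @param seed Integer seed (point selection and permutation tests).
#' @param out_dir Optional output directory; when given, result tables are
#'   written as tab-delimited text with a manifest recording the seed and a
#'   hash of the inputs.
#' @param years Farm accounting years for the intensity indicator.
#' @param n_perm Permutations for the residual Moran tests.
#' @param smooth_df Spline df for the intensity term.
#' @return A list: `sar_intensity`, `descriptors`, `covariates` (merged
#'   model table), `fits` (per-descriptor selected `"icm"` fits), `cv_error`
#'   (per-descriptor LOO-CV %), `interaction_fit`, `diagnostics`,
#'   `validation`.
#' @export
run_pipeline <- function(tables, seed, out_dir = NULL, years = 2004:2006,
                         n_perm = 199, smooth_df = 2) {
  if (missing(seed)) stop("'seed' is required")
  need <- c("survey", "farms", "edges", "clc_areas", "altitude", "climate",
            "site_sar", "sar_landuse")
  miss <- setdiff(need, names(tables))
  if (length(miss))
    stop("pipeline halted at input stage: missing tables ",
         paste(miss, collapse = ", "))
  val <- validate_tables(tables)
  if (nrow(val))
    stop("pipeline halted at validation stage: ", nrow(val),
         " violation(s); run validate_tables() for the list")
  tb <- lapply(tables, read_input)

  # --- intensity stage ---------------------------------------------------
  sars <- sort(unique(tb$farms$sar_id))
  w <- contiguity_matrix(tb$edges, sars)
  if (!is.null(tb$total_area)) {
    elig <- sar_eligibility(tb$farms, tb$total_area, years = years)
    if (length(elig) < 3)
      stop("pipeline halted at intensity stage: fewer than 3 eligible regions")
    w <- w[elig, elig, drop = FALSE]
    tb$farms <- tb$farms[tb$farms$sar_id %in% elig, , drop = FALSE]
  }
  sar_tab <- sar_intensity(tb$farms, w, years = years)

  # --- survey stage ------------------------------------------------------
  desc <- site_descriptors(tb$survey, seed = seed)

  # --- covariates stage --------------------------------------------------
  cov <- assemble_covariates(tb$clc_areas, tb$altitude, tb$climate,
                             tb$site_sar, tb$sar_landuse,
                             sar_intensity = sar_tab)
  dat <- merge(desc, cov, by = "site_id")
  dat <- dat[dat$flag == "ok" & dat$complete, , drop = FALSE]
  if (nrow(dat) < 30)
    stop("pipeline halted at covariates stage: fewer than 30 usable sites")

  # --- model stage -------------------------------------------------------
  base_terms <- c("altitude", "temp", "precip", "arable_grassland",
                  "non_irrigated_arable", "pastures", "complex_cultivation",
                  "shannon")
  smooth_term <- sprintf("s(ic_ha, %d)", smooth_df)
  fits <- list(); cv <- c(); diags <- list()
  for (resp in c("richness", "csi", "cti", "csig")) {
    fml <- stats::as.formula(paste(resp, "~", paste(c(smooth_term, base_terms),
                                                    collapse = " + ")))
    fit <- backward_select(icm(fml, dat, keep = smooth_term))
    fits[[resp]] <- fit
    cv[resp] <- loo_cv_error(fit)
    diags[[resp]] <- residual_diagnostics(
      fit, dat$sar_id[fit$rows], w, n_perm = n_perm, seed = seed + 7L)
  }
  ifml <- stats::as.formula(paste("csig ~ ic_ha * aggregated +",
                                  paste(base_terms, collapse = " + ")))
  ifit <- backward_select(fit_interaction_model(ifml, dat))

  out <- list(sar_intensity = sar_tab, descriptors = desc, covariates = dat,
              fits = fits, cv_error = cv, interaction_fit = ifit,
              diagnostics = diags, validation = val, seed = seed)

  if (!is.null(out_dir)) write_pipeline_outputs(out, tables, out_dir)
  out
}

write_pipeline_outputs <- function(out, tables, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f)
    utils::write.table(d, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(out$sar_intensity, "sar_intensity.tsv")
  wt(out$descriptors, "descriptors.tsv")
  reports <- do.call(rbind, lapply(names(out$fits), function(r) {
    tab <- summary(out$fits[[r]])$table
    cbind(response = r, tab,
          aic = summary(out$fits[[r]])$aic, cv_error_pct = out$cv_error[[r]])
  }))
  itab <- summary(out$interaction_fit)$table
  reports <- rbind(reports,
                   cbind(response = "csig_interaction", itab,
                         aic = summary(out$interaction_fit)$aic,
                         cv_error_pct = loo_cv_error(out$interaction_fit)))
  wt(reports, "fit_reports.tsv")
  diag_tab <- do.call(rbind, lapply(names(out$diagnostics), function(r) {
    d <- out$diagnostics[[r]]
    data.frame(response = r,
               shapiro_p = d$shapiro$p_value,
               breusch_pagan_p = d$breusch_pagan$p_value,
               moran_i = d$moran$statistic, moran_p = d$moran$p_value)
  }))
  wt(diag_tab, "diagnostics.tsv")
  # reproducibility manifest: seed, R version, and a hash per input file
  hashes <- vapply(names(tables), function(nm) {
    x <- tables[[nm]]
    if (is.character(x) && file.exists(x)) unname(tools::md5sum(x))
    else {
      tmp <- tempfile()
      utils::write.table(x, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
      h <- unname(tools::md5sum(tmp)); unlink(tmp); h
    }
  }, character(1))
  writeLines(c(sprintf("seed: %d", out$seed),
               sprintf("r_version: %s", as.character(getRversion())),
               sprintf("input_md5 %s: %s", names(hashes), hashes)),
             file.path(out_dir, "manifest.txt"))
  invisible(out)
}
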