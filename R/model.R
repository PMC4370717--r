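# Intensity-community models: Gaussian regressions of a community descriptor on
# agricultural intensity and covariates, with the intensity term entering either
# linearly or as an unpenalised fixed-df natural-cubic regression spline
# (written s(x, df) in the model formula). Because the spline df is fixed there
# is no smoothing-parameter estimation: the model is an ordinary least-squares
# fit on an expanded design, which keeps AIC, F-tests, stepwise selection and
# leave-one-out cross-validation exact and fast.

#' Fixed-df regression spline basis
#'
#' Natural cubic spline basis with exactly `df` columns (interior knots at
#' quantiles, as in [splines::ns()]), columns centred. `df = 1` reduces to the
#' centred variable itself, so a 1-df "smooth" is a plain linear term. The
#' returned basis carries the knots and centres needed to evaluate it at new
#' data (attribute `"basis"`).
#'
#' @param x Numeric vector.
#' @param df Integer >= 1: number of basis columns (effective parameters).
#' @param basis A `"basis"` attribute from a previous call: re-evaluates that
#'   basis (same knots, same centring) at the new `x`.
#' @return Numeric matrix with `df` columns.
#' @export
spline_basis <- function(x, df = 2, basis = NULL) {
  stopifnot(is.numeric(x))
  if (!is.null(basis)) {
    B <- if (basis$df == 1) matrix(as.numeric(x), ncol = 1)
         else unclass(splines::ns(x, knots = basis$knots,
                                  Boundary.knots = basis$Boundary.knots))
    B <- sweep(B, 2, basis$centers)
    attr(B, "basis") <- basis
    return(B)
  }
  df <- as.integer(df)
  if (df < 1) stop("'df' must be a positive integer")
  if (length(unique(x[!is.na(x)])) < df + 2)
    stop("too few distinct values in 'x' for a ", df, "-df spline")
  if (df == 1) {
    B <- matrix(as.numeric(x), ncol = 1)
    kn <- NULL; bk <- NULL
  } else {
    B0 <- splines::ns(x, df = df)
    kn <- attr(B0, "knots"); bk <- attr(B0, "Boundary.knots")
    B <- unclass(B0)
  }
  centers <- colMeans(B)
  B <- sweep(B, 2, centers)
  attr(B, "basis") <- list(df = df, knots = kn, Boundary.knots = bk,
                           centers = centers)
  B
}

# Coerce a model variable to a single numeric column (binary factors -> 0/1).
as_num_col <- function(v, name) {
  if (is.numeric(v)) return(as.numeric(v))
  if (is.logical(v)) return(as.numeric(v))
  if (is.factor(v) || is.character(v)) {
    v <- as.factor(v)
    if (nlevels(v) != 2)
      stop("variable '", name, "' must be numeric or a binary factor")
    return(as.numeric(v == levels(v)[2]))
  }
  stop("cannot use variable '", name, "' in the model")
}

# Parse the model formula into term blocks and an expanded design data.frame.
build_design <- function(formula, data, basis_list = NULL) {
  tf <- stats::terms(formula, specials = "s", data = data)
  if (attr(tf, "response") != 1) stop("the formula needs a response")
  resp <- deparse(attr(tf, "variables")[[2]])
  labels <- attr(tf, "term.labels")
  if (!resp %in% names(data)) stop("response '", resp, "' not found in data")

  used <- all.vars(formula)
  missing_vars <- setdiff(used, names(data))
  if (length(missing_vars))
    stop("variables not found in data: ", paste(missing_vars, collapse = ", "))
  ok <- stats::complete.cases(data[used])
  d <- data[ok, , drop = FALSE]

  blocks <- list()
  cols <- list()
  for (lb in labels) {
    if (grepl("^s\\(", lb)) {
      cl <- str2lang(lb)
      var <- deparse(cl[[2]])
      df <- 2L
      a <- as.list(cl)[-(1:2)]
      if (length(a)) {
        nm <- names(a); if (is.null(nm)) nm <- rep("", length(a))
        df <- as.integer(eval(if ("df" %in% nm) a[["df"]] else a[[1]]))
      }
      B <- spline_basis(as_num_col(d[[var]], var), df = df,
                        basis = if (!is.null(basis_list)) basis_list[[lb]])
      cn <- paste0("s_", make.names(var), "_", seq_len(ncol(B)))
      colnames(B) <- cn
      blocks[[lb]] <- list(label = lb, type = "smooth", vars = var, df = df,
                           cols = cn, basis = attr(B, "basis"),
                           xobs = as_num_col(d[[var]], var))
      cols[[lb]] <- B
    } else if (grepl(":", lb, fixed = TRUE)) {
      vs <- strsplit(lb, ":", fixed = TRUE)[[1]]
      x <- Reduce(`*`, lapply(vs, function(v) as_num_col(d[[v]], v)))
      cn <- paste(make.names(vs), collapse = "_x_")
      blocks[[lb]] <- list(label = lb, type = "interaction", vars = vs,
                           df = 1L, cols = cn, basis = NULL)
      cols[[lb]] <- stats::setNames(data.frame(x), cn)
    } else {
      x <- as_num_col(d[[lb]], lb)
      cn <- make.names(lb)
      blocks[[lb]] <- list(label = lb, type = "linear", vars = lb,
                           df = 1L, cols = cn, basis = NULL)
      cols[[lb]] <- stats::setNames(data.frame(x), cn)
    }
  }
  D <- if (length(cols))
    data.frame(.y = as.numeric(d[[resp]]), do.call(cbind, unname(cols)),
               check.names = FALSE)
  else data.frame(.y = as.numeric(d[[resp]]))
  list(response = resp, blocks = blocks, design = D, rows = which(ok))
}

fit_lm_on <- function(D, cols) {
  fml <- if (length(cols)) stats::reformulate(sprintf("`%s`", cols),
                                              response = ".y")
         else .y ~ 1
  fit <- stats::lm(fml, data = D)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient model; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit
}

#' Fit an intensity-community model
#'
#' Gaussian identity-link least-squares fit of a community descriptor on
#' intensity and covariates. Smooth terms are written `s(var, df)` in the
#' formula (fixed-df natural cubic regression spline, default `df = 2`);
#' `a:b` and `a*b` interactions of numeric or binary variables are supported.
#' Rows with missing values in any used variable are dropped.
#'
#' In summaries, linear and interaction terms are tested by t-tests and each
#' smooth term by the F-test comparing the fits with and without its whole
#' basis block, mirroring the conventional reporting of such models.
#'
#' @param formula Model formula, e.g.
#'   `csig ~ s(ic_ha, 2) + altitude + temp + precip`.
#' @param data Data frame with the descriptor and covariates (see
#'   [assemble_covariates()]).
#' @param keep Character vector of term labels (as they appear in the formula,
#'   e.g. `"s(ic_ha, 2)"`) that [backward_select()] must never drop.
#' @return An object of class `"icm"` with `print`, `summary`, `coef`,
#'   `vcov`, `predict`, `fitted`, `residuals`, `simulate`, `plot`, `logLik`
#'   and `AIC` methods.
#' @examples
#' d <- data.frame(x = runif(60, 0, 800), z = rnorm(60))
#' d$y <- 2 - 0.002 * d$x + 0.1 * d$z + rnorm(60, sd = 0.1)
#' fit <- icm(y ~ s(x, 2) + z, d)
#' summary(fit)
#' @export
icm <- function(formula, data, keep = NULL) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  des <- build_design(formula, data)
  bad_keep <- setdiff(keep, names(des$blocks))
  if (length(bad_keep))
    stop("'keep' names terms not in the model: ",
         paste(bad_keep, collapse = ", "))
  fit <- fit_lm_on(des$design, unlist(lapply(des$blocks, `[[`, "cols")))
  structure(list(call = match.call(), formula = formula,
                 response = des$response, blocks = des$blocks,
                 design = des$design, rows = des$rows, lm = fit,
                 keep = keep, n = nrow(des$design), selection = NULL),
            class = "icm")
}

# Refit an icm on a subset of its term blocks (same design data).
refit_icm <- function(object, labels) {
  blocks <- object$blocks[labels]
  fit <- fit_lm_on(object$design, unlist(lapply(blocks, `[[`, "cols")))
  object$blocks <- blocks
  object$lm <- fit
  object
}

#' @export
print.icm <- function(x, ...) {
  cat("Intensity-community model (Gaussian least squares)\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat("Terms: ", if (length(x$blocks))
    paste(names(x$blocks), collapse = " + ") else "(intercept only)",
    "\n", sep = "")
  cat(sprintf("n = %d, AIC = %.2f\n", x$n, stats::AIC(x$lm)))
  invisible(x)
}

#' @export
coef.icm <- function(object, ...) stats::coef(object$lm)

#' @export
vcov.icm <- function(object, ...) stats::vcov(object$lm)

#' @export
fitted.icm <- function(object, ...) stats::fitted(object$lm)

#' @export
residuals.icm <- function(object, ...) stats::residuals(object$lm)

#' @export
logLik.icm <- function(object, ...) stats::logLik(object$lm)

#' @export
nobs.icm <- function(object, ...) object$n

#' @export
formula.icm <- function(x, ...) x$formula

#' @export
simulate.icm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) { rng <- local_rng(seed); on.exit(rng()) }
  stats::simulate(object$lm, nsim = nsim, ...)
}

#' Predict from an intensity-community model
#'
#' @param object An `"icm"` fit.
#' @param newdata Data frame with the model's variables; omitted, returns the
#'   fitted values. Spline terms are re-evaluated with the knots and centring
#'   of the original fit.
#' @param se.fit Return standard errors of the mean prediction as well.
#' @param ... Unused.
#' @export
predict.icm <- function(object, newdata = NULL, se.fit = FALSE, ...) {
  if (is.null(newdata))
    return(if (se.fit) stats::predict(object$lm, se.fit = TRUE)
           else stats::fitted(object$lm))
  stopifnot(is.data.frame(newdata))
  cols <- list()
  for (b in object$blocks) {
    if (b$type == "smooth") {
      B <- spline_basis(as_num_col(newdata[[b$vars]], b$vars), basis = b$basis)
      colnames(B) <- b$cols
      cols[[b$label]] <- B
    } else if (b$type == "interaction") {
      x <- Reduce(`*`, lapply(b$vars, function(v) as_num_col(newdata[[v]], v)))
      cols[[b$label]] <- stats::setNames(data.frame(x), b$cols)
    } else {
      cols[[b$label]] <- stats::setNames(
        data.frame(as_num_col(newdata[[b$vars]], b$vars)), b$cols)
    }
  }
  D <- if (length(cols)) data.frame(do.call(cbind, unname(cols)),
                                    check.names = FALSE)
       else data.frame(row.names = seq_len(nrow(newdata)))
  stats::predict(object$lm, newdata = D, se.fit = se.fit)
}

#' Summarise an intensity-community model
#'
#' Per-term table: estimate, standard error and t-test for linear and
#' interaction terms; block F-test (no single estimate) for smooth terms.
#'
#' @param object An `"icm"` fit.
#' @param ... Unused.
#' @return A `"summary.icm"` object with a `table` data.frame (`term`,
#'   `estimate`, `se`, `statistic`, `test`, `p_value`), `aic`, `sigma`,
#'   `r_squared`, `df_residual`.
#' @export
summary.icm <- function(object, ...) {
  sm <- summary(object$lm)
  ct <- sm$coefficients
  rows <- list(data.frame(term = "(Intercept)",
                          estimate = ct["(Intercept)", 1],
                          se = ct["(Intercept)", 2],
                          statistic = ct["(Intercept)", 3], test = "t",
                          p_value = ct["(Intercept)", 4]))
  for (b in object$blocks) {
    if (b$df == 1L && length(b$cols) == 1L) {
      rows[[b$label]] <- data.frame(term = b$label,
                                    estimate = ct[b$cols, 1],
                                    se = ct[b$cols, 2],
                                    statistic = ct[b$cols, 3], test = "t",
                                    p_value = ct[b$cols, 4])
    } else {
      reduced <- fit_lm_on(object$design,
                           unlist(lapply(object$blocks[names(object$blocks) !=
                                                         b$label],
                                         `[[`, "cols")))
      a <- stats::anova(reduced, object$lm)
      rows[[b$label]] <- data.frame(term = b$label, estimate = NA_real_,
                                    se = NA_real_, statistic = a$F[2],
                                    test = "F", p_value = a$`Pr(>F)`[2])
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(call = object$call, table = tab, aic = stats::AIC(object$lm),
                 sigma = sm$sigma, r_squared = sm$r.squared,
                 df_residual = object$lm$df.residual, n = object$n),
            class = "summary.icm")
}

#' @export
print.summary.icm <- function(x, digits = 4, ...) {
  cat("Intensity-community model\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  tab <- x$table
  tab$estimate <- signif(tab$estimate, digits)
  tab$se <- signif(tab$se, digits)
  tab$statistic <- signif(tab$statistic, digits)
  tab$p_value <- format.pval(tab$p_value, digits = digits, eps = 1e-16)
  print(tab, row.names = FALSE)
  cat(sprintf("\nn = %d, residual sd = %.4g, R^2 = %.3f, AIC = %.2f\n",
              x$n, x$sigma, x$r_squared, x$aic))
  invisible(x)
}

#' Partial-effect plot of a model term
#'
#' Plots the estimated partial effect of a (typically smooth) term over the
#' range of its variable, with pointwise 95% confidence bounds and partial
#' residuals, in the manner of conventional additive-model plots.
#'
#' @param x An `"icm"` fit.
#' @param term Term label to plot; default the first smooth term (or first
#'   term if none is smooth).
#' @param n Grid size.
#' @param partial_resid Draw partial residuals.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.icm <- function(x, term = NULL,  n = 100, partial_resid = TRUE, ...) {
  if (is.null(term)) {
    sm <- vapply(x$blocks, function(b) b$type == "smooth", logical(1))
    term <- if (any(sm)) names(x$blocks)[sm][1] else names(x$blocks)[1]
  }
  b <- x$blocks[[term]]
  if (is.null(b)) stop("no term '", term, "' in the model")
  if (length(b$vars) != 1) stop("can only plot single-variable terms")
  Xb <- as.matrix(x$design[, b$cols, drop = FALSE])
  beta <- stats::coef(x$lm)[b$cols]
  V <- stats::vcov(x$lm)[b$cols, b$cols, drop = FALSE]
  xobs <- if (b$type == "smooth") b$xobs else x$design[[b$cols[1]]]
  rng <- range(xobs)
  grid <- seq(rng[1], rng[2], length.out = n)
  G <- if (b$type == "smooth") {
    g <- spline_basis(grid, basis = b$basis); colnames(g) <- b$cols; g
  } else matrix(grid, ncol = 1, dimnames = list(NULL, b$cols))
  eta <- as.numeric(G %*% beta)
  se <- sqrt(rowSums((G %*% V) * G))
  pr <- Xb %*% beta + stats::residuals(x$lm)
  ylim <- range(eta + 2 * se, eta - 2 * se, if (partial_resid) pr)
  graphics::plot(grid, eta, type = "l", lwd = 2, ylim = ylim,
                 xlab = b$vars, ylab = paste("partial effect on", x$response),
                 ...)
  graphics::lines(grid, eta + 1.96 * se, lty = 3)
  graphics::lines(grid, eta - 1.96 * se, lty = 3)
  if (partial_resid)
    graphics::points(xobs, pr, col = "grey60", pch = 16, cex = 0.6)
  invisible(x)
}

#' Backward stepwise AIC selection over term blocks
#'
#' Starting from the fitted (maximal) model, repeatedly removes the single
#' term whose removal lowers AIC the most, until no removal lowers AIC.
#' Smooth and interaction blocks are dropped whole; terms in `keep` are never
#' dropped; a main effect is never dropped while an interaction containing its
#' variable is in the model (marginality).
#'
#' @param object An `"icm"` fit (the maximal model).
#' @param keep Term labels never to drop; defaults to the `keep` recorded at
#'   fit time.
#' @param trace Print the selection path.
#' @return The selected `"icm"` fit, with the path in `$selection`
#'   (data.frame `step`, `dropped`, `aic`).
#' @export
backward_select <- function(object, keep = object$keep, trace = FALSE) {
  stopifnot(inherits(object, "icm"))
  cur <- object
  path <- data.frame(step = 0L, dropped = "(maximal model)",
                     aic = stats::AIC(cur$lm), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    labs <- names(cur$blocks)
    inter_vars <- unique(unlist(lapply(
      cur$blocks[vapply(cur$blocks, function(b) b$type == "interaction",
                        logical(1))], `[[`, "vars")))
    droppable <- labs[!labs %in% keep &
                        !vapply(cur$blocks, function(b)
                          b$type != "interaction" &&
                            any(b$vars %in% inter_vars), logical(1))]
    if (!length(droppable)) break
    aics <- vapply(droppable, function(lb)
      stats::AIC(fit_lm_on(cur$design,
                           unlist(lapply(cur$blocks[setdiff(labs, lb)],
                                         `[[`, "cols")))), numeric(1))
    if (min(aics) >= stats::AIC(cur$lm) - 1e-10) break
    drop <- droppable[which.min(aics)]
    cur <- refit_icm(cur, setdiff(labs, drop))
    step <- step + 1L
    path <- rbind(path, data.frame(step = step, dropped = drop,
                                   aic = stats::AIC(cur$lm)))
    if (trace) message("step ", step, ": dropped ", drop,
                       " (AIC ", round(stats::AIC(cur$lm), 2), ")")
  }
  cur$selection <- path
  cur
}

#' Leave-one-out cross-validation error
#'
#' Refits the model n times, each time leaving one observation out, and
#' summarises the out-of-sample absolute prediction errors as a percentage of
#' the observed values. The design (spline knots, centring) is held fixed
#' across folds, so for a linear model the LOO residuals equal
#' \eqn{e_i / (1 - h_{ii})}.
#'
#' @param object An `"icm"` fit.
#' @param type `"mean_ratio"` (default): `mean(|err|) / mean(y) * 100`;
#'   `"per_obs"`: `mean(|err_i / y_i|) * 100`.
#' @return A single percentage.
#' @export
loo_cv_error <- function(object, type = c("mean_ratio", "per_obs")) {
  type <- match.arg(type)
  stopifnot(inherits(object, "icm"))
  X <- stats::model.matrix(object$lm)
  y <- object$design$.y
  n <- length(y)
  if (n < 10) stop("need at least 10 observations for LOO-CV")
  pred <- vapply(seq_len(n), function(i) {
    beta <- stats::lm.fit(X[-i, , drop = FALSE], y[-i])$coefficients
    sum(X[i, ] * beta)
  }, numeric(1))
  err <- abs(pred - y)
  if (type == "mean_ratio") {
    if (mean(y) == 0) stop("mean of the response is zero; error undefined")
    mean(err) / mean(y) * 100
  } else {
    if (any(y == 0)) stop("response contains zeros; per-observation error undefined")
    mean(err / abs(y)) * 100
  }
}

#' Fit the intensity-by-aggregation interaction model
#'
#' Fits a Gaussian linear model with an interaction between continuous
#' intensity and the binary aggregation class (plus any further covariates),
#' e.g. `csig ~ ic_ha * aggregated + temp + precip`. With aggregation coded
#' 0/1, the `ic_ha` row of the summary is the slope in non-aggregated regions,
#' `aggregated` the intercept difference and `ic_ha:aggregated` the slope
#' difference in aggregated regions.
#'
#' The interaction and both of its main effects are placed in the always-keep
#' set for [backward_select()] unless `keep` overrides it.
#'
#' @param formula Model formula containing exactly one `a * b` (or `a:b` with
#'   both mains) interaction whose second variable is binary.
#' @param data Data frame.
#' @param keep Additional term labels never to drop (the interaction hierarchy
#'   is always kept).
#' @return An `"icm"` fit; the interaction label is stored in
#'   `attr(fit, "interaction")`.
#' @export
fit_interaction_model <- function(formula, data, keep = NULL) {
  tf <- stats::terms(formula, specials = "s", data = data)
  labs <- attr(tf, "term.labels")
  inter <- labs[grepl(":", labs, fixed = TRUE)]
  if (length(inter) == 0) stop("the formula contains no interaction term")
  for (lb in inter) {
    for (v in strsplit(lb, ":", fixed = TRUE)[[1]]) {
      col <- as_num_col(data[[v]], v)
      if (length(unique(col[!is.na(col)])) < 2)
        stop("interaction variable '", v, "' has a single level/value")
    }
  }
  fit <- icm(formula, data)
  mains <- unique(unlist(lapply(fit$blocks[inter], `[[`, "vars")))
  main_labels <- names(fit$blocks)[vapply(fit$blocks, function(b)
    b$type != "interaction" && length(b$vars) == 1 && b$vars %in% mains,
    logical(1))]
  fit$keep <- unique(c(keep, inter, main_labels))
  fit$call <- match.call()
  attr(fit, "interaction") <- inter
  fit
}

#' Residual diagnostics of an intensity-community model
#'
#' Shapiro-Wilk normality and (studentised) Breusch-Pagan homoscedasticity
#' checks on the residuals, plus a Moran's I permutation test on the per-region
#' mean residuals over the region contiguity matrix — the check that the model
#' has absorbed the spatial structure of the data. Report-only: nothing is
#' refitted.
#'
#' @param object An `"icm"` fit.
#' @param sar Per-observation region id, aligned with the rows used in the fit
#'   (`object$rows` indexes the original data).
#' @param w Region contiguity matrix; regions without observations are dropped
#'   from it before the Moran test.
#' @param n_perm,seed Passed to [morans_i_test()].
#' @return An `"icm_diag"` list: `shapiro` (`statistic`, `p_value`),
#'   `breusch_pagan` (`statistic`, `p_value`), `moran` (`statistic`,
#'   `p_value`, `n_regions`).
#' @export
residual_diagnostics <- function(object, sar, w, n_perm = 999, seed) {
  stopifnot(inherits(object, "icm"))
  if (missing(seed)) stop("'seed' is required")
  r <- stats::residuals(object$lm)
  if (length(sar) != length(r))
    stop("'sar' must give one region id per fitted observation (n = ",
         length(r), ")")
  sh <- stats::shapiro.test(r)
  bp <- lmtest::bptest(object$lm)
  msar <- tapply(r, as.character(sar), mean)
  common <- intersect(rownames(w), names(msar))
  if (length(common) < 3) stop("too few regions with observations for Moran's I")
  wsub <- w[common, common, drop = FALSE]
  mi <- morans_i_test(msar[common], wsub, n_perm = n_perm, seed = seed)
  structure(list(
    shapiro = list(statistic = unname(sh$statistic), p_value = sh$p.value),
    breusch_pagan = list(statistic = unname(bp$statistic), p_value = bp$p.value),
    moran = list(statistic = mi$statistic, p_value = mi$p_value,
                 n_regions = length(common))),
    class = "icm_diag")
}

#' @export
print.icm_diag <- function(x, ...) {
  cat("Residual diagnostics\n")
  cat(sprintf("  Shapiro-Wilk normality: W = %.4f, p = %.4g\n",
              x$shapiro$statistic, x$shapiro$p_value))
  cat(sprintf("  Breusch-Pagan homoscedasticity: BP = %.4f, p = %.4g\n",
              x$breusch_pagan$statistic, x$breusch_pagan$p_value))
  cat(sprintf("  Moran's I on per-region mean residuals (%d regions): I = %.4f, p = %.4g\n",
              x$moran$n_regions, x$moran$statistic, x$moran$p_value))
  invisible(x)
}
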