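lin_data <- function(n = 80, seed = 1, slope = 2, sd = 0.01) {
  set.seed(seed)
  d <- data.frame(x = runif(n, 0, 10), z = rnorm(n))
  d$y <- 1 + slope * d$x + rnorm(n, 0, sd)
  d
}

test_that("the spline basis has df columns and df = 1 is a linear term", {
  x <- runif(50, 0, 5)
  expect_equal(ncol(spline_basis(x, 1)), 1)
  expect_equal(ncol(spline_basis(x, 2)), 2)
  expect_equal(ncol(spline_basis(x, 4)), 4)
  expect_error(spline_basis(rep(1:2, 10), df = 2), "distinct")
  # a 1-df smooth fits exactly like a straight line
  d <- lin_data()
  f1 <- icm(y ~ s(x, 1), d)
  f2 <- icm(y ~ x, d)
  expect_equal(fitted(f1), fitted(f2), tolerance = 1e-10)
})

test_that("spline fits are invariant to affine rescaling of the covariate", {
  set.seed(4)
  d <- data.frame(x = runif(70, 0, 800))
  d$y <- exp(-d$x / 300) + rnorm(70, 0, 0.05)
  d$x2 <- 3 + 0.004 * d$x
  fa <- icm(y ~ s(x, 2), d)
  fb <- icm(y ~ s(x2, 2), d)
  expect_equal(fitted(fa), fitted(fb), tolerance = 1e-8)
  fa3 <- icm(y ~ s(x, 3), d)
  fb3 <- icm(y ~ s(x2, 3), d)
  expect_equal(fitted(fa3), fitted(fb3), tolerance = 1e-8)
})

test_that("the fit recovers a linear effect and satisfies the residual identity", {
  d <- lin_data()
  fit <- icm(y ~ x + z, d)
  sm <- summary(fit)
  b <- sm$table[sm$table$term == "x", ]
  expect_lt(abs(b$estimate - 2), 3 * b$se)
  expect_equal(fitted(fit) + residuals(fit), d$y, ignore_attr = TRUE)
  expect_equal(unname(predict(fit, d)), unname(fitted(fit)), tolerance = 1e-10)
  # collinear columns are reported by name
  d$xc <- 2 * d$x
  expect_error(icm(y ~ x + xc, d), "collinear")
})

test_that("smooth terms are tested by a block F-test with honest type-I error", {
  # under the null (no x effect) the F-test p-value is uniform
  set.seed(12)
  p <- replicate(400, {
    d <- data.frame(x = runif(40), y = 3 + rnorm(40))
    sm <- summary(icm(y ~ s(x, 2), d))
    sm$table$p_value[sm$table$term == "s(x, 2)"]
  })
  rej <- mean(p < 0.05)
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("prediction rebuilds spline bases with the training knots", {
  set.seed(7)
  d <- data.frame(x = runif(60, 0, 100))
  d$y <- sqrt(d$x) + rnorm(60, 0.1)
  fit <- icm(y ~ s(x, 3), d)
  nd <- data.frame(x = c(10, 50, 90))
  p <- predict(fit, nd)
  expect_length(p, 3)
  # predicting the training data reproduces the fitted values
  expect_equal(unname(predict(fit, d)), unname(fitted(fit)), tolerance = 1e-10)
  pse <- predict(fit, nd, se.fit = TRUE)
  expect_true(all(pse$se.fit > 0))
})

test_that("backward selection drops noise, keeps signal and honours 'keep'", {
  set.seed(19)
  n <- 300
  d <- data.frame(x = runif(n, 0, 800), n1 = rnorm(n), n2 = rnorm(n),
                  n3 = rnorm(n), true = rnorm(n))
  d$y <- 0.005 * d$x + 1.5 * d$true + rnorm(n)
  full <- icm(y ~ s(x, 2) + n1 + n2 + n3 + true, d, keep = "s(x, 2)")
  sel <- backward_select(full)
  expect_true("true" %in% names(sel$blocks))
  expect_true("s(x, 2)" %in% names(sel$blocks))   # kept by construction
  expect_lte(AIC(sel$lm), AIC(full$lm))
  expect_s3_class(sel$selection, "data.frame")
  # a maximal model where everything matters is a fixed point
  d2 <- lin_data(n = 200, sd = 0.5)
  d2$y <- d2$y + 2 * d2$z
  f2 <- backward_select(icm(y ~ x + z, d2))
  expect_setequal(names(f2$blocks), c("x", "z"))
})

test_that("marginality: main effects survive while their interaction is present", {
  set.seed(23)
  n <- 250
  d <- data.frame(x = runif(n, 0, 500), a = rbinom(n, 1, 0.5))
  d$y <- 1 + 0.0001 * d$x + 0.002 * d$x * d$a + rnorm(n, 0, 0.3)
  fit <- fit_interaction_model(y ~ x * a, d)
  sel <- backward_select(fit)
  expect_true(all(c("x", "a", "x:a") %in% names(sel$blocks)))
})

test_that("LOO-CV matches the hat-matrix identity and is order-invariant", {
  d <- lin_data(n = 60, sd = 1, seed = 3)
  fit <- icm(y ~ x + z, d)
  # closed-form LOO residuals of a linear model: e_i / (1 - h_ii)
  lmfit <- lm(y ~ x + z, d)
  h <- hatvalues(lmfit)
  loo_resid <- residuals(lmfit) / (1 - h)
  want <- mean(abs(loo_resid)) / mean(d$y) * 100
  expect_equal(loo_cv_error(fit), want, tolerance = 1e-10)
  # a perfectly linear response gives zero error
  dp <- data.frame(x = 1:20, y = 2 + 3 * (1:20))
  expect_equal(loo_cv_error(icm(y ~ x, dp)), 0, tolerance = 1e-8)
  # permutation invariance over row order
  set.seed(6)
  ds <- d[sample(nrow(d)), ]
  expect_equal(loo_cv_error(icm(y ~ x + z, ds)), loo_cv_error(fit),
               tolerance = 1e-9)
  # per-observation variant
  expect_gt(loo_cv_error(fit, type = "per_obs"), 0)
})

test_that("the interaction model is invariant to swapping the group coding", {
  set.seed(29)
  n <- 150
  d <- data.frame(x = runif(n, 100, 700), a = rbinom(n, 1, 0.5))
  d$y <- 2 - 0.001 * d$x - 0.2 * d$a + 5e-4 * d$x * d$a + rnorm(n, 0, 0.2)
  f0 <- fit_interaction_model(y ~ x * a, d)
  d2 <- d; d2$a <- 1 - d2$a
  f1 <- fit_interaction_model(y ~ x * a, d2)
  expect_equal(fitted(f0), fitted(f1), tolerance = 1e-9)
  # the slope difference flips sign under the recoding
  s0 <- summary(f0)$table; s1 <- summary(f1)$table
  expect_equal(s0$estimate[s0$term == "x:a"],
               -s1$estimate[s1$term == "x:a"], tolerance = 1e-9)
  d$a <- 1
  expect_error(fit_interaction_model(y ~ x * a, d), "single level")
  expect_error(fit_interaction_model(y ~ x + a, d), "no interaction")
})

test_that("residual diagnostics run the three checks and are seeded", {
  sim <- simulate_scenario(scenario_config(rows = 4, cols = 5, n_sites = 60,
                                           seed = 41))
  lsc <- sim$landscape
  d <- simulate_interaction_data(lsc, seed = 42)
  fit <- fit_interaction_model(y ~ ic_ha * aggregated, d)
  dg1 <- residual_diagnostics(fit, d$sar_id[fit$rows], lsc$w,
                              n_perm = 99, seed = 5)
  dg2 <- residual_diagnostics(fit, d$sar_id[fit$rows], lsc$w,
                              n_perm = 99, seed = 5)
  expect_identical(dg1, dg2)
  expect_true(dg1$shapiro$p_value >= 0 && dg1$shapiro$p_value <= 1)
  expect_true(dg1$moran$p_value >= 1 / 100)
  expect_output(print(dg1), "Moran")
})

test_that("simulate and plot methods work on a fitted model", {
  d <- lin_data(n = 50, sd = 0.3)
  fit <- icm(y ~ s(x, 2) + z, d)
  s1 <- simulate(fit, nsim = 2, seed = 10)
  s2 <- simulate(fit, nsim = 2, seed = 10)
  expect_equal(s1, s2)
  expect_equal(dim(s1), c(50, 2))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit))
  expect_invisible(plot(fit, term = "z"))
  expect_output(print(fit), "AIC")
  expect_output(print(summary(fit)), "s\\(x, 2\\)")
})
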