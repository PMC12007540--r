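default_knots <- c(2, 4, 22, 35, 75, 90)

test_that("restricted basis has k-1 columns, is linear below the first knot and in the tails", {
  b <- rcs_basis(seq(0, 100, by = 0.5), default_knots)
  expect_equal(ncol(b), 5L)  # 1 linear + (k-2) nonlinear
  expect_identical(colnames(b), c("age", paste0("s", 1:4)))
  # below the first knot every nonlinear term vanishes
  low <- rcs_basis(c(0, 1, 1.9), default_knots)
  expect_true(all(abs(low[, -1]) < 1e-14))
  # beyond the last knot the curve is linear: second derivative 0
  d2 <- tractlife:::rcs_basis_deriv2(c(95, 100, 120), default_knots)
  expect_lt(max(abs(d2)), 1e-12)
  expect_error(rcs_basis(1:10, c(5, 5, 10)), "ascending")
  expect_error(rcs_basis(1:10, c(2, 10)), "3 knots")
})

test_that("noise-free linear data give slope and zero nonlinear terms", {
  set.seed(21)
  tab <- data.frame(age = runif(200, 0, 100))
  tab$value <- 3 + 0.1 * tab$age
  fit <- fit_crcs(tab, spec = spline_spec(covariates = character()))
  expect_equal(unname(coef(fit)["age"]), 0.1, tolerance = 1e-10)
  expect_lt(max(abs(coef(fit)[paste0("s", 1:4)])), 1e-8)
  expect_equal(difference_per_year(fit, c(5, 50, 95)), rep(0.1, 3),
               tolerance = 1e-8)
  rs <- cohort_mean_rate(fit, "p", "f")
  expect_equal(rs$diff_per_year, rep(0.1, 4), tolerance = 1e-8)
})

test_that("coefficients generated from the basis itself are recovered exactly", {
  set.seed(33)
  ages <- runif(400, 0, 100)
  beta <- c(0.5, 0.08, -0.5, 0.3, -0.2, 0.15)
  tab <- data.frame(age = ages,
                    value = drop(cbind(1, rcs_basis(ages, default_knots)) %*%
                                   beta))
  fit <- fit_crcs(tab, spec = spline_spec(covariates = character()))
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-6)
})

test_that("a simulated sex effect is recovered within 3 standard errors", {
  spec <- trajectory_spec("linear", list(intercept = 1, slope = 0.02),
                          noise_sd = 0.2, sex_effect = 0.3,
                          n_per_cohort = 250)
  sim <- simulate_lifespan_table(spec, seed = 5)
  fit <- fit_crcs(sim$table)
  s <- summary(fit)$coefficients
  expect_lt(abs(s["sexM", "Estimate"] - 0.3), 3 * s["sexM", "Std. Error"])
})

test_that("fit preconditions are enforced", {
  tab <- data.frame(age = runif(30, 0, 100), value = rnorm(30))
  expect_error(fit_crcs(tab, spec = spline_spec(covariates = character())),
               "insufficient observations")
  # duplicate ages only -> rank-deficient spline design
  tab2 <- data.frame(age = rep(50, 100), value = rnorm(100))
  expect_error(fit_crcs(tab2, spec = spline_spec(covariates = character())),
               "rank-deficient")
})

test_that("analytic derivative matches the central finite difference oracle", {
  set.seed(2)
  ages <- runif(300, 0, 100)
  beta <- c(1, 0.05, -0.8, 0.5, -0.3, 0.2)
  tab <- data.frame(age = ages,
                    value = drop(cbind(1, rcs_basis(ages, default_knots)) %*%
                                   beta) + rnorm(300, 0, 0.1))
  fit <- fit_crcs(tab, spec = spline_spec(covariates = character()))
  grid <- seq(1, 99, by = 0.5)
  h <- 1e-4
  fd <- (predict_curve(fit, grid + h) - predict_curve(fit, grid - h)) / (2 * h)
  expect_lt(max(abs(difference_per_year(fit, grid) - fd)), 1e-6)
  # year-difference mode agrees to first order
  yd <- difference_per_year(fit, grid, method = "year_difference")
  expect_lt(max(abs(yd - fd)), 0.05)
})

test_that("percent difference per year recovers an exponential growth rate", {
  set.seed(14)
  ages <- runif(900, 20, 36)
  tab <- data.frame(age = ages, value = exp(0.02 * ages))
  fit <- fit_crcs(tab, spec = spline_spec(knots = c(22, 26, 30, 35),
                                          covariates = character()))
  expect_equal(percent_difference_per_year(fit, 28), 2, tolerance = 0.1)
  # scale invariance: a positive curve scaled by c has the same percent rate
  tab2 <- tab; tab2$value <- 7 * tab$value
  fit2 <- fit_crcs(tab2, spec = spline_spec(knots = c(22, 26, 30, 35),
                                            covariates = character()))
  expect_equal(percent_difference_per_year(fit2, c(24, 28, 32)),
               percent_difference_per_year(fit, c(24, 28, 32)),
               tolerance = 1e-8)
  # degenerate: fitted value numerically zero errors
  zero <- data.frame(age = runif(200, 0, 100), value = rnorm(200, 0, 1e-12))
  fz <- fit_crcs(zero, spec = spline_spec(covariates = character()))
  expect_error(percent_difference_per_year(fz, 50), "undefined")
})

test_that("bootstrap is deterministic, leaves the point fit unchanged, and B=1 collapses the band", {
  spec <- trajectory_spec("peaked_bump", noise_sd = 0.2, n_per_cohort = 120)
  sim <- simulate_lifespan_table(spec, seed = 3)
  f0 <- fit_crcs(sim$table)
  b1 <- bootstrap_fit(sim$table, B = 50, seed = 99)
  b2 <- bootstrap_fit(sim$table, B = 50, seed = 99)
  expect_identical(b1$bootstrap_coefficients, b2$bootstrap_coefficients)
  expect_identical(coef(b1), coef(f0))
  b3 <- bootstrap_fit(sim$table, B = 50, seed = 100)
  expect_false(identical(b1$bootstrap_coefficients,
                         b3$bootstrap_coefficients))
  single <- bootstrap_fit(sim$table, B = 1, seed = 1)
  band <- predict(single, c(10, 50), interval = "percentile")
  expect_equal(band$lower, band$upper)
})

test_that("an inverted-U peaking at 25 is located with a covering bootstrap interval", {
  sim <- simulate_lifespan_table(peak25_spec(), seed = 17)
  fit <- bootstrap_fit(sim$table, B = 200, seed = 17)
  ex <- find_extremum(fit, "max")
  expect_equal(ex$kind, "peak")
  expect_lt(abs(ex$age_at_extremum - 25), 2)
  expect_true(ex$ci_low <= 25 && 25 <= ex$ci_high)
  # direction = min on the negated data finds the same age
  neg <- sim$table; neg$value <- -neg$value
  fit_n <- fit_crcs(neg)
  ex_n <- find_extremum(fit_n, "min")
  expect_equal(ex_n$age_at_extremum, find_extremum(fit_crcs(sim$table),
                                                   "max")$age_at_extremum)
  expect_equal(ex_n$kind, "minimum")
})

test_that("strictly increasing data flag a boundary extremum", {
  set.seed(4)
  tab <- data.frame(age = runif(150, 0, 100))
  tab$value <- 0.05 * tab$age + rnorm(150, 0, 0.01)
  ex <- find_extremum(fit_crcs(tab, spec = spline_spec(
    covariates = character())), "max")
  expect_equal(ex$kind, "boundary")
  expect_equal(ex$age_at_extremum, max(tab$age), tolerance = 0.2)
  expect_true(is.na(ex$ci_low))  # no replicates -> missing CI
})

test_that("cohort windows are 0-5, 5-21, 22-35, 36+ and piecewise slopes are recovered", {
  w <- cohort_windows()
  expect_identical(names(w), c("infant", "development", "young_adult",
                               "aging"))
  expect_identical(w$infant, c(0, 5))
  expect_identical(w$development, c(5, 21))
  expect_identical(w$young_adult, c(22, 35))
  expect_identical(w$aging[1], 36)

  spec <- trajectory_spec("piecewise_slopes",
                          list(intercept = 1, breaks = c(21, 36),
                               slopes = c(1, 0, -1)),
                          noise_sd = 0, n_per_cohort = 300)
  sim <- simulate_lifespan_table(spec, seed = 9)
  fit <- fit_crcs(sim$table, spec = spline_spec(covariates = character()))
  rs <- cohort_mean_rate(fit, "p", "f")
  expect_identical(rs$cohort, names(w))
  expect_equal(rs$diff_per_year[rs$cohort == "development"], 1,
               tolerance = 0.15)
  expect_equal(rs$diff_per_year[rs$cohort == "aging"], -1,
               tolerance = 0.15)
})

test_that("coefficient error shrinks as n grows", {
  beta <- c(0.5, 0.08, -0.5, 0.3, -0.2, 0.15)
  rmse <- vapply(c(200, 2000), function(n) {
    set.seed(1)
    ages <- runif(n, 0, 100)
    tab <- data.frame(
      age = ages,
      value = drop(cbind(1, rcs_basis(ages, default_knots)) %*% beta) +
        rnorm(n, 0, 0.3))
    fit <- fit_crcs(tab, spec = spline_spec(covariates = character()))
    sqrt(mean((coef(fit) - beta)^2))
  }, numeric(1))
  expect_lt(rmse[2], rmse[1])
})

test_that("crcs methods behave like a standard model object", {
  spec <- trajectory_spec("linear", list(intercept = 2, slope = 0.05),
                          noise_sd = 0.1, n_per_cohort = 100)
  sim <- simulate_lifespan_table(spec, seed = 8)
  fit <- bootstrap_fit(sim$table, B = 20, seed = 1)
  expect_output(print(fit), "C-RCS trajectory fit")
  expect_output(print(summary(fit)), "Residual SD")
  expect_equal(length(residuals(fit)), fit$n_obs)
  expect_equal(fitted(fit) + residuals(fit), fit$y, tolerance = 1e-10)
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_equal(dim(sims), c(fit$n_obs, 2L))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
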