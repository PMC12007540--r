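#' Fit a covariate-adjusted restricted cubic spline (C-RCS) age trajectory
#'
#' Ordinary least squares of one feature of one pathway on
#' `[1, rcs_basis(age, knots), covariates]`. This is the normative lifespan
#' model used throughout the package: a cubic spline in age, constrained to
#' be linear beyond its boundary knots, with covariates (by default sex)
#' entering the linear predictor additively. Predictions from the fitted
#' object are reported at the covariate reference (covariates averaged over
#' the fitted sample), so the curve describes a sex-averaged trajectory.
#'
#' @param table a lifespan feature table (see [validate_feature_table()]),
#'   or any data.frame with columns `age`, `value` and the covariates.
#' @param pathway,feature which records to fit; ignored (with all rows used)
#'   when the table has no `pathway`/`feature` columns.
#' @param spec a [spline_spec()].
#' @param min_obs_factor minimum observations required per coefficient
#'   (default 10).
#' @return An object of class `crcs` with components `coefficients`,
#'   `knots`, `covariates`, `covariate_reference`, `age_range`, `n_obs`,
#'   `sigma`, `fitted.values`, `residuals`, and (after [bootstrap_fit()])
#'   `bootstrap_coefficients`.
#' @seealso [predict.crcs()], [difference_per_year()], [find_extremum()],
#'   [cohort_mean_rate()], [bootstrap_fit()]
#' @examples
#' sim <- simulate_lifespan_table(
#'   trajectory_spec("linear", list(intercept = 3, slope = 0.1),
#'                   noise_sd = 0.05, n_per_cohort = 60),
#'   seed = 1)
#' fit <- fit_crcs(sim$table, spec = spline_spec(covariates = character()))
#' coef(fit)[["age"]]
#' @export
fit_crcs <- function(table, pathway = NULL, feature = NULL,
                     spec = spline_spec(), min_obs_factor = 10) {
  dat <- subset_records(table, pathway, feature)
  X <- crcs_design(dat, spec)
  y <- dat$value
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  p <- ncol(X)
  if (nrow(X) < min_obs_factor * p)
    stop("insufficient observations: ", nrow(X), " for ", p,
         " coefficients (need >= ", min_obs_factor * p, ")")
  ls <- stats::lm.fit(X, y)
  if (ls$rank < p) stop("rank-deficient design matrix")
  ncov <- p - (length(spec$knots) - 1L) - 1L
  covref <- if (ncov > 0L) colMeans(X[, seq.int(p - ncov + 1L, p),
                                      drop = FALSE]) else numeric(0)
  res <- ls$residuals
  structure(list(
    coefficients = ls$coefficients,
    knots = spec$knots,
    covariates = spec$covariates,
    covariate_reference = covref,
    age_range = range(X[, "age"]),
    n_obs = nrow(X),
    sigma = sqrt(sum(res^2) / (nrow(X) - p)),
    fitted.values = ls$fitted.values,
    residuals = res,
    design = X, y = y,
    pathway = if (is.null(pathway)) dat$pathway[1L] else pathway,
    feature = if (is.null(feature)) dat$feature[1L] else feature,
    bootstrap_coefficients = NULL
  ), class = "crcs")
}

subset_records <- function(table, pathway, feature) {
  dat <- as.data.frame(table)
  if (!is.null(pathway) && "pathway" %in% names(dat))
    dat <- dat[dat$pathway == pathway, , drop = FALSE]
  if (!is.null(feature) && "feature" %in% names(dat))
    dat <- dat[dat$feature == feature, , drop = FALSE]
  if (!all(c("age", "value") %in% names(dat)))
    stop("table needs 'age' and 'value' columns")
  if (nrow(dat) == 0L) stop("no records for pathway '", pathway,
                            "', feature '", feature, "'")
  dat
}

# Full design matrix: intercept, spline columns, covariate columns.
# Character/factor covariates become treatment dummies (first level dropped,
# levels sorted), numeric covariates enter as given.
crcs_design <- function(dat, spec) {
  X <- cbind("(Intercept)" = rep(1, nrow(dat)),
             rcs_basis(dat$age, spec$knots))
  for (cv in spec$covariates) {
    if (!cv %in% names(dat)) stop("covariate '", cv, "' not in table")
    v <- dat[[cv]]
    if (is.numeric(v)) {
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- cv
    } else {
      lev <- sort(unique(as.character(v)))
      for (l in lev[-1L]) {
        X <- cbind(X, as.numeric(v == l))
        colnames(X)[ncol(X)] <- paste0(cv, l)
      }
    }
  }
  X
}

#' Case-resampling bootstrap of a C-RCS fit
#'
#' Refits the trajectory on `B` resamples of the observations (sessions are
#' resampled as independent rows, mirroring a cross-sectional treatment of
#' the data) and stores the replicate coefficient sets on the returned fit.
#' The point fit is unchanged. A rank-deficient replicate is redrawn (at
#' most 10 retries) before erroring. The default `B` in full analyses is
#' 10000; tests and examples use far fewer.
#'
#' @inheritParams fit_crcs
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed; the same seed gives bit-identical replicates.
#' @param fit optionally, an existing `crcs` fit to attach replicates to
#'   (then `table` is ignored).
#' @return the `crcs` fit with a `B x p` matrix `bootstrap_coefficients`.
#' @export
bootstrap_fit <- function(table = NULL, pathway = NULL, feature = NULL,
                          spec = spline_spec(), B = 1000L, seed = 1L,
                          fit = NULL) {
  if (is.null(fit))
    fit <- fit_crcs(table, pathway, feature, spec)
  stopifnot(inherits(fit, "crcs"), B >= 1L)
  X <- fit$design
  y <- fit$y
  n <- nrow(X)
  p <- ncol(X)
  boot <- matrix(NA_real_, B, p, dimnames = list(NULL, colnames(X)))
  set.seed(as.integer(seed))
  for (b in seq_len(B)) {
    for (try in seq_len(10L)) {
      idx <- sample.int(n, n, replace = TRUE)
      ls <- stats::lm.fit(X[idx, , drop = FALSE], y[idx])
      if (ls$rank == p) break
      if (try == 10L) stop("bootstrap replicate rank-deficient after 10 retries")
    }
    boot[b, ] <- ls$coefficients
  }
  fit$bootstrap_coefficients <- boot
  fit$bootstrap_seed <- as.integer(seed)
  fit
}

crcs_curve_matrix <- function(fit, ages, what = c("response", "derivative")) {
  what <- match.arg(what)
  if (what == "response") {
    Xc <- cbind(1, rcs_basis(ages, fit$knots))
    covpart <- fit$covariate_reference
  } else {
    Xc <- cbind(0, rcs_basis_deriv(ages, fit$knots))
    covpart <- rep(0, length(fit$covariate_reference))
  }
  if (length(covpart) > 0L)
    Xc <- cbind(Xc, matrix(covpart, nrow(Xc), length(covpart), byrow = TRUE))
  Xc
}

#' Predict from a C-RCS trajectory fit
#'
#' @param object a `crcs` fit.
#' @param ages ages (years) at which to evaluate; defaults to integer ages
#'   over the fitted range.
#' @param type `"response"` (fitted trajectory at the covariate reference),
#'   `"derivative"` (analytic first derivative, the cross-sectional
#'   difference per year), or `"percent"` (100 x derivative / response, the
#'   percent difference per year).
#' @param interval `"none"` or `"percentile"` (2.5/97.5 bootstrap percentile
#'   band; requires [bootstrap_fit()]).
#' @param level band coverage level (default 0.95).
#' @param eps `type = "percent"` errors when any `|response|` is below this.
#' @param ... unused.
#' @return numeric vector, or a data.frame with columns `age, estimate,
#'   lower, upper` when `interval = "percentile"`.
#' @export
predict.crcs <- function(object, ages = NULL,
                         type = c("response", "derivative", "percent"),
                         interval = c("none", "percentile"), level = 0.95,
                         eps = 1e-8, ...) {
  type <- match.arg(type)
  interval <- match.arg(interval)
  if (is.null(ages))
    ages <- seq(ceiling(object$age_range[1]), floor(object$age_range[2]))
  point <- function(beta) {
    f <- drop(crcs_curve_matrix(object, ages, "response") %*% beta)
    if (type == "response") return(f)
    d <- drop(crcs_curve_matrix(object, ages, "derivative") %*% beta)
    if (type == "derivative") return(d)
    if (any(abs(f) < eps))
      stop("percent difference per year undefined: |fitted value| < ", eps)
    100 * d / f
  }
  est <- point(object$coefficients)
  if (interval == "none") return(est)
  if (is.null(object$bootstrap_coefficients))
    stop("no bootstrap replicates; run bootstrap_fit() first")
  reps <- apply(object$bootstrap_coefficients, 1L, point)
  reps <- matrix(reps, ncol = length(ages), byrow = TRUE)
  a <- (1 - level) / 2
  data.frame(age = ages, estimate = est,
             lower = apply(reps, 2L, stats::quantile, probs = a),
             upper = apply(reps, 2L, stats::quantile, probs = 1 - a))
}

#' Fitted lifespan curve at given ages
#'
#' Convenience wrapper for `predict(fit, ages, type = "response")`.
#' @param fit a `crcs` fit.
#' @param ages ages in years.
#' @export
predict_curve <- function(fit, ages) predict(fit, ages, type = "response")

#' Cross-sectional difference per year
#'
#' The first derivative of the fitted trajectory at each age — a
#' cross-sectional rate of change, not a longitudinal one. By default the
#' analytic spline derivative; `method = "year_difference"` instead returns
#' the central one-year curve difference `f(age + 1/2) - f(age - 1/2)`,
#' which agrees with the derivative to first order.
#'
#' @param fit a `crcs` fit.
#' @param ages ages in years.
#' @param method `"derivative"` (default) or `"year_difference"`.
#' @return numeric vector, feature units per year.
#' @export
difference_per_year <- function(fit, ages,
                                method = c("derivative", "year_difference")) {
  method <- match.arg(method)
  if (method == "derivative") return(predict(fit, ages, type = "derivative"))
  predict_curve(fit, ages + 0.5) - predict_curve(fit, ages - 0.5)
}

#' Cross-sectional percent difference per year
#'
#' `100 * difference_per_year / fitted value`, in percent per year. Errors
#' when the fitted value is numerically zero.
#'
#' @inheritParams difference_per_year
#' @param eps minimum admissible `|fitted value|`.
#' @export
percent_difference_per_year <- function(fit, ages,
                                        method = c("derivative",
                                                   "year_difference"),
                                        eps = 1e-8) {
  method <- match.arg(method)
  if (method == "derivative")
    return(predict(fit, ages, type = "percent", eps = eps))
  f <- predict_curve(fit, ages)
  if (any(abs(f) < eps))
    stop("percent difference per year undefined: |fitted value| < ", eps)
  100 * difference_per_year(fit, ages, method = "year_difference") / f
}

#' Age at the peak or minimum of a fitted trajectory
#'
#' Dense grid search (0.1-year steps by default) over the fitted age range;
#' the 95% confidence interval is taken from the 2.5/97.5 percentiles of the
#' replicate extremum ages when bootstrap replicates are present. When the
#' extremum falls at an edge of the fitted range the `kind` is `"boundary"`
#' rather than `"peak"`/`"minimum"`.
#'
#' @param fit a `crcs` fit (bootstrap replicates optional).
#' @param direction `"max"` for a peak, `"min"` for a minimum.
#' @param step grid resolution in years.
#' @param level confidence level for the bootstrap interval.
#' @return An object of class `extremum_estimate`: list with
#'   `age_at_extremum`, `kind`, `ci_low`, `ci_high`.
#' @export
find_extremum <- function(fit, direction = c("max", "min"), step = 0.1,
                          level = 0.95) {
  direction <- match.arg(direction)
  stopifnot(inherits(fit, "crcs"))
  grid <- seq(fit$age_range[1], fit$age_range[2], by = step)
  pick <- if (direction == "max") which.max else which.min
  Xc <- crcs_curve_matrix(fit, grid, "response")
  est_idx <- pick(drop(Xc %*% fit$coefficients))
  age <- grid[est_idx]
  kind <- if (est_idx == 1L || est_idx == length(grid)) "boundary"
          else if (direction == "max") "peak" else "minimum"
  ci <- c(NA_real_, NA_real_)
  if (!is.null(fit$bootstrap_coefficients)) {
    rep_ages <- grid[apply(Xc %*% t(fit$bootstrap_coefficients), 2L, pick)]
    a <- (1 - level) / 2
    ci <- unname(stats::quantile(rep_ages, probs = c(a, 1 - a)))
  }
  structure(list(age_at_extremum = age, kind = kind,
                 ci_low = ci[1], ci_high = ci[2]),
            class = "extremum_estimate")
}

#' @export
print.extremum_estimate <- function(x, ...) {
  cat(sprintf("%s at age %.1f years", x$kind, x$age_at_extremum))
  if (!is.na(x$ci_low))
    cat(sprintf(" (95%% CI %.1f-%.1f)", x$ci_low, x$ci_high))
  cat("\n")
  invisible(x)
}

#' Cohort-averaged cross-sectional rates
#'
#' Averages the difference per year and the percent difference per year over
#' the integer ages inside each cohort window: infant 0-5, development 5-21,
#' young adult 22-35, aging 36 up to the fitted maximum age. A window with
#' no integer age inside the fitted range yields `NA` for that cohort.
#'
#' @param fit a `crcs` fit.
#' @param pathway,feature labels for the output rows (default: taken from
#'   the fit).
#' @param windows named list of `c(lo, hi)` age windows; the default is the
#'   four lifespan cohort windows above (`hi = Inf` is truncated to the
#'   fitted maximum).
#' @return data.frame with columns `pathway, feature, cohort, diff_per_year,
#'   pct_diff_per_year` (a rate-summary table).
#' @export
cohort_mean_rate <- function(fit, pathway = fit$pathway,
                             feature = fit$feature,
                             windows = cohort_windows()) {
  stopifnot(inherits(fit, "crcs"))
  rows <- lapply(names(windows), function(cohort) {
    w <- windows[[cohort]]
    lo <- max(ceiling(w[1]), ceiling(fit$age_range[1]))
    hi <- min(floor(w[2]), floor(fit$age_range[2]))
    if (hi < lo)
      return(data.frame(pathway = pathway, feature = feature,
                        cohort = cohort, diff_per_year = NA_real_,
                        pct_diff_per_year = NA_real_))
    ages <- seq(lo, hi)
    data.frame(pathway = pathway, feature = feature, cohort = cohort,
               diff_per_year = mean(difference_per_year(fit, ages)),
               pct_diff_per_year =
                 mean(percent_difference_per_year(fit, ages)))
  })
  do.call(rbind, rows)
}

#' The four lifespan cohort age windows
#'
#' Infant 0-5, development 5-21, young adult 22-35, aging 36+ years.
#' @return named list of `c(lo, hi)` windows.
#' @export
cohort_windows <- function() {
  list(infant = c(0, 5), development = c(5, 21),
       young_adult = c(22, 35), aging = c(36, Inf))
}

## ---- standard S3 methods ----

#' @export
print.crcs <- function(x, ...) {
  cat(sprintf("C-RCS trajectory fit: %s / %s\n", x$pathway, x$feature))
  cat(sprintf("  n = %d sessions, ages %.1f-%.1f, knots at %s\n",
              x$n_obs, x$age_range[1], x$age_range[2],
              paste(x$knots, collapse = ", ")))
  if (length(x$covariates) > 0L)
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  if (!is.null(x$bootstrap_coefficients))
    cat("  bootstrap replicates:", nrow(x$bootstrap_coefficients), "\n")
  cat("Coefficients:\n")
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' @export
coef.crcs <- function(object, ...) object$coefficients

#' @export
residuals.crcs <- function(object, ...) object$residuals

#' @export
fitted.crcs <- function(object, ...) object$fitted.values

#' Summary of a C-RCS fit
#'
#' Coefficient table with OLS standard errors (and bootstrap standard errors
#' when replicates are present), residual SD and the fitted peak.
#' @param object a `crcs` fit.
#' @param ... unused.
#' @export
summary.crcs <- function(object, ...) {
  X <- object$design
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- object$sigma * sqrt(diag(XtXinv))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `t value` = object$coefficients / se)
  if (!is.null(object$bootstrap_coefficients))
    tab <- cbind(tab, `Boot SE` = apply(object$bootstrap_coefficients, 2L,
                                        stats::sd))
  out <- list(fit = object, coefficients = tab,
              extremum = find_extremum(object, "max"))
  class(out) <- "summary.crcs"
  out
}

#' @export
print.summary.crcs <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Residual SD: %.4g on %d observations\n", x$fit$sigma,
              x$fit$n_obs))
  print(x$extremum)
  invisible(x)
}

#' Plot a fitted lifespan trajectory
#'
#' Observed sessions, the fitted sex-averaged curve, and (when bootstrap
#' replicates are present) the 95% percentile band.
#' @param x a `crcs` fit.
#' @param n_grid curve evaluation points.
#' @param ... passed to [graphics::plot()].
#' @export
plot.crcs <- function(x, n_grid = 200L, ...) {
  ages <- seq(x$age_range[1], x$age_range[2], length.out = n_grid)
  graphics::plot(x$design[, "age"], x$y, pch = 16, cex = 0.4,
                 col = "grey60", xlab = "age (years)",
                 ylab = x$feature, main = x$pathway, ...)
  if (!is.null(x$bootstrap_coefficients)) {
    band <- predict(x, ages, interval = "percentile")
    graphics::polygon(c(ages, rev(ages)), c(band$lower, rev(band$upper)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
  }
  graphics::lines(ages, predict_curve(x, ages), col = "steelblue", lwd = 2)
  invisible(x)
}

#' Simulate responses from a fitted trajectory
#'
#' Draws new observations at the fitted design points: fitted values plus
#' Gaussian noise with the residual SD.
#' @param object a `crcs` fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @export
simulate.crcs <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$fitted.values)
  out <- as.data.frame(replicate(
    nsim, object$fitted.values + stats::rnorm(n, 0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
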