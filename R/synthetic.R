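`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a synthetic streamline bundle with known analytic geometry
#'
#' Builds bundles whose length, span and curl are known in closed form, for
#' exercising and validating the shape metrics:
#'
#' * `straight`: parallel segments of length `params$length` along +x,
#'   start points scattered (radius `params$spread` mm) in the y-z plane.
#'   Analytic curl is exactly 1.
#' * `arc`: circular arcs of radius `params$radius` subtending
#'   `params$angle` radians in the x-y plane, stacked along z. Length is
#'   `radius * angle`, span `2 * radius * sin(angle/2)`.
#' * `helix`: helices of radius `params$radius`, pitch `params$pitch` mm per
#'   turn, `params$turns` turns.
#' * `cylinder_fill`: a solid cylinder of radius `params$radius` and length
#'   `params$length` along +x, filled with straight streamlines on a
#'   deterministic square cross-section lattice of spacing `params$spacing`
#'   mm (so digitised volume converges to `pi r^2 L` without sampling
#'   gaps); `n_streamlines` is ignored for this kind.
#'
#' Per-streamline positional jitter (`params$jitter_sd`, default 0) shifts
#' whole streamlines rigidly so the analytic arc length is preserved. The
#' analytic geometry is attached as `metadata` for tests.
#'
#' @param kind one of `"straight"`, `"arc"`, `"helix"`, `"cylinder_fill"`.
#' @param params named list of geometry parameters (see Details).
#' @param n_streamlines number of streamlines (ignored for
#'   `cylinder_fill`).
#' @param grid optional [reference_grid()] attached to the bundle.
#' @param seed integer seed; the same seed reproduces coordinates exactly.
#' @param origin world-mm origin of the bundle (default `c(0, 0, 0)`).
#' @param name pathway label.
#' @return A [streamline_bundle()] whose `metadata` holds `length_mm`,
#'   `span_mm`, `curl` (and `volume_mm3` for `cylinder_fill`).
#' @export
make_bundle <- function(kind = c("straight", "arc", "helix",
                                 "cylinder_fill"),
                        params = list(), n_streamlines = 50L, grid = NULL,
                        seed = 1L, origin = c(0, 0, 0), name = kind) {
  kind <- match.arg(kind)
  step <- params$step %||% 0.5
  jitter_sd <- params$jitter_sd %||% 0
  with_seed(seed, {
    sl <- switch(kind,
      straight = {
        len <- params$length %||% 80
        if (len <= 0) stop("degenerate params: length must be positive")
        spread <- params$spread %||% 1
        xs <- seq(0, len, by = min(step, len / 2))
        if (xs[length(xs)] < len) xs <- c(xs, len)
        lapply(seq_len(n_streamlines), function(i) {
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- spread * sqrt(stats::runif(1))
          off <- c(0, rad * cos(ang), rad * sin(ang))
          cbind(xs, 0, 0) + rep(origin + off, each = length(xs))
        })
      },
      arc = {
        r <- params$radius %||% 20
        ang <- params$angle %||% pi
        if (r <= 0 || ang <= 0) stop("degenerate params: radius/angle")
        spread <- params$spread %||% 1
        theta <- seq(0, ang, by = min(step / r, ang / 2))
        if (theta[length(theta)] < ang) theta <- c(theta, ang)
        lapply(seq_len(n_streamlines), function(i) {
          z <- spread * (stats::runif(1) - 0.5)
          cbind(r * sin(theta), r * (1 - cos(theta)), z) +
            rep(origin, each = length(theta))
        })
      },
      helix = {
        r <- params$radius %||% 10
        pitch <- params$pitch %||% 20
        turns <- params$turns %||% 2
        if (r <= 0 || turns <= 0) stop("degenerate params: radius/turns")
        total_len <- turns * sqrt((2 * pi * r)^2 + pitch^2)
        npts <- max(3L, ceiling(total_len / step) + 1L)
        t <- seq(0, 1, length.out = npts)
        a <- 2 * pi * turns * t
        lapply(seq_len(n_streamlines), function(i) {
          z0 <- (params$spread %||% 1) * (stats::runif(1) - 0.5)
          cbind(r * cos(a) - r, r * sin(a), pitch * turns * t + z0) +
            rep(origin, each = npts)
        })
      },
      cylinder_fill = {
        r <- params$radius %||% 5
        len <- params$length %||% 100
        if (r <= 0 || len <= 0) stop("degenerate params: radius/length")
        spacing <- params$spacing %||% 0.5
        offs <- seq(-ceiling(r / spacing), ceiling(r / spacing)) * spacing
        lattice <- expand.grid(y = offs, z = offs)
        lattice <- lattice[lattice$y^2 + lattice$z^2 <= r^2, , drop = FALSE]
        xs <- seq(0, len, by = min(step, len / 2))
        if (xs[length(xs)] < len) xs <- c(xs, len)
        lapply(seq_len(nrow(lattice)), function(i) {
          cbind(xs, lattice$y[i], lattice$z[i]) +
            rep(origin, each = length(xs))
        })
      })
    if (jitter_sd > 0)
      sl <- lapply(sl, function(s)
        s + rep(stats::rnorm(3, 0, jitter_sd), each = nrow(s)))
    meta <- switch(kind,
      straight = list(length_mm = params$length %||% 80,
                      span_mm = params$length %||% 80, curl = 1),
      arc = {
        r <- params$radius %||% 20; ang <- params$angle %||% pi
        list(length_mm = r * ang, span_mm = 2 * r * sin(ang / 2),
             curl = (r * ang) / (2 * r * sin(ang / 2)))
      },
      helix = {
        r <- params$radius %||% 10; pitch <- params$pitch %||% 20
        turns <- params$turns %||% 2
        list(length_mm = turns * sqrt((2 * pi * r)^2 + pitch^2))
      },
      cylinder_fill = {
        r <- params$radius %||% 5; len <- params$length %||% 100
        list(length_mm = len, span_mm = len, curl = 1,
             volume_mm3 = pi * r^2 * len)
      })
    streamline_bundle(sl, grid = grid, name = name, metadata = meta)
  })
}

#' Generate an analytic scalar volume
#'
#' Evaluates a known analytic field at the voxel centers of a grid:
#' `constant` (`params$value`), `linear_gradient`
#' (`params$slope * world[axis] + params$offset` along `params$axis`), or
#' `two_region` (`params$low` where `world[axis] < params$threshold`, else
#' `params$high`; either side may be `NA` to emulate a missing-coded
#' region).
#'
#' @param grid a [reference_grid()].
#' @param field one of `"constant"`, `"linear_gradient"`, `"two_region"`.
#' @param params named list of field parameters.
#' @param feature_name label.
#' @return A [scalar_volume()].
#' @export
make_scalar_volume <- function(grid,
                               field = c("constant", "linear_gradient",
                                         "two_region"),
                               params = list(), feature_name = field) {
  field <- match.arg(field)
  idx <- as.matrix(expand.grid(i = seq_len(grid$dims[1]) - 1L,
                               j = seq_len(grid$dims[2]) - 1L,
                               k = seq_len(grid$dims[3]) - 1L))
  world <- voxel_to_world(grid, idx)
  axis <- params$axis %||% 1L
  vals <- switch(field,
    constant = rep(params$value %||% 1, nrow(idx)),
    linear_gradient = (params$slope %||% 1) * world[, axis] +
      (params$offset %||% 0),
    two_region = ifelse(world[, axis] < (params$threshold %||% 0),
                        params$low %||% 0, params$high %||% 1))
  scalar_volume(array(vals, dim = grid$dims), grid, feature_name)
}

#' Trajectory specification for lifespan simulations
#'
#' Defines the ground-truth age trajectory, noise, sex effect, per-cohort
#' acquisition offsets and sampling design used by
#' [simulate_lifespan_table()]. Functional forms:
#'
#' * `linear`: `intercept + slope * age`.
#' * `rcs_coefficients`: a curve in the restricted-cubic-spline span,
#'   `params$coefficients` on `[1, rcs_basis(age, params$knots)]`.
#' * `peaked_bump`: `baseline + amplitude * exp(-(age - peak_age)^2 /
#'   (2 * width^2))`, an inverted-U with a known peak.
#' * `piecewise_slopes`: continuous piecewise-linear with `params$breaks`
#'   and `params$slopes` (one more slope than breaks), starting at
#'   `params$intercept`.
#'
#' @param form functional form (see above).
#' @param params named list of form parameters.
#' @param noise_sd Gaussian noise SD (feature units, default 0.2).
#' @param sex_effect additive shift for sex M relative to F (default 0).
#' @param cohort_offsets named numeric vector of per-cohort offsets
#'   (additive) or factors (multiplicative), e.g.
#'   `c(young_adult = 0.5)`; unnamed cohorts get the neutral value.
#' @param offset_mode `"additive"` or `"multiplicative"`.
#' @param windows named list of cohort age windows; default infant 0-5,
#'   development 5-21, young adult 22-35, aging 36-100.
#' @param n_per_cohort sessions per cohort (scalar or named vector;
#'   default 700 per cohort, ~2800 sessions, the scale of a full
#'   four-cohort lifespan study).
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(form = c("linear", "rcs_coefficients",
                                     "peaked_bump", "piecewise_slopes"),
                            params = list(), noise_sd = 0.2, sex_effect = 0,
                            cohort_offsets = NULL,
                            offset_mode = c("additive", "multiplicative"),
                            windows = NULL, n_per_cohort = 700L) {
  form <- match.arg(form)
  offset_mode <- match.arg(offset_mode)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(windows))
    windows <- list(infant = c(0, 5), development = c(5, 21),
                    young_adult = c(22, 35), aging = c(36, 100))
  if (any(unlist(windows) < 0) || any(unlist(windows) > 100))
    stop("cohort windows must lie within 0-100 years")
  if (length(n_per_cohort) == 1L)
    n_per_cohort <- stats::setNames(rep(as.integer(n_per_cohort),
                                        length(windows)), names(windows))
  structure(list(form = form, params = params, noise_sd = noise_sd,
                 sex_effect = sex_effect, cohort_offsets = cohort_offsets,
                 offset_mode = offset_mode, windows = windows,
                 n_per_cohort = n_per_cohort),
            class = "trajectory_spec")
}

trajectory_functions <- function(spec) {
  p <- spec$params
  switch(spec$form,
    linear = {
      i <- p$intercept %||% 0; s <- p$slope %||% 0.1
      list(f = function(a) i + s * a, df = function(a) rep(s, length(a)))
    },
    rcs_coefficients = {
      knots <- p$knots %||% c(2, 4, 22, 35, 75, 90)
      beta <- p$coefficients
      if (is.null(beta) || length(beta) != length(knots))
        stop("rcs_coefficients needs `coefficients` of length ",
             length(knots), " (intercept, age, ", length(knots) - 2L,
             " spline terms)")
      list(f = function(a) drop(cbind(1, rcs_basis(a, knots)) %*% beta),
           df = function(a) drop(rcs_basis_deriv(a, knots) %*% beta[-1L]))
    },
    peaked_bump = {
      b <- p$baseline %||% 1; amp <- p$amplitude %||% 1
      pk <- p$peak_age %||% 25; w <- p$width %||% 15
      list(f = function(a) b + amp * exp(-(a - pk)^2 / (2 * w^2)),
           df = function(a) -amp * (a - pk) / w^2 *
             exp(-(a - pk)^2 / (2 * w^2)))
    },
    piecewise_slopes = {
      brk <- p$breaks %||% c(21, 36)
      sl <- p$slopes %||% c(1, 0, -1)
      if (length(sl) != length(brk) + 1L)
        stop("piecewise_slopes needs one more slope than breaks")
      i0 <- p$intercept %||% 0
      f <- function(a) {
        vapply(a, function(x) {
          v <- i0; prev <- 0
          for (seg in seq_along(sl)) {
            hi <- if (seg <= length(brk)) brk[seg] else Inf
            v <- v + sl[seg] * (min(x, hi) - prev)
            if (x <= hi) return(v)
            prev <- hi
          }
          v
        }, numeric(1))
      }
      df <- function(a) sl[findInterval(a, brk) + 1L]
      list(f = f, df = df)
    })
}

#' Simulate a multi-cohort lifespan feature table with known ground truth
#'
#' Draws per-cohort session ages uniformly within each cohort window,
#' assigns sex at random, and generates
#' `value = trajectory(age) + sex_effect * (sex == M) + noise`, then applies
#' the per-cohort acquisition offset (added, or multiplied in
#' multiplicative mode). The true trajectory, its derivative, the true peak
#' age over 0-100 and the injected offsets are returned alongside the
#' table, so downstream tests never hard-code generator output.
#'
#' @param spec a [trajectory_spec()].
#' @param pathways,features labels to replicate the design over (each
#'   pathway x feature cell gets independent noise).
#' @param seed integer seed; identical seeds give identical tables.
#' @return list with `table` (a valid lifespan feature table) and `truth`
#'   (list: `f`, `df`, `peak_age`, `offsets`, `offset_mode`, `sex_effect`,
#'   `noise_sd`).
#' @export
simulate_lifespan_table <- function(spec, pathways = "pathway_1",
                                    features = "feature_1", seed = 1L) {
  stopifnot(inherits(spec, "trajectory_spec"))
  fns <- trajectory_functions(spec)
  with_seed(seed, {
    sessions <- do.call(rbind, lapply(names(spec$windows), function(ch) {
      n <- spec$n_per_cohort[[ch]]
      if (n < 1L) stop("empty cohort: ", ch)
      w <- spec$windows[[ch]]
      data.frame(cohort = ch, age = stats::runif(n, w[1], w[2]),
                 sex = sample(c("F", "M"), n, replace = TRUE))
    }))
    ns <- nrow(sessions)
    sessions$subject_id <- sprintf("sub-%05d", seq_len(ns))
    sessions$session_id <- paste0(sessions$subject_id, "_ses-1")
    neutral <- if (spec$offset_mode == "additive") 0 else 1
    off <- rep(neutral, ns)
    if (!is.null(spec$cohort_offsets)) {
      hit <- sessions$cohort %in% names(spec$cohort_offsets)
      off[hit] <- spec$cohort_offsets[sessions$cohort[hit]]
    }
    base <- fns$f(sessions$age) +
      spec$sex_effect * (sessions$sex == "M")
    cells <- expand.grid(pathway = pathways, feature = features,
                         stringsAsFactors = FALSE)
    tab <- do.call(rbind, lapply(seq_len(nrow(cells)), function(ci) {
      v <- base + stats::rnorm(ns, 0, spec$noise_sd)
      v <- if (spec$offset_mode == "additive") v + off else v * off
      data.frame(subject_id = sessions$subject_id,
                 session_id = sessions$session_id,
                 cohort = sessions$cohort, age = sessions$age,
                 sex = sessions$sex, pathway = cells$pathway[ci],
                 feature = cells$feature[ci], value = v)
    }))
    ages_grid <- seq(0, 100, by = 0.1)
    peak_age <- ages_grid[which.max(fns$f(ages_grid))]
    list(table = validate_feature_table(tab),
         truth = list(f = fns$f, df = fns$df, peak_age = peak_age,
                      offsets = spec$cohort_offsets,
                      offset_mode = spec$offset_mode,
                      sex_effect = spec$sex_effect,
                      noise_sd = spec$noise_sd))
  })
}

#' Slope covariance specification for cross-pathway rate simulations
#'
#' @param n_pathways number of pathways (default 63, a whole-brain pathway
#'   set).
#' @param mean_dev,mean_aging mean per-year rates in the development and
#'   aging cohorts.
#' @param sd_dev,sd_aging across-pathway SDs of the rates.
#' @param rho correlation between a pathway's development and aging rates
#'   (the "gain predicts loss" coupling), in `[-1, 1]`.
#' @param features feature labels; multiple features share the structure.
#' @param feature_rho correlation between different features' rates within
#'   a cohort (default 0, independent features).
#' @return An object of class `slope_covariance`.
#' @export
slope_covariance <- function(n_pathways = 63L, mean_dev = 1,
                             mean_aging = -0.5, sd_dev = 0.3,
                             sd_aging = 0.2, rho = 0,
                             features = "feature_1", feature_rho = 0) {
  if (abs(rho) > 1 || abs(feature_rho) > 1)
    stop("correlations must lie in [-1, 1]")
  structure(list(n_pathways = as.integer(n_pathways), mean_dev = mean_dev,
                 mean_aging = mean_aging, sd_dev = sd_dev,
                 sd_aging = sd_aging, rho = rho, features = features,
                 feature_rho = feature_rho),
            class = "slope_covariance")
}

#' Simulate per-pathway development and aging rates with known correlation
#'
#' Draws, for every pathway and feature, a (development, aging) rate pair
#' from a multivariate normal whose within-feature cross-cohort correlation
#' is `rho` and whose between-feature correlation is `feature_rho`. The
#' empirical development-aging correlation converges to `rho` as the
#' pathway count grows.
#'
#' @param cov a [slope_covariance()].
#' @param seed integer seed.
#' @return list with `rates` (a rate-summary data.frame with cohorts
#'   `development` and `aging`) and `truth` (the generating parameters).
#' @export
simulate_pathway_slopes <- function(cov = slope_covariance(), seed = 1L) {
  stopifnot(inherits(cov, "slope_covariance"))
  nf <- length(cov$features)
  sds <- rep(c(cov$sd_dev, cov$sd_aging), nf)
  means <- rep(c(cov$mean_dev, cov$mean_aging), nf)
  dim_tot <- 2L * nf
  R <- matrix(NA_real_, dim_tot, dim_tot)
  is_dev <- rep(c(TRUE, FALSE), nf)
  feat_of <- rep(seq_len(nf), each = 2L)
  for (a in seq_len(dim_tot)) for (b in seq_len(dim_tot)) {
    same_feat <- feat_of[a] == feat_of[b]
    same_cohort <- is_dev[a] == is_dev[b]
    R[a, b] <- if (a == b) 1
      else if (same_feat) cov$rho
      else if (same_cohort) cov$feature_rho
      else cov$feature_rho * cov$rho
  }
  Sigma <- diag(sds) %*% R %*% diag(sds)
  eig <- eigen(Sigma, symmetric = TRUE)
  if (any(eig$values < -1e-8 * max(abs(eig$values))))
    stop("covariance is not positive semidefinite")
  sqrtm <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), dim_tot) %*%
    t(eig$vectors)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(cov$n_pathways * dim_tot), cov$n_pathways)
    draws <- Z %*% sqrtm + rep(means, each = cov$n_pathways)
    pws <- sprintf("pathway_%02d", seq_len(cov$n_pathways))
    rates <- do.call(rbind, lapply(seq_len(nf), function(fi) {
      rbind(
        data.frame(pathway = pws, feature = cov$features[fi],
                   cohort = "development",
                   diff_per_year = draws[, 2L * fi - 1L],
                   pct_diff_per_year = NA_real_),
        data.frame(pathway = pws, feature = cov$features[fi],
                   cohort = "aging", diff_per_year = draws[, 2L * fi],
                   pct_diff_per_year = NA_real_))
    }))
    list(rates = rates, truth = unclass(cov))
  })
}
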