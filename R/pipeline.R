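#' Default pipeline configuration
#'
#' Returns the demo configuration for [run_pipeline()]: a fully synthetic
#' study (no external inputs) of `n_pathways` pathways and two features,
#' whose per-pathway development and aging slopes are drawn with a chosen
#' cross-cohort correlation `rho`, with a young-adult acquisition offset
#' injected and then re-estimated. All sizes are demo-scale; raise
#' `n_per_cohort` and `bootstrap_B` for production runs.
#'
#' @return nested named list of configuration values.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = list(
      n_pathways = 12L,
      features = c("FA", "MD"),
      rho = 0.8,
      mean_dev = 0.02, mean_aging = -0.01,
      sd_dev = 0.008, sd_aging = 0.004,
      intercept = 0.5,
      noise_sd = 0.05,
      sex_effect = 0.02,
      young_adult_offset = 0.1,
      n_per_cohort = 150L
    ),
    harmonize = list(target = "young_adult", mode = "additive"),
    fit = list(knots = c(2, 4, 22, 35, 75, 90), covariates = "sex",
               bootstrap_B = 200L),
    correlate = list(fdr = 0.05)
  )
}

stage_seed <- function(root, k) (as.integer(root) %% 100000L) * 1000L + k

#' Run the full synthetic lifespan pipeline
#'
#' Orchestrates the stages end to end on a deterministic synthetic study:
#' simulate per-pathway lifespan tables (piecewise development/aging slopes
#' drawn with the configured cross-cohort correlation, plus a young-adult
#' acquisition offset) -> harmonize -> fit C-RCS trajectories with
#' bootstrap -> summarize cohort rates and peaks -> correlate rates across
#' pathways and test whether developmental gain predicts aging loss.
#' Intermediates and results are written as CSV; a JSON manifest records
#' the configuration, seeds and output checksums. Identical configuration
#' and seed give byte-identical outputs; every stage draws its seed from
#' the root seed by a fixed derivation.
#'
#' @param config a configuration list (see [default_pipeline_config()]),
#'   or the path of a YAML file holding one; partial configurations are
#'   completed with the defaults.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return (invisibly) list with the output directory and the main tables:
#'   `table`, `harmonized`, `offsets`, `curves`, `rates`, `peaks`,
#'   `rate_correlations`, `gain_loss`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  root <- config$seed
  cs <- config$simulate

  ## stage 1: simulate -------------------------------------------------
  say("stage simulate: ", cs$n_pathways, " pathways x ",
      length(cs$features), " features")
  slopes <- simulate_pathway_slopes(
    slope_covariance(n_pathways = cs$n_pathways, mean_dev = cs$mean_dev,
                     mean_aging = cs$mean_aging, sd_dev = cs$sd_dev,
                     sd_aging = cs$sd_aging, rho = cs$rho,
                     features = cs$features),
    seed = stage_seed(root, 1L))
  sl <- slopes$rates
  tabs <- list()
  cell <- 0L
  for (pw in unique(sl$pathway)) for (ft in cs$features) {
    cell <- cell + 1L
    dev_slope <- sl$diff_per_year[sl$pathway == pw & sl$feature == ft &
                                    sl$cohort == "development"]
    aging_slope <- sl$diff_per_year[sl$pathway == pw & sl$feature == ft &
                                      sl$cohort == "aging"]
    spec <- trajectory_spec(
      "piecewise_slopes",
      params = list(intercept = cs$intercept, breaks = c(21, 36),
                    slopes = c(dev_slope, 0, aging_slope)),
      noise_sd = cs$noise_sd, sex_effect = cs$sex_effect,
      cohort_offsets = c(young_adult = cs$young_adult_offset),
      n_per_cohort = cs$n_per_cohort)
    sim <- simulate_lifespan_table(spec, pathways = pw, features = ft,
                                   seed = stage_seed(root, 100L + cell))
    tabs[[cell]] <- sim$table
  }
  table <- do.call(rbind, tabs)
  rownames(table) <- NULL
  write_feature_table(table, file.path(out_dir, "table.csv"))

  ## stage 2: harmonize ------------------------------------------------
  say("stage harmonize: target ", config$harmonize$target)
  fit_spec <- spline_spec(knots = config$fit$knots,
                          covariates = config$fit$covariates)
  offsets <- estimate_offsets(table,
                              target_cohorts = config$harmonize$target,
                              mode = config$harmonize$mode, spec = fit_spec)
  harmonized <- apply_offsets(table, offsets)
  utils::write.csv(offsets, file.path(out_dir, "offsets.csv"),
                   row.names = FALSE)
  write_feature_table(harmonized, file.path(out_dir, "harmonized.csv"))

  ## stage 3: fit + summarize ------------------------------------------
  say("stage fit: C-RCS with B = ", config$fit$bootstrap_B)
  combos <- unique(harmonized[, c("pathway", "feature")])
  curves <- rates <- peaks <- list()
  for (i in seq_len(nrow(combos))) {
    pw <- combos$pathway[i]; ft <- combos$feature[i]
    fit <- tryCatch(
      bootstrap_fit(harmonized, pw, ft, spec = fit_spec,
                    B = config$fit$bootstrap_B,
                    seed = stage_seed(root, 500L + i)),
      error = function(e) stop("stage fit failed for (", pw, ", ", ft,
                               "): ", conditionMessage(e)))
    ages <- seq(ceiling(fit$age_range[1]), floor(fit$age_range[2]))
    band <- predict(fit, ages, interval = "percentile")
    curves[[i]] <- cbind(pathway = pw, feature = ft, band)
    rates[[i]] <- cohort_mean_rate(fit)
    ex <- find_extremum(fit, "max")
    peaks[[i]] <- data.frame(pathway = pw, feature = ft,
                             age_at_peak = ex$age_at_extremum,
                             kind = ex$kind, ci_low = ex$ci_low,
                             ci_high = ex$ci_high)
  }
  curves <- do.call(rbind, curves)
  rates <- do.call(rbind, rates)
  peaks <- do.call(rbind, peaks)
  utils::write.csv(curves, file.path(out_dir, "curves.csv"),
                   row.names = FALSE)
  utils::write.csv(rates, file.path(out_dir, "rates.csv"),
                   row.names = FALSE)
  utils::write.csv(peaks, file.path(out_dir, "peaks.csv"),
                   row.names = FALSE)

  ## stage 4: correlate ------------------------------------------------
  say("stage correlate")
  fdr <- config$correlate$fdr
  rate_cors <- do.call(rbind, lapply(
    intersect(c("development", "aging"), unique(rates$cohort)),
    function(ch) {
      cm <- rate_correlation_matrix(rates, ch, q_level = fdr)
      ut <- which(upper.tri(cm$r), arr.ind = TRUE)
      data.frame(cohort = ch,
                 feature_a = cm$features[ut[, 1]],
                 feature_b = cm$features[ut[, 2]],
                 r = cm$r[ut], p = cm$p[ut], q = cm$q[ut], n = cm$n[ut])
    }))
  gain_loss <- gain_loss_correlation(rates, q_level = fdr)
  utils::write.csv(rate_cors, file.path(out_dir, "rate_correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(gain_loss, file.path(out_dir, "gain_loss.csv"),
                   row.names = FALSE)

  ## manifest ----------------------------------------------------------
  cfg_path <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(config, cfg_path)
  outputs <- c("table.csv", "offsets.csv", "harmonized.csv", "curves.csv",
               "rates.csv", "peaks.csv", "rate_correlations.csv",
               "gain_loss.csv")
  manifest <- list(
    package = "tractlife",
    package_version = as.character(utils::packageVersion("tractlife")),
    r_version = as.character(getRversion()),
    seed = root,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(out_dir = out_dir, table = table, harmonized = harmonized,
                 offsets = offsets, curves = curves, rates = rates,
                 peaks = peaks, rate_correlations = rate_cors,
                 gain_loss = gain_loss, true_slopes = slopes))
}
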