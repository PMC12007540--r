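#' Estimate between-cohort offsets under continuity assumptions
#'
#' Multi-cohort lifespan data can carry an acquisition offset in one cohort
#' (typically the young-adult cohort, acquired at a different resolution and
#' diffusion protocol). Because the cohorts do not overlap in age, reference
#' covariate-matched harmonization (e.g. ComBat) is not applicable; instead
#' the smooth-trajectory assumption is used: for each (pathway, feature) the
#' C-RCS age model is fitted to the reference cohorts only, the fit is
#' evaluated at the target cohort's ages (and covariates), and the offset is
#' the mean of observed minus predicted over target sessions (additive mode)
#' or the mean observed/predicted ratio (multiplicative mode). Offsets are
#' constant in age — an acquisition effect, not a biological one.
#'
#' The target cohort's age range must be bracketed by (or overlap) the
#' reference ages, with at least `min_flank` reference observations on each
#' side, otherwise the fit would extrapolate and the estimate is refused.
#'
#' @param table a lifespan feature table.
#' @param target_cohorts cohorts to estimate offsets for (default
#'   `"young_adult"`).
#' @param mode `"additive"` (offset in feature units) or `"multiplicative"`
#'   (unitless factor; requires a strictly positive reference prediction).
#' @param spec a [spline_spec()] for the reference fit.
#' @param min_flank minimum reference observations on each side of the
#'   target age range (default 20).
#' @return An object of class `cohort_offsets`: data.frame with columns
#'   `pathway, feature, cohort, offset, mode`; reference cohorts carry
#'   offset 0 (additive) or 1 (multiplicative).
#' @export
estimate_offsets <- function(table, target_cohorts = "young_adult",
                             mode = c("additive", "multiplicative"),
                             spec = spline_spec(), min_flank = 20L) {
  mode <- match.arg(mode)
  table <- validate_feature_table(table)
  bad <- setdiff(target_cohorts, COHORT_LEVELS)
  if (length(bad)) stop("unknown target cohort(s): ",
                        paste(bad, collapse = ", "))
  is_target <- table$cohort %in% target_cohorts
  combos <- unique(table[, c("pathway", "feature")])
  neutral <- if (mode == "additive") 0 else 1
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    pw <- combos$pathway[i]; ft <- combos$feature[i]
    sel <- table$pathway == pw & table$feature == ft & !is.na(table$value)
    ref <- table[sel & !is_target, , drop = FALSE]
    for (cohort in COHORT_LEVELS) {
      if (!any(table$cohort == cohort & sel)) next
      if (!cohort %in% target_cohorts) {
        rows[[length(rows) + 1L]] <- data.frame(
          pathway = pw, feature = ft, cohort = cohort, offset = neutral,
          mode = mode)
        next
      }
      tgt <- table[sel & table$cohort == cohort, , drop = FALSE]
      n_below <- sum(ref$age <= min(tgt$age))
      n_above <- sum(ref$age >= max(tgt$age))
      if (n_below < min_flank || n_above < min_flank)
        stop("cannot extrapolate: target cohort '", cohort,
             "' for (", pw, ", ", ft, ") is not bracketed by at least ",
             min_flank, " reference observations per side")
      fit <- fit_crcs(ref, spec = spec)
      Xt <- crcs_design(tgt, spec)
      pred <- drop(Xt %*% fit$coefficients)
      off <- if (mode == "additive") mean(tgt$value - pred)
             else mean(tgt$value / pred)
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = pw, feature = ft, cohort = cohort, offset = off,
        mode = mode)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_offsets", class(out))
  out
}

#' Apply estimated cohort offsets to a feature table
#'
#' Subtracts (additive mode) or divides out (multiplicative mode) the
#' per-(pathway, feature, cohort) offset from every matching record. Every
#' (pathway, feature, cohort) combination present in the table must be
#' covered by the offsets; reference cohorts carry neutral offsets and are
#' left unchanged, so applying a freshly estimated offset table never
#' touches reference records, and re-applying neutral offsets is a no-op.
#'
#' @param table a lifespan feature table.
#' @param offsets a `cohort_offsets` object from [estimate_offsets()].
#' @return the harmonized feature table.
#' @export
apply_offsets <- function(table, offsets) {
  table <- validate_feature_table(table)
  key <- function(pw, ft, ch) paste(pw, ft, ch, sep = "\r")
  off_map <- stats::setNames(offsets$offset,
                             key(offsets$pathway, offsets$feature,
                                 offsets$cohort))
  tab_keys <- key(table$pathway, table$feature, table$cohort)
  uncovered <- !tab_keys %in% names(off_map)
  if (any(uncovered)) {
    u <- table[uncovered, c("pathway", "feature", "cohort")][1L, ]
    stop("no offset for (", u$pathway, ", ", u$feature, ", ", u$cohort, ")")
  }
  o <- unname(off_map[tab_keys])
  mode <- offsets$mode[1L]
  table$value <- if (mode == "additive") table$value - o else table$value / o
  table
}
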