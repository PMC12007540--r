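#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR control: returns the monotone BH-adjusted values (via
#' [stats::p.adjust()]) and the rejection flags at the requested level.
#'
#' @param pvals numeric p values in `[0, 1]` (`NA` allowed and propagated).
#' @param q_level FDR level (default 0.05).
#' @return list with `q` (adjusted values) and `reject` (logical).
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.9))$reject
#' @export
bh_fdr <- function(pvals, q_level = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  q <- stats::p.adjust(pvals, method = "BH")
  list(q = q, reject = !is.na(q) & q <= q_level)
}

pearson_p <- function(r, n, n_covariates = 0L) {
  df <- n - 2L - n_covariates
  if (is.na(r) || df < 1L) return(NA_real_)
  r <- min(max(r, -1), 1)
  if (abs(r) == 1) return(0)
  tstat <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tstat), df)
}

# Correlation between two vectors on pairwise-complete rows, optionally
# partialling out covariate columns by OLS residualisation.
pair_correlation <- function(x, y, covariates = NULL,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
  n <- sum(ok)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n < 3L + k) return(list(r = NA_real_, p = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  if (!is.null(covariates)) {
    Z <- cbind(1, as.matrix(covariates)[ok, , drop = FALSE])
    x <- stats::lm.fit(Z, x)$residuals
    y <- stats::lm.fit(Z, y)$residuals
  }
  r <- stats::cor(x, y, method = method)
  list(r = r, p = pearson_p(r, n, k), n = n)
}

#' Cross-sessional correlation matrix between features of one pathway
#'
#' For one pathway, correlates every feature with every other feature over
#' sessions (pairwise-complete). In partial mode both features are first
#' residualised on the covariates (e.g. age and sex) by least squares and
#' the residuals are correlated, with the p value from a t distribution on
#' `n - 2 - #covariates` degrees of freedom. Adjusted q values control the
#' Benjamini-Hochberg FDR over the upper triangle of the matrix.
#'
#' @param table a lifespan feature table.
#' @param pathway which pathway to analyse (default: the only one present).
#' @param partial_covariates character vector among `"age"`, `"sex"`, or
#'   `NULL` for plain correlation.
#' @param method `"pearson"` (default, the linear correlation coefficient)
#'   or `"spearman"`.
#' @param q_level FDR level (default 0.05).
#' @return An object of class `correlation_matrix`: list with symmetric
#'   matrices `r`, `p`, `q`, `n` (features x features) and `features`.
#' @export
feature_correlation_matrix <- function(table, pathway = NULL,
                                       partial_covariates = NULL,
                                       method = "pearson", q_level = 0.05) {
  table <- validate_feature_table(table)
  if (is.null(pathway)) {
    pathway <- unique(table$pathway)
    if (length(pathway) > 1L)
      stop("multiple pathways in table; pick one with `pathway`")
  }
  tab <- table[table$pathway == pathway, , drop = FALSE]
  feats <- sort(unique(tab$feature))
  sess <- unique(tab$session_id)
  wide <- matrix(NA_real_, length(sess), length(feats),
                 dimnames = list(sess, feats))
  wide[cbind(match(tab$session_id, sess), match(tab$feature, feats))] <-
    tab$value
  covariates <- NULL
  if (!is.null(partial_covariates)) {
    meta <- tab[!duplicated(tab$session_id), , drop = FALSE]
    meta <- meta[match(sess, meta$session_id), , drop = FALSE]
    covariates <- sapply(partial_covariates, function(cv) {
      v <- meta[[cv]]
      if (is.numeric(v)) v else as.numeric(factor(v))
    })
    covariates <- matrix(covariates, ncol = length(partial_covariates),
                         dimnames = list(NULL, partial_covariates))
  }
  nf <- length(feats)
  r <- p <- q <- matrix(NA_real_, nf, nf, dimnames = list(feats, feats))
  n <- matrix(0L, nf, nf, dimnames = list(feats, feats))
  diag(r) <- 1
  diag(n) <- colSums(!is.na(wide))
  for (i in seq_len(nf - 1L)) for (j in seq.int(i + 1L, nf)) {
    pc <- pair_correlation(wide[, i], wide[, j], covariates, method)
    r[i, j] <- r[j, i] <- pc$r
    p[i, j] <- p[j, i] <- pc$p
    n[i, j] <- n[j, i] <- pc$n
  }
  upper <- upper.tri(q)
  q[upper] <- bh_fdr(p[upper], q_level)$q
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  structure(list(r = r, p = p, q = q, n = n, features = feats,
                 pathway = pathway, q_level = q_level,
                 partial_covariates = partial_covariates),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  kind <- if (is.null(x$partial_covariates)) "correlation"
          else paste0("partial correlation (| ",
                      paste(x$partial_covariates, collapse = ", "), ")")
  cat(sprintf("Feature %s matrix: %d features, %d significant pairs at q <= %g\n",
              kind, length(x$features),
              sum(x$q[upper.tri(x$q)] <= x$q_level, na.rm = TRUE),
              x$q_level))
  invisible(x)
}

rate_wide <- function(rates, cohort, value_col = "diff_per_year") {
  r <- as.data.frame(rates)
  r <- r[r$cohort == cohort & !is.na(r[[value_col]]), , drop = FALSE]
  feats <- sort(unique(r$feature))
  pws <- sort(unique(r$pathway))
  m <- matrix(NA_real_, length(pws), length(feats),
              dimnames = list(pws, feats))
  m[cbind(match(r$pathway, pws), match(r$feature, feats))] <- r[[value_col]]
  m
}

#' Cross-pathway correlation of per-year rates between features
#'
#' Within one cohort, correlates the vector of per-pathway rates
#' (difference per year) of each feature against that of every other
#' feature, asking whether pathways with steeper change in one feature also
#' change faster in another. BH-FDR is applied across pairs.
#'
#' @param rates a rate-summary data.frame (see [cohort_mean_rate()]) with
#'   columns `pathway, feature, cohort, diff_per_year`.
#' @param cohort cohort to analyse.
#' @param value_col rate column to correlate (default `diff_per_year`).
#' @param q_level FDR level.
#' @return A `correlation_matrix` (features x features, n = shared
#'   pathways).
#' @export
rate_correlation_matrix <- function(rates, cohort,
                                    value_col = "diff_per_year",
                                    q_level = 0.05) {
  m <- rate_wide(rates, cohort, value_col)
  feats <- colnames(m)
  nf <- length(feats)
  if (nf < 2L) stop("need at least 2 features with rates in cohort ", cohort)
  r <- p <- q <- matrix(NA_real_, nf, nf, dimnames = list(feats, feats))
  n <- matrix(0L, nf, nf, dimnames = list(feats, feats))
  diag(r) <- 1
  diag(n) <- colSums(!is.na(m))
  for (i in seq_len(nf - 1L)) for (j in seq.int(i + 1L, nf)) {
    pc <- pair_correlation(m[, i], m[, j])
    r[i, j] <- r[j, i] <- pc$r
    p[i, j] <- p[j, i] <- pc$p
    n[i, j] <- n[j, i] <- pc$n
  }
  upper <- upper.tri(q)
  q[upper] <- bh_fdr(p[upper], q_level)$q
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  structure(list(r = r, p = p, q = q, n = n, features = feats,
                 cohort = cohort, q_level = q_level,
                 partial_covariates = NULL),
            class = "correlation_matrix")
}

#' Does developmental gain predict aging loss?
#'
#' For each feature, correlates the per-pathway cross-sectional rate in the
#' development cohort with the per-pathway rate of the same feature in the
#' aging cohort. A strong negative correlation means pathways that gain
#' fastest during development lose fastest during aging. q values control
#' the BH-FDR across the feature family.
#'
#' @param rates a rate-summary data.frame covering the `development` and
#'   `aging` cohorts.
#' @param features features to test (default: all with rates in both
#'   cohorts).
#' @param value_col rate column (default `diff_per_year`).
#' @param q_level FDR level.
#' @return data.frame with columns `feature, r, p, q, n` (n = pathways).
#' @export
gain_loss_correlation <- function(rates, features = NULL,
                                  value_col = "diff_per_year",
                                  q_level = 0.05) {
  r <- as.data.frame(rates)
  for (needed in c("development", "aging"))
    if (!any(r$cohort == needed))
      stop("rates are missing the '", needed, "' cohort")
  dev <- rate_wide(r, "development", value_col)
  agn <- rate_wide(r, "aging", value_col)
  if (is.null(features))
    features <- intersect(colnames(dev), colnames(agn))
  if (length(features) == 0L) stop("no shared features across cohorts")
  pws <- intersect(rownames(dev), rownames(agn))
  out <- do.call(rbind, lapply(features, function(ft) {
    x <- if (ft %in% colnames(dev)) dev[pws, ft] else rep(NA_real_, length(pws))
    y <- if (ft %in% colnames(agn)) agn[pws, ft] else rep(NA_real_, length(pws))
    pc <- pair_correlation(x, y)
    data.frame(feature = ft, r = pc$r, p = pc$p, n = pc$n)
  }))
  out$q <- bh_fdr(out$p, q_level)$q
  out[, c("feature", "r", "p", "q", "n")]
}

#' Anterior-posterior gradient of per-pathway rates
#'
#' Regresses the per-pathway rate of one feature in one cohort on the
#' pathway's anterior-posterior (y) coordinate in standard space, with both
#' a linear and a quadratic model, to test whether rates vary
#' systematically from front to back of the brain.
#'
#' @param rates rate-summary data.frame.
#' @param centroids data.frame with columns `pathway, y_mm` (see
#'   [bundle_centroid()]).
#' @param cohort,feature which slice of the rates to model.
#' @param value_col rate column (default `pct_diff_per_year`, the percent
#'   change per year shown along this axis).
#' @return list with `linear` and `quadratic` components, each holding
#'   `coefficients` and `p_values`, plus `n` pathways used.
#' @export
ap_gradient <- function(rates, centroids, cohort, feature,
                        value_col = "pct_diff_per_year") {
  r <- as.data.frame(rates)
  r <- r[r$cohort == cohort & r$feature == feature, , drop = FALSE]
  d <- merge(r, as.data.frame(centroids), by = "pathway")
  d <- d[!is.na(d[[value_col]]) & is.finite(d$y_mm), , drop = FALSE]
  if (nrow(d) < 4L) stop("need at least 4 pathways with centroids")
  if (stats::sd(d$y_mm) == 0) stop("collinear centroids: y_mm is constant")
  lin <- stats::lm(d[[value_col]] ~ y_mm, data = d)
  quad <- stats::lm(d[[value_col]] ~ y_mm + I(y_mm^2), data = d)
  coefs_p <- function(m) {
    s <- summary(m)$coefficients
    list(coefficients = s[, "Estimate"], p_values = s[, "Pr(>|t|)"])
  }
  list(linear = coefs_p(lin), quadratic = coefs_p(quad), n = nrow(d))
}

#' Anterior-posterior centroid of a bundle
#'
#' Unweighted mean of all streamline points; the y (anterior-posterior)
#' component orders pathways from posterior (low y in RAS) to anterior.
#'
#' @param bundle a [streamline_bundle()] in standard (e.g. MNI) space.
#' @return data.frame with columns `pathway, y_mm` and attribute
#'   `centroid` (the full 3D mean).
#' @export
bundle_centroid <- function(bundle) {
  stopifnot(inherits(bundle, "streamline_bundle"))
  pts <- do.call(rbind, bundle$streamlines)
  ctr <- colMeans(pts)
  out <- data.frame(pathway = bundle$name, y_mm = ctr[2])
  attr(out, "centroid") <- ctr
  out
}
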