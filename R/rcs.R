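#' Restricted cubic spline basis
#'
#' Builds the design columns of a restricted cubic spline (natural cubic
#' spline) with the given knots: a linear term plus `k - 2` nonlinear terms
#'
#' \deqn{s_j(x) = \frac{(x-t_j)_+^3 - (x-t_{k-1})_+^3
#'   \frac{t_k-t_j}{t_k-t_{k-1}} + (x-t_k)_+^3
#'   \frac{t_{k-1}-t_j}{t_k-t_{k-1}}}{(t_k-t_1)^2}, \quad j = 1, \dots, k-2,}
#'
#' the standard restricted truncated-power basis, which is linear beyond the
#' boundary knots. The \eqn{(t_k-t_1)^2} normalisation keeps the columns on
#' the scale of `x` for conditioning; it rescales coefficients, not the
#' fitted curve.
#'
#' @param x numeric vector of evaluation points (ages in years).
#' @param knots numeric vector of at least 3 strictly ascending knots.
#' @return matrix with `length(knots) - 1` columns named
#'   `age, s1, ..., s(k-2)`.
#' @examples
#' b <- rcs_basis(0:100, knots = c(2, 4, 22, 35, 75, 90))
#' dim(b)  # 101 x 5
#' @export
rcs_basis <- function(x, knots) {
  knots <- check_knots(knots)
  cbind(age = x, rcs_terms(x, knots, power = 3L))
}

#' First derivative of the restricted cubic spline basis
#'
#' Columns are the derivatives with respect to `x` of the columns of
#' [rcs_basis()] (the linear column differentiates to 1).
#'
#' @inheritParams rcs_basis
#' @export
rcs_basis_deriv <- function(x, knots) {
  knots <- check_knots(knots)
  cbind(age = rep(1, length(x)), 3 * rcs_terms(x, knots, power = 2L))
}

# Second derivative, used to verify tail linearity.
rcs_basis_deriv2 <- function(x, knots) {
  knots <- check_knots(knots)
  cbind(age = rep(0, length(x)), 6 * rcs_terms(x, knots, power = 1L))
}

check_knots <- function(knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 3L) stop("at least 3 knots are required")
  if (any(diff(knots) <= 0)) stop("knots must be strictly ascending")
  knots
}

rcs_terms <- function(x, knots, power) {
  k <- length(knots)
  t1 <- knots[1]; tkm1 <- knots[k - 1L]; tk <- knots[k]
  norm <- (tk - t1)^2
  pp <- function(u) pmax(u, 0)^power
  out <- vapply(seq_len(k - 2L), function(j) {
    tj <- knots[j]
    (pp(x - tj) -
       pp(x - tkm1) * (tk - tj) / (tk - tkm1) +
       pp(x - tk) * (tkm1 - tj) / (tk - tkm1)) / norm
  }, numeric(length(x)))
  out <- matrix(out, nrow = length(x))
  colnames(out) <- paste0("s", seq_len(k - 2L))
  out
}

#' Spline specification for lifespan trajectory fits
#'
#' Bundles the knot locations and covariate names used by [fit_crcs()]. The
#' default knots (2, 4, 22, 35, 75, 90 years) follow expected developmental
#' shifts in brain volumetry, with five to six knots the usual compromise
#' between flexibility and overfitting; the default covariate is sex.
#'
#' @param knots ascending knot ages in years (>= 3).
#' @param covariates character vector of covariate column names in the
#'   feature table (may be empty).
#' @return An object of class `spline_spec`.
#' @export
spline_spec <- function(knots = c(2, 4, 22, 35, 75, 90),
                        covariates = "sex") {
  structure(list(knots = check_knots(knots),
                 covariates = as.character(covariates)),
            class = "spline_spec")
}
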