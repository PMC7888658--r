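#' @useDynLib nevosim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approxfun coef dist dlnorm lm optim quantile rbeta rlnorm
#'   rnorm runif sd setNames splinefun t.test uniroot var
NULL

# Shape-curve B-spline layout: degree 5, four uniform interior knots, ten
# control coefficients.  The endpoint conditions r(0)=0, r(R)=R, r'(0)=r'(R)=1,
# r''=r'''=0 at both ends pin the first and last four coefficients; the two
# free interior vertices are displaced along the r-axis by the scalar shape
# parameter p, which bends the profile from tapered (p < 0) through neutral to
# broad-shouldered / near-cylindrical (p > 0).

.shape_degree <- 5L

.shape_knots <- function(R) c(rep(0, 6), R * (1:4) / 5, rep(R, 6))

.greville <- function(knots, degree = .shape_degree) {
  n <- length(knots) - degree - 1L
  vapply(seq_len(n), function(i) mean(knots[(i + 1):(i + degree)]), 0)
}

# Convert a B-spline (knots, coefficients) to Taylor piecewise-polynomial
# form for the C++ kernels.  Exact: the spline is polynomial per interval.
.bs_to_ppoly <- function(knots, coefs, degree = .shape_degree) {
  breaks <- unique(knots)
  m <- length(breaks) - 1L
  cf <- matrix(0, 6, m)
  for (j in seq_len(m)) {
    x0 <- breaks[j]
    des <- splines::splineDesign(knots, x = rep(x0, 6), ord = degree + 1L,
                                 derivs = 0:5, outer.ok = TRUE)
    cf[, j] <- as.numeric(des %*% coefs) / factorial(0:5)
  }
  list(breaks = breaks, coef = cf)
}

.eval_bs <- function(knots, coefs, x, deriv = 0L, degree = .shape_degree) {
  L <- knots[length(knots)]
  x <- pmin(pmax(x, 0), L)
  des <- splines::splineDesign(knots, x = x, ord = degree + 1L,
                               derivs = rep(deriv, length(x)), outer.ok = TRUE)
  as.numeric(des %*% coefs)
}

#' Build a papilla shape curve
#'
#' Constructs the pair of B-spline components \eqn{(r(\theta), h(\theta))}
#' defining one dermal papilla as a surface of revolution.  The curve
#' satisfies, to machine precision, the smooth-transition boundary conditions
#' \eqn{r(0)=0}, \eqn{r(R)=R}, \eqn{r'(0)=r'(R)=1},
#' \eqn{r''=r'''=0} at both ends, and \eqn{h(0)=H}, \eqn{h(R)=0} with
#' \eqn{h'=h''=h'''=0} at both ends, so the papilla surface joins the planar
#' membrane three-times continuously differentiably.
#'
#' @param R base radius in micrometres (> 0).
#' @param H height in micrometres (> 0).
#' @param p scalar shape parameter in \code{[-1, 1]}; larger values displace
#'   the two free interior control vertices towards larger radii, producing a
#'   more shouldered (broad-topped) profile.
#' @return an object of class \code{nevo_shape_curve}.
#' @export
build_shape_curve <- function(R, H, p = 0) {
  if (!is.finite(R) || R <= 0) stop("R must be positive")
  if (!is.finite(H) || H <= 0) stop("H must be positive")
  if (!is.finite(p) || p < -1 || p > 1)
    stop("shape parameter p outside admissible interval [-1, 1]")
  knots <- .shape_knots(R)
  xi <- .greville(knots)
  r_coeffs <- xi                        # Greville: exact identity r = theta
  r_coeffs[5:6] <- r_coeffs[5:6] + 0.15 * R * p
  h_coeffs <- H * c(1, 1, 1, 1, 0.7, 0.3, 0, 0, 0, 0)
  if (any(diff(r_coeffs) <= 0))
    stop("shape-curve construction failed: r coefficients not increasing")
  structure(list(
    R = R, H = H, p = p, degree = .shape_degree,
    knots = knots, r_coeffs = r_coeffs, h_coeffs = h_coeffs,
    r_pp = .bs_to_ppoly(knots, r_coeffs),
    h_pp = .bs_to_ppoly(knots, h_coeffs)
  ), class = "nevo_shape_curve")
}

#' Evaluate a shape-curve component
#'
#' @param curve a \code{nevo_shape_curve}.
#' @param theta virtual radius, in \code{[0, R]} (micrometres).
#' @param comp \code{"r"} or \code{"h"}.
#' @param deriv derivative order (0 to 3).
#' @return numeric vector of component values.
#' @export
eval_shape <- function(curve, theta, comp = c("r", "h"), deriv = 0L) {
  comp <- match.arg(comp)
  cf <- if (comp == "r") curve$r_coeffs else curve$h_coeffs
  .eval_bs(curve$knots, cf, theta, deriv = deriv)
}

# theta at which h(theta) equals a given altitude; h is strictly decreasing
# over the interior so the solution is unique.
.shape_theta_at_height <- function(curve, z) {
  vapply(z, function(zi) {
    if (zi >= curve$H) return(0)
    if (zi <= 0) return(curve$R)
    uniroot(function(th) eval_shape(curve, th, "h") - zi,
            lower = 0, upper = curve$R, tol = 1e-10)$root
  }, 0)
}

#' Papilla radius at a given altitude
#'
#' Horizontal radius of the papilla surface at altitude \code{z} above the
#' base plane (used when fitting the shape model to section measurements).
#'
#' @param curve a \code{nevo_shape_curve}.
#' @param z altitude(s) in micrometres, within \code{[0, H]}.
#' @return radius (micrometres) at each altitude.
#' @export
shape_radius_at_height <- function(curve, z) {
  eval_shape(curve, .shape_theta_at_height(curve, z), "r")
}

#' @export
print.nevo_shape_curve <- function(x, ...) {
  cat(sprintf("papilla shape curve: R = %.2f um, H = %.2f um, p = %.3f\n",
              x$R, x$H, x$p))
  invisible(x)
}
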