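# Functional damping factors and intercellular force curves.  Damping
# curves map a generation number or a local density in [0,1] to a
# multiplicative factor in [0,1]; they are monotone piecewise-polynomial
# interpolants of named control points.  Force curves map an intercellular
# gap distance to a non-negative magnitude that vanishes beyond a cutoff.

#' Define a damping curve
#'
#' @param name curve name (one of \code{A}, \code{B}, \code{Q}, \code{R_gen},
#'   \code{G_a}, \code{G_r}, \code{H_a}, \code{H_r}, \code{A_nest},
#'   \code{B_nest}, \code{s}); informational.
#' @param x control-point abscissae (generation index or density in [0,1]),
#'   strictly increasing.
#' @param y control-point values. For the emigration-rate curve \code{s} the
#'   values are rates in d^-1; all other curves are clamped to [0,1].
#' @return an object of class \code{nevo_damping_curve} (callable).
#' @export
damping_curve <- function(name, x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2, all(diff(x) > 0))
  is_rate <- identical(name, "s")
  if (!is_rate) stopifnot(all(y >= 0), all(y <= 1))
  fn <- splinefun(x, y, method = "hyman")
  lo <- min(x); hi <- max(x)
  f <- function(t) {
    t <- pmin(pmax(t, lo), hi)
    v <- fn(t)
    if (is_rate) pmax(v, 0) else pmin(pmax(v, 0), 1)
  }
  structure(list(name = name, x = x, y = y, fn = f),
            class = "nevo_damping_curve")
}

#' Evaluate a damping curve
#' @param curve a [damping_curve()].
#' @param t evaluation points.
#' @return curve values.
#' @export
eval_curve <- function(curve, t) curve$fn(t)

#' Define an intercellular force curve
#'
#' @param name \code{"F_a"} (attraction) or \code{"F_r"} (repulsion).
#' @param cutoff distance (micrometres) beyond which the force vanishes.
#' @param magnitude value at zero gap (forces typically take values below 1).
#' @param shape decay shape: \code{"quadratic"} or \code{"linear"}.
#' @return an object of class \code{nevo_force_curve}.
#' @export
force_curve <- function(name, cutoff, magnitude = 1, shape = c("quadratic", "linear")) {
  shape <- match.arg(shape)
  stopifnot(cutoff >= 0, magnitude >= 0)
  f <- function(d) {
    d <- pmax(d, 0)
    t <- pmax(1 - d / max(cutoff, 1e-12), 0)
    magnitude * (if (shape == "quadratic") t^2 else t)
  }
  structure(list(name = name, cutoff = cutoff, magnitude = magnitude,
                 shape = shape, fn = f),
            class = "nevo_force_curve")
}

# tabulate a curve on a uniform grid for the C++ engine
.tabulate <- function(curve, xmax, n = 121L) {
  if (is.null(curve)) return(rep(1, n))
  xs <- seq(0, xmax, length.out = n)
  if (inherits(curve, "nevo_damping_curve") || inherits(curve, "nevo_force_curve"))
    curve$fn(xs)
  else if (is.function(curve)) curve(xs)
  else rep(as.numeric(curve), n)
}
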