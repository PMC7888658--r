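# Melanocyte agents and their stochastic events.  These reference
# implementations define the per-cell semantics; the C++ engine applies the
# same rules to whole populations.

#' Create a melanocyte agent record
#'
#' @param id unique integer id.
#' @param position 3D position (micrometres).
#' @param radius cell radius (micrometres, > 0).
#' @param generation divisions since simulation start.
#' @param strain nest identifier (\code{NA} for the default population).
#' @param strain_generation divisions since differentiation (nested cells).
#' @param p0 inherited base proliferation rate (per day).
#' @param nested whether the cell belongs to a nest strain.
#' @return a list of class \code{nevo_cell}.
#' @export
melanocyte <- function(id, position, radius = 5, generation = 0L,
                       strain = NA_integer_, strain_generation = 0L,
                       p0 = 0.05, nested = FALSE) {
  stopifnot(radius > 0, p0 >= 0, generation >= 0)
  if (nested && is.na(strain)) stop("nested cells must carry a strain id")
  structure(list(id = as.integer(id), position = as.numeric(position),
                 radius = radius, generation = as.integer(generation),
                 strain = strain,
                 strain_generation = as.integer(strain_generation),
                 p0 = p0, nested = isTRUE(nested)),
            class = "nevo_cell")
}

#' Density weighting function
#'
#' Quadratically decaying weight on the surface-gap distance between two
#' cells: maximum 0.02 at zero gap, vanishing at 100 micrometres.  Negative
#' gaps (overlapping cells) evaluate at zero distance.
#'
#' @param d gap distance(s) in micrometres (3D distance minus both radii).
#' @return dimensionless weights.
#' @export
weight <- function(d) {
  d <- pmax(d, 0)
  ifelse(d >= 100, 0, 0.02 * (1 - d / 100)^2)
}

#' Local melanocyte density
#'
#' Distance-weighted neighborhood measure: the sum of [weight()] over the
#' gap distances to all other cells, clamped to \code{[0, 1]} so it reads as
#' the ratio between the local cell count and the theoretical maximum.
#'
#' @param cell a [melanocyte()] (or list with \code{position}, \code{radius}).
#' @param population data frame with columns \code{x,y,z,radius} (may include
#'   the cell itself; any row at identical position with identical radius and
#'   matching id is excluded via the \code{id} column when present).
#' @param self_id id to exclude (defaults to \code{cell$id}).
#' @return density in \code{[0, 1]}.
#' @export
local_density <- function(cell, population, self_id = cell$id) {
  if (nrow(population) == 0) return(0)
  keep <- if (!is.null(population$id) && !is.null(self_id))
    population$id != self_id else rep(TRUE, nrow(population))
  pop <- population[keep, , drop = FALSE]
  if (nrow(pop) == 0) return(0)
  d <- sqrt((pop$x - cell$position[1])^2 + (pop$y - cell$position[2])^2 +
            (pop$z - cell$position[3])^2) - pop$radius - cell$radius
  min(1, sum(weight(d)))
}

#' Per-step cell-division probability
#'
#' Exact exponential form \eqn{p(g,\rho) = \exp(A(g) B(\rho) p_0 \Delta t) - 1}
#' derived from the aggregate exponential growth model.
#'
#' @param g generation number.
#' @param rho local density in \code{[0, 1]}.
#' @param p0 base proliferation rate (per day).
#' @param dt time step (days).
#' @param A generation damping curve (a [damping_curve()] or function).
#' @param B density damping curve.
#' @return probability in \code{[0, 1]}.
#' @export
division_probability <- function(g, rho, p0, dt, A, B) {
  stopifnot(dt > 0)
  Af <- if (is.function(A)) A else A$fn
  Bf <- if (is.function(B)) B else B$fn
  p <- exp(Af(g) * Bf(rho) * p0 * dt) - 1
  if (any(p > 1)) stop("division probability exceeds 1; p0 * dt too large")
  p
}

#' Symmetric cell division with inheritance
#'
#' Both filial cells carry the parent's generation number plus one.  Size,
#' location and base proliferation rate are inherited with additive Gaussian
#' noise (clamped at zero).  Strain membership is inherited; a default-type
#' parent differentiates into a newly founded nest strain with conditional
#' probability \code{q0}, in which case both daughters become nested with
#' the elevated nest proliferation rate.
#'
#' @param parent a [melanocyte()].
#' @param q0 conditional differentiation probability per division.
#' @param p0_nest base proliferation rate assigned to a newly founded strain.
#' @param sigma_p0 inheritance noise on \code{p0}.
#' @param sigma_radius inheritance noise on the radius.
#' @param offset displacement of each daughter from the parent position
#'   (micrometres); the two daughters are placed symmetrically.
#' @param new_ids integer ids for the daughters.
#' @param new_strain strain id to assign if differentiation occurs.
#' @return list of two \code{nevo_cell} daughters; attribute
#'   \code{"differentiated"} reports whether a new strain was founded.
#' @export
divide <- function(parent, q0 = 0, p0_nest = 0.1, sigma_p0 = 0.01,
                   sigma_radius = 0, offset = 0.5 * parent$radius,
                   new_ids = c(parent$id + 1L, parent$id + 2L),
                   new_strain = NA_integer_) {
  g <- parent$generation + 1L
  differentiated <- FALSE
  strain <- parent$strain
  sgen <- parent$strain_generation
  nested <- parent$nested
  base_p0 <- parent$p0
  if (!parent$nested && q0 > 0 && runif(1) < q0) {
    differentiated <- TRUE
    nested <- TRUE
    strain <- if (is.na(new_strain)) parent$id else new_strain
    sgen <- 1L
    base_p0 <- p0_nest
  } else if (parent$nested) {
    sgen <- parent$strain_generation + 1L
  }
  a <- runif(1, 0, 2 * pi); cz <- runif(1, -1, 1)
  sz <- sqrt(1 - cz^2)
  dir <- c(sz * cos(a), sz * sin(a), cz)
  mk <- function(id, sgn) {
    melanocyte(id, parent$position + sgn * offset * dir,
               radius = max(0.5, parent$radius + rnorm(1, 0, sigma_radius)),
               generation = g, strain = strain, strain_generation = sgen,
               p0 = max(0, base_p0 + rnorm(1, 0, sigma_p0)), nested = nested)
  }
  out <- list(mk(new_ids[1], +1), mk(new_ids[2], -1))
  attr(out, "differentiated") <- differentiated
  out
}

#' Draw an emigration event for a nested cell
#'
#' A nested cell detaches from its strain with per-step probability
#' \eqn{1 - \exp(-s(\gamma)\,\Delta t)} where \eqn{s} is the within-strain
#' generation dependent emigration rate (base rate 0.1 per day).  On
#' emigration the cell returns to the behavior of the default population.
#'
#' @param cell a nested [melanocyte()].
#' @param s_curve emigration-rate curve over the within-strain generation
#'   (a [damping_curve()] with \code{name = "s"}, or a function, in d^-1).
#' @param dt time step (days).
#' @return logical: whether the cell emigrates this step.
#' @export
emigration_event <- function(cell, s_curve, dt) {
  if (!isTRUE(cell$nested)) stop("emigration_event called on a non-nested cell")
  sf <- if (is.function(s_curve)) s_curve else s_curve$fn
  rate <- sf(cell$strain_generation)
  runif(1) < 1 - exp(-rate * dt)
}
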