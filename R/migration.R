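# Per-step velocity composition, collision correction and position update.
# Reference single-cell implementations of the movement pipeline; the C++
# engine vectorizes the same rules over the whole population.

#' Movement configuration
#'
#' @param D base diffusivity (um^2/d, in [0, 60]).
#' @param v_ext external-force magnitude (downward; interpreted as um/d).
#' @param tip_alt altitude (um) at which the downward force reaches full
#'   intensity (linear ramp from zero at the base plane).
#' @param K collision correction fraction in (0, 1].
#' @param v_derm dermal exclusion magnitudes \code{c(vertical, horizontal)}
#'   in um/d.
#' @param F_a,F_r force curves ([force_curve()]) or \code{NULL} (absent,
#'   the default case).
#' @param Q,R_gen,G_a,G_r,H_a,H_r damping curves or \code{NULL} (constant 1).
#' @return an object of class \code{nevo_movement_config}.
#' @export
movement_config <- function(D = 10, v_ext = 0, tip_alt = 100, K = 1,
                            v_derm = c(5, 5), F_a = NULL, F_r = NULL,
                            Q = NULL, R_gen = NULL, G_a = NULL, G_r = NULL,
                            H_a = NULL, H_r = NULL) {
  stopifnot(D >= 0, D <= 60, K > 0, K <= 1)
  structure(list(D = D, v_ext = v_ext, tip_alt = tip_alt, K = K,
                 v_derm = v_derm, F_a = F_a, F_r = F_r, Q = Q, R_gen = R_gen,
                 G_a = G_a, G_r = G_r, H_a = H_a, H_r = H_r),
            class = "nevo_movement_config")
}

.curve_val <- function(curve, x) {
  if (is.null(curve)) return(rep(1, length(x)))
  f <- if (is.function(curve)) curve else curve$fn
  f(x)
}

#' Initial velocity: external force plus diffusive noise
#'
#' \eqn{v^{(i)} = v_{ext} + \sqrt{2 D Q(\rho) R(g)}\,\Delta t^{-1/2} z} with
#' \eqn{z} a standard trivariate normal draw, so displacement variance per
#' unit time is independent of the step size.
#'
#' @param cfg a [movement_config()].
#' @param rho local density.
#' @param g generation number.
#' @param dt time step (days).
#' @param altitude cell altitude (um), for the altitude-scaled downward force.
#' @return 3D velocity vector (um/d).
#' @export
initial_velocity <- function(cfg, rho, g, dt, altitude = 0) {
  stopifnot(dt > 0)
  sig <- sqrt(2 * cfg$D * .curve_val(cfg$Q, rho) * .curve_val(cfg$R_gen, g) / dt)
  v <- sig * rnorm(3)
  if (cfg$v_ext > 0) {
    sc <- if (cfg$tip_alt > 0) min(1, max(0, altitude / cfg$tip_alt)) else 1
    v[3] <- v[3] - cfg$v_ext * sc
  }
  v
}

#' Neighbor interaction table
#'
#' @param unit matrix of unit vectors pointing from the cell to each
#'   neighbor (rows).
#' @param gap gap distances (3D distance minus both radii, micrometres).
#' @param same_strain logical: neighbor belongs to the same nest strain.
#' @param involves_nested logical: the pair involves at least one nested cell.
#' @return a data-frame-like neighbor table for the movement operators.
#' @export
neighbor_table <- function(unit, gap, same_strain = FALSE,
                           involves_nested = FALSE) {
  unit <- .as_point_matrix(unit, 3)
  n <- nrow(unit)
  list(unit = unit, gap = rep_len(gap, n),
       same_strain = rep_len(same_strain, n),
       involves_nested = rep_len(involves_nested, n))
}

#' Add pairwise intercellular forces
#'
#' Attraction applies only within a strain, repulsion only across strains
#' (pairs involving a nested cell); the default scenario with absent forces
#' leaves the velocity unchanged.
#'
#' @param v_i initial velocity (3-vector).
#' @param nbrs a [neighbor_table()].
#' @param cfg a [movement_config()].
#' @param rho local density.
#' @param g generation number.
#' @return modulated velocity \eqn{v^{(ii)}}.
#' @export
add_pair_forces <- function(v_i, nbrs, cfg, rho, g = 0) {
  if (is.null(cfg$F_a) && is.null(cfg$F_r)) return(v_i)
  v <- v_i
  for (k in seq_along(nbrs$gap)) {
    gp <- max(nbrs$gap[k], 0)
    f <- 0
    if (!is.null(cfg$F_a) && nbrs$same_strain[k])
      f <- f + cfg$F_a$fn(gp) * .curve_val(cfg$G_a, rho) * .curve_val(cfg$H_a, g)
    if (!is.null(cfg$F_r) && !nbrs$same_strain[k] && nbrs$involves_nested[k])
      f <- f - cfg$F_r$fn(gp) * .curve_val(cfg$G_r, rho) * .curve_val(cfg$H_r, g)
    v <- v + f * nbrs$unit[k, ]
  }
  v
}

#' Collision corrector
#'
#' For every neighbor whose gap would not absorb the projected advance
#' (\eqn{d_n < (\hat u_n \cdot v)\,\Delta t}), a fraction \code{K} of the
#' excess projected component is subtracted.  Neighbors are processed in
#' deterministic order of ascending gap, and the pass is repeated until no
#' neighbor triggers (bounded number of passes), so conflicting constraints
#' cannot leak overlap through a single sweep; the mechanism minimizes
#' overlap, it is not a physical collision.
#'
#' @param v_ii velocity after force modulation.
#' @param nbrs a [neighbor_table()].
#' @param K correction fraction in (0, 1].
#' @param dt time step (days).
#' @return corrected velocity \eqn{v^{(iii)}}.
#' @export
collision_correct <- function(v_ii, nbrs, K, dt) {
  v <- v_ii
  ord <- order(nbrs$gap)
  for (pass in 1:20) {
    changed <- FALSE
    for (k in ord) {
      u <- nbrs$unit[k, ]
      proj <- sum(u * v)
      if (nbrs$gap[k] < proj * dt - 1e-12) {
        v <- v - u * (proj * dt - nbrs$gap[k]) * K / dt
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  v
}

#' Constrained movement step along the membrane
#'
#' Projects the velocity into the tangent plane, pushes it forward to chart
#' coordinates, advances along the geodesic and maps back to the surface.
#'
#' @param membrane a [membrane_model()].
#' @param cell list with \code{position} (3D, on the surface) and optionally
#'   cached chart coordinates \code{chart}.
#' @param v_iii 3D velocity (um/d).
#' @param dt time step (days).
#' @param mode tangent handling, \code{"project"} or \code{"rotate"}.
#' @return list with \code{position} (3D), \code{chart} (2D) and
#'   \code{exited} (logical domain-exit signal).
#' @export
move_constrained <- function(membrane, cell, v_iii, dt,
                             mode = c("project", "rotate")) {
  mode <- match.arg(mode)
  u <- if (!is.null(cell$chart)) as.numeric(cell$chart)
       else chart_forward(membrane, cell$position)[1, ]
  vt <- project_to_tangent(membrane, cell$position, v_iii, mode)
  vbar <- pushforward(membrane, cell$position, vt)
  st <- geodesic_step(membrane, u, vbar, dt)
  if (st$exited)
    return(list(position = NULL, chart = st$u, exited = TRUE))
  list(position = chart_inverse(membrane, st$u)[1, ], chart = st$u,
       exited = FALSE)
}

#' Unconstrained movement step for nested cells
#'
#' Plain Euler step \eqn{x + \Delta t\,(v^{(iii)} + v_{derm})}; the dermal
#' exclusion velocity is zero in the epidermal compartment, vertical
#' (upward) below the base plane and horizontal (away from the papilla
#' axis) inside a papilla body.
#'
#' @param cell list with \code{position}.
#' @param v_iii 3D velocity.
#' @param membrane a [membrane_model()].
#' @param cfg a [movement_config()] (supplies \code{v_derm}).
#' @param dt time step (days).
#' @return new 3D position.
#' @export
move_nested <- function(cell, v_iii, membrane, cfg, dt) {
  x <- cell$position
  vd <- c(0, 0, 0)
  if (x[3] < 0) {
    vd[3] <- cfg$v_derm[1]
  } else {
    j <- .find_papilla(membrane, x[1:2])
    if (j > 0) {
      p <- membrane$papillae[[j]]
      w <- x[1:2] - p$center
      s <- sqrt(sum(w^2))
      u <- .snap_chart(membrane, x[1:2])
      alt <- chart_inverse(membrane, u)[1, 3]
      if (x[3] < alt) {
        dir <- if (s > 1e-9) w / s else { a <- runif(1, 0, 2 * pi); c(cos(a), sin(a)) }
        vd[1:2] <- cfg$v_derm[2] * dir
      }
    }
  }
  x + dt * (v_iii + vd)
}

# which papilla base disk contains horizontal position xy (0 if none)
.find_papilla <- function(membrane, xy) {
  for (j in seq_along(membrane$papillae)) {
    p <- membrane$papillae[[j]]
    if (sum((xy - p$center)^2) < p$R^2) return(j)
  }
  0L
}

# chart coordinates of the surface point directly above/below xy
.snap_chart <- function(membrane, xy) {
  j <- .find_papilla(membrane, xy)
  if (j == 0L) return(as.numeric(xy))
  p <- membrane$papillae[[j]]
  w <- xy - p$center
  s <- sqrt(sum(w^2))
  if (s < 1e-12) return(p$center)
  th <- uniroot(function(t) .eval_bs(p$knots, p$r_coeffs, t) - s,
                lower = 0, upper = p$R, tol = 1e-10)$root
  p$center + th * w / s
}
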