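# The basal membrane as a composite manifold: a planar base plane (altitude
# zero at the rete-ridge base), disjoint papilla charts, and an optional
# coarse vertical deformation field chi built from radially symmetric bumps.
#
# Chart convention: one global 2D coordinate frame u = (u1, u2) over the
# domain rectangle.  Outside papilla base disks, u is the horizontal position
# itself.  Inside the disk of papilla i, u encodes the virtual radius:
# the surface point at u is  c_i + r(|u - c_i|) * unit(u - c_i)  at altitude
# h(|u - c_i|).  The shape-curve endpoint conditions make the induced metric
# C^2 across disk rims and at papilla apices, so a single geodesic ODE
# integrates everywhere without chart hand-off.

#' Create a papilla chart
#'
#' @param center 2D horizontal location of the papilla axis (micrometres).
#' @param shape a [build_shape_curve()] object.
#' @return an object of class \code{nevo_papilla}.
#' @export
papilla_chart <- function(center, shape) {
  stopifnot(length(center) == 2, inherits(shape, "nevo_shape_curve"))
  structure(list(center = as.numeric(center), shape = shape),
            class = "nevo_papilla")
}

# unit bump profile reused for the deformation field chi: the h-component
# model with R = H = 1 (flat to third order at both ends)
.unit_profile_pp <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_shape_curve(1, 1, 0)$h_pp
    cache
  }
})

#' Assemble a membrane model
#'
#' @param extent domain rectangle as \code{c(Lx, Ly)} in micrometres; the
#'   domain is \code{[0, Lx] x [0, Ly]}.
#' @param papillae list of [papilla_chart()] objects with pairwise disjoint
#'   base disks lying inside the domain.
#' @param deformation optional list of coarse elevation/depression records,
#'   each \code{list(center=, radius=, amplitude=)}; amplitude is a signed
#'   altitude in micrometres, the vertical profile reuses the h-component
#'   model.
#' @return an object of class \code{nevo_membrane}.
#' @export
membrane_model <- function(extent, papillae = list(), deformation = list()) {
  extent <- as.numeric(extent)
  stopifnot(length(extent) == 2, all(extent > 0))
  pap <- lapply(papillae, function(p) {
    stopifnot(inherits(p, "nevo_papilla"))
    s <- p$shape
    if (p$center[1] - s$R < 0 || p$center[1] + s$R > extent[1] ||
        p$center[2] - s$R < 0 || p$center[2] + s$R > extent[2])
      stop("papilla base disk outside the simulation domain")
    list(center = p$center, R = s$R, H = s$H, p = s$p,
         degree = s$degree, knots = s$knots,
         r_coeffs = s$r_coeffs, h_coeffs = s$h_coeffs,
         r_pp = s$r_pp, h_pp = s$h_pp)
  })
  if (length(pap) > 1) {
    ctr <- t(vapply(pap, `[[`, numeric(2), "center"))
    rr <- vapply(pap, `[[`, 0, "R")
    dd <- as.matrix(dist(ctr))
    lim <- outer(rr, rr, `+`)
    diag(dd) <- Inf
    if (any(dd < lim - 1e-6))      # open disks: touching bases are disjoint
      stop("papilla base disks are not pairwise disjoint")
  }
  mem <- list(extent = extent, papillae = pap, deformation = deformation)
  if (length(deformation)) mem$profile_pp <- .unit_profile_pp()
  structure(mem, class = "nevo_membrane")
}

#' @export
print.nevo_membrane <- function(x, ...) {
  cat(sprintf("membrane: %.0f x %.0f um, %d papillae, %d deformation bumps\n",
              x$extent[1], x$extent[2], length(x$papillae),
              length(x$deformation)))
  invisible(x)
}

.as_point_matrix <- function(x, d) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == d)
    x
  } else {
    stopifnot(length(x) == d)
    matrix(x, 1)
  }
}

#' Surface point of a papilla chart
#'
#' Maps local polar coordinates (angle, virtual radius) of one papilla chart
#' to the 3D surface point \eqn{(x_i + r(\theta)\cos\alpha,
#' x_i + r(\theta)\sin\alpha, h(\theta))}.
#'
#' @param chart a [papilla_chart()].
#' @param alpha angle in \code{[0, 2*pi)}.
#' @param theta virtual radius in \code{[0, R]} (micrometres).
#' @return 3D point (micrometres).
#' @export
surface_point <- function(chart, alpha, theta) {
  stopifnot(inherits(chart, "nevo_papilla"))
  s <- chart$shape
  if (any(theta < 0 | theta > s$R)) stop("theta outside [0, R]")
  r <- eval_shape(s, theta, "r")
  h <- eval_shape(s, theta, "h")
  cbind(chart$center[1] + r * cos(alpha),
        chart$center[2] + r * sin(alpha),
        h)
}

#' Forward chart map: surface point to chart coordinates
#'
#' @param membrane a [membrane_model()].
#' @param x 3D surface point (or matrix of points, one per row).
#' @param tol altitude tolerance (micrometres) beyond which a point is
#'   rejected as off-manifold.
#' @return matrix of 2D chart coordinates.
#' @export
chart_forward <- function(membrane, x, tol = 1e-3) {
  x <- .as_point_matrix(x, 3)
  res <- .cpp_chart_forward(membrane, x, tol)
  if (any(res$off_manifold == 1L))
    stop("point does not lie on the membrane surface (within tolerance)")
  res$u
}

#' Inverse chart map: chart coordinates to surface point
#'
#' @param membrane a [membrane_model()].
#' @param u 2D chart coordinates (or matrix, one per row).
#' @return matrix of 3D surface points.
#' @export
chart_inverse <- function(membrane, u) {
  u <- .as_point_matrix(u, 2)
  ext <- membrane$extent
  if (any(u[, 1] < 0 | u[, 1] > ext[1] | u[, 2] < 0 | u[, 2] > ext[2]))
    stop("chart coordinates outside the domain extent")
  .cpp_surface_points(membrane, u)
}

#' Induced metric tensor at chart coordinates
#'
#' First fundamental form of the membrane surface pulled back to the chart;
#' symmetric positive definite, and the identity on the flat planar part.
#'
#' @param membrane a [membrane_model()].
#' @param u 2D chart coordinates.
#' @return 2x2 symmetric matrix.
#' @export
metric_tensor <- function(membrane, u) {
  u <- as.numeric(u)
  ext <- membrane$extent
  if (u[1] < 0 || u[1] > ext[1] || u[2] < 0 || u[2] > ext[2])
    stop("chart coordinates outside the domain extent")
  g <- .cpp_metric(membrane, u[1], u[2])
  matrix(c(g[1], g[2], g[2], g[3]), 2, 2)
}

# 3x2 Jacobian of the embedding at chart coordinates u
.surface_jacobian <- function(membrane, u) {
  .cpp_jacobian(membrane, u[1], u[2])
}

.surface_normal <- function(membrane, u) {
  J <- .surface_jacobian(membrane, u)
  n <- c(J[2, 1] * J[3, 2] - J[3, 1] * J[2, 2],
         J[3, 1] * J[1, 2] - J[1, 1] * J[3, 2],
         J[1, 1] * J[2, 2] - J[2, 1] * J[1, 2])
  n / sqrt(sum(n^2))
}

#' Project (or rotate) a 3D vector into the tangent plane
#'
#' @param membrane a [membrane_model()].
#' @param x 3D surface point.
#' @param v 3D vector.
#' @param mode \code{"project"} (orthogonal projection, default) or
#'   \code{"rotate"} (norm-preserving).
#' @return 3D tangent vector at \code{x}.
#' @export
project_to_tangent <- function(membrane, x, v, mode = c("project", "rotate")) {
  mode <- match.arg(mode)
  u <- chart_forward(membrane, x)[1, ]
  n <- .surface_normal(membrane, u)
  vt <- v - sum(v * n) * n
  if (mode == "rotate") {
    tn <- sqrt(sum(vt^2))
    if (tn > 1e-12) vt <- vt * sqrt(sum(v^2)) / tn
  }
  vt
}

#' Pushforward of a tangent vector to chart coordinates
#'
#' The differential of the chart map applied to a tangent vector at a surface
#' point: the unique 2D chart velocity whose embedded image is the given
#' tangent vector.
#'
#' @param membrane a [membrane_model()].
#' @param x 3D surface point.
#' @param v_tan tangent 3-vector at \code{x}.
#' @param tol relative tolerance on the normal component of \code{v_tan}.
#' @return 2D chart vector.
#' @export
pushforward <- function(membrane, x, v_tan, tol = 1e-6) {
  u <- chart_forward(membrane, x)[1, ]
  J <- .surface_jacobian(membrane, u)
  n <- .surface_normal(membrane, u)
  vn <- sqrt(sum(v_tan^2))
  if (vn > 0 && abs(sum(v_tan * n)) > max(tol * vn, 1e-12))
    stop("input vector is not tangent to the membrane at x")
  g <- crossprod(J)
  as.numeric(solve(g, crossprod(J, v_tan)))
}

#' Advance chart coordinates along a geodesic
#'
#' Integrates the geodesic equation of the chart metric with initial
#' conditions \code{(u, v)} over \code{[0, dt]} (classic Runge-Kutta with
#' substeps bounded so each substep's displacement is at most
#' \code{max_disp}).  The surface arc length traveled equals the metric norm
#' of \code{v} times \code{dt}.
#'
#' @param membrane a [membrane_model()].
#' @param u 2D chart coordinates.
#' @param v 2D chart velocity (micrometres per day).
#' @param dt time increment in days.
#' @param max_disp maximum chart displacement per internal substep
#'   (micrometres).
#' @return list with elements \code{u} (endpoint), \code{v} (transported
#'   velocity) and \code{exited} (\code{TRUE} if the path left the domain,
#'   in which case the caller discards the cell).
#' @export
geodesic_step <- function(membrane, u, v, dt, max_disp = 1) {
  stopifnot(dt > 0, all(is.finite(v)))
  .cpp_geodesic_step(membrane, as.numeric(u), as.numeric(v), dt, max_disp)
}

#' Serialize a membrane to JSON
#'
#' Stores extent, per-papilla \code{(x_i, R_i, H_i, p_i)} tuples, spline
#' coefficients and deformation records; [read_membrane()] reconstructs the
#' model losslessly.
#'
#' @param membrane a [membrane_model()].
#' @param path output file path.
#' @export
write_membrane <- function(membrane, path) {
  doc <- list(
    extent = membrane$extent,
    papillae = lapply(membrane$papillae, function(p)
      list(center = p$center, R = p$R, H = p$H, p = p$p,
           degree = p$degree, knots = p$knots,
           r_coeffs = p$r_coeffs, h_coeffs = p$h_coeffs)),
    deformation = membrane$deformation
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a membrane from JSON
#'
#' @param path file written by [write_membrane()].
#' @return a \code{nevo_membrane}.
#' @export
read_membrane <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  pap <- lapply(doc$papillae, function(p) {
    curve <- build_shape_curve(p$R, p$H, p$p)
    papilla_chart(p$center, curve)
  })
  def <- lapply(doc$deformation, function(b)
    list(center = as.numeric(b$center), radius = b$radius,
         amplitude = b$amplitude))
  membrane_model(doc$extent, pap, def)
}

#' Export the membrane surface as a Wavefront OBJ mesh
#'
#' Triangulated grid sample of the surface for visual inspection.
#'
#' @param membrane a [membrane_model()].
#' @param path output .obj path.
#' @param pitch grid pitch in micrometres.
#' @export
export_membrane_obj <- function(membrane, path, pitch = 10) {
  ext <- membrane$extent
  xs <- seq(0, ext[1], by = pitch)
  ys <- seq(0, ext[2], by = pitch)
  u <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  p <- chart_inverse(membrane, u)
  nx <- length(xs); ny <- length(ys)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.4f %.4f %.4f", p[, 1], p[, 2], p[, 3]), con)
  idx <- function(i, j) (j - 1L) * nx + i
  faces <- character(0)
  for (j in seq_len(ny - 1)) {
    i <- seq_len(nx - 1)
    faces <- c(faces,
               sprintf("f %d %d %d", idx(i, j), idx(i + 1L, j), idx(i, j + 1L)),
               sprintf("f %d %d %d", idx(i + 1L, j), idx(i + 1L, j + 1L),
                       idx(i, j + 1L)))
  }
  writeLines(faces, con)
  invisible(path)
}
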