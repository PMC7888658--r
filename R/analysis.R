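# Lesion quantification: enclosing/quantile disk areas, growth slopes,
# group comparison, nest statistics, vertical distribution, and the
# deterministic aggregate models (expected population size, expected nest
# size) that serve as independent oracles for the stochastic engine.

.circumcircle <- function(a, b, c) {
  ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-14) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  ctr <- c(ux, uy)
  list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
}

.disk_from <- function(pts, boundary) {
  # smallest disk with the given boundary points (0..3) containing pts,
  # randomized incremental recursion (Welzl)
  nb <- nrow(boundary)
  if (nb == 3L) {
    cc <- .circumcircle(boundary[1, ], boundary[2, ], boundary[3, ])
    if (is.null(cc)) {
      d <- as.matrix(dist(boundary))
      ij <- which(d == max(d), arr.ind = TRUE)[1, ]
      ctr <- (boundary[ij[1], ] + boundary[ij[2], ]) / 2
      cc <- list(center = ctr, radius = max(d) / 2)
    }
    return(cc)
  }
  disk <- switch(nb + 1L,
    list(center = c(0, 0), radius = -1),
    list(center = boundary[1, ], radius = 0),
    list(center = (boundary[1, ] + boundary[2, ]) / 2,
         radius = sqrt(sum((boundary[1, ] - boundary[2, ])^2)) / 2))
  if (nrow(pts) == 0L) return(disk)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (disk$radius >= 0 &&
        sum((p - disk$center)^2) <= disk$radius^2 * (1 + 1e-12)) next
    disk <- .disk_from(pts[seq_len(i - 1L), , drop = FALSE],
                       rbind(boundary, p))
  }
  disk
}

#' Smallest enclosing disk
#'
#' Exact minimal disk containing all points (randomized incremental
#' algorithm on the convex hull, expected linear time).
#'
#' @param points 2D point matrix (one row per point).
#' @return list with \code{center} and \code{radius}.
#' @export
smallest_enclosing_disk <- function(points) {
  points <- .as_point_matrix(points, 2)
  if (nrow(points) == 0L) stop("empty point set")
  if (nrow(points) == 1L)
    return(list(center = points[1, ], radius = 0))
  hull <- grDevices::chull(points)        # disk is determined by hull points
  pts <- points[hull, , drop = FALSE]
  pts <- pts[sample.int(nrow(pts)), , drop = FALSE]
  .disk_from(pts, matrix(0, 0, 2))
}

#' Quantile error disk
#'
#' Disk centred at the centroid whose radius is the empirical q-quantile of
#' the point distances to the centre; the 0.9 quantile disk is a robust
#' approximation of the visually apparent lesion area.
#'
#' @param points 2D point matrix.
#' @param q quantile in (0, 1].
#' @param center \code{"centroid"} (default) or \code{"enclosing"} (centre
#'   of the smallest enclosing disk).
#' @return list with \code{center} and \code{radius}.
#' @export
quantile_disk <- function(points, q = 0.9, center = c("centroid", "enclosing")) {
  points <- .as_point_matrix(points, 2)
  if (nrow(points) == 0L) stop("empty point set")
  center <- match.arg(center)
  ctr <- if (center == "centroid") colMeans(points)
         else smallest_enclosing_disk(points)$center
  d <- sqrt((points[, 1] - ctr[1])^2 + (points[, 2] - ctr[2])^2)
  list(center = ctr, radius = as.numeric(quantile(d, q)))
}

#' Lesion area series of a trajectory
#'
#' Per snapshot, the area (mm^2) of the smallest enclosing disk and of the
#' 0.9 quantile error disk of the horizontal cell positions.
#'
#' @param traj a \code{nevo_trajectory}.
#' @param q quantile for the error disk.
#' @return data frame with columns \code{time}, \code{area_med},
#'   \code{area_q90}, \code{n} (class \code{nevo_area_series}).
#' @export
area_series <- function(traj, q = 0.9) {
  rows <- lapply(seq_along(traj$times), function(i) {
    sn <- traj$snapshots[[i]]
    if (nrow(sn) == 0L) return(NULL)
    pts <- cbind(sn$x, sn$y)
    med <- smallest_enclosing_disk(pts)
    qd <- quantile_disk(pts, q)
    data.frame(time = traj$times[i],
               area_med = pi * med$radius^2 * 1e-6,
               area_q90 = pi * qd$radius^2 * 1e-6,
               n = nrow(sn))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("nevo_area_series", class(out))
  out
}

#' Growth slope by ordinary least squares
#'
#' @param time times in days.
#' @param area areas in mm^2.
#' @return slope in mm^2 per day.
#' @export
growth_slope <- function(time, area) {
  stopifnot(length(time) == length(area), length(time) >= 2)
  if (max(time) - min(time) <= 0) stop("all times identical")
  sum((time - mean(time)) * (area - mean(area))) / sum((time - mean(time))^2)
}

#' Compare growth-slope groups with an unpaired t-test
#'
#' @param slopes_a,slopes_b numeric slope vectors (each of length >= 2).
#' @param pooled use the pooled-variance test (default); \code{FALSE} gives
#'   Welch.
#' @return list with \code{t}, \code{p.value}, \code{df}.
#' @export
compare_slopes <- function(slopes_a, slopes_b, pooled = TRUE) {
  stopifnot(length(slopes_a) >= 2, length(slopes_b) >= 2)
  if (var(slopes_a) + var(slopes_b) <= 0) stop("degenerate variance")
  ht <- t.test(slopes_a, slopes_b, var.equal = pooled)
  list(t = unname(ht$statistic), p.value = ht$p.value,
       df = unname(ht$parameter))
}

#' Nest statistics over a trajectory
#'
#' Per snapshot: nest count, member counts per nest and mean nest size;
#' plus the time of maximal mean nest size and the mean size at that time.
#'
#' @param traj a \code{nevo_trajectory}.
#' @return list with \code{series} (data frame time, n_nests, mean_size,
#'   nested, total), \code{sizes} (list of per-nest member counts) and
#'   summary fields \code{t_max_mean_size}, \code{max_mean_size}.
#' @export
nest_statistics <- function(traj) {
  series <- lapply(seq_along(traj$times), function(i) {
    sn <- traj$snapshots[[i]]
    nested <- sn[sn$nested, , drop = FALSE]
    sizes <- if (nrow(nested)) table(nested$strain) else integer(0)
    data.frame(time = traj$times[i], n_nests = length(sizes),
               mean_size = if (length(sizes)) mean(sizes) else 0,
               nested = nrow(nested), total = nrow(sn))
  })
  series <- do.call(rbind, series)
  sizes <- lapply(seq_along(traj$times), function(i) {
    sn <- traj$snapshots[[i]]
    nested <- sn[sn$nested, , drop = FALSE]
    if (nrow(nested)) as.integer(table(nested$strain)) else integer(0)
  })
  imax <- which.max(series$mean_size)
  list(series = series, sizes = sizes,
       t_max_mean_size = series$time[imax],
       max_mean_size = series$mean_size[imax])
}

#' Time-averaged vertical distribution of cells
#'
#' @param traj a \code{nevo_trajectory}.
#' @param burn_in days discarded before averaging.
#' @param breaks altitude bin edges (micrometres).
#' @return normalized histogram (named vector of bin masses summing to 1).
#' @export
vertical_distribution <- function(traj, burn_in = 0,
                                  breaks = seq(0, 250, by = 10)) {
  keep <- which(traj$times >= burn_in)
  z <- unlist(lapply(keep, function(i) traj$snapshots[[i]]$z))
  z <- pmin(pmax(z, min(breaks)), max(breaks) - 1e-9)
  h <- tabulate(findInterval(z, breaks), nbins = length(breaks) - 1L)
  names(h) <- sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1])
  h / sum(h)
}

#' Expected population size (deterministic aggregate model)
#'
#' Generation-resolved difference-equation model for the expected melanocyte
#' count without spatial interaction: per step, generation g loses its
#' dividing mass at rate \eqn{p(g) = \exp(A(g) p_0 \Delta t) - 1} and
#' generation g+1 gains twice that mass.
#'
#' @param p0 base proliferation rate (d^-1).
#' @param A generation damping curve (or function; constant 1 by default).
#' @param dt step (days).
#' @param horizon span (days).
#' @param M0 initial population in generation 0.
#' @param gmax maximum generation tracked.
#' @return data frame with \code{time} and \code{expected} total count.
#' @export
expected_population <- function(p0, A = NULL, dt = 1, horizon = 100, M0 = 10,
                                gmax = 60) {
  Af <- if (is.null(A)) function(g) rep(1, length(g))
        else if (is.function(A)) A else A$fn
  g <- 0:gmax
  pg <- exp(Af(g) * p0 * dt) - 1
  m <- c(M0, rep(0, gmax))
  nt <- ceiling(horizon / dt)
  total <- numeric(nt + 1)
  total[1] <- sum(m)
  for (k in seq_len(nt)) {
    div <- pg * m
    m <- m - div
    m[-1] <- m[-1] + 2 * div[-length(div)]
    total[k + 1] <- sum(m)
  }
  data.frame(time = (0:nt) * dt, expected = total)
}

#' Expected nest size (deterministic aggregate model)
#'
#' Within-strain-generation-resolved recursion for the expected member count
#' of a single nest founded by one differentiated cell: generation gamma
#' gains twice the dividing mass of gamma-1 (division rate damped by the
#' within-strain senescence curve) and loses emigrating mass at rate
#' \eqn{1 - \exp(-s(\gamma)\Delta t)}.
#'
#' @param p0_nest nest proliferation rate (d^-1).
#' @param s_curve emigration-rate curve over within-strain generation.
#' @param A_nest within-strain-generation damping of nest proliferation.
#' @param dt step (days).
#' @param horizon span (days).
#' @param gmax_nest maximum within-strain generation tracked.
#' @return data frame with \code{time}, \code{expected} nest size, plus the
#'   attribute fields \code{t_max} and \code{size_max} of the maximum.
#' @export
expected_nest_size <- function(p0_nest = 0.1, s_curve = NULL, A_nest = NULL,
                               dt = 1, horizon = 400, gmax_nest = 40) {
  Af <- if (is.null(A_nest)) function(g) rep(1, length(g))
        else if (is.function(A_nest)) A_nest else A_nest$fn
  sf <- if (is.null(s_curve)) function(g) rep(0, length(g))
        else if (is.function(s_curve)) s_curve else s_curve$fn
  g <- 0:gmax_nest
  pg <- exp(Af(g) * p0_nest * dt) - 1
  eg <- 1 - exp(-sf(g) * dt)
  m <- c(1, rep(0, gmax_nest))
  nt <- ceiling(horizon / dt)
  total <- numeric(nt + 1)
  total[1] <- sum(m)
  for (k in seq_len(nt)) {
    div <- pg * m
    m <- m - div
    m[-1] <- m[-1] + 2 * div[-length(div)]
    m <- m * (1 - eg)
    total[k + 1] <- sum(m)
  }
  out <- data.frame(time = (0:nt) * dt, expected = total)
  imax <- which.max(out$expected)
  attr(out, "t_max") <- out$time[imax]
  attr(out, "size_max") <- out$expected[imax]
  out
}
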