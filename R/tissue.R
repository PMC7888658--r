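# Papilla shape statistics and procedural membrane synthesis: fit the
# (R, H, p) shape model to section measurements, fit sampling distributions,
# pack base disks densely and assemble membranes.

#' Correct section measurements for dehydration shrinkage
#'
#' Histopathologic sections shrink during processing; all measured lengths
#' are increased by 20\% exactly once before model fitting.
#'
#' @param lengths non-negative lengths in micrometres.
#' @return corrected lengths (input times 1.2).
#' @export
shrinkage_correct <- function(lengths) {
  if (any(lengths < 0, na.rm = TRUE)) stop("lengths must be non-negative")
  lengths * 1.2
}

#' Fit the shape model to one papilla measurement
#'
#' Given a measurement tuple (height, radius at the base, at half height and
#' at 10 um below the tip), finds the shape-curve parameters: the model
#' height is the measured height, and \code{(R, p)} minimize the squared
#' error between the model-implied radii at the three measured altitudes and
#' the recorded radii.
#'
#' @param H_bar measured height (micrometres).
#' @param r_base radius at altitude 0.
#' @param r_mid radius at altitude 0.5 H.
#' @param r_tip radius at 10 micrometres below the tip.
#' @return list with elements \code{R}, \code{H}, \code{p}, \code{converged}
#'   and the residual sum of squares \code{value}.  Non-convergence is
#'   flagged, not raised.
#' @export
fit_shape <- function(H_bar, r_base, r_mid, r_tip) {
  stopifnot(H_bar > 0, r_base > 0, r_mid > 0, r_tip > 0)
  H <- H_bar
  zs <- c(0, 0.5 * H, max(H - 10, 0.5 * H))
  target <- c(r_base, r_mid, r_tip)
  obj <- function(par) {
    cv <- try(build_shape_curve(par[1], H, par[2]), silent = TRUE)
    if (inherits(cv, "try-error")) return(1e8)
    sum((shape_radius_at_height(cv, zs) - target)^2)
  }
  fit <- try(optim(c(r_base, 0), obj, method = "L-BFGS-B",
                   lower = c(max(1, 0.25 * r_base), -1),
                   upper = c(4 * r_base + 50, 1)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(R = NA_real_, H = H, p = NA_real_, converged = FALSE,
                value = NA_real_))
  }
  list(R = fit$par[1], H = H, p = fit$par[2],
       converged = fit$convergence == 0, value = fit$value)
}

.fit_lognormal <- function(x, name) {
  if (sd(x) < 1e-12 * max(abs(x), 1))
    stop(sprintf("degenerate (constant) sample for variable '%s'", name))
  lx <- log(x)
  list(family = "lognormal", meanlog = mean(lx),
       sdlog = sqrt(mean((lx - mean(lx))^2)))
}

.fit_beta <- function(x, interval, name) {
  y <- (x - interval[1]) / diff(interval)
  if (sd(y) < 1e-12) stop(sprintf("degenerate (constant) sample for variable '%s'", name))
  y <- pmin(pmax(y, 1e-6), 1 - 1e-6)
  m <- mean(y); v <- var(y)
  k <- max(m * (1 - m) / v - 1, 0.1)          # method-of-moments start
  nll <- function(par) -sum(stats::dbeta(y, exp(par[1]), exp(par[2]), log = TRUE))
  fit <- optim(log(c(m * k, (1 - m) * k)), nll)
  list(family = "beta", shape1 = exp(fit$par[1]), shape2 = exp(fit$par[2]),
       interval = interval)
}

#' Fit sampling distributions to a shape-parameter ensemble
#'
#' Base radius and height are fitted with log-normal distributions, the
#' bounded shape parameter with a beta distribution scaled to its admissible
#' interval; statistical correlations are deliberately ignored.
#'
#' @param ensemble data frame with columns \code{R}, \code{H}, \code{p}
#'   (one fitted papilla per row; at least 10 rows).
#' @param density_target papillae per square millimetre aimed for when
#'   packing (within \code{[50, 160]}).
#' @param shoulder_weight mixture weight for the deliberate
#'   over-representation of the shouldered type when sampling \code{p}.
#' @return an object of class \code{nevo_papilla_stats}.
#' @export
fit_distributions <- function(ensemble, density_target = 80,
                              shoulder_weight = 0.5) {
  stopifnot(is.data.frame(ensemble), nrow(ensemble) >= 10)
  stopifnot(density_target >= 50, density_target <= 160)
  structure(list(
    R = .fit_lognormal(ensemble$R, "R"),
    H = .fit_lognormal(ensemble$H, "H"),
    p = .fit_beta(ensemble$p, c(-1, 1), "p"),
    density_target = density_target,
    shoulder_weight = shoulder_weight
  ), class = "nevo_papilla_stats")
}

.lnorm_par <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Built-in papilla statistics presets
#'
#' \code{"large"} corresponds to in-vivo-realistic papillae (base radius
#' centred in 56--75 um, height in 70--135 um); \code{"standard"} to the
#' histology-derived scale (shrinkage-corrected measurements without the
#' factor-two in-vivo inflation).
#'
#' @param size \code{"large"} or \code{"standard"}.
#' @return a \code{nevo_papilla_stats}.
#' @export
papilla_statistics_preset <- function(size = c("large", "standard")) {
  size <- match.arg(size)
  if (size == "large") {
    Rp <- .lnorm_par(65, 9.5); Hp <- .lnorm_par(100, 17); dens <- 60
  } else {
    Rp <- .lnorm_par(34, 10); Hp <- .lnorm_par(72, 18); dens <- 130
  }
  structure(list(
    R = c(list(family = "lognormal"), Rp),
    H = c(list(family = "lognormal"), Hp),
    p = list(family = "beta", shape1 = 2, shape2 = 2, interval = c(-1, 1)),
    density_target = dens,
    shoulder_weight = 0.6
  ), class = "nevo_papilla_stats")
}

#' Sample papilla shape parameters
#'
#' Draws independent \code{(R, H, p)} tuples from the fitted distributions.
#' The shouldered type is over-represented: with probability
#' \code{shoulder_weight} the shape parameter is drawn from a beta
#' distribution skewed towards the shouldered end of the interval.
#'
#' @param stats a \code{nevo_papilla_stats}.
#' @param n number of papillae.
#' @return data frame with columns \code{R}, \code{H}, \code{p}.
#' @export
sample_papillae <- function(stats, n) {
  stopifnot(inherits(stats, "nevo_papilla_stats"), n >= 1)
  R <- rlnorm(n, stats$R$meanlog, stats$R$sdlog)
  H <- rlnorm(n, stats$H$meanlog, stats$H$sdlog)
  iv <- stats$p$interval
  shoulder <- runif(n) < stats$shoulder_weight
  y <- ifelse(shoulder, rbeta(n, 6, 2), rbeta(n, stats$p$shape1, stats$p$shape2))
  p <- iv[1] + diff(iv) * y
  data.frame(R = R, H = H, p = p)
}

#' Pack papilla base disks into the domain
#'
#' Disks are seeded on a hexagonal lattice and their centres iteratively
#' relaxed to resolve overlaps (annealed local moves); disks that cannot be
#' placed without overlap are dropped.  The achieved density is reported.
#'
#' @param extent domain rectangle \code{c(Lx, Ly)} in micrometres.
#' @param radii disk radii in micrometres.
#' @param pitch lattice pitch in micrometres; defaults to twice the largest
#'   radius (guaranteed-disjoint seeding for uniform radii).
#' @param max_rounds relaxation rounds.
#' @return list with \code{centers} (matrix, placed disks), \code{radii},
#'   \code{placed} (indices into the input), and \code{density} in disks per
#'   square millimetre.
#' @export
pack_papillae <- function(extent, radii, pitch = NULL, max_rounds = 500) {
  stopifnot(all(radii > 0))
  extent <- as.numeric(extent)
  area <- prod(extent)
  if (sum(pi * radii^2) > area)
    stop("packing error: total disk area exceeds the domain area")
  if (is.null(pitch)) pitch <- 2 * max(radii)
  # hexagonal seeding
  dy <- pitch * sqrt(3) / 2
  ys <- seq(pitch / 2, extent[2] - pitch / 2, by = dy)
  sites <- do.call(rbind, lapply(seq_along(ys), function(k) {
    offs <- if (k %% 2 == 0) pitch / 2 else 0
    xs <- seq(pitch / 2 + offs, extent[1] - pitch / 2, by = pitch)
    cbind(xs, ys[k])
  }))
  n <- min(nrow(sites), length(radii))
  ord <- sample.int(length(radii))[seq_len(n)]
  r <- radii[ord]
  ctr <- sites[sample.int(nrow(sites), n), , drop = FALSE]
  # iterative local optimization: push overlapping pairs apart (with a small
  # separation margin so the final layout is strictly disjoint)
  margin <- 0.5
  for (round in seq_len(max_rounds)) {
    d <- as.matrix(dist(ctr))
    lim0 <- outer(r, r, `+`)
    lim <- lim0 + margin
    diag(d) <- Inf
    ov <- which(d < lim0 - 1e-9, arr.ind = TRUE)   # genuine overlaps only
    ov <- ov[ov[, 1] < ov[, 2], , drop = FALSE]
    if (nrow(ov) == 0) break
    step <- if (round < 0.8 * max_rounds) 0.8 else 0.4
    for (k in seq_len(nrow(ov))) {
      i <- ov[k, 1]; j <- ov[k, 2]
      dir <- ctr[j, ] - ctr[i, ]
      dd <- sqrt(sum(dir^2))
      if (dd < 1e-9) { a <- runif(1, 0, 2 * pi); dir <- c(cos(a), sin(a)); dd <- 1 }
      push <- step * (lim[i, j] - dd) / 2
      ctr[i, ] <- ctr[i, ] - push * dir / dd
      ctr[j, ] <- ctr[j, ] + push * dir / dd
    }
    ctr[, 1] <- pmin(pmax(ctr[, 1], r), extent[1] - r)
    ctr[, 2] <- pmin(pmax(ctr[, 2], r), extent[2] - r)
  }
  # drop disks that still overlap (worst offenders first)
  keep <- rep(TRUE, n)
  repeat {
    d <- as.matrix(dist(ctr[keep, , drop = FALSE]))
    lim <- outer(r[keep], r[keep], `+`)
    diag(d) <- Inf
    pen <- rowSums(pmax(lim - d - 1e-9, 0))
    if (all(pen <= 0)) break
    worst <- which(keep)[which.max(pen)]
    keep[worst] <- FALSE
  }
  list(centers = ctr[keep, , drop = FALSE], radii = r[keep],
       placed = ord[keep],
       density = sum(keep) / (area * 1e-6))
}

#' Generate a random membrane
#'
#' Composes papilla sampling, dense packing, shape-curve construction and
#' optional coarse-deformation sampling into a reproducible membrane model.
#'
#' @param extent domain rectangle \code{c(Lx, Ly)} in micrometres.
#' @param stats a \code{nevo_papilla_stats} (or preset name,
#'   \code{"large"}/\code{"standard"}).
#' @param n_bumps number of coarse elevation/depression records.
#' @param bump_amplitude range of signed bump amplitudes (micrometres).
#' @param bump_radius range of bump radii (micrometres).
#' @param seed optional integer seed for full reproducibility.
#' @return a \code{nevo_membrane}.
#' @export
generate_membrane <- function(extent, stats = "large", n_bumps = 0,
                              bump_amplitude = c(-15, 15),
                              bump_radius = c(300, 600), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(stats)) stats <- papilla_statistics_preset(stats)
  extent <- as.numeric(extent)
  area_mm2 <- prod(extent) * 1e-6
  # hexagonal pitch realizing the density target, bounded below by disk sizes
  pitch <- sqrt(2 / (sqrt(3) * stats$density_target * 1e-6))
  n_sites <- prod(extent) / (pitch^2 * sqrt(3) / 2)
  n_ask <- ceiling(n_sites * 1.05) + 2
  shapes <- sample_papillae(stats, n_ask)
  pk <- pack_papillae(extent, shapes$R, pitch = pitch)
  pap <- lapply(seq_along(pk$placed), function(k) {
    i <- pk$placed[k]
    papilla_chart(pk$centers[k, ],
                  build_shape_curve(shapes$R[i], shapes$H[i], shapes$p[i]))
  })
  def <- list()
  if (n_bumps > 0) {
    def <- lapply(seq_len(n_bumps), function(i)
      list(center = c(runif(1, 0, extent[1]), runif(1, 0, extent[2])),
           radius = runif(1, bump_radius[1], bump_radius[2]),
           amplitude = runif(1, bump_amplitude[1], bump_amplitude[2])))
  }
  membrane_model(extent, pap, def)
}
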