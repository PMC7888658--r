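# Simulation orchestration: configuration, initialization, stepping,
# trajectories and snapshot I/O.  A state is a list of per-cell vectors in
# the layout shared with the C++ engine.

#' Simulation configuration
#'
#' Collects every parameter of the agent model.  Defaults correspond to the
#' basic reticular configuration: base proliferation rate 0.05 per day,
#' differentiation off, absent intercellular forces.
#'
#' @param dt time step in days (typical value 1).
#' @param horizon simulated time span in days.
#' @param extent domain rectangle \code{c(Lx, Ly)} (micrometres).
#' @param membrane a [membrane_model()], or \code{NULL} to generate one from
#'   \code{membrane_stats} when the run starts.
#' @param membrane_stats papilla statistics preset name or object used when
#'   generating a membrane.
#' @param n_initial initial melanocyte count (about 10, placed centrally).
#' @param init_spread radius (um) of the central placement disk.
#' @param cell_radius default melanocyte radius (um).
#' @param p0 base proliferation rate (d^-1).
#' @param p0_nest nest proliferation rate (d^-1).
#' @param q0 conditional differentiation probability per division.
#' @param sigma_p0,sigma_radius inheritance noise standard deviations.
#' @param A,B generation / density damping curves for default cells.
#' @param A_nest within-strain-generation damping for nested proliferation.
#' @param B_nest density damping for nested proliferation (constant 1 by
#'   default: nest growth is limited by strain senescence, not by packing).
#' @param s_curve emigration rate over within-strain generation (d^-1).
#' @param movement a [movement_config()].
#' @param emitted_proliferate whether emigrated cells keep proliferating at
#'   the default rate (\code{FALSE} reproduces the isolated single-nest
#'   experiments, where emitted cells do not proliferate).
#' @param snapshot_interval days between recorded snapshots.
#' @param seed master seed (integer) for reproducibility.
#' @param max_substep geodesic substep bound (um).
#' @return an object of class \code{nevo_config}.
#' @export
simulation_config <- function(dt = 1, horizon = 100, extent = c(1000, 1000),
                              membrane = NULL, membrane_stats = "large",
                              n_initial = 10, init_spread = 50,
                              cell_radius = 5,
                              p0 = 0.05, p0_nest = 0.1, q0 = 0,
                              sigma_p0 = 0.01, sigma_radius = 0,
                              A = NULL, B = NULL, A_nest = NULL,
                              B_nest = NULL, s_curve = NULL,
                              movement = movement_config(),
                              emitted_proliferate = TRUE,
                              snapshot_interval = 10, seed = 1L,
                              max_substep = 1) {
  stopifnot(dt > 0, horizon >= dt, n_initial >= 0)
  structure(list(
    dt = dt, horizon = horizon, extent = as.numeric(extent),
    membrane = membrane, membrane_stats = membrane_stats,
    n_initial = n_initial, init_spread = init_spread,
    cell_radius = cell_radius,
    p0 = p0, p0_nest = p0_nest, q0 = q0,
    sigma_p0 = sigma_p0, sigma_radius = sigma_radius,
    A = A, B = B, A_nest = A_nest, B_nest = B_nest, s_curve = s_curve,
    movement = movement, emitted_proliferate = emitted_proliferate,
    snapshot_interval = snapshot_interval, seed = as.integer(seed),
    max_substep = max_substep
  ), class = "nevo_config")
}

# engine parameter list (tabulated curves) for the C++ step kernel
.engine_params <- function(config) {
  mv <- config$movement
  tab_g <- function(curve) if (is.null(curve)) rep(1, 61) else .tabulate(curve, 60, 61L)
  tab_rho <- function(curve) if (is.null(curve)) rep(1, 101) else .tabulate(curve, 1, 101L)
  gmax_nest <- 41L
  anest <- if (is.null(config$A_nest)) rep(1, gmax_nest)
           else .tabulate(config$A_nest, gmax_nest - 1L, gmax_nest)
  stab <- if (is.null(config$s_curve)) rep(0, gmax_nest)
          else .tabulate(config$s_curve, gmax_nest - 1L, gmax_nest)
  fa_cut <- if (is.null(mv$F_a)) 0 else mv$F_a$cutoff
  fr_cut <- if (is.null(mv$F_r)) 0 else mv$F_r$cutoff
  list(
    dt = config$dt, D = mv$D, K = mv$K, q0 = config$q0,
    p0_nest = config$p0_nest, p0_default = config$p0,
    sigma_p0 = config$sigma_p0, sigma_radius = config$sigma_radius,
    vext_mag = mv$v_ext, tip_alt = mv$tip_alt,
    vderm_vert = mv$v_derm[1], vderm_horiz = mv$v_derm[2],
    offset_frac = 0.5, max_substep = config$max_substep, chart_tol = 1e-3,
    emitted_proliferate = as.integer(isTRUE(config$emitted_proliferate)),
    tangent_rotate = 0L,
    A_tab = tab_g(config$A), B_tab = tab_rho(config$B),
    Q_tab = tab_rho(mv$Q), Rgen_tab = tab_g(mv$R_gen),
    Ga_tab = tab_rho(mv$G_a), Gr_tab = tab_rho(mv$G_r),
    Ha_tab = tab_g(mv$H_a), Hr_tab = tab_g(mv$H_r),
    Anest_tab = anest, Bnest_tab = tab_rho(config$B_nest),
    s_tab = stab,
    fa_cutoff = fa_cut, fr_cutoff = fr_cut,
    Fa_tab = if (fa_cut > 0) .tabulate(mv$F_a, fa_cut, 121L) else rep(0, 2),
    Fr_tab = if (fr_cut > 0) .tabulate(mv$F_r, fr_cut, 121L) else rep(0, 2)
  )
}

#' Initialize a simulation state
#'
#' Places the initial melanocytes on the membrane surface near the domain
#' centre (non-overlapping rejection sampling within \code{init_spread}),
#' all generation 0, default type.
#'
#' @param config a [simulation_config()].
#' @param membrane a [membrane_model()] (required; generate beforehand or
#'   via [run_simulation()]).
#' @param nested_founder if \code{TRUE}, a single nested founder cell
#'   (strain 1, within-strain generation 0) is placed instead of the default
#'   group -- the single-nest experiment setup.
#' @return a state object of class \code{nevo_state}.
#' @export
initialize_state <- function(config, membrane, nested_founder = FALSE) {
  n0 <- if (nested_founder) 1L else as.integer(config$n_initial)
  ctr <- membrane$extent / 2
  u <- matrix(0, 0, 2)
  tries <- 0
  while (nrow(u) < n0 && tries < 5000) {
    tries <- tries + 1
    a <- runif(1, 0, 2 * pi); r <- config$init_spread * sqrt(runif(1))
    cand <- ctr + r * c(cos(a), sin(a))
    if (nrow(u) == 0 ||
        min(sqrt(rowSums(sweep(u, 2, cand)^2))) >= 1.0 * config$cell_radius)
      u <- rbind(u, cand)
  }
  if (nrow(u) < n0) stop("initial placement infeasible")
  pos <- if (n0 > 0) chart_inverse(membrane, u) else matrix(0, 0, 3)
  state <- list(
    id = seq_len(n0), x = pos[, 1], y = pos[, 2], z = pos[, 3],
    u1 = u[, 1], u2 = u[, 2],
    radius = rep(config$cell_radius, n0),
    generation = rep(0L, n0),
    strain = rep(if (nested_founder) 1L else 0L, n0),
    strain_generation = rep(0L, n0),
    nested = rep(nested_founder, n0),
    p0 = rep(if (nested_founder) config$p0_nest else config$p0, n0),
    next_id = n0 + 1L, next_strain = if (nested_founder) 2L else 1L,
    time = 0
  )
  class(state) <- "nevo_state"
  state
}

#' Advance the simulation by one time step
#'
#' Executes the per-step scheme: density update, movement of all cells,
#' divisions and differentiation, emigrations, discard of domain exits.
#'
#' @param state a \code{nevo_state}.
#' @param membrane a [membrane_model()].
#' @param config a [simulation_config()] (or a prebuilt engine parameter
#'   list).
#' @return updated state; attribute \code{"events"} carries the step's event
#'   counts.
#' @export
sim_step <- function(state, membrane, config) {
  params <- if (inherits(config, "nevo_config")) .engine_params(config) else config
  res <- .cpp_sim_step(state, membrane, params)
  out <- res$state
  out$time <- state$time + params$dt
  class(out) <- "nevo_state"
  attr(out, "events") <- res$events
  out
}

#' Snapshot data frame of a state
#'
#' @param state a \code{nevo_state}.
#' @return data frame, one row per cell (id, position, radius, generation,
#'   strain, strain_generation, nested, p0).
#' @export
snapshot_df <- function(state) {
  data.frame(id = state$id, x = state$x, y = state$y, z = state$z,
             radius = state$radius, generation = state$generation,
             strain = state$strain,
             strain_generation = state$strain_generation,
             nested = state$nested, p0 = state$p0)
}

#' Run a simulation
#'
#' Wraps initialization and stepping; snapshots are recorded at the
#' configured interval together with a structured event log.
#'
#' @param config a [simulation_config()].
#' @param membrane optional [membrane_model()]; generated from
#'   \code{config$membrane_stats} when absent.
#' @param nested_founder start from a single nested founder (single-nest
#'   experiment) instead of the default central group.
#' @param progress print progress every ~100 steps.
#' @return an object of class \code{nevo_trajectory}: list with
#'   \code{times}, \code{snapshots} (data frames), \code{counts} (per-step
#'   population bookkeeping), \code{strain_founders}, \code{membrane},
#'   \code{config}.
#' @export
run_simulation <- function(config, membrane = NULL, nested_founder = FALSE,
                           progress = FALSE) {
  set.seed(config$seed)
  if (is.null(membrane)) membrane <- config$membrane
  if (is.null(membrane))
    membrane <- generate_membrane(config$extent, config$membrane_stats)
  state <- initialize_state(config, membrane, nested_founder)
  params <- .engine_params(config)
  nsteps <- ceiling(config$horizon / config$dt)
  every <- max(1L, round(config$snapshot_interval / config$dt))
  times <- 0
  snaps <- list(snapshot_df(state))
  counts <- data.frame(time = 0, n = length(state$id), births = 0L,
                       exits = 0L, differentiations = 0L, emigrations = 0L)
  founders <- data.frame(strain = integer(0), founder = integer(0),
                         time = numeric(0))
  for (k in seq_len(nsteps)) {
    state <- sim_step(state, membrane, params)
    state$time <- k * config$dt
    ev <- attr(state, "events")
    if (length(ev$new_strains))
      founders <- rbind(founders,
                        data.frame(strain = ev$new_strains,
                                   founder = ev$new_strain_founders,
                                   time = state$time))
    counts <- rbind(counts,
                    data.frame(time = state$time, n = length(state$id),
                               births = ev$divisions, exits = ev$exits,
                               differentiations = ev$differentiations,
                               emigrations = ev$emigrations))
    if (k %% every == 0L || k == nsteps) {
      times <- c(times, state$time)
      snaps[[length(snaps) + 1L]] <- snapshot_df(state)
    }
    if (progress && k %% 100L == 0L)
      message(sprintf("t = %.1f d, %d cells", state$time, length(state$id)))
  }
  structure(list(times = times, snapshots = snaps, counts = counts,
                 strain_founders = founders, membrane = membrane,
                 config = config),
            class = "nevo_trajectory")
}

#' @export
print.nevo_trajectory <- function(x, ...) {
  n_end <- nrow(x$snapshots[[length(x$snapshots)]])
  cat(sprintf("trajectory: %d snapshots over %.0f d, final population %d\n",
              length(x$times), max(x$times), n_end))
  invisible(x)
}

#' Write a trajectory as a directory of CSV snapshots plus a manifest
#'
#' @param traj a \code{nevo_trajectory}.
#' @param dir output directory (created).
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("snapshot_%05d.csv", seq_along(traj$times))
  for (i in seq_along(traj$times))
    utils::write.csv(traj$snapshots[[i]], file.path(dir, files[i]),
                     row.names = FALSE)
  manifest <- data.frame(time = traj$times, file = files)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param dir directory containing \code{manifest.csv} and snapshots.
#' @return a \code{nevo_trajectory} (without membrane/config).
#' @export
read_trajectory <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  snaps <- lapply(manifest$file, function(f)
    utils::read.csv(file.path(dir, f)))
  structure(list(times = manifest$time, snapshots = snaps,
                 counts = NULL, strain_founders = NULL,
                 membrane = NULL, config = NULL),
            class = "nevo_trajectory")
}
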