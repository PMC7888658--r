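# Scenario preset library.  Four reticular parameterizations (diffusive
# single cells only) and four globular parameterizations (nest-forming
# differentiation enabled).  Exact control points of the damping and
# emigration curves are package calibration: they are chosen so the presets
# reproduce the published qualitative shapes (proliferation and motility
# decline with generation and density; emigration either declines with
# within-strain generation, letting nests persist, or stays level /
# increases, dissolving them) and the published aggregate outcomes.

.preset_A <- function(arrest = 45) {
  damping_curve("A", c(0, arrest, 60), c(1, 1, 0))
}

.preset_B <- function(floor = 0) {
  # contact inhibition; in globular scenarios it bottoms out at a small
  # nonzero level so nests do not completely freeze the single-cell front
  y <- pmax(c(1, 0.95, 0.5, 0.1, 0), floor)
  damping_curve("B", c(0, 0.4, 0.7, 0.9, 1), y)
}

.preset_Q <- function() {
  damping_curve("Q", c(0, 0.5, 0.8, 1), c(1, 0.9, 0.3, 0.02))
}

.preset_Rgen <- function() {
  damping_curve("R_gen", c(0, 30, 60), c(1, 0.85, 0.3))
}

# within-strain senescence: full proliferation below the cap, none above
.preset_Anest <- function(cap) {
  damping_curve("A_nest", c(0, cap - 1, cap, 40), c(1, 1, 0, 0))
}

# emigration-rate curves (d^-1) over within-strain generation, evaluated at
# the integer generations 0..40
.preset_s <- function(type, ...) {
  g <- 0:40
  y <- switch(type,
    declining_fast = pmax(0.1 * exp(-g / 0.8), 0.008),
    declining      = pmax(0.1 * exp(-g / 0.6), 0.009),
    level          = rep(0.011, length(g)),
    increasing     = 0.004 + 0.0012 * g)
  damping_curve("s", g, y)
}

#' Scenario presets
#'
#' Named parameterizations \code{"reticular-1"} .. \code{"reticular-4"} and
#' \code{"globular-1"} .. \code{"globular-4"}.  Reticular scenarios differ
#' in diffusivity, growth arrest and downward force (scenarios 2--4 add the
#' downward force; 2 and 4 use the large-papilla tissue preset).  Globular
#' scenarios share the reticular base behavior and differ in within-strain
#' senescence and emigration: 1 and 2 let nests persist (emigration declines
#' with within-strain generation), 3 and 4 dissolve them (emigration level
#' or increasing).
#'
#' @param name preset name.
#' @param extent domain rectangle (micrometres).
#' @param horizon simulated days (defaults: 2000 reticular, 1000 globular).
#' @param dt step in days.
#' @param seed master seed.
#' @return a [simulation_config()].
#' @export
scenario_preset <- function(name, extent = c(5000, 5000), horizon = NULL,
                            dt = 1, seed = 1L) {
  spec <- switch(name,
    "reticular-1" = list(D = 2.5, v_ext = 0,   arrest = 35, stats = "standard"),
    "reticular-2" = list(D = 3,   v_ext = 0.5, arrest = 45, stats = "large"),
    "reticular-3" = list(D = 3.5, v_ext = 0.5, arrest = 35, stats = "standard"),
    "reticular-4" = list(D = 2,   v_ext = 0.5, arrest = 45, stats = "large"),
    "globular-1" = list(D = 30, v_ext = 0.5, arrest = 45, stats = "large",
                        cap = 10, s = "declining_fast"),
    "globular-2" = list(D = 30, v_ext = 0.5, arrest = 45, stats = "standard",
                        cap = 10, s = "declining"),
    "globular-3" = list(D = 30, v_ext = 0.5, arrest = 45, stats = "large",
                        cap = 10, s = "level"),
    "globular-4" = list(D = 30, v_ext = 0.5, arrest = 45, stats = "standard",
                        cap = 10, s = "increasing"),
    stop("unknown scenario preset: ", name)
  )
  globular <- !is.null(spec$cap)
  if (is.null(horizon)) horizon <- if (globular) 1000 else 2000
  mv <- movement_config(
    D = spec$D, v_ext = spec$v_ext, tip_alt = 100, K = 1,
    v_derm = c(5, 5),
    F_a = if (globular) force_curve("F_a", 12, 0.1) else NULL,
    F_r = if (globular) force_curve("F_r", 20, 0.3) else NULL,
    Q = .preset_Q(), R_gen = .preset_Rgen()
  )
  simulation_config(
    dt = dt, horizon = horizon, extent = extent,
    membrane_stats = spec$stats,
    n_initial = 10, p0 = 0.05, p0_nest = 0.1,
    q0 = if (globular) 0.1 else 0,
    sigma_p0 = 0.01,
    A = .preset_A(spec$arrest), B = .preset_B(),
    A_nest = if (globular) .preset_Anest(spec$cap) else NULL,
    B_nest = NULL,
    s_curve = if (globular) .preset_s(spec$s) else NULL,
    movement = mv, seed = seed
  )
}

#' Available scenario preset names
#' @return character vector of preset names.
#' @export
scenario_names <- function() {
  c(paste0("reticular-", 1:4), paste0("globular-", 1:4))
}

#' Write a simulation configuration to a JSON file
#'
#' Damping and force curves are stored as named control-point lists.
#'
#' @param config a [simulation_config()].
#' @param path output path.
#' @export
write_config <- function(config, path) {
  enc_curve <- function(cv) {
    if (is.null(cv)) return(NULL)
    list(name = cv$name, x = cv$x, y = cv$y)
  }
  enc_force <- function(fc) {
    if (is.null(fc)) return(NULL)
    list(name = fc$name, cutoff = fc$cutoff, magnitude = fc$magnitude,
         shape = fc$shape)
  }
  mv <- config$movement
  doc <- list(
    dt = config$dt, horizon = config$horizon, extent = config$extent,
    membrane_stats = if (is.character(config$membrane_stats))
      config$membrane_stats else "custom",
    n_initial = config$n_initial, init_spread = config$init_spread,
    cell_radius = config$cell_radius,
    p0 = config$p0, p0_nest = config$p0_nest, q0 = config$q0,
    sigma_p0 = config$sigma_p0, sigma_radius = config$sigma_radius,
    emitted_proliferate = config$emitted_proliferate,
    snapshot_interval = config$snapshot_interval, seed = config$seed,
    curves = list(A = enc_curve(config$A), B = enc_curve(config$B),
                  A_nest = enc_curve(config$A_nest),
                  B_nest = enc_curve(config$B_nest),
                  s = enc_curve(config$s_curve),
                  Q = enc_curve(mv$Q), R_gen = enc_curve(mv$R_gen),
                  G_a = enc_curve(mv$G_a), G_r = enc_curve(mv$G_r),
                  H_a = enc_curve(mv$H_a), H_r = enc_curve(mv$H_r)),
    forces = list(F_a = enc_force(mv$F_a), F_r = enc_force(mv$F_r)),
    movement = list(D = mv$D, v_ext = mv$v_ext, tip_alt = mv$tip_alt,
                    K = mv$K, v_derm = mv$v_derm)
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a simulation configuration from JSON
#'
#' @param path file written by [write_config()].
#' @return a [simulation_config()].
#' @export
read_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec_curve <- function(cv) {
    if (is.null(cv)) return(NULL)
    damping_curve(cv$name, as.numeric(cv$x), as.numeric(cv$y))
  }
  dec_force <- function(fc) {
    if (is.null(fc)) return(NULL)
    force_curve(fc$name, fc$cutoff, fc$magnitude, fc$shape)
  }
  cvs <- doc$curves
  mv <- movement_config(D = doc$movement$D, v_ext = doc$movement$v_ext,
                        tip_alt = doc$movement$tip_alt, K = doc$movement$K,
                        v_derm = as.numeric(doc$movement$v_derm),
                        F_a = dec_force(doc$forces$F_a),
                        F_r = dec_force(doc$forces$F_r),
                        Q = dec_curve(cvs$Q), R_gen = dec_curve(cvs$R_gen),
                        G_a = dec_curve(cvs$G_a), G_r = dec_curve(cvs$G_r),
                        H_a = dec_curve(cvs$H_a), H_r = dec_curve(cvs$H_r))
  simulation_config(
    dt = doc$dt, horizon = doc$horizon, extent = as.numeric(doc$extent),
    membrane_stats = doc$membrane_stats,
    n_initial = doc$n_initial, init_spread = doc$init_spread,
    cell_radius = doc$cell_radius,
    p0 = doc$p0, p0_nest = doc$p0_nest, q0 = doc$q0,
    sigma_p0 = doc$sigma_p0, sigma_radius = doc$sigma_radius,
    A = dec_curve(cvs$A), B = dec_curve(cvs$B),
    A_nest = dec_curve(cvs$A_nest), B_nest = dec_curve(cvs$B_nest),
    s_curve = dec_curve(cvs$s),
    movement = mv, emitted_proliferate = doc$emitted_proliferate,
    snapshot_interval = doc$snapshot_interval, seed = doc$seed
  )
}
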