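# simulation engine: initialization, stepping semantics, reproducibility,
# conservation bookkeeping

test_that("initialization places the default central group", {
  m <- flat_membrane()
  cfg <- simulation_config(extent = c(500, 500), n_initial = 10)
  set.seed(51)
  st <- initialize_state(cfg, m)
  expect_equal(length(st$id), 10)
  expect_true(all(st$generation == 0L))
  expect_false(any(st$nested))
  # within the central placement disk
  expect_true(all(sqrt((st$x - 250)^2 + (st$y - 250)^2) <= 50 + 1e-9))
  # empty initialization is a valid degenerate state
  cfg0 <- simulation_config(extent = c(500, 500), n_initial = 0, horizon = 10)
  st0 <- initialize_state(cfg0, m)
  expect_equal(length(st0$id), 0)
})

test_that("identity dynamics leave the state unchanged except time", {
  m <- flat_membrane()
  cfg <- simulation_config(extent = c(500, 500), p0 = 0,
                           movement = movement_config(D = 0, v_ext = 0))
  set.seed(52)
  st <- initialize_state(cfg, m)
  st2 <- sim_step(st, m, cfg)
  expect_equal(st2$x, st$x)
  expect_equal(st2$y, st$y)
  expect_equal(st2$generation, st$generation)
  expect_equal(st2$time, st$time + 1)
})

test_that("division frequency matches the exponential form", {
  # isolated cells, A = B = 1, p0 = 0.05, dt = 1: empirical frequency over
  # 1e5 trials within 3 sigma of exp(0.05) - 1
  m <- flat_membrane(c(100000, 200))
  n <- 100000L
  st <- list(id = seq_len(n), x = seq_len(n) - 0.5, y = rep(100, n),
             z = rep(0, n), u1 = seq_len(n) - 0.5, u2 = rep(100, n),
             radius = rep(0.0001, n), generation = rep(0L, n),
             strain = rep(0L, n), strain_generation = rep(0L, n),
             nested = rep(FALSE, n), p0 = rep(0.05, n),
             next_id = n + 1L, next_strain = 1L, time = 0)
  class(st) <- "nevo_state"
  cfg <- simulation_config(dt = 1, horizon = 1, extent = c(100000, 200),
                           p0 = 0.05, sigma_p0 = 0,
                           movement = movement_config(D = 0, v_ext = 0))
  set.seed(53)
  st2 <- sim_step(st, m, cfg)
  births <- attr(st2, "events")$divisions
  p_true <- exp(0.05) - 1
  se <- sqrt(n * p_true * (1 - p_true))
  expect_lt(abs(births - n * p_true), 3 * se)
})

test_that("runs are reproducible and conserve the population audit", {
  cfg <- scenario_preset("reticular-1", extent = c(600, 600), horizon = 60,
                         seed = 9)
  tr1 <- run_simulation(cfg)
  tr2 <- run_simulation(cfg)
  expect_identical(tr1$snapshots, tr2$snapshots)
  # conservation: count = initial + cumulative births - cumulative exits
  cnt <- tr1$counts
  expect_equal(cnt$n,
               cnt$n[1] + cumsum(cnt$births) - cumsum(cnt$exits))
  # generations never decrease along the trajectory (population minimum)
  gmin <- vapply(tr1$snapshots, function(s)
    if (nrow(s)) min(s$generation) else 0L, 0L)
  expect_true(all(diff(gmin) >= 0))
})

test_that("globular runs found nests with single-cell founder genealogy", {
  cfg <- scenario_preset("globular-1", extent = c(800, 800), horizon = 120,
                         seed = 10)
  tr <- run_simulation(cfg)
  expect_gt(nrow(tr$strain_founders), 0)
  # strain ids are unique founding events
  expect_false(any(duplicated(tr$strain_founders$strain)))
  last <- tr$snapshots[[length(tr$snapshots)]]
  nested <- last[last$nested, ]
  expect_true(all(nested$strain %in% tr$strain_founders$strain))
  # nest registry partitions the population
  expect_equal(nrow(nested) + sum(!last$nested), nrow(last))
})

test_that("snapshot CSV trajectories round-trip", {
  cfg <- scenario_preset("reticular-1", extent = c(500, 500), horizon = 30,
                         seed = 12)
  tr <- run_simulation(cfg)
  dir <- tempfile()
  write_trajectory(tr, dir)
  tr2 <- read_trajectory(dir)
  expect_equal(tr2$times, tr$times)
  expect_equal(tr2$snapshots[[length(tr2$snapshots)]]$x,
               tr$snapshots[[length(tr$snapshots)]]$x, tolerance = 1e-12)
})

test_that("config files round-trip through JSON", {
  cfg <- scenario_preset("globular-2", extent = c(900, 900), horizon = 50,
                         seed = 4)
  path <- tempfile(fileext = ".json")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$p0, cfg$p0)
  expect_equal(cfg2$q0, cfg$q0)
  expect_equal(eval_curve(cfg2$s_curve, 0:20), eval_curve(cfg$s_curve, 0:20),
               tolerance = 1e-12)
  expect_equal(cfg2$movement$F_r$cutoff, cfg$movement$F_r$cutoff)
  # identical runs from the reloaded config
  tr1 <- run_simulation(cfg)
  tr2 <- run_simulation(cfg2)
  expect_identical(tr1$counts$n, tr2$counts$n)
})
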