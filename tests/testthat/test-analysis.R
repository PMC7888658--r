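# lesion quantification and the deterministic aggregate oracles

test_that("smallest enclosing disk is exact", {
  expect_error(smallest_enclosing_disk(matrix(0, 0, 2)), "empty")
  d1 <- smallest_enclosing_disk(matrix(c(3, 4), 1))
  expect_equal(d1$radius, 0)
  d2 <- smallest_enclosing_disk(rbind(c(0, 0), c(2, 0)))
  expect_equal(d2$radius, 1)
  expect_equal(d2$center, c(1, 0))
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  d3 <- smallest_enclosing_disk(tri)
  expect_equal(d3$radius, 1 / sqrt(3), tolerance = 1e-9)
  # brute-force oracle on random sets: best disk over all pairs and triples
  brute <- function(pts) {
    best <- Inf
    n <- nrow(pts)
    contains <- function(c0, r0) all(sqrt((pts[, 1] - c0[1])^2 +
                                          (pts[, 2] - c0[2])^2) <= r0 + 1e-9)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      c0 <- (pts[i, ] + pts[j, ]) / 2
      r0 <- sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2
      if (contains(c0, r0)) best <- min(best, r0)
    }
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      cc <- nevosim:::.circumcircle(pts[i, ], pts[j, ], pts[k, ])
      if (!is.null(cc) && contains(cc$center, cc$radius))
        best <- min(best, cc$radius)
    }
    best
  }
  set.seed(61)
  for (rep in 1:10) {
    pts <- matrix(rnorm(24), ncol = 2)
    expect_equal(smallest_enclosing_disk(pts)$radius, brute(pts),
                 tolerance = 1e-9)
  }
})

test_that("quantile disk is centred at the centroid with quantile radius", {
  same <- matrix(rep(c(2, 3), 10), ncol = 2, byrow = TRUE)
  expect_equal(quantile_disk(same)$radius, 0)
  th <- seq(0, 2 * pi, length.out = 11)[-11]
  circ <- cbind(cos(th), sin(th))
  qd <- quantile_disk(circ, 0.9)
  expect_equal(qd$center, c(0, 0), tolerance = 1e-12)
  expect_equal(qd$radius, 1, tolerance = 1e-9)
  set.seed(62)
  pts <- matrix(rnorm(100), ncol = 2)
  expect_lte(quantile_disk(pts, 0.9)$radius, quantile_disk(pts, 1)$radius)
  expect_equal(quantile_disk(pts, 1)$radius,
               max(sqrt(rowSums(sweep(pts, 2, colMeans(pts))^2))))
})

test_that("growth slope equals the closed-form least-squares solution", {
  t <- c(0, 10, 20, 35, 50)
  expect_equal(growth_slope(t, 2 + 0.003 * t), 0.003, tolerance = 1e-14)
  expect_equal(growth_slope(t, rep(5, 5)), 0)
  set.seed(63)
  y <- rnorm(5)
  oracle <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  expect_equal(growth_slope(t, y), oracle, tolerance = 1e-12)
  expect_error(growth_slope(rep(1, 3), 1:3), "identical")
})

test_that("compare_slopes matches the pooled t-test oracle", {
  a <- c(1.1, 1.3, 0.9, 1.2)
  b <- c(2.0, 2.4, 1.8, 2.2)
  res <- compare_slopes(a, b)
  # closed-form pooled t
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  # identical groups: t = 0, p = 1
  res0 <- compare_slopes(a, a)
  expect_equal(res0$t, 0)
  expect_equal(res0$p.value, 1)
  # scale invariance
  res2 <- compare_slopes(10 * a, 10 * b)
  expect_equal(res2$t, res$t, tolerance = 1e-10)
})

test_that("area series converts disk radii to mm^2", {
  # fabricate a trajectory: all cells inside a 564.19 um-radius circle
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  snap <- data.frame(x = 1000 + 564.19 * cos(th), y = 1000 + 564.19 * sin(th))
  traj <- structure(list(times = 0, snapshots = list(snap)),
                    class = "nevo_trajectory")
  as <- area_series(traj)
  expect_equal(as$area_med, 1.0, tolerance = 1e-3)   # pi r^2 = 1 mm^2
  expect_lte(as$area_q90, as$area_med)
  # single-cell snapshot gives zero areas
  traj1 <- structure(list(times = 0,
                          snapshots = list(data.frame(x = 1, y = 2))),
                     class = "nevo_trajectory")
  as1 <- area_series(traj1)
  expect_equal(as1$area_med, 0)
})

test_that("expected population follows the exponential law and the engine", {
  ep0 <- expected_population(0, dt = 1, horizon = 50, M0 = 10)
  expect_true(all(ep0$expected == 10))
  ep <- expected_population(0.05, dt = 0.01, horizon = 100, M0 = 10)
  expect_equal(ep$expected[nrow(ep)], 10 * exp(0.05 * 100), tolerance = 0.01)
})

test_that("expected nest size balances proliferation and emigration", {
  # s == 0: pure generation-limited growth, monotone non-decreasing
  en0 <- expected_nest_size(0.1, s_curve = NULL, horizon = 100)
  expect_true(all(diff(en0$expected) >= -1e-12))
  # constant s equal to the division gain keeps the size near 1
  p_step <- exp(0.1) - 1
  s_bal <- log(1 + p_step)   # (1+p)(1-e) = 1: emigration loss == division gain
  enb <- expected_nest_size(0.1, s_curve = function(g) rep(s_bal, length(g)),
                            horizon = 200)
  expect_equal(enb$expected[101], 1, tolerance = 0.05)
})

test_that("vertical distribution is a normalized histogram", {
  snap <- data.frame(x = 1:5, y = 1:5, z = c(0, 5, 12, 30, 100))
  traj <- structure(list(times = c(0, 10),
                         snapshots = list(snap, snap)),
                    class = "nevo_trajectory")
  h <- vertical_distribution(traj, burn_in = 5)
  expect_equal(sum(h), 1)
  # flat membrane: all mass in the lowest bin
  m <- flat_membrane()
  cfg <- simulation_config(extent = c(500, 500), horizon = 20, p0 = 0,
                           movement = movement_config(D = 5))
  tr <- run_simulation(cfg, membrane = m)
  hf <- vertical_distribution(tr)
  expect_equal(hf[[1]], 1)
})

test_that("growth tables round-trip and slopes are recovered exactly", {
  path <- tempfile(fileext = ".csv")
  synth_growth_table(path, seed = 5)
  tab <- read_growth_table(path)
  expect_equal(length(tab), 38)
  pats <- attr(tab, "patterns")
  expect_equal(sum(pats == "reticular"), 13)
  expect_equal(sum(pats == "globular"), 25)
  slopes <- vapply(tab, function(d) growth_slope(d$time_d, d$area_mm2), 0)
  expect_equal(mean(slopes[pats == "reticular"]), 1.928e-3, tolerance = 1e-9)
  expect_equal(mean(slopes[pats == "globular"]), 6.005e-3, tolerance = 1e-9)
  # write -> read is lossless
  path2 <- tempfile(fileext = ".csv")
  write_growth_table(tab, pats, path2)
  tab2 <- read_growth_table(path2)
  expect_equal(tab2[[1]]$area_mm2, tab[[1]]$area_mm2, tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_growth_table(bad), "time_d")
})

test_that("nest statistics report dissolution and peak size", {
  mk <- function(strains) {
    data.frame(x = seq_along(strains), y = 0, z = 0, radius = 5,
               generation = 1L, strain = strains,
               strain_generation = 1L, nested = strains > 0, p0 = 0.1)
  }
  traj <- structure(list(times = c(0, 10, 20),
                         snapshots = list(mk(c(1, 1, 0)),
                                          mk(c(1, 1, 1, 2, 2, 0)),
                                          mk(c(2, 2, 0)))),
                    class = "nevo_trajectory")
  ns <- nest_statistics(traj)
  expect_equal(ns$series$n_nests, c(1, 2, 1))     # nest 1 dissolved
  expect_equal(ns$series$mean_size, c(2, 2.5, 2))
  expect_equal(ns$t_max_mean_size, 10)
  # partition: nested + singles = total
  expect_equal(ns$series$nested + (ns$series$total - ns$series$nested),
               ns$series$total)
})
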