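# tissue synthesis: shrinkage correction, shape fitting, distribution
# fitting, sampling, packing, membrane generation

test_that("shrinkage correction multiplies lengths by 1.2 exactly once", {
  expect_equal(shrinkage_correct(50), 60)
  expect_equal(shrinkage_correct(0), 0)
  expect_equal(shrinkage_correct(shrinkage_correct(50)), 72)  # not idempotent
  expect_error(shrinkage_correct(c(3, -1)), "non-negative")
})

test_that("fit_shape recovers known parameters within 2%", {
  set.seed(11)
  for (k in 1:8) {
    R0 <- runif(1, 20, 60); H0 <- runif(1, 50, 120); p0 <- runif(1, -0.8, 0.8)
    cv <- build_shape_curve(R0, H0, p0)
    zs <- c(0, 0.5 * H0, H0 - 10)
    rr <- shape_radius_at_height(cv, zs)
    fit <- fit_shape(H0, rr[1], rr[2], rr[3])
    expect_true(fit$converged)
    expect_equal(fit$R, R0, tolerance = 0.02)
    expect_equal(fit$p, p0, tolerance = 0.05)  # |p| <= 1: absolute 2% of range
  }
})

test_that("fit_shape pins the base radius and saturates for cylinders", {
  cv <- build_shape_curve(40, 80, 0.3)
  rr <- shape_radius_at_height(cv, c(0, 40, 70))
  expect_equal(rr[1], 40, tolerance = 1e-6)    # r(R) = R pins the base
  # near-cylindrical measurement drives p to the broad end of its range
  fit <- fit_shape(80, 40, 39, 38)
  expect_gt(fit$p, 0.95)
})

test_that("fit_distributions recovers simulated parameters", {
  set.seed(12)
  n <- 1000
  ens <- data.frame(R = rlnorm(n, log(40), 0.25),
                    H = rlnorm(n, log(80), 0.2),
                    p = 2 * rbeta(n, 3, 2) - 1)
  st <- fit_distributions(ens)
  expect_equal(st$R$meanlog, log(40), tolerance = 0.05)
  expect_equal(st$R$sdlog, 0.25, tolerance = 0.05)
  expect_equal(st$H$meanlog, log(80), tolerance = 0.05)
  expect_equal(st$p$shape1, 3, tolerance = 0.1 * 3)
  expect_equal(st$p$shape2, 2, tolerance = 0.1 * 2)
  ens$R <- 40
  expect_error(fit_distributions(ens), "'R'")
})

test_that("sampled papillae match the in-vivo calibration ranges", {
  set.seed(13)
  st <- papilla_statistics_preset("large")
  sh <- sample_papillae(st, 10000)
  expect_gt(mean(sh$R), 56); expect_lt(mean(sh$R), 75)
  expect_gt(mean(sh$H), 70); expect_lt(mean(sh$H), 135)
  expect_true(all(sh$R > 0 & sh$H > 0))
  expect_true(all(sh$p >= -1 & sh$p <= 1))
  # determinism under a fixed seed
  set.seed(99); a <- sample_papillae(st, 50)
  set.seed(99); b <- sample_papillae(st, 50)
  expect_identical(a, b)
})

test_that("packing produces disjoint disks near the hexagonal bound", {
  set.seed(14)
  pk <- pack_papillae(c(1000, 1000), rep(50, 120))
  # hexagonal-lattice bound 1/(sqrt(3)/2 * (2R)^2) ~ 115 per mm^2
  expect_gt(length(pk$radii), 0.9 * 115 * (1 - 0.11))  # minus boundary effect
  d <- as.matrix(dist(pk$centers)); diag(d) <- Inf
  lim <- outer(pk$radii, pk$radii, `+`)
  expect_true(all(d >= lim - 1e-6))
  expect_true(all(pk$centers[, 1] >= pk$radii - 1e-9 &
                  pk$centers[, 1] <= 1000 - pk$radii + 1e-9))
  expect_error(pack_papillae(c(100, 100), rep(50, 10)), "packing error")
})

test_that("generated membranes land in the in-vivo density window", {
  for (preset in c("large", "standard")) {
    mem <- generate_membrane(c(1000, 1000), preset, seed = 21)
    dens <- length(mem$papillae)
    expect_gte(dens, 50); expect_lte(dens, 160)
  }
  # reproducibility: identical serialized membranes from the same seed
  m1 <- generate_membrane(c(800, 800), "standard", seed = 7)
  m2 <- generate_membrane(c(800, 800), "standard", seed = 7)
  f1 <- tempfile(); f2 <- tempfile()
  write_membrane(m1, f1); write_membrane(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # zero-papillae membrane degenerates to planar kinematics
  m0 <- flat_membrane()
  expect_equal(as.numeric(chart_inverse(m0, c(10, 20))), c(10, 20, 0))
  expect_equal(metric_tensor(m0, c(10, 20)), diag(2))
})

test_that("packing density approaches the hexagonal bound as extent grows", {
  set.seed(15)
  dens <- vapply(c(600, 1600), function(L) {
    n_max <- floor(0.95 * L^2 / (pi * 40^2))
    pk <- pack_papillae(c(L, L), rep(40, n_max))
    length(pk$radii) / (L^2 * 1e-6)
  }, 0)
  bound <- 1 / (sqrt(3) / 2 * 80^2) * 1e6
  expect_gt(dens[2], dens[1])                   # boundary effect shrinks
  expect_gt(dens[2], 0.9 * bound)
})

test_that("measurement tables round-trip and feed the fitting pipeline", {
  path <- tempfile(fileext = ".csv")
  synth_measurement_table(path, seed = 3)
  tab <- read_measurement_table(path)
  expect_equal(nrow(tab$papilla), 100)
  expect_equal(nrow(tab$confocal), 40)
  expect_equal(mean(tab$papilla$H_bar), 59.7, tolerance = 1e-9)
  expect_equal(sd(tab$papilla$H_bar), 18.2, tolerance = 1e-9)
  # malformed layout errors name the missing column
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_measurement_table(bad), "H_bar")
})
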