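# membrane geometry: charts, metric, tangent operations, geodesics

test_that("chart round trip is the identity to 1e-6 um", {
  m <- one_papilla_membrane()
  set.seed(1)
  u <- cbind(runif(1000, 0, 200), runif(1000, 0, 200))
  x <- chart_inverse(m, u)
  expect_lt(max(abs(chart_forward(m, x) - u)), 1e-6)
})

test_that("planar part and apex behave as projections", {
  m <- one_papilla_membrane()
  expect_equal(as.numeric(chart_inverse(m, c(20, 30))), c(20, 30, 0))
  expect_equal(as.numeric(chart_inverse(m, c(100, 100))), c(100, 100, 60))
  expect_equal(as.numeric(chart_forward(m, c(20, 30, 0))), c(20, 30))
  # surface is single-valued: inverse of any chart point is one surface point
  expect_error(chart_forward(m, c(20, 30, 5)), "surface")
  expect_error(chart_inverse(m, c(-5, 30)), "extent")
})

test_that("metric is identity on the flat part and unity meridionally at the rim", {
  m <- one_papilla_membrane()
  expect_equal(metric_tensor(m, c(30, 30)), diag(2), tolerance = 1e-12)
  g <- metric_tensor(m, c(100 + 30 - 1e-9, 100))
  expect_equal(g, diag(2), tolerance = 1e-6)   # forced by r'(R)=1, h'(R)=0
})

test_that("metric agrees with the finite-difference Gram matrix", {
  m <- one_papilla_membrane()
  set.seed(2)
  for (k in 1:20) {
    u0 <- c(100, 100) + runif(2, -28, 28)
    g <- metric_tensor(m, u0)
    eps <- 1e-4
    J1 <- (chart_inverse(m, u0 + c(eps, 0)) - chart_inverse(m, u0 - c(eps, 0))) / (2 * eps)
    J2 <- (chart_inverse(m, u0 + c(0, eps)) - chart_inverse(m, u0 - c(0, eps))) / (2 * eps)
    Jm <- rbind(J1, J2)
    expect_equal(g, Jm %*% t(Jm), tolerance = 1e-4, ignore_attr = TRUE)
    # positive definiteness
    expect_true(all(eigen(g, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("project_to_tangent removes the normal component", {
  m <- one_papilla_membrane()
  # planar region: vertical removed, horizontal kept
  v <- project_to_tangent(m, c(20, 30, 0), c(1, 2, 3))
  expect_equal(v, c(1, 2, 0))
  # on the papilla flank: result orthogonal to normal, norm non-increasing
  set.seed(3)
  for (k in 1:200) {
    u0 <- c(100, 100) + runif(2, -25, 25)
    x <- chart_inverse(m, u0)[1, ]
    w <- rnorm(3)
    vt <- project_to_tangent(m, x, w)
    n <- nevosim:::.surface_normal(m, u0)
    expect_lt(abs(sum(vt * n)), 1e-8)
    expect_lte(sqrt(sum(vt^2)), sqrt(sum(w^2)) + 1e-12)
    # idempotent on tangent vectors
    expect_equal(project_to_tangent(m, x, vt), vt, tolerance = 1e-9)
  }
  # rotation mode preserves the norm
  x <- chart_inverse(m, c(112, 95))[1, ]
  w <- c(1, -2, 0.5)
  vr <- project_to_tangent(m, x, w, mode = "rotate")
  expect_equal(sqrt(sum(vr^2)), sqrt(sum(w^2)), tolerance = 1e-9)
})

test_that("pushforward is linear and consistent with curves through x", {
  m <- one_papilla_membrane()
  u0 <- c(110, 96)
  x <- chart_inverse(m, u0)[1, ]
  vt <- project_to_tangent(m, x, c(2, 1, 0))
  v2 <- pushforward(m, x, vt)
  expect_equal(pushforward(m, x, 3 * vt), 3 * v2, tolerance = 1e-9)
  # finite-difference consistency: psi(gamma(eps)) - psi(gamma(0)) ~ eps*v2
  eps <- 1e-5
  st <- geodesic_step(m, u0, v2, eps, max_disp = 0.01)
  expect_equal((st$u - u0) / eps, v2, tolerance = 1e-3)
  # planar region: horizontal components returned unchanged
  expect_equal(pushforward(m, c(20, 30, 0), c(1, 2, 0)), c(1, 2))
  expect_error(pushforward(m, x, c(0, 0, 1)), "tangent")
})

test_that("geodesics: flat limit, zero velocity, arc-length preservation", {
  m0 <- flat_membrane()
  st <- geodesic_step(m0, c(50, 60), c(3, 4), 2)
  expect_equal(st$u, c(56, 68), tolerance = 1e-12)
  m <- one_papilla_membrane()
  st0 <- geodesic_step(m, c(110, 100), c(0, 0), 1)
  expect_equal(st0$u, c(110, 100))
  set.seed(4)
  for (k in 1:30) {
    u0 <- c(100, 100) + runif(2, -25, 25)
    v0 <- rnorm(2) * 5
    st <- geodesic_step(m, u0, v0, 1)
    if (st$exited) next
    expect_equal(metric_norm(m, st$u, st$v), metric_norm(m, u0, v0),
                 tolerance = 1e-3)
  }
  # domain exit is signalled
  stx <- geodesic_step(m, c(195, 100), c(50, 0), 1)
  expect_true(stx$exited)
})

test_that("on-manifold invariant holds over long geodesic walks", {
  m <- one_papilla_membrane()
  set.seed(5)
  u <- c(95, 100); v <- c(4, 2)
  for (k in 1:1000) {
    st <- geodesic_step(m, u, v, 0.2)
    if (st$exited) { u <- c(100, 100) + runif(2, -20, 20); v <- rnorm(2) * 4; next }
    u <- st$u; v <- st$v
    if (k %% 100 == 0) {
      x <- chart_inverse(m, u)
      expect_lt(max(abs(chart_forward(m, x) - rbind(u))), 1e-6)
    }
  }
  expect_true(TRUE)
})

test_that("geodesics cross the papilla rim with continuous direction", {
  m <- one_papilla_membrane()
  # start on the planar part aiming at the papilla
  u <- c(60, 100); v <- c(5, 0.8)
  prev <- NULL; max_jump <- 0
  for (k in 1:200) {
    st <- geodesic_step(m, u, v, 0.01)
    dir <- atan2(st$u[2] - u[2], st$u[1] - u[1])
    if (!is.null(prev)) max_jump <- max(max_jump, abs(dir - prev))
    prev <- dir; u <- st$u; v <- st$v
  }
  expect_lt(max_jump * 180 / pi, 0.5)
})

test_that("membrane serialization round-trips losslessly", {
  m <- one_papilla_membrane(R = 25, H = 55, p = -0.4)
  path <- tempfile(fileext = ".json")
  write_membrane(m, path)
  m2 <- read_membrane(path)
  expect_equal(m2$extent, m$extent)
  expect_equal(m2$papillae[[1]]$r_coeffs, m$papillae[[1]]$r_coeffs,
               tolerance = 1e-12)
  u <- cbind(runif(50, 0, 200), runif(50, 0, 200))
  expect_equal(chart_inverse(m2, u), chart_inverse(m, u), tolerance = 1e-9)
})

test_that("membrane validation rejects bad layouts", {
  s <- build_shape_curve(30, 60, 0)
  expect_error(membrane_model(c(100, 100),
                              list(papilla_chart(c(20, 50), s))),
               "outside")
  expect_error(membrane_model(c(300, 300),
                              list(papilla_chart(c(100, 100), s),
                                   papilla_chart(c(140, 100), s))),
               "disjoint")
})

test_that("deformation field chi shifts altitudes smoothly", {
  m <- membrane_model(c(1000, 1000),
                      list(papilla_chart(c(300, 300),
                                         build_shape_curve(30, 60, 0))),
                      deformation = list(list(center = c(600, 600),
                                              radius = 300, amplitude = 20)))
  expect_equal(chart_inverse(m, c(600, 600))[3], 20, tolerance = 1e-9)
  expect_equal(chart_inverse(m, c(950, 600))[3], 0, tolerance = 1e-9)
  # round trip still holds under chi
  set.seed(6)
  u <- cbind(runif(200, 0, 1000), runif(200, 0, 1000))
  x <- chart_inverse(m, u)
  expect_lt(max(abs(chart_forward(m, x) - u)), 1e-6)
  # metric consistent with FD Gram matrix where chi is active
  u0 <- c(520, 560)
  g <- metric_tensor(m, u0)
  eps <- 1e-4
  J1 <- (chart_inverse(m, u0 + c(eps, 0)) - chart_inverse(m, u0 - c(eps, 0))) / (2 * eps)
  J2 <- (chart_inverse(m, u0 + c(0, eps)) - chart_inverse(m, u0 - c(0, eps))) / (2 * eps)
  Jm <- rbind(J1, J2)
  expect_equal(g, Jm %*% t(Jm), tolerance = 1e-4, ignore_attr = TRUE)
})
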