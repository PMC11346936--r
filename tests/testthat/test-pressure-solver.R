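fluid4 <- function(mu = 5e-3) fluid_properties(mu = mu)

test_that("the creeping-flow pressure gradient matches analytic solutions", {
  # zero flow -> zero gradient
  z <- analytic_flow("poiseuille", nx = 15, ny = 11, dx = 1, U0 = 0)
  gz <- pressure_gradient(z$field, fluid4())
  expect_equal(max(abs(gz$gx)), 0); expect_equal(max(abs(gz$gy)), 0)

  # rigid translation: lap u = 0
  tr <- analytic_flow("translation", nx = 15, ny = 11, dx = 1, U0 = 300, V0 = -100)
  gt <- pressure_gradient(tr$field, fluid4())
  expect_lt(max(abs(gt$gx)), 1e-12); expect_lt(max(abs(gt$gy)), 1e-12)

  # plane Poiseuille: grad P = (-8 mu U0 / h^2, 0) uniformly
  U0 <- 200; mu <- 5e-3; ny <- 21; dx <- 0.5
  po <- analytic_flow("poiseuille", nx = 41, ny = ny, dx = dx, U0 = U0, mu = mu)
  gp <- pressure_gradient(po$field, fluid4(mu))
  h <- (ny - 1) * dx
  expect_equal(as.vector(gp$gx), rep(-8 * mu * U0 / h^2, 21 * 41),
               tolerance = 1e-9)
  expect_lt(max(abs(gp$gy)), 1e-12)

  expect_error(pressure_gradient(po$field, fluid4(), include_inertia = TRUE),
               "3 phases")
})

test_that("omnidirectional integration is exact for linear pressure fields", {
  d <- c(15, 15, 1)
  gp <- list(gx = array(2, d), gy = array(0, d), dx = 1, dy = 1,
             x = 0:14, y = 0:14, mask = NULL, meta = list())
  pf <- omnidirectional_integrate(gp, reference_node = c(1, 1),
                                  tol = 1e-13, max_iter = 5000)
  expect_equal(pf$P[, , 1], matrix(rep(2 * (0:14), each = 15), 15, 15),
               tolerance = 1e-10)

  gz <- list(gx = array(0, d), gy = array(0, d), dx = 1, dy = 1,
             x = 0:14, y = 0:14, mask = NULL, meta = list())
  pz <- omnidirectional_integrate(gz, reference_node = c(8, 8))
  expect_equal(max(abs(pz$P)), 0)
})

test_that("the Poiseuille pressure drop is recovered within 2%", {
  U0 <- 200; mu <- 5e-3; nx <- 41; ny <- 21; dx <- 0.5
  po <- analytic_flow("poiseuille", nx = nx, ny = ny, dx = dx, U0 = U0, mu = mu)
  gp <- pressure_gradient(po$field, fluid4(mu))
  pf <- omnidirectional_integrate(gp, reference_node = c(11, 1))
  expect_true(all(pf$converged))
  expect_true(all(pf$residual <= 1e-3))
  h <- (ny - 1) * dx; L <- (nx - 1) * dx
  dP <- pf$P[11, 1, 1] - pf$P[11, nx, 1]
  expect_equal(dP, 8 * mu * U0 * L / h^2, tolerance = 0.02)
})

test_that("pressure is linear in viscosity and its HR*mu form invariant", {
  po <- analytic_flow("poiseuille", nx = 25, ny = 15, dx = 1, U0 = 150)
  solve_at <- function(mu) {
    gp <- pressure_gradient(po$field, fluid4(mu))
    omnidirectional_integrate(gp, reference_node = c(8, 1), tol = 1e-6)
  }
  p1 <- solve_at(2e-3); p2 <- solve_at(4e-3)
  expect_equal(p2$P, 2 * p1$P, tolerance = 1e-6)
  n1 <- nondimensionalize(p1, hr = 120, mu = 2e-3)
  n2 <- nondimensionalize(p2, hr = 120, mu = 4e-3)
  rng <- diff(range(n1$P_nd, na.rm = TRUE))
  expect_lt(max(abs(n2$P_nd - n1$P_nd), na.rm = TRUE), 0.01 * rng)

  expect_equal(nondimensionalize(matrix((130 / 60) * 3e-3, 2, 2),
                                 hr = 130, mu = 3e-3),
               matrix(1, 2, 2))
  expect_error(nondimensionalize(p1, hr = 0, mu = 1e-3), "hr")
})

test_that("path families agree on smooth fields (orientation independence)", {
  po <- analytic_flow("poiseuille", nx = 25, ny = 15, dx = 1, U0 = 150)
  gp <- pressure_gradient(po$field, fluid4(5e-3))
  pf <- omnidirectional_integrate(gp, reference_node = c(8, 1), tol = 1e-8,
                                  return_families = TRUE)
  fams <- attr(pf$P, "families")
  expect_length(fams, 8)
  stack <- simplify2array(fams)
  sd_node <- apply(stack, c(1, 2), sd)
  rng <- diff(range(pf$P[, , 1]))
  expect_lt(max(sd_node, na.rm = TRUE), 0.05 * rng)
})

test_that("canal pressure drops respect the probe sign convention", {
  d <- c(11, 21, 3)
  P <- array(0, d)
  for (p in 1:3) P[, , p] <- matrix(rep(seq(10, -10, length.out = 21) * p,
                                        each = 11), 11, 21)
  pf <- structure(list(P = P, mask = matrix(TRUE, 11, 21),
                       x = 0:20, y = 0:10, dx = 1, dy = 1,
                       residual = rep(0, 3), converged = rep(TRUE, 3)),
                  class = "pressure_field")
  reg <- canal_region("AVC", upstream = c(2, 5), downstream = c(18, 5),
                      radius = 0)
  s <- canal_pressure_drop(pf, reg)
  swap <- canal_pressure_drop(pf, canal_region("AVC", c(18, 5), c(2, 5)))
  expect_equal(swap$dP, -s$dP)
  expect_true(all(s$dP > 0)); expect_false(any(s$retrograde))
  expect_true(all(swap$retrograde))

  # uniform pressure: identically zero drop
  pu <- pf; pu$P[] <- 7
  su <- canal_pressure_drop(pu, reg)
  expect_equal(su$dP, rep(0, 3))

  # probe outside the mask: phase marked missing, not interpolated
  pm <- pf; pm$mask[5, 3] <- FALSE
  sm <- canal_pressure_drop(pm, canal_region("AVC", c(2, 4), c(18, 4)))
  expect_true(all(is.na(sm$dP)))
  expect_error(canal_region("AVC", c(1, 1), c(1, 1)), "differ")
})
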