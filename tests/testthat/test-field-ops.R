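test_that("gradients are exact for constant and linear fields", {
  u <- array(7, c(10, 12, 1)); v <- array(-3, c(10, 12, 1))
  f <- velocity_field(u, v, dx = 0.7, dy = 1.3)
  g <- compact_richardson_gradient(f)
  for (comp in list(g$dudx, g$dudy, g$dvdx, g$dvdy))
    expect_equal(max(abs(comp)), 0)

  a <- 4.2
  x <- (0:11) * 0.7
  u2 <- array(matrix(rep(a * x, each = 10), 10, 12), c(10, 12, 1))
  f2 <- velocity_field(u2, v, dx = 0.7, dy = 1.3)
  g2 <- compact_richardson_gradient(f2)
  expect_equal(as.vector(g2$dudx), rep(a, 120), tolerance = 1e-12)
})

test_that("the Richardson-extrapolated stencil is 4th order on sin(kx)", {
  n <- 64; h <- 0.3; k <- 1
  x <- (0:(n - 1)) * h
  M <- matrix(rep(sin(k * x), each = 8), 8, n)
  d_cr <- embryoflow:::cr_deriv(M, h, "x")
  interior <- 3:(n - 2)
  err4 <- max(abs(d_cr[4, interior] - k * cos(k * x[interior])))
  # 2nd-order central difference for comparison
  d2 <- (M[4, 3:n] - M[4, 1:(n - 2)]) / (2 * h)
  err2 <- max(abs(d2[interior - 1] - k * cos(k * x[interior])))
  bound4 <- h^4 * k^5 / 30 * 1.1
  expect_lt(err4, bound4)
  expect_lt(err4, err2)
})

test_that("the gradient operator is linear", {
  set.seed(8)
  mk <- function() velocity_field(array(rnorm(9 * 11), c(9, 11, 1)),
                                  array(rnorm(9 * 11), c(9, 11, 1)),
                                  dx = 0.5, dy = 0.8)
  f1 <- mk(); f2 <- mk()
  a <- 2.5; b <- -1.25
  fc <- velocity_field(a * f1$u + b * f2$u, a * f1$v + b * f2$v,
                       dx = 0.5, dy = 0.8)
  g1 <- compact_richardson_gradient(f1)
  g2 <- compact_richardson_gradient(f2)
  gc <- compact_richardson_gradient(fc)
  expect_equal(gc$dudx, a * g1$dudx + b * g2$dudx, tolerance = 1e-12)
  expect_equal(gc$dvdy, a * g1$dvdy + b * g2$dvdy, tolerance = 1e-12)
})

test_that("reconstruction fills masked regions divergence-free", {
  # empty mask: untouched
  fl <- analytic_flow("rotation", nx = 20, ny = 20, dx = 1, omega = 2)
  same <- reconstruct_masked_region(fl$field, matrix(FALSE, 20, 20))
  expect_identical(same$u, fl$field$u)

  # rigid rotation with a masked block: recovered to round-off-ish
  region <- matrix(FALSE, 20, 20); region[8:13, 8:13] <- TRUE
  f2 <- fl$field
  f2$u[, , 1][region] <- 0; f2$v[, , 1][region] <- 0
  f2$mask[, , 1][region] <- FALSE
  fr <- reconstruct_masked_region(f2, region)
  rel <- sqrt(mean((fr$u[, , 1][region] - fl$field$u[, , 1][region])^2 +
                   (fr$v[, , 1][region] - fl$field$v[, , 1][region])^2)) /
         sqrt(mean(fl$field$u[, , 1][region]^2 + fl$field$v[, , 1][region]^2))
  expect_lt(rel, 0.01)

  # smooth vortex with a masked canal-like strip: within 5% RMS
  nx <- 28; ny <- 20
  k <- 2 * pi / 27
  g <- expand.grid(y = 0:(ny - 1), x = 0:(nx - 1))
  u <- matrix(sin(k * g$x) * cos(k * g$y), ny, nx) * 100
  v <- matrix(-cos(k * g$x) * sin(k * g$y), ny, nx) * 100
  f3 <- velocity_field(array(u, c(ny, nx, 1)), array(v, c(ny, nx, 1)), 1, 1)
  strip <- matrix(FALSE, ny, nx); strip[8:13, 12:17] <- TRUE
  f4 <- f3; f4$u[, , 1][strip] <- 0; f4$v[, , 1][strip] <- 0
  f4$mask[, , 1][strip] <- FALSE
  fr2 <- reconstruct_masked_region(f4, strip)
  rel2 <- sqrt(mean((fr2$u[, , 1][strip] - f3$u[, , 1][strip])^2 +
                    (fr2$v[, , 1][strip] - f3$v[, , 1][strip])^2)) /
          sqrt(mean(f3$u[, , 1][strip]^2 + f3$v[, , 1][strip]^2))
  expect_lt(rel2, 0.05)

  # interior of the reconstructed region is divergence-free by construction
  dv <- divergence(fr2)[, , 1]
  interior <- matrix(FALSE, ny, nx); interior[9:12, 13:16] <- TRUE
  expect_lt(max(abs(dv[interior])), 1e-8)

  # idempotence: a second application changes nothing
  fr3 <- reconstruct_masked_region(fr2, strip)
  expect_equal(fr3$u, fr2$u, tolerance = 1e-12)
  expect_equal(fr3$v, fr2$v, tolerance = 1e-12)
})

test_that("reconstruction refuses an invalid donor ring", {
  fl <- analytic_flow("rotation", nx = 16, ny = 16, dx = 1, omega = 1)
  region <- matrix(FALSE, 16, 16); region[7:10, 7:10] <- TRUE
  f <- fl$field
  f$mask[6, 7, 1] <- FALSE          # poke a hole in the donor ring
  expect_error(reconstruct_masked_region(f, region), "donor ring")
})

test_that("wall shear rate matches the analytic channel solutions", {
  walls <- function(fl, ny) {
    y0 <- fl$field$y[1]; y1 <- fl$field$y[ny]
    xs <- fl$field$x[3:(length(fl$field$x) - 2)]
    rbind(data.frame(x = xs, y = y0, nx = 0, ny = -1),
          data.frame(x = xs, y = y1, nx = 0, ny = 1))
  }
  # rigid translation: zero shear
  tr <- analytic_flow("translation", nx = 15, ny = 11, dx = 1, U0 = 50, V0 = 20)
  g0 <- wall_shear_rate(tr$field, walls(tr, 11))
  expect_equal(max(g0$gamma[[1]]), 0)

  # Couette: Uw / h at both walls
  cu <- analytic_flow("couette", nx = 15, ny = 21, dx = 1, Uw = 80)
  gc <- wall_shear_rate(cu$field, walls(cu, 21))
  expect_equal(gc$gamma[[1]], rep(80 / 20, 22), tolerance = 1e-10)

  # Poiseuille: 4 U0 / h at the walls
  po <- analytic_flow("poiseuille", nx = 15, ny = 21, dx = 1, U0 = 120)
  gp <- wall_shear_rate(po$field, walls(po, 21))
  expect_equal(gp$gamma[[1]], rep(4 * 120 / 20, 22), tolerance = 1e-8)

  # frame invariance: adding a uniform velocity changes nothing
  shifted <- po$field; shifted$u <- shifted$u + 500; shifted$v <- shifted$v - 200
  gs <- wall_shear_rate(shifted, walls(po, 21))
  expect_equal(gs$gamma[[1]], gp$gamma[[1]], tolerance = 1e-10)
})
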