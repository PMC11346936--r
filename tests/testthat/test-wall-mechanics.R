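test_that("segmentation recovers the annulus wall within 2 px", {
  an <- annulus_field()
  wb <- suppressWarnings(segment_wall(an$field))
  b <- wb$points[[1]]
  expect_gte(nrow(b), 50)
  rb <- sqrt((b$x - an$center)^2 + (b$y - an$center)^2)
  expect_lt(max(abs(rb - an$R2)), 2)      # Hausdorff distance to true wall
  # normals point outward
  expect_gt(mean(((b$x - an$center) * b$nx + (b$y - an$center) * b$ny) /
                   sqrt((b$x - an$center)^2 + (b$y - an$center)^2)), 0.9)
})

test_that("segmentation is invariant to a global velocity scale", {
  an <- annulus_field()
  wb1 <- suppressWarnings(segment_wall(an$field))
  sc <- an$field; sc$u <- sc$u * 37; sc$v <- sc$v * 37
  wb2 <- suppressWarnings(segment_wall(sc))
  expect_equal(wb1$points[[1]]$x, wb2$points[[1]]$x)
  expect_equal(wb1$areas, wb2$areas)
})

test_that("segmentation rejects a zero field", {
  z <- velocity_field(array(0, c(20, 20, 1)), array(0, c(20, 20, 1)), 1, 1)
  expect_error(segment_wall(z), "no flow")
})

test_that("deformation gradient is identity for a static field", {
  f <- velocity_field(array(0, c(10, 10, 5)), array(0, c(10, 10, 5)),
                      dx = 1, dy = 1, phase_times = (0:4) * 0.01)
  def <- accumulate_deformation(f, reference_phase = 1)
  for (p in 1:5) {
    expect_equal(def$F11[, , p], matrix(1, 10, 10))
    expect_equal(def$F12[, , p], matrix(0, 10, 10))
  }
  expect_equal(def$cycle_drift, 0)
})

test_that("a prescribed uniform stretch accumulates to F11 = lambda", {
  lam <- 1.2; Tw <- 1; np <- 40; dt <- Tw / np
  x <- (0:11) * 2
  # Eulerian field of the homogeneous stretch x(t) = X (1 + (lam-1) t/T):
  # u(x, t) = c x / (1 + c t), c = (lam-1)/T; closed-form F11 = lambda
  cc <- (lam - 1) / Tw
  u <- array(0, c(12, 12, np + 1)); v <- array(0, c(12, 12, np + 1))
  for (p in 1:(np + 1)) {
    t <- (p - 1) * dt
    u[, , p] <- matrix(rep(cc / (1 + cc * t) * x, each = 12), 12, 12)
  }
  f <- velocity_field(u, v, dx = 2, dy = 2, phase_times = (0:np) * dt)
  def <- accumulate_deformation(f, reference_phase = 1)
  expect_equal(mean(def$F11[4:9, 4:9, np + 1]), lam, tolerance = 0.01)
  E <- green_lagrange(def)
  expect_equal(mean(E$E11[4:9, 4:9, np + 1]), (lam^2 - 1) / 2, tolerance = 0.015)
  # F = I at the reference phase, exactly
  expect_equal(def$F11[, , 1], matrix(1, 12, 12))
  expect_equal(E$E11[, , 1], matrix(0, 12, 12))
})

test_that("solid-body rotation yields an orthogonal F and zero strain", {
  fl <- analytic_flow("rotation", nx = 16, ny = 16, dx = 1, omega = 1)
  np <- 40
  u <- array(rep(fl$field$u[, , 1] * 0.3, np + 1), c(16, 16, np + 1))
  v <- array(rep(fl$field$v[, , 1] * 0.3, np + 1), c(16, 16, np + 1))
  f <- velocity_field(u, v, dx = 1, dy = 1, phase_times = (0:np) * 0.025)
  def <- accumulate_deformation(f, 1)
  core <- 5:12
  FtF <- def$F11[core, core, np + 1]^2 + def$F21[core, core, np + 1]^2
  expect_equal(as.vector(FtF), rep(1, 64), tolerance = 0.01)
  E <- green_lagrange(def)
  expect_lt(max(abs(E$E11[core, core, np + 1])), 1e-6)
  expect_lt(max(abs(E$E12[core, core, np + 1])), 1e-6)
})

test_that("Green-Lagrange strain has its closed-form values and objectivity", {
  mkdef <- function(F11, F12, F21, F22) list(
    F11 = array(F11, c(1, 1, 1)), F12 = array(F12, c(1, 1, 1)),
    F21 = array(F21, c(1, 1, 1)), F22 = array(F22, c(1, 1, 1)))
  # identity
  E0 <- green_lagrange(mkdef(1, 0, 0, 1))
  expect_equal(as.numeric(E0$E11), 0); expect_equal(as.numeric(E0$E12), 0)
  # pure rotation by any angle
  for (th in c(0.3, 1.2, 2.9)) {
    Er <- green_lagrange(mkdef(cos(th), -sin(th), sin(th), cos(th)))
    expect_lt(max(abs(c(Er$E11, Er$E12, Er$E22))), 1e-14)
  }
  # uniaxial stretch lambda = 1.2: E11 = (1.2^2 - 1)/2 = 0.22
  Es <- green_lagrange(mkdef(1.2, 0, 0, 1))
  expect_equal(as.numeric(Es$E11), 0.22, tolerance = 1e-12)
  expect_equal(as.numeric(Es$principal_pct), 22, tolerance = 1e-12)

  # objectivity: superposed rotation leaves E unchanged
  set.seed(21)
  for (i in 1:5) {
    Fm <- matrix(rnorm(4, sd = 0.2), 2, 2) + diag(2)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    RF <- R %*% Fm
    E1 <- green_lagrange(mkdef(Fm[1, 1], Fm[1, 2], Fm[2, 1], Fm[2, 2]))
    E2 <- green_lagrange(mkdef(RF[1, 1], RF[1, 2], RF[2, 1], RF[2, 2]))
    expect_equal(as.numeric(E1$E11), as.numeric(E2$E11), tolerance = 1e-12)
    expect_equal(as.numeric(E1$E12), as.numeric(E2$E12), tolerance = 1e-12)
  }
})

test_that("peak wall strain averages the three largest boundary values", {
  # grid whose columns carry the values 0,1,2,3,4,5,0 (percent)
  vals <- c(0, 1, 2, 3, 4, 5, 0)
  principal <- array(matrix(rep(vals, each = 3), 3, 7), c(3, 7, 1))
  strain <- structure(list(principal_pct = principal,
                           x = 0:6, y = 0:2, dx = 1, dy = 1),
                      class = "strain_field")
  boundary <- structure(list(points = list(
    data.frame(x = 1:5, y = 1, nx = 0, ny = -1))), class = "wall_boundary")
  s <- peak_wall_strain(strain, boundary)
  expect_equal(s$strain_pct, mean(c(5, 4, 3)))   # = 4.0
  expect_equal(attr(s, "peak"), 4)

  # uniform boundary strain s -> series value s
  pu <- array(2.5, c(3, 7, 1))
  su <- peak_wall_strain(structure(list(principal_pct = pu, x = 0:6, y = 0:2,
                                        dx = 1, dy = 1),
                                   class = "strain_field"), boundary)
  expect_equal(su$strain_pct, 2.5)

  # fewer than 3 valid samples -> missing
  b2 <- structure(list(points = list(data.frame(x = c(1, 2), y = 1,
                                                nx = 0, ny = -1))),
                  class = "wall_boundary")
  pna <- array(NA_real_, c(3, 7, 1)); pna[2, 2, 1] <- 1; pna[2, 3, 1] <- 2
  s2 <- peak_wall_strain(structure(list(principal_pct = pna, x = 0:6,
                                        y = 0:2, dx = 1, dy = 1),
                                   class = "strain_field"), b2)
  expect_true(is.na(s2$strain_pct))
})

test_that("phantom wall motion recovers the prescribed peak strain", {
  spec <- small_heart_spec(amplitude = 0.05)
  spec$frame_rate <- 96                    # fine time stepping for tracking
  ph <- generate_phantom_heart(spec, render = FALSE, grid_spacing = 6)
  tr <- ph$truth
  def <- accumulate_deformation(tr$field, reference_phase = 1)
  E <- green_lagrange(def)
  # sample on the prescribed ventricle wall at the reference phase
  wall <- tr$wall[[1]]
  ci <- (wall$x - tr$field$x[1]) / tr$field$dx + 1
  ri <- (wall$y - tr$field$y[1]) / tr$field$dy + 1
  p_half <- which.max(tr$strain_pct)       # peak diastolic stretch
  keep <- ci > 2 & ci < length(tr$field$x) - 1 & ri > 2 & ri < length(tr$field$y) - 1
  vals <- embryoflow:::bilinear_at(E$principal_pct[, , p_half],
                                   ri[keep], ci[keep])
  expect_equal(median(vals, na.rm = TRUE), max(tr$strain_pct),
               tolerance = 0.10)
})
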