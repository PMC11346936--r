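test_that("POD strips a static background while keeping moving tracers", {
  set.seed(1)
  ny <- 48; nx <- 64; nt <- 12
  bg <- matrix(runif(ny * nx), ny, nx)
  frames <- array(0, c(ny, nx, nt))
  for (t in seq_len(nt))   # one blob walking across a static background
    frames[, , t] <- embryoflow:::cpp_add_blobs(bg, 10 + 3 * t, 24, 2, 2.5, 4)
  st <- image_stack(frames, 0.25, 400)
  out <- pod_background_removal(st, energy_cutoff = 0.90)

  # oracle: direct singular decomposition of the reshaped stack
  X <- matrix(frames, ny * nx, nt)
  sv <- svd(X)
  k <- attr(out, "pod")$removed
  Xres <- X - sv$u[, 1:k, drop = FALSE] %*%
    (diag(sv$d[1:k], k) %*% t(sv$v[, 1:k, drop = FALSE]))
  expect_equal(array(Xres, dim(frames)), out$frames, tolerance = 1e-8)

  # background pixels quieten by > 90%; blob-track pixels keep variance
  blob_rows <- 20:28; blob_cols <- 10:48
  bg_mask <- matrix(TRUE, ny, nx); bg_mask[blob_rows, blob_cols] <- FALSE
  var_in <- apply(frames, c(1, 2), var)
  var_out <- apply(out$frames, c(1, 2), var)
  # static background pixels have ~zero temporal variance already; compare
  # total energy instead (mean square about zero)
  en_in <- apply(frames, c(1, 2), function(z) mean(z^2))
  en_out <- apply(out$frames, c(1, 2), function(z) mean(z^2))
  expect_lt(mean(en_out[bg_mask]) / mean(en_in[bg_mask]), 0.10)
  expect_gt(sum(var_out[!bg_mask]), 0.5 * sum(var_in[!bg_mask]))
})

test_that("POD handles degenerate stacks as specified", {
  frames <- array(rep(matrix(runif(300), 15, 20), 5), c(15, 20, 5))
  st <- image_stack(frames, 0.25, 400)
  expect_warning(out <- pod_background_removal(st), "identical|fluctuation")
  expect_lt(sum(out$frames^2) / sum(frames^2), 1e-10)
  zero <- image_stack(array(0, c(10, 10, 4)), 0.25, 400)
  expect_error(pod_background_removal(zero), "degenerate")
})

test_that("an identical image pair yields zero displacement everywhere", {
  set.seed(3)
  fr <- array(rep(matrix(runif(120 * 160), 120, 160), 2), c(120, 160, 2))
  st <- image_stack(fr, 0.25, 400)
  f <- suppressWarnings(ensemble_piv(st, cycle_period_frames = 2,
                                     schedule = fast_schedule()))
  expect_true(all(abs(f$u[f$mask]) < 1e-10))
  expect_true(all(abs(f$v[f$mask]) < 1e-10))
})

test_that("uniform integer and sub-pixel shifts are recovered within 0.1 px", {
  for (shift in c(3, 0.5)) {
    st <- uniform_shift_stack(px_per_frame = c(shift, 0), n_frames = 6)
    f <- ensemble_piv(st, cycle_period_frames = 3, schedule = fast_schedule())
    upx <- f$u / (st$pixel_size * st$frame_rate)
    expect_lt(max(abs(upx[f$mask] - shift)), 0.1)
    vpx <- f$v / (st$pixel_size * st$frame_rate)
    expect_lt(max(abs(vpx[f$mask])), 0.1)
  }
})

test_that("the vector grid spacing is window resolution times (1 - overlap)", {
  set.seed(4)
  fr <- array(runif(100 * 100 * 2), c(100, 100, 2))
  sched <- pass_schedule(list(c(64, 32, 0.75)),
                         min_iterations = 1, max_iterations = 1)
  st60 <- image_stack(fr, pixel_size = 0.16, frame_rate = 400)
  f60 <- suppressWarnings(ensemble_piv(st60, 2, sched, validate = FALSE))
  expect_identical(f60$dx, 32 * 0.25 * 0.16)          # 1.28 um at 60x
  st40 <- image_stack(fr, pixel_size = 0.25, frame_rate = 400)
  f40 <- suppressWarnings(ensemble_piv(st40, 2, sched, validate = FALSE))
  expect_identical(f40$dx, 2)                          # 2 um at 40x
})

test_that("normalized-median validation flags and replaces lone spikes", {
  u <- array(100, c(7, 7, 1)); v <- array(50, c(7, 7, 1))
  f <- velocity_field(u, v, dx = 1, dy = 1)
  out <- validate_vectors(f)
  expect_false(any(out$replaced))     # uniform field: nothing flagged

  u2 <- u; u2[4, 4, 1] <- 1000        # 10x the neighbourhood median
  f2 <- velocity_field(u2, v, dx = 1, dy = 1)
  out2 <- validate_vectors(f2)
  expect_true(out2$replaced[4, 4, 1])
  expect_equal(out2$u[4, 4, 1], 100)  # replaced by the median
  expect_equal(sum(out2$replaced), 1)

  tiny <- velocity_field(array(1, c(2, 2, 1)), array(0, c(2, 2, 1)), 1, 1)
  expect_warning(validate_vectors(tiny), "skipped")
  expect_error(validate_vectors(f, threshold = -1), "positive")
  expect_error(validate_vectors(f, neighborhood = 4), "odd")
})

test_that("ensemble averaging over more cycles raises the peak ratio", {
  spec <- phantom_spec(n_particles = 150, background_amplitude = 0,
                       noise_sd = 0.25, dropout = 0, seed = 9)
  scale <- spec$pixel_size * spec$frame_rate
  flow <- function(x, y, t) list(u = rep(2 * scale, length(x)),
                                 v = rep(0, length(x)))
  st <- render_particle_images(spec, flow, nx = 128, ny = 96, n_frames = 17)
  sched <- pass_schedule(list(c(64, 32, 0.5)), min_iterations = 1,
                         max_iterations = 1)
  f8 <- ensemble_piv(st, cycle_period_frames = 2, schedule = sched)
  st1 <- image_stack(st$frames[, , 1:2], st$pixel_size, st$frame_rate)
  f1 <- suppressWarnings(ensemble_piv(st1, cycle_period_frames = 2,
                                      schedule = sched))
  expect_gt(attr(f8, "qc")$peak_ratio, attr(f1, "qc")$peak_ratio)
})

test_that("phase averaging is invariant to which cycle is labelled first", {
  # an exactly periodic stack: one rendered cycle tiled three times
  spec <- phantom_spec(n_particles = 120, background_amplitude = 0,
                       noise_sd = 0, dropout = 0, seed = 13)
  scale <- spec$pixel_size * spec$frame_rate
  flow <- function(x, y, t) list(u = rep(1.5 * scale, length(x)),
                                 v = rep(0.5 * scale, length(x)))
  one <- render_particle_images(spec, flow, nx = 96, ny = 96, n_frames = 4)
  fr <- one$frames[, , c(1:4, 1:4, 1:4)]
  st <- image_stack(fr, spec$pixel_size, spec$frame_rate)
  rot <- image_stack(fr[, , c(5:12, 1:4)], spec$pixel_size, spec$frame_rate)
  sched <- pass_schedule(list(c(48, 24, 0.5)), min_iterations = 1,
                         max_iterations = 1)
  f <- ensemble_piv(st, cycle_period_frames = 4, schedule = sched)
  f_rot <- ensemble_piv(rot, cycle_period_frames = 4, schedule = sched)
  expect_equal(f$u, f_rot$u, tolerance = 1e-10)
  expect_equal(f$v, f_rot$v, tolerance = 1e-10)
})

test_that("oversized windows and short stacks are rejected", {
  st <- uniform_shift_stack(n_frames = 3, nx = 80, ny = 60)
  expect_error(ensemble_piv(st, 2, pass_schedule(list(c(96, 48, 0.5)))),
               "exceeds")
  expect_error(ensemble_piv(st, 1, fast_schedule()), ">= 2")
})
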