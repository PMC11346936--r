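# Shared phantom builders for the test suite. Everything is generated in
# code at test time; sizes are kept small so the whole suite stays fast.

# Blob-seeded stack advected by a spatially uniform flow of `px_per_frame`
# pixels/frame (converted internally to um/s).
uniform_shift_stack <- function(px_per_frame = c(3, 0), n_frames = 6,
                                nx = 160, ny = 120, n_particles = 150,
                                noise_sd = 0, seed = 7) {
  spec <- phantom_spec(n_particles = n_particles, background_amplitude = 0,
                       noise_sd = noise_sd, dropout = 0, seed = seed)
  scale <- spec$pixel_size * spec$frame_rate
  flow <- function(x, y, t) list(u = rep(px_per_frame[1] * scale, length(x)),
                                 v = rep(px_per_frame[2] * scale, length(x)))
  render_particle_images(spec, flow, nx = nx, ny = ny, n_frames = n_frames)
}

# Fast two-pass schedule for phantom-scale images.
fast_schedule <- function() {
  pass_schedule(list(c(64, 32, 0.5), c(32, 32, 0.5)),
                min_iterations = 1, max_iterations = 3)
}

# Annular channel with sqrt boundary-layer ramps: speed omega * r tapering
# to zero at both walls; the true outer wall radius is `R2` grid units.
annulus_field <- function(n = 160, R1 = 25, R2 = 60, delta = 10, omega = 5) {
  ctr <- (n - 1) / 2
  g <- expand.grid(y = 0:(n - 1), x = 0:(n - 1))
  r <- sqrt((g$x - ctr)^2 + (g$y - ctr)^2)
  ramp <- function(d) pmin(pmax(d, 0), delta) / delta
  prof <- sqrt(ramp(R2 - r) * ramp(r - R1)) * (r >= R1 & r <= R2)
  th <- atan2(g$y - ctr, g$x - ctr)
  u <- matrix(-sin(th) * omega * r * prof, n, n)
  v <- matrix(cos(th) * omega * r * prof, n, n)
  list(field = velocity_field(array(u, c(n, n, 1)), array(v, c(n, n, 1)),
                              dx = 1, dy = 1),
       center = ctr, R2 = R2)
}

# Small two-chamber phantom for pipeline-level tests: a scaled-down beat
# (few cycles, coarse frame rate) that still exercises every stage.
small_heart_spec <- function(seed = 11, amplitude = 0.08) {
  phantom_spec(chamber_semiaxes = c(12, 12), canal_width = 14,
               canal_length = 14, wall_amplitude = amplitude, period = 0.75,
               frame_rate = 40, n_cycles = 4, pixel_size = 0.25,
               background_amplitude = 2, noise_sd = 0.02, dropout = 0.02,
               seed = seed)
}

# Miniature phantom for pipeline smoke/determinism tests: smaller chambers
# and fewer cycles, same acquisition regime otherwise.
tiny_heart_spec <- function(seed = 11) {
  phantom_spec(chamber_semiaxes = c(8.5, 8.5), canal_width = 14,
               canal_length = 10, wall_amplitude = 0.08, period = 0.75,
               frame_rate = 32, n_cycles = 2, pixel_size = 0.25,
               background_amplitude = 2, noise_sd = 0.02, dropout = 0.02,
               seed = seed)
}

# Pipeline configuration matched to the small heart phantom.
small_heart_config <- function(ph, schedule = NULL, seed = 11) {
  tr <- ph$truth
  xa <- tr$centers$atrium; xv <- tr$centers$ventricle
  cy <- tr$centers$y; A <- unname(tr$semiaxes["A"])
  a <- ph$spec$wall_amplitude
  w <- ph$spec$canal_width
  sm_v <- (1 + a) * 1.03; sm_a <- sqrt(2 - (1 - a)^2) * 1.03
  in_lumen <- function(x, y)
    ((x - xv) / (A * sm_v))^2 + ((y - cy) / (A * sm_v))^2 <= 1 |
    ((x - xa) / (A * sm_a))^2 + ((y - cy) / (A * sm_a))^2 <= 1 |
    (abs(y - cy) <= w / 2 & x > xa & x < xv)
  pipeline_config(
    stack = ph$stack,
    lumen = in_lumen,
    validate = "final",
    schedule = schedule %||% pass_schedule(
      list(c(96, 48, 0.5), c(48, 24, 0.5), c(16, 16, 0.5)),
      min_iterations = 2, max_iterations = 3),
    avc_upstream = c(xa + 0.85 * A, cy),
    avc_downstream = c(xv - 0.85 * A, cy),
    probe_radius = 2,
    ref_locus = c(xv + 0.5 * A, cy),
    ventricle_roi = c(xv - 2, xv + A + 2),
    rheology = list(ht = 20),
    inlet_diameter = ph$spec$canal_width,
    seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One shared full-scale end-to-end run, computed lazily and cached for the
# session so several test blocks can interrogate it.
.e2e_cache <- new.env(parent = emptyenv())
get_e2e <- function() {
  if (!is.null(.e2e_cache$res)) return(.e2e_cache$res)
  spec <- small_heart_spec(seed = 11)
  base <- generate_phantom_heart(spec, render = FALSE)
  ub_max <- max(abs(base$truth$ubar(seq(0, spec$period, length.out = 500))))
  gamma_true <- 6 * ub_max / spec$canal_width
  spec$mu <- as.numeric(walburn_schneck_viscosity(20, gamma_true))
  ph <- generate_phantom_heart(spec)
  res <- run_pipeline(small_heart_config(ph))
  .e2e_cache$res <- list(res = res, truth = ph$truth, spec = spec,
                         gamma_true = gamma_true)
  .e2e_cache$res
}
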