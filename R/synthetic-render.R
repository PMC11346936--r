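#' Phantom specification
#'
#' Parameters of a synthetic micro-PIV recording: geometry, wall-motion
#' law, tracer photometry, sensor model and acquisition settings. Defaults
#' reproduce the acquisition regime the package targets: 4 s of recording
#' at 400 frames/s spanning 8 cardiac cycles (0.5 s period), 0.25 um/px
#' (40x preset), and a seeding density of roughly 10-15 corpuscle patterns
#' per 48 px interrogation window.
#'
#' @param geometry `"two_chamber"` (elliptical atrium and ventricle joined
#'   by a canal) or `"channel"` (straight channel).
#' @param chamber_semiaxes `c(a, b)` chamber semi-axes, um.
#' @param canal_width canal width, um (must be smaller than the chamber
#'   minor axis; the atrioventricular canal spans 6-10 um, the outflow
#'   tract 10-14 um).
#' @param canal_length nominal canal length, um.
#' @param wall_amplitude fractional amplitude of the periodic wall scale
#'   oscillation (0 <= a < 1; two-chamber phantoms additionally need
#'   `(1+a)^2 < 2` so the antiphase partner chamber stays real).
#' @param period cardiac period, s (> 0).
#' @param n_cycles number of cycles recorded.
#' @param frame_rate frames per second.
#' @param pixel_size um per pixel.
#' @param n_particles tracer count (`NULL`: derived from
#'   `particle_density` and the lumen area).
#' @param particle_density tracers per px^2 (default 12 / 48^2).
#' @param particle_radius tracer Gaussian radius (sd), px.
#' @param particle_peak tracer peak intensity.
#' @param background_amplitude amplitude of the static background pattern.
#' @param noise_sd additive Gaussian sensor noise, intensity units.
#' @param dropout per-frame probability that a tracer drops out of focus.
#' @param vortex_strength relative strength of the optional intracardiac
#'   swirl (0, the default, disables it; the swirl wall speed scales with
#'   this times the canal mean speed).
#' @param mu dynamic viscosity used for the phantom's pressure ground
#'   truth, Pa s.
#' @param seed RNG seed (all phantom randomness derives from it).
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(geometry = c("two_chamber", "channel"),
                         chamber_semiaxes = c(14, 10),
                         canal_width = 8, canal_length = 12,
                         wall_amplitude = 0.05, period = 0.5,
                         n_cycles = 8, frame_rate = 400, pixel_size = 0.25,
                         n_particles = NULL, particle_density = 12 / 48^2,
                         particle_radius = 2.5, particle_peak = 1,
                         background_amplitude = 2, noise_sd = 0.02,
                         dropout = 0.02, vortex_strength = 0, mu = 5e-3,
                         seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot_positive(period, pixel_size, frame_rate,
                     .names = c("period", "pixel_size", "frame_rate"))
  if (!is.null(n_particles) && n_particles < 0) stop("particle count must be >= 0")
  if (wall_amplitude < 0 || wall_amplitude >= 1)
    stop("wall-motion amplitude must lie in [0, 1): the wall would self-intersect")
  if (canal_width >= 2 * chamber_semiaxes[2])
    stop("canal width must be smaller than the chamber minor axis")
  structure(list(
    geometry = geometry, chamber_semiaxes = chamber_semiaxes,
    canal_width = canal_width, canal_length = canal_length,
    wall_amplitude = wall_amplitude, period = period, n_cycles = n_cycles,
    frame_rate = frame_rate, pixel_size = pixel_size,
    n_particles = n_particles, particle_density = particle_density,
    particle_radius = particle_radius, particle_peak = particle_peak,
    background_amplitude = background_amplitude, noise_sd = noise_sd,
    dropout = dropout, vortex_strength = vortex_strength, mu = mu,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Static background pattern: low-frequency smoothed noise, deterministic
# given the current RNG state.
make_background <- function(ny, nx, amplitude) {
  if (amplitude == 0) return(matrix(0, ny, nx))
  raw <- matrix(rnorm(ny * nx), ny, nx)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(raw), sigma = 6))
  amplitude * (sm - min(sm)) / max(1e-12, diff(range(sm)))
}

#' Render tracer-seeded images over a prescribed flow
#'
#' Seeds Gaussian-profile blobs uniformly inside the lumen and advects
#' their continuous centres through the velocity field (midpoint
#' Runge-Kutta per frame), rendering each frame as blobs + static
#' background pattern + per-pixel Gaussian noise. Out-of-plane loss is
#' emulated by random per-frame blob dropout. Rendering is bit-identical
#' under a fixed seed.
#'
#' @param spec a [phantom_spec] (photometry, noise, acquisition, seed).
#' @param flow either a function `f(x, y, t)` returning `list(u, v)` in
#'   um/s at physical coordinates (um, s), or a single-phase
#'   [velocity_field] sampled bilinearly (steady flow).
#' @param lumen function `f(x, y, t)` returning logical: where tracers may
#'   live. `NULL` means the whole frame.
#' @param nx,ny frame size in px.
#' @param n_frames number of frames (default `n_cycles * period *
#'   frame_rate`).
#' @param replenish optional tracer replenishment for flow-through regions
#'   that the prescribed field flushes (e.g. the canal): a list with
#'   `fn(x, y, t)` (logical membership), `area(t)` (region area, um^2) and
#'   `density` (tracers per um^2). After each advection step the region is
#'   topped back up to its target count with uniformly seeded tracers,
#'   emulating the continuous supply of corpuscles from upstream.
#' @return an [image_stack]; attribute `"centers"` holds the per-frame
#'   tracer centre coordinates (um) for ground-truth checks.
#' @export
render_particle_images <- function(spec, flow, lumen = NULL, nx = 192, ny = 128,
                                   n_frames = NULL, replenish = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  nt <- as.integer(n_frames %||% round(spec$n_cycles * spec$period * spec$frame_rate))
  if (nt < 2) stop("need at least 2 frames")
  ps <- spec$pixel_size
  fun <- if (is.function(flow)) flow else {
    stopifnot(inherits(flow, "velocity_field"))
    function(x, y, t) sample_field(flow, x, y, 1L)
  }
  lum <- lumen %||% function(x, y, t) rep(TRUE, length(x))

  with_local_seed(spec$seed, {
    bg <- make_background(ny, nx, spec$background_amplitude)
    n_want <- spec$n_particles %||% round(spec$particle_density * nx * ny)
    # rejection-sample initial positions inside the lumen (um coordinates)
    px <- numeric(0); py <- numeric(0)
    guard <- 0
    while (length(px) < n_want && guard < 200) {
      m <- max(64, 2 * (n_want - length(px)))
      cx <- runif(m, 0, (nx - 1) * ps); cy <- runif(m, 0, (ny - 1) * ps)
      ok <- lum(cx, cy, 0)
      px <- c(px, cx[ok])[seq_len(min(n_want, length(px) + sum(ok)))]
      py <- c(py, cy[ok])[seq_len(length(px))]
      guard <- guard + 1
    }
    n <- length(px)
    if (n < n_want && n_want > 0)
      warning("could only seed ", n, " of ", n_want, " tracers inside the lumen")
    amp <- if (n) spec$particle_peak * runif(n, 0.8, 1.2) else numeric(0)

    dt <- 1 / spec$frame_rate
    frames <- array(0, c(ny, nx, nt))
    centers <- vector("list", nt)
    for (t in seq_len(nt)) {
      tm <- (t - 1) * dt
      centers[[t]] <- cbind(x = px, y = py)
      img <- bg
      if (n) {
        vis <- runif(n) >= spec$dropout
        if (any(vis))
          img <- cpp_add_blobs(img, px[vis] / ps, py[vis] / ps, amp[vis],
                               spec$particle_radius, 4)
      }
      if (spec$noise_sd > 0) img <- img + matrix(rnorm(ny * nx, sd = spec$noise_sd), ny, nx)
      frames[, , t] <- img
      if (n) {  # midpoint advection to the next frame
        uv1 <- fun(px, py, tm)
        xm <- px + uv1$u * dt / 2; ym <- py + uv1$v * dt / 2
        uv2 <- fun(xm, ym, tm + dt / 2)
        px <- px + uv2$u * dt; py <- py + uv2$v * dt
      }
      if (!is.null(replenish)) {
        t_next <- tm + dt
        deficit <- round(replenish$density * replenish$area(t_next)) -
          sum(replenish$fn(px, py, t_next))
        tries <- 0
        while (deficit > 0 && tries < 50) {
          cxn <- runif(4 * deficit, 0, (nx - 1) * ps)
          cyn <- runif(4 * deficit, 0, (ny - 1) * ps)
          ok <- replenish$fn(cxn, cyn, t_next)
          take <- which(ok)[seq_len(min(deficit, sum(ok)))]
          if (length(take)) {
            px <- c(px, cxn[take]); py <- c(py, cyn[take])
            amp <- c(amp, spec$particle_peak * runif(length(take), 0.8, 1.2))
            n <- length(px)
            deficit <- deficit - length(take)
          }
          tries <- tries + 1
        }
      }
    }
    stack <- image_stack(frames, ps, spec$frame_rate)
    attr(stack, "centers") <- centers
    stack
  })
}
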