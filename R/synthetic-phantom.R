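#' Two-chamber beating-heart phantom with full ground truth
#'
#' Builds an analytic two-chamber phantom: an "atrium" and a "ventricle"
#' (ellipses of equal rest area) joined by a plane channel ("canal"),
#' beating in antiphase so that total lumen area is conserved. The
#' ventricle wall scale follows `s_V(t) = 1 - a cos(2 pi t / T)` (smallest
#' at t = 0, which is the end-of-systole strain reference; the first half
#' period is diastole), the atrium follows `s_A = sqrt(2 - s_V^2)`. Inside
#' each chamber the velocity is the affine field of the wall motion
#' (`(s'/s) (x - c)`, divergence `2 s'/s`); inside the canal it is a plane
#' Poiseuille profile whose flux equals the rate of change of the ventricle
#' area, so 2D mass conservation ties the canal flow to the wall motion.
#'
#' Ground truth provided: the continuous velocity closure and a sampled
#' per-phase [velocity_field]; the canal pressure-drop series from the
#' plane-Poiseuille (lubrication) solution `dP = 12 mu u_mean L_c / w^2`;
#' the ventricle wall contour per phase; ejection fraction of the
#' cylindrical volume model; the wall-strain series of the prescribed
#' motion; the endocardial-work value of the prescribed pressure-strain
#' path; heart rate and period.
#'
#' @param spec a [phantom_spec] with `geometry = "two_chamber"`.
#' @param grid_spacing ground-truth velocity grid spacing, px (default 8).
#' @param render render tracer images (set `FALSE` to get truth only).
#' @return list with `stack` (an [image_stack], or `NULL`), `truth` (see
#'   details) and `spec`.
#' @export
generate_phantom_heart <- function(spec = phantom_spec(), grid_spacing = 8,
                                   render = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$geometry != "two_chamber")
    stop("generate_phantom_heart needs a two-chamber geometry")
  a <- spec$wall_amplitude
  if ((1 + a)^2 >= 2)
    stop("wall-motion amplitude too large: antiphase chamber area would be negative")
  A <- spec$chamber_semiaxes[1]; B <- spec$chamber_semiaxes[2]
  w <- spec$canal_width; Lc <- spec$canal_length
  Tp <- spec$period; ps <- spec$pixel_size

  sV <- function(t) 1 - a * cos(2 * pi * t / Tp)
  dsV <- function(t) a * (2 * pi / Tp) * sin(2 * pi * t / Tp)
  sA <- function(t) sqrt(pmax(2 - sV(t)^2, 1e-12))
  dsA <- function(t) -sV(t) * dsV(t) / sA(t)

  margin <- 4                      # um clearance around the moving walls
  smax <- 1 + a; sAmax <- sqrt(2 - (1 - a)^2)
  xa <- margin + A * sAmax         # atrium centre
  xv <- xa + A + Lc + A            # ventricle centre (rest-length canal)
  cy <- margin + B * max(smax, sAmax)
  W_um <- xv + A * sAmax + margin
  H_um <- 2 * cy
  nx <- ceiling(W_um / ps); ny <- ceiling(H_um / ps)

  in_ell <- function(x, y, cx0, s) ((x - cx0) / (A * s))^2 + ((y - cy) / (B * s))^2 <= 1
  A0 <- pi * A * B                 # rest area of each chamber, um^2
  ubar <- function(t) A0 * 2 * sV(t) * dsV(t) / w   # canal mean speed, um/s

  # Optional intracardiac swirl along the chamber's elliptical
  # streamlines, stream function psi = q(t) rho^2 in wall-following scaled
  # coordinates: linear in the coordinates, so its Laplacian is zero (the
  # chamber pressure stays exactly uniform) and the chamber deformation
  # gradient stays spatially homogeneous with the closed form
  # F = (s/s0) expm(M Theta). For circular chambers the swirl is a rigid
  # rotation and leaves the strain ground truth untouched. Off by default.
  kv <- spec$vortex_strength
  swirl <- function(x, y, cx0, s, t) {
    q <- 0.5 * kv * ubar(t) * sqrt(A * B)
    list(u = 2 * q * (y - cy) / (B^2 * s^2),
         v = -2 * q * (x - cx0) / (A^2 * s^2))
  }
  # The myocardium/tissue surrounding the lumen deforms with the chambers:
  # outside the lumen the velocity is the two chambers' affine wall-motion
  # fields blended linearly across the canal midline, so the field is
  # CONTINUOUS across each chamber wall (tissue and chamber share the
  # affine motion there) and every material point outside the canal
  # carries the chamber's homogeneous deformation -- which is what makes
  # the wall-strain ground truth exact wherever the wall is detected.
  x_mid_canal <- (xa + A + xv - A) / 2
  blend_w <- 10                         # um, tissue blend zone width
  flow <- function(x, y, t) {
    sv <- sV(t); sa <- sA(t)
    u <- numeric(length(x)); v <- numeric(length(x))
    ic <- !in_ell(x, y, xv, sv) & !in_ell(x, y, xa, sa) &
      abs(y - cy) <= w / 2 & x > xa & x < xv
    iv <- !ic & in_ell(x, y, xv, sv)
    ia <- !ic & !iv & in_ell(x, y, xa, sa)
    it_ <- !ic & !iv & !ia                # tissue
    rv <- dsV(t) / sv; ra <- dsA(t) / sa
    vv <- swirl(x[iv], y[iv], xv, sv, t)
    va <- swirl(x[ia], y[ia], xa, sa, t)
    u[iv] <- rv * (x[iv] - xv) + vv$u; v[iv] <- rv * (y[iv] - cy) + vv$v
    u[ia] <- ra * (x[ia] - xa) + va$u; v[ia] <- ra * (y[ia] - cy) + va$v
    u[ic] <- 1.5 * ubar(t) * (1 - (2 * (y[ic] - cy) / w)^2)
    wt <- pmin(pmax((x[it_] - x_mid_canal + blend_w / 2) / blend_w, 0), 1)
    u[it_] <- (1 - wt) * ra * (x[it_] - xa) + wt * rv * (x[it_] - xv)
    v[it_] <- ((1 - wt) * ra + wt * rv) * (y[it_] - cy)
    list(u = u, v = v)
  }
  lumen <- function(x, y, t)
    in_ell(x, y, xv, sV(t)) | in_ell(x, y, xa, sA(t)) |
      (abs(y - cy) <= w / 2 & x > xa & x < xv)

  # -- ground truth ---------------------------------------------------------
  frames_per_cycle <- round(Tp * spec$frame_rate)
  np <- frames_per_cycle - 1L
  pt <- (seq_len(np) - 0.5) / spec$frame_rate
  gx <- seq(0, (nx - 1) * ps, by = grid_spacing * ps)
  gy <- seq(0, (ny - 1) * ps, by = grid_spacing * ps)
  g <- expand.grid(y = gy, x = gx)
  u <- array(0, c(length(gy), length(gx), np)); v <- u
  for (p in seq_len(np)) {
    uv <- flow(g$x, g$y, pt[p])
    u[, , p] <- matrix(uv$u, length(gy), length(gx))
    v[, , p] <- matrix(uv$v, length(gy), length(gx))
  }
  field <- velocity_field(u, v, dx = grid_spacing * ps, dy = grid_spacing * ps,
                          x = gx, y = gy, phase_times = pt,
                          pixel_size = ps, frame_rate = spec$frame_rate,
                          n_cycles = spec$n_cycles)

  dP <- 12 * spec$mu * ubar(pt) * Lc / w^2          # Pa (um units cancel)
  theta <- seq(0, 2 * pi, length.out = 181)[-181]
  wall <- lapply(pt, function(t) data.frame(
    x = xv + A * sV(t) * cos(theta), y = cy + B * sV(t) * sin(theta)))

  # closed-form ventricle deformation: F(t) = (s/s0) expm(M Theta) with
  # M = [[0, 1/B^2], [-1/A^2, 0]] and Theta = 2 kv sqrt(AB) A0 ln(s/s0)/w
  # (the swirl angle integral evaluates analytically); every chamber
  # material point carries the same F, so the wall strain IS this value.
  strain_of <- function(t) {
    s0 <- 1 - a
    lam <- sV(t) / s0
    th <- 2 * kv * sqrt(A * B) * A0 * log(sV(t) / s0) / w
    phi <- th / (A * B)
    vapply(seq_along(t), function(i) {
      R <- cos(phi[i]) * diag(2) +
        sin(phi[i]) * (A * B) * matrix(c(0, -1 / A^2, 1 / B^2, 0), 2, 2)
      Fm <- lam[i] * R
      E <- (t(Fm) %*% Fm - diag(2)) / 2
      ev <- eigen(E, symmetric = TRUE)$values
      100 * ev[which.max(abs(ev))]
    }, 0)
  }
  strain_pct <- strain_of(pt)
  dias <- dsV(pt) > 0
  # prescribed pressure-strain path area over diastole, fine sampling
  tf <- seq(0, Tp / 2, length.out = 2001)
  ew <- pracma::trapz(strain_of(tf), 12 * spec$mu * ubar(tf) * Lc / w^2)

  ef <- 100 * (1 - ((1 - a) / (1 + a))^3)           # cylindrical volume model

  truth <- list(
    flow = flow, lumen = lumen, field = field,
    dP_series = data.frame(phase = seq_len(np), time = pt, dP = dP,
                           diastole = dias),
    wall = wall, strain_pct = strain_pct, ew = ew, ef = ef,
    period = Tp, hr = 60 / Tp, frames_per_cycle = frames_per_cycle,
    canal = list(width = w, length = Lc, x_mid = (xa + A + xv - A) / 2, y_center = cy),
    centers = list(atrium = xa, ventricle = xv, y = cy),
    semiaxes = c(A = A, B = B), amplitude = a, mu = spec$mu,
    area = function(t) A0 * sV(t)^2, ubar = ubar,
    geometry = list(nx = nx, ny = ny, margin = margin)
  )

  stack <- NULL
  if (render) { # tracers seeded over the whole frame: RBC patterns inside
    # the lumen, tissue speckle outside, all advected by the same field.
    # The canal is flow-through (the affine chamber fields do not feed
    # Lagrangian parcels into it), so its tracer population is replenished
    # to the seeding density every frame, as upstream blood supply would.
    repl <- if (spec$wall_amplitude > 0) list(
      fn = function(x, y, t) !in_ell(x, y, xv, sV(t)) &
        !in_ell(x, y, xa, sA(t)) & abs(y - cy) <= w / 2 & x > xa & x < xv,
      area = function(t) w * max(0, (xv - A * sV(t)) - (xa + A * sA(t))),
      density = 1.5 * spec$particle_density / ps^2) else NULL
    stack <- render_particle_images(spec, flow, lumen = NULL,
                                    nx = nx, ny = ny, replenish = repl)
  }
  list(stack = stack, truth = truth, spec = spec)
}
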