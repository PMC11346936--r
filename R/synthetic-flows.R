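#' Analytic ground-truth flow fields
#'
#' Closed-form incompressible velocity fields sampled on a regular grid,
#' together with their exact pressure and wall-shear solutions. These are
#' the oracles for the gradient, pressure-integration, and shear-rate
#' operators: every returned quantity has a pen-and-paper value.
#'
#' Supported kinds:
#' \describe{
#'   \item{`poiseuille`}{plane channel flow along x between walls at the top
#'     and bottom grid rows; centreline speed `U0`, parabolic profile,
#'     pressure gradient `-8 mu U0 / h^2` (h = wall-to-wall height), wall
#'     shear rate `4 U0 / h`.}
#'   \item{`couette`}{linear shear `u = Uw * y / h`; uniform shear `Uw / h`,
#'     zero pressure gradient.}
#'   \item{`pulsatile_poiseuille`}{the Poiseuille profile with its amplitude
#'     modulated by `sin(2 pi HR/60 t)` across phases. In the creeping-flow
#'     regime relevant here (Wo << 1) the pressure gradient follows the
#'     instantaneous profile quasi-statically.}
#'   \item{`translation`}{uniform velocity `(U0, V0)`; zero gradient, zero
#'     shear, zero pressure gradient.}
#'   \item{`rotation`}{solid-body rotation at angular rate `omega` about the
#'     grid centre; divergence-free, zero strain rate.}
#' }
#'
#' @param kind one of `"poiseuille"`, `"couette"`, `"pulsatile_poiseuille"`,
#'   `"translation"`, `"rotation"`.
#' @param nx,ny grid nodes per axis.
#' @param dx,dy grid spacing, micrometres.
#' @param U0 centreline / translation speed, um/s (>= 0).
#' @param V0 y-translation speed for `translation`, um/s.
#' @param Uw wall speed for `couette`, um/s.
#' @param omega angular rate for `rotation`, rad/s.
#' @param mu dynamic viscosity, Pa s (> 0).
#' @param hr heart rate in bpm for the pulsatile kind.
#' @param n_phases number of phases to sample (pulsatile kind).
#' @param frame_rate phase sampling rate, Hz.
#' @return a list with elements `field` (a [velocity_field]), and `truth`:
#'   `pressure` (Pa, zero at the first node), `dpdx`, `dpdy` (Pa/um),
#'   `wall_shear` (1/s), `h` (um), and `fun(x, y, t)` giving the continuous
#'   velocity in um/s.
#' @export
analytic_flow <- function(kind = c("poiseuille", "couette",
                                   "pulsatile_poiseuille", "translation",
                                   "rotation"),
                          nx = 32, ny = 32, dx = 1, dy = dx,
                          U0 = 100, V0 = 0, Uw = 100, omega = 1,
                          mu = 4e-3, hr = 120, n_phases = 1L,
                          frame_rate = 400) {
  kind <- match.arg(kind)
  stopifnot_positive(dx, dy, mu, .names = c("dx", "dy", "mu"))
  if (U0 < 0) stop("`U0` must be >= 0")
  x <- (seq_len(nx) - 1) * dx
  y <- (seq_len(ny) - 1) * dy
  h <- y[ny] - y[1]
  if (h <= 0 && kind %in% c("poiseuille", "couette", "pulsatile_poiseuille"))
    stop("channel height must be positive (need ny >= 2)")
  yc <- (y[1] + y[ny]) / 2
  xc <- (x[1] + x[nx]) / 2

  amp <- function(t) sin(2 * pi * (hr / 60) * t)
  fun <- switch(kind,
    poiseuille = function(xq, yq, t = 0)
      list(u = U0 * (1 - (2 * (yq - yc) / h)^2), v = 0 * yq),
    pulsatile_poiseuille = function(xq, yq, t = 0)
      list(u = amp(t) * U0 * (1 - (2 * (yq - yc) / h)^2), v = 0 * yq),
    couette = function(xq, yq, t = 0)
      list(u = Uw * (yq - y[1]) / h, v = 0 * yq),
    translation = function(xq, yq, t = 0)
      list(u = rep(U0, length(xq)), v = rep(V0, length(xq))),
    rotation = function(xq, yq, t = 0)
      list(u = -omega * (yq - yc), v = omega * (xq - xc))
  )

  np <- if (kind == "pulsatile_poiseuille") as.integer(n_phases) else 1L
  times <- (seq_len(np) - 1) / frame_rate
  u <- array(0, c(ny, nx, np)); v <- array(0, c(ny, nx, np))
  g <- expand.grid(y = y, x = x)
  for (p in seq_len(np)) {
    uv <- fun(g$x, g$y, times[p])
    u[, , p] <- matrix(uv$u, ny, nx)
    v[, , p] <- matrix(uv$v, ny, nx)
  }

  dpdx <- switch(kind,
    poiseuille = -8 * mu * U0 / h^2,
    pulsatile_poiseuille = -8 * mu * U0 / h^2 * amp(times),
    0)
  P <- array(0, c(ny, nx, np))
  for (p in seq_len(np))
    P[, , p] <- matrix(rep(dpdx[min(p, length(dpdx))] * (x - x[1]), each = ny), ny, nx)

  wall_shear <- switch(kind,
    poiseuille = 4 * U0 / h,
    pulsatile_poiseuille = 4 * U0 / h * abs(amp(times)),
    couette = Uw / h,
    0)

  list(
    field = velocity_field(u, v, dx, dy, x = x, y = y, phase_times = times),
    truth = list(pressure = P, dpdx = dpdx, dpdy = 0, wall_shear = wall_shear,
                 h = h, mu = mu, fun = fun)
  )
}
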