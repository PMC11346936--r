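#' Phase-resolved velocity field on a regular grid
#'
#' The central container of the pipeline: per-phase `u` (x-component) and
#' `v` (y-component) velocity grids in micrometres per second, on a regular
#' grid with spacing `dx`, `dy` micrometres. `x` and `y` give the physical
#' coordinates of grid columns/rows (micrometres, same frame as the source
#' images); `mask` marks nodes carrying a valid measurement.
#'
#' @param u,v numeric arrays `ny x nx x nphase`, micrometres/second.
#' @param dx,dy grid spacing, micrometres.
#' @param x,y optional node coordinate vectors (defaults to `0:(n-1) * d`).
#' @param phase_times optional per-phase timestamps, seconds.
#' @param mask optional logical array marking valid nodes (default all).
#' @param pixel_size,frame_rate optional acquisition metadata carried along
#'   so downstream steps can convert between pixels/frame and um/s.
#' @param n_cycles number of cardiac cycles averaged into the field.
#' @return an object of class `velocity_field`.
#' @export
velocity_field <- function(u, v, dx, dy, x = NULL, y = NULL,
                           phase_times = NULL, mask = NULL,
                           pixel_size = NULL, frame_rate = NULL,
                           n_cycles = 1L) {
  if (length(dim(u)) == 2) u <- array(u, c(dim(u), 1L))
  if (length(dim(v)) == 2) v <- array(v, c(dim(v), 1L))
  stopifnot(identical(dim(u), dim(v)))
  stopifnot_positive(dx, dy, .names = c("dx", "dy"))
  d <- dim(u)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (length(dim(mask)) == 2) mask <- array(mask, d)
  if (any(!is.finite(u[mask])) || any(!is.finite(v[mask])))
    stop("velocity values must be finite on valid nodes")
  structure(list(
    u = u, v = v, dx = dx, dy = dy,
    x = x %||% ((seq_len(d[2]) - 1) * dx),
    y = y %||% ((seq_len(d[1]) - 1) * dy),
    phase_times = phase_times %||% (seq_len(d[3]) - 1),
    mask = mask, pixel_size = pixel_size, frame_rate = frame_rate,
    n_cycles = n_cycles
  ), class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$u)
  cat(sprintf(
    "<velocity_field> %d x %d nodes, %d phase(s), dx = %.3g um, dy = %.3g um\n",
    d[2], d[1], d[3], x$dx, x$dy))
  cat(sprintf("  speed range: %.3g .. %.3g um/s; %.1f%% valid nodes\n",
              min(sqrt(x$u^2 + x$v^2)), max(sqrt(x$u^2 + x$v^2)),
              100 * mean(x$mask)))
  invisible(x)
}

n_phases <- function(field) dim(field$u)[3]

# Bilinear sampling of one phase of the field at physical coordinates
# (micrometres). Returns list(u, v). Points outside the grid are clamped.
sample_field <- function(field, xq, yq, phase = 1L) {
  ci <- (xq - field$x[1]) / field$dx  # 0-based grid col coordinate
  ri <- (yq - field$y[1]) / field$dy
  list(
    u = cpp_bilinear(field$u[, , phase], matrix(ci, ncol = 1), matrix(ri, ncol = 1))[, 1],
    v = cpp_bilinear(field$v[, , phase], matrix(ci, ncol = 1), matrix(ri, ncol = 1))[, 1]
  )
}

#' Write per-phase vectors as tabular text
#'
#' One CSV with columns `phase, x, y, u, v, valid`.
#' @param field a `velocity_field`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_velocity_csv <- function(field, path) {
  d <- dim(field$u)
  g <- expand.grid(y = field$y, x = field$x)
  rows <- do.call(rbind, lapply(seq_len(d[3]), function(p) {
    data.frame(phase = p, x = g$x, y = g$y,
               u = as.vector(field$u[, , p]), v = as.vector(field$v[, , p]),
               valid = as.vector(field$mask[, , p]))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
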