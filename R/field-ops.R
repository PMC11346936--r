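# Differential operators on gridded velocity fields.
#
# First derivatives use Richardson extrapolation of second-order central
# differences at steps h and 2h, i.e. the classic fourth-order five-point
# stencil (-f[i+2] + 8 f[i+1] - 8 f[i-1] + f[i-2]) / (12 h). Nodes within
# two of a boundary fall back to plain central differences, and boundary
# nodes to one-sided second-order differences; nodes whose stencil touches
# an invalid (masked) neighbour degrade the same way.

shift_mat <- function(M, dj = 0L, di = 0L, fill = NA_real_) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(fill, nr, nc)
  ri <- seq_len(nr) - di; ci <- seq_len(nc) - dj
  ok_r <- ri >= 1 & ri <= nr; ok_c <- ci >= 1 & ci <= nc
  out[ok_r, ok_c] <- M[ri[ok_r], ci[ok_c]]
  out
}

# Derivative of a matrix along columns (x). For rows, pass t(M) and
# transpose back. `valid` is an optional logical matrix; invalid nodes are
# excluded from stencils and get NA results themselves.
cr_deriv_cols <- function(M, h, valid = NULL) {
  nc <- ncol(M)
  if (!is.null(valid)) M[!valid] <- NA_real_
  if (nc < 3) stop("need at least 3 nodes along each axis to differentiate")
  p1 <- shift_mat(M, -1); m1 <- shift_mat(M, 1)
  p2 <- shift_mat(M, -2); m2 <- shift_mat(M, 2)
  d4 <- (-p2 + 8 * p1 - 8 * m1 + m2) / (12 * h)   # 4th-order interior
  d2 <- (p1 - m1) / (2 * h)                       # central fallback
  df <- (-3 * M + 4 * p1 - p2) / (2 * h)          # one-sided forward
  db <- (3 * M - 4 * m1 + m2) / (2 * h)           # one-sided backward
  out <- d4
  out[is.na(out)] <- d2[is.na(out)]
  out[is.na(out)] <- df[is.na(out)]
  out[is.na(out)] <- db[is.na(out)]
  if (!is.null(valid)) out[!valid] <- NA_real_
  out
}

cr_deriv <- function(M, h, axis = c("x", "y"), valid = NULL) {
  axis <- match.arg(axis)
  if (axis == "x") cr_deriv_cols(M, h, valid)
  else t(cr_deriv_cols(t(M), h, if (is.null(valid)) NULL else t(valid)))
}

#' Compact-Richardson velocity gradients
#'
#' Computes the four in-plane velocity gradient components per phase with a
#' fourth-order Richardson-extrapolated central stencil (one-sided
#' second-order at boundaries, degraded stencils next to masked nodes).
#' Units: 1/s for um/s velocities on a um grid.
#'
#' @param field a [velocity_field].
#' @return an object of class `gradient_field` with arrays `dudx`, `dudy`,
#'   `dvdx`, `dvdy` on the same grid.
#' @export
compact_richardson_gradient <- function(field) {
  d <- dim(field$u)
  if (min(d[1], d[2]) < 5)
    warning("fewer than 5 nodes per axis: falling back to central differences")
  out <- list(dudx = array(NA_real_, d), dudy = array(NA_real_, d),
              dvdx = array(NA_real_, d), dvdy = array(NA_real_, d))
  for (p in seq_len(d[3])) {
    valid <- field$mask[, , p]
    valid_arg <- if (all(valid)) NULL else valid
    out$dudx[, , p] <- cr_deriv(field$u[, , p], field$dx, "x", valid_arg)
    out$dudy[, , p] <- cr_deriv(field$u[, , p], field$dy, "y", valid_arg)
    out$dvdx[, , p] <- cr_deriv(field$v[, , p], field$dx, "x", valid_arg)
    out$dvdy[, , p] <- cr_deriv(field$v[, , p], field$dy, "y", valid_arg)
  }
  structure(c(out, list(dx = field$dx, dy = field$dy, x = field$x,
                        y = field$y, mask = field$mask)),
            class = "gradient_field")
}

#' Discrete in-plane divergence
#'
#' Central-difference divergence du/dx + dv/dy (one-sided at boundaries),
#' the planar form of the continuity constraint used for reconstruction.
#'
#' @param field a [velocity_field].
#' @return array of divergence values (1/s).
#' @export
divergence <- function(field) {
  d <- dim(field$u)
  out <- array(NA_real_, d)
  for (p in seq_len(d[3])) {
    dudx <- (shift_mat(field$u[, , p], -1) - shift_mat(field$u[, , p], 1)) / (2 * field$dx)
    dvdy <- (shift_mat(field$v[, , p], di = -1) - shift_mat(field$v[, , p], di = 1)) / (2 * field$dy)
    out[, , p] <- dudx + dvdy
  }
  out
}

#' Divergence-free reconstruction of a masked region
#'
#' Replaces vectors inside `region` by a mass-conserving fill: a discrete
#' stream function psi is fitted in least squares to the surrounding valid
#' vectors (u = d(psi)/dy, v = -d(psi)/dx with central differences, plus a
#' weak smoothness penalty), and the region vectors are regenerated from
#' psi. Because the central-difference operators commute, the reconstructed
#' interior is divergence-free to machine precision. Vectors outside the
#' region are untouched; the operation is idempotent.
#'
#' @param field a [velocity_field].
#' @param region logical `ny x nx` matrix naming the nodes to reconstruct
#'   (applied to every phase). Must be strictly interior to the grid with a
#'   fully valid one-node donor ring around it.
#' @param lambda weight of the smoothness penalty (relative; default 1e-3).
#' @return the field with region nodes replaced and marked valid.
#' @export
reconstruct_masked_region <- function(field, region, lambda = 1e-3) {
  d <- dim(field$u)
  region <- matrix(as.logical(region), d[1], d[2])
  if (!any(region)) return(field)
  ij <- which(region, arr.ind = TRUE)
  if (min(ij) <= 2 || max(ij[, 1]) > d[1] - 2 || max(ij[, 2]) > d[2] - 2)
    stop("region must be strictly interior to the grid (2-node margin)")
  # donor ring: 8-neighbourhood dilation minus the region
  ring <- region
  for (dj in -1:1) for (di in -1:1)
    ring <- ring | shift_mat(region * 1, dj, di, fill = 0) > 0
  ring <- ring & !region

  i0 <- max(1, min(ij[, 1]) - 2); i1 <- min(d[1], max(ij[, 1]) + 2)
  j0 <- max(1, min(ij[, 2]) - 2); j1 <- min(d[2], max(ij[, 2]) + 2)
  nr <- i1 - i0 + 1; nc <- j1 - j0 + 1
  idx <- function(i, j) (j - 1) * nr + i          # psi unknown index in patch
  in_region_p <- region[i0:i1, j0:j1]

  for (p in seq_len(d[3])) {
    bad <- ring & !field$mask[, , p]
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("donor ring has invalid vectors (e.g. node row %d, col %d, phase %d)",
                   w[1], w[2], p))
    }
    up <- field$u[, , p][i0:i1, j0:j1]
    vp <- field$v[, , p][i0:i1, j0:j1]
    rows_i <- integer(0); rows_j <- integer(0); rows_x <- numeric(0)
    rhs <- numeric(0); nrow_ls <- 0L
    add_row <- function(cols, vals, b) {
      nrow_ls <<- nrow_ls + 1L
      rows_i <<- c(rows_i, rep(nrow_ls, length(cols)))
      rows_j <<- c(rows_j, cols); rows_x <<- c(rows_x, vals)
      rhs <<- c(rhs, b)
    }
    sc <- max(sd(c(up[!in_region_p], vp[!in_region_p])), 1e-12)
    lap <- function(i, j) list(
      cols = c(idx(i, j), idx(i + 1, j), idx(i - 1, j), idx(i, j + 1), idx(i, j - 1)),
      vals = c(-4, 1, 1, 1, 1))
    for (j in 2:(nc - 1)) for (i in 2:(nr - 1)) {
      if (!in_region_p[i, j]) {  # data rows at known nodes
        add_row(c(idx(i + 1, j), idx(i - 1, j)),
                c(1, -1) / (2 * field$dy) / sc, up[i, j] / sc)
        add_row(c(idx(i, j + 1), idx(i, j - 1)),
                c(-1, 1) / (2 * field$dx) / sc, vp[i, j] / sc)
      }
      # smoothness: differences of the discrete Laplacian between adjacent
      # nodes (vanishes for any quadratic psi, so rigid rotation and
      # uniform-strain fields are reconstructed exactly)
      l0 <- lap(i, j)
      if (i + 1 <= nr - 1) {
        l1 <- lap(i + 1, j)
        add_row(c(l0$cols, l1$cols),
                lambda * c(l0$vals, -l1$vals) / (field$dx * field$dy) / sc, 0)
      }
      if (j + 1 <= nc - 1) {
        l1 <- lap(i, j + 1)
        add_row(c(l0$cols, l1$cols),
                lambda * c(l0$vals, -l1$vals) / (field$dx * field$dy) / sc, 0)
      }
    }
    add_row(idx(1, 1), 1, 0)  # gauge: psi defined up to a constant
    A <- Matrix::sparseMatrix(i = rows_i, j = rows_j, x = rows_x,
                              dims = c(nrow_ls, nr * nc))
    AtA <- Matrix::crossprod(A) + Matrix::Diagonal(nr * nc, 1e-12)
    psi <- matrix(as.numeric(Matrix::solve(AtA, Matrix::crossprod(A, rhs))), nr, nc)
    for (k in seq_len(nrow(ij))) {
      i <- ij[k, 1] - i0 + 1; j <- ij[k, 2] - j0 + 1
      field$u[ij[k, 1], ij[k, 2], p] <- (psi[i + 1, j] - psi[i - 1, j]) / (2 * field$dy)
      field$v[ij[k, 1], ij[k, 2], p] <- -(psi[i, j + 1] - psi[i, j - 1]) / (2 * field$dx)
      field$mask[ij[k, 1], ij[k, 2], p] <- TRUE
    }
  }
  field
}

#' Shear rate along a wall boundary
#'
#' Directional derivative of the velocity vector along the local outward
#' wall normal, evaluated by sampling the gradient field at each boundary
#' point: gamma = |(du/dn, dv/dn)| in 1/s. Being built purely from
#' gradients, the result is invariant to adding a uniform velocity.
#'
#' @param field a [velocity_field].
#' @param boundary a `wall_boundary` (see [segment_wall]) or a single
#'   data frame with columns `x`, `y`, `nx`, `ny` (micrometres / unit
#'   normals) applied to every phase.
#' @param grads optional precomputed [compact_richardson_gradient] output.
#' @return list with `series` (data frame: phase, peak, mean gamma),
#'   `gamma` (per-phase list of per-point values) and `gamma_peak`, the
#'   cycle-peak shear rate used by the viscosity model.
#' @export
wall_shear_rate <- function(field, boundary, grads = NULL) {
  grads <- grads %||% compact_richardson_gradient(field)
  np <- n_phases(field)
  pts_for <- function(p) {
    if (inherits(boundary, "wall_boundary")) boundary$points[[min(p, length(boundary$points))]]
    else boundary
  }
  gamma <- vector("list", np)
  for (p in seq_len(np)) {
    b <- pts_for(p)
    keep <- !duplicated(round(cbind(b$x, b$y), 9))
    if (any(!keep)) b <- b[keep, , drop = FALSE]
    ci <- (b$x - field$x[1]) / field$dx + 1
    ri <- (b$y - field$y[1]) / field$dy + 1
    comp <- function(arr) bilinear_at(arr[, , p], ri, ci)
    dudn <- comp(grads$dudx) * b$nx + comp(grads$dudy) * b$ny
    dvdn <- comp(grads$dvdx) * b$nx + comp(grads$dvdy) * b$ny
    gamma[[p]] <- sqrt(dudn^2 + dvdn^2)
  }
  series <- data.frame(
    phase = seq_len(np),
    peak = vapply(gamma, function(g) max(g, na.rm = TRUE), 0),
    mean = vapply(gamma, function(g) mean(g, na.rm = TRUE), 0))
  list(series = series, gamma = gamma, gamma_peak = max(series$peak))
}
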