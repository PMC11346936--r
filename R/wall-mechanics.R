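#' Automated endocardial wall segmentation
#'
#' Locates the wall from the flow itself, avoiding manual tracing: the
#' velocity-gradient magnitude is multiplied by the velocity magnitude
#' (suppressing noisy gradients in non-flow regions), the product field is
#' filtered to retain values at or above its 90th percentile, binarized by
#' Otsu's method, cleaned by erosion + dilation with a disc element
#' (radius 3 nodes) and hole filling (8-connectivity), and the largest
#' connected component is kept as the lumen mask; its traced boundary is
#' the wall polyline. Normals are computed from a 5-point moving-average
#' smoothed polyline and oriented outward (away from the mask).
#'
#' The percentile + Otsu combination is scale-covariant, so segmentation
#' is invariant to a global velocity scale factor.
#'
#' The morphological scales (disc radius, hole filling) are those of a
#' pixel-resolution field; when the vector grid is coarser than the
#' acquisition pixels the product field is bilinearly upsampled (factor
#' `upsample`, auto-chosen from `pixel_size` when available) before
#' thresholding so the disc element keeps its intended physical size.
#'
#' @param field a [velocity_field].
#' @param grads optional precomputed [compact_richardson_gradient].
#' @param phases phases to segment (default all).
#' @param percentile retention percentile of the product field
#'   (default 0.90).
#' @param disk_radius morphological disc radius in (upsampled) nodes
#'   (default 3).
#' @param upsample integer upsampling factor for the product field;
#'   `NULL` picks `dx / (2 * pixel_size)` capped at 8 when the field
#'   carries acquisition metadata, else 1.
#' @return a `wall_boundary`: per-phase data frames (`x`, `y` um, `nx`,
#'   `ny` outward unit normals), per-phase lumen masks (upsampled grid)
#'   with their coordinates, per-phase masks on the vector grid
#'   (`grid_masks`), and lumen areas (um^2).
#' @export
segment_wall <- function(field, grads = NULL, phases = NULL,
                         percentile = 0.90, disk_radius = 3,
                         upsample = NULL) {
  stopifnot(inherits(field, "velocity_field"))
  grads <- grads %||% compact_richardson_gradient(field)
  phases <- phases %||% seq_len(n_phases(field))
  up <- upsample %||% (if (!is.null(field$pixel_size))
    max(1L, min(8L, round(field$dx / (2 * field$pixel_size)))) else 1L)
  d <- dim(field$u)
  fx <- if (up > 1) seq(field$x[1], field$x[d[2]],
                        length.out = (d[2] - 1) * up + 1) else field$x
  fy <- if (up > 1) seq(field$y[1], field$y[d[1]],
                        length.out = (d[1] - 1) * up + 1) else field$y
  pts <- vector("list", length(phases))
  masks <- vector("list", length(phases))
  grid_masks <- vector("list", length(phases))
  areas <- numeric(length(phases))
  brush <- EBImage::makeBrush(2 * disk_radius + 1, shape = "disc")
  Xq <- matrix(rep((fx - field$x[1]) / field$dx, each = length(fy)),
               length(fy), length(fx))
  Yq <- matrix(rep((fy - field$y[1]) / field$dy, length(fx)),
               length(fy), length(fx))
  for (k in seq_along(phases)) {
    p <- phases[k]
    speed <- sqrt(field$u[, , p]^2 + field$v[, , p]^2)
    gmag <- sqrt(grads$dudx[, , p]^2 + grads$dudy[, , p]^2 +
                 grads$dvdx[, , p]^2 + grads$dvdy[, , p]^2)
    prod <- speed * gmag
    prod[is.na(prod)] <- 0
    if (max(prod) <= 0)
      stop("segmentation failed: the velocity field carries no flow")
    if (up > 1) prod <- cpp_bilinear(prod, Xq, Yq)
    thr <- quantile(prod, percentile)
    f <- prod; f[f < thr] <- 0
    fn <- f / max(f)
    ot <- EBImage::otsu(EBImage::Image(fn), range = c(0, 1))
    bw <- EBImage::Image(fn > ot)
    # closing bridges the discontinuities between nearby high-product
    # structures, opening then removes isolated speckle (disc radius 3)
    bw <- EBImage::erode(EBImage::dilate(bw, brush), brush)
    bw <- EBImage::dilate(EBImage::erode(bw, brush), brush)
    bw <- EBImage::fillHull(bw)
    lbl <- EBImage::bwlabel(bw)
    tab <- tabulate(as.integer(lbl)[as.integer(lbl) > 0])
    if (!length(tab)) stop("segmentation failed: no connected component survived")
    comp <- (as.matrix(lbl) == which.max(tab))
    border <- c(comp[1, ], comp[nrow(comp), ], comp[, 1], comp[, ncol(comp)])
    if (mean(border) > 0.5)
      warning("largest component touches most of the frame border: ",
              "segmentation likely captured background")
    cl <- contourLines(x = fx, y = fy, z = t(comp * 1), levels = 0.5)
    if (!length(cl)) stop("segmentation failed: no boundary contour found")
    cl <- cl[[which.max(lengths(lapply(cl, `[[`, "x")))]]
    b <- data.frame(x = cl$x, y = cl$y)
    if (nrow(b) > 1 && isTRUE(all.equal(b[1, ], b[nrow(b), ], check.attributes = FALSE)))
      b <- b[-nrow(b), ]
    if (nrow(b) < 50)
      warning("wall boundary has only ", nrow(b), " points; strain extrema ",
              "may be unstable (fewer than the recommended > 50)")
    b <- cbind(b, boundary_normals(b, comp, fx, fy))
    pts[[k]] <- b
    masks[[k]] <- comp
    grid_masks[[k]] <- matrix(comp[cbind(
      rep(seq(1, length(fy), length.out = d[1]), d[2]),
      rep(seq(1, length(fx), length.out = d[2]), each = d[1]))], d[1], d[2])
    areas[k] <- sum(comp) * (fx[2] - fx[1]) * (fy[2] - fy[1])
  }
  structure(list(points = pts, masks = masks, grid_masks = grid_masks,
                 areas = areas, phases = phases,
                 x = fx, y = fy, dx = field$dx, dy = field$dy),
            class = "wall_boundary")
}

# Outward unit normals of a closed polyline, from the tangent of a 5-point
# moving-average smoothed curve; orientation fixed by probing the mask on
# the lumen side.
boundary_normals <- function(b, comp, fx, fy) {
  n <- nrow(b)
  sm <- function(z) {
    zp <- c(z[(n - 1):n], z, z[1:2])
    (zp[1:n] + zp[2:(n + 1)] + zp[3:(n + 2)] + zp[4:(n + 3)] + zp[5:(n + 4)]) / 5
  }
  xs <- sm(b$x); ys <- sm(b$y)
  tx <- c(xs[2:n], xs[1]) - c(xs[n], xs[1:(n - 1)])
  ty <- c(ys[2:n], ys[1]) - c(ys[n], ys[1:(n - 1)])
  len <- sqrt(tx^2 + ty^2); len[len == 0] <- 1
  nx <- ty / len; ny <- -tx / len
  # orient outward: the mask should NOT be found a step along the normal
  hx <- fx[2] - fx[1]; hy <- fy[2] - fy[1]
  step <- 1.5 * max(hx, hy)
  ci <- pmin(pmax((b$x + nx * step - fx[1]) / hx + 1, 1), ncol(comp))
  ri <- pmin(pmax((b$y + ny * step - fy[1]) / hy + 1, 1), nrow(comp))
  inside <- comp[cbind(round(ri), round(ci))]
  if (mean(inside) > 0.5) { nx <- -nx; ny <- -ny }
  data.frame(nx = nx, ny = ny)
}

#' Accumulated deformation gradient from the velocity field
#'
#' Pseudo-Lagrangian kinematics: the grid nodes of the reference phase
#' (conventionally end of ventricle systole) are advected through the
#' phase-resolved velocity field (midpoint Runge-Kutta per phase step,
#' bilinear field sampling), and the deformation gradient at each later
#' phase is `F = I + grad_X(displacement)` with Compact-Richardson
#' gradients taken on the reference grid. `F` is exactly the identity at
#' the reference phase. Trajectories leaving the valid grid are flagged
#' invalid from that phase on; the accumulated `F` over one full cycle is
#' returned as a drift QC metric.
#'
#' @param field a [velocity_field] covering one full cycle.
#' @param reference_phase phase index used as the undeformed state.
#' @return a `deformation_field`: arrays `F11, F12, F21, F22`
#'   (`ny x nx x nphase`), `valid`, and `cycle_drift` (mean |F_cycle - I|).
#' @export
accumulate_deformation <- function(field, reference_phase = 1L) {
  stopifnot(inherits(field, "velocity_field"))
  d <- dim(field$u); np <- d[3]
  if (reference_phase < 1 || reference_phase > np)
    stop("reference phase out of range")
  dt <- if (np > 1) diff(field$phase_times[1:2]) else 1
  g <- expand.grid(y = field$y, x = field$x)
  X0 <- g$x; Y0 <- g$y
  xs <- X0; ys <- Y0
  ok <- rep(TRUE, length(xs))
  F11 <- array(NA_real_, d); F12 <- array(NA_real_, d)
  F21 <- array(NA_real_, d); F22 <- array(NA_real_, d)
  valid <- array(TRUE, d)
  store <- function(p, xs, ys, ok) {
    dxm <- matrix(xs - X0, d[1], d[2]); dym <- matrix(ys - Y0, d[1], d[2])
    F11[, , p] <<- 1 + cr_deriv(dxm, field$dx, "x")
    F12[, , p] <<- cr_deriv(dxm, field$dy, "y")
    F21[, , p] <<- cr_deriv(dym, field$dx, "x")
    F22[, , p] <<- 1 + cr_deriv(dym, field$dy, "y")
    valid[, , p] <<- matrix(ok, d[1], d[2])
  }
  store(reference_phase, xs, ys, ok)
  order_fwd <- c(seq(reference_phase, np), seq_len(reference_phase - 1))
  xr <- range(field$x); yr <- range(field$y)
  for (k in seq_len(np - 1)) {
    p <- order_fwd[k]; p_next <- order_fwd[k + 1]
    uv1 <- sample_field(field, xs, ys, p)
    xm <- xs + uv1$u * dt / 2; ym <- ys + uv1$v * dt / 2
    uv2 <- sample_field(field, xm, ym, p)
    xs <- xs + uv2$u * dt; ys <- ys + uv2$v * dt
    ok <- ok & xs >= xr[1] & xs <= xr[2] & ys >= yr[1] & ys <= yr[2]
    store(p_next, xs, ys, ok)
  }
  # close the cycle for the drift metric
  uv1 <- sample_field(field, xs, ys, order_fwd[np])
  xm <- xs + uv1$u * dt / 2; ym <- ys + uv1$v * dt / 2
  uv2 <- sample_field(field, xm, ym, order_fwd[np])
  xe <- xs + uv2$u * dt; ye <- ys + uv2$v * dt
  drift <- mean(sqrt((xe - X0)^2 + (ye - Y0)^2)[ok], na.rm = TRUE)
  structure(list(F11 = F11, F12 = F12, F21 = F21, F22 = F22, valid = valid,
                 reference_phase = reference_phase, cycle_drift = drift,
                 x = field$x, y = field$y, dx = field$dx, dy = field$dy),
            class = "deformation_field")
}

#' Green-Lagrange strain from the deformation gradient
#'
#' `E = (F^T F - I) / 2` per node and phase: symmetric, zero for any rigid
#' motion (F orthogonal), and equal to `(lambda^2 - 1)/2` along a uniaxial
#' stretch lambda. The scalar wall strain reported downstream is 100 times
#' the largest-magnitude principal value of E (sign retained).
#'
#' @param def a `deformation_field` (or list with F11, F12, F21, F22).
#' @return a `strain_field`: arrays `E11, E12, E22` and `principal_pct`
#'   (scalar strain, percent).
#' @export
green_lagrange <- function(def) {
  E11 <- (def$F11^2 + def$F21^2 - 1) / 2
  E22 <- (def$F12^2 + def$F22^2 - 1) / 2
  E12 <- (def$F11 * def$F12 + def$F21 * def$F22) / 2
  tr2 <- (E11 + E22) / 2
  rad <- sqrt(((E11 - E22) / 2)^2 + E12^2)
  e1 <- tr2 + rad; e2 <- tr2 - rad
  principal <- ifelse(abs(e1) >= abs(e2), e1, e2)
  if (!is.null(def$valid)) principal[!def$valid] <- NA_real_
  structure(list(E11 = E11, E12 = E12, E22 = E22,
                 principal_pct = 100 * principal,
                 valid = def$valid %||% NULL,
                 reference_phase = def$reference_phase %||% NA,
                 x = def$x %||% NULL, y = def$y %||% NULL,
                 dx = def$dx %||% NULL, dy = def$dy %||% NULL),
            class = "strain_field")
}

#' Peak endocardial wall strain series
#'
#' For every phase the scalar strain is sampled at the wall boundary
#' points and the three largest values are averaged, yielding the peak
#' endocardial strain variation along the cycle; the diastolic peak and
#' its phase are reported. Phases with fewer than 3 valid boundary
#' samples are marked missing.
#'
#' @param strain a `strain_field` (see [green_lagrange]).
#' @param boundary a `wall_boundary` (see [segment_wall]).
#' @return data frame: phase, `strain_pct`; attributes `peak`,
#'   `peak_phase`.
#' @export
peak_wall_strain <- function(strain, boundary) {
  stopifnot(inherits(boundary, "wall_boundary"))
  np <- dim(strain$principal_pct)[3]
  out <- numeric(np)
  for (p in seq_len(np)) {
    b <- boundary$points[[min(p, length(boundary$points))]]
    ci <- (b$x - strain$x[1]) / strain$dx + 1
    ri <- (b$y - strain$y[1]) / strain$dy + 1
    vals <- bilinear_at(strain$principal_pct[, , p], ri, ci)
    vals <- vals[is.finite(vals)]
    out[p] <- if (length(vals) >= 3) mean(sort(vals, decreasing = TRUE)[1:3])
              else NA_real_
  }
  res <- data.frame(phase = seq_len(np), strain_pct = out)
  pk <- which.max(out)
  attr(res, "peak") <- out[pk]; attr(res, "peak_phase") <- pk
  res
}
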