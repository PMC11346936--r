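#' Pressure gradient from the velocity field
#'
#' Assembles the right-hand side of the rearranged incompressible
#' Navier-Stokes momentum balance, `grad P = -rho (du/dt + u . grad u) +
#' mu lap u`, per phase and node. In the creeping-flow regime of the
#' embryonic heart (Re << 1, Wo << 1) the inertial terms are negligible
#' and the default keeps only the viscous term `mu lap u`; the full
#' unsteady form is available via `include_inertia = TRUE` (needing >= 3
#' phases for the central time difference, taken cyclically). Laplacians
#' are built by repeated Compact-Richardson differentiation.
#'
#' Units: velocities um/s on a um grid with `mu` in Pa s give the gradient
#' in Pa/um.
#'
#' @param field a [velocity_field].
#' @param fluid a [fluid_properties].
#' @param grads optional precomputed [compact_richardson_gradient].
#' @param include_inertia include `-rho (du/dt + u . grad u)`.
#' @return list with arrays `gx`, `gy` (Pa/um), grid info, and the inputs
#'   recorded in `meta`.
#' @export
pressure_gradient <- function(field, fluid, grads = NULL,
                              include_inertia = FALSE) {
  stopifnot(inherits(field, "velocity_field"), inherits(fluid, "fluid_properties"))
  np <- n_phases(field)
  if (include_inertia && np < 3)
    stop("the unsteady term needs at least 3 phases for a central time difference")
  grads <- grads %||% compact_richardson_gradient(field)
  d <- dim(field$u)
  gx <- array(0, d); gy <- array(0, d)
  for (p in seq_len(np)) {
    lap_u <- cr_deriv(grads$dudx[, , p], field$dx, "x") +
             cr_deriv(grads$dudy[, , p], field$dy, "y")
    lap_v <- cr_deriv(grads$dvdx[, , p], field$dx, "x") +
             cr_deriv(grads$dvdy[, , p], field$dy, "y")
    gx[, , p] <- fluid$mu * lap_u      # Pa s * 1/(um s) = Pa/um
    gy[, , p] <- fluid$mu * lap_v
    if (include_inertia) {
      dt <- diff(field$phase_times[1:2])
      pm <- if (p == 1) np else p - 1
      pp <- if (p == np) 1 else p + 1
      dudt <- (field$u[, , pp] - field$u[, , pm]) / (2 * dt)
      dvdt <- (field$v[, , pp] - field$v[, , pm]) / (2 * dt)
      conv_u <- field$u[, , p] * grads$dudx[, , p] + field$v[, , p] * grads$dudy[, , p]
      conv_v <- field$u[, , p] * grads$dvdx[, , p] + field$v[, , p] * grads$dvdy[, , p]
      # rho [kg/m^3] * (um/s^2) -> Pa/m scaled by 1e-6, then Pa/um by 1e-6
      gx[, , p] <- gx[, , p] - fluid$rho * (dudt + conv_u) * 1e-12
      gy[, , p] <- gy[, , p] - fluid$rho * (dvdt + conv_v) * 1e-12
    }
  }
  list(gx = gx, gy = gy, dx = field$dx, dy = field$dy, x = field$x, y = field$y,
       mask = field$mask,
       meta = list(mu = fluid$mu, rho = fluid$rho, inertia = include_inertia))
}

# Build the 8 path families (4 orientations x 2 senses) for one mask.
# Each segment is a run of consecutive in-mask nodes along the direction;
# returns list of segments, each a list(idx = linear node indices, w =
# per-step projected spacing onto the direction as c(dx_step, dy_step)).
build_path_families <- function(mask, dx, dy) {
  nr <- nrow(mask); nc <- ncol(mask)
  lin <- function(i, j) (j - 1) * nr + i
  runs <- function(ii, jj) {        # split a node sequence at mask gaps
    inm <- mask[cbind(ii, jj)]
    segs <- list()
    r <- rle(inm)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) if (r$values[k] && r$lengths[k] >= 2)
      segs[[length(segs) + 1]] <- lin(ii[starts[k]:ends[k]], jj[starts[k]:ends[k]])
    segs
  }
  fam <- list()
  add_family <- function(segs, step) {
    rev_segs <- lapply(segs, rev)
    fam[[length(fam) + 1]] <<- list(segs = segs, step = step)
    fam[[length(fam) + 1]] <<- list(segs = rev_segs, step = -step)
  }
  # rows (x direction)
  segs <- list()
  for (i in seq_len(nr)) segs <- c(segs, runs(rep(i, nc), seq_len(nc)))
  add_family(segs, c(dx, 0))
  # columns (y direction)
  segs <- list()
  for (j in seq_len(nc)) segs <- c(segs, runs(seq_len(nr), rep(j, nr)))
  add_family(segs, c(0, dy))
  # main diagonals (down-right)
  segs <- list()
  for (s in (1 - nc):(nr - 1)) {
    i <- seq(max(1, 1 + s), min(nr, nc + s)); j <- i - s
    if (length(i) >= 2) segs <- c(segs, runs(i, j))
  }
  add_family(segs, c(dx, dy))
  # anti-diagonals (up-right)
  segs <- list()
  for (s in 2:(nr + nc)) {
    i <- seq(min(nr, s - 1), max(1, s - nc)); j <- s - i
    if (length(i) >= 2) segs <- c(segs, runs(i, j))
  }
  add_family(segs, c(dx, -dy))
  fam
}

#' Omnidirectional pressure integration
#'
#' Integrates a pressure-gradient field into a relative pressure field by
#' averaging second-order trapezoidal line integrals over eight path
#' families (horizontal, vertical and both diagonal ray directions, each
#' traversed in both senses), iterating the family average -- each sweep
#' re-seeds every ray from the current averaged estimate at its starting
#' node -- until the normalized residual (max per-node change over the
#' field range) drops below `tol`. The pressure is pinned to zero at
#' `reference_node` every phase.
#'
#' @param gp output of [pressure_gradient].
#' @param reference_node `c(row, col)` grid index of the zero-pressure
#'   node (conventionally the ventricle/BA outflow boundary node).
#' @param mask optional logical matrix restricting integration to
#'   flow-connected nodes (default: the field's valid mask).
#' @param tol normalized residual tolerance (default 1e-3).
#' @param max_iter iteration cap; non-convergence is flagged, not fatal.
#' @return a `pressure_field`: array `P` (Pa, zero at the reference node),
#'   `residual` and `converged` per phase, grid info and the path count.
#' @export
omnidirectional_integrate <- function(gp, reference_node, mask = NULL,
                                      tol = 1e-3, max_iter = 300,
                                      return_families = FALSE) {
  d <- dim(gp$gx)
  m <- mask %||% (if (!is.null(gp$mask)) gp$mask[, , 1] else matrix(TRUE, d[1], d[2]))
  m <- matrix(as.logical(m), d[1], d[2])
  if (!m[reference_node[1], reference_node[2]])
    stop("reference node must lie inside the integration mask")
  fam <- build_path_families(m, gp$dx, gp$dy)
  P <- array(0, d); res <- numeric(d[3]); conv <- logical(d[3])
  ref_lin <- (reference_node[2] - 1) * d[1] + reference_node[1]
  for (p in seq_len(d[3])) {
    gxv <- as.vector(gp$gx[, , p]); gyv <- as.vector(gp$gy[, , p])
    gxv[is.na(gxv)] <- 0; gyv[is.na(gyv)] <- 0
    Pc <- rep(0, d[1] * d[2])
    r <- Inf; it <- 0
    while (it < max_iter) {
      it <- it + 1
      acc <- rep(0, d[1] * d[2]); cnt <- rep(0, d[1] * d[2])
      for (f in fam) {
        sx <- f$step[1]; sy <- f$step[2]
        for (seg in f$segs) {
          g <- gxv[seg] * sx + gyv[seg] * sy
          inc <- (g[-length(g)] + g[-1]) / 2           # trapezoid steps
          vals <- Pc[seg[1]] + c(0, cumsum(inc))
          acc[seg] <- acc[seg] + vals
          cnt[seg] <- cnt[seg] + 1
        }
      }
      Pn <- ifelse(cnt > 0, acc / pmax(cnt, 1), Pc)
      Pn <- Pn - Pn[ref_lin]
      rng <- diff(range(Pn[m])); if (!is.finite(rng) || rng == 0) rng <- 1
      r <- max(abs(Pn - Pc)[m]) / rng
      Pc <- Pn
      if (r <= tol) break
    }
    Pm <- matrix(Pc, d[1], d[2]); Pm[!m] <- NA_real_
    Pm <- Pm - Pm[reference_node[1], reference_node[2]]
    P[, , p] <- Pm
    res[p] <- r; conv[p] <- r <= tol
    if (return_families && p == 1) {
      fam_P <- lapply(fam, function(f) {
        Pf <- rep(NA_real_, d[1] * d[2])
        for (seg in f$segs) {
          g <- gxv[seg] * f$step[1] + gyv[seg] * f$step[2]
          Pf[seg] <- Pc[seg[1]] + c(0, cumsum((g[-length(g)] + g[-1]) / 2))
        }
        matrix(Pf - Pf[ref_lin], d[1], d[2])
      })
      attr(P, "families") <- fam_P
    }
  }
  if (!all(conv))
    warning("pressure integration did not reach the residual tolerance in ",
            sum(!conv), " phase(s); results flagged non-converged")
  structure(list(P = P, residual = res, converged = conv,
                 reference_node = reference_node, mask = m,
                 x = gp$x, y = gp$y, dx = gp$dx, dy = gp$dy,
                 n_paths = length(fam), meta = gp$meta),
            class = "pressure_field")
}

#' Non-dimensionalize a pressure field by heart rate and viscosity
#'
#' Divides the pressure by `HR * mu` with the heart rate converted to 1/s,
#' the natural pressure scale of creeping pulsatile flow; the scaled field
#' is comparable across stages and species.
#'
#' @param pf a `pressure_field` (or plain array).
#' @param hr heart rate, beats per minute (> 0).
#' @param mu dynamic viscosity, Pa s (> 0).
#' @return the input with `P_nd` added (and scaling metadata).
#' @export
nondimensionalize <- function(pf, hr, mu) {
  stopifnot_positive(hr, mu, .names = c("hr", "mu"))
  scale <- (hr / 60) * mu
  if (inherits(pf, "pressure_field")) {
    pf$P_nd <- pf$P / scale
    pf$meta$hr <- hr; pf$meta$mu_nd <- mu
    pf
  } else pf / scale
}

#' Canal region descriptor
#'
#' Probe pair for a pressure-drop series across a cushion region: the
#' upstream and downstream loci (um coordinates) with an optional
#' disc-averaging radius. The sign convention is `dP = P(upstream) -
#' P(downstream)`, positive in the forward-flow direction; swapping the
#' probes negates the series exactly.
#'
#' @param label `"AVC"` or `"OFT"`.
#' @param upstream,downstream `c(x, y)` probe centres, um.
#' @param radius disc-averaging radius, um (0 = point probe).
#' @return a `canal_region`.
#' @export
canal_region <- function(label = c("AVC", "OFT"), upstream, downstream,
                         radius = 0) {
  label <- match.arg(label)
  if (isTRUE(all.equal(upstream, downstream)))
    stop("upstream and downstream probes must differ")
  structure(list(label = label, upstream = upstream, downstream = downstream,
                 radius = radius), class = "canal_region")
}

#' Pressure-drop series across a canal
#'
#' Per-phase `dP = P(upstream) - P(downstream)` (disc-averaged over
#' in-mask nodes within `radius`), with the non-dimensional twin when
#' present. Phases where a probe disc contains no valid node are marked
#' missing rather than interpolated. Negative drops are flagged as
#' retrograde.
#'
#' @param pf a `pressure_field` (see [omnidirectional_integrate]).
#' @param region a [canal_region].
#' @return data frame: phase, dP (Pa), dP_nd (if available), retrograde;
#'   attributes `peak` and `peak_phase` for the series maximum.
#' @export
canal_pressure_drop <- function(pf, region) {
  stopifnot(inherits(pf, "pressure_field"), inherits(region, "canal_region"))
  d <- dim(pf$P)
  probe_mean <- function(arr2, locus) {
    ci <- (locus[1] - pf$x[1]) / pf$dx + 1
    ri <- (locus[2] - pf$y[1]) / pf$dy + 1
    if (region$radius <= 0) {
      i <- round(ri); j <- round(ci)
      if (i < 1 || i > d[1] || j < 1 || j > d[2] || !pf$mask[i, j]) return(NA_real_)
      return(arr2[i, j])
    }
    rr <- ceiling(region$radius / pf$dy); rc <- ceiling(region$radius / pf$dx)
    ii <- max(1, round(ri) - rr):min(d[1], round(ri) + rr)
    jj <- max(1, round(ci) - rc):min(d[2], round(ci) + rc)
    sel <- outer(ii, jj, function(i, j)
      ((j - ci) * pf$dx)^2 + ((i - ri) * pf$dy)^2 <= region$radius^2) &
      pf$mask[ii, jj]
    if (!any(sel)) return(NA_real_)
    mean(arr2[ii, jj][sel], na.rm = TRUE)
  }
  dP <- vapply(seq_len(d[3]), function(p)
    probe_mean(pf$P[, , p], region$upstream) -
    probe_mean(pf$P[, , p], region$downstream), 0)
  out <- data.frame(phase = seq_len(d[3]), dP = dP, retrograde = !is.na(dP) & dP < 0)
  if (!is.null(pf$P_nd))
    out$dP_nd <- vapply(seq_len(d[3]), function(p)
      probe_mean(pf$P_nd[, , p], region$upstream) -
      probe_mean(pf$P_nd[, , p], region$downstream), 0)
  pk <- which.max(out$dP)
  attr(out, "peak") <- if (length(pk)) out$dP[pk] else NA_real_
  attr(out, "peak_phase") <- if (length(pk)) pk else NA_integer_
  attr(out, "label") <- region$label
  out
}
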