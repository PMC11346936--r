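#' Multi-pass PIV interrogation schedule
#'
#' Ordered list of correlation passes, each `(window size px, window
#' resolution px, overlap fraction)`. The vector grid spacing of a pass is
#' `resolution * (1 - overlap)` pixels. The default schedule is a 96 px
#' first pass (48 px resolution, 50% overlap) followed by two 64 px passes
#' (32 px resolution) at 50% and 75% overlap, with 3 to 6 iterative window
#' deformation iterations per pass and Blackman apodization.
#'
#' @param passes list of numeric triples `c(window, resolution, overlap)`.
#' @param min_iterations,max_iterations bounds on the deformation
#'   iterations within each pass.
#' @param apodization window function name (only `"blackman"` supported).
#' @return a `pass_schedule` object.
#' @export
pass_schedule <- function(passes = list(c(96, 48, 0.50),
                                        c(64, 32, 0.50),
                                        c(64, 32, 0.75)),
                          min_iterations = 3L, max_iterations = 6L,
                          apodization = "blackman") {
  for (p in passes) {
    if (length(p) != 3) stop("each pass must be c(window, resolution, overlap)")
    if (p[2] > p[1]) stop("window resolution must not exceed window size")
    if (p[3] < 0 || p[3] >= 1) stop("overlap must lie in [0, 1)")
  }
  if (min_iterations > max_iterations)
    stop("min_iterations must not exceed max_iterations")
  if (!identical(apodization, "blackman"))
    stop("only the Blackman apodization window is implemented")
  structure(list(passes = passes, min_iterations = as.integer(min_iterations),
                 max_iterations = as.integer(max_iterations),
                 apodization = apodization), class = "pass_schedule")
}

# Ensemble cross-correlation of paired window cubes, zero-padded to `pad`
# and fftshifted (zero displacement at pad/2 + 1). FFTW-backed; the
# Armadillo implementation `cpp_xcorr_ensemble` computes the same plane and
# serves as an independent cross-check in the tests.
xcorr_ensemble <- function(A, B, pad) {
  nr <- dim(A)[1]; nc <- dim(A)[2]; k <- dim(A)[3]
  if (length(pad) == 1) pad <- c(pad, pad)
  acc <- matrix(0 + 0i, pad[1], pad[2])
  Ap <- matrix(0, pad[1], pad[2]); Bp <- matrix(0, pad[1], pad[2])
  for (s in seq_len(k)) {
    Ap[1:nr, 1:nc] <- A[, , s]; Bp[1:nr, 1:nc] <- B[, , s]
    acc <- acc + Conj(fftwtools::fftw2d(Ap)) * fftwtools::fftw2d(Bp)
  }
  plane <- Re(fftwtools::fftw2d(acc, inverse = 1)) / (pad[1] * pad[2] * k)
  hr_ <- pad[1] / 2; hc <- pad[2] / 2
  plane[c((hr_ + 1):pad[1], 1:hr_), c((hc + 1):pad[2], 1:hc)]
}

# 3-point Gaussian sub-pixel fit along one axis; falls back to a parabolic
# fit when the log is undefined, then to the integer peak. Returns
# list(delta, fit = "gaussian" | "parabolic" | "integer").
subpixel_fit1 <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0 && (log(cm) + log(cp) - 2 * log(c0)) < 0) {
    return(list(delta = (log(cm) - log(cp)) / (2 * (log(cm) + log(cp) - 2 * log(c0))),
                fit = "gaussian"))
  }
  den <- cm + cp - 2 * c0
  if (den < 0) return(list(delta = (cm - cp) / (2 * den), fit = "parabolic"))
  list(delta = 0, fit = "integer")
}

# Locate the correlation peak of an ensemble plane (pad x pad, zero lag at
# pad/2 + 1). Ties are broken toward the smaller displacement magnitude.
# Returns displacement (dx, dy) in px, the peak ratio (primary over
# secondary peak outside a 3 px exclusion zone), and the fit kind.
locate_peak <- function(plane, max_disp) {
  if (length(max_disp) == 1) max_disp <- c(max_disp, max_disp)
  ctr_r <- nrow(plane) / 2 + 1; ctr_c <- ncol(plane) / 2 + 1
  lo_r <- max(2, ctr_r - max_disp[2]); hi_r <- min(nrow(plane) - 1, ctr_r + max_disp[2])
  lo_c <- max(2, ctr_c - max_disp[1]); hi_c <- min(ncol(plane) - 1, ctr_c + max_disp[1])
  sub <- plane[lo_r:hi_r, lo_c:hi_c]
  mx <- max(sub)
  cand <- which(sub == mx, arr.ind = TRUE)
  if (nrow(cand) > 1) {   # tie: smallest displacement magnitude wins
    dmag <- (cand[, 1] + lo_r - 1 - ctr_r)^2 + (cand[, 2] + lo_c - 1 - ctr_c)^2
    cand <- cand[which.min(dmag), , drop = FALSE]
  }
  pi_ <- cand[1, 1] + lo_r - 1; pj <- cand[1, 2] + lo_c - 1
  fx <- subpixel_fit1(plane[pi_, pj - 1], plane[pi_, pj], plane[pi_, pj + 1])
  fy <- subpixel_fit1(plane[pi_ - 1, pj], plane[pi_, pj], plane[pi_ + 1, pj])
  # secondary peak for the detectability ratio
  ex <- 3
  masked <- sub
  ii <- pmax(1, cand[1, 1] - ex):pmin(nrow(masked), cand[1, 1] + ex)
  jj <- pmax(1, cand[1, 2] - ex):pmin(ncol(masked), cand[1, 2] + ex)
  masked[ii, jj] <- -Inf
  second <- suppressWarnings(max(masked))
  ratio <- if (is.finite(second) && second > 0) mx / second else Inf
  list(dx = pj - ctr_c + fx$delta, dy = pi_ - ctr_r + fy$delta,
       ratio = ratio, fit = c(fx$fit, fy$fit))
}

# Normalized-median outlier test on one phase (matrix components, px or
# um/s -- the statistic is scale-free apart from eps). Returns the filtered
# components and the replacement flags.
nmt_filter <- function(u, v, valid, threshold = 2, neighborhood = 3, eps = 0.1) {
  nr <- nrow(u); nc <- ncol(u)
  r <- (neighborhood - 1) %/% 2
  flag <- matrix(FALSE, nr, nc)
  mu <- u; mv <- v
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!valid[i, j]) next
    ii <- max(1, i - r):min(nr, i + r); jj <- max(1, j - r):min(nc, j + r)
    sel <- valid[ii, jj]; sel[match(i, ii), match(j, jj)] <- FALSE
    nu <- u[ii, jj][sel]; nv <- v[ii, jj][sel]
    if (length(nu) < 3) next
    mU <- median(nu); mV <- median(nv)
    rU <- abs(u[i, j] - mU) / (median(abs(nu - mU)) + eps)
    rV <- abs(v[i, j] - mV) / (median(abs(nv - mV)) + eps)
    if (max(rU, rV) > threshold) {
      flag[i, j] <- TRUE; mu[i, j] <- mU; mv[i, j] <- mV
    }
  }
  list(u = mu, v = mv, replaced = flag)
}

#' Ensemble phase-correlation PIV
#'
#' Recovers the phase-averaged velocity field of a periodic flow from an
#' image sequence. Consecutive frame pairs are assigned to cardiac phases
#' by frame index modulo the cycle period; for every phase and
#' interrogation window the cross-correlation spectra of all cycles are
#' averaged before a single peak detection (ensemble correlation), which
#' raises the correlation signal-to-noise far above a single image pair.
#' Passes proceed coarse to fine per `schedule` with symmetric iterative
#' window deformation (each image deformed by half the predictor field,
#' bilinear intensity interpolation, Blackman apodization); iteration stops
#' once the largest displacement update drops below `conv_tol` px (after at
#' least the scheduled minimum). Sub-pixel peak location uses a three-point
#' Gaussian estimator with parabolic and integer fallbacks, and a
#' normalized-median outlier validation runs between iterations. A final
#' 3x3 median filter is applied to the last pass only.
#'
#' @param stack an [image_stack] (typically POD-filtered).
#' @param cycle_period_frames frames per cardiac cycle (>= 2; fractional
#'   values are nearest-phase binned via rounding).
#' @param schedule a [pass_schedule].
#' @param validate when to run the normalized-median test: `"all"` (every
#'   deformation iteration of every pass), `"final"` (only on the final
#'   pass, whose grid is designed to resolve the flow -- on coarser passes
#'   a jet narrower than the vector spacing is structurally flagged as an
#'   outlier and would be erased from the predictor), or `"none"`.
#'   `TRUE`/`FALSE` map to `"all"`/`"none"`.
#' @param outlier_threshold,neighborhood validation parameters (see
#'   [validate_vectors]).
#' @param conv_tol deformation convergence tolerance, px (default 0.1).
#' @return a [velocity_field] (um/s) with `qc` attribute: mean correlation
#'   peak ratio, replaced-vector fraction, sub-pixel fallback counts.
#' @export
ensemble_piv <- function(stack, cycle_period_frames,
                         schedule = pass_schedule(), validate = "all",
                         outlier_threshold = 2, neighborhood = 3,
                         conv_tol = 0.1) {
  stopifnot(inherits(stack, "image_stack"), inherits(schedule, "pass_schedule"))
  if (isTRUE(validate)) validate <- "all"
  if (isFALSE(validate)) validate <- "none"
  validate <- match.arg(validate, c("all", "final", "none"))
  fr <- stack$frames
  ny <- dim(fr)[1]; nx <- dim(fr)[2]; nt <- dim(fr)[3]
  P <- as.integer(round(cycle_period_frames))
  if (P < 2) stop("cycle_period_frames must be >= 2")
  if (nt < 2 * P)
    warning("fewer than two full cycles available: ensemble averaging is ",
            "limited to a single cycle")
  np <- P - 1L
  t_all <- seq_len(nt - 1L)
  phase_of <- ((t_all - 1L) %% P) + 1L
  pairs_by_phase <- lapply(seq_len(np), function(p) t_all[phase_of == p])
  if (any(lengths(pairs_by_phase) == 0))
    stop("stack too short: some phases have no image pair")

  pred <- NULL   # list(u, v [nyg,nxg,np] px/frame, cx, cy 0-based px)
  qc <- list(peak_ratio = NA_real_, replaced_fraction = 0,
             fallback = c(gaussian = 0, parabolic = 0, integer = 0))


  for (k in seq_along(schedule$passes)) {
    ps <- schedule$passes[[k]]
    win <- ps[1]; res <- ps[2]; ov <- ps[3]
    spacing <- res * (1 - ov)
    if (win > nx || win > ny)
      stop(sprintf("window size %d exceeds image extent %d x %d", win, nx, ny))
    cx <- seq(win / 2 - 0.5, (nx - 1) - (win / 2 - 0.5) + 1e-9, by = spacing)
    cy <- seq(win / 2 - 0.5, (ny - 1) - (win / 2 - 0.5) + 1e-9, by = spacing)
    nxg <- length(cx); nyg <- length(cy)
    offs <- seq(-(win - 1) / 2, (win - 1) / 2)
    Xo <- matrix(rep(offs, each = win), win, win)   # col offsets
    Yo <- t(Xo)
    apod <- outer(blackman_window(win), blackman_window(win))
    pad <- 2L * win

    # predictor on this grid, px/frame
    u_pd <- array(0, c(nyg, nxg, np)); v_pd <- array(0, c(nyg, nxg, np))
    if (!is.null(pred)) {
      gc_ <- (cx - pred$cx[1]) / (pred$cx[2] - pred$cx[1])
      gr_ <- (cy - pred$cy[1]) / (pred$cy[2] - pred$cy[1])
      Xq <- matrix(rep(gc_, each = nyg), nyg, nxg)
      Yq <- matrix(rep(gr_, nxg), nyg, nxg)
      for (p in seq_len(np)) {
        u_pd[, , p] <- cpp_bilinear(pred$u[, , p], Xq, Yq)
        v_pd[, , p] <- cpp_bilinear(pred$v[, , p], Xq, Yq)
      }
    }

    u_m <- array(0, c(nyg, nxg, np)); v_m <- array(0, c(nyg, nxg, np))
    valid <- array(TRUE, c(nyg, nxg, np))
    upd <- array(Inf, c(nyg, nxg, np))   # per-window last displacement update
    last_pass <- k == length(schedule$passes)
    ratios <- c()
    for (it in seq_len(schedule$max_iterations)) {
      max_upd <- 0
      ratios <- c(); fb <- c(gaussian = 0, parabolic = 0, integer = 0)
      for (p in seq_len(np)) {
        ts <- pairs_by_phase[[p]]
        ncyc <- length(ts)
        A <- array(0, c(win, win, ncyc)); B <- array(0, c(win, win, ncyc))
        for (ix in seq_len(nxg)) for (iy in seq_len(nyg)) {
          if (it > 1 && (!valid[iy, ix, p] || upd[iy, ix, p] < conv_tol)) {
            u_m[iy, ix, p] <- u_pd[iy, ix, p]; v_m[iy, ix, p] <- v_pd[iy, ix, p]
            next   # window already converged (or carries no signal)
          }
          Xp <- cx[ix] + Xo; Yp <- cy[iy] + Yo
          # per-pixel deformation: interpolate the predictor field inside
          # the window when it varies across the grid
          if (!is.null(pred) || it > 1) {
            Xg <- (Xp - cx[1]) / spacing; Yg <- (Yp - cy[1]) / spacing
            duw <- cpp_bilinear(u_pd[, , p], Xg, Yg)
            dvw <- cpp_bilinear(v_pd[, , p], Xg, Yg)
          } else {
            duw <- matrix(u_pd[iy, ix, p], win, win)
            dvw <- matrix(v_pd[iy, ix, p], win, win)
          }
          okA <- TRUE
          for (s in seq_len(ncyc)) {
            a <- cpp_bilinear(fr[, , ts[s]], Xp - duw / 2, Yp - dvw / 2)
            b <- cpp_bilinear(fr[, , ts[s] + 1L], Xp + duw / 2, Yp + dvw / 2)
            if (s == 1 && (sd(a) == 0 || sd(b) == 0)) { okA <- FALSE; break }
            A[, , s] <- (a - mean(a)) * apod
            B[, , s] <- (b - mean(b)) * apod
          }
          if (!okA) { valid[iy, ix, p] <- FALSE; u_m[iy, ix, p] <- 0; v_m[iy, ix, p] <- 0; next }
          plane <- xcorr_ensemble(A, B, pad)
          pk <- locate_peak(plane, max_disp = win / 2)
          fb[pk$fit[1]] <- fb[pk$fit[1]] + 1
          u_m[iy, ix, p] <- u_pd[iy, ix, p] + pk$dx
          v_m[iy, ix, p] <- v_pd[iy, ix, p] + pk$dy
          valid[iy, ix, p] <- TRUE
          upd[iy, ix, p] <- max(abs(pk$dx), abs(pk$dy))
          max_upd <- max(max_upd, upd[iy, ix, p])
          if (last_pass && is.finite(pk$ratio)) ratios <- c(ratios, pk$ratio)
        }
        do_validate <- validate == "all" || (validate == "final" && last_pass)
        if (do_validate && nyg >= neighborhood && nxg >= neighborhood) {
          f <- nmt_filter(u_m[, , p], v_m[, , p], valid[, , p],
                          outlier_threshold, neighborhood)
          u_m[, , p] <- f$u; v_m[, , p] <- f$v
          qc$replaced_fraction <- mean(f$replaced)
        }
      }
      u_pd <- u_m; v_pd <- v_m
      qc$fallback <- fb
      if (it >= schedule$min_iterations && max_upd < conv_tol) break
    }
    if (last_pass && length(ratios)) qc$peak_ratio <- mean(ratios)
    pred <- list(u = u_pd, v = v_pd, cx = cx, cy = cy)
  }

  # fill isolated invalid windows (e.g. locally tracer-free interrogation
  # spots) from the median of their valid neighbours; nodes with at least
  # 4 valid 8-neighbours are filled and marked interpolated, while large
  # signal-free regions stay invalid
  interpolated <- array(FALSE, dim(valid))
  for (p in seq_len(np)) {
    for (sweep in 1:2) {
      vl <- valid[, , p]
      if (all(vl)) break
      idx <- which(!vl, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1]; j <- idx[r, 2]
        ii <- max(1, i - 1):min(nyg, i + 1); jj <- max(1, j - 1):min(nxg, j + 1)
        sel <- vl[ii, jj]; sel[match(i, ii), match(j, jj)] <- FALSE
        if (sum(sel) >= 4) {
          u_m[i, j, p] <- median(u_m[, , p][ii, jj][sel])
          v_m[i, j, p] <- median(v_m[, , p][ii, jj][sel])
          valid[i, j, p] <- TRUE
          interpolated[i, j, p] <- TRUE
        }
      }
    }
  }
  pred$u <- u_m; pred$v <- v_m

  # final-pass 3x3 median filtering of the vectors
  for (p in seq_len(np)) {
    pred$u[, , p] <- median_filter2(pred$u[, , p])
    pred$v[, , p] <- median_filter2(pred$v[, , p])
  }

  scale <- stack$pixel_size * stack$frame_rate   # px/frame -> um/s
  field <- velocity_field(
    u = pred$u * scale, v = pred$v * scale,
    dx = spacing_last <- (schedule$passes[[length(schedule$passes)]][2] *
           (1 - schedule$passes[[length(schedule$passes)]][3])) * stack$pixel_size,
    dy = spacing_last,
    x = pred$cx * stack$pixel_size, y = pred$cy * stack$pixel_size,
    phase_times = (seq_len(np) - 0.5) / stack$frame_rate,
    mask = valid, pixel_size = stack$pixel_size,
    frame_rate = stack$frame_rate,
    n_cycles = max(lengths(pairs_by_phase)))
  qc$interpolated_fraction <- mean(interpolated)
  attr(field, "qc") <- qc
  field
}

#' Normalized-median outlier validation
#'
#' Universal outlier test: a vector whose fluctuation from the local
#' neighbourhood median, normalized by the neighbourhood's median absolute
#' fluctuation, exceeds `threshold` is flagged and replaced by that median.
#'
#' @param field a [velocity_field].
#' @param threshold detection threshold (default 2).
#' @param neighborhood odd neighbourhood width in vector-grid nodes
#'   (default 3, i.e. 3x3).
#' @return the field with outliers replaced; `field$replaced` records the
#'   per-phase replacement flags.
#' @export
validate_vectors <- function(field, threshold = 2, neighborhood = 3) {
  stopifnot(inherits(field, "velocity_field"))
  if (neighborhood %% 2 != 1 || neighborhood < 3)
    stop("`neighborhood` must be an odd integer >= 3")
  if (threshold <= 0) stop("`threshold` must be positive")
  d <- dim(field$u)
  if (d[1] < neighborhood || d[2] < neighborhood) {
    warning("field smaller than the validation neighbourhood: skipped")
    return(field)
  }
  eps <- if (!is.null(field$pixel_size) && !is.null(field$frame_rate))
    0.1 * field$pixel_size * field$frame_rate else 0.1
  replaced <- array(FALSE, d)
  for (p in seq_len(d[3])) {
    f <- nmt_filter(field$u[, , p], field$v[, , p], field$mask[, , p],
                    threshold, neighborhood, eps)
    field$u[, , p] <- f$u; field$v[, , p] <- f$v
    replaced[, , p] <- f$replaced
  }
  field$replaced <- replaced
  field
}
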