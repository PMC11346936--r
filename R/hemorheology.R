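#' Count corpuscle patterns from the averaged autocorrelation
#'
#' Estimates the number of red-blood-corpuscle patterns in a cropped
#' region from the time-averaged spatial autocorrelation of the image
#' sequence. For randomly placed, non-overlapping Gaussian tracers the
#' zero-lag autocorrelation mass equals the tracer count times the
#' single-tracer correlation mass `a^2 pi sigma^2`; the tracer width sigma
#' is recovered from the central-peak width of the averaged
#' autocorrelation (a tracer of sd sigma gives a correlation peak of sd
#' `sigma * sqrt(2)`), and the peak intensity `a` is taken from
#' `particle_peak` or estimated from the brightest blob pixels.
#'
#' @param stack an [image_stack] (>= 10 frames for a stable average).
#' @param crop optional `list(x = c(j0, j1), y = c(i0, i1))` pixel index
#'   ranges (1-based, inclusive); default the full frame.
#' @param particle_peak single-tracer peak intensity; `NULL` estimates it
#'   from the 99.9th percentile of the background-subtracted intensities.
#' @param background `"temporal"` subtracts the per-pixel temporal mean
#'   (removes any static pattern); `"scalar"` subtracts each frame's mean.
#' @return the estimated pattern count `Nrbc` (0 when no peak rises above
#'   the noise floor), with attributes `sigma` (fitted tracer sd, px) and
#'   `peak` (intensity used).
#' @export
count_rbc_patterns <- function(stack, crop = NULL, particle_peak = NULL,
                               background = c("temporal", "scalar")) {
  stopifnot(inherits(stack, "image_stack"))
  background <- match.arg(background)
  fr <- stack$frames
  if (!is.null(crop))
    fr <- fr[crop$y[1]:crop$y[2], crop$x[1]:crop$x[2], , drop = FALSE]
  d <- dim(fr)
  if (d[3] < 10) warning("fewer than 10 frames: the averaged autocorrelation may be unstable")
  if (sd(fr) < .Machine$double.eps * max(1, abs(mean(fr))) * 100)
    stop("featureless crop: no intensity structure to autocorrelate")
  if (background == "temporal") {
    mu <- apply(fr, c(1, 2), mean)
    fr <- sweep(fr, c(1, 2), mu)
  }
  ny2 <- 2 * d[1]; nx2 <- 2 * d[2]
  acc <- matrix(0, ny2, nx2)
  for (t in seq_len(d[3])) {
    f <- fr[, , t]
    if (background == "scalar") f <- f - mean(f)
    Fp <- matrix(0, ny2, nx2); Fp[1:d[1], 1:d[2]] <- f
    FT <- fft(Fp)
    acc <- acc + Re(fft(Mod(FT)^2, inverse = TRUE)) / (ny2 * nx2)
  }
  R <- acc / d[3]
  R <- R[c((d[1] + 1):ny2, 1:d[1]), c((d[2] + 1):nx2, 1:d[2])]  # fftshift
  ci <- d[1] + 1; cj <- d[2] + 1
  R0 <- R[ci, cj]
  noise_floor <- median(abs(R)) + 5 * mad(as.vector(R))
  if (!is.finite(R0) || R0 <= noise_floor) {
    out <- 0
    attr(out, "sigma") <- NA_real_; attr(out, "peak") <- NA_real_
    return(out)
  }
  fitw <- function(cm, c0, cp) {  # 3-point Gaussian width along one axis
    if (cm <= 0 || cp <= 0 || c0 <= max(cm, cp)) return(NA_real_)
    den <- 2 * log(c0) - log(cm) - log(cp)
    if (den <= 0) return(NA_real_)
    sqrt(1 / den)
  }
  sx <- fitw(R[ci, cj - 1], R0, R[ci, cj + 1])
  sy <- fitw(R[ci - 1, cj], R0, R[ci + 1, cj])
  if (is.na(sx) && is.na(sy)) {
    # a one-pixel peak is uncorrelated noise, not a tracer pattern
    out <- 0
    attr(out, "sigma") <- NA_real_; attr(out, "peak") <- NA_real_
    return(out)
  }
  sig_corr <- mean(c(sx, sy), na.rm = TRUE)
  if (sig_corr < 1) {   # narrower than any resolvable tracer: noise peak
    out <- 0
    attr(out, "sigma") <- sig_corr / sqrt(2); attr(out, "peak") <- NA_real_
    return(out)
  }
  sigma_p <- sig_corr / sqrt(2)
  a <- particle_peak %||% as.numeric(quantile(abs(fr), 0.999))
  n <- R0 / (a^2 * pi * sigma_p^2)
  out <- n
  attr(out, "sigma") <- sigma_p; attr(out, "peak") <- a
  out
}

#' Hematocrit from the corpuscle count
#'
#' `Ht = 100 * V_rbc * Nrbc / (crop_area * depth_of_focus)`: the percent
#' blood volume occupied by red blood corpuscles in the interrogated
#' volume.
#'
#' @param n_rbc corpuscle pattern count (>= 0).
#' @param v_rbc single-corpuscle volume, um^3.
#' @param crop_area interrogated area, um^2.
#' @param depth_of_focus optical depth of focus, um.
#' @return hematocrit in percent by volume.
#' @export
hematocrit <- function(n_rbc, v_rbc, crop_area, depth_of_focus) {
  stopifnot_positive(v_rbc, crop_area, depth_of_focus,
                     .names = c("v_rbc", "crop_area", "depth_of_focus"))
  if (n_rbc < 0) stop("`n_rbc` must be >= 0")
  ht <- 100 * v_rbc * n_rbc / (crop_area * depth_of_focus)
  if (ht > 100)
    warning(sprintf("hematocrit %.1f%% exceeds 100%%: check V_rbc / volume inputs", ht))
  ht
}

#' Walburn-Schneck non-Newtonian blood viscosity
#'
#' Shear-thinning viscosity as a function of hematocrit and shear rate:
#' `mu = C1 exp(C2 Ht) exp(C4 TPMA / Ht^2) gamma^(-C3 Ht)` with Ht in
#' percent, gamma in 1/s, and TPMA (total protein minus albumin) in g/L so
#' that `C4 * TPMA` is dimensionless. The empirical prefactor yields poise;
#' the result is converted to Pa s via [POISE_TO_PAS].
#'
#' @param ht hematocrit, percent (> 0; the model is singular at 0).
#' @param gamma shear rate, 1/s (> 0); conventionally the peak wall shear
#'   rate recorded over a cardiac cycle.
#' @param constants model constants: `C1` (poise), `C2` (1/%), `C3` (1/%),
#'   `C4` (L/g), `TPMA` (g/L; 45 mg/mL = 45 g/L).
#' @return dynamic viscosity in Pa s, with attribute `cP` (centipoise).
#' @export
walburn_schneck_viscosity <- function(ht, gamma,
                                      constants = list(C1 = 0.00797,
                                                       C2 = 0.0608,
                                                       C3 = 0.00499,
                                                       C4 = 14.59,
                                                       TPMA = 45)) {
  if (any(ht <= 0)) stop("the viscosity model is singular at Ht = 0")
  if (any(gamma <= 0)) stop("shear rate must be positive")
  cns <- constants
  mu_poise <- cns$C1 * exp(cns$C2 * ht) * exp(cns$C4 * cns$TPMA / ht^2) *
    gamma^(-cns$C3 * ht)
  mu <- mu_poise * POISE_TO_PAS
  attr(mu, "cP") <- mu * 1000
  mu
}

#' Fluid properties bundle
#'
#' @param rho blood density, kg/m^3 (default 1025).
#' @param mu dynamic viscosity, Pa s.
#' @return a `fluid_properties` list.
#' @export
fluid_properties <- function(rho = 1025, mu) {
  stopifnot_positive(rho, mu, .names = c("rho", "mu"))
  structure(list(rho = rho, mu = as.numeric(mu)), class = "fluid_properties")
}
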