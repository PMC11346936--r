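#' Heart rate from a velocity waveform
#'
#' The dominant non-zero frequency of the Fourier transform of an
#' instantaneous velocity series gives the heart rate; the cycle period in
#' frames is returned for phase binning. The spectral resolution
#' (sampling rate over series length, in bpm) bounds the estimate's
#' granularity and is reported alongside.
#'
#' @param values instantaneous velocity samples (uniformly sampled).
#' @param sample_rate sampling rate, Hz.
#' @param min_snr required ratio of the dominant spectral amplitude to the
#'   median amplitude; below it the series is considered flat.
#' @return list: `hr` (bpm), `frequency` (Hz), `period_frames` (rounded),
#'   `period_frames_exact`, `resolution_bpm`.
#' @export
heart_rate <- function(values, sample_rate, min_snr = 4) {
  n <- length(values)
  if (n < 8) stop("series too short for a spectral heart-rate estimate")
  x <- values - mean(values)
  if (sd(x) == 0) stop("flat series: no cardiac frequency peak above the noise floor")
  sp <- Mod(fft(x))[2:floor(n / 2)]
  freqs <- (1:(floor(n / 2) - 1)) * sample_rate / n
  k <- which.max(sp)
  if (sp[k] < min_snr * median(sp))
    stop("no dominant spectral peak: series looks aperiodic or flat")
  f0 <- freqs[k]
  if (f0 * n / sample_rate < 2)
    warning("fewer than 2 full cycles in the series: heart rate is uncertain")
  list(hr = 60 * f0, frequency = f0,
       period_frames = as.integer(round(sample_rate / f0)),
       period_frames_exact = sample_rate / f0,
       resolution_bpm = 60 * sample_rate / n)
}

#' Reynolds and Womersley numbers of the cardiac flow
#'
#' `Re = rho V d / mu` and `Wo = d sqrt(rho omega / mu)` with
#' `omega = 2 pi HR / 60`, based on the atrial inlet diameter. Inputs are
#' in the acquisition units (um, um/s) and converted to SI internally.
#'
#' @param d atrial inlet diameter, um (> 0).
#' @param velocity characteristic velocity, um/s (>= 0; conventionally the
#'   cycle-peak velocity magnitude at the inlet).
#' @param fluid a [fluid_properties].
#' @param hr heart rate, bpm (> 0).
#' @return list: `Re`, `Wo`, `omega` (rad/s).
#' @export
reynolds_womersley <- function(d, velocity, fluid, hr) {
  stopifnot(inherits(fluid, "fluid_properties"))
  stopifnot_positive(d, hr, .names = c("d", "hr"))
  if (velocity < 0) stop("characteristic velocity must be >= 0")
  d_m <- d * 1e-6; v_m <- velocity * 1e-6
  omega <- 2 * pi * hr / 60
  list(Re = fluid$rho * v_m * d_m / fluid$mu,
       Wo = d_m * sqrt(fluid$rho * omega / fluid$mu),
       omega = omega)
}

#' Ventricle geometry for the cylindrical volume model
#'
#' Planar measurements cannot resolve depth, so the ventricle depth is
#' assumed equal to its breadth (`D2 = D1`) and the volume follows the
#' cylindrical model `Vol = (pi/4) L D1 D2`. The projected area is
#' reported with the conventional formula `A = pi L D1`; note this is 4x
#' the area of an ellipse with those axes -- we keep the convention as
#' stated but flag the discrepancy here.
#'
#' @param L ventricle length, um.
#' @param D1 ventricle breadth, um.
#' @param D2 ventricle depth, um (default `D1`).
#' @return a `heart_geometry`: L, D1, D2, `A` (um^2), `Vol` (um^3).
#' @export
heart_geometry <- function(L, D1, D2 = D1) {
  stopifnot_positive(L, D1, D2, .names = c("L", "D1", "D2"))
  structure(list(L = L, D1 = D1, D2 = D2, A = pi * L * D1,
                 Vol = pi / 4 * L * D1 * D2),
            class = "heart_geometry")
}

#' Ejection fraction from end-diastolic and end-systolic geometry
#'
#' `EF = 100 (Vol_dias - Vol_sys) / Vol_dias` with the cylindrical volume
#' model of [heart_geometry]. A systolic volume exceeding the diastolic
#' one yields a negative EF with a warning rather than an error.
#'
#' @param diastole,systole `heart_geometry` objects at end-diastole /
#'   end-systole.
#' @return ejection fraction, percent.
#' @export
ejection_fraction <- function(diastole, systole) {
  stopifnot(inherits(diastole, "heart_geometry"), inherits(systole, "heart_geometry"))
  if (diastole$Vol <= 0) stop("zero diastolic volume")
  if (systole$Vol > diastole$Vol)
    warning("systolic volume exceeds diastolic volume: EF reported negative")
  100 * (diastole$Vol - systole$Vol) / diastole$Vol
}

#' Endocardial work from the pressure-strain path
#'
#' Trapezoidal integral of the AVC pressure drop with respect to wall
#' strain along the sampled diastolic path, in Pa-%. The path is open --
#' pressure across the canal is only defined while it carries flow -- so
#' this is a path integral, not a loop area: non-monotone strain excursions
#' legitimately reduce the net value. Positive values mean pressure drives
#' the wall while strain increases.
#'
#' @param strain_pct wall strain samples, percent, ordered by time.
#' @param dP pressure drop samples, Pa, same order.
#' @return endocardial work, Pa-%.
#' @export
endocardial_work <- function(strain_pct, dP) {
  if (length(strain_pct) != length(dP)) stop("strain and pressure lengths differ")
  ok <- is.finite(strain_pct) & is.finite(dP)
  if (sum(ok) < 2) stop("need at least 2 paired samples to integrate")
  pracma::trapz(strain_pct[ok], dP[ok])
}

#' Developmental-stage classification from endocardial work
#'
#' The endocardial work separates the developmental stages of the
#' embryonic heart: below 100 Pa-% the linear heart tube, from 100 to
#' below 300 Pa-% the looped-chamber stage, and at or above 300 Pa-% the
#' fully formed chambers. Boundary values are assigned to the higher
#' stage (half-open intervals), making the classification a partition of
#' all non-negative finite values.
#'
#' @param ew endocardial work, Pa-%.
#' @return one of `"linear"`, `"looped"`, `"formed"` (`NA` with a warning
#'   for negative input).
#' @export
classify_stage <- function(ew) {
  if (!is.finite(ew)) stop("endocardial work must be finite")
  if (ew < 0) {
    warning("negative endocardial work cannot be staged")
    return(NA_character_)
  }
  if (ew < 100) "linear" else if (ew < 300) "looped" else "formed"
}
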