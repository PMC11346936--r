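#' Pipeline configuration
#'
#' Validated bundle of everything one analysis run needs. Either `stack`
#' (an [image_stack]) / `input` (a TIFF path plus `pixel_size`,
#' `frame_rate`) or `phantom` (a [phantom_spec]) must be given, plus the
#' probe loci that anchor the pressure-drop measurements. All coordinates
#' are micrometres in the image frame.
#'
#' @param stack an [image_stack], or `NULL`.
#' @param input path to a multi-page TIFF (alternative to `stack`).
#' @param phantom a [phantom_spec] (alternative to both).
#' @param pixel_size,frame_rate acquisition metadata for `input`; the
#'   presets 0.25 um/px and 0.16 um/px correspond to the 40x and 60x
#'   objectives.
#' @param schedule a [pass_schedule].
#' @param pod_cutoff POD cumulative-energy cutoff (see
#'   [pod_background_removal]).
#' @param avc_upstream,avc_downstream AVC probe loci `c(x, y)` um
#'   (upstream = atrium side). Required.
#' @param oft_upstream,oft_downstream optional OFT probe loci.
#' @param probe_radius disc-averaging radius for probes, um.
#' @param forward unit-ish vector of the forward AVC flow direction
#'   (atrium to ventricle), default `c(1, 0)`.
#' @param ref_locus zero-pressure locus `c(x, y)` um (snapped to the
#'   nearest in-mask node); default the AVC downstream probe.
#' @param ventricle_roi `c(xmin, xmax)` um band containing the ventricle,
#'   used to isolate its mask for geometry/EF.
#' @param canal_strip optional `list(x = c(x0, x1), y = c(y0, y1))` um
#'   region to rebuild by divergence-free reconstruction.
#' @param rheology list: either `ht` (%) directly, or `v_rbc` (um^3),
#'   `depth_of_focus` (um), optional `crop`, `particle_peak` for the
#'   autocorrelation hematocrit estimate.
#' @param rho blood density, kg/m^3.
#' @param inlet_diameter atrial inlet diameter for Re/Wo, um (default:
#'   canal strip width, else 10).
#' @param creeping_flow drop the inertial terms of the pressure gradient
#'   (the Re << 1, Wo << 1 regime); `FALSE` uses the full unsteady form.
#' @param pressure_tol omnidirectional-integration residual tolerance.
#' @param lumen function `f(x, y)` returning logical: the analyst-marked
#'   blood-filled region (chambers plus canals), used as the pressure
#'   integration mask so every integration path stays inside the flow
#'   domain. `NULL` integrates over all valid-vector nodes.
#' @param outlier_threshold normalized-median validation threshold passed
#'   to the PIV engine (default 2).
#' @param validate when the PIV engine runs outlier validation: `"all"`
#'   passes (default) or `"final"` pass only -- the latter is appropriate
#'   when a canal is narrower than the coarse-pass vector spacing, where
#'   its jet is structurally flagged as an outlier on those grids.
#' @param seed RNG seed for the run.
#' @param outdir optional output directory; when given, every stage's
#'   tables are written as CSV before the next stage begins.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(stack = NULL, input = NULL, phantom = NULL,
                            pixel_size = NULL, frame_rate = NULL,
                            schedule = pass_schedule(),
                            pod_cutoff = 0.90,
                            avc_upstream, avc_downstream,
                            oft_upstream = NULL, oft_downstream = NULL,
                            probe_radius = 2,
                            forward = c(1, 0),
                            ref_locus = NULL,
                            ventricle_roi = NULL,
                            canal_strip = NULL,
                            rheology = list(ht = 20),
                            rho = 1025,
                            inlet_diameter = NULL,
                            creeping_flow = TRUE,
                            pressure_tol = 1e-3,
                            lumen = NULL,
                            outlier_threshold = 2,
                            validate = "all",
                            seed = 1L, outdir = NULL) {
  if (is.null(stack) && is.null(input) && is.null(phantom))
    stop("configuration invalid: no input (stack, TIFF path, or phantom spec)")
  if (!is.null(input)) {
    if (!file.exists(input)) stop("input file does not exist: ", input)
    if (is.null(pixel_size) || is.null(frame_rate))
      stop("reading a TIFF needs `pixel_size` and `frame_rate`")
  }
  if (missing(avc_upstream) || missing(avc_downstream) ||
      is.null(avc_upstream) || is.null(avc_downstream))
    stop("configuration invalid: AVC probe loci are required")
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  structure(list(
    stack = stack, input = input, phantom = phantom,
    pixel_size = pixel_size, frame_rate = frame_rate,
    schedule = schedule, pod_cutoff = pod_cutoff,
    avc_upstream = avc_upstream, avc_downstream = avc_downstream,
    oft_upstream = oft_upstream, oft_downstream = oft_downstream,
    probe_radius = probe_radius, forward = forward / sqrt(sum(forward^2)),
    ref_locus = ref_locus %||% avc_downstream,
    ventricle_roi = ventricle_roi, canal_strip = canal_strip,
    rheology = rheology, rho = rho, inlet_diameter = inlet_diameter,
    creeping_flow = creeping_flow, pressure_tol = pressure_tol,
    lumen = lumen, outlier_threshold = outlier_threshold,
    validate = validate,
    seed = as.integer(seed), outdir = outdir
  ), class = "pipeline_config")
}

# Instantaneous (single-pair, no ensemble) velocity series at one locus,
# used to find the cardiac frequency before any phase binning exists.
instantaneous_velocity_series <- function(stack, center_um, window = c(64, 32)) {
  # rectangular interrogation region: wide along the canal axis, narrow
  # across it, so only the canal's motion population is correlated
  if (length(window) == 1) window <- c(window, window)
  fr <- stack$frames
  ps <- stack$pixel_size
  wx <- min(window[1], ncol(fr[, , 1])); wy <- min(window[2], nrow(fr[, , 1]))
  cxp <- center_um[1] / ps; cyp <- center_um[2] / ps
  j0 <- round(min(max(cxp - wx / 2 + 1, 1), ncol(fr[, , 1]) - wx + 1))
  i0 <- round(min(max(cyp - wy / 2 + 1, 1), nrow(fr[, , 1]) - wy + 1))
  apod <- outer(blackman_window(wy), blackman_window(wx))
  nt <- dim(fr)[3]
  u <- numeric(nt - 1); v <- numeric(nt - 1)
  for (t in seq_len(nt - 1)) {
    a <- fr[i0:(i0 + wy - 1), j0:(j0 + wx - 1), t]
    b <- fr[i0:(i0 + wy - 1), j0:(j0 + wx - 1), t + 1]
    if (sd(a) == 0 || sd(b) == 0) next
    pl <- xcorr_ensemble(array((a - mean(a)) * apod, c(wy, wx, 1)),
                         array((b - mean(b)) * apod, c(wy, wx, 1)),
                         c(2L * wy, 2L * wx))
    pk <- locate_peak(pl, c(wx / 2, wy / 2))
    u[t] <- pk$dx; v[t] <- pk$dy
  }
  list(u = u * ps * stack$frame_rate, v = v * ps * stack$frame_rate)
}

#' Run the full analysis pipeline
#'
#' Orchestrates images -> POD background removal -> heart rate -> ensemble
#' PIV -> (optional) divergence-free canal reconstruction -> gradients ->
#' wall segmentation and shear -> hematocrit and Walburn-Schneck viscosity
#' -> pressure field and canal pressure drops -> wall strain -> ejection
#' fraction, Re/Wo, endocardial work and stage. Each stage's outputs are
#' retained in the returned manifest (and written to `outdir` as CSV when
#' configured) before the next stage begins; a failing stage aborts with
#' its name in the error.
#'
#' @param config a [pipeline_config].
#' @return a `pipeline_result`: `summary` (one-row data frame), `field`,
#'   `pressure`, `dP_avc` / `dP_oft`, `strain_series`, `boundary`, `qc`,
#'   and `manifest` (config snapshot, stage timings, output inventory).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  t_start <- Sys.time()
  timings <- c(); outputs <- character(0)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)), call. = FALSE))
    timings[name] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    r
  }
  emit <- function(obj, file, writer = write.csv) {
    if (is.null(config$outdir)) return(invisible(NULL))
    p <- file.path(config$outdir, file)
    writer(obj, p)
    outputs <<- c(outputs, p)
  }

  truth <- NULL
  raw <- stage("load", {
    if (!is.null(config$stack)) config$stack
    else if (!is.null(config$input))
      read_image_stack(config$input, config$pixel_size, config$frame_rate)
    else {
      ph <- generate_phantom_heart(config$phantom)
      truth <- ph$truth
      ph$stack
    }
  })

  filtered <- stage("pod", pod_background_removal(raw, config$pod_cutoff))

  hr_est <- stage("heart_rate", {
    probe_mid <- (config$avc_upstream + config$avc_downstream) / 2
    gap <- sqrt(sum((config$avc_downstream - config$avc_upstream)^2))
    wx <- max(16, round(0.6 * gap / raw$pixel_size))   # stay inside the canal
    wy <- if (!is.null(config$inlet_diameter))
      max(16, round(config$inlet_diameter / raw$pixel_size)) else 32
    s <- instantaneous_velocity_series(filtered, probe_mid, window = c(wx, wy))
    proj <- s$u * config$forward[1] + s$v * config$forward[2]
    heart_rate(proj, raw$frame_rate)
  })

  field <- stage("piv",
    ensemble_piv(filtered, hr_est$period_frames, config$schedule,
                 validate = config$validate,
                 outlier_threshold = config$outlier_threshold))
  emit_field <- function() emit(field, "velocity.csv",
                                function(o, p) write_velocity_csv(o, p))
  emit_field()

  if (!is.null(config$canal_strip)) {
    field <- stage("reconstruct", {
      region <- outer(field$y, field$x, function(yy, xx)
        xx >= config$canal_strip$x[1] & xx <= config$canal_strip$x[2] &
        yy >= config$canal_strip$y[1] & yy <= config$canal_strip$y[2])
      tryCatch(reconstruct_masked_region(field, region),
               error = function(e) { warning("canal reconstruction skipped: ",
                                             conditionMessage(e)); field })
    })
  }

  grads <- stage("gradients", compact_richardson_gradient(field))

  # phase-resolved AVC through-flow (um/s, forward-positive)
  probe_mid <- (config$avc_upstream + config$avc_downstream) / 2
  q_avc <- vapply(seq_len(n_phases(field)), function(p) {
    uv <- sample_field(field, probe_mid[1], probe_mid[2], p)
    uv$u * config$forward[1] + uv$v * config$forward[2]
  }, 0)
  dias <- q_avc > 0

  p_star <- which.max(vapply(seq_len(n_phases(field)), function(p)
    median(sqrt(field$u[, , p]^2 + field$v[, , p]^2)), 0))
  boundary <- stage("segmentation", segment_wall(field, grads, phases = p_star))
  emit(boundary$points[[1]], "wall_boundary.csv",
       function(o, p) write.csv(o, p, row.names = FALSE))
  # ventricle-specific wall: segment the ROI crop so the largest connected
  # component is the ventricle itself (the strain analysis targets the
  # ventricle wall, not the whole heart)
  boundary_vent <- stage("segmentation_ventricle", {
    roi <- config$ventricle_roi
    if (is.null(roi)) boundary
    else {
      sel <- field$x >= roi[1] & field$x <= roi[2]
      sub <- velocity_field(field$u[, sel, , drop = FALSE],
                            field$v[, sel, , drop = FALSE],
                            field$dx, field$dy, x = field$x[sel], y = field$y,
                            phase_times = field$phase_times,
                            mask = field$mask[, sel, , drop = FALSE],
                            pixel_size = field$pixel_size,
                            frame_rate = field$frame_rate)
      tryCatch(segment_wall(sub, phases = p_star),
               error = function(e) {
                 warning("ventricle-crop segmentation failed (",
                         conditionMessage(e), "); falling back to the ",
                         "ROI-filtered whole-heart boundary")
                 b <- boundary$points[[1]]
                 b <- b[b$x >= roi[1] & b$x <= roi[2], , drop = FALSE]
                 structure(list(points = list(b)), class = "wall_boundary")
               })
    }
  })

  shear <- stage("wall_shear", wall_shear_rate(field, boundary, grads))

  rh <- config$rheology
  ht <- stage("hematocrit", {
    if (!is.null(rh$ht)) rh$ht
    else {
      n_rbc <- count_rbc_patterns(raw, crop = rh$crop,
                                  particle_peak = rh$particle_peak)
      crop_area <- if (!is.null(rh$crop)) {
        diff(range(rh$crop$x)) * diff(range(rh$crop$y)) * raw$pixel_size^2
      } else prod(dim(raw$frames)[1:2]) * raw$pixel_size^2
      hematocrit(as.numeric(n_rbc), rh$v_rbc, crop_area, rh$depth_of_focus)
    }
  })
  mu <- stage("viscosity",
              as.numeric(walburn_schneck_viscosity(ht, shear$gamma_peak)))
  fluid <- fluid_properties(rho = config$rho, mu = mu)

  pressure <- stage("pressure", {
    gp <- pressure_gradient(field, fluid, grads,
                            include_inertia = !config$creeping_flow)
    # integrate over the blood-filled domain: the analyst-marked lumen
    # when provided (so paths cannot shortcut through tissue), restricted
    # to nodes that carried valid measurements in most phases
    mask <- apply(field$mask, c(1, 2), mean) >= 0.5
    if (!is.null(config$lumen)) {
      lum <- outer(field$y, field$x, function(yy, xx) config$lumen(xx, yy))
      mask <- mask & lum
    }
    ref_ij <- mask_boundary_node_nearest(mask, field, config$ref_locus)
    pf <- omnidirectional_integrate(gp, reference_node = ref_ij, mask = mask,
                                    tol = config$pressure_tol)
    nondimensionalize(pf, hr_est$hr, mu)
  })

  dP_avc <- stage("pressure_drop", {
    reg <- canal_region("AVC", config$avc_upstream, config$avc_downstream,
                        radius = config$probe_radius)
    canal_pressure_drop(pressure, reg)
  })
  emit(dP_avc, "dP_avc.csv", function(o, p) write.csv(o, p, row.names = FALSE))
  dP_oft <- NULL
  if (!is.null(config$oft_upstream)) {
    reg <- canal_region("OFT", config$oft_upstream, config$oft_downstream,
                        radius = config$probe_radius)
    dP_oft <- canal_pressure_drop(pressure, reg)
    emit(dP_oft, "dP_oft.csv", function(o, p) write.csv(o, p, row.names = FALSE))
  }

  # reference phase: end of ventricle systole = upward zero crossing of the
  # AVC through-flow (start of the diastolic run)
  p_ref <- {
    runs <- which(dias & !c(dias[length(dias)], dias[-length(dias)]))
    if (length(runs)) runs[1] else which.max(q_avc > 0)
  }
  def <- stage("deformation", accumulate_deformation(field, p_ref))
  strain <- stage("strain", green_lagrange(def))
  strain_series <- stage("strain_series",
                         peak_wall_strain(strain, boundary_vent))
  emit(strain_series, "strain.csv", function(o, p) write.csv(o, p, row.names = FALSE))

  ef_geom <- stage("ejection_fraction", {
    bv <- boundary_vent$points[[1]]
    roi <- config$ventricle_roi %||% range(bv$x)
    if (nrow(bv) < 10) {
      warning("too few ventricle boundary points in the ROI; using the ",
              "whole-heart boundary for the geometric anchor")
      bv <- boundary$points[[1]]
    }
    Lstar <- diff(range(bv$x)); Dstar <- diff(range(bv$y))
    # area scale of the ventricle per phase from mean det F over the valid
    # nodes inside the ventricle band
    in_roi <- outer(field$y, field$x, function(yy, xx)
      xx >= roi[1] & xx <= roi[2]) & (apply(field$mask, c(1, 2), mean) >= 0.5)
    detF <- vapply(seq_len(n_phases(field)), function(p) {
      dd <- (def$F11[, , p] * def$F22[, , p] -
             def$F12[, , p] * def$F21[, , p])[in_roi & def$valid[, , p]]
      mean(dd, na.rm = TRUE)
    }, 0)
    s_rel <- sqrt(pmax(detF, 0)) / sqrt(max(detF[p_star], .Machine$double.eps))
    p_dias <- which.max(s_rel); p_sys <- which.min(s_rel)
    dias_g <- heart_geometry(Lstar * s_rel[p_dias], Dstar * s_rel[p_dias])
    sys_g <- heart_geometry(Lstar * s_rel[p_sys], Dstar * s_rel[p_sys])
    list(ef = ejection_fraction(dias_g, sys_g), dias = dias_g, sys = sys_g,
         p_dias = p_dias, p_sys = p_sys)
  })

  ew <- stage("endocardial_work", {
    sel <- dias & is.finite(strain_series$strain_pct) & is.finite(dP_avc$dP)
    ord <- which(sel)
    if (length(ord) < 2) {
      warning("fewer than 2 valid diastolic pressure-strain pairs: ",
              "endocardial work not computable for this recording")
      NA_real_
    } else endocardial_work(strain_series$strain_pct[ord], dP_avc$dP[ord])
  })
  stage_label <- if (is.finite(ew)) classify_stage(max(ew, 0)) else NA_character_

  d_inlet <- config$inlet_diameter %||%
    (if (!is.null(config$canal_strip)) diff(config$canal_strip$y) else 10)
  v_char <- max(abs(q_avc))
  rw <- reynolds_womersley(d_inlet, v_char, fluid, hr_est$hr)

  summary <- data.frame(
    hr_bpm = hr_est$hr, Re = rw$Re, Wo = rw$Wo,
    area_um2 = ef_geom$dias$A, ef_pct = ef_geom$ef,
    ht_pct = ht, mu_Pas = mu, gamma_peak = shear$gamma_peak,
    peak_dP_avc = attr(dP_avc, "peak") %||% NA_real_,
    peak_dP_oft = if (!is.null(dP_oft)) attr(dP_oft, "peak") else NA_real_,
    peak_strain_pct = (attr(strain_series, "peak") %||% NA_real_)[1],
    ew_pa_pct = ew, stage = stage_label)
  emit(summary, "summary.csv", function(o, p) write.csv(o, p, row.names = FALSE))

  qc <- list(piv = attr(field, "qc"),
             pressure_residual = pressure$residual,
             pressure_converged = pressure$converged,
             cycle_drift_um = def$cycle_drift)
  manifest <- list(
    config = config[setdiff(names(config), c("stack", "phantom"))],
    seed = config$seed, timings = timings, outputs = outputs, qc = qc,
    version = as.character(utils::packageVersion("embryoflow")),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  if (!is.null(config$outdir)) {
    mp <- file.path(config$outdir, "manifest.json")
    jsonlite::write_json(manifest[c("seed", "timings", "outputs", "version",
                                    "elapsed_s")], mp, auto_unbox = TRUE)
    outputs <- c(outputs, mp)
  }
  structure(list(summary = summary, field = field, pressure = pressure,
                 dP_avc = dP_avc, dP_oft = dP_oft,
                 strain_series = strain_series, boundary = boundary,
                 heart_rate = hr_est, q_avc = q_avc, diastole = dias,
                 reference_phase = p_ref, ef = ef_geom, truth = truth,
                 qc = qc, manifest = manifest),
            class = "pipeline_result")
}

# Nearest in-mask node to a physical locus that lies on the mask boundary
# (has at least one out-of-mask 4-neighbour); falls back to nearest in-mask
# node if the mask has no boundary (full rectangle).
mask_boundary_node_nearest <- function(mask, field, locus) {
  nb <- shift_mat(mask * 1, 1, 0, 0) * shift_mat(mask * 1, -1, 0, 0) *
        shift_mat(mask * 1, 0, 1, 0) * shift_mat(mask * 1, 0, -1, 0)
  bnd <- mask & nb == 0
  if (!any(bnd)) bnd <- mask
  ij <- which(bnd, arr.ind = TRUE)
  dd <- (field$x[ij[, 2]] - locus[1])^2 + (field$y[ij[, 1]] - locus[2])^2
  ij[which.min(dd), ]
}

#' Write a phantom fixture to disk
#'
#' Renders the phantom and writes the image stack as 16-bit multi-page
#' TIFF, the ground-truth velocity field and pressure-drop series as CSV,
#' and the acquisition metadata as a YAML header.
#'
#' @param spec a [phantom_spec].
#' @param outdir output directory (created if needed).
#' @return invisibly, the list of files written.
#' @export
generate_fixture <- function(spec, outdir) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  }
  ph <- generate_phantom_heart(spec)
  files <- c(
    stack = file.path(outdir, "phantom.tiff"),
    velocity = file.path(outdir, "truth_velocity.csv"),
    dP = file.path(outdir, "truth_dP.csv"),
    meta = file.path(outdir, "metadata.yaml"))
  write_image_stack(ph$stack, files["stack"])
  write_velocity_csv(ph$truth$field, files["velocity"])
  write.csv(ph$truth$dP_series, files["dP"], row.names = FALSE)
  yaml::write_yaml(list(
    pixel_size_um = spec$pixel_size, frame_rate_hz = spec$frame_rate,
    period_s = ph$truth$period, hr_bpm = ph$truth$hr,
    frames_per_cycle = ph$truth$frames_per_cycle,
    ef_pct = ph$truth$ef, ew_pa_pct = ph$truth$ew, seed = spec$seed),
    files["meta"])
  invisible(files)
}
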