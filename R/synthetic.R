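# Seeded generators for everything the pipeline consumes: a plasma bolus
# input, regional 1TC/2TC tissue curves on the 26-frame protocol, the
# arterial-ROI mixture, a background curve, and a vessel phantom volume.

#' Synthetic plasma input (bolus) curve
#'
#' A standard bolus shape: zero until `t0`, linear rise to the peak at
#' `t_peak`, then a tri-exponential decay
#' `A (c1 e^{-mu1 dt} + c2 e^{-mu2 dt} + c3 e^{-mu3 dt})`. Defaults give a
#' sharp first-pass peak, a fast distribution phase and a slow terminal
#' tail, qualitatively matching measured plasma curves for brain PET
#' tracers.
#'
#' @param schedule A [frame_schedule()] on which to frame-average the curve.
#' @param A Peak amplitude (activity units, e.g. kBq/mL), default 100.
#' @param t0 Appearance time (min), default 0.25.
#' @param t_peak Peak time (min), default 0.75.
#' @param frac Mixing fractions of the three decay terms (sum 1).
#' @param rates Decay rates (min^-1), fastest first.
#' @return A plasma-role [tac()]; the continuous curve is attached as
#'   attribute `"fun"`.
#' @export
make_aif <- function(schedule = make_schedule(), A = 100,
                     t0 = 0.25, t_peak = 0.75,
                     frac = c(0.75, 0.2, 0.05),
                     rates = c(3.0, 0.25, 0.012)) {
  if (t_peak <= t0) stop("t_peak must be > t0")
  if (any(frac < 0) || any(rates <= 0) || A < 0)
    stop("amplitudes must be >= 0 and rates > 0")
  frac <- frac / sum(frac)
  fun <- function(t) {
    out <- numeric(length(t))
    rise <- t > t0 & t <= t_peak
    out[rise] <- A * (t[rise] - t0) / (t_peak - t0)
    dec <- t > t_peak
    dt <- t[dec] - t_peak
    out[dec] <- A * (frac[1] * exp(-rates[1] * dt) +
                       frac[2] * exp(-rates[2] * dt) +
                       frac[3] * exp(-rates[3] * dt))
    out
  }
  dt <- 1 / 120
  tt <- seq(0, schedule$end[schedule$F], by = dt)
  out <- tac(schedule, frame_average(tt, fun(tt), schedule), role = "plasma")
  attr(out, "fun") <- fun
  out
}

# heteroscedastic reconstructed-PET-like noise: variance proportional to
# activity divided by frame duration
add_tac_noise <- function(x, level, seed = NULL) {
  if (level <= 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  sd <- level * sqrt(pmax(x$values, 0) / x$schedule$duration)
  v <- x$values + stats::rnorm(length(sd), 0, sd)
  if (x$role %in% c("plasma", "whole_blood")) v <- pmax(v, 0)
  tac(x$schedule, v, role = x$role)
}

#' Cohort kinetic presets
#'
#' Regional 2TC rate constants emulating amyloid-negative ("PiB-",
#' cortical k3/k4 about 0–0.1) and amyloid-positive ("PiB+", cortical k3/k4
#' about 0.3–0.7) subjects. Delivery (K1/k2 = 3.2) is matched to the
#' cerebellar reference so the reference-region condition holds exactly.
#'
#' @param cohort `"PiB+"` or `"PiB-"`.
#' @return Named list of [kinetics_2tc()].
#' @export
cohort_kinetics <- function(cohort = c("PiB+", "PiB-")) {
  cohort <- match.arg(cohort)
  R <- 3.2   # K1/k2 matched across regions
  mk <- function(K1, bp, k4 = 0.04)
    kinetics_2tc(K1, K1 / R, k3 = bp * k4, k4 = if (bp > 0) k4 else 0)
  if (cohort == "PiB+") {
    list(cerebellum = mk(0.30, 0),
         precuneus  = mk(0.28, 0.60),
         prefrontal = mk(0.27, 0.50),
         temporal   = mk(0.29, 0.35),
         caudate    = mk(0.25, 0.30))
  } else {
    list(cerebellum = mk(0.30, 0),
         precuneus  = mk(0.28, 0.08),
         prefrontal = mk(0.27, 0.05),
         temporal   = mk(0.29, 0.10),
         caudate    = mk(0.25, 0.02))
  }
}

#' Generate a complete synthetic subject
#'
#' Produces everything the quantification pipeline consumes: the true
#' plasma input, regional tissue curves (closed-form 2TC forward model on
#' the 26-frame protocol), a background curve, the arterial-ROI curve built
#' by the recovery/spill-over mixture `C_ROIa = r C_B + s C_BG` (with `C_B`
#' obtained from the input via the configured parent-fraction model), and a
#' truth record with every generating parameter. Optionally adds seeded
#' heteroscedastic noise and a vessel phantom.
#'
#' The arterial-ROI curve is generated through the same dual-1TC
#' reconstruction chain the estimator inverts (driven by the reference
#' region's true rate constants), so on noiseless data the IDAIF cost at the
#' true parameters is exactly zero and recovery tests are self-consistent.
#'
#' @param seed Integer seed (drives noise and any phantom randomness).
#' @param cohort `"PiB+"` (default) or `"PiB-"`; ignored if `kinetics`
#'   given.
#' @param kinetics Optional named list of [kinetics_2tc()] (must include
#'   `ref_region`).
#' @param ref_region Region driving the AIF reconstruction, default
#'   `"cerebellum"`.
#' @param noise Noise level (0 = noiseless; 0.3 is PET-like for these
#'   defaults: about 3% CV on late 5-minute frames of a large region).
#' @param schedule Frame schedule, default the 26-frame 60-min protocol.
#' @param r,s True recovery and spill-over coefficients.
#' @param pf A [parent_fraction_model()].
#' @param bg_kinetics Background-region kinetics (1TC).
#' @param aif_args List of arguments for [make_aif()].
#' @param include_phantom Also generate a vessel phantom and a 4D PET
#'   phantom (slower).
#' @return List: `schedule`, `true_aif`, `cp_implied` (input implied by the
#'   generating chain on the frame grid), `tacs` (named region list),
#'   `croia`, `cbg`, `r`, `s`, `pf`, `t_peak`, `truth` (per-region VT/BP/DVR
#'   and all parameters), optionally `phantom` and `pet4d`.
#' @export
make_subject <- function(seed = 1L, cohort = "PiB+", kinetics = NULL,
                         ref_region = "cerebellum", noise = 0,
                         schedule = make_schedule(), r = 0.55, s = 0.15,
                         pf = parent_fraction_model(),
                         bg_kinetics = kinetics_2tc(0.15, 0.05),
                         aif_args = list(), include_phantom = FALSE) {
  if (is.null(kinetics)) kinetics <- cohort_kinetics(cohort)
  if (!ref_region %in% names(kinetics))
    stop("ref_region '", ref_region, "' missing from kinetics")
  aif <- do.call(make_aif, c(list(schedule = schedule), aif_args))
  aif_fun <- attr(aif, "fun")
  tacs <- lapply(kinetics, function(k) forward_2tc(k, aif_fun, schedule))
  cbg <- tac(schedule,
             forward_2tc(bg_kinetics, aif_fun, schedule)$values,
             role = "background")
  kref <- kinetics[[ref_region]]
  t_peak <- detect_tpeak(tacs[[ref_region]])
  theta_true <- idaif_params(
    K1 = kref$K1, k2 = kref$k2, k2a = kref$k2 / (1 + kref$bp),
    s = s, r = r, t_peak = t_peak, t_late = 40)
  cp_implied <- aif_from_tissue(tacs[[ref_region]], theta_true)
  cb <- whole_blood_from_plasma(cp_implied, pf)
  croia <- roia_model(cb, cbg, r, s)
  truth <- list(
    kinetics = kinetics, bg_kinetics = bg_kinetics, r = r, s = s,
    theta = theta_true, noise = noise, seed = seed,
    vt = vapply(kinetics, function(k) k$vt, numeric(1)),
    bp = vapply(kinetics, function(k) k$bp, numeric(1)),
    dvr = vapply(kinetics, function(k) k$dvr, numeric(1)))
  if (noise > 0) {
    set.seed(seed)
    tacs <- lapply(tacs, add_tac_noise, level = noise)
    cbg <- add_tac_noise(cbg, noise)
    croia <- add_tac_noise(croia, noise)
  }
  out <- list(schedule = schedule, true_aif = aif, cp_implied = cp_implied,
              tacs = tacs, croia = croia, cbg = cbg, r = r, s = s, pf = pf,
              t_peak = t_peak, ref_region = ref_region, truth = truth)
  if (include_phantom) {
    out$phantom <- make_vessel_phantom(seed = seed)
    out$pet4d <- make_pet4d_phantom(out$phantom, cb, cbg)
  }
  out
}

#' Curved-tube vessel phantom
#'
#' A bright curved tube (sinusoidal centerline along z) in a mid-intensity
#' tissue background with seeded Gaussian noise — a stand-in for a
#' time-of-flight MR angiography volume — plus the exact geometric vessel
#' mask and a rectangular voxel-index box enclosing the central tube
#' segment (the carotid-box analogue).
#'
#' @param shape Grid size in voxels (length 3), default 64^3.
#' @param voxel_mm Voxel size (mm), default 2 mm isotropic.
#' @param tube_radius_mm Tube radius, default 4 mm.
#' @param curve_amplitude_mm Sinusoidal centerline amplitude, default 8 mm.
#' @param tube_intensity,tissue_intensity,noise_sd Intensity model.
#' @param seed RNG seed for the noise.
#' @return List: `mra` (intensity [volume_image()]), `vessel_mask` (binary),
#'   `box` (3x2 voxel-index matrix), `meta` (geometry record).
#' @export
make_vessel_phantom <- function(shape = c(64L, 64L, 64L),
                                voxel_mm = c(2, 2, 2),
                                tube_radius_mm = 4,
                                curve_amplitude_mm = 8,
                                tube_intensity = 100,
                                tissue_intensity = 20,
                                noise_sd = 2, seed = 1L) {
  ext <- shape * voxel_mm
  cx <- ext[1] / 2; cy <- ext[2] / 2
  if (tube_radius_mm + curve_amplitude_mm > min(cx, cy))
    stop("tube does not fit inside the grid")
  # voxel-center coordinates (mm)
  xs <- (seq_len(shape[1]) - 0.5) * voxel_mm[1]
  ys <- (seq_len(shape[2]) - 0.5) * voxel_mm[2]
  zs <- (seq_len(shape[3]) - 0.5) * voxel_mm[3]
  mask <- array(0, dim = shape)
  for (k in seq_len(shape[3])) {
    x0 <- cx + curve_amplitude_mm * sin(2 * pi * zs[k] / ext[3])
    d2 <- outer((xs - x0)^2, (ys - cy)^2, "+")
    mask[, , k] <- as.numeric(d2 <= tube_radius_mm^2)
  }
  set.seed(seed)
  mra <- tissue_intensity + (tube_intensity - tissue_intensity) * mask +
    array(stats::rnorm(prod(shape), 0, noise_sd), dim = shape)
  kz <- round(shape[3] / 3):round(2 * shape[3] / 3)
  half_xy_mm <- tube_radius_mm + curve_amplitude_mm + 22
  hx <- ceiling(half_xy_mm / voxel_mm[1]); hy <- ceiling(half_xy_mm / voxel_mm[2])
  box <- rbind(c(max(1, round(shape[1] / 2) - hx), min(shape[1], round(shape[1] / 2) + hx)),
               c(max(1, round(shape[2] / 2) - hy), min(shape[2], round(shape[2] / 2) + hy)),
               c(min(kz), max(kz)))
  list(mra = volume_image(mra, voxel_mm),
       vessel_mask = volume_image(mask, voxel_mm),
       box = box,
       meta = list(tube_radius_mm = tube_radius_mm,
                   curve_amplitude_mm = curve_amplitude_mm,
                   length_mm = ext[3], seed = seed))
}

#' Dynamic 4D PET phantom from a vessel phantom
#'
#' Each frame is `cb[f] * vessel + ct[f] * (1 - vessel)` blurred with the
#' PET point-spread function, so that a TAC extracted over an arterial ROI
#' genuinely exhibits partial-volume recovery and tissue spill-over.
#'
#' @param phantom Output of [make_vessel_phantom()].
#' @param cb Whole-blood [tac()] (vessel voxel values).
#' @param ct Tissue [tac()] (non-vessel voxel values).
#' @param fwhm_mm PSF FWHM (mm), default 8.
#' @return 4D [volume_image()] with the schedule of `cb`.
#' @export
make_pet4d_phantom <- function(phantom, cb, ct, fwhm_mm = 8) {
  stopifnot(is_tac(cb), is_tac(ct))
  if (!same_schedule(cb$schedule, ct$schedule))
    stop("cb and ct must share a schedule")
  m <- phantom$vessel_mask$data
  sm <- smooth_to_pet_resolution(phantom$vessel_mask, fwhm_mm)$data
  d <- dim(m)
  F <- cb$schedule$F
  arr <- array(0, dim = c(d, F))
  # linearity: blur(cb*m + ct*(1-m)) = cb*blur(m) + ct*(blur(1) - blur(m));
  # blur(1) with zero padding is 1 in the interior, computed once
  ones_sm <- smooth_to_pet_resolution(
    volume_image(array(1, dim = d), phantom$vessel_mask$voxel_mm), fwhm_mm)$data
  for (f in seq_len(F))
    arr[, , , f] <- cb$values[f] * sm + ct$values[f] * (ones_sm - sm)
  volume_image(arr, phantom$vessel_mask$voxel_mm, schedule = cb$schedule)
}
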