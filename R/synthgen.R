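# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth: tracked ultrasound sweeps of an
# analytic phantom, EMG/torque trials obeying a linear co-contraction model,
# and subject-level crossover datasets with configurable intervention
# effects.

#' Simulate a tracked ultrasound sweep of a tendon phantom
#'
#' Produces ordered frames along the phantom centerline (a straight segment
#' along world z). Each frame carries a probe pose and a regular polygon
#' (in sub-pixel image coordinates) sampling the circular phantom
#' cross-section at that station. The first and last frames carry the two
#' anatomical landmarks (calcaneal notch at station 0, soleus
#' muscle-tendon junction at the far end).
#'
#' Pose noise is isotropic Gaussian translation jitter plus small-angle
#' rotation jitter; the defaults emulate a tracked system with point
#' reconstruction accurate to about +/-0.4 mm.
#'
#' @param phantom A [make_phantom()] object.
#' @param frame_spacing_mm Distance between acquired frames, mm
#'   (default 0.1, a slow steady sweep).
#' @param pose_noise_mm SD of translation jitter per axis, mm (default 0;
#'   use ~0.2 for realistic tracking noise).
#' @param rot_noise_deg SD of small-angle rotation jitter per axis, degrees
#'   (default `pose_noise_mm / 2`, i.e. 0 when translation noise is 0).
#' @param contour_points Vertices per contour polygon (>= 8, default 64).
#' @param seed Integer seed; the sweep is bitwise reproducible from it.
#' @return An object of class `tracked_sweep` with `frames` (each a list of
#'   `pose`, `contour_px`, optional `landmark`), the `calibration` used,
#'   `frame_spacing_mm` and the generating `phantom`.
#' @export
simulate_sweep <- function(phantom, frame_spacing_mm = 0.1,
                           pose_noise_mm = 0,
                           rot_noise_deg = pose_noise_mm / 2,
                           contour_points = 64, seed = 1L) {
  stopifnot(inherits(phantom, "tendon_phantom"))
  if (frame_spacing_mm <= 0) stop("frame_spacing_mm must be positive")
  if (frame_spacing_mm > phantom$length_mm) {
    stop("frame spacing exceeds phantom length; no sweep possible")
  }
  if (contour_points < 8) stop("contour_points must be at least 8")
  set.seed(as.integer(seed))

  L <- phantom$length_mm
  stations <- seq(0, L, by = frame_spacing_mm)
  if (max(stations) < L - 1e-9) stations <- c(stations, L)

  # image geometry: 0.05 mm/px, 800x800 px, tendon centered at (400, 400);
  # calibration shifts the image center onto the probe origin
  sp <- c(0.05, 0.05)
  ctr_px <- c(400, 400)
  cal <- us_calibration(
    pixel_spacing_mm = sp,
    translation = c(-ctr_px[2] * sp[2], -ctr_px[1] * sp[1], 0)
  )

  theta <- 2 * pi * (seq_len(contour_points) - 1) / contour_points
  frames <- vector("list", length(stations))
  for (i in seq_along(stations)) {
    s <- stations[i]
    radius <- sqrt(phantom$area_profile(s / L) / pi)
    contour_px <- cbind(
      row = ctr_px[1] + radius * sin(theta) / sp[1],
      col = ctr_px[2] + radius * cos(theta) / sp[2]
    )
    t_i <- c(0, 0, s)
    R_i <- diag(3)
    if (pose_noise_mm > 0) t_i <- t_i + rnorm(3, sd = pose_noise_mm)
    if (rot_noise_deg > 0) {
      R_i <- rotvec_to_rotmat(rnorm(3, sd = rot_noise_deg * pi / 180))
    }
    fr <- list(pose = probe_pose(R_i, t_i), contour_px = contour_px)
    if (i == 1L) {
      fr$landmark <- list(name = "calcaneal_notch", pixel_rc = ctr_px)
    } else if (i == length(stations)) {
      fr$landmark <- list(name = "soleus_mtj", pixel_rc = ctr_px)
    }
    frames[[i]] <- fr
  }
  structure(list(
    frames = frames, calibration = cal,
    frame_spacing_mm = frame_spacing_mm,
    phantom = phantom,
    params = list(pose_noise_mm = pose_noise_mm,
                  rot_noise_deg = rot_noise_deg,
                  contour_points = contour_points, seed = as.integer(seed))
  ), class = "tracked_sweep")
}

#' @export
print.tracked_sweep <- function(x, ...) {
  cat(sprintf("Tracked sweep: %d frames, %.3g mm spacing, %d-point contours\n",
              length(x$frames), x$frame_spacing_mm,
              x$params$contour_points))
  invisible(x)
}

#' Simulate a study participant
#'
#' Draws the per-participant quantities the measurement chain depends on:
#' plantarflexion MVIC torque, tendon moment arm, resting free-tendon length
#' and mean CSA, true tendon stiffness, and the true antagonist
#' co-contraction parameters (slope and intercept of the tibialis anterior
#' EMG-to-dorsiflexion-torque line).
#'
#' Defaults reflect a healthy recreationally active adult cohort: moment arm
#' 43.3 +/- 3.9 mm, resting free tendon about 50 mm and 44 mm^2 (about
#' 2.2 ml), stiffness centred near 330 N mm^-1 and truncated to the
#' physiologic band.
#'
#' @param seed Integer seed.
#' @param stiffness_band Allowed stiffness range, N mm^-1 (default 200-600);
#'   draws are truncated to it.
#' @return An object of class `simulated_subject`.
#' @export
simulate_subject <- function(seed = 1L, stiffness_band = c(200, 600)) {
  set.seed(as.integer(seed))
  stopifnot(length(stiffness_band) == 2, all(stiffness_band > 0))
  k <- 0
  repeat {
    k <- rnorm(1, 330, 55)
    if (k >= stiffness_band[1] && k <= stiffness_band[2]) break
  }
  subj <- list(
    mvic_torque_Nm    = max(50, rnorm(1, 100, 15)),
    moment_arm_mm     = max(30, rnorm(1, 43.3, 3.93)),
    rest_length_mm    = max(30, rnorm(1, 50, 6)),
    rest_mean_csa_mm2 = max(25, rnorm(1, 44, 6)),
    true_stiffness_Nmm = k,
    cocontraction_true = c(p1 = max(20, rnorm(1, 60, 10)),
                           p2 = max(0.1, rnorm(1, 1, 0.3))),
    seed = as.integer(seed)
  )
  structure(subj, class = "simulated_subject")
}

#' @export
print.simulated_subject <- function(x, ...) {
  cat("Simulated subject\n")
  cat(sprintf("  MVIC torque:    %.1f N m\n", x$mvic_torque_Nm))
  cat(sprintf("  moment arm:     %.1f mm\n", x$moment_arm_mm))
  cat(sprintf("  rest length:    %.1f mm, mean CSA %.1f mm^2\n",
              x$rest_length_mm, x$rest_mean_csa_mm2))
  cat(sprintf("  true stiffness: %.1f N mm^-1\n", x$true_stiffness_Nmm))
  cat(sprintf("  co-contraction: P1 = %.1f, P2 = %.2f\n",
              x$cocontraction_true["p1"], x$cocontraction_true["p2"]))
  invisible(x)
}

# Band-limited (20-450 Hz) unit-RMS noise carrier, amplitude-modulated so
# the RMS envelope of the raw signal tracks `envelope`.
modulated_emg <- function(envelope, fs_hz) {
  n <- length(envelope)
  carrier <- rnorm(n)
  if (fs_hz > 2 * 450) {
    bf <- signal::butter(4, c(20, 450) / (fs_hz / 2), type = "pass")
    carrier <- signal::filtfilt(bf, carrier)
  }
  carrier <- carrier / sqrt(mean(carrier^2))
  envelope * carrier
}

#' Simulate a paired torque and EMG trial
#'
#' Two trial modes:
#' * `"DF_MVIC"`: a ramped maximal dorsiflexion effort. Torque ramps from 0
#'   to the dorsiflexion maximum (30% of plantarflexion MVIC) and holds; the
#'   tibialis anterior EMG envelope is tied to torque through the subject's
#'   true co-contraction line `torque = P1 * envelope + P2`, plus additive
#'   Gaussian torque noise. Used to fit the co-contraction model.
#' * `"PF_staged"`: a ramp-and-hold plantarflexion at
#'   `target_fraction x MVIC` (35/55/75%) sustained for the scanning
#'   duration. The recorded *net* torque is the true plantarflexion torque
#'   minus the antagonist dorsiflexion torque implied by the simulated TA
#'   co-contraction, so adding the modelled antagonist torque back recovers
#'   the true torque.
#'
#' @param subject A [simulate_subject()] object.
#' @param mode `"DF_MVIC"` or `"PF_staged"`.
#' @param target_fraction Target torque as a fraction of MVIC; for staged
#'   mode one of 0.35, 0.55, 0.75.
#' @param duration_s Trial duration, s (default 8, the standardized scanning
#'   duration; must be positive).
#' @param fs_hz Sampling rate, Hz (default 1000).
#' @param noise_sd Additive torque noise SD, N m (default 0).
#' @param ramp_s Ramp time to target, s (default 2).
#' @param coactivation Staged-mode TA co-activation level: TA envelope as a
#'   fraction of its dorsiflexion-MVIC envelope (default 0.08).
#' @param seed Integer seed.
#' @return A list of class `emg_torque_trial`: `torque` and `emg` (both
#'   [ts_signal()]), `envelope_true`, `true_pf_torque_Nm` (staged mode),
#'   `fs_hz` and the call parameters.
#' @export
simulate_emg_torque_trial <- function(subject,
                                      mode = c("DF_MVIC", "PF_staged"),
                                      target_fraction = 0.75,
                                      duration_s = 8, fs_hz = 1000,
                                      noise_sd = 0, ramp_s = 2,
                                      coactivation = 0.08, seed = 1L) {
  stopifnot(inherits(subject, "simulated_subject"))
  mode <- match.arg(mode)
  if (duration_s <= 0) stop("duration_s must be positive")
  if (mode == "PF_staged" &&
      !isTRUE(any(abs(target_fraction - c(0.35, 0.55, 0.75)) < 1e-9))) {
    stop("staged target_fraction must be one of 0.35, 0.55, 0.75")
  }
  set.seed(as.integer(seed))
  n <- round(duration_s * fs_hz)
  t <- (seq_len(n) - 1) / fs_hz
  p1 <- subject$cocontraction_true[["p1"]]
  p2 <- subject$cocontraction_true[["p2"]]
  ramp <- pmin(1, t / max(ramp_s, 1e-9))

  if (mode == "DF_MVIC") {
    # torque starts from the passive level p2 (zero TA activity), so the
    # (envelope, torque) pairs lie on the co-contraction line throughout
    df_max <- 0.30 * subject$mvic_torque_Nm
    torque_true <- p2 + (df_max - p2) * ramp
    envelope <- pmax(0, (torque_true - p2) / p1)
    torque <- torque_true + if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
    true_pf <- NULL
  } else {
    target <- target_fraction * subject$mvic_torque_Nm
    true_pf <- target * ramp
    df_max_env <- (0.30 * subject$mvic_torque_Nm - p2) / p1
    envelope <- coactivation * df_max_env * ramp
    antagonist <- p1 * envelope + p2
    torque <- true_pf - antagonist +
      if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
  }
  emg <- modulated_emg(envelope, fs_hz)
  structure(list(
    torque = ts_signal(torque, fs_hz, "N m"),
    emg = ts_signal(emg, fs_hz, "mV"),
    envelope_true = ts_signal(envelope, fs_hz, "mV"),
    true_pf_torque_Nm = true_pf,
    mode = mode, target_fraction = target_fraction,
    ramp_s = ramp_s, fs_hz = fs_hz, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "emg_torque_trial")
}

#' Intervention effect specification for the crossover generator
#'
#' Per-intervention mean change and SD of change for tendon volume (ml) and
#' stiffness (N mm^-1), plus baseline distributions and the within-subject
#' correlation of baselines across sessions. Defaults are calibrated to the
#' acute-loading contrasts the pipeline is designed to detect: the
#' long-duration high-intensity protocol produces the largest reductions,
#' the short-duration protocol leaves volume essentially unchanged while
#' stiffness increases, and the long-duration low-intensity protocol sits
#' in between.
#'
#' @param interventions Character vector of intervention labels.
#' @param volume_change_ml,stiffness_change_Nmm Named mean changes
#'   (post - pre) per intervention.
#' @param volume_change_sd_ml,stiffness_change_sd_Nmm SDs of the change
#'   scores (>= 0).
#' @param baseline_volume_ml,baseline_volume_sd_ml Between-subject baseline
#'   volume distribution.
#' @param baseline_stiffness_Nmm,baseline_stiffness_sd_Nmm Between-subject
#'   baseline stiffness distribution.
#' @param within_subject_correlation Correlation of a subject's baselines
#'   across interventions, in `[-1, 1]` (default 0.8).
#' @param seed Integer seed.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(interventions = c("8s75", "2s75", "8s35"),
                        volume_change_ml = c("8s75" = -0.3, "2s75" = -0.05,
                                             "8s35" = -0.1),
                        stiffness_change_Nmm = c("8s75" = -67.35,
                                                 "2s75" = 37.78,
                                                 "8s35" = -36.45),
                        volume_change_sd_ml = 0.12,
                        stiffness_change_sd_Nmm = 45,
                        baseline_volume_ml = 2.2,
                        baseline_volume_sd_ml = 0.5,
                        baseline_stiffness_Nmm = 328,
                        baseline_stiffness_sd_Nmm = 55,
                        within_subject_correlation = 0.8,
                        seed = 1L) {
  stopifnot(all(interventions %in% names(volume_change_ml)),
            all(interventions %in% names(stiffness_change_Nmm)))
  if (volume_change_sd_ml < 0 || stiffness_change_sd_Nmm < 0 ||
      baseline_volume_sd_ml < 0 || baseline_stiffness_sd_Nmm < 0) {
    stop("standard deviations must be non-negative")
  }
  if (abs(within_subject_correlation) > 1) {
    stop("within_subject_correlation must lie in [-1, 1]")
  }
  structure(list(
    interventions = interventions,
    volume_change_ml = volume_change_ml[interventions],
    stiffness_change_Nmm = stiffness_change_Nmm[interventions],
    volume_change_sd_ml = volume_change_sd_ml,
    stiffness_change_sd_Nmm = stiffness_change_sd_Nmm,
    baseline_volume_ml = baseline_volume_ml,
    baseline_volume_sd_ml = baseline_volume_sd_ml,
    baseline_stiffness_Nmm = baseline_stiffness_Nmm,
    baseline_stiffness_sd_Nmm = baseline_stiffness_sd_Nmm,
    within_subject_correlation = within_subject_correlation,
    seed = as.integer(seed)
  ), class = "effect_spec")
}

#' Simulate a crossover trial dataset
#'
#' Each subject undergoes every intervention (in a seeded random period
#' order) with pre and post measurements of tendon volume and stiffness.
#' A subject's baseline is a shared random effect (variance fraction given
#' by the within-subject correlation) plus independent session noise, so
#' baselines are identical across interventions in expectation; the post
#' value is the pre value plus the intervention-specific change drawn from
#' the effect specification.
#'
#' @param n_subjects Number of subjects (>= 2; 16 is the design the
#'   statistics target).
#' @param spec An [effect_spec()].
#' @param baselines Optional data frame (`subject`, `volume_ml`,
#'   `stiffness_Nmm`) anchoring each subject's expected baseline, e.g.
#'   measured values from the reconstruction chain; defaults to draws from
#'   the spec's baseline distribution.
#' @return A data frame of class `crossover_dataset` with columns
#'   `subject`, `intervention`, `period`, `time` (`pre`/`post`),
#'   `volume_ml`, `stiffness_Nmm`.
#' @export
simulate_crossover_dataset <- function(n_subjects = 16, spec = effect_spec(),
                                       baselines = NULL) {
  stopifnot(inherits(spec, "effect_spec"))
  if (n_subjects < 2) stop("need at least 2 subjects")
  set.seed(spec$seed)
  iv <- spec$interventions
  k <- length(iv)
  rho <- spec$within_subject_correlation

  if (is.null(baselines)) {
    subj_vol <- rnorm(n_subjects, spec$baseline_volume_ml,
                      sqrt(abs(rho)) * spec$baseline_volume_sd_ml)
    subj_stiff <- rnorm(n_subjects, spec$baseline_stiffness_Nmm,
                        sqrt(abs(rho)) * spec$baseline_stiffness_sd_Nmm)
  } else {
    stopifnot(nrow(baselines) == n_subjects)
    subj_vol <- baselines$volume_ml
    subj_stiff <- baselines$stiffness_Nmm
  }
  sess_sd_vol <- sqrt(max(0, 1 - abs(rho))) * spec$baseline_volume_sd_ml
  sess_sd_stiff <- sqrt(max(0, 1 - abs(rho))) * spec$baseline_stiffness_sd_Nmm

  rows <- vector("list", n_subjects * k)
  r <- 0L
  for (s in seq_len(n_subjects)) {
    periods <- sample(k)
    for (j in seq_len(k)) {
      pre_vol <- subj_vol[s] + rnorm(1, sd = sess_sd_vol)
      pre_stiff <- subj_stiff[s] + rnorm(1, sd = sess_sd_stiff)
      d_vol <- rnorm(1, spec$volume_change_ml[iv[j]],
                     spec$volume_change_sd_ml)
      d_stiff <- rnorm(1, spec$stiffness_change_Nmm[iv[j]],
                       spec$stiffness_change_sd_Nmm)
      r <- r + 1L
      rows[[r]] <- data.frame(
        subject = sprintf("S%02d", s), intervention = iv[j],
        period = periods[j],
        time = c("pre", "post"),
        volume_ml = c(pre_vol, pre_vol + d_vol),
        stiffness_Nmm = c(pre_stiff, pre_stiff + d_stiff)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("crossover_dataset", "data.frame")
  out
}
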