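# End-to-end orchestration: intervention presets, per-subject measurement
# chain (sweeps -> geometry, EMG/torque -> force, force-elongation ->
# stiffness/modulus), crossover dataset assembly and group statistics.

#' Isometric intervention specification
#'
#' Load parameters of one intervention: contraction duration, intensity
#' (fraction of MVIC), repetitions, sets and the rest scheme. The three
#' shipped presets share the loading volume (10 repetitions x 4 sets) and
#' rest times (10 s between repetitions, 3 min between sets) and differ in
#' duration/intensity:
#' * `"8s75"`: 8 s contractions at 75% MVIC
#' * `"2s75"`: 2 s contractions at 75% MVIC
#' * `"8s35"`: 8 s contractions at 35% MVIC
#'
#' @param name Label.
#' @param contraction_duration_s Contraction duration, s.
#' @param intensity_fraction Target intensity as a fraction of MVIC.
#' @param repetitions,sets Loading volume (defaults 10 x 4).
#' @param rest_between_reps_s,rest_between_sets_s Rest scheme, s.
#' @return Object of class `intervention_spec`.
#' @export
intervention_spec <- function(name, contraction_duration_s,
                              intensity_fraction, repetitions = 10,
                              sets = 4, rest_between_reps_s = 10,
                              rest_between_sets_s = 180) {
  stopifnot(contraction_duration_s > 0, intensity_fraction > 0,
            intensity_fraction <= 1, repetitions >= 1, sets >= 1)
  structure(list(
    name = name,
    contraction_duration_s = contraction_duration_s,
    intensity_fraction = intensity_fraction,
    repetitions = repetitions, sets = sets,
    rest_between_reps_s = rest_between_reps_s,
    rest_between_sets_s = rest_between_sets_s
  ), class = "intervention_spec")
}

#' @rdname intervention_spec
#' @param preset One of `"8s75"`, `"2s75"`, `"8s35"`.
#' @export
intervention_preset <- function(preset = c("8s75", "2s75", "8s35")) {
  preset <- match.arg(preset)
  switch(preset,
    "8s75" = intervention_spec("8s75", 8, 0.75),
    "2s75" = intervention_spec("2s75", 2, 0.75),
    "8s35" = intervention_spec("8s35", 8, 0.35)
  )
}

#' @export
print.intervention_spec <- function(x, ...) {
  cat(sprintf("Intervention %s: %g s x %d reps x %d sets at %.0f%% MVIC (total load %g s)\n",
              x$name, x$contraction_duration_s, x$repetitions, x$sets,
              100 * x$intensity_fraction, total_load_duration(x)))
  invisible(x)
}

#' Total loading duration of an intervention
#'
#' Contraction duration times repetitions times sets (time under tension,
#' excluding rest). The 8 s preset gives 320 s.
#'
#' @param spec An [intervention_spec()].
#' @return Seconds.
#' @export
total_load_duration <- function(spec) {
  stopifnot(inherits(spec, "intervention_spec"))
  spec$contraction_duration_s * spec$repetitions * spec$sets
}

#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run; a run is reproducible from its
#' configuration alone. Serializable to YAML via [write_run_config()].
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_subjects Cohort size (default 16).
#' @param frame_spacing_mm Sweep frame spacing (default 0.1 mm).
#' @param pose_noise_mm Sweep pose noise SD (default 0.2 mm, ~ +/-0.4 mm
#'   point reconstruction error).
#' @param contour_points Contour polygon vertices (default 64).
#' @param slice_interval_mm Contouring interval for reconstruction
#'   (default 5 mm).
#' @param staged_fractions Staged contraction levels (default 35/55/75%).
#' @param scan_duration_s Staged scan duration (default 8 s).
#' @param emg_noise_sd Torque noise SD during trials, N m (default 0.5).
#' @param effects An [effect_spec()]; its seed is overridden by `seed`.
#' @param force_through_origin Stiffness/modulus fit option.
#' @param icc_form `"agreement"` or `"consistency"`.
#' @param outdir Optional output directory for CSV/JSON artefacts.
#' @return Object of class `run_config` (a list).
#' @export
run_config <- function(seed = 1L, n_subjects = 16,
                       frame_spacing_mm = 0.1, pose_noise_mm = 0.2,
                       contour_points = 64, slice_interval_mm = 5,
                       staged_fractions = c(0.35, 0.55, 0.75),
                       scan_duration_s = 8, emg_noise_sd = 0.5,
                       effects = effect_spec(),
                       force_through_origin = FALSE,
                       icc_form = "agreement", outdir = NULL) {
  structure(list(
    seed = as.integer(seed), n_subjects = n_subjects,
    frame_spacing_mm = frame_spacing_mm, pose_noise_mm = pose_noise_mm,
    contour_points = contour_points, slice_interval_mm = slice_interval_mm,
    staged_fractions = staged_fractions, scan_duration_s = scan_duration_s,
    emg_noise_sd = emg_noise_sd, effects = effects,
    force_through_origin = force_through_origin, icc_form = icc_form,
    outdir = outdir
  ), class = "run_config")
}

# Deterministic per-stage sub-seed, kept well below 2^31 (arithmetic in
# doubles to avoid integer overflow when chaining).
sub_seed <- function(seed, stage, i = 0L) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(stage) * 101 +
                as.numeric(i)) %% 2000000011)
}

subject_phantom <- function(subject, length_mm = subject$rest_length_mm) {
  # mild linear taper around the subject's mean CSA; total volume preserved
  make_phantom(length_mm, list(type = "linear",
                               area_start = 1.2 * subject$rest_mean_csa_mm2,
                               area_end = 0.8 * subject$rest_mean_csa_mm2))
}

#' Measure one subject through the full chain
#'
#' Simulates and analyses a complete baseline measurement session for one
#' subject: two resting sweeps and two sweeps per staged level (scanned,
#' reconstructed, repeat scans averaged); dorsiflexion trials to fit the
#' co-contraction model; staged plantarflexion trials processed through
#' the bandpass + RMS envelope + co-contraction correction + moment-arm
#' chain to per-level tendon force; and the stiffness and Young's modulus
#' fits.
#'
#' @param subject A [simulate_subject()] object.
#' @param config A [run_config()].
#' @param seed Seed for this subject's measurement session.
#' @return List with `geometry` (resting [reconstruct_geometry()] result,
#'   first scan), `rest_length_mm`, `mean_csa_mm2`, `volume_ml`,
#'   `cocontraction` model, `forces` data frame (`level`, `force_N`,
#'   `length_mm`, `elongation_mm`), `stiffness`, `modulus` and `mvic_Nm`.
#' @export
measure_subject <- function(subject, config = run_config(), seed = config$seed) {
  stopifnot(inherits(subject, "simulated_subject"))
  fr <- config$staged_fractions
  arm <- moment_arm(subject$moment_arm_mm + 6.7, 6.7) # value = subject arm

  scan_state <- function(length_mm, i) {
    ph <- subject_phantom(subject, length_mm)
    geos <- lapply(1:2, function(r) {
      sw <- simulate_sweep(ph, config$frame_spacing_mm,
                           pose_noise_mm = config$pose_noise_mm,
                           contour_points = config$contour_points,
                           seed = sub_seed(seed, 1L, 10L * i + r))
      reconstruct_geometry(sw, config$slice_interval_mm)
    })
    list(length_mm = mean(vapply(geos, `[[`, numeric(1), "length_mm")),
         geometry = geos[[1]])
  }

  rest <- scan_state(subject$rest_length_mm, 0L)

  # co-contraction fit from up to 3 dorsiflexion trials
  df_trials <- lapply(1:3, function(i) {
    tr <- simulate_emg_torque_trial(subject, "DF_MVIC", duration_s = 5,
                                    noise_sd = config$emg_noise_sd,
                                    seed = sub_seed(seed, 2L, i))
    env <- rms_envelope(bandpass(tr$emg))
    data.frame(envelope = env$samples, torque_Nm = tr$torque$samples)
  })
  ccm <- fit_cocontraction(df_trials)

  # staged levels: torque/EMG trial -> true torque -> force; sweeps -> length
  levels <- lapply(seq_along(fr), function(j) {
    f <- fr[j]
    tr <- simulate_emg_torque_trial(subject, "PF_staged", target_fraction = f,
                                    duration_s = config$scan_duration_s,
                                    noise_sd = config$emg_noise_sd,
                                    seed = sub_seed(seed, 3L, j))
    env <- rms_envelope(bandpass(tr$emg))
    true_tq <- true_pf_torque(tr$torque, env, ccm)
    pl <- plateau_torque(true_tq, ramp_s = tr$ramp_s,
                         target_Nm = f * subject$mvic_torque_Nm)
    force <- tendon_force(pl$torque_Nm, arm)
    true_force <- f * subject$mvic_torque_Nm / (subject$moment_arm_mm / 1000)
    elong <- true_force / subject$true_stiffness_Nmm
    st <- scan_state(subject$rest_length_mm + elong, j)
    data.frame(level = sprintf("%.0f", 100 * f), force_N = force,
               length_mm = st$length_mm, retrial = pl$retrial)
  })
  lv <- do.call(rbind, levels)

  sts <- staged_trial_set(
    rest_lengths_mm = rest$length_mm,
    level_lengths_mm = setNames(as.list(lv$length_mm), lv$level),
    level_forces_N = setNames(lv$force_N, lv$level)
  )
  mech <- analyze_staged(sts, mean_csa_mm2 = rest$geometry$mean_csa_mm2,
                         force_through_origin = config$force_through_origin)

  list(
    geometry = rest$geometry,
    rest_length_mm = rest$length_mm,
    mean_csa_mm2 = rest$geometry$mean_csa_mm2,
    volume_ml = rest$geometry$volume_ml,
    cocontraction = ccm,
    forces = cbind(lv, elongation_mm = sts$levels$elongation_mm),
    stiffness = mech$stiffness,
    modulus = mech$modulus,
    mvic_Nm = subject$mvic_torque_Nm
  )
}

#' Run the full pipeline
#'
#' Simulates a cohort, measures every subject through the reconstruction
#' and force chains, assembles the crossover dataset (pre/post outcomes
#' per intervention anchored at each subject's measured baseline), and
#' runs the group statistics: repeated-measures ANOVA, interaction
#' contrasts and simple effects for volume and stiffness, plus a
#' change-score summary per intervention.
#'
#' When `config$outdir` is set, per-subject measurements and every group
#' table are written as CSV and a run log as JSON.
#'
#' @param config A [run_config()].
#' @return Object of class `pipeline_result`: `measurements` (per-subject
#'   data frame), `dataset` (crossover data), `anova`, `contrasts`,
#'   `simple_effects` (each a list with `volume_ml`/`stiffness_Nmm`),
#'   `change_summary` and `log`.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    simulate_subject(seed = sub_seed(config$seed, 0L, i))
  })
  meas <- lapply(seq_along(subjects), function(i) {
    m <- measure_subject(subjects[[i]], config,
                         seed = sub_seed(config$seed, 5L, i))
    data.frame(
      subject = sprintf("S%02d", i),
      rest_length_mm = m$rest_length_mm,
      mean_csa_mm2 = m$mean_csa_mm2,
      volume_ml = m$volume_ml,
      stiffness_Nmm = m$stiffness$stiffness_Nmm,
      modulus_MPa = m$modulus$modulus_MPa,
      p1_slope = m$cocontraction$p1_slope,
      p2_intercept = m$cocontraction$p2_intercept,
      true_stiffness_Nmm = subjects[[i]]$true_stiffness_Nmm,
      mvic_Nm = m$mvic_Nm
    )
  })
  measurements <- do.call(rbind, meas)

  eff <- config$effects
  eff$seed <- sub_seed(config$seed, 7L)
  dataset <- simulate_crossover_dataset(
    config$n_subjects, eff,
    baselines = data.frame(subject = measurements$subject,
                           volume_ml = measurements$volume_ml,
                           stiffness_Nmm = measurements$stiffness_Nmm)
  )

  outcomes <- c("volume_ml", "stiffness_Nmm")
  anova <- lapply(outcomes, function(o) rm_anova_2x3(dataset, o))
  contrasts <- lapply(outcomes, function(o) interaction_contrasts(dataset, o))
  simple <- lapply(outcomes, function(o) simple_effects(dataset, o))
  names(anova) <- names(contrasts) <- names(simple) <- outcomes

  change_summary <- do.call(rbind, lapply(outcomes, function(o) {
    cs <- change_scores(dataset, o)
    agg <- do.call(rbind, lapply(split(cs$change, cs$intervention), function(v) {
      data.frame(mean_change = mean(v), sd_change = sd(v))
    }))
    data.frame(outcome = o, intervention = rownames(agg), agg,
               row.names = NULL)
  }))

  log <- list(
    seed = config$seed, n_subjects = config$n_subjects,
    frame_spacing_mm = config$frame_spacing_mm,
    pose_noise_mm = config$pose_noise_mm,
    contour_points = config$contour_points,
    slice_interval_mm = config$slice_interval_mm,
    force_through_origin = config$force_through_origin,
    icc_form = config$icc_form,
    package_version = as.character(utils::packageVersion("tendonmech")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  res <- structure(list(
    measurements = measurements, dataset = dataset,
    anova = anova, contrasts = contrasts, simple_effects = simple,
    change_summary = change_summary, log = log, config = config
  ), class = "pipeline_result")

  if (!is.null(config$outdir)) write_pipeline_result(res, config$outdir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run: %d subjects (seed %d)\n",
              x$log$n_subjects, x$log$seed))
  for (o in names(x$anova)) {
    tb <- x$anova[[o]]$table
    i <- tb$effect == "time:intervention"
    cat(sprintf("  %s interaction: F(%d,%d) = %.3f, p = %.3g\n",
                o, tb$df1[i], tb$df2[i], tb$F[i], tb$p[i]))
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' CSV tables (per-subject measurements, crossover dataset, ANOVA tables,
#' contrasts, simple effects, change summary) plus a JSON run log.
#'
#' @param result A [run_all()] result.
#' @param outdir Directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_result <- function(result, outdir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    write.csv(df, file.path(outdir, name), row.names = FALSE)
  }
  wcsv(result$measurements, "measurements.csv")
  wcsv(as.data.frame(result$dataset), "crossover_dataset.csv")
  for (o in names(result$anova)) {
    wcsv(result$anova[[o]]$table, sprintf("anova_%s.csv", o))
    wcsv(result$contrasts[[o]], sprintf("contrasts_%s.csv", o))
    wcsv(result$simple_effects[[o]], sprintf("simple_effects_%s.csv", o))
  }
  wcsv(result$change_summary, "change_summary.csv")
  jsonlite::write_json(result$log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Change-score plot (one panel per outcome)
#'
#' Mean change score per intervention with +/- SD error bars, in the style
#' of a trial's change-score figure. Requires ggplot2.
#'
#' @param result A [run_all()] result (or a `change_summary`-shaped data
#'   frame).
#' @return A ggplot object.
#' @export
plot_change_scores <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  cs <- if (inherits(result, "pipeline_result")) result$change_summary else result
  ggplot2::ggplot(cs, ggplot2::aes(x = .data$intervention,
                                   y = .data$mean_change)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_change - .data$sd_change,
      ymax = .data$mean_change + .data$sd_change), width = 0.2) +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = "Intervention", y = "Change score (post - pre)") +
    ggplot2::theme_minimal()
}
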