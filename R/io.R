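# Interchange formats. Sweeps travel as JSON (pose quaternion +
# translation, contour vertex lists, landmark flags), signals and datasets
# as CSV, geometry as JSON, run configurations as YAML. World coordinates
# are a right-handed frame in mm; pixels are (row, col) from the top-left.

#' Write / read a tracked sweep as JSON
#'
#' Frames are serialized with pose as unit quaternion `(w,x,y,z)` plus
#' translation (mm), the contour as a vertex list in pixel (row, col)
#' coordinates, and landmark flags for the two anatomical sites.
#'
#' @param sweep A [simulate_sweep()] object.
#' @param path Output file.
#' @return `path` (write) / a `tracked_sweep` (read), invisibly for write.
#' @export
write_sweep_json <- function(sweep, path) {
  stopifnot(inherits(sweep, "tracked_sweep"))
  frames <- lapply(sweep$frames, function(fr) {
    out <- list(
      quaternion = rotmat_to_quat(fr$pose$rotation),
      translation_mm = fr$pose$translation,
      contour_px = unname(apply(fr$contour_px, 1, function(v) c(v[1], v[2]),
                                simplify = FALSE))
    )
    if (!is.null(fr$landmark)) {
      out$landmark <- list(name = fr$landmark$name,
                           pixel_rc = as.numeric(fr$landmark$pixel_rc))
    }
    out
  })
  obj <- list(
    coordinate_frame = "right-handed world frame, mm; pixel origin top-left, (row, col)",
    frame_spacing_mm = sweep$frame_spacing_mm,
    calibration = list(
      pixel_spacing_mm = sweep$calibration$pixel_spacing_mm,
      quaternion = rotmat_to_quat(sweep$calibration$rotation),
      translation_mm = sweep$calibration$translation
    ),
    frames = frames
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sweep_json
#' @export
read_sweep_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  cal <- us_calibration(
    pixel_spacing_mm = as.numeric(obj$calibration$pixel_spacing_mm),
    rotation = as.numeric(obj$calibration$quaternion),
    translation = as.numeric(obj$calibration$translation_mm)
  )
  frames <- lapply(obj$frames, function(fr) {
    contour <- do.call(rbind, lapply(fr$contour_px, as.numeric))
    colnames(contour) <- c("row", "col")
    out <- list(
      pose = probe_pose(as.numeric(fr$quaternion),
                        as.numeric(fr$translation_mm)),
      contour_px = contour
    )
    if (!is.null(fr$landmark)) {
      out$landmark <- list(name = fr$landmark$name,
                           pixel_rc = as.numeric(fr$landmark$pixel_rc))
    }
    out
  })
  structure(list(frames = frames, calibration = cal,
                 frame_spacing_mm = as.numeric(obj$frame_spacing_mm),
                 params = list()),
            class = "tracked_sweep")
}

#' Write / read a torque + EMG trial as CSV
#'
#' Columns `time_s`, `torque_Nm`, `emg_V`.
#'
#' @param trial A [simulate_emg_torque_trial()] result, or a list with
#'   `torque` and `emg` [ts_signal()]s.
#' @param path File path.
#' @export
write_signal_csv <- function(trial, path) {
  tq <- trial$torque; emg <- trial$emg
  stopifnot(inherits(tq, "ts_signal"), inherits(emg, "ts_signal"),
            length(tq$samples) == length(emg$samples))
  df <- data.frame(
    time_s = (seq_along(tq$samples) - 1) / tq$fs_hz,
    torque_Nm = tq$samples,
    emg_V = emg$samples
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_s", "torque_Nm", "emg_V") %in% names(df)))
  fs <- 1 / stats::median(diff(df$time_s))
  list(torque = ts_signal(df$torque_Nm, fs, "N m"),
       emg = ts_signal(df$emg_V, fs, "mV"))
}

#' Write / read a crossover dataset as CSV
#'
#' Columns `subject`, `intervention`, `period`, `time`, `volume_ml`,
#' `stiffness_Nmm`.
#'
#' @param dataset A [simulate_crossover_dataset()] data frame.
#' @param path File path.
#' @export
write_crossover_csv <- function(dataset, path) {
  write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_crossover_csv
#' @export
read_crossover_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "intervention", "period", "time")
  stopifnot(all(need %in% names(df)))
  class(df) <- c("crossover_dataset", "data.frame")
  df
}

#' Write tendon geometry as JSON (+ per-slice CSV)
#'
#' The JSON holds length, mean CSA, volume and landmarks; the optional CSV
#' has one row per slice (`station_mm`, `area_mm2`).
#'
#' @param geometry A [reconstruct_geometry()] result.
#' @param path JSON path.
#' @param slices_csv Optional CSV path for the slice table.
#' @export
write_geometry_json <- function(geometry, path, slices_csv = NULL) {
  stopifnot(inherits(geometry, "tendon_geometry"))
  obj <- list(
    coordinate_frame = "right-handed world frame, mm",
    length_mm = geometry$length_mm,
    mean_csa_mm2 = geometry$mean_csa_mm2,
    volume_ml = geometry$volume_ml,
    landmarks = lapply(geometry$landmarks, as.numeric),
    slices = geometry$slices
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  if (!is.null(slices_csv)) {
    write.csv(geometry$slices, slices_csv, row.names = FALSE)
  }
  invisible(path)
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()] object.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- unclass(config)
  obj$effects <- unclass(obj$effects)
  obj$effects$volume_change_ml <- as.list(obj$effects$volume_change_ml)
  obj$effects$stiffness_change_Nmm <- as.list(obj$effects$stiffness_change_Nmm)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  eff <- obj$effects
  effects <- effect_spec(
    interventions = as.character(eff$interventions),
    volume_change_ml = unlist(eff$volume_change_ml),
    stiffness_change_Nmm = unlist(eff$stiffness_change_Nmm),
    volume_change_sd_ml = eff$volume_change_sd_ml,
    stiffness_change_sd_Nmm = eff$stiffness_change_sd_Nmm,
    baseline_volume_ml = eff$baseline_volume_ml,
    baseline_volume_sd_ml = eff$baseline_volume_sd_ml,
    baseline_stiffness_Nmm = eff$baseline_stiffness_Nmm,
    baseline_stiffness_sd_Nmm = eff$baseline_stiffness_sd_Nmm,
    within_subject_correlation = eff$within_subject_correlation,
    seed = eff$seed
  )
  run_config(
    seed = obj$seed, n_subjects = obj$n_subjects,
    frame_spacing_mm = obj$frame_spacing_mm,
    pose_noise_mm = obj$pose_noise_mm,
    contour_points = obj$contour_points,
    slice_interval_mm = obj$slice_interval_mm,
    staged_fractions = as.numeric(obj$staged_fractions),
    scan_duration_s = obj$scan_duration_s,
    emg_noise_sd = obj$emg_noise_sd,
    effects = effects,
    force_through_origin = obj$force_through_origin,
    icc_form = obj$icc_form,
    outdir = obj$outdir
  )
}
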