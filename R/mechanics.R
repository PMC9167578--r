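# Tendon mechanics: elongation, force-elongation stiffness, stress-strain
# and Young's modulus from staged contraction levels.

#' Tendon elongation at a contraction level
#'
#' Mean resting length subtracted from the mean length at the level.
#' Small negative values can arise from measurement noise; they are
#' flagged (attribute `negative`), not clamped.
#'
#' @param level_length_mm,resting_length_mm Positive lengths, mm.
#' @return Elongation in mm with logical attribute `negative`.
#' @export
elongation <- function(level_length_mm, resting_length_mm) {
  if (any(level_length_mm <= 0) || any(resting_length_mm <= 0)) {
    stop("lengths must be positive")
  }
  e <- level_length_mm - resting_length_mm
  if (any(e < 0)) {
    warning("negative elongation (level length below resting length); ",
            "flagged as within-noise, not clamped")
  }
  structure(e, negative = e < 0)
}

# R^2 computed directly from residuals (summary.lm warns on exact fits,
# which are legitimate inputs here, e.g. three collinear staged points)
r_squared_of <- function(fit, y) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  1 - sum(residuals(fit)^2) / ss_tot
}

as_force_elongation <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("force_N", "elongation_mm") %in% names(points)))
  points
}

#' Tendon stiffness from the force-elongation curve
#'
#' Ordinary least-squares slope of force on elongation across the staged
#' contraction levels (free intercept; the fit is not forced through the
#' origin). With the usual three levels (35/55/75% MVIC) the slope is the
#' individual tendon stiffness in N mm^-1.
#'
#' @param points Data frame with columns `force_N` and `elongation_mm`
#'   (>= 2 rows, distinct elongations).
#' @param force_through_origin Fit `force ~ elongation + 0` instead
#'   (default `FALSE`).
#' @return Object of class `stiffness_result`: `stiffness_Nmm` (slope),
#'   `intercept_N`, `r_squared`, `n`.
#' @export
stiffness <- function(points, force_through_origin = FALSE) {
  points <- as_force_elongation(points)
  if (nrow(points) < 2) stop("stiffness fit needs at least 2 points")
  if (var(points$elongation_mm) == 0) {
    stop("elongations are identical; stiffness slope is undefined")
  }
  fit <- if (force_through_origin) {
    lm(force_N ~ elongation_mm + 0, data = points)
  } else {
    lm(force_N ~ elongation_mm, data = points)
  }
  co <- coef(fit)
  structure(list(
    stiffness_Nmm = unname(co[["elongation_mm"]]),
    intercept_N = if (force_through_origin) 0 else unname(co[[1]]),
    r_squared = r_squared_of(fit, points$force_N),
    n = nrow(points)
  ), class = "stiffness_result")
}

#' @export
print.stiffness_result <- function(x, ...) {
  cat(sprintf("Stiffness: %.2f N mm^-1 (intercept %.2f N, R^2 = %.4f, n = %d)\n",
              x$stiffness_Nmm, x$intercept_N, x$r_squared, x$n))
  invisible(x)
}

#' Convert force-elongation points to stress-strain
#'
#' Stress is force over the average resting CSA (N/mm^2 = MPa); strain is
#' elongation over the resting length, stored as a dimensionless fraction
#' (rendered as percent only in reports).
#'
#' @param points Data frame with `force_N`, `elongation_mm`.
#' @param mean_csa_mm2 Average resting cross-sectional area, mm^2 (> 0).
#' @param resting_length_mm Resting free-tendon length, mm (> 0).
#' @return Data frame with `stress_MPa` and `strain` columns (input
#'   columns retained).
#' @export
stress_strain <- function(points, mean_csa_mm2, resting_length_mm) {
  points <- as_force_elongation(points)
  if (mean_csa_mm2 <= 0) stop("mean_csa_mm2 must be positive")
  if (resting_length_mm <= 0) stop("resting_length_mm must be positive")
  points$stress_MPa <- points$force_N / mean_csa_mm2
  points$strain <- points$elongation_mm / resting_length_mm
  points
}

#' Young's modulus from the stress-strain curve
#'
#' Ordinary least-squares slope of stress on strain across the entire
#' stress range. Because stress and strain are linear rescalings of force
#' and elongation, the identity `E = k * L0 / CSA` holds exactly against
#' [stiffness()] computed on the same points.
#'
#' @param ss_points Data frame with `stress_MPa` and `strain` columns, as
#'   from [stress_strain()].
#' @param force_through_origin Fit without intercept (default `FALSE`).
#' @return Object of class `modulus_result`: `modulus_MPa`,
#'   `intercept_MPa`, `r_squared`, `n`.
#' @export
youngs_modulus <- function(ss_points, force_through_origin = FALSE) {
  stopifnot(is.data.frame(ss_points),
            all(c("stress_MPa", "strain") %in% names(ss_points)))
  if (nrow(ss_points) < 2) stop("modulus fit needs at least 2 points")
  if (var(ss_points$strain) == 0) {
    stop("strains are identical; modulus slope is undefined")
  }
  fit <- if (force_through_origin) {
    lm(stress_MPa ~ strain + 0, data = ss_points)
  } else {
    lm(stress_MPa ~ strain, data = ss_points)
  }
  co <- coef(fit)
  structure(list(
    modulus_MPa = unname(co[["strain"]]),
    intercept_MPa = if (force_through_origin) 0 else unname(co[[1]]),
    r_squared = r_squared_of(fit, ss_points$stress_MPa),
    n = nrow(ss_points)
  ), class = "modulus_result")
}

#' @export
print.modulus_result <- function(x, ...) {
  cat(sprintf("Young's modulus: %.2f MPa (R^2 = %.4f, n = %d)\n",
              x$modulus_MPa, x$r_squared, x$n))
  invisible(x)
}

#' Assemble a staged trial set
#'
#' Per-state measurements for the staged protocol: two resting scans and,
#' for each contraction level, two scans plus the resolved tendon force.
#' Repeat scans are averaged; a discrepancy between repeats beyond
#' `repeat_tolerance_mm` is reported via warning.
#'
#' @param rest_lengths_mm Numeric vector (usually 2) of resting lengths.
#' @param level_lengths_mm Named list: per level (e.g. `"35"`), numeric
#'   vector of repeat lengths.
#' @param level_forces_N Named numeric: per level, tendon force in N.
#' @param repeat_tolerance_mm Allowed repeat-scan discrepancy before a
#'   warning (default 1 mm).
#' @return Object of class `staged_trial_set` with `resting_length_mm` and
#'   a data frame `levels` (`level`, `length_mm`, `force_N`,
#'   `elongation_mm`).
#' @export
staged_trial_set <- function(rest_lengths_mm, level_lengths_mm,
                             level_forces_N, repeat_tolerance_mm = 1) {
  stopifnot(length(rest_lengths_mm) >= 1, all(rest_lengths_mm > 0))
  lv <- names(level_lengths_mm)
  if (is.null(lv) || anyDuplicated(lv)) {
    stop("level_lengths_mm must be a named list with distinct levels")
  }
  if (!setequal(lv, names(level_forces_N))) {
    stop("levels of lengths and forces disagree")
  }
  check_repeats <- function(v, what) {
    if (length(v) > 1 && diff(range(v)) > repeat_tolerance_mm) {
      warning(sprintf("repeat scans of %s differ by %.2f mm (tolerance %.2f mm)",
                      what, diff(range(v)), repeat_tolerance_mm))
    }
    mean(v)
  }
  rest <- check_repeats(rest_lengths_mm, "resting length")
  lens <- vapply(lv, function(l) check_repeats(level_lengths_mm[[l]],
                                               paste0("level ", l)), numeric(1))
  forces <- as.numeric(level_forces_N[lv])
  if (any(diff(forces) <= 0)) {
    stop("forces must be strictly increasing across levels")
  }
  levels_df <- data.frame(
    level = lv, length_mm = lens, force_N = forces,
    elongation_mm = as.numeric(elongation(lens, rest)),
    row.names = NULL
  )
  structure(list(resting_length_mm = rest, levels = levels_df),
            class = "staged_trial_set")
}

#' Stiffness and modulus for a staged trial set
#'
#' Convenience wrapper: fits [stiffness()] on the force-elongation points
#' of a [staged_trial_set()] and, when geometry is supplied, the
#' stress-strain fit for Young's modulus.
#'
#' @param sts A [staged_trial_set()].
#' @param mean_csa_mm2 Optional average resting CSA for the modulus.
#' @param force_through_origin Passed to the fits.
#' @return List with `stiffness` ([stiffness()] result) and, when CSA is
#'   given, `modulus` ([youngs_modulus()] result).
#' @export
analyze_staged <- function(sts, mean_csa_mm2 = NULL,
                           force_through_origin = FALSE) {
  stopifnot(inherits(sts, "staged_trial_set"))
  pts <- sts$levels[, c("force_N", "elongation_mm")]
  out <- list(stiffness = stiffness(pts, force_through_origin))
  if (!is.null(mean_csa_mm2)) {
    ss <- stress_strain(pts, mean_csa_mm2, sts$resting_length_mm)
    out$modulus <- youngs_modulus(ss, force_through_origin)
  }
  out
}
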