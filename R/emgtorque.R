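# EMG and torque signal processing: bandpass filtering, RMS envelope,
# the linear antagonist co-contraction model, moment-arm conversion of
# torque to tendon force, and MVIC acceptance.

#' Sampled signal container
#'
#' @param samples Numeric vector of finite samples.
#' @param fs_hz Sampling rate, Hz (> 0; default 1000).
#' @param units Units tag (informational).
#' @return An object of class `ts_signal`.
#' @export
ts_signal <- function(samples, fs_hz = 1000, units = "") {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("signal samples must be finite")
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("fs_hz must be positive")
  structure(list(samples = samples, fs_hz = fs_hz, units = units),
            class = "ts_signal")
}

#' @export
print.ts_signal <- function(x, ...) {
  cat(sprintf("Signal: %d samples at %g Hz%s (%.3g s)\n",
              length(x$samples), x$fs_hz,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              length(x$samples) / x$fs_hz))
  invisible(x)
}

signal_samples <- function(x) if (inherits(x, "ts_signal")) x$samples else as.numeric(x)

#' Zero-phase Butterworth bandpass filter
#'
#' 4th-order Butterworth bandpass applied forward and backward
#' (zero phase), the community default for surface EMG conditioning.
#' The default 20-450 Hz band removes motion artefact and baseline drift
#' below 20 Hz and out-of-band noise above 450 Hz.
#'
#' @param x A [ts_signal()] (or numeric vector with `fs_hz` given).
#' @param lo,hi Band edges in Hz; requires `lo < hi < fs/2`.
#' @param fs_hz Sampling rate when `x` is a bare numeric vector.
#' @param order Filter order per band edge (default 4).
#' @return A [ts_signal()] of the same length.
#' @export
bandpass <- function(x, lo = 20, hi = 450, fs_hz = NULL, order = 4) {
  fs <- if (inherits(x, "ts_signal")) x$fs_hz else fs_hz
  if (is.null(fs)) stop("supply fs_hz for numeric input")
  if (!(lo < hi)) stop("need lo < hi")
  if (hi >= fs / 2) {
    stop(sprintf("upper band edge %g Hz must be below the Nyquist frequency %g Hz",
                 hi, fs / 2))
  }
  v <- signal_samples(x)
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  # reflect-pad before the forward-backward pass to suppress edge transients
  pad <- min(length(v) - 1L, max(100L, round(3 * fs / lo)))
  vp <- c(2 * v[1] - rev(v[2:(pad + 1L)]), v,
          2 * v[length(v)] - rev(v[(length(v) - pad):(length(v) - 1L)]))
  out <- signal::filtfilt(bf, vp)[(pad + 1L):(pad + length(v))]
  ts_signal(out, fs, if (inherits(x, "ts_signal")) x$units else "")
}

#' Sliding-window RMS envelope
#'
#' Root-mean-square over a centered sliding window; at the edges the window
#' shrinks to the available samples. Output has the same length as the
#' input and is non-negative.
#'
#' @param x A [ts_signal()] or numeric vector.
#' @param window Window length in samples (default 200; must be >= 1 and
#'   no longer than the signal).
#' @return A [ts_signal()] envelope (fs taken from the input when
#'   available).
#' @export
rms_envelope <- function(x, window = 200) {
  v <- signal_samples(x)
  n <- length(v)
  if (window < 1) stop("window must be at least 1 sample")
  if (window > n) {
    stop(sprintf("window (%d) exceeds signal length (%d)", window, n))
  }
  half <- window %/% 2
  cs <- cumsum(c(0, v^2))
  lo <- pmax(1L, seq_len(n) - half + 1L)
  hi <- pmin(n, seq_len(n) + (window - half))
  env <- sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  ts_signal(env, if (inherits(x, "ts_signal")) x$fs_hz else 1000,
            if (inherits(x, "ts_signal")) x$units else "")
}

#' Fit the linear co-contraction model
#'
#' Ordinary least squares of recorded dorsiflexion torque on the tibialis
#' anterior EMG envelope, pooled over the supplied trials:
#' `torque = P1 * envelope + P2`. P1 is the slope of the EMG-torque
#' relationship, P2 the regression constant; the fitted line later converts
#' antagonist EMG observed during plantarflexion into an antagonist torque
#' estimate.
#'
#' @param df_trials A data frame with columns `envelope` and `torque_Nm`
#'   (or `torque`), or a list of such data frames (one per dorsiflexion
#'   trial) pooled before fitting.
#' @return An object of class `cocontraction_model` with `p1_slope`,
#'   `p2_intercept`, `r_squared`, `residual_sd`, `se` (slope and intercept
#'   standard errors) and `n`.
#' @export
fit_cocontraction <- function(df_trials) {
  if (is.data.frame(df_trials)) df_trials <- list(df_trials)
  pooled <- do.call(rbind, lapply(df_trials, function(d) {
    tq <- if ("torque_Nm" %in% names(d)) d$torque_Nm else d$torque
    if (is.null(tq) || is.null(d$envelope)) {
      stop("each trial needs 'envelope' and 'torque_Nm' columns")
    }
    data.frame(envelope = d$envelope, torque = tq)
  }))
  if (nrow(pooled) < 2 || var(pooled$envelope) == 0) {
    stop("co-contraction fit needs at least 2 distinct envelope values")
  }
  fit <- lm(torque ~ envelope, data = pooled)
  # diagnostics computed directly (summary.lm warns on exact fits, and a
  # noiseless synthetic trial is a legitimate input)
  n <- nrow(pooled)
  rss <- sum(residuals(fit)^2)
  tss <- sum((pooled$torque - mean(pooled$torque))^2)
  sigma <- sqrt(rss / (n - 2))
  sxx <- sum((pooled$envelope - mean(pooled$envelope))^2)
  structure(list(
    p1_slope = unname(coef(fit)[2]),
    p2_intercept = unname(coef(fit)[1]),
    r_squared = if (tss == 0) 1 else 1 - rss / tss,
    residual_sd = sigma,
    se = c(p1 = sigma / sqrt(sxx),
           p2 = sigma * sqrt(1 / n + mean(pooled$envelope)^2 / sxx)),
    n = n
  ), class = "cocontraction_model")
}

#' @export
print.cocontraction_model <- function(x, ...) {
  cat(sprintf("Co-contraction model: torque = %.4g * envelope + %.4g (R^2 = %.4f, n = %d)\n",
              x$p1_slope, x$p2_intercept, x$r_squared, x$n))
  invisible(x)
}

#' Correct net plantarflexion torque for antagonist co-contraction
#'
#' Adds the estimated antagonist dorsiflexion torque
#' `P1 * envelope + P2` to the net plantarflexion torque, elementwise, to
#' obtain the true plantarflexion torque.
#'
#' @param net_pf_torque Net torque series (N m), [ts_signal()] or numeric.
#' @param ta_envelope Time-aligned tibialis anterior EMG envelope.
#' @param model A [fit_cocontraction()] model.
#' @return True plantarflexion torque, same container type as the input.
#' @export
true_pf_torque <- function(net_pf_torque, ta_envelope, model) {
  stopifnot(inherits(model, "cocontraction_model"))
  net <- signal_samples(net_pf_torque)
  env <- signal_samples(ta_envelope)
  if (length(net) != length(env)) {
    stop(sprintf("torque (%d) and envelope (%d) lengths differ",
                 length(net), length(env)))
  }
  out <- net + model$p1_slope * env + model$p2_intercept
  if (inherits(net_pf_torque, "ts_signal")) {
    ts_signal(out, net_pf_torque$fs_hz, "N m")
  } else {
    out
  }
}

#' Achilles tendon moment arm from the two-distance method
#'
#' `d1` is the distance from the probe tip (aligned with the ankle centre
#' of rotation) to the centre of rotation; `d2` the depth from the skin to
#' the tendon midline (line of action). The moment arm is `d1 - d2`, the
#' perpendicular distance from the centre of rotation to the line of
#' action.
#'
#' @param d1_mm,d2_mm Distances in mm with `d1 > d2 > 0`.
#' @return An object of class `moment_arm` with `value_mm`.
#' @export
moment_arm <- function(d1_mm, d2_mm) {
  if (!is.numeric(d1_mm) || !is.numeric(d2_mm) || d2_mm <= 0) {
    stop("d1_mm and d2_mm must be positive numbers")
  }
  if (d2_mm >= d1_mm) {
    stop(sprintf("need d1 > d2 > 0, got d1 = %g, d2 = %g", d1_mm, d2_mm))
  }
  structure(list(d1_mm = d1_mm, d2_mm = d2_mm, value_mm = d1_mm - d2_mm),
            class = "moment_arm")
}

#' @export
print.moment_arm <- function(x, ...) {
  cat(sprintf("Moment arm: %.2f mm (d1 = %.2f, d2 = %.2f)\n",
              x$value_mm, x$d1_mm, x$d2_mm))
  invisible(x)
}

#' Tendon force from true torque and moment arm
#'
#' `F = torque / (moment arm in m)`; the arm is supplied in mm and
#' converted internally.
#'
#' @param true_torque_Nm Torque (N m), scalar or series.
#' @param arm A [moment_arm()] object or the arm value in mm.
#' @return Force in N, same shape as the torque input.
#' @export
tendon_force <- function(true_torque_Nm, arm) {
  arm_mm <- if (inherits(arm, "moment_arm")) arm$value_mm else arm
  if (!is.numeric(arm_mm) || arm_mm <= 0) {
    stop("moment arm must be positive (mm)")
  }
  signal_samples(true_torque_Nm) / (arm_mm / 1000)
}

# Peak torque of one trial: maximum of a centered moving average over the
# hold window, which rejects single-sample spikes.
trial_peak <- function(x, fs_hz = 1000, hold_window_s = 0.5) {
  v <- signal_samples(x)
  w <- max(1L, round(hold_window_s * if (inherits(x, "ts_signal")) x$fs_hz else fs_hz))
  w <- min(w, length(v))
  cs <- cumsum(c(0, v))
  n <- length(v)
  mw <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  max(mw)
}

#' Maximal voluntary isometric contraction (MVIC) from repeated trials
#'
#' Extracts a plateau peak per trial (moving-average maximum over the hold
#' window) and applies the acceptance rule: the MVIC is accepted when the
#' two highest trial peaks lie within 10% of each other.
#'
#' @param trials List of 1-5 torque series ([ts_signal()] or numeric).
#' @param fs_hz Sampling rate for bare numeric trials.
#' @param hold_window_s Plateau averaging window, s (default 0.5).
#' @param tolerance Relative agreement required between the two highest
#'   peaks (default 0.10).
#' @return An object of class `mvic_result`: `peaks_Nm`, `accepted`,
#'   `mvic_Nm` (the highest peak), `reason` when not accepted.
#' @export
mvic <- function(trials, fs_hz = 1000, hold_window_s = 0.5,
                 tolerance = 0.10) {
  if (!is.list(trials)) trials <- list(trials)
  if (length(trials) > 5) stop("at most 5 MVIC trials expected")
  peaks <- vapply(trials, trial_peak, numeric(1),
                  fs_hz = fs_hz, hold_window_s = hold_window_s)
  res <- list(peaks_Nm = peaks, mvic_Nm = max(peaks))
  if (length(peaks) < 2) {
    res$accepted <- FALSE
    res$reason <- "fewer than 2 trials; agreement rule cannot be applied"
  } else {
    srt <- sort(peaks, decreasing = TRUE)
    rel <- (srt[1] - srt[2]) / srt[1]
    res$accepted <- rel <= tolerance
    res$reason <- if (res$accepted) NA_character_ else
      sprintf("two highest peaks differ by %.1f%% (> %.0f%%)",
              100 * rel, 100 * tolerance)
  }
  structure(res, class = "mvic_result")
}

#' @export
print.mvic_result <- function(x, ...) {
  cat(sprintf("MVIC: %.2f N m (%s; peaks: %s)\n", x$mvic_Nm,
              if (x$accepted) "accepted" else paste0("NOT accepted - ", x$reason),
              paste(sprintf("%.1f", x$peaks_Nm), collapse = ", ")))
  invisible(x)
}

#' Plateau torque of a staged ramp-and-hold trial
#'
#' Mean torque over the central 50% of the hold phase (the part of the
#' trial after the ramp). When a target is given, deviation of the plateau
#' mean beyond the tolerance raises a re-trial flag, mirroring re-scanning
#' when a participant cannot achieve or steadily hold the target.
#'
#' @param x Torque series ([ts_signal()] or numeric).
#' @param ramp_s Ramp duration preceding the hold, s.
#' @param fs_hz Sampling rate for bare numeric input.
#' @param target_Nm Optional target torque, N m.
#' @param tolerance Relative deviation triggering the flag (default 0.05).
#' @return List with `torque_Nm` (plateau mean), `retrial` flag and
#'   `deviation` (relative, `NA` without a target).
#' @export
plateau_torque <- function(x, ramp_s = 2, fs_hz = 1000, target_Nm = NULL,
                           tolerance = 0.05) {
  v <- signal_samples(x)
  fs <- if (inherits(x, "ts_signal")) x$fs_hz else fs_hz
  i0 <- min(length(v), round(ramp_s * fs) + 1L)
  hold <- v[i0:length(v)]
  nh <- length(hold)
  central <- hold[max(1, round(nh * 0.25)):max(1, round(nh * 0.75))]
  m <- mean(central)
  dev <- if (is.null(target_Nm)) NA_real_ else abs(m - target_Nm) / target_Nm
  list(torque_Nm = m,
       retrial = isTRUE(dev > tolerance),
       deviation = dev)
}
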