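# Tendon phantoms: tapering tubular objects with closed-form volume, used as
# ground truth for sweep simulation and volume-reconstruction validation.
# They stand in for the free Achilles tendon between its two anatomical
# landmarks (calcaneal notch and soleus muscle-tendon junction).

#' Create an analytic tendon phantom
#'
#' A phantom is a straight tube whose cross-sectional area varies along the
#' normalised arclength \eqn{s \in [0, 1]} according to `area_profile_spec`.
#' Its true volume is the closed-form integral of the area profile times the
#' length, so reconstruction accuracy can be quantified exactly.
#'
#' @param length_mm Tendon length in mm; must be > 0.
#' @param area_profile_spec A list describing the cross-sectional area
#'   profile (mm^2) over `s in [0, 1]`. One of:
#'   * `list(type = "constant", area = a)`
#'   * `list(type = "linear", area_start = a0, area_end = a1)` (linear taper)
#'   * `list(type = "quadratic", coef = c(c0, c1, c2))`, i.e.
#'     `A(s) = c0 + c1 s + c2 s^2` with non-negative coefficients and `c0 > 0`.
#' @return An object of class `tendon_phantom` with elements `length_mm`,
#'   `area_profile` (a vectorised function of `s`), `profile_spec` and
#'   `true_volume_ml`.
#' @examples
#' ph <- make_phantom(50, list(type = "constant", area = pi * 4^2))
#' ph$true_volume_ml  # cylinder: pi * 16 * 50 / 1000 = 2.513 ml
#' @export
make_phantom <- function(length_mm, area_profile_spec) {
  if (!is.numeric(length_mm) || length(length_mm) != 1 ||
      !is.finite(length_mm) || length_mm <= 0) {
    stop("phantom length_mm must be a single positive number, got ",
         deparse(length_mm))
  }
  spec <- area_profile_spec
  if (!is.list(spec) || is.null(spec$type)) {
    stop("area_profile_spec must be a list with a 'type' field")
  }
  prof <- switch(spec$type,
    constant = {
      a <- spec$area
      if (!is.numeric(a) || length(a) != 1 || a <= 0) {
        stop("constant profile requires a single positive 'area' (mm^2)")
      }
      list(fn = function(s) rep(a, length(s)), integral = a)
    },
    linear = {
      a0 <- spec$area_start; a1 <- spec$area_end
      if (!is.numeric(a0) || !is.numeric(a1) || a0 <= 0 || a1 <= 0) {
        stop("linear profile requires positive 'area_start' and 'area_end'")
      }
      list(fn = function(s) a0 + (a1 - a0) * s, integral = (a0 + a1) / 2)
    },
    quadratic = {
      co <- spec$coef
      if (!is.numeric(co) || length(co) != 3 || co[1] <= 0 || any(co < 0)) {
        stop("quadratic profile requires coef = c(c0, c1, c2) with c0 > 0 ",
             "and all coefficients non-negative")
      }
      list(fn = function(s) co[1] + co[2] * s + co[3] * s^2,
           integral = co[1] + co[2] / 2 + co[3] / 3)
    },
    stop("unknown area profile type: ", spec$type)
  )
  structure(list(
    length_mm      = length_mm,
    area_profile   = prof$fn,
    profile_spec   = spec,
    true_volume_ml = prof$integral * length_mm / 1000
  ), class = "tendon_phantom")
}

#' @export
print.tendon_phantom <- function(x, ...) {
  cat("Tendon phantom\n")
  cat(sprintf("  length:      %.2f mm\n", x$length_mm))
  cat(sprintf("  profile:     %s\n", x$profile_spec$type))
  cat(sprintf("  true volume: %.4f ml\n", x$true_volume_ml))
  invisible(x)
}
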