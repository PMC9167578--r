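# Shared fixtures: analytic polygons, reference phantoms and a reduced-size
# pipeline configuration for fast end-to-end runs.

regular_polygon <- function(n, r, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# inscribed regular n-gon area, the discretization oracle for circular
# cross-sections
ngon_area <- function(n, r) (n / 2) * r^2 * sin(2 * pi / n)

cylinder_phantom <- function(r = 4, length_mm = 50) {
  make_phantom(length_mm, list(type = "constant", area = pi * r^2))
}

taper_phantom <- function() {
  make_phantom(60, list(type = "linear", area_start = 60, area_end = 40))
}

random_rotation <- function() {
  q <- rnorm(4)
  quat_to_rotmat(q / sqrt(sum(q^2)))
}

fast_config <- function(seed = 1L, n_subjects = 6) {
  run_config(seed = seed, n_subjects = n_subjects,
             frame_spacing_mm = 0.5, pose_noise_mm = 0.1,
             contour_points = 32)
}
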