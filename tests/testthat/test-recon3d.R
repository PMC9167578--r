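# Reconstruction: rigid pixel->world transforms, two-point length,
# shoelace areas, trapezoidal volume and the mean-CSA identity.

test_that("pixel_to_world composes calibration and pose rigidly", {
  cal_id <- us_calibration(pixel_spacing_mm = c(1, 1))
  pose_id <- probe_pose()
  expect_equal(pixel_to_world(c(0, 0), cal_id, pose_id), c(0, 0, 0))

  t <- c(3, -2, 7)
  pose_t <- probe_pose(translation = t)
  p <- pixel_to_world(c(5, 9), cal_id, pose_t)
  expect_equal(p, pixel_to_world(c(5, 9), cal_id, pose_id) + t)

  # two pixels 10 px apart at 0.1 mm/px -> 1.0 mm apart under any pose
  cal <- us_calibration(pixel_spacing_mm = c(0.1, 0.1))
  set.seed(101)
  for (i in 1:20) {
    pose <- probe_pose(random_rotation(), rnorm(3, sd = 50))
    w <- pixel_to_world(rbind(c(12, 30), c(12, 40)), cal, pose)
    expect_equal(sqrt(sum((w[1, ] - w[2, ])^2)), 1.0, tolerance = 1e-9)
  }
})

test_that("pixel_to_world preserves all pairwise pixel distances (isometry)", {
  set.seed(7)
  cal <- us_calibration(pixel_spacing_mm = c(0.2, 0.2),
                        rotation = random_rotation(),
                        translation = rnorm(3))
  px <- matrix(runif(20, 0, 100), ncol = 2)
  d_px <- dist(px * 0.2)
  for (i in 1:10) {
    pose <- probe_pose(random_rotation(), rnorm(3, sd = 100))
    w <- pixel_to_world(px, cal, pose)
    expect_equal(as.numeric(dist(w)), as.numeric(d_px), tolerance = 1e-9)
  }
})

test_that("non-orthonormal rotations are rejected", {
  expect_error(probe_pose(rotation = diag(3) * 1.01), "orthonormal")
  expect_error(us_calibration(pixel_spacing_mm = c(0, 0.1)), "positive")
})

test_that("quaternion round-trip preserves rotations", {
  set.seed(12)
  for (i in 1:25) {
    R <- random_rotation()
    expect_equal(quat_to_rotmat(rotmat_to_quat(R)), R, tolerance = 1e-9)
  }
})

test_that("tendon_length is the landmark chord and names missing sites", {
  expect_equal(tendon_length(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(tendon_length(c(0, 0, 0), c(0, 0, 50)), 50)
  expect_error(tendon_length(NULL, c(0, 0, 1)), "calcaneal_notch")
  expect_error(tendon_length(c(0, 0, 1), c(NA, 0, 1)), "soleus_mtj")
})

test_that("contour_area matches shoelace values and is orientation-free", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(contour_area(sq), 1.0)
  expect_equal(contour_area(sq[4:1, ]), 1.0) # reversed orientation

  g64 <- regular_polygon(64, 4)
  expect_equal(contour_area(g64), ngon_area(64, 4), tolerance = 1e-12)
  expect_equal(contour_area(g64), 50.1848, tolerance = 1e-5)

  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(contour_area(bow), "self-intersecting")
  expect_error(contour_area(sq[1:2, ]), "3 vertices")
})

test_that("3D contours are projected when planar, rejected when not", {
  g <- regular_polygon(32, 3)
  set.seed(5)
  R <- random_rotation()
  g3 <- cbind(g, 0) %*% t(R)
  g3 <- sweep(g3, 2, c(4, -1, 9), "+")
  expect_equal(contour_area(g3), ngon_area(32, 3), tolerance = 1e-9)

  warped <- cbind(g, c(rep(0, 16), rep(2, 16)))
  expect_error(contour_area(warped), "planar")
})

test_that("reconstruct_volume: prism, exact linear taper, error cases", {
  prism <- data.frame(station_mm = c(0, 50), area_mm2 = c(50, 50))
  expect_equal(reconstruct_volume(prism), 2.5)

  st <- seq(0, 60, by = 5)
  taper <- data.frame(station_mm = st, area_mm2 = 60 - st / 3)
  expect_equal(reconstruct_volume(taper), 3.0) # trapezoid exact for linear

  expect_error(reconstruct_volume(taper[c(2, 1, 3:13), ]), "increasing")
  expect_error(reconstruct_volume(data.frame(station_mm = c(0, 0),
                                             area_mm2 = c(10, 10))),
               "increasing")
  expect_error(reconstruct_volume(prism[1, , drop = FALSE]), "at least 2")
})

test_that("mean_csa is the length-weighted mean and ties to volume exactly", {
  st <- seq(0, 60, by = 5)
  taper <- data.frame(station_mm = st, area_mm2 = 60 - st / 3)
  expect_equal(mean_csa(taper), 50) # midpoint of the linear profile
  expect_equal(mean_csa(data.frame(station_mm = c(0, 10, 30),
                                   area_mm2 = c(50, 50, 50))), 50)
  set.seed(30)
  irregular <- data.frame(station_mm = sort(runif(9, 0, 40)),
                          area_mm2 = runif(9, 30, 70))
  span <- diff(range(irregular$station_mm))
  expect_equal(mean_csa(irregular) * span / 1000,
               reconstruct_volume(irregular), tolerance = 1e-12)
  expect_error(mean_csa(data.frame(station_mm = numeric(0),
                                   area_mm2 = numeric(0))), "no slices")
})

test_that("noiseless sweep reconstruction recovers the generator truth", {
  ph <- cylinder_phantom()
  sw <- simulate_sweep(ph, 0.1, pose_noise_mm = 0, contour_points = 64,
                       seed = 2)
  g <- reconstruct_geometry(sw, slice_interval_mm = 5)
  expect_equal(g$length_mm, 50, tolerance = 1e-4)
  expect_lt(abs(g$volume_ml - ph$true_volume_ml) / ph$true_volume_ml, 0.01)
  expect_equal(g$mean_csa_mm2 * diff(range(g$slices$station_mm)) / 1000,
               g$volume_ml, tolerance = 1e-12)

  tp <- taper_phantom()
  g2 <- reconstruct_geometry(simulate_sweep(tp, 0.1, seed = 3), 5)
  expect_lt(abs(g2$volume_ml - 3) / 3, 0.005)
})

test_that("volume error shrinks monotonically with slice spacing", {
  ph <- make_phantom(40, list(type = "quadratic", coef = c(30, 20, 10)))
  # reference volume carries the constant inscribed-polygon area factor,
  # isolating the interpolation error the spacing controls
  npts <- 64
  poly_factor <- (npts / 2) * sin(2 * pi / npts) / pi
  truth <- ph$true_volume_ml * poly_factor
  sw <- simulate_sweep(ph, 0.25, contour_points = npts, seed = 4)
  errs <- vapply(c(10, 5, 2), function(iv) {
    abs(reconstruct_geometry(sw, slice_interval_mm = iv)$volume_ml - truth)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # and the finest spacing is within 1% of the analytic truth
  expect_lt(errs[3] / truth, 0.01)
})

test_that("rigid motion of the whole sweep leaves geometry invariant", {
  ph <- taper_phantom()
  sw <- simulate_sweep(ph, 0.5, pose_noise_mm = 0.1, seed = 6)
  g0 <- reconstruct_geometry(sw, 5)
  set.seed(9)
  R <- random_rotation(); t <- c(100, -50, 30)
  sw_mov <- sw
  sw_mov$frames <- lapply(sw$frames, function(fr) {
    fr$pose <- probe_pose(R %*% fr$pose$rotation,
                          as.numeric(R %*% fr$pose$translation + t))
    fr
  })
  g1 <- reconstruct_geometry(sw_mov, 5)
  expect_equal(g1$length_mm, g0$length_mm, tolerance = 1e-9)
  expect_equal(g1$volume_ml, g0$volume_ml, tolerance = 1e-9)
  expect_equal(g1$slices$area_mm2, g0$slices$area_mm2, tolerance = 1e-9)
})
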