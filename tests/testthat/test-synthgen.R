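# Synthetic-data generators: closed-form phantom volumes, sweep structure,
# EMG/torque trial construction and the crossover dataset.

test_that("phantom volume matches the closed-form integral", {
  cyl <- make_phantom(50, list(type = "constant", area = pi * 4^2))
  expect_equal(cyl$true_volume_ml, pi * 16 * 50 / 1000) # 2.513 ml
  expect_equal(round(cyl$true_volume_ml, 3), 2.513)

  tap <- make_phantom(60, list(type = "linear", area_start = 60, area_end = 40))
  expect_equal(tap$true_volume_ml, 3.000)

  quad <- make_phantom(30, list(type = "quadratic", coef = c(40, 10, 6)))
  expect_equal(quad$true_volume_ml, (40 + 10 / 2 + 6 / 3) * 30 / 1000)
  # machine-precision agreement with numeric quadrature of the profile
  s <- seq(0, 1, length.out = 20001)
  a <- quad$area_profile(s)
  num <- sum(diff(s) * (head(a, -1) + tail(a, -1)) / 2) * 30 / 1000
  expect_equal(quad$true_volume_ml, num, tolerance = 1e-9)
})

test_that("degenerate phantom specs are rejected", {
  expect_error(make_phantom(0, list(type = "constant", area = 50)),
               "positive")
  expect_error(make_phantom(-5, list(type = "constant", area = 50)))
  expect_error(make_phantom(50, list(type = "constant", area = -1)))
  expect_error(make_phantom(50, list(type = "linear", area_start = 0,
                                     area_end = 40)))
  expect_error(make_phantom(50, list(type = "quadratic", coef = c(-1, 0, 1))))
  expect_error(make_phantom(50, list(type = "cubic")), "unknown")
})

test_that("sweep frame count, contour areas and landmarks are correct", {
  ph <- cylinder_phantom()
  sw <- simulate_sweep(ph, frame_spacing_mm = 0.1, pose_noise_mm = 0,
                       contour_points = 64, seed = 3)
  expect_length(sw$frames, 501) # length / spacing + 1

  # noiseless polygons equal the inscribed 64-gon area at every station
  areas <- vapply(sw$frames[c(1, 250, 501)], function(fr) {
    contour_area(pixel_to_world(fr$contour_px, sw$calibration, fr$pose))
  }, numeric(1))
  expect_equal(areas, rep(ngon_area(64, 4), 3), tolerance = 1e-9)
  expect_lt(abs(areas[1] - pi * 16) / (pi * 16), 0.002) # within 0.2% of 50.265

  expect_equal(sw$frames[[1]]$landmark$name, "calcaneal_notch")
  expect_equal(sw$frames[[501]]$landmark$name, "soleus_mtj")

  expect_error(simulate_sweep(ph, frame_spacing_mm = 60), "exceeds")
  expect_error(simulate_sweep(ph, contour_points = 4), "at least 8")
})

test_that("sweeps are bitwise reproducible from their seed", {
  ph <- taper_phantom()
  a <- simulate_sweep(ph, 0.5, pose_noise_mm = 0.3, seed = 11)
  b <- simulate_sweep(ph, 0.5, pose_noise_mm = 0.3, seed = 11)
  c <- simulate_sweep(ph, 0.5, pose_noise_mm = 0.3, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$frames[[2]]$pose$translation,
                         c$frames[[2]]$pose$translation))
})

test_that("EMG/torque trials obey the linear co-contraction construction", {
  s <- simulate_subject(7)
  p1 <- s$cocontraction_true[["p1"]]; p2 <- s$cocontraction_true[["p2"]]

  tr <- simulate_emg_torque_trial(s, "DF_MVIC", duration_s = 5,
                                  noise_sd = 0, seed = 1)
  # noiseless: torque sits on the line P1 * envelope + P2 at every sample
  expect_equal(tr$torque$samples,
               p1 * tr$envelope_true$samples + p2, tolerance = 1e-12)

  st <- simulate_emg_torque_trial(s, "PF_staged", 0.75, duration_s = 8,
                                  noise_sd = 0, seed = 2)
  expect_length(st$torque$samples, 8000) # 8 s at 1000 Hz
  # noiseless hold: true torque is exactly the target
  expect_equal(tail(st$true_pf_torque_Nm, 1000),
               rep(0.75 * s$mvic_torque_Nm, 1000))
  # net + modelled antagonist recovers the true torque
  antagonist <- p1 * st$envelope_true$samples + p2
  expect_equal(st$torque$samples + antagonist, st$true_pf_torque_Nm,
               tolerance = 1e-12)

  expect_error(simulate_emg_torque_trial(s, "PF_staged", 0.5), "0.35")
  expect_error(simulate_emg_torque_trial(s, "DF_MVIC", duration_s = 0),
               "positive")
})

test_that("raw EMG carrier reproduces the programmed envelope", {
  s <- simulate_subject(8)
  st <- simulate_emg_torque_trial(s, "PF_staged", 0.55, duration_s = 8,
                                  noise_sd = 0, seed = 9)
  env <- rms_envelope(bandpass(st$emg))
  hold <- 3001:7500
  rel <- mean(env$samples[hold]) / mean(st$envelope_true$samples[hold]) - 1
  expect_lt(abs(rel), 0.05)
})

test_that("crossover dataset has the balanced structure and null behaviour", {
  spec0 <- effect_spec(volume_change_ml = c("8s75" = 0, "2s75" = 0, "8s35" = 0),
                       stiffness_change_Nmm = c("8s75" = 0, "2s75" = 0,
                                                "8s35" = 0),
                       volume_change_sd_ml = 0, stiffness_change_sd_Nmm = 0,
                       seed = 5)
  d0 <- simulate_crossover_dataset(16, spec0)
  expect_equal(nrow(d0), 16 * 3 * 2)
  pre <- d0[d0$time == "pre", ]; post <- d0[d0$time == "post", ]
  expect_equal(post$volume_ml, pre$volume_ml)       # null effect: post = pre
  expect_equal(post$stiffness_Nmm, pre$stiffness_Nmm)

  d1 <- simulate_crossover_dataset(16, effect_spec(seed = 5))
  d2 <- simulate_crossover_dataset(16, effect_spec(seed = 5))
  expect_identical(d1, d2)
  expect_error(simulate_crossover_dataset(1, effect_spec()), "at least 2")

  # each subject sees each intervention once per time point
  expect_true(all(table(d1$subject, d1$intervention, d1$time) == 1))
})

test_that("calibrated effects reproduce the expected change-score ordering", {
  d <- simulate_crossover_dataset(16, effect_spec(seed = 21))
  ch <- aggregate(cbind(volume_ml, stiffness_Nmm) ~ subject + intervention,
                  data = transform(d, volume_ml = ifelse(time == "post", volume_ml, -volume_ml),
                                   stiffness_Nmm = ifelse(time == "post", stiffness_Nmm, -stiffness_Nmm)),
                  FUN = sum)
  mv <- tapply(ch$volume_ml, ch$intervention, mean)
  ms <- tapply(ch$stiffness_Nmm, ch$intervention, mean)
  expect_lt(mv[["8s75"]], mv[["2s75"]])   # largest volume reduction
  expect_lt(mv[["8s75"]], mv[["8s35"]])
  expect_lt(ms[["8s75"]], 0)
  expect_gt(ms[["2s75"]], 0)              # short-duration stiffness increase
})

test_that("simulated subjects respect the physiologic stiffness band", {
  for (seed in 1:20) {
    s <- simulate_subject(seed)
    expect_gte(s$true_stiffness_Nmm, 200)
    expect_lte(s$true_stiffness_Nmm, 600)
    expect_true(all(unlist(s[c("mvic_torque_Nm", "moment_arm_mm",
                               "rest_length_mm", "rest_mean_csa_mm2")]) > 0))
  }
})
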