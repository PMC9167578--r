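# Crossover inference and reliability: ANOVA strata against the aov()
# oracle, contrasts, simple effects, effect sizes, normality, ICC, CV,
# SEM/MDC and the sample-size utility.

null_dataset <- function(n = 16, seed = 1) {
  spec <- effect_spec(volume_change_ml = c("8s75" = 0, "2s75" = 0, "8s35" = 0),
                      stiffness_change_Nmm = c("8s75" = 0, "2s75" = 0,
                                               "8s35" = 0),
                      volume_change_sd_ml = 0.1, stiffness_change_sd_Nmm = 30,
                      seed = seed)
  simulate_crossover_dataset(n, spec)
}

test_that("interaction degrees of freedom follow the balanced design", {
  d <- simulate_crossover_dataset(16, effect_spec(seed = 2))
  r <- rm_anova_2x3(d, "volume_ml")
  it <- r$table[r$table$effect == "time:intervention", ]
  expect_equal(it$df1, 2)
  expect_equal(it$df2, 30)
  for (n in c(5, 9, 12)) {
    rn <- rm_anova_2x3(simulate_crossover_dataset(n, effect_spec(seed = n)),
                       "stiffness_Nmm")
    itn <- rn$table[rn$table$effect == "time:intervention", ]
    expect_equal(c(itn$df1, itn$df2), c(2, (n - 1) * 2))
  }
})

test_that("all three strata match the aov() decomposition", {
  d <- simulate_crossover_dataset(10, effect_spec(seed = 33))
  mine <- rm_anova_2x3(d, "stiffness_Nmm")$table
  d$subject <- factor(d$subject); d$time <- factor(d$time)
  d$intervention <- factor(d$intervention)
  or <- summary(aov(stiffness_Nmm ~ time * intervention +
                      Error(subject / (time * intervention)), data = d))
  get_f <- function(stratum, row) {
    tb <- or[[stratum]][[1]]
    tb[trimws(rownames(tb)) == row, "F value"]
  }
  expect_equal(mine$F[mine$effect == "time"],
               get_f("Error: subject:time", "time"), tolerance = 1e-8)
  expect_equal(mine$F[mine$effect == "intervention"],
               get_f("Error: subject:intervention", "intervention"),
               tolerance = 1e-8)
  expect_equal(mine$F[mine$effect == "time:intervention"],
               get_f("Error: subject:time:intervention", "time:intervention"),
               tolerance = 1e-8)
})

test_that("a uniform time shift produces no interaction", {
  d <- null_dataset(12, seed = 4)
  # add the same constant to every post value
  d$volume_ml[d$time == "post"] <-
    d$volume_ml[d$time == "pre"][match(
      paste(d$subject, d$intervention)[d$time == "post"],
      paste(d$subject, d$intervention)[d$time == "pre"])] + 0.4
  r <- rm_anova_2x3(d, "volume_ml")
  expect_lt(r$table$F[r$table$effect == "time:intervention"], 1e-9)
})

test_that("incomplete designs are rejected with the offending cells", {
  d <- simulate_crossover_dataset(6, effect_spec(seed = 6))
  expect_error(rm_anova_2x3(d[-1, ], "volume_ml"), "S01")
  expect_error(rm_anova_2x3(d, "missing_col"), "lacks columns")
})

test_that("interaction contrasts are antisymmetric and detect known gaps", {
  d <- null_dataset(16, seed = 7)
  # deterministic changes: -0.3 under 8s75, -0.1 under 2s75, 0 under 8s35
  key <- paste(d$subject, d$intervention)
  pre_idx <- match(key[d$time == "post"], key[d$time == "pre"])
  shift <- c("8s75" = -0.3, "2s75" = -0.1, "8s35" = 0)
  d$volume_ml[d$time == "post"] <-
    d$volume_ml[d$time == "pre"][pre_idx] +
    shift[as.character(d$intervention[d$time == "post"])]
  ct <- interaction_contrasts(d, "volume_ml")
  r_ab <- ct[ct$intervention_a == "8s75" & ct$intervention_b == "2s75", ]
  expect_equal(r_ab$estimate, -0.2, tolerance = 1e-12)
  expect_lt(r_ab$p, 1e-10)

  cs <- tendonmech:::change_scores(d, "volume_ml")
  a <- cs$change[cs$intervention == "8s75"]
  b <- cs$change[cs$intervention == "2s75"]
  expect_equal(effect_size(a, b), -effect_size(b, a))

  same <- null_dataset(16, seed = 8)
  ct0 <- interaction_contrasts(same, "volume_ml")
  expect_true(all(abs(ct0$estimate) < 0.15)) # no systematic separation
})

test_that("simple effects report change, percent change and MDC flags", {
  d <- null_dataset(10, seed = 9)
  d$volume_ml[d$time == "post"] <- d$volume_ml[d$time == "pre"][match(
    paste(d$subject, d$intervention)[d$time == "post"],
    paste(d$subject, d$intervention)[d$time == "pre"])]
  se <- simple_effects(d, "volume_ml")
  expect_equal(se$mean_change, rep(0, 3))
  expect_equal(se$p, rep(1, 3))

  d2 <- simulate_crossover_dataset(16, effect_spec(seed = 10))
  se2 <- simple_effects(d2, "volume_ml", mdc = 0.5)
  r875 <- se2[se2$intervention == "8s75", ]
  expect_lt(r875$mean_change, 0)
  expect_equal(r875$pct_change, 100 * r875$mean_change / r875$mean_pre)
  expect_true(all(se2$within_measurement_error)) # all |changes| < 0.5 ml
})

test_that("effect size follows the pooled change-score definition", {
  set.seed(11)
  a <- rnorm(200, -0.3, 0.1); b <- rnorm(200, -0.1, 0.1)
  expect_equal(effect_size(a, b), -2, tolerance = 0.15)
  expect_equal(effect_size(a, a), 0)
  # closed form on a hand-made pair
  a2 <- c(-0.4, -0.2); b2 <- c(-0.2, 0)
  pooled <- sqrt((var(a2) + var(b2)) / 2)
  expect_equal(effect_size(a2, b2), (mean(a2) - mean(b2)) / pooled)
  expect_error(effect_size(c(1, 1), c(1, 1)), "zero")
  expect_error(effect_size(1, c(1, 2)), "at least 2")
})

test_that("effect size and contrasts ignore a common additive constant", {
  d <- simulate_crossover_dataset(12, effect_spec(seed = 12))
  d2 <- d; d2$volume_ml <- d2$volume_ml + 100
  expect_equal(interaction_contrasts(d, "volume_ml")$estimate,
               interaction_contrasts(d2, "volume_ml")$estimate,
               tolerance = 1e-9)
})

test_that("Lilliefors-corrected KS separates normal from exponential", {
  set.seed(13)
  norm_p <- replicate(40, ks_normality(rnorm(100))$p)
  expect_gte(mean(norm_p > 0.05), 0.90)
  exp_p <- replicate(40, ks_normality(rexp(200))$p)
  expect_gte(mean(exp_p < 0.05), 0.90)
  expect_error(ks_normality(c(1, 2, 3)), "at least 4")
  expect_error(ks_normality(rep(2, 10)), "constant")
})

test_that("ICC handles perfect, independent and known-variance data", {
  set.seed(14)
  base <- rnorm(20, 100, 10)
  perfect <- cbind(base, base)
  expect_equal(icc_3_1(perfect, form = "consistency")$icc, 1)
  expect_equal(icc_3_1(perfect)$icc, 1, tolerance = 1e-12)

  indep_icc <- replicate(20, icc_3_1(cbind(rnorm(200), rnorm(200)))$icc)
  expect_lt(abs(mean(indep_icc)), 0.05)

  # variance components sigma2_s = 9, sigma2_e = 1 -> ICC -> 0.9
  subj <- rnorm(400, 0, 3)
  m <- cbind(subj + rnorm(400), subj + rnorm(400))
  ic <- icc_3_1(m)
  expect_equal(ic$icc, 0.9, tolerance = 0.05)
  expect_true(ic$icc_ci95[1] < ic$icc && ic$icc < ic$icc_ci95[2])
  # agreement is penalised relative to consistency under a session shift
  shifted <- cbind(subj + rnorm(400), subj + rnorm(400) + 2)
  ics <- icc_3_1(shifted)
  expect_lt(ics$icc_agreement, ics$icc_consistency)

  expect_error(icc_3_1(m[1:3, ]), "at least 5")
  expect_error(icc_3_1(m[, 1, drop = FALSE]), "at least 2")
  m_na <- m; m_na[1, 1] <- NA
  expect_error(icc_3_1(m_na), "missing")
})

test_that("CV, SEM and MDC follow their formulas", {
  expect_equal(cv_percent(cbind(c(100, 50), c(100, 50))), 0)
  expect_equal(cv_percent(matrix(c(90, 110), nrow = 1)),
               sd(c(90, 110)) / 100 * 100) # 14.14%
  expect_equal(round(cv_percent(matrix(c(90, 110), nrow = 1)), 2), 14.14)
  m <- matrix(runif(20, 50, 150), ncol = 2)
  expect_equal(cv_percent(m), cv_percent(m * 3), tolerance = 1e-12)
  expect_error(cv_percent(matrix(c(0, 0), nrow = 1)), "zero")

  expect_equal(mdc(1), 1.96 * sqrt(2))
  expect_equal(round(mdc(1), 4), 2.7719)
  expect_equal(mdc(0), 0)
  expect_equal(mdc(3), 3 * mdc(1)) # linear
  expect_error(mdc(-1), "non-negative")
  expect_equal(sem_measure(10, 0.91), 3)
})

test_that("crossover sample size follows the paired normal approximation", {
  r <- crossover_sample_size(1, 0.05, 0.8, 0.5)
  expect_equal(r$n, 8) # (1.96 + 0.8416)^2 * 1 = 7.85 -> 8
  expect_match(r$formula, "1 - rho")
  expect_equal(crossover_sample_size(1, 0.05, 0.8, 0.9999)$n, 2)
  ns <- vapply(c(0.3, 0.5, 0.8, 1.2), function(es)
    crossover_sample_size(es)$n, integer(1))
  expect_true(all(diff(ns) <= 0)) # monotone decreasing in ES
  expect_error(crossover_sample_size(0), "positive")
})

test_that("relative change difference reproduces the printed ratios", {
  expect_equal(round(relative_change_difference(-67.35, -36.45)), 46)
  expect_equal(round(relative_change_difference(-67.35, 37.78)), 44)
  expect_error(relative_change_difference(0, 1), "non-zero")
})

test_that("randomization sequences are seeded permutations", {
  r1 <- randomize_sequences(16, seed = 3)
  r2 <- randomize_sequences(16, seed = 3)
  expect_identical(r1, r2)
  counts <- table(r1$subject, r1$intervention)
  expect_true(all(counts == 1))
})
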