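# Crossover-trial inference and reliability metrics: balanced two-factor
# within-subject ANOVA (time x intervention), interaction contrasts on
# change scores, simple effects, change-score effect sizes, Lilliefors
# normality, ICC (two-way), CV, SEM/MDC and the crossover sample-size
# utility.

check_balanced <- function(data, outcome) {
  need <- c("subject", "intervention", "time", outcome)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("dataset lacks columns: ", paste(miss, collapse = ", "))
  tab <- table(data$subject, data$intervention, data$time)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    cells <- apply(bad, 1, function(i) {
      paste(dimnames(tab)[[1]][i[1]], dimnames(tab)[[2]][i[2]],
            dimnames(tab)[[3]][i[3]], sep = "/")
    })
    stop("design is not complete/balanced; offending cells: ",
         paste(unique(cells), collapse = ", "))
  }
  invisible(tab)
}

#' Two-factor repeated-measures ANOVA (time x intervention)
#'
#' Univariate within-subjects ANOVA on a complete balanced crossover
#' dataset, by sums-of-squares decomposition over the subject, time,
#' intervention and time-by-intervention strata. Each effect is tested
#' against its own subject-by-effect interaction stratum. Sphericity is
#' assumed (no correction), so the interaction degrees of freedom are
#' `((t-1)(k-1), (n-1)(t-1)(k-1))` — `(2, 30)` for 16 subjects in the
#' 2 (time) x 3 (intervention) design.
#'
#' @param data Data frame with columns `subject`, `intervention`, `time`
#'   and the outcome; each subject x intervention x time cell exactly once.
#' @param outcome Name of the outcome column.
#' @return Object of class `rm_anova_result`: a data frame `table` with
#'   rows `time`, `intervention`, `time:intervention` (columns `df1`,
#'   `df2`, `ss_effect`, `ss_error`, `F`, `p`) plus `n_subjects`.
#' @export
rm_anova_2x3 <- function(data, outcome) {
  check_balanced(data, outcome)
  y <- data[[outcome]]
  s <- factor(data$subject); iv <- factor(data$intervention)
  tm <- factor(data$time)
  n <- nlevels(s); k <- nlevels(iv); t <- nlevels(tm)
  if (n < 3) stop("need at least 3 subjects")
  g <- mean(y)
  m_s <- tapply(y, s, mean); m_i <- tapply(y, iv, mean)
  m_t <- tapply(y, tm, mean)
  m_si <- tapply(y, list(s, iv), mean); m_st <- tapply(y, list(s, tm), mean)
  m_it <- tapply(y, list(iv, tm), mean)

  ss_s  <- k * t * sum((m_s - g)^2)
  ss_t  <- n * k * sum((m_t - g)^2)
  ss_i  <- n * t * sum((m_i - g)^2)
  ss_it <- n * sum((m_it - outer(m_i, m_t, "+") + g)^2)
  ss_si <- t * sum((m_si - outer(m_s, m_i, "+") + g)^2)
  ss_st <- k * sum((m_st - outer(m_s, m_t, "+") + g)^2)
  ss_tot <- sum((y - g)^2)
  ss_sit <- ss_tot - ss_s - ss_t - ss_i - ss_it - ss_si - ss_st

  eff <- data.frame(
    effect = c("time", "intervention", "time:intervention"),
    df1 = c(t - 1, k - 1, (t - 1) * (k - 1)),
    df2 = c((n - 1) * (t - 1), (n - 1) * (k - 1),
            (n - 1) * (t - 1) * (k - 1)),
    ss_effect = c(ss_t, ss_i, ss_it),
    ss_error = c(ss_st, ss_si, ss_sit)
  )
  eff$F <- (eff$ss_effect / eff$df1) / (eff$ss_error / eff$df2)
  eff$p <- pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  structure(list(table = eff, n_subjects = n, outcome = outcome),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA on %s (n = %d)\n",
              x$outcome, x$n_subjects))
  tb <- x$table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-18s F(%d,%d) = %.3f, p = %.4g\n",
                tb$effect[i], tb$df1[i], tb$df2[i], tb$F[i], tb$p[i]))
  }
  invisible(x)
}

change_scores <- function(data, outcome) {
  check_balanced(data, outcome)
  pre <- data[data$time == "pre", ]
  post <- data[data$time == "post", ]
  key <- function(d) paste(d$subject, d$intervention)
  post <- post[match(key(pre), key(post)), ]
  data.frame(subject = pre$subject, intervention = pre$intervention,
             pre = pre[[outcome]], post = post[[outcome]],
             change = post[[outcome]] - pre[[outcome]])
}

#' Pairwise interaction contrasts on change scores
#'
#' For every ordered pair of interventions, a paired comparison of the
#' per-subject change scores (post minus pre): mean difference, 95% CI,
#' paired t-test p-value and the change-score effect size. No multiplicity
#' correction is applied.
#'
#' @inheritParams rm_anova_2x3
#' @param conf_level Confidence level for the CI (default 0.95).
#' @return Data frame with one row per unordered pair: `intervention_a`,
#'   `intervention_b`, `estimate` (mean change a - mean change b),
#'   `ci_lo`, `ci_hi`, `t`, `df`, `p`, `effect_size`.
#' @export
interaction_contrasts <- function(data, outcome, conf_level = 0.95) {
  cs <- change_scores(data, outcome)
  ivs <- unique(as.character(cs$intervention))
  pairs <- utils::combn(ivs, 2)
  out <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- cs$change[cs$intervention == pairs[1, j]]
    names(a) <- cs$subject[cs$intervention == pairs[1, j]]
    b <- cs$change[cs$intervention == pairs[2, j]]
    names(b) <- cs$subject[cs$intervention == pairs[2, j]]
    b <- b[names(a)]
    d <- a - b
    n <- length(d)
    se <- sd(d) / sqrt(n)
    est <- mean(d)
    tval <- if (se == 0) ifelse(est == 0, 0, sign(est) * Inf) else est / se
    p <- 2 * pt(abs(tval), n - 1, lower.tail = FALSE)
    hw <- qt(1 - (1 - conf_level) / 2, n - 1) * se
    es <- tryCatch(effect_size(a, b), error = function(e) NA_real_)
    out[[j]] <- data.frame(
      intervention_a = pairs[1, j], intervention_b = pairs[2, j],
      estimate = est, ci_lo = est - hw, ci_hi = est + hw,
      t = tval, df = n - 1, p = p, effect_size = es
    )
  }
  do.call(rbind, out)
}

#' Simple effects: pre versus post within each intervention
#'
#' Paired t-test of pre versus post per intervention, with the mean change
#' and the percent change relative to the pre-intervention mean. When an
#' MDC is supplied, mean changes smaller than it are flagged as within
#' measurement error.
#'
#' @inheritParams rm_anova_2x3
#' @param mdc Optional minimal detectable change in outcome units.
#' @return Data frame with `intervention`, `mean_pre`, `mean_post`,
#'   `mean_change`, `pct_change`, `t`, `df`, `p`,
#'   `within_measurement_error` (`NA` without an MDC).
#' @export
simple_effects <- function(data, outcome, mdc = NULL) {
  cs <- change_scores(data, outcome)
  ivs <- unique(as.character(cs$intervention))
  out <- lapply(ivs, function(iv) {
    d <- cs[cs$intervention == iv, ]
    n <- nrow(d)
    se <- sd(d$change) / sqrt(n)
    est <- mean(d$change)
    tval <- if (se == 0) ifelse(est == 0, 0, sign(est) * Inf) else est / se
    p <- if (se == 0 && est == 0) 1 else
      2 * pt(abs(tval), n - 1, lower.tail = FALSE)
    data.frame(
      intervention = iv,
      mean_pre = mean(d$pre), mean_post = mean(d$post),
      mean_change = est,
      pct_change = 100 * est / mean(d$pre),
      t = tval, df = n - 1, p = p,
      within_measurement_error =
        if (is.null(mdc)) NA else abs(est) < mdc
    )
  })
  do.call(rbind, out)
}

#' Change-score effect size between two interventions
#'
#' Difference of mean change scores divided by the pooled (n-1 weighted)
#' standard deviation of the change scores.
#'
#' @param changes_a,changes_b Numeric change-score vectors (>= 2 values
#'   each).
#' @return The effect size (dimensionless).
#' @export
effect_size <- function(changes_a, changes_b) {
  if (length(changes_a) < 2 || length(changes_b) < 2) {
    stop("need at least 2 change scores per group")
  }
  na <- length(changes_a); nb <- length(changes_b)
  pooled <- sqrt(((na - 1) * var(changes_a) + (nb - 1) * var(changes_b)) /
                   (na + nb - 2))
  if (pooled == 0) stop("pooled change-score SD is zero; effect size undefined")
  (mean(changes_a) - mean(changes_b)) / pooled
}

#' Kolmogorov-Smirnov normality test (Lilliefors-corrected)
#'
#' One-sample KS test against a normal distribution with mean and SD
#' estimated from the sample, with the Lilliefors correction for the
#' estimated parameters.
#'
#' @param values Numeric sample, n >= 4, non-constant.
#' @return List with `statistic` and `p`.
#' @export
ks_normality <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4) stop("need at least 4 values")
  if (sd(values) == 0) stop("values are constant; normality test undefined")
  res <- nortest::lillie.test(values)
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Intraclass correlation from a two-way model
#'
#' Single-rater ICC from the two-way (subjects x sessions) mean squares.
#' Both the consistency form ICC(3,1) = (MSR - MSE) / (MSR + (k-1) MSE)
#' and the absolute-agreement form (which additionally charges the
#' session mean-square) are computed; absolute agreement is reported by
#' default. 95% CIs follow the F-distribution bounds of McGraw & Wong.
#'
#' @param measurements Numeric matrix, subjects in rows (>= 5), sessions
#'   in columns (>= 2); no missing cells.
#' @param form `"agreement"` (default) or `"consistency"`.
#' @param conf_level CI level (default 0.95).
#' @return Object of class `icc_result`: `icc`, `icc_ci95`, `form`,
#'   `icc_consistency`, `icc_agreement`, mean squares and dimensions.
#' @export
icc_3_1 <- function(measurements, form = c("agreement", "consistency"),
                    conf_level = 0.95) {
  form <- match.arg(form)
  m <- as.matrix(measurements)
  if (anyNA(m)) stop("missing cells in the measurement matrix")
  n <- nrow(m); k <- ncol(m)
  if (n < 5) stop("need at least 5 subjects")
  if (k < 2) stop("need at least 2 sessions")
  g <- mean(m)
  ssr <- k * sum((rowMeans(m) - g)^2)
  ssc <- n * sum((colMeans(m) - g)^2)
  sse <- sum((m - g)^2) - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))

  icc_c <- (msr - mse) / (msr + (k - 1) * mse)
  icc_a <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf_level

  if (form == "consistency") {
    icc <- icc_c
    fobs <- msr / mse
    fl <- fobs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- fobs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    icc <- icc_a
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lo, hi)
  }
  structure(list(
    icc = icc, icc_ci95 = ci, form = form,
    icc_consistency = icc_c, icc_agreement = icc_a,
    ms = c(msr = msr, msc = msc, mse = mse),
    n_subjects = n, n_sessions = k
  ), class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s): %.4f [%.4f, %.4f] (n = %d subjects, k = %d sessions)\n",
              x$form, x$icc, x$icc_ci95[1], x$icc_ci95[2],
              x$n_subjects, x$n_sessions))
  invisible(x)
}

#' Mean within-subject coefficient of variation
#'
#' Per-subject SD over mean of the repeated measures (as a percentage),
#' averaged across subjects.
#'
#' @param measurements Numeric matrix, subjects in rows, repeats in
#'   columns; positive subject means required.
#' @return CV in percent.
#' @export
cv_percent <- function(measurements) {
  m <- as.matrix(measurements)
  mu <- rowMeans(m)
  if (any(mu == 0)) stop("zero subject mean; CV undefined")
  mean(apply(m, 1, sd) / mu) * 100
}

#' Standard error of measurement
#'
#' `SEM = pooled SD x sqrt(1 - ICC)`.
#'
#' @param pooled_sd SD of the measurements (>= 0).
#' @param icc Reliability coefficient in `[-1, 1]`.
#' @return SEM in measurement units.
#' @export
sem_measure <- function(pooled_sd, icc) {
  if (pooled_sd < 0) stop("pooled_sd must be non-negative")
  if (icc > 1) stop("icc cannot exceed 1")
  pooled_sd * sqrt(1 - icc)
}

#' Minimal detectable change
#'
#' `MDC = SEM x 1.96 x sqrt(2)`: the smallest change exceeding measurement
#' error at 95% confidence over two measurements.
#'
#' @param sem Standard error of measurement (>= 0).
#' @return MDC in measurement units.
#' @export
mdc <- function(sem) {
  if (any(sem < 0)) stop("sem must be non-negative")
  sem * 1.96 * sqrt(2)
}

#' Sample size for a paired/crossover comparison
#'
#' Normal-approximation sample size for detecting a standardized effect
#' `es` on change scores in a paired design with correlation `rho` between
#' repeated measures:
#' `n = (z_(1-alpha/2) + z_power)^2 * 2 (1 - rho) / es^2`, rounded up,
#' with a floor of 2. The formula used is returned alongside the result.
#'
#' @param es Standardized effect size (> 0).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param correlation Correlation between repeated measures, `|rho| < 1`
#'   (default 0.2).
#' @return List with `n`, the inputs and `formula` (a string).
#' @export
crossover_sample_size <- function(es, alpha = 0.05, power = 0.80,
                                  correlation = 0.2) {
  if (es <= 0) stop("effect size must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)")
  }
  if (abs(correlation) >= 1) stop("|correlation| must be < 1")
  za <- qnorm(1 - alpha / 2); zb <- qnorm(power)
  n_raw <- (za + zb)^2 * 2 * (1 - correlation) / es^2
  list(
    n = max(2L, as.integer(ceiling(n_raw))),
    n_unrounded = n_raw,
    es = es, alpha = alpha, power = power, correlation = correlation,
    formula = "n = (z_{1-alpha/2} + z_{power})^2 * 2 * (1 - rho) / ES^2"
  )
}

#' Relative difference between two mean changes
#'
#' How much larger (in percent of the first) the magnitude of change `a`
#' is than the magnitude of change `b`: `(|a| - |b|) / |a| * 100`. Used to
#' compare intervention responses, e.g. mean stiffness changes of 67.35
#' versus 36.45 N mm^-1 give 46% (nearest integer).
#'
#' @param change_a,change_b Mean changes (any sign).
#' @return Percent difference relative to `|change_a|`.
#' @export
relative_change_difference <- function(change_a, change_b) {
  if (change_a == 0) stop("change_a must be non-zero")
  (abs(change_a) - abs(change_b)) / abs(change_a) * 100
}

#' Seeded randomization sequences for a crossover trial
#'
#' Computer-based random allocation of intervention order, one permutation
#' per subject.
#'
#' @param n_subjects Number of subjects.
#' @param interventions Character vector of intervention labels.
#' @param seed Integer seed.
#' @return Data frame `subject`, `period`, `intervention`.
#' @export
randomize_sequences <- function(n_subjects,
                                interventions = c("8s75", "2s75", "8s35"),
                                seed = 1L) {
  set.seed(as.integer(seed))
  k <- length(interventions)
  do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    data.frame(subject = sprintf("S%02d", s), period = seq_len(k),
               intervention = interventions[sample(k)])
  }))
}
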