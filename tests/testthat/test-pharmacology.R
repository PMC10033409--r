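test_that("saturation binding fits recover Bmax and Kd", {
  L <- c(5, 15, 50, 150, 500, 1500)  # pM
  bound <- 100 * L / (50 + L)
  f <- fit_saturation(L, bound)
  expect_equal(f$Bmax, 100, tolerance = 1e-6)
  expect_equal(f$Kd, 50, tolerance = 1e-6)
  expect_true(is.na(f$flag))
  # bound at L = Kd equals Bmax / 2
  expect_equal(100 * 50 / (50 + 50), 100 / 2)

  # 5% noise at a fixed seed on a duplicated 10-point design: Kd within 15%
  Ld <- rep(10^seq(0.5, 3.5, length.out = 10), each = 2)
  mu <- 100 * Ld / (50 + Ld)
  noisy <- withr::with_seed(14, mu + rnorm(length(mu), 0, 5))
  fn <- fit_saturation(Ld, noisy)
  expect_equal(fn$Kd, 50, tolerance = 0.15)
  expect_error(fit_saturation(c(1, 2, 3), c(1, 2, 3)), ">= 4")
})

test_that("competition fits nest correctly and recover planted IC50s", {
  A <- seq(-10, -4, by = 0.5)
  # two-site with F1 = 1 reproduces the one-site curve exactly (1e-10)
  y1 <- icl3kit:::.one_site_curve(A, 100, 0, -6.5)
  y2 <- icl3kit:::.two_site_curve(A, 100, 0, 1, -6.5, -8)
  expect_equal(y1, y2, tolerance = 1e-10)
  y2b <- icl3kit:::.two_site_curve(A, 100, 0, 0, -3, -6.5)
  expect_equal(y1, y2b, tolerance = 1e-10)

  # noiseless one-site round trip from IC50 = 300 nM
  Y <- icl3kit:::.one_site_curve(A, 100, 0, log10(300e-9))
  f1 <- fit_competition(A, Y, sites = 1)
  expect_equal(f1$IC50, 300e-9, tolerance = 1e-6)
  expect_equal(f1$Bmax, 100, tolerance = 1e-6)
  # midpoint property: Y at A = log10(IC50) is (Bmax + Bmin) / 2
  expect_equal(icl3kit:::.one_site_curve(log10(300e-9), 100, 0, log10(300e-9)),
               50)

  # two-site recovery with a genuine mixture
  Y2 <- icl3kit:::.two_site_curve(A, 100, 0, 0.4, -8, -5.5)
  f2 <- fit_competition(A, Y2, sites = 2, tracer_L = 50e-12,
                        tracer_KD = 25e-12)
  ics <- sort(c(f2$IC50_1, f2$IC50_2))
  expect_equal(ics, sort(c(1e-8, 10^-5.5)), tolerance = 1e-3)
  expect_true(f2$F1 >= 0 && f2$F1 <= 1)
  # the weighted-average IC50 and its Cheng-Prusoff Ki are attached
  wavg <- f2$F1 * f2$IC50_1 + (1 - f2$F1) * f2$IC50_2
  expect_equal(f2$IC50, wavg, tolerance = 1e-9)
  expect_equal(f2$Ki, cheng_prusoff(f2$IC50, 50e-12, 25e-12))

  # degenerate two-site fit on one-site data pins F1 and warns
  expect_warning(fd <- fit_competition(A, Y, sites = 2), "one-site")
  expect_equal(fd$flag, "F1_pinned_consider_one_site")
})

test_that("Cheng-Prusoff conversion satisfies its closed-form identities", {
  expect_equal(cheng_prusoff(300e-9, 50e-12, 25e-12), 100e-9)  # 300/(1+2)
  expect_equal(cheng_prusoff(1e-6, 1e-12, 1e-9), 1e-6, tolerance = 1e-3)
  expect_equal(cheng_prusoff(1e-6, 1e-9, 1e-9), 5e-7)  # L = KD halves IC50
  # monotone decreasing in L, increasing in KD, always <= IC50
  Ls <- 10^seq(-12, -8, 0.5)
  kis <- cheng_prusoff(1e-6, Ls, 1e-10)
  expect_true(all(diff(kis) < 0))
  expect_true(all(kis <= 1e-6))
  kds <- cheng_prusoff(1e-6, 1e-10, 10^seq(-12, -8, 0.5))
  expect_true(all(diff(kds) > 0))
  expect_error(cheng_prusoff(-1, 1, 1), "input error")
})

test_that("Hill fits recover dose-response parameters and efficacy", {
  conc <- 10^seq(-11, -4, 0.5)
  E <- icl3kit:::.hill_curve(log10(conc), 1, 0, log10(10e-9), 1)
  f <- fit_hill(conc, E)
  expect_equal(f$EC50, 10e-9, tolerance = 1e-6)
  expect_equal(f$NH, 1, tolerance = 1e-6)
  expect_equal(f$efficacy, log10(1 / 10e-9), tolerance = 1e-6)
  # midpoint property
  expect_equal(icl3kit:::.hill_curve(log10(10e-9), 1, 0, log10(10e-9), 1), 0.5)
  # doubling Emax at fixed EC50 raises efficacy by log10(2)
  f2 <- fit_hill(conc, 2 * E)
  expect_equal(f2$efficacy - f$efficacy, log10(2), tolerance = 1e-6)

  # parameter recovery at 5% noise, 4 replicates, over 100 seeds
  ok_ec50 <- ok_nh <- logical(100)
  for (s in 1:100) {
    d <- gen_dose_response(preset = "fig4c-wt", replicates = 4,
                           noise_sd_fraction = 0.05, seed = s)
    avg <- aggregate(response ~ conc, d, mean)
    fs <- fit_hill(avg$conc, avg$response)
    ok_ec50[s] <- abs(fs$EC50 - 10e-9) / 10e-9 < 0.25
    ok_nh[s] <- abs(fs$NH - 1) < 0.30
  }
  expect_gt(mean(ok_ec50), 0.95)
  expect_gt(mean(ok_nh), 0.95)

  expect_error(fit_hill(10^(-8:-5), rep(1, 4)), ">= 5")
})

test_that("differential metrics, percent bound and ratios compute exactly", {
  expect_equal(as.numeric(delta_metric(c(0.30, 0.32), c(0.25, 0.27))), 0.05)
  expect_equal(as.numeric(delta_metric(c(1, 2), c(1, 2))), 0)
  # antisymmetric under arm swap
  a <- c(0.4, 0.5); b <- c(0.1, 0.3)
  expect_equal(as.numeric(delta_metric(a, b)),
               -as.numeric(delta_metric(b, a)))
  expect_equal(attr(delta_metric(a, b, mode = "InsP1"), "mode"), "InsP1")
  expect_error(delta_metric(numeric(0), 1), "input error")

  expect_equal(fret_ratio(665, 620), 665 / 620)
  expect_error(fret_ratio(1, 0), "input error")

  expect_equal(as.numeric(percent_bound(100, 25)), 75)
  expect_equal(as.numeric(percent_bound(100, 100)), 0)
  expect_equal(as.numeric(percent_bound(1000, c(400, 420))), 59)
  # percent bound + percent free = 100 by construction
  pb <- as.numeric(percent_bound(1000, c(400, 420)))
  expect_equal(pb + 100 * mean(c(400, 420)) / 1000, 100)
  expect_equal(attr(percent_bound(100, 120), "flag"), "outside_0_100")
  expect_error(percent_bound(0, 10), "input error")
})

test_that("kinetic traces are smoothed, normalized and plateau-read", {
  # constant trace: normalized 1.0 everywhere, specific signal 0 with control 1
  tr <- gen_kinetic_trace(baseline = 500, fold_change = 1, noise_sd = 0)
  res <- process_kinetic_trace(tr$time, tr$lum, tr$drug_index,
                               control_value = 1.0)
  expect_equal(res$plateau, 1.0, tolerance = 1e-12)
  expect_equal(res$specific_signal, 0, tolerance = 1e-12)
  expect_equal(unname(res$windows), c(3, 8))

  # noiseless rise to 2.4x: plateau 2.4 after normalization
  tr2 <- gen_kinetic_trace(baseline = 1000, fold_change = 2.4,
                           rise_constant = 30, drug_time = 300,
                           total_time = 900, dt = 5, noise_sd = 0)
  res2 <- process_kinetic_trace(tr2$time, tr2$lum, tr2$drug_index,
                                control_value = 0.5)
  expect_equal(res2$plateau, 2.4, tolerance = 0.01)
  expect_equal(res2$specific_signal, 2.4 - 0.5, tolerance = 0.01)

  # invariance to multiplying the raw trace by a constant
  res2b <- process_kinetic_trace(tr2$time, 37 * tr2$lum, tr2$drug_index, 0.5)
  expect_equal(res2b$normalized, res2$normalized, tolerance = 1e-12)
  expect_equal(res2b$plateau, res2$plateau, tolerance = 1e-12)

  expect_error(process_kinetic_trace(1:10, rep(1, 10), 8), "input error")
})

test_that("Z-score filtering removes only flagged outliers beyond |Z| = 3", {
  # all-equal values: zero comparator variance, nothing removed
  expect_warning(r0 <- zscore_outlier_filter(rep(2, 5),
                                             c(TRUE, rep(FALSE, 4))),
                 "zero variance")
  expect_equal(r0$retained, rep(2, 5))

  # construct a candidate with known leave-one-out Z
  base <- c(0, 0.1, -0.1, 0.05, -0.05)
  m <- mean(base); s <- sd(base)
  big <- m + 3.5 * s
  small <- m + 2.9 * s
  # flagged |Z| = 3.5 -> removed
  r1 <- zscore_outlier_filter(c(base, big), c(rep(FALSE, 5), TRUE))
  expect_equal(r1$removed, 6L)
  expect_equal(r1$z[6], 3.5, tolerance = 1e-12)
  # unflagged |Z| = 3.5 -> retained
  r2 <- zscore_outlier_filter(c(base, big), rep(FALSE, 6))
  expect_equal(r2$removed, integer(0))
  expect_equal(length(r2$retained), 6L)
  # flagged |Z| = 2.9 -> retained
  r3 <- zscore_outlier_filter(c(base, small), c(rep(FALSE, 5), TRUE))
  expect_equal(r3$removed, integer(0))
  expect_equal(r3$z[6], 2.9, tolerance = 1e-12)
})
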