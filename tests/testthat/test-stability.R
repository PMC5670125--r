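test_that("melting normalization maps baseline/plateau to 0/1", {
  # raw fluorescence: baseline 100, plateau 900, one mid-transition point 500
  T <- seq(25, 95, 2.5)
  y <- c(rep(100, 10), 300, 500, 700, rep(900, 16))
  cv <- curve_table(T, y, "melting")
  nz <- normalize_melting(cv)
  expect_equal(nz$y[T == 25][1], 0)
  expect_equal(nz$y[12], 0.5)           # the 500 point
  expect_equal(max(nz$y), 1)

  # idempotence on a curve with exact 0/1 plateaus
  nz2 <- normalize_melting(nz)
  expect_equal(nz2$y, nz$y, tolerance = 1e-9)

  flat <- curve_table(T, rep(5, length(T)), "melting")
  expect_error(normalize_melting(flat), "no transition")
})

test_that("normalized noiseless sigmoids cross 0.5 at the generator midpoint", {
  sp <- sigmoid_spec(59.63, 4.72, baseline = 120, amplitude = 780)
  nz <- normalize_melting(simulate_melting_curve(sp, seed = 1))
  cross <- suppressWarnings(stats::approx(nz$y, nz$x, xout = 0.5)$y)
  expect_equal(cross, 59.63, tolerance = 0.02)
})

test_that("logistic fit is self-consistent and obeys the slope identity", {
  # fit(simulate(spec, noise=0)) recovers the spec (no normalization step,
  # so recovery is limited only by the optimizer)
  sp <- sigmoid_spec(62.04, 4.72)
  cv <- simulate_melting_curve(sp, seed = 1)
  fit <- fit_unfolding(cv)
  expect_equal(fit$midpoint, 62.04, tolerance = 1e-6)
  expect_equal(fit$k, 4.72, tolerance = 1e-6)
  expect_equal(fit$max_slope * fit$k, 25, tolerance = 1e-9)
  expect_equal(fit$onset, 62.04 - 4.72 * log(19), tolerance = 1e-5)
  expect_lt(fit$onset, fit$midpoint)
  expect_equal(fit$residual_rms, 0, tolerance = 1e-7)
})

test_that("temperature-shift equivariance: +c moves midpoint and onset only", {
  sp <- sigmoid_spec(55, 4)
  f0 <- fit_unfolding(simulate_melting_curve(sp, seed = 1))
  spc <- sigmoid_spec(55 + 7, 4, T_grid = seq(25, 95, 0.5) + 7)
  fc <- fit_unfolding(simulate_melting_curve(spc, seed = 1))
  expect_equal(fc$midpoint - f0$midpoint, 7, tolerance = 1e-5)
  expect_equal(fc$onset - f0$onset, 7, tolerance = 1e-5)
  expect_equal(fc$k, f0$k, tolerance = 1e-6)
  expect_equal(fc$max_slope, f0$max_slope, tolerance = 1e-6)
})

test_that("midpoint recovery is unbiased under realistic noise", {
  errs <- vapply(1:50, function(s) {
    sp <- sigmoid_spec(60, 4, noise_sd = 0.02)
    fit_unfolding(simulate_melting_curve(sp, seed = s))$midpoint - 60
  }, 0)
  expect_lt(abs(mean(errs)), 0.2)
})

test_that("T50 fitting recovers the inactivation midpoint", {
  sp <- sigmoid_spec(49, 3, direction = "activity", amplitude = 100,
                     T_grid = seq(37, 70, 1))
  fit <- fit_t50(simulate_melting_curve(sp, seed = 1))
  expect_equal(fit$midpoint, 49, tolerance = 1e-4)
  # half the activity survives at the fitted midpoint, by construction
  expect_equal(100 / (1 + exp((fit$midpoint - fit$midpoint) / fit$k)), 50)

  # percent-scale guard
  frac <- curve_table(seq(37, 70, 1), 0.9 / (1 + exp((seq(37, 70, 1) - 49) / 3)),
                      "activity")
  expect_error(fit_t50(frac), "percent")

  t50s <- vapply(1:50, function(s) {
    spn <- sigmoid_spec(49, 3, direction = "activity", amplitude = 100,
                        noise_sd = 5, T_grid = seq(37, 70, 1))
    fit_t50(simulate_melting_curve(spn, seed = s))$midpoint
  }, 0)
  expect_lt(stats::sd(t50s), 1)
  expect_lt(abs(mean(t50s) - 49), 0.5)
})

test_that("Michaelis-Menten fitting recovers noiseless parameters exactly", {
  sp <- kinetics_spec(Km = 0.89, kcat = 59.77, E0_mg = 0.001,
                      E0_nmol = 0.02813)
  fit <- fit_michaelis_menten(simulate_kinetics(sp, seed = 1),
                              E0_mg = 0.001, E0_nmol = 0.02813)
  expect_equal(fit$Km, 0.89, tolerance = 1e-6)
  expect_equal(fit$kcat, 59.77, tolerance = 1e-6)
  expect_equal(fit$efficiency, fit$kcat / fit$Km)
  expect_equal(fit$specific_activity, fit$Vmax / 0.001)
})

test_that("kinetics scale equivariance: rates x c scale Vmax/kcat, not Km", {
  sp <- kinetics_spec(Km = 2, kcat = 10, E0_mg = 0.01, E0_nmol = 0.3, cv = 0.03)
  cv <- simulate_kinetics(sp, seed = 5)
  f1 <- fit_michaelis_menten(cv, 0.01, 0.3)
  cv3 <- curve_table(cv$x, 3 * cv$y, "kinetics")
  f3 <- fit_michaelis_menten(cv3, 0.01, 0.3)
  expect_equal(f3$Km, f1$Km, tolerance = 1e-8)
  expect_equal(f3$Vmax, 3 * f1$Vmax, tolerance = 1e-8)
  expect_equal(f3$kcat, 3 * f1$kcat, tolerance = 1e-8)
  expect_equal(f3$specific_activity, 3 * f1$specific_activity, tolerance = 1e-8)
})

test_that("saturating-only substrate designs give a wide Km uncertainty", {
  Km <- 0.5; Vmax <- 2
  S <- Km * c(20, 30, 40, 50, 60, 80)
  set.seed(9)
  v <- Vmax * S / (Km + S) * (1 + rnorm(length(S), sd = 0.05))
  fit <- fit_michaelis_menten(curve_table(S, v, "kinetics"), 1, 1)
  expect_gt(fit$se$Km / fit$Km, 0.5)
  # profile-likelihood oracle: RSS stays within the 1-sigma threshold over a
  # wide Km range, confirming the reported uncertainty is genuine
  rss <- function(km) {
    vm <- sum(v * S / (km + S)) / sum((S / (km + S))^2)
    sum((v - vm * S / (km + S))^2)
  }
  rss_hat <- rss(fit$Km)
  thresh <- rss_hat * (1 + stats::qf(0.683, 1, length(S) - 2) / (length(S) - 2))
  in_band <- vapply(fit$Km * c(0.5, 1.5), function(km) rss(km) <= thresh,
                    TRUE)
  expect_true(all(in_band))
})
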