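test_that("Butterworth low-pass has the documented frequency response", {
  rate <- 1000
  t <- seq(0, 4, by = 1 / rate)
  # DC gain one
  expect_equal(butterworth_lowpass(rep(2.5, length(t)), rate),
               rep(2.5, length(t)), tolerance = 1e-4)
  # single-pass magnitude 1/sqrt(2) at the 18 Hz cutoff
  x18 <- sin(2 * pi * 18 * t)
  y18 <- butterworth_lowpass(x18, rate, zero_phase = FALSE)
  mid <- t > 1 & t < 3    # steady state
  ratio <- diff(range(y18[mid])) / diff(range(x18[mid]))
  expect_equal(ratio, 1 / sqrt(2), tolerance = 0.02)
  # a 100 Hz component is attenuated by more than 40 dB single-pass
  x100 <- sin(2 * pi * 100 * t)
  y100 <- butterworth_lowpass(x100, rate, zero_phase = FALSE)
  expect_lt(max(abs(y100[mid])), 10^(-40 / 20))
  expect_error(butterworth_lowpass(x18, rate = 30), "twice the cutoff")
})

test_that("contact events are the threshold crossings", {
  t <- seq(0, 1, by = 0.001)
  z <- ifelse(t >= 0.2 & t <= 0.6, 500, 0)
  ev <- detect_events(z, t)
  expect_lt(abs(ev$heel_strike - 0.2), 0.0011)   # within one sample
  expect_lt(abs(ev$toe_off - 0.6), 0.0011)
  expect_error(detect_events(rep(0, 10), seq(0, 1, length.out = 10)),
               "no contact")
  # ramped pulse: interpolated crossings match a brute-force scan
  z2 <- pmax(0, 400 * (t - 0.3)) * (t < 0.7)
  ev2 <- detect_events(z2, t, threshold = 20)
  brute_up <- t[min(which(z2 > 20))]
  expect_lt(abs(ev2$heel_strike - (0.3 + 20 / 400)), 1e-3)
  expect_lte(ev2$heel_strike, brute_up)
})

test_that("phase normalization resamples to 101 points between events", {
  t <- seq(0, 1, by = 0.01)
  ev <- list(heel_strike = 0.2, toe_off = 0.8)
  ramp <- phase_normalize(t, t, ev)
  expect_length(ramp$values, 101)
  expect_equal(ramp$values, seq(0.2, 0.8, length.out = 101),
               tolerance = 1e-12)
  # identity on an already-101-point series between its endpoints
  s <- sin(seq(0, pi, length.out = 101))
  ts <- seq(0, 1, length.out = 101)
  again <- phase_normalize(s, ts, list(heel_strike = 0, toe_off = 1))
  expect_equal(again$values, s, tolerance = 1e-9)
  # mid-phase value of a sinusoid matches analytic evaluation
  y <- sin(2 * pi * t)
  pn <- phase_normalize(y, t, ev)
  expect_equal(pn$values[51], sin(2 * pi * 0.5), tolerance = 1e-6)
  expect_error(phase_normalize(y, t, list(heel_strike = 0.8,
                                          toe_off = 0.2)), "order")
})

test_that("body-size normalization uses BW and BW x BH", {
  expect_equal(normalize_grf(63.3 * 9.81, 63.3), 100)
  expect_equal(normalize_grf(0, 70), 0)
  expect_equal(normalize_grm(104.9, 63.3, 1.69),
               104.9 / (63.3 * 9.81 * 1.69) * 100)
  expect_equal(normalize_grm(104.9, 63.3, 1.69), 10.0, tolerance = 1e-3)
})

test_that("agreement metrics match hand-computed formulas", {
  est <- c(1, 2, 3, 4, 5)
  ref <- c(2, 2, 4, 4, 6)
  m <- compare_series(est, ref)
  # independent arithmetic
  n <- 5
  rho_hand <- (sum(est * ref) - n * mean(est) * mean(ref)) /
    ((n - 1) * stats::sd(est) * stats::sd(ref))
  rmse_hand <- sqrt(mean((est - ref)^2))
  rrmse_hand <- rmse_hand / mean(c(diff(range(est)),
                                   diff(range(ref)))) * 100
  expect_equal(m$rho, rho_hand, tolerance = 1e-12)
  expect_equal(m$rmse, rmse_hand, tolerance = 1e-12)
  expect_equal(m$rrmse, rrmse_hand, tolerance = 1e-12)
  # trivial cases
  perfect <- compare_series(est, est)
  expect_equal(perfect$rho, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$rrmse, 0)
  anti <- compare_series(est - 3, -(est - 3))
  expect_equal(anti$rho, -1)
  # symmetry and affine invariance
  sw <- compare_series(ref, est)
  expect_equal(sw$rmse, m$rmse)
  expect_equal(sw$rrmse, m$rrmse)
  expect_equal(compare_series(2 * est + 7, ref)$rho, m$rho)
  # degenerate input
  flat <- compare_series(rep(1, 5), ref)
  expect_true(is.na(flat$rho))
  expect_equal(flat$class, "undefined")
})

test_that("correlation bands reproduce the published classification", {
  expect_equal(classify_correlation(0.749), "strong")
  expect_equal(classify_correlation(0.520), "moderate")
  expect_equal(classify_correlation(0.95), "excellent")
  expect_equal(classify_correlation(0.2), "weak")
  expect_equal(classify_correlation(-0.481), "weak")
  expect_equal(classify_correlation(c(0.35, 0.67, 0.9)),
               c("weak", "moderate", "strong"))
  expect_error(classify_correlation(1.2))
})

test_that("metrics report covers the shared channels", {
  est <- list(vertical = c(1, 2, 3), medial = c(0, 1, 0))
  ref <- list(vertical = c(1, 2, 4), anterior = c(1, 1, 1))
  rep <- metrics_report(est, ref)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$channel, "vertical")
  expect_true(all(c("rho", "class", "rmse", "rrmse") %in% names(rep)))
})

test_that("phase-normalized self-comparison is exact", {
  t <- seq(0, 1, by = 0.001)
  z <- 600 * exp(-((t - 0.5) / 0.15)^2) + 30
  ev <- detect_events(z, t, threshold = 50)
  p1 <- phase_normalize(z, t, ev)
  m <- compare_series(p1, p1)
  expect_equal(m$rho, 1, tolerance = 1e-12)
})
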