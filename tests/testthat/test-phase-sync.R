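test_that("NBG bandpass is zero-phase, selective and symmetric", {
  fs <- 2000; t <- (1:(fs * 5)) / fs
  x <- sin(2 * pi * 80 * t)
  y <- bandpass_nbg(x, 80, fs)
  mid <- (fs):(4 * fs)
  # passband gain and zero phase shift (regression against the input)
  expect_gt(stats::sd(y[mid]) / stats::sd(x[mid]), 0.9)
  expect_equal(stats::coef(stats::lm(y[mid] ~ x[mid]))[[2]], 1,
               tolerance = 0.01)
  # selectivity: attenuation grows monotonically away from the band; the
  # 65-tap design reaches 20 dB rejection by +-40 Hz and >60 dB by +-60 Hz
  att <- vapply(c(10, 20, 40, 60), function(f_off) {
    z <- bandpass_nbg(sin(2 * pi * (80 + f_off) * t), 80, fs)
    20 * log10(stats::sd(z[mid]) / stats::sd(x[mid]))
  }, 0)
  expect_true(all(diff(att) < 0))
  expect_lt(att[3], -20)
  expect_lt(att[4], -60)
  # forward-backward symmetry: filtering the reversed signal and reversing
  # back gives the same output
  n <- stats::rnorm(fs * 2)
  expect_equal(rev(bandpass_nbg(rev(n), 80, fs)),
               bandpass_nbg(n, 80, fs), tolerance = 1e-8)
  expect_error(bandpass_nbg(x, 3, fs), "invalid")
})

test_that("instantaneous phase obeys the analytic-signal identities", {
  fs <- 2000; t <- (0:(fs * 2 - 1)) / fs
  ph <- instantaneous_phase(cos(2 * pi * 80 * t))$phase
  mid <- 200:(length(ph) - 200)
  dphi <- diff(ph[mid])
  dphi <- dphi[dphi > 0]          # drop wrap points
  expect_equal(stats::median(dphi) * fs, 2 * pi * 80, tolerance = 0.01)
  # identical signals: zero difference everywhere
  x <- bandpass_nbg(stats::rnorm(fs * 2), 80, fs)
  p1 <- instantaneous_phase(x)$phase
  expect_true(all(abs(p1 - instantaneous_phase(x)$phase) == 0))
  # quarter-period delay of an 80-Hz tone: difference pi/2
  lag <- round(fs / 80 / 4)
  y <- cos(2 * pi * 80 * (t - lag / fs))
  p2 <- instantaneous_phase(cos(2 * pi * 80 * t))$phase
  p3 <- instantaneous_phase(y)$phase
  d <- (p2 - p3)[mid]
  expect_equal(stats::median(d %% (2 * pi)), 2 * pi * 80 * lag / fs,
               tolerance = 0.02)
  # all-zero input: undefined phases, not garbage
  pz <- instantaneous_phase(numeric(100))
  expect_true(all(is.na(pz$phase)))
})

test_that("von Mises concentration estimates match a grid-search MLE oracle", {
  for (kappa in c(0.5, 2, 8)) {
    th <- rvonmises(1000, 0.3, kappa, seed = round(kappa * 10))
    est <- fit_von_mises(th)
    oracle <- oracle_vm_kappa(th)
    expect_equal(est$kappa, oracle, tolerance = 0.15)
    expect_lt(abs(est$mu - 0.3), 0.2)
  }
  # direct recovery window for kappa = 2 (stated contract)
  th2 <- rvonmises(1000, 0, 2, seed = 7)
  expect_gt(fit_von_mises(th2)$kappa, 1.7)
  expect_lt(fit_von_mises(th2)$kappa, 2.3)
})

test_that("von Mises estimator handles degenerate and small samples", {
  u <- rvonmises(1000, 0, 0, seed = 12)
  expect_lt(fit_von_mises(u)$kappa, 0.1)
  same <- fit_von_mises(rep(1.2, 50))
  expect_equal(same$kappa, 1000)            # kappa_max cap
  expect_equal(same$mu, 1.2)
  small <- fit_von_mises(stats::runif(5))
  expect_true(is.na(small$kappa))
  expect_match(small$diagnostic, "few")
})

test_that("concentration relates to circular variance as sigma^2 = 1/kappa", {
  th <- rvonmises(4000, 0, 8, seed = 5)
  est <- fit_von_mises(th)
  sigma2 <- stats::var(th)   # concentrated: wrapping negligible
  expect_equal(sigma2 * est$kappa, 1, tolerance = 0.1)
})

test_that("estimated kappa is monotone in generating kappa", {
  med <- vapply(c(0.5, 2, 8), function(k) {
    stats::median(vapply(1:20, function(r)
      fit_von_mises(rvonmises(500, 0, k, seed = 1000 * k + r))$kappa, 0))
  }, 0)
  expect_true(all(diff(med) > 0))
})

test_that("structure-pair kappa is symmetric and respects generator topology", {
  ss <- coupling_session(kappa = 8, seed = 21)
  centers <- c(M1 = 80, dStr = 80, OFC = 80)
  km <- kappa_matrix(ss$recording, centers, amp_gate = 0.25)
  expect_equal(km$kappa["M1", "dStr"], km$kappa["dStr", "M1"])
  expect_equal(km$kappa["M1", "dStr"], 8, tolerance = 0.15)
  expect_lt(km$kappa["M1", "OFC"], 0.2)   # independent generators
  # monopolar contract: kappa uses raw wires, so a pure common-mode bipolar
  # cancellation cannot occur; wire count equals the map rows
  ph <- wire_phases(ss$recording, centers)
  expect_equal(nrow(ph$phase), nrow(ss$recording$channel_map))
})

test_that("kappa difference maps contrast treatments and keep missing pairs undefined", {
  ss_v <- coupling_session(kappa = 8, seed = 61)
  ss_t <- coupling_session(kappa = 2, seed = 62)
  centers <- c(M1 = 80, dStr = 80, OFC = 80)
  km_v <- kappa_matrix(ss_v$recording, centers)
  km_t <- kappa_matrix(ss_t$recording, centers)
  dm <- kappa_difference_map(km_t, km_v)
  expect_lt(dm$diff["M1", "dStr"], -3)      # 8 -> 2 on the coupled pair
  expect_lt(abs(dm$diff["M1", "OFC"]), 0.5) # untouched pair near zero
  # identical condition: all-zero map
  dm0 <- kappa_difference_map(km_v, km_v)
  expect_true(all(dm0$diff[is.finite(dm0$diff)] == 0))
  # undefined reference pair stays absent, not zero
  km_na <- km_v; km_na$kappa["M1", "OFC"] <- NA
  dmna <- kappa_difference_map(km_t, km_na)
  expect_true(is.na(dmna$diff["M1", "OFC"]))
})
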