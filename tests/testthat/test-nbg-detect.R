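# synthetic spectra straight from the parametric model
model_spectrum <- function(freq, A, B, C, D = 0, E = 0)
  A * exp(-((freq - B) / C)^2) + D * freq + E

test_that("peak-model fit recovers known parameters from noisy spectra", {
  freq <- seq(65, 110, by = 0.5)
  errs <- t(vapply(1:40, function(i) {
    set.seed(500 + i)
    y <- model_spectrum(freq, 10, 80, 5) + stats::rnorm(length(freq), 0, 0.5)
    cf <- coef(fit_peak_model(freq, y, c(65, 110)))
    c(dB = abs(cf["B"] - 80), relA = abs(cf["A"] - 10) / 10,
      relC = abs(cf["C"] - 5) / 5)
  }, c(dB = 0, relA = 0, relC = 0)))
  expect_lt(stats::median(errs[, "dB"]), 1)
  expect_lt(stats::median(errs[, "relA"]), 0.1)
  expect_lt(stats::median(errs[, "relC"]), 0.2)
})

test_that("flat and degenerate spectra never raise and are not detected", {
  freq <- seq(65, 110, by = 0.5)
  ft <- fit_peak_model(freq, rep(0, length(freq)), c(65, 110))
  expect_lt(abs(coef(ft)["A"]), 0.5)
  expect_false(classify_detection(ft)$detected)
  ft2 <- fit_peak_model(freq, stats::rnorm(length(freq), 0, 0.1),
                        c(65, 110))
  expect_s3_class(ft2, "peak_fit")
  expect_error(fit_peak_model(freq, rep(0, length(freq)), c(110, 65)), "lo")
})

test_that("detection thresholds reproduce the printed conditions exactly", {
  fit0 <- list(A = 10, B = 80, C = 5, D = 0, E = 0, r2 = 0.9)
  alter <- function(...) utils::modifyList(fit0, list(...))
  printed <- nbg_thresholds(bands = list(gamma = c(30, 70),
                                         hfo = c(115, 170)))
  cases <- list(
    # fit, thresholds, detected, class
    list(fit0, printed, FALSE, NA),                 # 80 Hz: neither class
    list(fit0, nbg_thresholds(), TRUE, "nbg"),      # custom 65-110 band
    list(alter(B = 140, A = 5, C = 8, D = 0.2, E = 1, r2 = 0.5),
         printed, TRUE, "hfo"),
    list(alter(B = 50), printed, TRUE, "gamma"),
    list(alter(r2 = 0.15, B = 50), printed, FALSE, NA),
    list(alter(A = 150, B = 50), printed, FALSE, NA),
    list(alter(A = 2, B = 50), printed, FALSE, NA),     # strict bounds
    list(alter(A = 99.9, B = 50), printed, TRUE, "gamma"),
    list(alter(C = 1, B = 50), printed, FALSE, NA),
    list(alter(C = 20, B = 50), printed, FALSE, NA),
    list(alter(D = 1, B = 50), printed, FALSE, NA),
    list(alter(E = -10, B = 50), printed, FALSE, NA),
    list(alter(B = 70), printed, FALSE, NA),            # gamma is open
    list(alter(B = 69.9), printed, TRUE, "gamma"),
    list(alter(B = 115), printed, FALSE, NA),
    list(alter(B = 116), printed, TRUE, "hfo"))
  for (cs in cases) {
    got <- classify_detection(cs[[1]], cs[[2]])
    expect_identical(got$detected, cs[[3]])
    if (!is.na(cs[[4]])) expect_identical(got$band_class, cs[[4]])
  }
})

test_that("band power matches a quadrature oracle on the analytic model", {
  freq <- seq(40, 120, by = 0.01)
  y <- model_spectrum(freq, 10, 80, 5)
  oracle <- stats::integrate(function(f) model_spectrum(f, 10, 80, 5),
                             70, 90)$value / 20
  expect_equal(band_power(freq, y, 80), oracle, tolerance = 1e-3)
  expect_equal(band_power(freq, rep(7, length(freq)), 80), 7)
  expect_error(band_power(freq, y, 130), "outside")
})

test_that("NBG tracking reproduces the ground-truth detection rate and peak", {
  ss <- nbg_epoch_session()
  tr <- track_nbg(ss$spectra, "M1")
  expect_equal(tr$detection_rate, mean(ss$truth$nbg_window_flags),
               tolerance = 0.05)
  expect_equal(tr$median_peak_hz, 80, tolerance = 1)
  expect_true(all(tr$windows$detected %in% c(TRUE, FALSE)))
  expect_gte(tr$detection_rate, 0); expect_lte(tr$detection_rate, 1)
  # structure without the oscillation: no detections
  tr0 <- track_nbg(ss$spectra, "OFC")
  expect_lt(tr0$detection_rate, 0.05)
})

test_that("a drifting generated peak is tracked and its median recovered", {
  cfg <- session_config(duration_s = 240, structures = "M1",
                        wires_per_structure = 2, chi = 1.5,
                        oscillations = list(
                          oscillation_spec(80, 6, 1.2, "M1", kappa = 3,
                                           drift_hz = c(75, 85))),
                        behavior = FALSE, seed = 17)
  ss <- generate_session(cfg)
  tr <- track_nbg(lfp_spectra(ss$recording), "M1")
  expect_gt(tr$detection_rate, 0.5)
  expect_equal(tr$median_peak_hz, 80, tolerance = 1)
  b <- tr$windows$B[tr$windows$detected]
  expect_gt(stats::cor(seq_along(b), b), 0.8)   # follows the drift
})

# build a minimal nbg_track by hand for feature-distance contracts
mock_track <- function(values, detected = is.finite(values), rate = NULL) {
  structure(list(windows = data.frame(t = seq_along(values) * 4,
                                      A = values, B = values, C = values,
                                      detected = detected,
                                      band_power = values),
                 detection_rate = rate %||% mean(detected),
                 median_peak_hz = stats::median(values[detected]),
                 structure = "mock", window_s = 8),
            class = "nbg_track")
}

test_that("feature distance is 1 - r with an exact 5% detection gate", {
  v <- sin(seq(0, 6, length.out = 50)) * 5 + 80
  tr_a <- mock_track(v)
  tr_b <- mock_track(v)                                   # identical
  tr_c <- mock_track(-(v - mean(v)) + mean(v))            # negated
  fd <- feature_distance(list(a = tr_a, b = tr_b, c = tr_c), "peak")
  expect_equal(unname(fd$distance["a", "b"]), 0, tolerance = 1e-12)
  expect_equal(unname(fd$distance["a", "c"]), 2, tolerance = 1e-12)
  expect_equal(fd$distance, t(fd$distance))
  expect_true(all(diag(fd$distance) == 0))
  # gate: rate below 0.05 excluded, exactly 0.05 retained
  tr_low <- mock_track(v, rate = 0.049)
  tr_edge <- mock_track(v, rate = 0.05)
  fd2 <- feature_distance(list(a = tr_a, low = tr_low, edge = tr_edge))
  expect_false("low" %in% fd2$gated)
  expect_true("edge" %in% fd2$gated)
})

test_that("shared-generator structures are closer in feature space than independent ones", {
  ss <- coupling_session(kappa = 8, seed = 21)
  sp <- lfp_spectra(ss$recording)
  trks <- lapply(c(M1 = "M1", dStr = "dStr", OFC = "OFC"),
                 function(s) track_nbg(sp, s))
  fd <- feature_distance(trks, "peak")
  expect_lt(fd$distance["M1", "dStr"],
            min(fd$distance["M1", "OFC"], fd$distance["dStr", "OFC"]))
})

test_that("AIMs-gamma correlation finds slaved power and flags degenerate inputs", {
  env <- drug_envelope(drug_profile(), seq(5, 175, by = 10))
  aims <- data.frame(t_min = seq(10, 180, by = 10),
                     global = round(env * 20))
  bp <- env * 8 + stats::rnorm(18, 0, 0.3)
  track <- mock_track(rep(bp, each = 150))   # 10-min bins of 8-s hops
  track$windows$t <- seq(0, by = 4, length.out = nrow(track$windows))
  r <- aims_gamma_correlation(track, aims)
  expect_gt(r, 0.8)
  const <- aims; const$global <- 5
  rc <- aims_gamma_correlation(track, const)
  expect_true(is.na(rc))
  expect_match(attr(rc, "reason"), "variance")
  # permutation null: correlation collapses
  set.seed(99)
  perm <- replicate(100, {
    p <- aims; p$global <- sample(p$global)
    abs(aims_gamma_correlation(track, p))
  })
  expect_lt(stats::median(perm), 0.3)
})
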