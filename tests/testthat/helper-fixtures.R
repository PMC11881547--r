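# Lazily built, cached session fixtures shared across test files. All
# fixtures are generated in code under fixed seeds; nothing is stored on
# disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# One-structure session with a drug-gated NBG epoch over 120-360 s of 480 s.
nbg_epoch_session <- function() fixture("nbg_epoch", function() {
  cfg <- session_config(duration_s = 480, structures = c("M1", "OFC"),
                        wires_per_structure = 2, chi = 1.5,
                        oscillations = list(
                          oscillation_spec(80, 6, 1.2, "M1", kappa = 3,
                                           schedule = matrix(c(120, 360), 1))),
                        behavior = FALSE, seed = 11)
  ss <- generate_session(cfg)
  ss$spectra <- lfp_spectra(ss$recording)
  ss
})

# Two coupled structures sharing an always-on NBG at kappa = 8, plus an
# uncoupled third structure with its own independent oscillation.
coupling_session <- function(kappa = 8, seed = 21, duration_s = 120)
  fixture(sprintf("coupling_%g_%d_%g", kappa, seed, duration_s), function() {
    cfg <- session_config(duration_s = duration_s,
                          structures = c("M1", "dStr", "OFC"),
                          wires_per_structure = 2, chi = 1.5,
                          oscillations = list(
                            oscillation_spec(80, 6, 2.5, c("M1", "dStr"),
                                             kappa = kappa),
                            oscillation_spec(80, 6, 2.5, "OFC", kappa = 2)),
                          behavior = FALSE, seed = seed)
    generate_session(cfg)
  })

# Independent-oracle periodogram: Welch average of raw FFT periodograms,
# written against base R only (no package spectral code).
oracle_psd <- function(x, fs, nseg = 8) {
  n <- floor(length(x) / nseg)
  acc <- 0
  for (k in seq_len(nseg)) {
    seg <- x[((k - 1) * n + 1):(k * n)]
    seg <- seg - mean(seg)
    acc <- acc + Mod(stats::fft(seg))^2 / n
  }
  p <- acc / nseg
  list(freq = (0:(n - 1)) * fs / n, power = p)
}

# Independent log-log slope oracle on the Welch periodogram.
oracle_slope <- function(x, fs, band = c(2, 100), nseg = 16) {
  p <- oracle_psd(x, fs, nseg)
  sel <- p$freq >= band[1] & p$freq <= band[2]
  unname(stats::coef(stats::lm(log10(p$power[sel]) ~
                                 log10(p$freq[sel])))[2])
}

# Grid-search maximum-likelihood oracle for the von Mises concentration.
oracle_vm_kappa <- function(theta, grid = exp(seq(log(0.01), log(50),
                                                  length.out = 400))) {
  cc <- mean(cos(theta)); ss <- mean(sin(theta))
  mu <- atan2(ss, cc)
  ll <- vapply(grid, function(k)
    k * sum(cos(theta - mu)) - length(theta) *
      log(2 * pi * besselI(k, 0, expon.scaled = TRUE)) -
      length(theta) * k, 0)
  grid[which.max(ll)]
}
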