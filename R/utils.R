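# Internal numerical helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
local_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Smallest 5-smooth integer >= n (keeps mixed-radix FFTs away from large primes).
next_fast_len <- function(n) {
  n <- as.integer(ceiling(n))
  if (n <= 6L) return(max(n, 1L))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

hanning_taper <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1L)) / (n - 1L)))
}

# One-sided power spectral density of the columns of `w` (already tapered is
# handled by `u2`, the mean-square of the taper). Returned power satisfies
# sum(psd) * df ~= variance of the untapered series (Parseval, taper-corrected).
# Real windows are packed two-per-complex-column before the FFT and separated
# by Hermitian symmetry, halving the dominant transform cost.
psd_from_windows <- function(w, fs, u2) {
  n <- nrow(w); m <- ncol(w)
  nf <- floor(n / 2)
  sel <- seq_len(nf + 1L)
  pw <- matrix(0, nf + 1L, m)
  if (m >= 2L) {
    half <- m %/% 2L
    z <- w[, 2L * seq_len(half) - 1L, drop = FALSE] +
      1i * w[, 2L * seq_len(half), drop = FALSE]
    ft <- stats::mvfft(z)
    g <- Conj(ft[c(1L, n:2L), , drop = FALSE])
    pw[, 2L * seq_len(half) - 1L] <-
      Mod((ft[sel, , drop = FALSE] + g[sel, , drop = FALSE]) / 2)^2
    pw[, 2L * seq_len(half)] <-
      Mod((ft[sel, , drop = FALSE] - g[sel, , drop = FALSE]) / 2)^2
  }
  if (m %% 2L == 1L)
    pw[, m] <- Mod(stats::fft(w[, m])[sel])^2
  p <- pw / (fs * n * u2)
  p[2:(nf + 1L), ] <- 2 * p[2:(nf + 1L), ]
  if (n %% 2L == 0L) p[nf + 1L, ] <- p[nf + 1L, ] / 2
  list(freq = (0:nf) * fs / n, power = p)
}

# Band-limited resampling of every column of `x` to `m` rows via Fourier
# truncation / zero-padding. Treating the result at the original sampling rate
# stretches time by m/n and scales frequencies by n/m.
fft_resample_mat <- function(ft, n, m) {
  nh <- (min(n, m) - 1L) %/% 2L
  y <- matrix(0 + 0i, m, ncol(ft))
  y[1L, ] <- ft[1L, ]
  if (nh > 0L) {
    y[2:(nh + 1L), ] <- ft[2:(nh + 1L), , drop = FALSE]
    y[(m - nh + 1L):m, ] <- ft[(n - nh + 1L):n, , drop = FALSE]
  }
  Re(stats::mvfft(y, inverse = TRUE)) / n
}

# Extract possibly-overlapping analysis windows of `n` samples as a matrix.
window_starts <- function(len, n, hop) {
  if (len < n) stop("series shorter than one analysis window", call. = FALSE)
  seq(1L, len - n + 1L, by = hop)
}

window_matrix <- function(x, starts, n) {
  matrix(x[outer(seq_len(n) - 1L, starts, "+")], nrow = n)
}

wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # map the representative of pi from -pi to +pi to keep angles in (-pi, pi]
  y[y == -pi] <- pi
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
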