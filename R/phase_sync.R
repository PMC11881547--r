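#' Zero-phase narrowband filter around the NBG frequency
#'
#' Bandpass of +-`half_width` Hz around `center`, using an order-64 FIR
#' filter applied forwards and backwards (zero group delay, so no
#' phase-difference bias is introduced between channels).
#'
#' @param x numeric series.
#' @param center band center (Hz), typically the session median NBG
#'   frequency.
#' @param fs sampling rate (Hz).
#' @param half_width half band width (Hz, default 5).
#' @param order FIR filter order (default 64, i.e. 65 taps).
#' @return filtered series of the same length.
#' @export
bandpass_nbg <- function(x, center, fs, half_width = 5, order = 64) {
  lo <- center - half_width; hi <- center + half_width
  if (lo <= 0 || hi >= fs / 2) stop_invalid("band %g-%g Hz invalid for fs %g",
                                            lo, hi, fs)
  b <- signal::fir1(order, c(lo, hi) / (fs / 2), type = "pass")
  signal::filtfilt(b, x)
}

#' Instantaneous phase via the analytic signal
#'
#' Hilbert-transforms a band-limited series into its complex analytic signal
#' `z(t)` and returns the instantaneous phase `arg z(t)` and amplitude
#' `|z(t)|`. Phases are undefined (NA) where the amplitude is zero.
#'
#' @param x band-limited numeric series.
#' @return list of class `phase_series`: `phase` (radians, `(-pi, pi]`),
#'   `amplitude`.
#' @export
instantaneous_phase <- function(x) {
  n_orig <- length(x)
  # extend by even reflection to a 5-smooth length: mixed-radix FFTs on
  # awkward lengths are prohibitively slow, and the narrowband inputs decay
  # any edge effect of the extension within a fraction of a second
  m <- next_fast_len(n_orig)
  if (m > n_orig && n_orig > 1L) {
    k <- min(m - n_orig, n_orig - 1L)
    x <- c(x, x[seq(n_orig - 1L, by = -1L, length.out = k)],
           numeric(m - n_orig - k))
  }
  n <- length(x)
  ft <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  z <- stats::fft(ft * h, inverse = TRUE) / n
  z <- z[seq_len(n_orig)]
  amp <- Mod(z)
  ph <- Arg(z)
  ph[amp == 0] <- NA_real_
  structure(list(phase = ph, amplitude = amp), class = "phase_series")
}

# A1(kappa) = I1(kappa)/I0(kappa), the von Mises mean resultant length.
.vm_a1 <- function(kappa)
  besselI(kappa, 1, expon.scaled = TRUE) /
  besselI(kappa, 0, expon.scaled = TRUE)

# Classical inversion of the mean resultant length (the estimator used in
# circular-statistics toolboxes).
.vm_kappa_from_rbar <- function(rbar, kappa_max = 1000) {
  if (!is.finite(rbar)) return(NA_real_)
  k <- if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
  if (!is.finite(k) || k > kappa_max) kappa_max else max(k, 0)
}

#' Fit a von Mises distribution to phase differences
#'
#' Circular mean direction `mu` and concentration `kappa` estimated from the
#' mean resultant length by the classical piecewise approximation. `kappa`
#' plays the role of an inverse circular variance (`sigma^2 ~ 1/kappa` for
#' concentrated samples) and is capped at `kappa_max` for degenerate
#' (near-identical) samples. Fewer than `min_n` usable angles gives an
#' undefined fit (`kappa = NA`) rather than an error.
#'
#' @param theta angles in radians.
#' @param kappa_max concentration cap (default 1000).
#' @param min_n minimum sample count (default 10).
#' @return object of class `von_mises_fit`: `mu`, `kappa`, `rbar`, `n`.
#' @export
fit_von_mises <- function(theta, kappa_max = 1000, min_n = 10) {
  theta <- theta[is.finite(theta)]
  n <- length(theta)
  if (n < min_n)
    return(structure(list(mu = NA_real_, kappa = NA_real_, rbar = NA_real_,
                          n = n, diagnostic = "too few samples"),
                     class = "von_mises_fit"))
  cc <- sum(cos(theta)); ss <- sum(sin(theta))
  rbar <- sqrt(cc^2 + ss^2) / n
  structure(list(mu = atan2(ss, cc),
                 kappa = .vm_kappa_from_rbar(rbar, kappa_max),
                 rbar = rbar, n = n, diagnostic = NULL),
            class = "von_mises_fit")
}

#' @export
print.von_mises_fit <- function(x, ...) {
  if (is.na(x$kappa)) {
    cat(sprintf("von Mises fit: undefined (%s, n = %d)\n",
                x$diagnostic %||% "no samples", x$n))
  } else {
    cat(sprintf("von Mises fit: mu = %.3f rad, kappa = %.3f (Rbar %.3f, n %d)\n",
                x$mu, x$kappa, x$rbar, x$n))
  }
  invisible(x)
}

#' @export
coef.von_mises_fit <- function(object, ...)
  c(mu = object$mu, kappa = object$kappa)

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler; used to generate phase-difference samples
#' with known concentration.
#'
#' @param n sample count.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0); 0 gives the circular uniform.
#' @param seed integer seed.
#' @return angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1, seed = 1) {
  local_seed(seed, {
    if (kappa < 1e-9) return(wrap_angle(stats::runif(n, -pi, pi)))
    tau <- 1 + sqrt(1 + 4 * kappa^2)
    rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
    r <- (1 + rho^2) / (2 * rho)
    out <- numeric(n); got <- 0L
    while (got < n) {
      m <- n - got
      u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
      acc <- sum(ok)
      if (acc > 0L) {
        out[(got + 1L):(got + acc)] <-
          sign(u3[ok] - 0.5) * acos(f[ok])
        got <- got + acc
      }
    }
    wrap_angle(out + mu)
  })
}

#' Decimated instantaneous phases per wire
#'
#' Bandpass-filters each monopolar wire +-`half_width` Hz around its
#' structure's center frequency, extracts the Hilbert phase, restricts it to
#' the analysis window and decimates to `decim_ms` spacing (phase samples on
#' heavily autocorrelated grids inflate concentration estimates). Phase
#' analysis deliberately uses monopolar series, unlike the bipolar spectral
#' chain.
#'
#' @param rec a [multichannel_recording()].
#' @param centers named numeric vector of band centers per structure (Hz);
#'   a single unnamed value is used for all structures.
#' @param window_s optional `(start, end)` analysis window (s).
#' @param half_width,order bandpass parameters (see [bandpass_nbg()]).
#' @param decim_ms phase sample spacing after decimation (ms).
#' @param hemisphere hemisphere to analyze.
#' @return list of class `wire_phases`: `phase` (wires x samples), `map`.
#' @export
wire_phases <- function(rec, centers, window_s = NULL, half_width = 5,
                        order = 64, decim_ms = 10, hemisphere = "lesioned") {
  stopifnot(inherits(rec, "multichannel_recording"))
  map <- rec$channel_map
  if (!is.null(hemisphere)) map <- map[map$hemisphere %in% hemisphere, ]
  if (is.null(names(centers)))
    centers <- stats::setNames(rep(centers[1], length(unique(map$structure))),
                               unique(map$structure))
  step <- max(1L, round(decim_ms / 1000 * rec$fs))
  n <- ncol(rec$samples)
  idx <- seq(1L, n, by = step)
  if (!is.null(window_s))
    idx <- idx[idx >= window_s[1] * rec$fs + 1 & idx <= window_s[2] * rec$fs]
  ph <- amp <- matrix(NA_real_, nrow(map), length(idx))
  for (r in seq_len(nrow(map))) {
    ctr <- centers[[map$structure[r]]]
    if (is.null(ctr) || is.na(ctr)) next
    filt <- bandpass_nbg(rec$samples[map$channel[r], ], ctr, rec$fs,
                         half_width, order)
    hp <- instantaneous_phase(filt)
    ph[r, ] <- hp$phase[idx]
    amp[r, ] <- hp$amplitude[idx]
  }
  structure(list(phase = ph, amplitude = amp, map = map, centers = centers,
                 decim_ms = decim_ms), class = "wire_phases")
}

#' Phase-coupling concentration for one structure pair
#'
#' Fits a von Mises distribution to the instantaneous phase differences of
#' every cross-structure wire pair and returns the median concentration
#' kappa - the functional-connectivity readout for the pair of structures.
#'
#' @param phases a [wire_phases()] result.
#' @param struct_a,struct_b structure labels (order irrelevant).
#' @param amp_gate quantile in `[0, 1)`: drop phase samples whose joint
#'   analytic amplitude (minimum of the two wires) falls below this
#'   quantile. The default 0 uses all samples; gating counteracts the
#'   decoherence contributed by near-zero-amplitude stretches, where the
#'   instantaneous phase is noise-dominated.
#' @return list: `kappa` (median over wire pairs, `NA` if no valid pair),
#'   `pairs` data frame (`wire_i`, `wire_j`, `mu`, `kappa`, `n`).
#' @export
structure_pair_kappa <- function(phases, struct_a, struct_b, amp_gate = 0) {
  wa <- which(phases$map$structure == struct_a)
  wb <- which(phases$map$structure == struct_b)
  if (!length(wa) || !length(wb))
    stop_invalid("no wires in one of the structures")
  rows <- NULL
  for (i in wa) for (j in wb) {
    d <- wrap_angle(phases$phase[i, ] - phases$phase[j, ])
    if (amp_gate > 0 && !is.null(phases$amplitude)) {
      am <- pmin(phases$amplitude[i, ], phases$amplitude[j, ])
      d <- d[am >= stats::quantile(am, amp_gate, na.rm = TRUE)]
    }
    vf <- fit_von_mises(d)
    rows <- rbind(rows, data.frame(wire_i = phases$map$channel[i],
                                   wire_j = phases$map$channel[j],
                                   mu = vf$mu, kappa = vf$kappa, n = vf$n))
  }
  kap <- rows$kappa[is.finite(rows$kappa)]
  list(kappa = if (length(kap)) stats::median(kap) else NA_real_,
       pairs = rows)
}

#' Structure-pair kappa matrix
#'
#' Median von Mises concentration of phase differences for every pair of
#' structures, computed on monopolar wires within the analysis window. The
#' band center of a pair is the mean of the two structures' centers when
#' they differ.
#'
#' @param rec a [multichannel_recording()].
#' @param centers named numeric vector of per-structure band centers (Hz);
#'   structures with `NA` center are skipped.
#' @param window_s optional `(start, end)` analysis window (s).
#' @param half_width,order,decim_ms see [wire_phases()].
#' @param amp_gate amplitude-gate quantile, see [structure_pair_kappa()];
#'   default 0 (all samples in the window).
#' @param hemisphere hemisphere to analyze.
#' @return object of class `kappa_matrix`: symmetric `kappa` matrix
#'   (structures x structures, `NA` where undefined), `pairs` data frame,
#'   `window_s`, `centers`.
#' @export
kappa_matrix <- function(rec, centers, window_s = NULL, half_width = 5,
                         order = 64, decim_ms = 10, amp_gate = 0,
                         hemisphere = "lesioned") {
  structs <- names(centers)[is.finite(unlist(centers))]
  if (length(structs) < 2L) stop_invalid("need >= 2 structures with centers")
  map <- rec$channel_map
  if (!is.null(hemisphere)) map <- map[map$hemisphere %in% hemisphere, ]
  k <- matrix(NA_real_, length(structs), length(structs),
              dimnames = list(structs, structs))
  rows <- NULL
  n <- ncol(rec$samples)
  step <- max(1L, round(decim_ms / 1000 * rec$fs))
  idx <- seq(1L, n, by = step)
  if (!is.null(window_s))
    idx <- idx[idx >= window_s[1] * rec$fs + 1 & idx <= window_s[2] * rec$fs]
  pad <- round(2 * rec$fs)
  i0 <- max(1L, min(idx) - pad); i1 <- min(n, max(idx) + pad)
  # per-(wire, pair-center rounded to 0.5 Hz) cache of decimated phases;
  # only the analysis window (plus edge padding) is ever filtered
  cache <- new.env(parent = emptyenv())
  get_phase <- function(ch, ctr) {
    key <- sprintf("%d@%.1f", ch, ctr)
    if (is.null(cache[[key]])) {
      filt <- bandpass_nbg(rec$samples[ch, i0:i1], ctr, rec$fs,
                           half_width, order)
      hp <- instantaneous_phase(filt)
      cache[[key]] <- list(phase = hp$phase[idx - i0 + 1L],
                           amplitude = hp$amplitude[idx - i0 + 1L])
    }
    cache[[key]]
  }
  for (i in seq_along(structs)[-length(structs)])
    for (j in (i + 1):length(structs)) {
      ctr <- round(mean(c(centers[[structs[i]]],
                          centers[[structs[j]]])) * 2) / 2
      ch_a <- map$channel[map$structure == structs[i]]
      ch_b <- map$channel[map$structure == structs[j]]
      both <- c(ch_a, ch_b)
      cached <- lapply(both, get_phase, ctr = ctr)
      ph <- structure(list(
        phase = do.call(rbind, lapply(cached, `[[`, "phase")),
        amplitude = do.call(rbind, lapply(cached, `[[`, "amplitude")),
        map = map[match(both, map$channel), , drop = FALSE],
        centers = ctr, decim_ms = decim_ms), class = "wire_phases")
      spk <- structure_pair_kappa(ph, structs[i], structs[j],
                                  amp_gate = amp_gate)
      k[i, j] <- k[j, i] <- spk$kappa
      rows <- rbind(rows, data.frame(struct_a = structs[i],
                                     struct_b = structs[j],
                                     center_hz = ctr, kappa = spk$kappa,
                                     n_wire_pairs = nrow(spk$pairs)))
    }
  structure(list(kappa = k, pairs = rows, window_s = window_s,
                 centers = centers), class = "kappa_matrix")
}

#' @export
print.kappa_matrix <- function(x, digits = 2, ...) {
  cat("structure-pair phase-coupling kappa (median over wire pairs):\n")
  print(round(x$kappa, digits))
  invisible(x)
}

#' Treatment difference map of phase coupling
#'
#' Elementwise kappa difference `treatment - reference` over the structure
#' pairs measured in both conditions; pairs undefined in either condition
#' are absent (NA), not zero. Negative entries denote reduced phase coupling
#' under the treatment.
#'
#' @param treated,reference [kappa_matrix()] objects.
#' @return object of class `kappa_diff_map` with the difference matrix
#'   `diff` over the intersection of defined pairs.
#' @export
kappa_difference_map <- function(treated, reference) {
  common <- intersect(rownames(treated$kappa), rownames(reference$kappa))
  if (length(common) < 2L) stop_invalid("no common structures")
  if (!setequal(rownames(treated$kappa), rownames(reference$kappa)))
    message("structure sets differ; using their intersection")
  d <- treated$kappa[common, common] - reference$kappa[common, common]
  structure(list(diff = d, structures = common),
            class = "kappa_diff_map")
}

#' @export
print.kappa_diff_map <- function(x, digits = 2, ...) {
  cat("kappa difference map (treatment - reference; negative = reduced coupling):\n")
  print(round(x$diff, digits))
  invisible(x)
}
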