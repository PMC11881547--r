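#' Multichannel LFP recording
#'
#' Container for a channels x samples matrix with its sampling rate, channel
#' map (channel -> structure, hemisphere) and session metadata. The analysis
#' chain assumes signals downsampled to 2000 Hz.
#'
#' @param samples numeric matrix, channels in rows (microvolts).
#' @param fs sampling rate (Hz).
#' @param channel_map data frame with columns `channel`, `structure`,
#'   `hemisphere` (`"lesioned"` or `"intact"`), one row per channel.
#' @param meta list of session metadata (treatment label, injection offset).
#' @return an object of class `multichannel_recording`.
#' @export
multichannel_recording <- function(samples, fs, channel_map, meta = list()) {
  samples <- as.matrix(samples)
  if (!is.data.frame(channel_map) ||
      !all(c("channel", "structure", "hemisphere") %in% names(channel_map)))
    stop_invalid("channel_map needs columns channel, structure, hemisphere")
  if (nrow(channel_map) != nrow(samples))
    stop_invalid("channel_map must have one row per channel")
  if (!all(seq_len(nrow(samples)) %in% channel_map$channel))
    stop_invalid("channel %d has no channel_map entry",
                 setdiff(seq_len(nrow(samples)), channel_map$channel)[1])
  if (!all(channel_map$hemisphere %in% c("lesioned", "intact")))
    stop_invalid("hemisphere labels must be 'lesioned' or 'intact'")
  structure(list(samples = samples, fs = fs,
                 channel_map = channel_map[order(channel_map$channel), ,
                                           drop = FALSE],
                 meta = meta),
            class = "multichannel_recording")
}

#' @export
print.multichannel_recording <- function(x, ...) {
  cat(sprintf("multichannel recording: %d channels x %d samples (%.1f min at %g Hz)\n",
              nrow(x$samples), ncol(x$samples),
              ncol(x$samples) / x$fs / 60, x$fs))
  cat(sprintf("  structures: %s\n",
              paste(unique(x$channel_map$structure), collapse = ", ")))
  invisible(x)
}

#' Derive within-structure bipolar LFPs
#'
#' Differential series between every pair of wires located in the same
#' structure. Referencing nearby wires against each other suppresses
#' volume-conducted sources common to the structure, isolating local
#' currents. Structures with fewer than two wires are skipped with a warning.
#'
#' @param rec a [multichannel_recording()].
#' @param hemisphere restrict to one hemisphere label (default `"lesioned"`),
#'   or `NULL` for both.
#' @return an object of class `bipolar_series`: `series` (pairs x time),
#'   `pairs` (data frame `channel_i`, `channel_j`, `structure`), `fs`.
#' @export
derive_bipolar <- function(rec, hemisphere = "lesioned") {
  stopifnot(inherits(rec, "multichannel_recording"))
  map <- rec$channel_map
  if (!is.null(hemisphere)) map <- map[map$hemisphere %in% hemisphere, ]
  if (nrow(map) == 0L) stop_invalid("empty channel map")
  pairs <- NULL
  for (s in unique(map$structure)) {
    ch <- sort(map$channel[map$structure == s])
    if (length(ch) < 2L) {
      warning(sprintf("structure '%s' has < 2 wires; skipped", s),
              call. = FALSE)
      next
    }
    cmb <- utils::combn(ch, 2)
    pairs <- rbind(pairs, data.frame(channel_i = cmb[1, ],
                                     channel_j = cmb[2, ], structure = s,
                                     stringsAsFactors = FALSE))
  }
  if (is.null(pairs)) stop_invalid("no structure has >= 2 wires")
  series <- rec$samples[pairs$channel_i, , drop = FALSE] -
    rec$samples[pairs$channel_j, , drop = FALSE]
  structure(list(series = series, pairs = pairs, fs = rec$fs),
            class = "bipolar_series")
}

#' @export
print.bipolar_series <- function(x, ...) {
  cat(sprintf("bipolar series: %d within-structure pairs, %d samples at %g Hz\n",
              nrow(x$pairs), ncol(x$series), x$fs))
  invisible(x)
}

# Aggregate native-resolution PSD bins onto a coarser regular grid (mean in
# linear power), e.g. 0.125-Hz bins from 8-s windows onto the 0.5-Hz grid.
.aggregate_bins <- function(freq, power, bin_hz) {
  k <- floor(freq / bin_hz + 0.5)
  keep <- k >= 1L
  k <- k[keep]
  if (is.matrix(power)) {
    agg <- rowsum(power[keep, , drop = FALSE], k)
    cnt <- as.vector(rowsum(rep(1, length(k)), k))
    list(freq = as.numeric(rownames(agg)) * bin_hz, power = agg / cnt)
  } else {
    agg <- rowsum(power[keep], k)
    cnt <- as.vector(rowsum(rep(1, length(k)), k))
    list(freq = as.numeric(rownames(agg)) * bin_hz,
         power = as.vector(agg) / cnt)
  }
}

#' Compute a spectrogram
#'
#' Single-taper (Hanning) power spectral density per analysis window,
#' reported on a regular output grid by averaging adjacent native bins in
#' linear power (8-s windows give 0.125-Hz native resolution, aggregated
#' onto the 0.5-Hz grid).
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param window_s window length in seconds (default 8).
#' @param overlap fractional window overlap (default 0.5).
#' @param fmax upper frequency bound (Hz, default 300).
#' @param bin_hz output grid spacing (Hz, default 0.5).
#' @return class `spectrogram`: `power` (windows x frequency, linear),
#'   `freq`, `t` (window start times, s), plus the windowing parameters.
#' @export
compute_spectrogram <- function(x, fs, window_s = 8, overlap = 0.5,
                                fmax = 300, bin_hz = 0.5) {
  n <- round(window_s * fs)
  if (length(x) < n) stop_invalid("series shorter than one window")
  starts <- window_starts(length(x), n, max(1L, round(n * (1 - overlap))))
  w <- window_matrix(x, starts, n)
  tap <- hanning_taper(n)
  p <- psd_from_windows(w * tap, fs, mean(tap^2))
  keep <- p$freq <= fmax
  agg <- .aggregate_bins(p$freq[keep], p$power[keep, , drop = FALSE], bin_hz)
  structure(list(power = t(agg$power), freq = agg$freq,
                 t = (starts - 1L) / fs, window_s = window_s,
                 overlap = overlap, fs = fs, taper = "hanning"),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("spectrogram: %d windows (%g s, %d%% overlap) x %d bins (%g-%g Hz)\n",
              nrow(x$power), x$window_s, round(100 * x$overlap),
              length(x$freq), min(x$freq), max(x$freq)))
  invisible(x)
}

# --- IRASA -------------------------------------------------------------------

#' @keywords internal
default_irasa_factors <- function() seq(1.1, 1.9, by = 0.05)

# Core irregular-resampling engine. Splits x into tapered windows, computes
# the total PSD and, for each resampling factor h, the PSDs of the h- and
# 1/h-resampled windows interpolated back onto the native frequency grid.
# The fractal (aperiodic) PSD is the median across h of the geometric means
# sqrt(P_h * P_1/h): a power-law spectrum is invariant under time-series
# resampling, while oscillatory peaks are displaced to f/h and f*h and
# removed by the median. Per-window PSDs are averaged before the geometric
# mean to avoid the downward noise bias of medians on raw periodograms.
#
# per_window = TRUE returns per-window total and fractal matrices instead of
# window-averaged spectra (used for 4-s brain-state windows).
irasa_engine <- function(x, fs, window_s = 8, overlap = 0.5,
                         factors = default_irasa_factors(), fmax = 300,
                         max_windows = Inf, per_window = FALSE) {
  if (length(factors) < 1L || any(factors <= 1))
    stop_invalid("resampling factors must all exceed 1")
  n <- round(window_s * fs)
  if (length(x) < n) stop_invalid("series shorter than one window")
  starts <- window_starts(length(x), n, max(1L, round(n * (1 - overlap))))
  if (is.finite(max_windows) && length(starts) > max_windows)
    starts <- starts[unique(round(seq(1L, length(starts),
                                      length.out = max_windows)))]
  w <- window_matrix(x, starts, n)
  tap <- hanning_taper(n); u2 <- mean(tap^2)
  tot <- psd_from_windows(w * tap, fs, u2)
  freq <- tot$freq
  keep <- freq <= fmax
  nw <- ncol(w)

  raw_ft <- stats::mvfft(w)   # untapered, for band-limited resampling
  geo <- array(NA_real_, c(sum(keep), length(factors), if (per_window) nw else 1L))
  for (j in seq_along(factors)) {
    h <- factors[j]
    ps <- lapply(c(h, 1 / h), function(hh) {
      m <- next_fast_len(n * hh)
      y <- fft_resample_mat(raw_ft, n, m)
      tp <- hanning_taper(m)
      p <- psd_from_windows(y * tp, fs, mean(tp^2))
      # linear interpolation of all window PSDs onto the native grid in one
      # pass (the resampled grid is shared across windows)
      fo <- freq[keep]
      lo <- findInterval(fo, p$freq, all.inside = TRUE)
      wt <- (fo - p$freq[lo]) / (p$freq[lo + 1L] - p$freq[lo])
      wt <- pmin(pmax(wt, 0), 1)
      p$power[lo, , drop = FALSE] * (1 - wt) +
        p$power[lo + 1L, , drop = FALSE] * wt
    })
    if (per_window) {
      geo[, j, ] <- sqrt(ps[[1]] * ps[[2]])
    } else {
      geo[, j, 1L] <- sqrt(rowMeans(ps[[1]]) * rowMeans(ps[[2]]))
    }
  }
  if (per_window) {
    # vectorized median over factors: radix sort within (bin, window) cells
    nf <- length(factors); nb <- sum(keep)
    g <- matrix(aperm(geo, c(2, 1, 3)), nrow = nf)
    gs <- matrix(g[order(col(g), g, method = "radix")], nrow = nf)
    med <- if (nf %% 2L == 1L) gs[(nf + 1L) %/% 2L, ] else
      (gs[nf %/% 2L, ] + gs[nf %/% 2L + 1L, ]) / 2
    frac <- matrix(med, nb, nw)
    list(freq = freq[keep], total = tot$power[keep, , drop = FALSE],
         fractal = frac, t = (starts - 1L) / fs)
  } else {
    frac <- apply(geo[, , 1L, drop = FALSE], 1, stats::median)
    list(freq = freq[keep], total = rowMeans(tot$power[keep, , drop = FALSE]),
         fractal = frac, t = (starts - 1L) / fs)
  }
}

#' Separate oscillatory and aperiodic spectral components (IRASA)
#'
#' Irregular-resampling auto-spectral analysis: the power spectrum of the
#' arrhythmic (fractal) component of a signal is unaffected by time-series
#' resampling, so the median across resampling factors `h` of the geometric
#' mean of the h- and 1/h-resampled spectra isolates the aperiodic component.
#' The normalized spectrum (`dB_fractal`) is the total spectrum expressed in
#' dB relative to the fractal component and emphasizes genuinely rhythmic
#' activity.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param window_s,overlap analysis windowing (defaults 8 s, 50%).
#' @param factors resampling factors `h > 1` (each paired with `1/h`);
#'   default `seq(1.1, 1.9, 0.05)`, the method's published set.
#' @param fmax upper frequency bound (Hz).
#' @param bin_hz output grid spacing (Hz).
#' @param max_windows cap on the number of windows used (evenly subsampled);
#'   `Inf` uses all.
#' @return class `fractal_decomposition`: `freq`, `total_db`, `fractal_db`,
#'   `normalized_db` (= total - fractal, dB), `factors`.
#' @export
irasa_decompose <- function(x, fs, window_s = 8, overlap = 0.5,
                            factors = default_irasa_factors(), fmax = 300,
                            bin_hz = 0.5, max_windows = Inf) {
  eng <- irasa_engine(x, fs, window_s, overlap, factors, fmax,
                      max_windows = max_windows)
  at <- .aggregate_bins(eng$freq, eng$total, bin_hz)
  af <- .aggregate_bins(eng$freq, eng$fractal, bin_hz)
  total_db <- 10 * log10(at$power)
  fractal_db <- 10 * log10(af$power)
  structure(list(freq = at$freq, total_db = total_db,
                 fractal_db = fractal_db,
                 normalized_db = total_db - fractal_db,
                 factors = factors),
            class = "fractal_decomposition")
}

#' @export
print.fractal_decomposition <- function(x, ...) {
  cat(sprintf("fractal decomposition: %d bins (%g-%g Hz), %d resampling factors\n",
              length(x$freq), min(x$freq), max(x$freq), length(x$factors)))
  cat(sprintf("  aperiodic slope (2-100 Hz): %.2f\n", fractal_slope(x)))
  invisible(x)
}

#' @export
plot.fractal_decomposition <- function(x, ...) {
  graphics::matplot(x$freq, cbind(x$total_db, x$fractal_db), type = "l",
                    lty = c(1, 2), col = c("black", "red"),
                    xlab = "Frequency (Hz)", ylab = "Power (dB)", ...)
  graphics::legend("topright", c("total", "fractal"), lty = c(1, 2),
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Log-log slope of the fractal component
#'
#' Least-squares slope of `log10(fractal power)` against `log10(f)`; for a
#' `1/f^chi` background this recovers `-chi`.
#'
#' @param decomp a [irasa_decompose()] result.
#' @param band frequency range for the fit (Hz).
#' @return the fitted slope (dimensionless).
#' @export
fractal_slope <- function(decomp, band = c(2, 100)) {
  sel <- decomp$freq >= band[1] & decomp$freq <= band[2]
  stats::coef(stats::lm(decomp$fractal_db[sel] / 10 ~
                          log10(decomp$freq[sel])))[[2]]
}

#' Per-structure fractal-normalized spectrograms
#'
#' The pipeline workhorse: derives within-structure bipolar pairs, computes
#' per-pair spectrograms, estimates each pair's session-level aperiodic
#' (fractal) spectrum with IRASA over a subsample of windows, normalizes
#' every window's spectrum to it (dB difference) and averages the normalized
#' spectra across the structure's pairs (arithmetic mean in the dB domain).
#'
#' @param rec a [multichannel_recording()].
#' @param structures structures to process (default: all with >= 2 wires).
#' @param hemisphere hemisphere to analyze (default lesioned).
#' @param window_s,overlap,fmax,bin_hz spectrogram parameters.
#' @param factors IRASA resampling factors.
#' @param fractal_windows number of windows used for the session fractal
#'   estimate per pair (evenly spaced).
#' @return class `lfp_spectra`: list with `freq`, `t` and per-structure
#'   elements `normalized` (windows x freq, dB_fractal), `fractal_db`,
#'   `n_pairs`.
#' @export
lfp_spectra <- function(rec, structures = NULL, hemisphere = "lesioned",
                        window_s = 8, overlap = 0.5, fmax = 300,
                        bin_hz = 0.5, factors = default_irasa_factors(),
                        fractal_windows = 12) {
  stopifnot(inherits(rec, "multichannel_recording"))
  map <- rec$channel_map
  if (!is.null(hemisphere)) map <- map[map$hemisphere %in% hemisphere, ]
  if (nrow(map) == 0L) stop_invalid("empty channel map")
  counts <- table(map$structure)
  eligible <- names(counts)[counts >= 2]
  for (s in setdiff(unique(map$structure), eligible))
    warning(sprintf("structure '%s' has < 2 wires; skipped", s),
            call. = FALSE)
  if (is.null(structures)) structures <- eligible
  out <- list(); freq <- NULL; tt <- NULL
  for (s in structures) {
    ch <- sort(map$channel[map$structure == s])
    if (length(ch) < 2L) stop_invalid("unknown structure '%s'", s)
    cmb <- utils::combn(ch, 2)
    acc <- NULL; frac_acc <- NULL
    # pairs are streamed one at a time to bound memory on long sessions
    for (i in seq_len(ncol(cmb))) {
      pair_series <- rec$samples[cmb[1, i], ] - rec$samples[cmb[2, i], ]
      sp <- compute_spectrogram(pair_series, rec$fs, window_s, overlap,
                                fmax, bin_hz)
      eng <- irasa_engine(pair_series, rec$fs, window_s, overlap,
                          factors, fmax, max_windows = fractal_windows)
      af <- .aggregate_bins(eng$freq, eng$fractal, bin_hz)
      norm_db <- 10 * log10(sp$power) -
        matrix(10 * log10(af$power), nrow(sp$power), length(af$freq),
               byrow = TRUE)
      acc <- if (is.null(acc)) norm_db else acc + norm_db
      frac_acc <- if (is.null(frac_acc)) 10 * log10(af$power) else
        frac_acc + 10 * log10(af$power)
      freq <- sp$freq; tt <- sp$t
    }
    out[[s]] <- list(normalized = acc / ncol(cmb),
                     fractal_db = frac_acc / ncol(cmb),
                     n_pairs = ncol(cmb))
  }
  structure(list(structures = out, freq = freq, t = tt,
                 window_s = window_s, overlap = overlap),
            class = "lfp_spectra")
}

#' @export
print.lfp_spectra <- function(x, ...) {
  cat(sprintf("normalized LFP spectra: %d structures, %d windows, %d bins\n",
              length(x$structures), length(x$t), length(x$freq)))
  invisible(x)
}

#' Average normalized spectrum of a structure
#'
#' Arithmetic mean in the dB domain of the fractal-normalized spectra of the
#' structure's electrode pairs, optionally restricted to a time window.
#'
#' @param spectra an [lfp_spectra()] result, or a list of
#'   [irasa_decompose()] results sharing a frequency grid.
#' @param structure structure label (for `lfp_spectra` input).
#' @param window_s optional `(start, end)` window (s) to average over.
#' @return list `freq`, `normalized_db`.
#' @export
average_structure_spectrum <- function(spectra, structure = NULL,
                                       window_s = NULL) {
  if (inherits(spectra, "lfp_spectra")) {
    if (is.null(structure) || !structure %in% names(spectra$structures))
      stop_invalid("unknown structure '%s'", structure %||% "<missing>")
    m <- spectra$structures[[structure]]$normalized
    sel <- if (is.null(window_s)) seq_len(nrow(m)) else
      which(spectra$t >= window_s[1] & spectra$t +
              spectra$window_s <= window_s[2])
    if (!length(sel)) stop_invalid("window contains no spectra")
    list(freq = spectra$freq, normalized_db = colMeans(m[sel, , drop = FALSE]))
  } else {
    if (!length(spectra)) stop_invalid("no decompositions supplied")
    stopifnot(all(vapply(spectra, inherits, TRUE, "fractal_decomposition")))
    list(freq = spectra[[1]]$freq,
         normalized_db = rowMeans(vapply(spectra, `[[`,
                                         numeric(length(spectra[[1]]$freq)),
                                         "normalized_db")))
  }
}
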