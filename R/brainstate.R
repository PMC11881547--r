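#' Whole-spectrum brain-state spectrum of a structure
#'
#' Collects monopolar signals from the structure's electrodes in short
#' (default 4-s) windows within the analysis period, normalizes each
#' window's spectrum to its aperiodic component (per-window IRASA) and
#' averages the normalized spectra over windows and recording sites. The
#' result lives on the native 0.25-Hz grid restricted to 1-200 Hz and is
#' the substrate for across-treatment spectral correlations.
#'
#' @param rec a [multichannel_recording()].
#' @param structure structure label.
#' @param period_s `(start, end)` analysis period (s), e.g. the peak
#'   (40-80 min) or late (120-160 min) window; `NULL` uses the whole
#'   recording.
#' @param window_s window length (s, default 4, non-overlapping).
#' @param factors IRASA resampling factors, scaled to the shorter window: a
#'   coarser grid (`seq(1.1, 1.9, 0.1)`) than the 8-s default, since 4-s
#'   windows resolve fewer independent frequencies per factor.
#' @param frange frequency range (Hz, default 1-200).
#' @param hemisphere hemisphere to analyze.
#' @return object of class `state_spectrum`: `freq`, `spectrum`
#'   (dB_fractal), `structure`, `period_s`, `n_windows`, `n_sites`.
#' @export
state_spectrum <- function(rec, structure, period_s = NULL, window_s = 4,
                           factors = seq(1.1, 1.9, by = 0.1),
                           frange = c(1, 200), hemisphere = "lesioned") {
  stopifnot(inherits(rec, "multichannel_recording"))
  map <- rec$channel_map
  if (!is.null(hemisphere)) map <- map[map$hemisphere %in% hemisphere, ]
  ch <- map$channel[map$structure == structure]
  if (!length(ch)) stop_invalid("no electrodes in structure '%s'", structure)
  i0 <- if (is.null(period_s)) 1L else round(period_s[1] * rec$fs) + 1L
  i1 <- if (is.null(period_s)) ncol(rec$samples) else
    min(ncol(rec$samples), round(period_s[2] * rec$fs))
  if (i1 - i0 + 1L < window_s * rec$fs)
    stop_invalid("period shorter than one %g-s window", window_s)
  acc <- NULL; nwin <- 0L; freq <- NULL
  for (cc in ch) {
    eng <- irasa_engine(rec$samples[cc, i0:i1], rec$fs, window_s,
                        overlap = 0, factors = factors, fmax = frange[2],
                        per_window = TRUE)
    keep <- eng$freq >= frange[1] & eng$freq <= frange[2]
    norm_db <- 10 * log10(eng$total[keep, , drop = FALSE]) -
      10 * log10(eng$fractal[keep, , drop = FALSE])
    acc <- if (is.null(acc)) rowSums(norm_db) else acc + rowSums(norm_db)
    nwin <- nwin + ncol(norm_db)
    freq <- eng$freq[keep]
  }
  structure(list(freq = freq, spectrum = acc / nwin, structure = structure,
                 period_s = period_s, n_windows = nwin,
                 n_sites = length(ch), source = "single session"),
            class = "state_spectrum")
}

#' @export
print.state_spectrum <- function(x, ...) {
  cat(sprintf("brain-state spectrum [%s]: %d bins %g-%g Hz, %d windows x %d sites (%s)\n",
              x$structure, length(x$freq), min(x$freq), max(x$freq),
              x$n_windows, x$n_sites, x$source))
  invisible(x)
}

#' Average several brain-state spectra into a condition reference
#'
#' @param spectra list of [state_spectrum()] objects on one frequency grid.
#' @return a `state_spectrum` with `source = "condition average"`.
#' @export
average_state_spectrum <- function(spectra) {
  if (!length(spectra)) stop_invalid("no spectra supplied")
  stopifnot(all(vapply(spectra, inherits, TRUE, "state_spectrum")))
  f <- spectra[[1]]$freq
  if (!all(vapply(spectra, function(s) isTRUE(all.equal(s$freq, f)), TRUE)))
    stop_invalid("spectra are not on a common frequency grid")
  out <- spectra[[1]]
  out$spectrum <- rowMeans(vapply(spectra, `[[`, numeric(length(f)),
                                  "spectrum"))
  out$source <- "condition average"
  out$n_windows <- sum(vapply(spectra, `[[`, 0L, "n_windows"))
  out
}

#' Spectral similarity of a test condition to two references
#'
#' For each test-condition session, the Pearson correlation between its
#' normalized brain-state spectrum and each reference's condition-average
#' spectrum; the two resulting correlation samples are compared with a
#' two-sided Wilcoxon rank-sum test (reporting plumbing, annotated as
#' underpowered for a single session).
#'
#' @param tests list of [state_spectrum()] objects (test sessions).
#' @param ref_a,ref_b reference `state_spectrum` objects (typically
#'   condition averages).
#' @return object of class `similarity_result`: data frame `r` (`session`,
#'   `r_a`, `r_b`), `p_value`, `note`.
#' @export
treatment_similarity <- function(tests, ref_a, ref_b) {
  if (inherits(tests, "state_spectrum")) tests <- list(tests)
  f <- ref_a$freq
  grids_ok <- isTRUE(all.equal(f, ref_b$freq)) &&
    all(vapply(tests, function(s) isTRUE(all.equal(s$freq, f)), TRUE))
  if (!grids_ok) stop_invalid("spectra are not on a common frequency grid")
  r_a <- vapply(tests, function(s) stats::cor(s$spectrum, ref_a$spectrum), 0)
  r_b <- vapply(tests, function(s) stats::cor(s$spectrum, ref_b$spectrum), 0)
  note <- NULL; p <- NA_real_
  if (length(tests) < 2L) {
    note <- "single test session; comparison underpowered"
  } else if (identical(ref_a$spectrum, ref_b$spectrum)) {
    note <- "identical references"
    p <- 1
  } else {
    p <- stats::wilcox.test(r_a, r_b, exact = FALSE)$p.value
  }
  structure(list(r = data.frame(session = seq_along(tests), r_a = r_a,
                                r_b = r_b),
                 p_value = p, note = note, structure = ref_a$structure),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, digits = 3, ...) {
  cat(sprintf("spectral similarity [%s]: median r_a %.3f vs r_b %.3f (n %d)\n",
              x$structure %||% "?", stats::median(x$r$r_a),
              stats::median(x$r$r_b), nrow(x$r)))
  if (!is.na(x$p_value))
    cat(sprintf("  two-sided rank-sum p = %.3g\n", x$p_value))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
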