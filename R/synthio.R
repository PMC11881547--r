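#' Drug-response time profile
#'
#' Piecewise-linear envelope of a drug response: zero before onset, a linear
#' rise across the onset interval, a plateau at 1 during the peak interval and
#' a linear decay back to zero at `end_min`. Times are minutes after levodopa
#' injection. The defaults follow the canonical time course of peak-dose
#' dyskinesia: onset 20-40 min, peak effect 40-80 min, decay ending around
#' 120 min.
#'
#' @param onset_min two-element numeric, start and end of the rising phase.
#' @param peak_min two-element numeric, plateau interval (envelope = 1).
#' @param end_min time at which the envelope returns to zero.
#' @return an object of class `drug_profile`.
#' @export
drug_profile <- function(onset_min = c(20, 40), peak_min = c(40, 80),
                         end_min = 120) {
  if (onset_min[2] > peak_min[1] + 1e-9 || peak_min[2] > end_min)
    stop_invalid("drug profile intervals must be ordered: onset <= peak <= end")
  structure(list(onset_min = onset_min, peak_min = peak_min,
                 end_min = end_min), class = "drug_profile")
}

#' @export
print.drug_profile <- function(x, ...) {
  cat(sprintf("drug profile: onset %g-%g min, peak %g-%g min, end %g min\n",
              x$onset_min[1], x$onset_min[2], x$peak_min[1], x$peak_min[2],
              x$end_min))
  invisible(x)
}

#' Evaluate a drug-response envelope
#'
#' @param profile a [drug_profile()], or `NULL` for a null (all-zero) response.
#' @param t_min times in minutes after injection.
#' @return envelope values in `[0, 1]`.
#' @export
drug_envelope <- function(profile, t_min) {
  if (is.null(profile)) return(numeric(length(t_min)) + 0)
  stopifnot(inherits(profile, "drug_profile"))
  on <- profile$onset_min; pk <- profile$peak_min; end <- profile$end_min
  e <- numeric(length(t_min))
  rise <- t_min >= on[1] & t_min < pk[1]
  e[rise] <- (t_min[rise] - on[1]) / max(on[2] - on[1], 1e-9)
  e[t_min >= pk[1] & t_min <= pk[2]] <- 1
  fall <- t_min > pk[2] & t_min < end
  e[fall] <- (end - t_min[fall]) / max(end - pk[2], 1e-9)
  pmin(pmax(e, 0), 1)
}

# Rescale a profile's time axis (used to fit the canonical 180-min course into
# shorter desk-scale sessions).
scale_profile <- function(profile, factor) {
  drug_profile(profile$onset_min * factor, profile$peak_min * factor,
               profile$end_min * factor)
}

#' Describe one synthetic narrowband oscillation
#'
#' @param center_hz center frequency (Hz); may drift linearly if `drift_hz`
#'   is a two-element vector `(f_start, f_end)` spanning the session.
#' @param bandwidth_hz full spectral width of the band-limited process (Hz).
#' @param amplitude RMS amplitude of the oscillation during on-epochs, in
#'   units of the (unit-variance) aperiodic background.
#' @param structures character vector of structures that carry the
#'   oscillation (they share one generator and are phase-coupled).
#' @param kappa target von Mises concentration of the instantaneous phase
#'   difference between any two wires carrying the oscillation. `kappa = 0`
#'   draws an independent oscillation per wire (uniform phase differences).
#' @param schedule either `NULL` (always on), the string `"drug"` (on while
#'   the session's drug envelope exceeds 0.5), `"drug-env"` (amplitude
#'   follows the envelope continuously), or a two-column matrix of
#'   `(on_s, off_s)` epochs.
#' @param gain_sd standard deviation of the per-wire log-normal coupling
#'   gain; wire-to-wire gain differences keep the oscillation visible in
#'   bipolar derivations even under tight phase coupling.
#' @param drift_hz optional `(f_start, f_end)` linear drift of the center.
#' @return an object of class `oscillation_spec`.
#' @export
oscillation_spec <- function(center_hz, bandwidth_hz, amplitude, structures,
                             kappa = 0, schedule = NULL, gain_sd = 0.3,
                             drift_hz = NULL) {
  if (bandwidth_hz <= 0 || bandwidth_hz >= 2 * center_hz)
    stop_invalid("need 0 < bandwidth < 2 * center")
  if (kappa < 0) stop_invalid("kappa must be >= 0")
  structure(list(center_hz = center_hz, bandwidth_hz = bandwidth_hz,
                 amplitude = amplitude, structures = structures,
                 kappa = kappa, schedule = schedule, gain_sd = gain_sd,
                 drift_hz = drift_hz),
            class = "oscillation_spec")
}

#' Configure a synthetic recording session
#'
#' Defines the generative conditions of a simulated multichannel LFP session:
#' per-structure aperiodic (1/f^chi) backgrounds, scheduled narrowband
#' oscillations with controlled cross-wire phase coupling, a drug-response
#' time course, and matching rotational behavior / AIMs schedules.
#'
#' The default is a desk-scale session: 11 structures (sensorimotor and
#' cognitive-limbic groups), 4 wires per structure, 30 min at 2000 Hz, with
#' the drug time course compressed proportionally from the canonical 180-min
#' session. `long = TRUE` switches to the full 180-min course.
#'
#' @param duration_s session length in seconds.
#' @param fs sampling rate (Hz).
#' @param structures character vector of structure labels.
#' @param wires_per_structure electrodes per structure.
#' @param chi aperiodic exponent(s), recycled over structures; each wire gets
#'   an independent unit-variance 1/f^chi background.
#' @param oscillations list of [oscillation_spec()] objects; `NULL` gives the
#'   default set (a drug-gated 80-Hz narrowband gamma in M1/dStr/thal with
#'   kappa 8, an always-on 85-Hz limbic oscillation with kappa 2, and an
#'   always-on 7-Hz theta).
#' @param drug_profile a [drug_profile()] in minutes, or `NULL` to scale the
#'   canonical profile to the session length.
#' @param window_s,overlap analysis windowing assumed by the ground-truth
#'   per-window flags (must match the downstream spectrogram settings).
#' @param phase_noise_hz bandwidth of the smooth per-wire phase-jitter
#'   process (Hz); must stay below the +-5 Hz phase-analysis band.
#' @param behavior logical; also generate a rotation trajectory and an AIMs
#'   schedule tied to the drug profile.
#' @param n_contra,n_ipsi rotation counts for the synthetic trajectory.
#' @param frame_rate video frame rate (Hz) for the trajectory.
#' @param long use the full 180-min session length and canonical profile.
#' @param seed integer seed; identical seed and configuration give
#'   bit-identical output.
#' @return an object of class `session_config`.
#' @export
session_config <- function(duration_s = 1800, fs = 2000,
                           structures = c("M1", "S1", "dStr", "vStr", "thal",
                                          "mPFC", "OFC", "OC", "dHipp",
                                          "vHipp", "amyg"),
                           wires_per_structure = 4, chi = 2,
                           oscillations = NULL, drug_profile = NULL,
                           window_s = 8, overlap = 0.5, phase_noise_hz = 2,
                           behavior = TRUE, n_contra = 24, n_ipsi = 4,
                           frame_rate = 30, long = FALSE, seed = 1) {
  if (long) duration_s <- 10800
  if (duration_s <= 0 || fs <= 0) stop_invalid("duration_s and fs must be > 0")
  if (is.null(drug_profile))
    drug_profile <- scale_profile(lidlfp::drug_profile(),
                                  (duration_s / 60) / 180)
  if (is.null(oscillations)) {
    oscillations <- list(
      nbg = oscillation_spec(80, 6, 0.8, c("M1", "dStr", "thal"),
                             kappa = 8, schedule = "drug"),
      limbic = oscillation_spec(85, 12, 0.4, c("dHipp", "vHipp", "OFC"),
                                kappa = 2),
      theta = oscillation_spec(7, 3, 0.5, c("S1", "thal", "dHipp"),
                               kappa = 2))
  }
  chi <- rep_len(chi, length(structures))
  if (any(chi < 0 | chi > 3)) stop_invalid("chi must lie in [0, 3]")
  fmax_osc <- if (length(oscillations)) max(vapply(oscillations, function(o)
    max(o$center_hz, o$drift_hz %||% 0) + o$bandwidth_hz / 2, 0)) else 0
  if (fs <= 2 * fmax_osc)
    stop_invalid("fs must exceed twice the highest oscillation frequency")
  for (o in oscillations)
    if (is.matrix(o$schedule) &&
        (any(o$schedule < 0) || any(o$schedule > duration_s)))
      stop_invalid("oscillation schedule outside [0, duration_s]")
  if (!all(vapply(oscillations, function(o)
    all(o$structures %in% structures), TRUE)))
    stop_invalid("oscillation references an unknown structure")
  structure(list(duration_s = duration_s, fs = fs, structures = structures,
                 wires_per_structure = wires_per_structure, chi = chi,
                 oscillations = oscillations, drug_profile = drug_profile,
                 window_s = window_s, overlap = overlap,
                 phase_noise_hz = phase_noise_hz, behavior = behavior,
                 n_contra = n_contra, n_ipsi = n_ipsi,
                 frame_rate = frame_rate, seed = as.integer(seed)),
            class = "session_config")
}

# --- elementary generators ---------------------------------------------------

.aperiodic_core <- function(chi, n, fs) {
  nh <- (n - 1L) %/% 2L
  f <- (1:nh) * fs / n
  amp <- f^(-chi / 2)
  z <- complex(real = stats::rnorm(nh), imaginary = stats::rnorm(nh)) * amp
  spec <- complex(length.out = n)
  spec[2:(nh + 1L)] <- z
  spec[n:(n - nh + 1L)] <- Conj(z)
  if (n %% 2L == 0L)
    spec[n / 2 + 1L] <- stats::rnorm(1) * (fs / 2)^(-chi / 2)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  # normalize to unit variance in the analysis band (>= 1 Hz): for steep
  # exponents the sub-1-Hz drift would otherwise dominate the variance and
  # make oscillation amplitudes mean different things at different session
  # lengths (Parseval on the constructed spectrum, so exact)
  v_hi <- (2 * sum(Mod(z[f >= 1])^2) +
             if (n %% 2L == 0L) Mod(spec[n / 2 + 1L])^2 else 0) / n^2
  x / sqrt(v_hi)
}

#' Generate aperiodic (1/f^chi) background noise
#'
#' Synthesizes a zero-mean, unit-variance series whose power spectrum follows
#' `f^(-chi)` exactly in expectation, by spectral shaping of white noise
#' (amplitude proportional to `f^(-chi/2)`, independent random phases).
#'
#' @param chi aperiodic exponent in `[0, 3]`; `chi = 0` gives white noise.
#' @param duration_s,fs length (s) and sampling rate (Hz).
#' @param seed integer seed.
#' @return numeric vector of `duration_s * fs` samples.
#' @export
generate_aperiodic <- function(chi, duration_s, fs, seed = 1) {
  if (duration_s <= 0 || fs < 2) stop_invalid("need duration_s > 0 and fs >= 2")
  if (chi < 0 || chi > 3) stop_invalid("chi must lie in [0, 3]")
  n <- round(duration_s * fs)
  local_seed(seed, .aperiodic_core(chi, n, fs))
}

# Smooth unit-variance Gaussian process, brick-wall lowpassed at `cutoff` Hz.
# Synthesized on a coarse grid (>= 25x oversampling of the cutoff) and
# linearly interpolated to the full rate.
.smooth_gauss <- function(n, fs, cutoff) {
  fs_c <- min(fs, 50 * cutoff)
  nc <- max(64L, ceiling(n * fs_c / fs))
  x <- stats::rnorm(nc)
  sp <- stats::fft(x)
  k <- floor(cutoff * nc / fs_c)
  if (k + 2L <= nc - k) sp[(k + 2L):(nc - k)] <- 0
  y <- Re(stats::fft(sp, inverse = TRUE)) / nc
  if (nc < n)
    y <- stats::approx(seq(0, 1, length.out = nc), y,
                       xout = seq(0, 1, length.out = n))$y
  y <- y[seq_len(n)]
  y / stats::sd(y)
}

# Schedule epochs -> gating envelope with raised-cosine edge ramps.
.schedule_envelope <- function(epochs, n, fs, ramp_s = 0.1) {
  env <- numeric(n)
  for (r in seq_len(nrow(epochs))) {
    i0 <- max(1L, round(epochs[r, 1] * fs) + 1L)
    i1 <- min(n, round(epochs[r, 2] * fs))
    if (i1 <= i0) next
    env[i0:i1] <- 1
    nr <- min(round(ramp_s * fs), (i1 - i0) %/% 2L)
    if (nr > 0L) {
      ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
      env[i0:(i0 + nr - 1L)] <- ramp
      env[(i1 - nr + 1L):i1] <- rev(ramp)
    }
  }
  env
}

# Resolve an oscillation's schedule against the session drug profile.
.resolve_schedule <- function(schedule, profile, duration_s) {
  if (is.null(schedule)) return(matrix(c(0, duration_s), 1))
  if (is.matrix(schedule)) return(schedule)
  if (identical(schedule, "drug") || identical(schedule, "drug-env")) {
    t_min <- seq(0, duration_s / 60, by = 1 / 60)   # 1-s resolution
    on <- drug_envelope(profile, t_min) > 0.5
    if (!any(on)) return(matrix(numeric(0), 0, 2))
    d <- diff(c(0L, as.integer(on), 0L))
    cbind(t_min[which(d == 1)] * 60, t_min[which(d == -1) - 1L] * 60)
  } else stop_invalid("unknown schedule")
}

# Complex analytic oscillation: lowpassed complex baseband times a carrier
# whose instantaneous frequency may drift linearly. Unit RMS in the real part
# before gating; returns list(analytic, env, f_inst).
.osc_analytic_core <- function(spec, duration_s, fs, profile) {
  n <- round(duration_s * fs)
  # Gaussian band profile truncated at +-bandwidth: power falls to 1/2 at
  # +-bandwidth/2 (FWHM = bandwidth), so the spectral argmax is the center.
  nh <- max(floor(spec$bandwidth_hz * n / fs), 1L)
  f_off <- (-nh:nh) * fs / n
  wgt <- exp(-log(2) / 2 * (f_off / (spec$bandwidth_hz / 2))^2)
  bb <- complex(length.out = n)
  idx <- c(1L, 2:(nh + 1L), (n - nh + 1L):n)      # offsets 0, 1..nh, -nh..-1
  ord <- c(nh + 1L, (nh + 2L):(2L * nh + 1L), 1L:nh)
  bb[idx] <- complex(real = stats::rnorm(length(idx)),
                     imaginary = stats::rnorm(length(idx))) * wgt[ord]
  b <- stats::fft(bb, inverse = TRUE) / n
  f_inst <- if (is.null(spec$drift_hz)) rep(spec$center_hz, n) else
    seq(spec$drift_hz[1], spec$drift_hz[2], length.out = n)
  phase <- 2 * pi * cumsum(f_inst) / fs
  a <- b * exp(1i * phase)
  a <- a / stats::sd(Re(a))
  epochs <- .resolve_schedule(spec$schedule, profile, duration_s)
  env <- if (identical(spec$schedule, "drug-env")) {
    drug_envelope(profile, seq_len(n) / fs / 60)
  } else .schedule_envelope(epochs, n, fs)
  list(analytic = a * env, env_epochs = epochs, f_inst = f_inst)
}

#' Generate a scheduled narrowband oscillation
#'
#' Band-limited Gaussian noise (not a pure sinusoid, so the recovered peak
#' width is meaningful) centered on `center_hz`, gated by `schedule` with
#' 100-ms raised-cosine edge ramps.
#'
#' @param center_hz,bandwidth_hz spectral center and full width (Hz).
#' @param amplitude RMS amplitude during on-epochs; 0 gives an all-zero
#'   series.
#' @param schedule `NULL` (always on) or a two-column matrix of
#'   `(on_s, off_s)` epochs.
#' @param duration_s,fs length (s) and sampling rate (Hz).
#' @param seed integer seed.
#' @param drift_hz optional `(f_start, f_end)` linear drift of the center.
#' @return numeric vector of `duration_s * fs` samples.
#' @export
generate_oscillation <- function(center_hz, bandwidth_hz, amplitude,
                                 schedule = NULL, duration_s, fs, seed = 1,
                                 drift_hz = NULL) {
  if (center_hz >= fs / 2) stop_invalid("center must be below Nyquist")
  spec <- oscillation_spec(center_hz, bandwidth_hz, amplitude, character(),
                           schedule = schedule, drift_hz = drift_hz)
  if (amplitude == 0) return(numeric(round(duration_s * fs)))
  o <- local_seed(seed, .osc_analytic_core(spec, duration_s, fs, NULL))
  amplitude * Re(o$analytic)
}

# kappa (target pair concentration) -> per-wire Gaussian phase-jitter SD.
# For Gaussian psi, |E exp(i psi)| = exp(-sigma^2 / 2); independent jitter on
# the two wires gives pair mean resultant length exp(-sigma_w^2), matched to
# the von Mises A1(kappa) = I1(kappa) / I0(kappa).
.jitter_sd_for_kappa <- function(kappa) {
  a1 <- besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
  sqrt(-log(a1))
}

#' Generate a full synthetic session with ground truth
#'
#' Builds a multichannel recording per the configuration: every wire receives
#' an independent aperiodic background plus, for each oscillation spec whose
#' structure list contains the wire's structure, a shared band-limited
#' oscillation with a per-wire log-normal gain and a smooth per-wire phase
#' jitter drawn so the wire-pair phase-difference concentration matches the
#' spec's `kappa`. Ground truth sufficient to score every downstream stage is
#' returned alongside.
#'
#' @param cfg a [session_config()].
#' @return a list of class `synthetic_session` with elements `recording`
#'   (a [multichannel_recording()]), `truth` (per-window NBG flags and peak
#'   frequencies, per-pair coupling targets, rotation events, AIMs schedule),
#'   and, when `cfg$behavior` is set, `trajectory` and `aims`.
#' @export
generate_session <- function(cfg) {
  stopifnot(inherits(cfg, "session_config"))
  local_seed(cfg$seed, {
    n <- round(cfg$duration_s * cfg$fs)
    S <- length(cfg$structures); W <- cfg$wires_per_structure
    n_chan <- S * W
    map <- data.frame(channel = seq_len(n_chan),
                      structure = rep(cfg$structures, each = W),
                      hemisphere = "lesioned",
                      stringsAsFactors = FALSE)
    dat <- matrix(0, n_chan, n)
    for (ch in seq_len(n_chan))
      dat[ch, ] <- .aperiodic_core(cfg$chi[(ch - 1L) %/% W + 1L], n, cfg$fs)

    osc_truth <- vector("list", length(cfg$oscillations))
    for (k in seq_along(cfg$oscillations)) {
      o <- cfg$oscillations[[k]]
      wires <- map$channel[map$structure %in% o$structures]
      if (o$amplitude == 0 || length(wires) == 0L) next
      shared <- if (o$kappa >= 1e-3)
        .osc_analytic_core(o, cfg$duration_s, cfg$fs, cfg$drug_profile)
      sd_w <- if (o$kappa >= 1e-3) .jitter_sd_for_kappa(o$kappa) else NA_real_
      for (w in wires) {
        osc <- if (o$kappa >= 1e-3) shared else
          .osc_analytic_core(o, cfg$duration_s, cfg$fs, cfg$drug_profile)
        gain <- exp(stats::rnorm(1, 0, o$gain_sd))
        psi <- if (is.na(sd_w) || sd_w == 0) 0 else
          sd_w * .smooth_gauss(n, cfg$fs, cfg$phase_noise_hz)
        a <- osc$analytic
        dat[w, ] <- dat[w, ] + o$amplitude * gain *
          (Re(a) * cos(psi) - Im(a) * sin(psi))
      }
      osc_truth[[k]] <- list(spec = o,
                             epochs = if (o$kappa >= 1e-3) shared$env_epochs
                                      else osc$env_epochs,
                             f_inst = if (o$kappa >= 1e-3) shared$f_inst
                                      else osc$f_inst)
    }

    rec <- multichannel_recording(dat, cfg$fs, map,
                                  meta = list(treatment = "synthetic",
                                              injection_s = 0))

    # ground-truth per-window NBG flags, aligned with the analysis windowing
    hop <- cfg$window_s * (1 - cfg$overlap)
    win_t0 <- seq(0, cfg$duration_s - cfg$window_s, by = hop)
    nbg_band <- c(65, 110)
    nbg_idx <- which(vapply(cfg$oscillations, function(o)
      o$center_hz > nbg_band[1] && o$center_hz < nbg_band[2] &&
        o$amplitude > 0, TRUE))[1]
    flags <- rep(FALSE, length(win_t0)); peak_f <- rep(NA_real_, length(win_t0))
    if (!is.na(nbg_idx) && !is.null(osc_truth[[nbg_idx]])) {
      ot <- osc_truth[[nbg_idx]]
      for (i in seq_along(win_t0)) {
        a <- win_t0[i]; b <- a + cfg$window_s
        cov <- 0
        if (nrow(ot$epochs))
          cov <- sum(pmax(0, pmin(b, ot$epochs[, 2]) -
                            pmax(a, ot$epochs[, 1])))
        flags[i] <- cov >= cfg$window_s / 2
        peak_f[i] <- mean(ot$f_inst[round(a * cfg$fs + 1):round(b * cfg$fs)])
      }
    }

    kap <- do.call(rbind, lapply(seq_along(cfg$oscillations), function(k) {
      o <- cfg$oscillations[[k]]
      if (length(o$structures) < 2L) return(NULL)
      pr <- utils::combn(sort(o$structures), 2)
      data.frame(struct_a = pr[1, ], struct_b = pr[2, ], kappa = o$kappa,
                 center_hz = o$center_hz, stringsAsFactors = FALSE)
    }))

    out <- list(recording = rec,
                truth = list(window_t0 = win_t0, nbg_window_flags = flags,
                             true_peak_freq = peak_f, true_kappa = kap,
                             drug_profile = cfg$drug_profile),
                config = cfg)
    if (cfg$behavior) {
      traj <- generate_trajectory(cfg$n_contra, cfg$n_ipsi,
                                  frame_rate = cfg$frame_rate,
                                  duration_s = cfg$duration_s,
                                  seed = cfg$seed + 1L)
      # observation grid compressed with the session: 18 observations at
      # any scale (10-min intervals over the canonical 180-min course)
      aims <- generate_aims_schedule(cfg$drug_profile, seed = cfg$seed + 2L,
                                     duration_min = cfg$duration_s / 60,
                                     bin_min = (cfg$duration_s / 60) / 18)
      out$trajectory <- traj
      out$aims <- aims
      out$truth$true_rotations <- attr(traj, "events")
      out$truth$true_aims <- aims
    }
    class(out) <- "synthetic_session"
    out
  })
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("synthetic session: %d channels, %.1f min at %g Hz, %d window flags\n",
              nrow(x$recording$samples), x$config$duration_s / 60,
              x$config$fs, length(x$truth$nbg_window_flags)))
  invisible(x)
}

#' Generate a synthetic rotation trajectory
#'
#' Builds a pose-tracking coordinate table (front point and center point per
#' video frame) whose heading angle traces exactly `n_contra + n_ipsi`
#' complete revolutions, optionally interleaved with partial (7/8-turn)
#' arcs followed by a reversal, which a correct rotation detector must not
#' count. Completed-rotation times and directions are attached as the
#' `"events"` attribute.
#'
#' @param n_contra,n_ipsi counts of complete contralateral / ipsilateral
#'   rotations (with respect to `lesion_side`).
#' @param frame_rate video frame rate (Hz).
#' @param noise_px SD of Gaussian pixel noise added to all coordinates.
#' @param seed integer seed (event ordering and noise).
#' @param lesion_side `"right"` or `"left"`; a right lesion maps
#'   counter-clockwise (increasing angle, y up) rotations to "contra".
#' @param partial_arcs number of injected incomplete arcs.
#' @param duration_s optional minimum duration; trailing frames hold pose.
#' @param rot_duration_s,gap_s seconds per revolution and idle gap length.
#' @param radius_px,center_px body radius and arena center in pixels.
#' @return a data frame (`t_s`, front/center x, y, likelihoods) of class
#'   `synthetic_trajectory`, with attributes `events` (data frame of
#'   completion time and direction), `frame_rate` and `lesion_side`.
#' @export
generate_trajectory <- function(n_contra, n_ipsi, frame_rate = 30,
                                noise_px = 0, seed = 1,
                                lesion_side = "right", partial_arcs = 0,
                                duration_s = NULL, rot_duration_s = 2,
                                gap_s = 1, radius_px = 40,
                                center_px = c(320, 240)) {
  if (n_contra < 0 || n_ipsi < 0 || frame_rate <= 0)
    stop_invalid("counts must be >= 0 and frame_rate > 0")
  contra_sign <- if (identical(lesion_side, "right")) 1 else -1
  local_seed(seed, {
    kinds <- c(rep("contra", n_contra), rep("ipsi", n_ipsi),
               rep("partial", partial_arcs))
    if (length(kinds) > 1L) kinds <- sample(kinds)
    # continuous-time angle path, sampled at frame_rate
    seg_t <- c(); seg_a <- c(); t_cur <- 0; a_cur <- 0
    events <- data.frame(t_s = numeric(0), direction = character(0))
    add <- function(dt, da) {
      seg_t <<- c(seg_t, t_cur); seg_a <<- c(seg_a, a_cur)
      t_cur <<- t_cur + dt; a_cur <<- a_cur + da
    }
    add(gap_s, 0)
    for (k in kinds) {
      if (k == "partial") {
        # fixed sweep direction: an arc plus its reversal can then never
        # concatenate with a neighbor into a monotone 8-sector passage
        add(rot_duration_s * 7 / 8, 2 * pi * 7 / 8)
        add(rot_duration_s * 7 / 8, -2 * pi * 7 / 8)
      } else {
        sgn <- if (k == "contra") contra_sign else -contra_sign
        add(rot_duration_s, sgn * 2 * pi)
        events <- rbind(events,
                        data.frame(t_s = t_cur, direction = k))
      }
      add(gap_s, 0)
    }
    seg_t <- c(seg_t, t_cur); seg_a <- c(seg_a, a_cur)
    total <- max(t_cur + gap_s, duration_s %||% 0)
    t <- seq(0, total, by = 1 / frame_rate)
    theta <- stats::approx(seg_t, seg_a, xout = pmin(t, t_cur),
                           rule = 2)$y
    fx <- center_px[1] + radius_px * cos(theta)
    fy <- center_px[2] + radius_px * sin(theta)
    traj <- data.frame(t_s = t,
                       front_x = fx + stats::rnorm(length(t), 0, noise_px),
                       front_y = fy + stats::rnorm(length(t), 0, noise_px),
                       center_x = center_px[1] +
                         stats::rnorm(length(t), 0, noise_px),
                       center_y = center_px[2] +
                         stats::rnorm(length(t), 0, noise_px),
                       front_likelihood = 1, center_likelihood = 1)
    attr(traj, "events") <- events
    attr(traj, "frame_rate") <- frame_rate
    attr(traj, "lesion_side") <- lesion_side
    class(traj) <- c("synthetic_trajectory", "data.frame")
    traj
  })
}

#' Generate a synthetic AIMs rating schedule
#'
#' One 1-min observation every 10 min (18 observations over a 180-min
#' session), with per-subtype severities on the 0/1/2/2.5 scale and
#' amplitudes on the 1-4 scale following the drug-response envelope, plus
#' mild seeded rater jitter.
#'
#' @param profile a [drug_profile()] or `NULL` (null response, all scores 0).
#' @param seed integer seed.
#' @param duration_min schedule length in minutes.
#' @param bin_min observation spacing in minutes.
#' @return data frame with columns `t_min`, `subtype`, `severity`,
#'   `amplitude` (three rows - axial, limb, orolingual - per observation).
#' @export
generate_aims_schedule <- function(profile, seed = 1, duration_min = 180,
                                   bin_min = 10) {
  if (duration_min < bin_min)
    return(data.frame(t_min = numeric(0), subtype = character(0),
                      severity = numeric(0), amplitude = numeric(0)))
  t_min <- seq(bin_min, duration_min, by = bin_min)
  subtypes <- c("axial", "limb", "orolingual")
  local_seed(seed, {
    rows <- lapply(subtypes, function(st) {
      e <- drug_envelope(profile, t_min)
      lev <- findInterval(e, c(0.15, 0.5, 0.9))   # 0..3
      jit <- sample(c(-1L, 0L, 0L, 0L, 1L), length(e), replace = TRUE)
      lev <- ifelse(lev > 0L, pmin(pmax(lev + jit, 1L), 3L), 0L)
      sev <- c(0, 1, 2, 2.5)[lev + 1L]
      amp <- pmin(pmax(ceiling(e * 4), 1L), 4L)
      data.frame(t_min = t_min, subtype = st, severity = sev,
                 amplitude = amp, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out[order(out$t_min, out$subtype), , drop = FALSE]
  })
}
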