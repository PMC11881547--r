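#' Smooth pose-tracking coordinates
#'
#' Zero-phase low-pass (4th-order Butterworth, applied forwards and
#' backwards) of the front- and center-point coordinates, suppressing
#' tracking jitter while preserving the slow rotational sweep. Frames whose
#' tracking likelihood falls below `min_likelihood` (when likelihood columns
#' are present) are linearly interpolated from their neighbors first.
#'
#' @param traj data frame with columns `t_s`, `front_x`, `front_y`,
#'   `center_x`, `center_y` and optional `front_likelihood`,
#'   `center_likelihood`.
#' @param frame_rate frames per second; taken from the `"frame_rate"`
#'   attribute if missing.
#' @param cutoff low-pass cutoff (Hz, default 5).
#' @param min_likelihood confidence threshold for dropping frames.
#' @return the trajectory with smoothed coordinate columns.
#' @export
smooth_coordinates <- function(traj, frame_rate = NULL, cutoff = 5,
                               min_likelihood = 0.6) {
  frame_rate <- frame_rate %||% attr(traj, "frame_rate") %||%
    (1 / stats::median(diff(traj$t_s)))
  if (frame_rate <= 2 * cutoff)
    stop_invalid("frame rate %g Hz must exceed twice the %g Hz cutoff",
                 frame_rate, cutoff)
  bf <- signal::butter(4, cutoff / (frame_rate / 2), type = "low")
  # odd-reflection padding suppresses filtfilt startup transients
  pad_filt <- function(x) {
    n <- length(x)
    p <- min(n - 1L, round(3 * frame_rate))
    xp <- c(2 * x[1] - rev(x[2:(p + 1L)]), x,
            2 * x[n] - rev(x[(n - p):(n - 1L)]))
    as.numeric(signal::filtfilt(bf, xp))[(p + 1L):(p + n)]
  }
  cols <- c("front_x", "front_y", "center_x", "center_y")
  for (cl in cols) {
    v <- traj[[cl]]
    lik_col <- paste0(sub("_[xy]$", "", cl), "_likelihood")
    if (lik_col %in% names(traj)) {
      bad <- traj[[lik_col]] < min_likelihood
      if (any(bad) && !all(bad))
        v <- stats::approx(which(!bad), v[!bad], xout = seq_along(v),
                           rule = 2)$y
    }
    traj[[cl]] <- pad_filt(v)
  }
  traj
}

#' Heading angle of the animal
#'
#' The vector angle of the front body point with respect to the center point
#' per video frame: `atan2(front_y - center_y, front_x - center_x)`, wrapped
#' to `(-pi, pi]` (0 = front due east of center, `+pi/2` = due north,
#' counter-clockwise positive with y up). Frames with coincident points are
#' undefined (NA).
#'
#' @param traj (smoothed) trajectory data frame.
#' @return numeric vector of angles (radians) with attribute `t_s`.
#' @export
heading_angle <- function(traj) {
  dx <- traj$front_x - traj$center_x
  dy <- traj$front_y - traj$center_y
  a <- atan2(dy, dx)
  a[dx == 0 & dy == 0] <- NA_real_
  attr(a, "t_s") <- traj$t_s
  a
}

#' Detect complete rotations from a heading-angle series
#'
#' The circumference is divided into `n_sectors` (default 8) 45-degree
#' sectors with sector 0 centered on angle 0. A complete rotation is
#' registered when the heading advances monotonically through all sectors in
#' one direction (adjacent transitions only), returning to the start sector;
#' any reversal resets the accumulation, so incomplete arcs are discarded.
#' Sector transitions use a small hysteresis (default 5 degrees) so tracking
#' jitter at a boundary cannot fabricate transitions. Direction is mapped to
#' contralateral / ipsilateral by `lesion_side`: counter-clockwise rotations
#' (increasing angle, y up) are contralateral for a right-hemisphere lesion.
#'
#' @param angle heading-angle series (radians) as from [heading_angle()],
#'   with a `t_s` attribute or accompanied by `t_s`.
#' @param lesion_side `"right"` or `"left"`; required, no default mapping.
#' @param t_s frame times (s); defaults to the series attribute.
#' @param n_sectors number of sectors (default 8).
#' @param hysteresis_deg hysteresis at sector boundaries (degrees).
#' @param max_undefined maximum tolerated fraction of undefined frames.
#' @return object of class `rotation_events`: `events` data frame (`t_s`,
#'   `direction` in contra/ipsi), `n_contra`, `n_ipsi`.
#' @export
detect_rotations <- function(angle, lesion_side, t_s = attr(angle, "t_s"),
                             n_sectors = 8, hysteresis_deg = 5,
                             max_undefined = 0.05) {
  if (!lesion_side %in% c("left", "right"))
    stop_invalid("lesion_side must be 'left' or 'right'")
  if (is.null(t_s)) stop_invalid("frame times t_s required")
  und <- !is.finite(angle)
  if (mean(und) > max_undefined)
    stop_invalid("%.1f%% of frames undefined (limit %.1f%%)",
                 100 * mean(und), 100 * max_undefined)
  ok <- which(!und)
  a <- angle[ok]; tt <- t_s[ok]
  width <- 2 * pi / n_sectors
  hyst <- hysteresis_deg * pi / 180 / 2   # penetration past the boundary
  # continuous (unwrapped) angle relative to the current sector center
  sec <- floor((a[1] + width / 2) / width)
  unwrapped <- cumsum(c(a[1], wrap_angle(diff(a))))
  center <- sec * width
  events <- data.frame(t_s = numeric(0), direction = character(0))
  run_dir <- 0L; run_len <- 0L
  contra_sign <- if (lesion_side == "right") 1 else -1
  for (i in seq_along(unwrapped)) {
    repeat {
      delta <- unwrapped[i] - center
      step <- if (delta > width / 2 + hyst) 1L
              else if (delta < -(width / 2 + hyst)) -1L else 0L
      if (step == 0L) break
      center <- center + step * width
      if (step == run_dir) run_len <- run_len + 1L
      else { run_dir <- step; run_len <- 1L }
      if (run_len == n_sectors) {
        dir <- if (run_dir == contra_sign * 1L) "contra" else "ipsi"
        events <- rbind(events, data.frame(t_s = tt[i], direction = dir))
        run_len <- 0L
      }
    }
  }
  structure(list(events = events,
                 n_contra = sum(events$direction == "contra"),
                 n_ipsi = sum(events$direction == "ipsi"),
                 lesion_side = lesion_side, n_sectors = n_sectors),
            class = "rotation_events")
}

#' @export
print.rotation_events <- function(x, ...) {
  cat(sprintf("rotation events: %d contralateral, %d ipsilateral (lesion %s)\n",
              x$n_contra, x$n_ipsi, x$lesion_side))
  invisible(x)
}

#' Bin rotation events and summarize peak / late periods
#'
#' Counts contralateral rotation events from the time of levodopa
#' administration in non-overlapping 10-min bins (half-open `[t, t + 10)`;
#' boundary events go to the later bin) and averages them as counts per
#' minute over the peak-effect (40-80 min) and late (120-160 min) periods.
#' Events before time zero are excluded with a message.
#'
#' @param events a [detect_rotations()] result, or a data frame with `t_s`
#'   and `direction`.
#' @param duration_min session span in minutes after injection.
#' @param t0_s injection time (s) on the event clock.
#' @param bin_min bin width (minutes).
#' @param peak_min,late_min reporting windows (minutes).
#' @return object of class `rotation_bins`: `bins` data frame (`t_min`,
#'   `contra`, `ipsi`), `peak_mean`, `late_mean` (contralateral counts/min).
#' @export
bin_rotations <- function(events, duration_min, t0_s = 0, bin_min = 10,
                          peak_min = c(40, 80), late_min = c(120, 160)) {
  ev <- if (inherits(events, "rotation_events")) events$events else events
  t_min <- (ev$t_s - t0_s) / 60
  early <- t_min < 0
  if (any(early)) {
    message(sprintf("%d events before levodopa administration excluded",
                    sum(early)))
    ev <- ev[!early, , drop = FALSE]; t_min <- t_min[!early]
  }
  edges <- seq(0, ceiling(duration_min / bin_min) * bin_min, by = bin_min)
  idx <- findInterval(t_min, edges, rightmost.closed = FALSE)
  bins <- data.frame(t_min = edges[-length(edges)])
  bins$contra <- vapply(seq_len(nrow(bins)), function(k)
    sum(idx == k & ev$direction == "contra"), 0L)
  bins$ipsi <- vapply(seq_len(nrow(bins)), function(k)
    sum(idx == k & ev$direction == "ipsi"), 0L)
  in_win <- function(win) t_min >= win[1] & t_min < win[2] &
    ev$direction == "contra"
  structure(list(bins = bins,
                 peak_mean = sum(in_win(peak_min)) / diff(peak_min),
                 late_mean = sum(in_win(late_min)) / diff(late_min),
                 peak_min = peak_min, late_min = late_min),
            class = "rotation_bins")
}

#' @export
print.rotation_bins <- function(x, ...) {
  cat(sprintf("rotations: %d contra total; peak %.2f /min (%g-%g), late %.2f /min (%g-%g)\n",
              sum(x$bins$contra), x$peak_mean, x$peak_min[1], x$peak_min[2],
              x$late_mean, x$late_min[1], x$late_min[2]))
  invisible(x)
}

#' Global AIMs (ALO) score
#'
#' For each observation, the products severity x amplitude of the three
#' dyskinesia subtypes (axial, limb, orolingual) are summed into the global
#' ALO score, bounded by 30 (all subtypes at severity 2.5 and amplitude 4).
#' Severities must lie on the 0/1/2/2.5 scale and amplitudes on 1-4.
#'
#' @param aims data frame with columns `t_min`, `subtype`, `severity`,
#'   `amplitude` (long format, up to three subtype rows per observation).
#' @param peak_min,late_min reporting windows (minutes).
#' @return object of class `aims_scores`: `scores` data frame (`t_min`,
#'   `global`), `peak_mean`, `late_mean`.
#' @export
global_aims <- function(aims, peak_min = c(40, 80), late_min = c(120, 160)) {
  need <- c("t_min", "subtype", "severity", "amplitude")
  if (!all(need %in% names(aims)))
    stop_invalid("AIMs table needs columns %s", paste(need, collapse = ", "))
  bad_sev <- which(!aims$severity %in% c(0, 1, 2, 2.5))
  if (length(bad_sev))
    stop_invalid("row %d: severity %s not on the 0/1/2/2.5 scale",
                 bad_sev[1], aims$severity[bad_sev[1]])
  bad_amp <- which(!aims$amplitude %in% 1:4)
  if (length(bad_amp))
    stop_invalid("row %d: amplitude %s not on the 1-4 scale",
                 bad_amp[1], aims$amplitude[bad_amp[1]])
  glob <- tapply(aims$severity * aims$amplitude, aims$t_min, sum)
  scores <- data.frame(t_min = as.numeric(names(glob)),
                       global = as.numeric(glob))
  scores <- scores[order(scores$t_min), , drop = FALSE]
  win_mean <- function(win) {
    sel <- scores$t_min > win[1] & scores$t_min <= win[2]
    if (any(sel)) mean(scores$global[sel]) else NA_real_
  }
  structure(list(scores = scores, peak_mean = win_mean(peak_min),
                 late_mean = win_mean(late_min)),
            class = "aims_scores")
}

#' @export
print.aims_scores <- function(x, ...) {
  cat(sprintf("global AIMs: %d observations, max %g, peak mean %.2f, late mean %.2f\n",
              nrow(x$scores), max(x$scores$global), x$peak_mean,
              x$late_mean))
  invisible(x)
}
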