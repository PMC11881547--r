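#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the canonical
#' defaults: 8-s / 50%-overlap spectrogram windows, 0-300 Hz, the published
#' IRASA factor set, the 65-110 Hz NBG analysis band with the printed
#' detection thresholds, +-5 Hz order-64 zero-phase bandpass with 10-ms
#' phase decimation, 10-min behavior bins, and peak / late reporting windows
#' at 40-80 and 120-160 min (scaled proportionally for sessions shorter
#' than 180 min).
#'
#' @param recording a [multichannel_recording()] or a directory for
#'   [read_recording()].
#' @param trajectory optional trajectory data frame or CSV path.
#' @param aims optional AIMs table or CSV path.
#' @param lesion_side `"left"` or `"right"` (required for behavior).
#' @param treatment treatment label carried into the report.
#' @param injection_s levodopa injection time on the recording clock (s).
#' @param windows_min list with `peak` and `late` `(start, end)` windows in
#'   minutes; `NULL` scales the canonical windows to the session length.
#' @param band NBG analysis band (Hz).
#' @param thresholds an [nbg_thresholds()].
#' @param window_s,overlap,fmax spectrogram parameters.
#' @param factors IRASA resampling factors for the 8-s spectral chain.
#' @param state_factors IRASA factors for the 4-s brain-state windows
#'   (coarser grid, scaled to the shorter window).
#' @param fractal_windows windows per pair for the session fractal.
#' @param state_window_s brain-state window length (s).
#' @param stages subset of `c("spectra", "detect", "phase", "behavior",
#'   "compare")` to run.
#' @param seed integer seed recorded in the report.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(recording, trajectory = NULL, aims = NULL,
                            lesion_side = "right", treatment = "unknown",
                            injection_s = 0, windows_min = NULL,
                            band = c(65, 110),
                            thresholds = nbg_thresholds(),
                            window_s = 8, overlap = 0.5, fmax = 300,
                            factors = default_irasa_factors(),
                            state_factors = seq(1.1, 1.9, by = 0.1),
                            fractal_windows = 12, state_window_s = 4,
                            stages = c("spectra", "detect", "phase",
                                       "behavior", "compare"),
                            seed = 1) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(recording = recording, trajectory = trajectory,
                 aims = aims, lesion_side = lesion_side,
                 treatment = treatment, injection_s = injection_s,
                 windows_min = windows_min, band = band,
                 thresholds = thresholds, window_s = window_s,
                 overlap = overlap, fmax = fmax, factors = factors,
                 state_factors = state_factors,
                 fractal_windows = fractal_windows,
                 state_window_s = state_window_s, stages = stages,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# canonical 40-80 / 120-160 min reporting windows, scaled to short sessions
.reporting_windows <- function(cfg, duration_min) {
  if (!is.null(cfg$windows_min)) return(cfg$windows_min)
  sc <- min(1, duration_min / 180)
  list(peak = c(40, 80) * sc, late = c(120, 160) * sc)
}

#' Validate pipeline inputs
#'
#' Checks the recording sampling rate (2000 Hz contract; other rates yield a
#' warning and a resample plan note), channel-map completeness and
#' hemisphere labels, and the schemas of the optional trajectory and AIMs
#' tables. Issues are classified as `"fatal"` or `"warning"`.
#'
#' @param rec a [multichannel_recording()].
#' @param trajectory optional trajectory data frame.
#' @param aims optional AIMs table.
#' @return object of class `validation_report`: data frame `issues`
#'   (`level`, `message`), logical `ok` (no fatal issues).
#' @export
validate_inputs <- function(rec, trajectory = NULL, aims = NULL) {
  issues <- data.frame(level = character(0), message = character(0))
  note <- function(level, msg)
    issues <<- rbind(issues, data.frame(level = level, message = msg))
  if (!inherits(rec, "multichannel_recording")) {
    note("fatal", "recording is not a multichannel_recording")
  } else {
    missing_ch <- setdiff(seq_len(nrow(rec$samples)),
                          rec$channel_map$channel)
    if (length(missing_ch))
      note("fatal", sprintf("channel %d missing from channel map",
                            missing_ch[1]))
    bad_h <- setdiff(unique(rec$channel_map$hemisphere),
                     c("lesioned", "intact"))
    if (length(bad_h))
      note("fatal", sprintf("invalid hemisphere label '%s'", bad_h[1]))
    if (rec$fs != 2000)
      note("warning",
           sprintf("fs = %g Hz, not 2000; plan: resample to 2000 Hz",
                   rec$fs))
  }
  if (!is.null(trajectory)) {
    need <- c("t_s", "front_x", "front_y", "center_x", "center_y")
    miss <- setdiff(need, names(trajectory))
    if (length(miss))
      note("fatal", sprintf("trajectory lacks column '%s'", miss[1]))
  }
  if (!is.null(aims)) {
    need <- c("t_min", "subtype", "severity", "amplitude")
    miss <- setdiff(need, names(aims))
    if (length(miss))
      note("fatal", sprintf("AIMs table lacks column '%s'", miss[1]))
    else if (!all(aims$severity %in% c(0, 1, 2, 2.5)))
      note("fatal", "AIMs severities off the 0/1/2/2.5 scale")
  }
  structure(list(issues = issues,
                 ok = !any(issues$level == "fatal")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x$issues)) cat("inputs valid: clean pass\n")
  else for (i in seq_len(nrow(x$issues)))
    cat(sprintf("[%s] %s\n", x$issues$level[i], x$issues$message[i]))
  invisible(x)
}

#' Run the full analysis pipeline on one session
#'
#' Executes the configured stages in order - normalized spectra, NBG
#' detection and feature tracking, phase-coupling kappa matrix, behavior
#' (rotations and AIMs), and brain-state spectra for the peak and late
#' periods - and assembles a reproducible session report. Stage failures
#' abort with a stage-named error; outputs of completed stages are kept in
#' the error's `partial` attribute.
#'
#' @param cfg a [pipeline_config()].
#' @return object of class `session_report` with per-stage outputs, stage
#'   timings, the configuration, and `report_hash` (MD5 over the serialized
#'   stage outputs; identical configuration and seed give an identical
#'   hash).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  rec <- if (is.character(cfg$recording)) read_recording(cfg$recording)
         else cfg$recording
  traj <- if (is.character(cfg$trajectory)) read_trajectory(cfg$trajectory)
          else cfg$trajectory
  aims <- if (is.character(cfg$aims)) read_aims(cfg$aims) else cfg$aims
  val <- validate_inputs(rec, traj, aims)
  if (!val$ok)
    stop(sprintf("stage validate: %s", val$issues$message[1]),
         call. = FALSE)
  duration_min <- ncol(rec$samples) / rec$fs / 60
  wins <- .reporting_windows(cfg, duration_min)
  out <- list(validation = val)
  timings <- c()
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      err <- simpleError(sprintf("stage %s: %s", name, conditionMessage(e)))
      attr(err, "partial") <- out
      stop(err)
    })
    timings[[name]] <<- as.numeric(Sys.time() - t0, units = "secs")
    message(sprintf("stage %-8s done in %6.1f s", name, timings[[name]]))
    res
  }

  if ("spectra" %in% cfg$stages) {
    out$spectra <- run_stage("spectra",
      lfp_spectra(rec, window_s = cfg$window_s, overlap = cfg$overlap,
                  fmax = cfg$fmax, factors = cfg$factors,
                  fractal_windows = cfg$fractal_windows))
  }
  if ("detect" %in% cfg$stages && !is.null(out$spectra)) {
    out$detect <- run_stage("detect", {
      tracks <- lapply(names(out$spectra$structures), function(s)
        track_nbg(out$spectra, s, band = cfg$band,
                  thresholds = cfg$thresholds))
      names(tracks) <- names(out$spectra$structures)
      summaries <- do.call(rbind, c(lapply(tracks, summary),
                                    make.row.names = FALSE))
      fd <- tryCatch(feature_distance(tracks), error = function(e) NULL)
      list(tracks = tracks, summaries = summaries, feature_distance = fd)
    })
  }
  if ("phase" %in% cfg$stages && !is.null(out$detect)) {
    out$phase <- run_stage("phase", {
      centers <- vapply(out$detect$tracks, `[[`, 0, "median_peak_hz")
      # the bandpass center is the median NBG frequency of the recording:
      # one center per session, pooled over all detected windows
      b_all <- unlist(lapply(out$detect$tracks, function(tr)
        tr$windows$B[tr$windows$detected]))
      session_center <- if (length(b_all)) stats::median(b_all) else NA_real_
      km <- if (is.finite(session_center)) {
        structs <- unique(rec$channel_map$structure)
        kappa_matrix(rec,
                     stats::setNames(rep(session_center, length(structs)),
                                     structs),
                     window_s = wins$late * 60)
      }
      list(centers = centers, session_center_hz = session_center,
           kappa = km)
    })
  }
  if ("behavior" %in% cfg$stages && !is.null(traj)) {
    out$behavior <- run_stage("behavior", {
      sm <- smooth_coordinates(traj)
      rot <- detect_rotations(heading_angle(sm), cfg$lesion_side)
      bins <- bin_rotations(rot, duration_min, t0_s = cfg$injection_s,
                            peak_min = wins$peak, late_min = wins$late)
      sc <- if (!is.null(aims))
        global_aims(aims, peak_min = wins$peak, late_min = wins$late)
      corr <- if (!is.null(sc) && !is.null(out$detect)) {
        best <- which.max(vapply(out$detect$tracks, `[[`, 0,
                                 "detection_rate"))
        aims_gamma_correlation(out$detect$tracks[[best]], sc$scores,
                               bin_min = 10 * min(1, duration_min / 180))
      }
      list(rotations = rot, bins = bins, aims = sc,
           aims_gamma_r = corr)
    })
  }
  if ("compare" %in% cfg$stages) {
    out$compare <- run_stage("compare", {
      structs <- unique(rec$channel_map$structure)
      res <- list()
      for (p in c("peak", "late")) {
        res[[p]] <- lapply(structs, function(s)
          state_spectrum(rec, s, period_s = wins[[p]] * 60,
                         window_s = cfg$state_window_s,
                         factors = cfg$state_factors))
        names(res[[p]]) <- structs
      }
      res
    })
  }

  payload <- out[setdiff(names(out), "validation")]
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(payload, tf, version = 3, compress = FALSE)
  hash <- unname(tools::md5sum(tf))
  structure(list(stages = out, timings = timings,
                 config = cfg, windows_min = wins,
                 treatment = cfg$treatment, seed = cfg$seed,
                 report_hash = hash,
                 versions = list(R = as.character(getRversion()))),
            class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("session report [%s], seed %d, hash %s\n", x$treatment,
              x$seed, substr(x$report_hash, 1, 8)))
  cat("  stages:", paste(setdiff(names(x$stages), "validation"),
                         collapse = ", "), "\n")
  if (!is.null(x$stages$detect))
    print(x$stages$detect$summaries, digits = 3)
  invisible(x)
}

#' Write a session report's tables to disk
#'
#' Feature tables and summaries as CSV, kappa pairs and behavior summaries
#' as CSV/JSON, and a provenance record (report hash, seed, versions).
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_report <- function(report, dir) {
  stopifnot(inherits(report, "session_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- report$stages
  if (!is.null(st$detect)) {
    feats <- do.call(rbind, lapply(names(st$detect$tracks), function(s)
      cbind(structure = s, st$detect$tracks[[s]]$windows)))
    utils::write.csv(feats, file.path(dir, "nbg_features.csv"),
                     row.names = FALSE)
    utils::write.csv(st$detect$summaries,
                     file.path(dir, "nbg_summaries.csv"), row.names = FALSE)
  }
  if (!is.null(st$phase) && !is.null(st$phase$kappa))
    utils::write.csv(st$phase$kappa$pairs,
                     file.path(dir, "kappa_pairs.csv"), row.names = FALSE)
  if (!is.null(st$behavior)) {
    utils::write.csv(st$behavior$bins$bins,
                     file.path(dir, "rotation_bins.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(n_contra = st$behavior$rotations$n_contra,
           n_ipsi = st$behavior$rotations$n_ipsi,
           rotation_peak_per_min = st$behavior$bins$peak_mean,
           rotation_late_per_min = st$behavior$bins$late_mean,
           aims_peak_mean = st$behavior$aims$peak_mean %||% NA,
           aims_late_mean = st$behavior$aims$late_mean %||% NA,
           aims_gamma_r = as.numeric(st$behavior$aims_gamma_r %||% NA)),
      file.path(dir, "behavior_summary.json"), auto_unbox = TRUE,
      digits = NA, na = "null")
  }
  jsonlite::write_json(
    list(report_hash = report$report_hash, seed = report$seed,
         treatment = report$treatment,
         windows_min = report$windows_min,
         versions = report$versions),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
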