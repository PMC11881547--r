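# On-disk formats: recordings as flat binary (little-endian float32,
# channel-interleaved frames) with a JSON sidecar and a channel-map CSV;
# trajectories and AIMs tables as CSV; ground truth as JSON.

#' Write a recording to disk
#'
#' Writes `<dir>/data.bin` (float32, little-endian, channel-interleaved:
#' sample-major frames), `<dir>/meta.json` and `<dir>/channel_map.csv`.
#'
#' @param rec a [multichannel_recording()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "multichannel_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$samples), con, size = 4, endian = "little")
  jsonlite::write_json(list(n_channels = nrow(rec$samples),
                            n_samples = ncol(rec$samples),
                            fs = rec$fs, dtype = "float32",
                            byte_order = "little",
                            layout = "channel_interleaved",
                            meta = rec$meta),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(rec$channel_map, file.path(dir, "channel_map.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a recording written by [write_recording()]
#'
#' @param dir directory containing `data.bin`, `meta.json`,
#'   `channel_map.csv`.
#' @return a [multichannel_recording()].
#' @export
read_recording <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop_invalid("unreadable recording: %s",
                                            meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  n <- meta$n_channels * meta$n_samples
  x <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  map <- utils::read.csv(file.path(dir, "channel_map.csv"),
                         stringsAsFactors = FALSE)
  multichannel_recording(matrix(x, meta$n_channels, meta$n_samples),
                         meta$fs, map, as.list(meta$meta))
}

#' Read a pose-tracking coordinate table
#'
#' Accepts either a plain table (columns `t_s` or `frame`, `front_x`,
#' `front_y`, `center_x`, `center_y`, optional likelihoods) or a
#' DeepLabCut-style CSV with the three header rows scorer / bodyparts /
#' coords, in which case the named front and center body parts are
#' extracted (several parts are averaged).
#'
#' @param path CSV path.
#' @param front,center body-part names for DeepLabCut-style tables.
#' @param frame_rate frames per second (to build `t_s` from frame indices).
#' @return trajectory data frame with a `"frame_rate"` attribute.
#' @export
read_trajectory <- function(path, front = c("nose", "mouth"),
                            center = c("tailbase", "bodycenter"),
                            frame_rate = 30) {
  if (!file.exists(path)) stop_invalid("unreadable file: %s", path)
  first <- readLines(path, n = 2L)
  if (grepl("bodyparts", first[2] %||% "", fixed = TRUE) ||
      grepl("scorer", first[1], fixed = TRUE)) {
    hdr <- utils::read.csv(path, header = FALSE, nrows = 3L,
                           stringsAsFactors = FALSE)
    dat <- utils::read.csv(path, header = FALSE, skip = 3L)
    parts <- tolower(as.character(unlist(hdr[2, ])))
    coords <- tolower(as.character(unlist(hdr[3, ])))
    pick <- function(names_want, coord) {
      cols <- which(parts %in% tolower(names_want) & coords == coord)
      if (!length(cols)) stop_invalid("body part(s) %s not found",
                                      paste(names_want, collapse = "/"))
      rowMeans(dat[, cols, drop = FALSE])
    }
    lik <- function(names_want) {
      cols <- which(parts %in% tolower(names_want) &
                      coords == "likelihood")
      if (!length(cols)) rep(1, nrow(dat)) else
        rowMeans(dat[, cols, drop = FALSE])
    }
    traj <- data.frame(t_s = (seq_len(nrow(dat)) - 1L) / frame_rate,
                       front_x = pick(front, "x"),
                       front_y = pick(front, "y"),
                       center_x = pick(center, "x"),
                       center_y = pick(center, "y"),
                       front_likelihood = lik(front),
                       center_likelihood = lik(center))
  } else {
    traj <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"t_s" %in% names(traj)) {
      if (!"frame" %in% names(traj))
        stop_invalid("trajectory needs a t_s or frame column")
      traj$t_s <- (traj$frame - min(traj$frame)) / frame_rate
    }
    need <- c("front_x", "front_y", "center_x", "center_y")
    if (!all(need %in% names(traj)))
      stop_invalid("trajectory needs columns %s",
                   paste(need, collapse = ", "))
  }
  attr(traj, "frame_rate") <- frame_rate
  traj
}

#' Write / read an AIMs rating table
#'
#' @param aims data frame (`t_min`, `subtype`, `severity`, `amplitude`).
#' @param path CSV path.
#' @return the path / the table.
#' @export
write_aims <- function(aims, path) {
  utils::write.csv(aims, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aims
#' @export
read_aims <- function(path) {
  if (!file.exists(path)) stop_invalid("unreadable file: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write ground truth as JSON
#'
#' @param truth the `truth` element of a [generate_session()] result.
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
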