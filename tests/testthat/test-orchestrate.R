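# small but complete synthetic bundle for pipeline-level tests
pipeline_bundle <- function() fixture("pipeline_bundle", function() {
  cfg <- session_config(duration_s = 300,
                        structures = c("M1", "dStr", "OFC"),
                        wires_per_structure = 2, chi = 1.5,
                        oscillations = list(
                          oscillation_spec(80, 6, 1.2, c("M1", "dStr"),
                                           kappa = 8, schedule = "drug")),
                        behavior = TRUE, n_contra = 8, n_ipsi = 2,
                        seed = 77)
  generate_session(cfg)
})

test_that("input validation distinguishes fatal issues from warnings", {
  ss <- pipeline_bundle()
  v <- validate_inputs(ss$recording, ss$trajectory, ss$aims)
  expect_true(v$ok)
  expect_equal(nrow(v$issues), 0)
  # missing channel-map row is fatal and names the channel
  rec_bad <- ss$recording
  rec_bad$channel_map <- rec_bad$channel_map[-2, ]
  v2 <- validate_inputs(rec_bad)
  expect_false(v2$ok)
  expect_match(v2$issues$message[1], "channel 2")
  # wrong sampling rate: warning plus a resample plan, not fatal
  rec_fs <- ss$recording; rec_fs$fs <- 1000
  v3 <- validate_inputs(rec_fs)
  expect_true(v3$ok)
  expect_match(v3$issues$message[1], "resample")
  # malformed AIMs table is fatal
  bad_aims <- ss$aims; bad_aims$severity[1] <- 9
  expect_false(validate_inputs(ss$recording, aims = bad_aims)$ok)
})

bundle_report <- function() fixture("bundle_report", function() {
  ss <- pipeline_bundle()
  cfg <- pipeline_config(ss$recording, trajectory = ss$trajectory,
                         aims = ss$aims, treatment = "vehicle", seed = 77)
  suppressMessages(run_pipeline(cfg))
})

test_that("the pipeline produces a complete, reproducible report", {
  ss <- pipeline_bundle()
  cfg <- pipeline_config(ss$recording, trajectory = ss$trajectory,
                         aims = ss$aims, treatment = "vehicle", seed = 77)
  r1 <- bundle_report()
  expect_s3_class(r1, "session_report")
  expect_true(all(c("spectra", "detect", "phase", "behavior", "compare")
                  %in% names(r1$stages)))
  expect_true(is.data.frame(r1$stages$detect$summaries))
  expect_equal(r1$stages$behavior$rotations$n_contra, 8)
  # determinism: identical configuration gives an identical report hash
  r2 <- suppressMessages(run_pipeline(cfg))
  expect_identical(r1$report_hash, r2$report_hash)
})

test_that("stages can be disabled without disturbing the others", {
  ss <- pipeline_bundle()
  cfg <- pipeline_config(ss$recording, trajectory = ss$trajectory,
                         aims = ss$aims,
                         stages = c("spectra", "detect", "behavior"),
                         seed = 77)
  r <- suppressMessages(run_pipeline(cfg))
  expect_null(r$stages$phase)
  expect_null(r$stages$compare)
  expect_false(is.null(r$stages$detect))
  full <- bundle_report()
  expect_identical(r$stages$detect$summaries, full$stages$detect$summaries)
})

test_that("reporting windows scale with session length", {
  ss <- pipeline_bundle()
  cfg <- pipeline_config(ss$recording, seed = 1)
  r <- suppressMessages(run_pipeline(
    pipeline_config(ss$recording, stages = "spectra", seed = 1)))
  sc <- (300 / 60) / 180
  expect_equal(r$windows_min$peak, c(40, 80) * sc)
  expect_equal(r$windows_min$late, c(120, 160) * sc)
})

test_that("recordings, trajectories and AIMs tables round-trip through disk", {
  ss <- pipeline_bundle()
  dir <- tempfile("recio")
  write_recording(ss$recording, dir)
  back <- read_recording(dir)
  expect_equal(back$samples, ss$recording$samples, tolerance = 1e-6)
  expect_equal(back$fs, ss$recording$fs)
  expect_equal(back$channel_map$structure, ss$recording$channel_map$structure)
  unlink(dir, recursive = TRUE)
  # AIMs CSV
  p <- tempfile(fileext = ".csv")
  write_aims(ss$aims, p)
  expect_equal(read_aims(p)$severity, ss$aims$severity)
  unlink(p)
})

test_that("DeepLabCut-style pose tables are parsed into trajectories", {
  # three header rows (scorer / bodyparts / coords), averaged parts
  n <- 10
  hdr <- c("scorer,m1,m1,m1,m1,m1,m1",
           "bodyparts,nose,nose,nose,tailbase,tailbase,tailbase",
           "coords,x,y,likelihood,x,y,likelihood")
  rows <- sapply(seq_len(n), function(i)
    paste(c(i, 10 + i, 20, 0.99, 1, 2, 0.98), collapse = ","))
  p <- tempfile(fileext = ".csv")
  writeLines(c(hdr, rows), p)
  tr <- read_trajectory(p, front = "nose", center = "tailbase",
                        frame_rate = 30)
  expect_equal(nrow(tr), n)
  expect_equal(tr$front_x, 10 + seq_len(n))
  expect_equal(tr$center_y, rep(2, n))
  expect_equal(tr$t_s[2] - tr$t_s[1], 1 / 30)
  unlink(p)
  expect_error(read_trajectory(tempfile()), "unreadable")
})

test_that("report tables are written to disk with provenance", {
  dir <- tempfile("report")
  write_session_report(bundle_report(), dir)
  expect_true(file.exists(file.path(dir, "nbg_features.csv")))
  expect_true(file.exists(file.path(dir, "behavior_summary.json")))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_identical(prov$report_hash, bundle_report()$report_hash)
  feats <- utils::read.csv(file.path(dir, "nbg_features.csv"))
  expect_true(all(c("structure", "t", "A", "B", "C", "detected")
                  %in% names(feats)))
  unlink(dir, recursive = TRUE)
})
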