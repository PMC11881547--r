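test_that("coordinate smoothing removes jitter and preserves slow sweeps", {
  fr <- 30; t <- (0:(fr * 30 - 1)) / fr
  const <- data.frame(t_s = t, front_x = 100, front_y = 50,
                      center_x = 0, center_y = 0)
  sm <- smooth_coordinates(const, frame_rate = fr)
  expect_equal(sm$front_x, rep(100, length(t)), tolerance = 1e-6)
  # 10-Hz jitter on top of a fixed position: amplitude reduced >= 80%
  jit <- data.frame(t_s = t, front_x = 100 + 5 * sin(2 * pi * 10 * t),
                    front_y = 50, center_x = 0, center_y = 0)
  smj <- smooth_coordinates(jit, frame_rate = fr)
  expect_lt(stats::sd(smj$front_x - 100), 0.2 * stats::sd(jit$front_x - 100))
  # 0.2-Hz circular sweep: amplitude preserved within 2%
  sweep <- data.frame(t_s = t, front_x = 40 * cos(2 * pi * 0.2 * t),
                      front_y = 40 * sin(2 * pi * 0.2 * t),
                      center_x = 0, center_y = 0)
  sms <- smooth_coordinates(sweep, frame_rate = fr)
  mid <- 100:(length(t) - 100)
  r <- sqrt(sms$front_x[mid]^2 + sms$front_y[mid]^2)
  expect_true(all(abs(r - 40) / 40 < 0.02))
  expect_error(smooth_coordinates(const, frame_rate = 8), "cutoff")
  # low-likelihood frames are interpolated before filtering
  spik <- const
  spik$front_likelihood <- 1; spik$center_likelihood <- 1
  spik$front_x[100] <- 1e4; spik$front_likelihood[100] <- 0.1
  sms2 <- smooth_coordinates(spik, frame_rate = fr)
  expect_lt(max(abs(sms2$front_x - 100)), 1)
})

test_that("heading angle follows the stated convention", {
  traj <- data.frame(t_s = 0:3,
                     front_x = c(1, 0, -1, 0), front_y = c(0, 1, 0, -1),
                     center_x = 0, center_y = 0)
  a <- heading_angle(traj)
  expect_equal(as.numeric(a), c(0, pi / 2, pi, -pi / 2))
  # coincident points undefined
  traj2 <- data.frame(t_s = 0, front_x = 5, front_y = 5, center_x = 5,
                      center_y = 5)
  expect_true(is.na(heading_angle(traj2)[1]))
  # uniform circular motion: linear unwrapped angle at the angular velocity
  fr <- 30; t <- (0:(fr * 10 - 1)) / fr; w <- 2 * pi * 0.4
  circ <- data.frame(t_s = t, front_x = cos(w * t), front_y = sin(w * t),
                     center_x = 0, center_y = 0)
  ang <- heading_angle(circ)
  unw <- cumsum(c(ang[1], (diff(ang) + pi) %% (2 * pi) - pi))
  slope <- stats::coef(stats::lm(unw ~ t))[[2]]
  expect_equal(slope, w, tolerance = 0.01)
})

test_that("rotation counting is exact on noiseless mixed-direction trajectories", {
  cases <- list(c(3, 0, 0), c(0, 4, 0), c(25, 25, 5), c(50, 0, 3),
                c(12, 7, 4))
  for (cs in cases) {
    tr <- generate_trajectory(cs[1], cs[2], partial_arcs = cs[3],
                              seed = sum(cs) + 1)
    rot <- detect_rotations(heading_angle(smooth_coordinates(tr)), "right")
    expect_equal(rot$n_contra, cs[1])
    expect_equal(rot$n_ipsi, cs[2])
  }
  # lesion-side mapping flips the labels
  tr <- generate_trajectory(5, 2, seed = 3)
  rot_l <- detect_rotations(heading_angle(smooth_coordinates(tr)), "left")
  expect_equal(rot_l$n_contra, 2)
  expect_equal(rot_l$n_ipsi, 5)
  expect_error(detect_rotations(1:10, "up"), "lesion_side")
})

test_that("rotation counts are invariant to translation, scaling and frame rate", {
  tr <- generate_trajectory(11, 4, seed = 9, partial_arcs = 2)
  count <- function(x) {
    r <- detect_rotations(heading_angle(smooth_coordinates(x)), "right")
    c(r$n_contra, r$n_ipsi)
  }
  base <- count(tr)
  expect_equal(base, c(11, 4))
  aff <- tr
  for (cl in c("front_x", "center_x")) aff[[cl]] <- aff[[cl]] * 3 + 250
  for (cl in c("front_y", "center_y")) aff[[cl]] <- aff[[cl]] * 3 - 80
  expect_equal(count(aff), base)
  tr60 <- generate_trajectory(11, 4, seed = 9, partial_arcs = 2,
                              frame_rate = 60)
  expect_equal(count(tr60), base)
})

test_that("noise below the body radius leaves counts unchanged", {
  for (npx in c(1, 3)) {
    tr <- generate_trajectory(8, 3, noise_px = npx, seed = 31)
    rot <- detect_rotations(heading_angle(smooth_coordinates(tr)), "right")
    expect_equal(c(rot$n_contra, rot$n_ipsi), c(8, 3))
  }
})

test_that("rotation bins are half-open, conservative and summarized per period", {
  # 12 events uniformly inside 40-80 min: peak mean 0.3 per min
  ev <- data.frame(t_s = seq(40.5, 79.5, length.out = 12) * 60,
                   direction = "contra")
  b <- bin_rotations(ev, duration_min = 180)
  expect_equal(b$peak_mean, 0.3)
  expect_equal(b$late_mean, 0)
  expect_equal(sum(b$bins$contra), 12)
  # boundary events belong to the later bin
  evb <- data.frame(t_s = c(600, 600, 1200), direction = "contra")
  bb <- bin_rotations(evb, duration_min = 60)
  expect_equal(bb$bins$contra[bb$bins$t_min == 10], 2)
  expect_equal(bb$bins$contra[bb$bins$t_min == 20], 1)
  # empty events: all-zero bins
  b0 <- bin_rotations(data.frame(t_s = numeric(0),
                                 direction = character(0)), 60)
  expect_true(all(b0$bins$contra == 0))
  # pre-injection events excluded with a message
  expect_message(bpre <- bin_rotations(
    data.frame(t_s = c(-5, 100), direction = "contra"), 60), "excluded")
  expect_equal(sum(bpre$bins$contra), 1)
  # bin totals conserve event counts
  tr <- generate_trajectory(20, 6, seed = 13)
  rot <- detect_rotations(heading_angle(smooth_coordinates(tr)), "right")
  bt <- bin_rotations(rot, duration_min = 10)
  expect_equal(sum(bt$bins$contra), rot$n_contra)
  expect_equal(sum(bt$bins$ipsi), rot$n_ipsi)
})

test_that("global AIMs score is the severity-amplitude sum on the printed scales", {
  a <- data.frame(t_min = rep(10, 3),
                  subtype = c("axial", "limb", "orolingual"),
                  severity = c(2, 1, 0), amplitude = c(3, 2, 1))
  expect_equal(global_aims(a)$scores$global, 8)
  amax <- data.frame(t_min = rep(10, 3),
                     subtype = c("axial", "limb", "orolingual"),
                     severity = 2.5, amplitude = 4)
  expect_equal(global_aims(amax)$scores$global, 30)   # scale maximum
  azero <- amax; azero$severity <- 0
  expect_equal(global_aims(azero)$scores$global, 0)
  # validation names the offending row
  bad <- a; bad$severity[2] <- 1.7
  expect_error(global_aims(bad), "row 2")
  bad2 <- a; bad2$amplitude[3] <- 5
  expect_error(global_aims(bad2), "row 3")
  # window means over the observation grid
  sched <- generate_aims_schedule(drug_profile(), seed = 2)
  g <- global_aims(sched)
  manual <- g$scores$global[g$scores$t_min > 40 & g$scores$t_min <= 80]
  expect_equal(g$peak_mean, mean(manual))
})
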