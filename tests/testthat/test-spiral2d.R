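test_that("tip tracking pins a rigidly rotating field to its center", {
  rf <- rotating_field()
  traj <- track_tips(rf$frames, u_iso = 0, dx = rf$dx,
                     frame_time = rf$time)
  expect_gt(nrow(traj$tips), 0)
  # a tip in (nearly) every frame, always within 2*dx of the true center
  expect_gte(mean(traj$counts$n_tips >= 1), 0.95)
  d <- sqrt((traj$tips$x - rf$center[1])^2 + (traj$tips$y - rf$center[2])^2)
  expect_lt(max(d), 2 * rf$dx)
})

test_that("uniform and planar-wave frames contain no tips", {
  n <- 40
  flat <- array(0.3, dim = c(n, n, 5))
  traj <- track_tips(flat, u_iso = 0.5, dx = 0.05,
                     frame_time = seq(0, 20, by = 5))
  expect_equal(nrow(traj$tips), 0)
  expect_true(all(traj$counts$n_tips == 0))
  # traveling planar front: isoline and zero-velocity contour are parallel
  xs <- (seq_len(n) - 1) * 0.05
  times <- seq(0, 40, by = 5)
  frames <- vapply(times, function(t) {
    matrix(rep(1 / (1 + exp((xs - 0.3 - 0.02 * t) / 0.08)), n), n, n)
  }, matrix(0, n, n))
  ptraj <- track_tips(frames, u_iso = 0.5, dx = 0.05, frame_time = times)
  expect_equal(nrow(ptraj$tips), 0)
})

test_that("rotation periods are recovered from synthetic inputs", {
  # probe trace with activations every 150 ms
  tt <- seq(0, 2000, by = 1)
  u <- as.numeric((tt %% 150) < 30)
  expect_equal(rotation_period(data.frame(time = tt, u = u)), 150,
               tolerance = 0.01)
  # circular tip trajectory with omega = 2*pi/200
  times <- seq(0, 800, by = 5)
  traj <- structure(list(
    tips = tibble::tibble(time = times,
                          x = 2 + cos(2 * pi * times / 200),
                          y = 2 + sin(2 * pi * times / 200),
                          track = 1L),
    counts = tibble::tibble(time = times, n_tips = 1L),
    dx = 0.02, frame_dt = 5
  ), class = "mm_tip_trajectory")
  expect_equal(rotation_period(traj), 200, tolerance = 1e-6)
  # insufficient cycles yield an unsustained NA, not a number
  short <- data.frame(time = 0:300, u = as.numeric(0:300 %in% 100:120))
  expect_message(pp <- rotation_period(short), "unsustained")
  expect_true(is.na(pp))
})

test_that("dynamics classification applies the tip-count rules", {
  mk_traj <- function(counts, times, tips = NULL) {
    structure(list(
      tips = tips %||% tibble::tibble(time = numeric(0), x = numeric(0),
                                      y = numeric(0), track = integer(0)),
      counts = tibble::tibble(time = times, n_tips = counts),
      dx = 0.02, frame_dt = diff(times[1:2])
    ), class = "mm_tip_trajectory")
  }
  times <- seq(0, 1000, by = 10)
  expect_equal(classify_dynamics(mk_traj(rep(0L, length(times)), times),
                                 1000, s2_time = 0), "no_reentry")
  # four concurrent tips for 500 ms: breakup
  counts <- ifelse(times >= 300 & times <= 800, 4L, 1L)
  circ <- tibble::tibble(time = times,
                         x = 2 + cos(2 * pi * times / 150),
                         y = 2 + sin(2 * pi * times / 150), track = 1L)
  expect_equal(classify_dynamics(mk_traj(counts, times, circ), 1000),
               "breakup")
  # single sustained tip to the end of the run: stable
  expect_equal(classify_dynamics(mk_traj(rep(1L, length(times)), times,
                                         circ), 1000), "stable")
  # tips vanish mid-run after full rotations: terminated
  counts_t <- ifelse(times <= 600, 1L, 0L)
  circ_t <- dplyr::filter(circ, time <= 600)
  expect_equal(classify_dynamics(mk_traj(counts_t, times, circ_t), 1000),
               "terminated")
})

test_that("an S1-only sheet sweeps planarly and returns to rest", {
  p <- model_parameters()
  cfg <- grid2d_config(side = 1.6, frame_dt = 10, t_total = 400,
                       stim_amplitude = 0.5, probe_xy = c(1.2, 0.8))
  sh <- run_2d(p, cfg, s2_enabled = FALSE)
  expect_s3_class(sh, "mm_sheet")
  # the wave front stays planar: y-variation of u negligible mid-run
  mid <- sh$frames[, , which.min(abs(sh$frame_time - 30))]
  expect_lt(max(apply(mid, 1, function(r) diff(range(r)))), 1e-6)
  traj <- track_tips(sh)
  expect_true(all(traj$counts$n_tips == 0))
  expect_equal(classify_dynamics(traj, cfg$t_total, s2_time = 0),
               "no_reentry")
  # probe saw the wave pass exactly once
  pr <- sh$probes[sh$probes$probe == 1, c("time", "u")]
  expect_length(activation_times(pr), 1)
  # default geometry matches the reference setup
  expect_equal(grid2d_config()$side, 9.6)
  expect_equal(grid2d_config()$n, 480)
})
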