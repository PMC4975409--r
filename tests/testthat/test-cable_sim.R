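test_that("no-flux Laplacian uses mirror ghosts with the expected flux budget", {
  expect_equal(laplacian_noflux(rep(3, 10), 0.5), rep(0, 10))
  expect_equal(laplacian_noflux(c(0, 1, 2, 3), 1), c(2, 0, 0, -2))
  set.seed(1)
  for (k in 1:5) {
    u <- rnorm(20)
    # interior terms telescope; the only residual flux is the mirror term
    # at each boundary, which vanishes when the boundary gradient does
    imbalance <- (u[2] - u[1]) + (u[19] - u[20])
    expect_equal(sum(laplacian_noflux(u, 0.1)) * 0.1^2, imbalance,
                 tolerance = 1e-10)
    u[c(1, 20)] <- u[c(2, 19)]   # flat boundaries: exact conservation
    expect_lt(abs(sum(laplacian_noflux(u, 0.1)) * 0.1), 1e-12)
  }
  expect_error(laplacian_noflux(c(1, 2), 1), "at least 3")
})

test_that("configuration guards reject unstable or malformed setups", {
  cfg <- cable_config()
  expect_equal(cfg$n_cells, 100)
  expect_equal(cfg$dx, 0.02)
  expect_equal(cfg$dt, 0.01)
  expect_error(cable_config(n_cells = 5), ">= 10")
  expect_error(cable_config(D = 0.03), "unstable")
  expect_error(grid2d_config(D = 0.011), "unstable")
})

test_that("an unstimulated cable stays at rest", {
  rec <- run_cable(model_parameters(), default_cable(),
                   stimulus_times = numeric(0), t_end = 200)
  expect_lt(max(abs(rec$trace$u)), 1e-6)
  expect_equal(nrow(rec$activations), 0)
})

test_that("a stimulated cable propagates with ordered activations", {
  p <- model_parameters()
  cfg <- default_cable()
  rec <- run_cable(p, cfg, stimulus_times = 10, t_end = 500)
  act <- rec$activations
  # one activation per cell, strictly later with distance from the stimulus
  expect_equal(sort(unique(act$site)), 1:100)
  interior <- act[act$site >= 5, ]
  expect_true(all(diff(interior$time[order(interior$site)]) > 0))
  t25 <- act$time[act$site == 25]
  t75 <- act$time[act$site == 75]
  cv <- conduction_velocity(t25, t75, 1.0)
  expect_gt(cv, 10)
  expect_lt(cv, 200)
})

test_that("shifting the stimulus site translates the activation profile", {
  p <- model_parameters()
  amp <- default_amp()
  cfg_a <- cable_config(stim_amplitude = amp)
  cfg_b <- cable_config(stim_amplitude = amp, stim_cells = 11:13)
  ra <- run_cable(p, cfg_a, stimulus_times = 10, t_end = 400)
  rb <- run_cable(p, cfg_b, stimulus_times = 10, t_end = 400)
  ta <- ra$activations
  tb <- rb$activations
  # interior sites ahead of both stimuli: activation delayed by the
  # conduction time over 10 cells, CV unchanged
  cv_a <- conduction_velocity(ta$time[ta$site == 40], ta$time[ta$site == 80],
                              40 * cfg_a$dx)
  cv_b <- conduction_velocity(tb$time[tb$site == 50], tb$time[tb$site == 90],
                              40 * cfg_a$dx)
  expect_lt(abs(cv_a - cv_b) / cv_a, 0.01)
  expect_lt(abs(ta$time[ta$site == 40] - tb$time[tb$site == 50]), 0.5)
})

test_that("compiled diffusion matches the reference Laplacian step for step", {
  p <- model_parameters()
  set.seed(3)
  n <- 50
  u0 <- runif(n)
  st <- cbind(u0, runif(n), runif(n), runif(n))
  nstep <- 200
  out <- atriafit:::mm_cable_run(as.numeric(p), st, 0, nstep * 0.01, 0.02,
                                 0.01, 0.001, numeric(0), 2, 0, integer(0),
                                 as.integer(0:(n - 1)), 1000L, 0.2, 50,
                                 diffusion_only = TRUE)
  expect_true(out$ok)
  u_ref <- u0
  for (k in seq_len(nstep)) {
    u_ref <- u_ref + 0.01 * 0.001 * laplacian_noflux(u_ref, 0.02)
  }
  expect_equal(out$state[, 1], u_ref, tolerance = 1e-13)
  # with flat boundary gradients the spatial mean is conserved per step
  u0[c(1, 2)] <- 0.5
  u0[c(n - 1, n)] <- 0.25
  one <- atriafit:::mm_cable_run(as.numeric(p), cbind(u0, 0, 0, 0), 0,
                                 0.01, 0.02, 0.01, 0.001, numeric(0), 2, 0,
                                 integer(0), as.integer(0:(n - 1)), 1L,
                                 0.2, 50, diffusion_only = TRUE)
  expect_lt(abs(mean(one$state[, 1]) - mean(u0)), 1e-14)
})

test_that("stimulus calibration finds a propagating amplitude", {
  amp <- default_amp()
  expect_gt(amp, 0.01)
  expect_lt(amp, 10)
  # half the safety-factored amplitude still propagates (it is 2x threshold)
  cfg <- cable_config(stim_amplitude = amp / 1.5)
  rec <- run_cable(model_parameters(), cfg, stimulus_times = 10,
                   t_end = 300)
  expect_gt(nrow(rec$activations), 90)
})
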