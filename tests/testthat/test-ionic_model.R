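test_that("resting state is a fixed point with vanishing derivatives", {
  p <- model_parameters()
  rs <- resting_state(p)
  expect_equal(rs$u, 0)
  expect_equal(rs$v, 1)
  expect_equal(rs$w, 1)
  expect_equal(rs$s, (1 + tanh(-p[["k_s"]] * p[["u_s"]])) / 2)
  d <- ionic_derivatives(rs, p)
  expect_lt(abs(d$J_ion), 1e-9)
  expect_lt(abs(d$dv), 1e-9)
  expect_lt(abs(d$dw), 1e-9)
  expect_lt(abs(d$ds), 1e-9)

  # elevated resting potential: w follows the sub-threshold branch
  p2 <- model_parameters(u_o = 0.05, theta_vminus = 0.08, theta_o = 0.08)
  rs2 <- resting_state(p2)
  expect_equal(rs2$w, 1 - 0.05 / p2[["tau_winf"]])
  expect_equal(rs2$v, 1)

  # holding the state without stimulus leaves it unchanged
  tr <- run_cell(p, stimulus_times = numeric(0), t_end = 1000,
                 stim_amplitude = 0)
  expect_lt(max(abs(tr$u - rs$u)), 1e-6)
})

test_that("individual current terms follow their definitions", {
  p <- model_parameters()
  # below every threshold with u = u_o all currents vanish
  d0 <- ionic_derivatives(data.frame(u = 0, v = 1, w = 1, s = 0), p)
  expect_equal(d0$J_ion, 0)
  expect_equal(d0$dv, 0)
  expect_equal(d0$dw, 0)
  # slow inward current contributes -w*s/tau_si above theta_w
  p2 <- model_parameters(tau_si = 2)
  st <- data.frame(u = 0.5, v = 0, w = 0.5, s = 0.5)
  st0 <- transform(st, s = 0)
  dsi <- ionic_derivatives(st, p2)$J_ion - ionic_derivatives(st0, p2)$J_ion
  expect_equal(dsi, -0.125)
})

test_that("ionic_derivatives matches the independent scalar oracle", {
  p <- model_parameters()
  set.seed(42)
  n <- 1000
  states <- data.frame(u = runif(n, -0.4, 1.9), v = runif(n),
                       w = runif(n), s = runif(n))
  # include threshold ties to pin down the H(0) = 1 convention
  states$u[1:4] <- c(p[["theta_v"]], p[["theta_w"]], p[["theta_vminus"]],
                     p[["theta_o"]])
  d <- ionic_derivatives(states, p)
  ref <- t(mapply(oracle_derivs, states$u, states$v, states$w, states$s,
                  MoreArgs = list(p = p)))
  expect_rel_equal(d$J_ion, ref[, "J_ion"], 1e-12)
  expect_rel_equal(d$dv, ref[, "dv"], 1e-12)
  expect_rel_equal(d$dw, ref[, "dw"], 1e-12)
  expect_rel_equal(d$ds, ref[, "ds"], 1e-12)
})

test_that("explicit Euler stepping is exact arithmetic on the derivatives", {
  p <- model_parameters()
  rs <- resting_state(p)
  expect_equal(step_euler(rs, 0, 0.01, p), rs)
  one <- step_euler(rs, I_stim = 0.5, dt = 0.01, p)
  expect_equal(one$u, 0.005)
  expect_error(step_euler(data.frame(u = 3, v = 1, w = 1, s = 0), 0, 0.01, p))
})

test_that("a suprathreshold pulse elicits an AP matching a fine-timestep run", {
  p <- model_parameters()
  coarse <- run_cell(p, stimulus_times = 10, t_end = 500, dt = 0.01,
                     stim_amplitude = 0.6)
  fine <- run_cell(p, stimulus_times = 10, t_end = 500, dt = 0.001,
                   stim_amplitude = 0.6)
  expect_lt(abs(max(coarse$u) - max(fine$u)) / max(fine$u), 0.01)
  a_c <- activation_times(coarse)
  a_f <- activation_times(fine)
  expect_lt(abs(apd90(coarse, a_c[1]) - apd90(fine, a_f[1])) /
              apd90(fine, a_f[1]), 0.01)
})

test_that("gates stay in [0,1] along a paced trajectory", {
  p <- model_parameters()
  tr <- run_cell(p, stimulus_times = seq(10, 1210, by = 400), t_end = 1600,
                 stim_amplitude = 0.6)
  expect_true(all(tr$v >= 0 & tr$v <= 1))
  expect_true(all(tr$w >= 0 & tr$w <= 1))
  expect_true(all(tr$s >= 0 & tr$s <= 1))
})

test_that("an early second stimulus falls in the refractory period", {
  p <- model_parameters()
  # S2 290 ms after S1 (just past 90% repolarization): only a brief graded
  # response; S2 at 450 ms: fully recovered, full second AP
  early <- run_cell(p, stimulus_times = c(10, 300), t_end = 700,
                    stim_amplitude = 0.6)
  late <- run_cell(p, stimulus_times = c(10, 460), t_end = 900,
                   stim_amplitude = 0.6)
  plateau_ms <- function(tr, t0) {
    sum(tr$u[tr$time >= t0 & tr$time < t0 + 250] > 0.5) *
      (tr$time[2] - tr$time[1])
  }
  expect_lt(plateau_ms(early, 300), 80)
  expect_gt(plateau_ms(late, 460), 150)
  # 100 ms after the early S2 the cell is back near rest; after the late
  # S2 it is still on the plateau
  expect_lt(early$u[early$time == 400], 0.05)
  expect_gt(late$u[late$time == 560], 0.5)
  expect_length(activation_times(late), 2)
})
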