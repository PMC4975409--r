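test_that("activation detection interpolates threshold crossings", {
  flat <- data.frame(time = 0:200, u = rep(0, 201))
  expect_length(activation_times(flat), 0)
  expect_error(activation_times(data.frame(time = numeric(0),
                                           u = numeric(0))), "empty")
  # square pulse stepping 0 -> 1 at t = 100: detection within one sample
  sq <- data.frame(time = 0:200, u = as.numeric(0:200 >= 100))
  a <- activation_times(sq)
  expect_length(a, 1)
  expect_lt(abs(a - 100), 1)
  # refractory guard merges chatter around one upstroke
  chatter <- data.frame(time = seq(0, 20, by = 0.5),
                        u = rep(c(0, 1), 21)[1:41])
  expect_length(activation_times(chatter, refractory = 50), 1)
})

test_that("a paced cell yields one detection per beat at the pacing CL", {
  p <- model_parameters()
  stims <- seq(10, 10 + 9 * 400, by = 400)
  tr <- run_cell(p, stimulus_times = stims, t_end = 4400,
                 stim_amplitude = 0.6)
  a <- activation_times(tr)
  expect_length(a, 10)
  expect_true(all(abs(diff(a) - 400) < 1))
})

test_that("apd90 measures 90% repolarization with interpolation", {
  # rectangular AP of 100 ms
  rect <- data.frame(time = seq(-20, 200, by = 1),
                     u = as.numeric(seq(-20, 200, by = 1) >= 0 &
                                    seq(-20, 200, by = 1) <= 100))
  expect_lt(abs(apd90(rect, 0) - 100), 1)
  # triangular AP decaying linearly over 200 ms: 90% repol at t = 180
  tt <- seq(-20, 250, by = 1)
  tri <- data.frame(time = tt, u = ifelse(tt < 0, 0, pmax(1 - tt / 200, 0)))
  expect_equal(apd90(tri, 0), 180, tolerance = 1e-6)
  # unresolved repolarization raises a typed error
  plateau <- data.frame(time = 0:100, u = rep(1, 101))
  expect_error(apd90(plateau, 0), class = "atriafit_unresolved_apd")
})

test_that("conduction velocity converts distance over delay to cm/s", {
  expect_equal(conduction_velocity(0, 10, 1), 100)
  expect_equal(conduction_velocity(5, 25, 1), 50)
  expect_error(conduction_velocity(10, 10, 1),
               class = "atriafit_no_propagation")
  expect_error(conduction_velocity(0, 10, -1), "distance")
})

test_that("upstroke interval spans 10% to peak of the rising phase", {
  tt <- seq(-5, 30, by = 0.01)
  ramp <- data.frame(time = tt,
                     u = pmin(pmax(tt / 2, 0), 1))
  expect_equal(upstroke_interval(ramp, 0), 1.8, tolerance = 0.02)
  step <- data.frame(time = seq(-5, 30, by = 1),
                     u = as.numeric(seq(-5, 30, by = 1) >= 0))
  expect_lte(upstroke_interval(step, 0), 1)
})

test_that("morphology normalization is affine-invariant and masks the artifact window", {
  p <- model_parameters()
  tr <- default_cell_trace()
  a <- activation_times(tr)[1]
  seg <- tr[tr$time > a - 20 & tr$time < a + 400, c("time", "u")]
  m1 <- normalize_morphology(seg, artifact_cutoff_ms = 10, activation = a)
  seg2 <- transform(seg, u = 3.7 * u - 80)   # arbitrary affine rescaling
  m2 <- normalize_morphology(seg2, artifact_cutoff_ms = 10, activation = a)
  expect_equal(m1$grid, m2$grid, tolerance = 1e-12)
  expect_equal(max(m1$grid$v_norm), 1)
  expect_true(all(m1$grid$t_norm >= 0 & m1$grid$t_norm <= 1 + 1e-9))
  # mask boundary sits exactly at 10 ms after activation
  expect_equal(m1$artifact_cutoff, 10 / m1$apd90)
  raw_times <- a + m1$grid$t_norm * m1$apd90
  expect_true(all(raw_times[m1$grid$masked] < a + 10 + 1e-6))
  expect_true(all(raw_times[!m1$grid$masked] >= a + 10 - 1e-6))
  expect_error(normalize_morphology(data.frame(time = 0:10,
                                               u = rep(1, 11))),
               "zero-amplitude")
})

test_that("S1-S2 protocol produces monotone restitution anchored at steady state", {
  s <- default_s1s2()
  pts <- s$points[s$points$captured, ]
  expect_equal(s$s1_cl, 500)
  # degenerate S2 = S1 CL reproduces steady pacing within 2%
  row0 <- pts[pts$S2 == 500, ]
  expect_lt(abs(row0$APD - s$apd_s1) / s$apd_s1, 0.02)
  # APD(DI) non-decreasing in DI (monotone restitution)
  o <- order(pts$DI)
  expect_true(all(diff(pts$APD[o]) > -1))
  # failed captures are flagged rather than dropped
  expect_true(any(!s$points$captured))
  expect_true(all(is.na(s$points$APD[!s$points$captured])))
  # DI bookkeeping: DI = S2 - APD90(last S1)
  expect_equal(pts$DI, pts$S2 - s$apd_s1)
  # shapes captured per captured S2 with near-collapsing morphology
  expect_gte(length(s$shapes), nrow(pts) - 1)
  grids <- vapply(s$shapes, function(sh) {
    g <- atriafit:::resample_morphology(sh)
    ifelse(g$masked, NA, g$v_norm)
  }, numeric(200))
  spread <- mean(abs(grids - rowMeans(grids)), na.rm = TRUE)
  expect_lt(spread, 0.1)
})
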