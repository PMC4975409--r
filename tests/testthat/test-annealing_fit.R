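# a fake simulated curve set matching the error_components input contract
fake_sim <- function(ds, apd_scale = 1, cv_scale = 1, morph_offset = 0) {
  shape <- ds$morphology
  if (morph_offset != 0) {
    shape$grid$v_norm <- shape$grid$v_norm + morph_offset
  }
  list(points = tibble::tibble(
         S2 = ds$di_cl_points$CL,
         DI = ds$apd_points$DI,
         APD = ds$apd_points$APD * apd_scale,
         CV = approx(ds$cv_di_points$DI, ds$cv_di_points$CV,
                     xout = ds$apd_points$DI, rule = 2)$y * cv_scale,
         captured = TRUE),
       shapes = list(`500` = shape),
       upstroke = 1.5)
}

test_that("error components reproduce hand-computed percent errors", {
  ds <- generate_patient(patient_spec(noise_sd = list(apd = 0, cv = 0,
                                                      morph = 0), seed = 3))
  exact <- error_components(fake_sim(ds), ds)
  expect_lt(exact$e_apd, 1e-6)
  expect_lt(exact$e_cv, 0.3)   # smoothed CV target vs piecewise-linear sim
  expect_lt(exact$e_morph, 1e-6)
  expect_lt(exact$total, 0.2)
  # uniform 10% APD inflation
  infl <- error_components(fake_sim(ds, apd_scale = 1.1), ds)
  expect_equal(infl$e_apd, 10, tolerance = 0.01)
  # constant morphology offset of 0.05 on the unmasked grid
  off <- error_components(fake_sim(ds, morph_offset = 0.05), ds)
  expect_equal(off$e_morph, 5, tolerance = 0.05)
  # weighted total
  wtd <- error_components(fake_sim(ds, apd_scale = 1.1), ds,
                          weights = c(apd = 1, cv = 0, morph = 1))
  expect_equal(wtd$total, (wtd$e_apd + wtd$e_morph) / 2, tolerance = 1e-9)
  # a simulated curve that misses the target DI range is penalized
  short <- fake_sim(ds)
  short$points <- short$points[short$points$DI > 150, ]
  pen <- error_components(short, ds, uncovered_penalty = 25)
  expect_gt(pen$e_apd, exact$e_apd)
})

test_that("proposals respect mask, temperature scaling and bounds", {
  p <- model_parameters()
  cfg <- fit_config(sigma = 0.12, move_subset = NULL, min_step_frac = 0)
  set.seed(5)
  # vanishing temperature: proposal collapses onto the input (no step
  # floor)
  q0 <- propose_parameters(p, temperature = 1e-30, t0 = 1, cfg = cfg)
  expect_equal(as.numeric(q0), as.numeric(p), tolerance = 1e-9)
  # masked parameters never move
  draws <- replicate(300, {
    q <- propose_parameters(p, 1, 1, cfg)
    q[c("u_o", "u_u", "theta_v")]
  })
  expect_true(all(draws == c(p[["u_o"]], p[["u_u"]], p[["theta_v"]])))
  # log-perturbation sd of a scale parameter tracks sigma * sqrt(T/T0)
  ratio <- 0.5
  lp <- replicate(10000, {
    q <- propose_parameters(p, ratio, 1, cfg)
    log(q[["tau_si"]] / p[["tau_si"]])
  })
  target_sd <- cfg$sigma * sqrt(ratio)
  expect_lt(abs(sd(lp) - target_sd) / target_sd, 0.05)
  # bounds clip: huge sigma cannot escape the tenfold box
  cfg_wide <- fit_config(sigma = 10)
  qs <- replicate(200, propose_parameters(p, 1, 1, cfg_wide)[["tau_fi"]])
  expect_true(all(qs >= p[["tau_fi"]] * 0.1 - 1e-12 &
                  qs <= p[["tau_fi"]] * 10 + 1e-12))
})

test_that("the annealer locates the minimum of a toy quadratic surface", {
  obj <- function(xy) (xy[1] - 3)^2 + (xy[2] + 1)^2
  prop <- function(cur, temp, t0) cur + rnorm(2, 0, temp / t0)
  hits <- 0
  traces_monotone <- TRUE
  for (r in 1:100) {
    set.seed(1000 + r)
    res <- sa_optimize(obj, c(0, 0), prop, n_iterations = 50,
                       moves_per_iteration = 20, cooling_factor = 0.9,
                       initial_temperature = 1)
    # within 1% of the optimum location (0.03 on coordinates of order 3)
    if (sqrt(res$best_error) < 0.04) hits <- hits + 1
    if (any(diff(res$trace$E_best) > 0)) traces_monotone <- FALSE
  }
  expect_gte(hits, 95)
  expect_true(traces_monotone)
})

test_that("the greedy limit reduces to hill climbing", {
  obj <- function(xy) sum(xy^2)
  prop <- function(cur, temp, t0) cur + rnorm(2, 0, 0.3)
  set.seed(7)
  res <- sa_optimize(obj, c(2, 2), prop, n_iterations = 20,
                     moves_per_iteration = 10, greedy = TRUE)
  expect_equal(res$trace$E_current, res$trace$E_best)
  expect_true(all(diff(res$trace$E_best) <= 0))
})

test_that("distinct seeds can settle in distinct equally good minima", {
  # double-well objective: two symmetric optima at +1 and -1
  obj <- function(x) (x^2 - 1)^2
  prop <- function(cur, temp, t0) cur + rnorm(1, 0, 0.8 * temp / t0)
  finals <- vapply(1:40, function(s) {
    set.seed(s)
    sa_optimize(obj, 0.01, prop, n_iterations = 40,
                moves_per_iteration = 10)$best
  }, numeric(1))
  expect_true(any(finals > 0.9) && any(finals < -0.9))
  errs <- (finals^2 - 1)^2
  expect_lt(max(errs), 0.01)
})

test_that("annealing a self-consistent target is reproducible and stays near zero", {
  ds <- model_truth_dataset()
  truth <- attr(ds, "truth_params")
  cable <- default_cable()
  # a fixed T0 skips the pilot evaluations; two iterations suffice to
  # exercise acceptance bookkeeping and reproducibility
  cfg <- fit_config(n_iterations = 2, moves_per_iteration = 2,
                    initial_temperature = 5, seed = 21)
  fit1 <- anneal(ds, init = truth, cfg = cfg, cable = cable)
  # starting at truth, the best error cannot exceed the self-fit floor
  base <- error_components(
    s1s2_restitution(truth, cable, s2_list = ds$di_cl_points$CL[
      unique(round(seq(1, nrow(ds$di_cl_points), length.out = 6)))]),
    ds)
  expect_lte(fit1$errors$total, base$total + 1e-9)
  expect_lt(fit1$errors$e_apd, 2)
  expect_true(all(diff(fit1$trace$E_best) <= 0))
  # reproducibility under the same seed
  fit2 <- anneal(ds, init = truth, cfg = cfg, cable = cable)
  expect_equal(as.numeric(fit1$params), as.numeric(fit2$params))
  expect_equal(fit1$trace, fit2$trace)
  # tidy/glance accessors
  td <- tidy(fit1)
  expect_true(all(c("term", "estimate", "init") %in% names(td)))
  expect_equal(nrow(td), 28)
  expect_equal(glance(fit1)$iterations, 2)
})
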