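make_shape <- function(v, cutoff = 0.05) {
  g <- seq(0, 1, length.out = length(v))
  structure(list(grid = tibble::tibble(t_norm = g, v_norm = v,
                                       masked = g < cutoff),
                 artifact_cutoff = cutoff, apd90 = 300),
            class = "mm_morphology")
}

test_that("morphology averaging is the identity on identical shapes", {
  g <- seq(0, 1, length.out = 200)
  v <- (1 - g^2)
  v <- (v - min(v)) / (max(v) - min(v))
  sh <- make_shape(v)
  avg1 <- average_morphology(list(sh))
  expect_equal(avg1$grid$v_norm, v, tolerance = 1e-10)
  avg3 <- average_morphology(list(sh, sh, sh))
  expect_equal(avg3$grid$v_norm, v, tolerance = 1e-10)
  # symmetric perturbations cancel
  eps <- 0.05 * sin(8 * pi * g)
  up <- make_shape(pmin(pmax(v + eps, 0), 1))
  dn <- make_shape(pmin(pmax(v - eps, 0), 1))
  # keep perturbed values inside [0,1] so the +/- pair is exact
  keep <- v + abs(eps) <= 1 & v - abs(eps) >= 0
  avg <- average_morphology(list(up, dn))
  expect_lt(max(abs(avg$grid$v_norm[keep] - v[keep])), 1e-6)
  expect_error(average_morphology(list(make_shape(v, 0.05),
                                       make_shape(v, 0.5))),
               "inconsistent")
})

test_that("simulated-shape average lies within the input envelope", {
  s <- default_s1s2()
  shapes <- s$shapes
  avg <- average_morphology(shapes)
  grids <- vapply(shapes, function(sh) {
    atriafit:::resample_morphology(sh)$v_norm
  }, numeric(200))
  lo <- apply(grids, 1, min)
  hi <- apply(grids, 1, max)
  inside <- avg$grid$v_norm >= lo - 0.02 & avg$grid$v_norm <= hi + 0.02
  expect_gt(mean(inside), 0.95)
})

test_that("polynomial morphology fits recover exact polynomials", {
  g <- seq(0, 1, length.out = 200)
  v <- 0.2 + 0.9 * g - 1.4 * g^2 + 0.5 * g^3
  sh <- make_shape(pmin(pmax(v, 0), 1), cutoff = 0)
  fit <- fit_morphology_polynomial(sh, degree = 3)
  expect_lt(fit$rms, 1e-10)
  expect_equal(fit$coefficients, c(0.2, 0.9, -1.4, 0.5), tolerance = 1e-6)
  expect_equal(predict_polyfit(fit, 0.5),
               min(max(0.2 + 0.45 - 0.35 + 0.0625, 0), 1),
               tolerance = 1e-6)
  cst <- fit_morphology_polynomial(make_shape(rep(0.7, 50), 0), degree = 0)
  expect_equal(cst$coefficients, 0.7)
  # high-order fit of a simulated AP shape is tight
  s <- default_s1s2()
  f12 <- fit_morphology_polynomial(average_morphology(s$shapes), 12)
  expect_lt(f12$rms, 0.01)
})

test_that("logarithmic APD fit recovers generating coefficients and slope", {
  di <- c(40, 60, 90, 140, 200, 260)
  pts <- data.frame(DI = di, APD = 100 + 30 * log(di))
  fit <- fit_apd_log(pts)
  expect_equal(fit$a, 100, tolerance = 1e-9)
  expect_equal(fit$b, 30, tolerance = 1e-9)
  # max slope equals the numerical derivative of the fitted curve at min DI
  h <- 1e-4
  num_slope <- ((fit$a + fit$b * log(40 + h)) -
                (fit$a + fit$b * log(40 - h))) / (2 * h)
  expect_equal(fit$max_slope, num_slope, tolerance = 1e-5)
  flat <- fit_apd_log(data.frame(DI = c(50, 200), APD = c(250, 250)))
  expect_equal(flat$b, 0)
  expect_error(fit_apd_log(data.frame(DI = c(-1, 10), APD = c(1, 2))),
               "DI")
})

test_that("CV restitution composes CV(CL) with DI(CL)", {
  cl <- seq(300, 500, by = 50)
  flat <- cv_of_di(data.frame(CL = cl, CV = 60),
                   data.frame(CL = cl, DI = cl - 240))
  expect_equal(flat$CV, rep(60, length(cl)), tolerance = 1e-9)
  # linear CV(CL) with DI = CL - c becomes linear CV(DI), same slope
  lin <- cv_of_di(data.frame(CL = cl, CV = 30 + 0.05 * cl),
                  data.frame(CL = cl, DI = cl - 240))
  slopes <- diff(lin$CV) / diff(lin$DI)
  expect_equal(slopes, rep(0.05, length(cl) - 1), tolerance = 1e-9)
  # non-monotone DI(CL) triggers isotonic correction with a warning
  expect_warning(
    iso <- cv_of_di(data.frame(CL = cl, CV = 60),
                    data.frame(CL = cl, DI = c(100, 140, 120, 180, 210))),
    "isotonic")
  expect_true(!is.unsorted(iso$DI))
  expect_error(cv_of_di(data.frame(CL = c(100, 120), CV = c(60, 60)),
                        data.frame(CL = c(400, 500), DI = c(100, 200))),
               "overlap")
})

test_that("patient bundles round-trip through the directory format", {
  ds <- generate_patient(patient_spec(seed = 5))
  dir <- withr::local_tempdir()
  write_patient_bundle(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("morphology.csv", "apd_restitution.csv", "cv_vs_cl.csv",
      "di_vs_cl.csv", "meta.json")))))
  back <- read_patient_bundle(dir)
  expect_equal(back$apd_points, ds$apd_points, tolerance = 1e-9)
  expect_equal(back$cv_cl_points, ds$cv_cl_points, tolerance = 1e-9)
  expect_equal(back$morphology$grid$v_norm, ds$morphology$grid$v_norm,
               tolerance = 1e-9)
  expect_equal(back$apd_logfit$a, ds$apd_logfit$a, tolerance = 1e-6)
  # incomplete bundles are rejected with the missing file named
  file.remove(file.path(dir, "cv_vs_cl.csv"))
  expect_error(read_patient_bundle(dir), "cv_vs_cl.csv")
})
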