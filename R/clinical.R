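#' Average several morphology shapes
#'
#' Pointwise mean of normalized AP shapes on a common 200-point normalized
#' time grid (linear resampling), re-normalized to span `[0, 1]`. Clinical
#' AP shapes are roughly cycle-length independent, which is what makes the
#' average meaningful.
#'
#' @param shapes list of `mm_morphology` objects (>= 1) with a common
#'   artifact cutoff.
#' @param cutoff_tol largest admissible spread of the normalized artifact
#'   cutoffs before they count as inconsistent.
#' @param n grid resolution.
#' @return An `mm_morphology` on the common grid.
#' @export
average_morphology <- function(shapes, cutoff_tol = 0.1, n = 200) {
  if (!length(shapes)) abort("need at least one shape")
  cutoffs <- vapply(shapes, function(s) s$artifact_cutoff, numeric(1))
  if (diff(range(cutoffs)) > cutoff_tol) {
    abort("inconsistent artifact cutoffs across shapes")
  }
  cutoff <- max(cutoffs)
  V <- vapply(shapes, function(s) resample_morphology(s, n)$v_norm,
              numeric(n))
  v <- rowMeans(V)
  v <- (v - min(v)) / (max(v) - min(v))
  g <- seq(0, 1, length.out = n)
  structure(list(
    grid = tibble(t_norm = g, v_norm = v, masked = g < cutoff),
    artifact_cutoff = cutoff,
    apd90 = mean(vapply(shapes, function(s) s$apd90 %||% NA_real_,
                        numeric(1)), na.rm = TRUE)
  ), class = "mm_morphology")
}

#' Polynomial fit to a morphology shape
#'
#' Least-squares polynomial fit on the unmasked part of the normalized
#' shape, using an orthogonal basis internally for conditioning. The
#' clinical workflow fits a high-order polynomial to the artifact-corrected
#' average morphology; degree 12 is the default.
#'
#' @param shape an `mm_morphology`.
#' @param degree polynomial degree.
#' @return An object of class `mm_polyfit`: list with power-basis
#'   `coefficients` (constant first), `degree`, `rms` residual and the
#'   fitting window. Use [predict_polyfit()] to evaluate (clamped to
#'   `[0, 1]`).
#' @export
fit_morphology_polynomial <- function(shape, degree = 12) {
  g <- shape$grid[!shape$grid$masked, ]
  if (nrow(g) < degree + 1) abort("not enough unmasked samples for this degree")
  if (degree == 0) {
    co <- mean(g$v_norm)
    return(structure(list(coefficients = co, degree = 0,
                          rms = sqrt(mean((g$v_norm - co)^2)),
                          range = range(g$t_norm)), class = "mm_polyfit"))
  }
  fit <- stats::lm(v_norm ~ poly(t_norm, degree), data = g)
  rms <- sqrt(mean(stats::residuals(fit)^2))
  # recover power-basis coefficients by exact interpolation of the fitted
  # polynomial at Chebyshev nodes
  rng <- range(g$t_norm)
  nodes <- (rng[1] + rng[2]) / 2 +
    (rng[2] - rng[1]) / 2 * cos(pi * (0:degree) / degree)
  vals <- stats::predict(fit, newdata = data.frame(t_norm = nodes))
  V <- outer(nodes, 0:degree, `^`)
  co <- solve(V, vals)
  structure(list(coefficients = as.numeric(co), degree = degree, rms = rms,
                 range = rng), class = "mm_polyfit")
}

#' Evaluate a morphology polynomial fit
#'
#' @param fit an `mm_polyfit`.
#' @param t_norm normalized times to evaluate at.
#' @return Fitted normalized voltage, clamped to `[0, 1]`.
#' @export
predict_polyfit <- function(fit, t_norm) {
  v <- drop(outer(t_norm, 0:fit$degree, `^`) %*% fit$coefficients)
  pmin(pmax(v, 0), 1)
}

#' Logarithmic APD restitution fit
#'
#' Least squares for `APD = a + b * ln(DI)`, the standard clinical form of
#' the APD restitution curve. The maximum slope of the fitted curve over
#' the data range is `b / min(DI)`.
#'
#' @param points data frame with columns `DI` and `APD` (ms); all `DI > 0`.
#' @return An object of class `mm_apdfit`: list with `a`, `b` (ms),
#'   `max_slope`, and the fitted `points`.
#' @export
fit_apd_log <- function(points) {
  points <- tibble::as_tibble(points)[, c("DI", "APD")]
  points <- points[stats::complete.cases(points), ]
  if (nrow(points) < 2) abort("need at least two APD restitution points")
  if (any(points$DI <= 0)) abort("all DI must be > 0")
  fit <- stats::lm(APD ~ log(DI), data = points)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  if (is.na(b)) b <- 0  # degenerate: identical DIs
  structure(list(a = a, b = b, max_slope = b / min(points$DI),
                 points = points), class = "mm_apdfit")
}

#' @export
print.mm_apdfit <- function(x, ...) {
  cat(sprintf("<mm_apdfit> APD = %.1f + %.1f ln(DI) ms; max slope %.2f\n",
              x$a, x$b, x$max_slope))
  invisible(x)
}

#' Compose CV restitution from CV(CL) and DI(CL)
#'
#' Fits a polynomial (default degree 2) to the measured CV-versus-CL
#' points, interpolates the DI-versus-CL relation monotonically, and emits
#' the CV restitution curve `(DI(CL), CV_fit(CL))` at each measured cycle
#' length. A non-monotone DI(CL) relation is corrected isotonically with a
#' warning.
#'
#' @param cv_cl_points data frame with columns `CL` (ms) and `CV` (cm/s).
#' @param di_cl_points data frame with columns `CL` (ms) and `DI` (ms).
#' @param poly_degree degree of the CV(CL) polynomial.
#' @return A tibble with columns `DI`, `CV`, `CL`.
#' @export
cv_of_di <- function(cv_cl_points, di_cl_points, poly_degree = 2) {
  cvp <- tibble::as_tibble(cv_cl_points)[, c("CL", "CV")]
  dip <- tibble::as_tibble(di_cl_points)[, c("CL", "DI")]
  cvp <- cvp[stats::complete.cases(cvp), ]
  dip <- dip[stats::complete.cases(dip), ]
  if (max(dip$CL) < min(cvp$CL) || min(dip$CL) > max(cvp$CL)) {
    abort("CL ranges of CV(CL) and DI(CL) do not overlap")
  }
  dip <- dplyr::arrange(dip, .data$CL)
  if (is.unsorted(dip$DI)) {
    warn("DI(CL) not monotone; applying isotonic correction")
    dip$DI <- stats::isoreg(dip$CL, dip$DI)$yf
  }
  deg <- min(poly_degree, nrow(cvp) - 1)
  fit <- if (deg >= 1) {
    stats::lm(CV ~ poly(CL, deg), data = cvp)
  } else {
    stats::lm(CV ~ 1, data = cvp)
  }
  cls <- cvp$CL[cvp$CL >= min(dip$CL) & cvp$CL <= max(dip$CL)]
  di <- stats::approx(dip$CL, dip$DI, xout = cls, rule = 2)$y
  cv <- stats::predict(fit, newdata = data.frame(CL = cls))
  tibble(DI = di, CV = as.numeric(cv), CL = cls)
}

#' Assemble a clinical dataset
#'
#' Bundles one "patient": the averaged normalized AP morphology target,
#' APD restitution points with their logarithmic fit, the CV(CL) and
#' DI(CL) tables, the derived CV(DI) curve, and an optional upstroke
#' interval target.
#'
#' @param morphology an `mm_morphology` (typically from
#'   [average_morphology()]).
#' @param apd_points data frame `DI`, `APD` (ms).
#' @param cv_cl_points data frame `CL`, `CV`.
#' @param di_cl_points data frame `CL`, `DI`.
#' @param upstroke_dt optional upstroke interval target, ms.
#' @param label patient label.
#' @param cv_poly_degree degree for [cv_of_di()].
#' @return An object of class `clinical_dataset`.
#' @export
clinical_dataset <- function(morphology, apd_points, cv_cl_points,
                             di_cl_points, upstroke_dt = NA_real_,
                             label = "patient", cv_poly_degree = 2) {
  stopifnot(inherits(morphology, "mm_morphology"))
  apd_points <- tibble::as_tibble(apd_points)
  if (any(apd_points$DI <= 0) || any(apd_points$APD <= 0)) {
    abort("APD restitution points must have positive DI and APD")
  }
  structure(list(
    morphology = morphology,
    apd_points = apd_points,
    apd_logfit = fit_apd_log(apd_points),
    cv_cl_points = tibble::as_tibble(cv_cl_points),
    di_cl_points = tibble::as_tibble(di_cl_points),
    cv_di_points = cv_of_di(cv_cl_points, di_cl_points, cv_poly_degree),
    upstroke_dt = upstroke_dt,
    label = label
  ), class = "clinical_dataset")
}

#' @export
print.clinical_dataset <- function(x, ...) {
  cat(sprintf(
    "<clinical_dataset> '%s': %d APD points (max slope %.2f), %d CV points, morphology %d samples\n",
    x$label, nrow(x$apd_points), x$apd_logfit$max_slope,
    nrow(x$cv_di_points), nrow(x$morphology$grid)))
  invisible(x)
}

#' @export
tidy.clinical_dataset <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$apd_points, curve = "apd_restitution",
                  x = .data$DI, y = .data$APD, .keep = "none"),
    dplyr::mutate(x$cv_di_points, curve = "cv_restitution",
                  x = .data$DI, y = .data$CV, .keep = "none"),
    dplyr::mutate(x$morphology$grid[!x$morphology$grid$masked, ],
                  curve = "morphology", x = .data$t_norm, y = .data$v_norm,
                  .keep = "none")
  )
}

#' Read and write patient bundles
#'
#' A patient bundle is a directory holding `morphology.csv`
#' (`t_norm,v_norm`), `apd_restitution.csv` (`DI_ms,APD_ms`),
#' `cv_vs_cl.csv` (`CL_ms,CV_cm_s`), `di_vs_cl.csv` (`CL_ms,DI_ms`) and
#' `meta.json` — the same schema for simulated and clinical data.
#'
#' @param dir bundle directory.
#' @rdname patient_bundle
#' @return `read_patient_bundle()` returns a `clinical_dataset`;
#'   `write_patient_bundle()` returns `dir` invisibly.
#' @export
read_patient_bundle <- function(dir) {
  need <- c("morphology.csv", "apd_restitution.csv", "cv_vs_cl.csv",
            "di_vs_cl.csv", "meta.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    abort(paste0("patient bundle incomplete; missing: ",
                 paste(missing, collapse = ", ")))
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  mo <- utils::read.csv(file.path(dir, "morphology.csv"))
  if (!all(c("t_norm", "v_norm") %in% names(mo))) {
    abort("morphology.csv must have columns t_norm, v_norm")
  }
  cutoff <- meta$artifact_cutoff %||% 0
  morph <- structure(list(
    grid = tibble(t_norm = mo$t_norm, v_norm = mo$v_norm,
                  masked = mo$t_norm < cutoff),
    artifact_cutoff = cutoff, apd90 = meta$apd90 %||% NA_real_
  ), class = "mm_morphology")
  ap <- utils::read.csv(file.path(dir, "apd_restitution.csv"))
  cv <- utils::read.csv(file.path(dir, "cv_vs_cl.csv"))
  di <- utils::read.csv(file.path(dir, "di_vs_cl.csv"))
  clinical_dataset(
    morphology = morph,
    apd_points = tibble(DI = ap$DI_ms, APD = ap$APD_ms),
    cv_cl_points = tibble(CL = cv$CL_ms, CV = cv$CV_cm_s),
    di_cl_points = tibble(CL = di$CL_ms, DI = di$DI_ms),
    upstroke_dt = meta$upstroke_dt %||% NA_real_,
    label = meta$label %||% basename(dir)
  )
}

#' @param ds a `clinical_dataset`.
#' @rdname patient_bundle
#' @export
write_patient_bundle <- function(ds, dir) {
  stopifnot(inherits(ds, "clinical_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(
    data.frame(t_norm = ds$morphology$grid$t_norm,
               v_norm = ds$morphology$grid$v_norm),
    file.path(dir, "morphology.csv"), row.names = FALSE)
  utils::write.csv(data.frame(DI_ms = ds$apd_points$DI,
                              APD_ms = ds$apd_points$APD),
                   file.path(dir, "apd_restitution.csv"), row.names = FALSE)
  utils::write.csv(data.frame(CL_ms = ds$cv_cl_points$CL,
                              CV_cm_s = ds$cv_cl_points$CV),
                   file.path(dir, "cv_vs_cl.csv"), row.names = FALSE)
  utils::write.csv(data.frame(CL_ms = ds$di_cl_points$CL,
                              DI_ms = ds$di_cl_points$DI),
                   file.path(dir, "di_vs_cl.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    label = ds$label,
    artifact_cutoff = ds$morphology$artifact_cutoff,
    apd90 = ds$morphology$apd90,
    upstroke_dt = ds$upstroke_dt,
    apd_logfit = list(a = ds$apd_logfit$a, b = ds$apd_logfit$b)
  ), file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
  invisible(dir)
}
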