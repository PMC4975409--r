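# morphology template bank: three archetypes spanning the variety of
# clinical AP shapes; all are 1 at their peak and 0.1 at normalized time 1
# (the 90% repolarization point by construction)
mm_morphology_templates <- list(
  # smooth monotone repolarization without a dome
  decay = function(t) {
    v <- 1 - 0.9 * (3 * t^2 - 2 * t^3)
    v^1.3
  },
  # sustained plateau with a late, steep repolarization
  plateau = function(t) {
    0.1 + 0.9 / (1 + exp((t - 0.78) / 0.07))
  },
  # near-linear (triangular) repolarization
  triangular = function(t) {
    pmax(1 - 0.9 * t, 0.1)
  }
)

#' Specify a synthetic patient
#'
#' Describes a synthetic "patient" with the statistical structure of a
#' clinical pacing study: a cycle-length independent normalized AP
#' morphology with a masked initial artifact window, a logarithmic APD
#' restitution, and a CV restitution that is either flat or decreases
#' toward short diastolic intervals.
#'
#' In `parametric` mode the dataset is sampled from the specified curves;
#' in `model_truth` mode the full cable protocols are run on a known truth
#' parameter set, so fits can be scored against ground truth.
#'
#' @param mode `"parametric"` or `"model_truth"`.
#' @param apd_max maximum APD (at the baseline cycle length), ms; clinical
#'   values span roughly 220-380 ms.
#' @param max_slope target maximum APD restitution slope (clinically about
#'   0.57-1.15).
#' @param apd_logfit optional explicit `c(a, b)` for `APD = a + b ln(DI)`;
#'   overrides `apd_max`/`max_slope`.
#' @param cv_profile list with `type` (`"flat"` or `"decreasing"`),
#'   `level` (cm/s) and `droop` (fractional CV loss at the shortest DI).
#' @param morphology_template one of `"decay"`, `"plateau"`,
#'   `"triangular"`.
#' @param noise_sd list of per-channel noise standard deviations:
#'   `apd` (ms), `cv` (cm/s), `morph` (normalized voltage).
#' @param truth_params `mm_params` used in `model_truth` mode.
#' @param block_cl shortest cycle length of the sampling ladder, ms.
#' @param artifact_cutoff_ms masked initial window, ms.
#' @param seed RNG seed making the dataset reproducible.
#' @return A list of class `patient_spec`.
#' @export
patient_spec <- function(mode = c("parametric", "model_truth"),
                         apd_max = 300, max_slope = 0.8,
                         apd_logfit = NULL,
                         cv_profile = list(type = "flat", level = 60,
                                           droop = 0.25),
                         morphology_template = "plateau",
                         noise_sd = list(apd = 5, cv = 3, morph = 0.01),
                         truth_params = NULL, block_cl = 250,
                         artifact_cutoff_ms = 10, seed = 1) {
  mode <- match.arg(mode)
  if (apd_max < 150 || apd_max > 450) abort("apd_max must be in [150, 450] ms")
  if (max_slope < 0) abort("max_slope must be >= 0")
  if (any(unlist(noise_sd) < 0)) abort("noise sds must be >= 0")
  if (!morphology_template %in% names(mm_morphology_templates)) {
    abort(paste0("unknown morphology template; use one of: ",
                 paste(names(mm_morphology_templates), collapse = ", ")))
  }
  structure(list(mode = mode, apd_max = apd_max, max_slope = max_slope,
                 apd_logfit = apd_logfit, cv_profile = cv_profile,
                 morphology_template = morphology_template,
                 noise_sd = noise_sd, truth_params = truth_params,
                 block_cl = block_cl,
                 artifact_cutoff_ms = artifact_cutoff_ms, seed = seed),
            class = "patient_spec")
}

# clinical sampling ladder: 50-ms rungs to 300 ms then 10-ms decrements
spec_cl_ladder <- function(block_cl) {
  cls <- c(500, 450, 400, 350, 300)
  if (block_cl < 290) cls <- c(cls, seq(290, block_cl, by = -10))
  cls[cls >= block_cl]
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic patient dataset
#'
#' Produces a [clinical_dataset()] from a [patient_spec()]. Parametric
#' mode samples the specified APD and CV curves at the clinical cycle
#' length ladder (diastolic intervals solved self-consistently from
#' `DI = CL - APD(DI)`), adds Gaussian noise, and builds a plausible
#' normalized morphology from the template bank. Model-truth mode runs the
#' full S1-S2 cable protocol on the truth parameters and packages the
#' outputs. Deterministic given the `patient_spec()` seed.
#'
#' @param spec a [patient_spec()].
#' @param cfg a [cable_config()] (model-truth mode only).
#' @param label patient label.
#' @return A `clinical_dataset`; in model-truth mode the truth parameters
#'   and the raw protocol output are attached as attributes `truth_params`
#'   and `truth_protocol`.
#' @export
generate_patient <- function(spec, cfg = cable_config(), label = NULL) {
  stopifnot(inherits(spec, "patient_spec"))
  label <- label %||% paste0("synthetic-", spec$mode)
  with_local_seed(spec$seed, {
    if (spec$mode == "parametric") {
      generate_parametric_patient(spec, label)
    } else {
      generate_model_truth_patient(spec, cfg, label)
    }
  })
}

generate_parametric_patient <- function(spec, label) {
  cls <- spec_cl_ladder(spec$block_cl)
  di_max <- 500 - spec$apd_max
  a <- b <- NULL
  set_ab <- function(bv) {
    b <<- bv
    a <<- spec$apd_max - bv * log(di_max)
  }
  if (is.null(spec$apd_logfit)) {
    # the requested maximum slope is imposed at the 40 ms refractory
    # floor where the ladder blocks, so the realized slope at the
    # shortest sampled DI lands at ~max_slope
    set_ab(spec$max_slope * 40)
  } else {
    a <- spec$apd_logfit[1]
    b <- spec$apd_logfit[2]
  }
  # DI from the steady-pacing bookkeeping DI = CL - APD(a + b ln DI).
  # g(di) = di + a + b ln(di) - cl is strictly increasing, so the root is
  # unique; roots below the 40 ms refractory floor count as loss of 1:1
  # capture (where real ladders end)
  di_floor <- 40
  solve_di <- function(cl) {
    if (b == 0) {
      di <- cl - a
      return(if (is.finite(di) && di >= di_floor) di else NA_real_)
    }
    g <- function(di) di + a + b * log(di) - cl
    if (g(cl) <= 0) return(NA_real_)
    di <- stats::uniroot(g, c(1e-9, cl), tol = 1e-10)$root
    if (di >= di_floor) di else NA_real_
  }
  di <- vapply(cls, solve_di, numeric(1))
  # rungs without a feasible DI are where this patient blocks (capture
  # failure): the ladder stops there, mirroring the clinical protocol
  feasible <- !is.na(di)
  if (sum(feasible) < 3) {
    abort("infeasible spec: APD(a,b) does not admit positive DI over the ladder")
  }
  cls <- cls[feasible]
  di <- di[feasible]
  apd_true <- a + b * log(di)
  if (any(apd_true <= 0)) abort("infeasible spec: non-positive APD over the ladder")
  di_rng <- range(di)
  cv_fun <- function(d) {
    lvl <- spec$cv_profile$level
    if (identical(spec$cv_profile$type, "flat")) return(rep(lvl, length(d)))
    lvl * (1 - spec$cv_profile$droop *
             (di_rng[2] - d) / (di_rng[2] - di_rng[1]))
  }
  cv_true <- cv_fun(di)
  apd_pts <- tibble(DI = di, APD = apd_true + stats::rnorm(length(di), 0, spec$noise_sd$apd))
  cv_cl <- tibble(CL = cls, CV = cv_true + stats::rnorm(length(cls), 0, spec$noise_sd$cv))
  di_cl <- tibble(CL = cls, DI = di)
  g <- seq(0, 1, length.out = 200)
  tmpl <- mm_morphology_templates[[spec$morphology_template]]
  v <- tmpl(g) + stats::rnorm(200, 0, spec$noise_sd$morph)
  v <- pmin(pmax(v, 0), 1)
  v <- (v - min(v)) / (max(v) - min(v))
  cutoff <- spec$artifact_cutoff_ms / spec$apd_max
  morph <- structure(list(
    grid = tibble(t_norm = g, v_norm = v, masked = g < cutoff),
    artifact_cutoff = cutoff, apd90 = spec$apd_max
  ), class = "mm_morphology")
  ds <- clinical_dataset(morph, apd_pts, cv_cl, di_cl, label = label)
  attr(ds, "generator") <- list(a = a, b = b, cv_fun = cv_fun,
                                cls = cls, di = di)
  ds
}

generate_model_truth_patient <- function(spec, cfg, label) {
  truth <- validate_parameters(spec$truth_params %||% default_parameters())
  prot <- s1s2_restitution(truth, cfg,
                           artifact_cutoff_ms = spec$artifact_cutoff_ms)
  pts <- dplyr::filter(prot$points, .data$captured, !is.na(.data$APD),
                       .data$DI > 0)
  ns <- spec$noise_sd
  apd_pts <- tibble(DI = pts$DI,
                    APD = pts$APD + stats::rnorm(nrow(pts), 0, ns$apd))
  cv_ok <- !is.na(pts$CV)
  cv_cl <- tibble(CL = pts$S2[cv_ok],
                  CV = pts$CV[cv_ok] + stats::rnorm(sum(cv_ok), 0, ns$cv))
  di_cl <- tibble(CL = pts$S2, DI = pts$DI)
  morph <- average_morphology(prot$shapes)
  if (ns$morph > 0) {
    morph$grid$v_norm <- pmin(pmax(
      morph$grid$v_norm + stats::rnorm(nrow(morph$grid), 0, ns$morph), 0), 1)
  }
  ds <- clinical_dataset(morph, apd_pts, cv_cl, di_cl,
                         upstroke_dt = prot$upstroke, label = label)
  attr(ds, "truth_params") <- truth
  attr(ds, "truth_protocol") <- prot
  ds
}
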