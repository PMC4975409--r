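#' Annealing fit configuration
#'
#' Settings for the simulated-annealing parameter fit. The schedule
#' follows the clinical fitting procedure: 50 iterations, with the
#' temperature reduced by 10% after each. The temperature sets the
#' proposal scale (and the Metropolis acceptance of uphill moves), so the
#' search contracts as it cools.
#'
#' @param n_iterations number of temperature stages.
#' @param cooling_factor multiplicative temperature decay per stage.
#' @param moves_per_iteration candidate moves evaluated per stage.
#' @param initial_temperature `"auto"` (calibrated so the median uphill
#'   move of a 20-move pilot is accepted with probability `pilot_accept`)
#'   or a number.
#' @param pilot_accept auto-calibration target acceptance of the median
#'   uphill pilot move.
#' @param sigma proposal scale: log-sd of multiplicative moves for scale
#'   parameters (time constants, steepnesses) and fraction of the valid
#'   interval for additive moves (thresholds, midpoints), both damped by
#'   `sqrt(T/T0)` (see [propose_parameters()]).
#' @param bounds_mult multiplicative bounds `c(lo, hi)` relative to the
#'   initial value, for scale parameters.
#' @param bounds_add_frac additive half-range as a fraction of the valid
#'   interval, for thresholds/midpoints.
#' @param weights named weights `morph`, `apd`, `cv`, `upstroke` of the
#'   error components. The upstroke term defaults to 0 because clinical
#'   upstrokes are unavailable.
#' @param fit_mask names of parameters held fixed (see
#'   [default_fit_mask()]).
#' @param uncovered_penalty percent error charged to a target point whose
#'   diastolic interval is not covered by the simulated curve.
#' @param s1_cl,n_s1,s2_fit S1-S2 protocol used to evaluate candidates:
#'   S1 cycle length (ms), conditioning beats, and the S2 coupling
#'   intervals simulated per candidate. The default (`NULL`) takes up to
#'   `n_s2_fit` values spanning the target's own cycle-length ladder, so
#'   the simulated curve covers the target's DI range.
#' @param n_s2_fit number of S2 values used when `s2_fit` is derived from
#'   the target.
#' @param largest_s2_only compare only the largest-S2 morphology instead
#'   of all captured shapes.
#' @param di_extrapolation DI margin (ms) passed to [error_components()]
#'   as `extrapolation`.
#' @param move_subset number of free parameters perturbed per move
#'   (`NULL`: all of them; a vector: a size drawn uniformly from it each
#'   move). Small subsets behave like randomized coordinate descent and
#'   handle strongly anisotropic error surfaces better; mixing in an
#'   occasional multi-parameter move lets correlated directions relax.
#' @param min_step_frac lower bound on the temperature damping of the
#'   proposal scale: the step never falls below
#'   `sigma * min_step_frac`. Zero restores proposals that vanish with
#'   the temperature.
#' @param seed RNG seed for the whole fit.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_iterations = 50, cooling_factor = 0.9,
                       moves_per_iteration = 20,
                       initial_temperature = "auto", sigma = 0.3,
                       pilot_accept = 0.15,
                       bounds_mult = c(0.1, 10), bounds_add_frac = 0.5,
                       weights = c(morph = 1, apd = 1, cv = 1, upstroke = 0),
                       fit_mask = default_fit_mask(),
                       uncovered_penalty = 25,
                       s1_cl = 500, n_s1 = 8,
                       s2_fit = NULL, n_s2_fit = 6, di_extrapolation = 10,
                       largest_s2_only = FALSE, move_subset = c(1, 1, 1, 3),
                       min_step_frac = 0.07, seed = NULL) {
  if (cooling_factor <= 0 || cooling_factor >= 1) {
    abort("cooling_factor must be in (0, 1)")
  }
  w <- c(morph = 0, apd = 0, cv = 0, upstroke = 0)
  w[names(weights)] <- weights
  if (any(w < 0) || all(w == 0)) abort("weights must be >= 0 and not all zero")
  structure(list(
    n_iterations = n_iterations, cooling_factor = cooling_factor,
    moves_per_iteration = moves_per_iteration,
    initial_temperature = initial_temperature, sigma = sigma,
    pilot_accept = pilot_accept,
    bounds_mult = bounds_mult, bounds_add_frac = bounds_add_frac,
    weights = w, fit_mask = fit_mask,
    uncovered_penalty = uncovered_penalty, s1_cl = s1_cl, n_s1 = n_s1,
    s2_fit = s2_fit, n_s2_fit = n_s2_fit,
    di_extrapolation = di_extrapolation,
    largest_s2_only = largest_s2_only, move_subset = move_subset,
    min_step_frac = min_step_frac, seed = seed
  ), class = "fit_config")
}

#' Percent-error breakdown of a simulated curve set against a target
#'
#' The component errors follow the clinical quantification: the APD error
#' is the mean over the target restitution points of
#' `100 * |APD_sim - APD_tgt| / APD_tgt`, with the simulated APD linearly
#' interpolated in DI; the CV error is analogous; the morphology error is
#' the mean absolute difference of the normalized voltages (already in
#' `[0, 1]`, so reported directly in percent of full amplitude) over the
#' unmasked 200-point grid, averaged over the compared S2 shapes; the
#' upstroke error is the relative error of the 10-100% upstroke interval.
#' The total is the weighted mean of the active components. Target points
#' within `extrapolation` ms of the simulated DI range are compared
#' against an edge-linear extrapolation of the simulated curve (the
#' simulated range is shifted relative to the target's by the
#' candidate's APD(S1) mismatch, so the extreme target points almost
#' always sit a few ms outside it); points farther out are charged
#' `uncovered_penalty`.
#'
#' @param sim an `mm_s1s2` result (or a list with elements `points`,
#'   `shapes`, `upstroke`).
#' @param target a [clinical_dataset()].
#' @param weights named weights (`morph`, `apd`, `cv`, `upstroke`).
#' @param uncovered_penalty percent error for uncovered target points.
#' @param largest_s2_only compare only the largest-S2 shape.
#' @param extrapolation DI margin (ms) over which the simulated curves
#'   are extrapolated edge-linearly before the penalty applies.
#' @return An object of class `error_breakdown`: list with `e_morph`,
#'   `e_apd`, `e_cv`, `e_upstroke`, `total` (percent) and the per-point
#'   `residuals` tibble.
#' @export
error_components <- function(sim, target,
                             weights = c(morph = 1, apd = 1, cv = 1,
                                         upstroke = 0),
                             uncovered_penalty = 25,
                             largest_s2_only = FALSE,
                             extrapolation = 10) {
  w <- c(morph = 0, apd = 0, cv = 0, upstroke = 0)
  w[names(weights)] <- weights
  pts <- dplyr::filter(sim$points, .data$captured)
  res <- list()

  curve_err <- function(tgt_x, tgt_y, sim_x, sim_y, what) {
    ok <- !is.na(sim_x) & !is.na(sim_y)
    sim_x <- sim_x[ok]; sim_y <- sim_y[ok]
    if (length(sim_x) < 2) {
      return(tibble(curve = what, x = tgt_x, err = uncovered_penalty))
    }
    o <- order(sim_x)
    sx <- sim_x[o]
    sy <- sim_y[o]
    n <- length(sx)
    yhat <- stats::approx(sx, sy, xout = tgt_x, rule = 1)$y
    # edge-linear extrapolation over a small DI margin
    lo <- is.na(yhat) & tgt_x < sx[1] & tgt_x >= sx[1] - extrapolation
    hi <- is.na(yhat) & tgt_x > sx[n] & tgt_x <= sx[n] + extrapolation
    if (any(lo)) {
      sl <- (sy[2] - sy[1]) / (sx[2] - sx[1])
      yhat[lo] <- sy[1] + sl * (tgt_x[lo] - sx[1])
    }
    if (any(hi)) {
      sl <- (sy[n] - sy[n - 1]) / (sx[n] - sx[n - 1])
      yhat[hi] <- sy[n] + sl * (tgt_x[hi] - sx[n])
    }
    err <- ifelse(is.na(yhat), uncovered_penalty,
                  100 * abs(yhat - tgt_y) / tgt_y)
    tibble(curve = what, x = tgt_x, err = err)
  }

  e_apd <- e_cv <- e_morph <- e_upstroke <- NA_real_
  if (w[["apd"]] > 0) {
    r <- curve_err(target$apd_points$DI, target$apd_points$APD,
                   pts$DI, pts$APD, "apd")
    res$apd <- r
    e_apd <- mean(r$err)
  }
  if (w[["cv"]] > 0) {
    r <- curve_err(target$cv_di_points$DI, target$cv_di_points$CV,
                   pts$DI, pts$CV, "cv")
    res$cv <- r
    e_cv <- mean(r$err)
  }
  if (w[["morph"]] > 0) {
    tgt <- resample_morphology(target$morphology)
    mask <- tgt$masked | tgt$t_norm < (target$morphology$artifact_cutoff %||% 0)
    shapes <- sim$shapes
    if (!length(shapes)) {
      e_morph <- uncovered_penalty
    } else {
      if (largest_s2_only) shapes <- shapes[1]
      per_shape <- vapply(shapes, function(s) {
        sg <- resample_morphology(s)
        keep <- !mask & !sg$masked
        100 * mean(abs(sg$v_norm[keep] - tgt$v_norm[keep]))
      }, numeric(1))
      e_morph <- mean(per_shape)
      res$morph <- tibble(curve = "morph", x = as.numeric(names(shapes)),
                          err = per_shape)
    }
  }
  if (w[["upstroke"]] > 0) {
    if (is.na(target$upstroke_dt) || is.na(sim$upstroke)) {
      e_upstroke <- uncovered_penalty
    } else {
      e_upstroke <- 100 * abs(sim$upstroke - target$upstroke_dt) /
        target$upstroke_dt
    }
  }
  comp <- c(morph = e_morph, apd = e_apd, cv = e_cv, upstroke = e_upstroke)
  act <- w > 0
  total <- sum(w[act] * comp[act]) / sum(w[act])
  structure(list(e_morph = e_morph, e_apd = e_apd, e_cv = e_cv,
                 e_upstroke = e_upstroke, total = total,
                 residuals = dplyr::bind_rows(res), weights = w),
            class = "error_breakdown")
}

#' @export
print.error_breakdown <- function(x, ...) {
  cat(sprintf(
    "<error_breakdown> total %.2f%% (morph %.2f%%, apd %.2f%%, cv %.2f%%, upstroke %s)\n",
    x$total, x$e_morph, x$e_apd, x$e_cv,
    ifelse(is.na(x$e_upstroke), "-", sprintf("%.2f%%", x$e_upstroke))))
  invisible(x)
}

# per-parameter proposal metadata: type and bounds around the initial point
proposal_plan <- function(init, cfg) {
  nm <- names(init)
  mult <- nm %in% mm_par_multiplicative
  lo <- hi <- numeric(length(init))
  lo[mult] <- init[mult] * cfg$bounds_mult[1]
  hi[mult] <- init[mult] * cfg$bounds_mult[2]
  # additive parameters: thresholds live in [0, 1); midpoints/levels in
  # [0, 1.5]. Thresholds are floored just above u_o: a threshold at or
  # below the resting potential degenerates the gate steady states and
  # leaves the tissue inexcitable.
  thresholds <- nm %in% c("theta_v", "theta_w", "theta_vminus", "theta_o")
  valid_hi <- ifelse(thresholds, 0.95, 1.5)
  valid_lo <- ifelse(thresholds, init[["u_o"]] + 1e-3, 0)
  add <- !mult
  lo[add] <- pmax(init[add] - cfg$bounds_add_frac * valid_hi[add],
                  valid_lo[add])
  hi[add] <- pmin(init[add] + cfg$bounds_add_frac * valid_hi[add],
                  valid_hi[add])
  free <- !(nm %in% cfg$fit_mask)
  list(mult = mult, lo = lo, hi = hi, free = free,
       add_range = valid_hi)
}

#' Propose a perturbed parameter set
#'
#' Each unmasked parameter is perturbed — multiplicatively by
#' `exp(sigma * sqrt(T/T0) * N(0,1))` for scale parameters (time
#' constants and steepnesses), additively by
#' `sigma * sqrt(T/T0) * range * N(0,1)` for thresholds and midpoints —
#' then clipped to its bounds. Masked parameters are untouched. As
#' `T -> 0` the proposal converges to the input.
#'
#' The proposal amplitude contracts with the square root of the
#' temperature rather than the temperature itself: because the Metropolis
#' selectivity is governed by the ratio of the proposal-induced error
#' change to `T`, a linearly damped proposal keeps that ratio constant
#' over the whole schedule and the chain never becomes selective; the
#' square-root damping makes selectivity sharpen as the system cools
#' while the step size still vanishes.
#'
#' @param params current `mm_params`.
#' @param temperature current temperature `T` (> 0).
#' @param t0 reference (initial) temperature.
#' @param cfg a [fit_config()].
#' @param plan internal proposal plan; recomputed from `params` if `NULL`.
#' @return A proposed `mm_params`.
#' @export
propose_parameters <- function(params, temperature, t0, cfg = fit_config(),
                               plan = NULL) {
  stopifnot(temperature > 0, t0 > 0)
  p <- as.numeric(params)
  names(p) <- names(params)
  plan <- plan %||% proposal_plan(p, cfg)
  damp <- max(sqrt(min(temperature / t0, 1)), cfg$min_step_frac %||% 0)
  scale <- cfg$sigma * damp
  n_free <- sum(plan$free)
  for (attempt in 1:20) {
    q <- p
    z <- stats::rnorm(length(p))
    k <- cfg$move_subset
    if (length(k) > 1) k <- sample(k, 1)   # mixture over subset sizes
    if (!is.null(k) && k < n_free) {
      # perturb only a random subset of the free parameters this move
      keep <- sample(which(plan$free), k)
      z[setdiff(seq_along(z), keep)] <- 0
    }
    i <- plan$free & plan$mult
    q[i] <- p[i] * exp(scale * z[i])
    i <- plan$free & !plan$mult
    q[i] <- p[i] + scale * plan$add_range[i] * z[i]
    q <- pmin(pmax(q, plan$lo), plan$hi)
    q[!plan$free] <- p[!plan$free]   # masked parameters are never touched
    ok <- tryCatch({ validate_parameters(q); TRUE },
                   error = function(e) FALSE)
    if (ok) return(validate_parameters(q))
  }
  validate_parameters(p)
}

#' Randomly perturb a parameter set
#'
#' Multiplies every free (unmasked) parameter by an independent
#' `uniform(1 - frac, 1 + frac)` factor — the standard way to displace a
#' fitting initial condition from a reference set. Because [anneal()]
#' requires the pacing protocols to be runnable at the initial point,
#' draws are repeated (up to `max_tries`) until the S1 train captures 1:1
#' on the given cable; pass `cable = NULL` to skip that check.
#'
#' @param params an `mm_params` to perturb.
#' @param frac perturbation half-width (0.5 = +/-50%).
#' @param mask parameter names left untouched.
#' @param cable a [cable_config()] used for the runnability check, or
#'   `NULL`.
#' @param s1_cl,n_s1 S1 train used for the check.
#' @param max_tries redraw budget.
#' @return A perturbed `mm_params`.
#' @export
perturb_parameters <- function(params, frac = 0.5,
                               mask = default_fit_mask(), cable = NULL,
                               s1_cl = 500, n_s1 = 8, max_tries = 20) {
  params <- validate_parameters(params)
  free <- setdiff(names(params), mask)
  for (k in seq_len(max_tries)) {
    q <- unclass(params)
    q[free] <- q[free] * stats::runif(length(free), 1 - frac, 1 + frac)
    cand <- tryCatch(validate_parameters(q), error = function(e) NULL)
    if (is.null(cand)) next
    if (is.null(cable)) return(cand)
    ok <- tryCatch({
      amp <- calibrate_stimulus(cand, cable)
      stim <- (seq_len(n_s1) - 1) * s1_cl
      raw <- cable_run_raw(cand, cable, stim, stim[n_s1] + 100, amp = amp)
      isTRUE(raw$ok) &&
        length(raw$act[[cable$measure_cell]]) >= n_s1 - 1
    }, error = function(e) FALSE)
    if (ok) return(cand)
  }
  abort("no runnable perturbation found within max_tries draws")
}

#' Simulated annealing on an arbitrary objective
#'
#' The optimization core used by [anneal()]: Metropolis acceptance
#' `exp(-dE/T)` for uphill moves, geometric cooling, proposals via
#' `propose_fn(current, T, T0)`. Exposed separately so the optimizer can
#' be exercised on cheap analytic objectives.
#'
#' @param objective function mapping a candidate to a scalar error
#'   (may return `Inf`).
#' @param init initial candidate.
#' @param propose_fn function `(candidate, T, T0) -> candidate`.
#' @param n_iterations,moves_per_iteration,cooling_factor schedule.
#' @param initial_temperature `"auto"` or a number. Auto-calibration runs
#'   a 20-move pilot from `init` and sets `T0` so the median uphill step
#'   is accepted with probability `pilot_accept`.
#' @param pilot_accept target acceptance probability of the median uphill
#'   pilot move under auto-calibration.
#' @param greedy if `TRUE`, uphill moves are always rejected
#'   (hill-climbing limit).
#' @param on_iteration optional callback invoked with the one-row trace
#'   tibble after each iteration (used for live logging).
#' @param pilot_filter predicate on candidate errors; pilot moves whose
#'   error fails it (e.g. protocol-failure penalties) are excluded from
#'   the temperature calibration so `T0` reflects the local error scale.
#' @return List with `best`, `best_error`, `trace` (tibble per iteration:
#'   `iteration`, `temperature`, `E_current`, `E_best`, `acceptance`),
#'   `accepted` move count and `n_evaluations`.
#' @export
sa_optimize <- function(objective, init, propose_fn,
                        n_iterations = 50, moves_per_iteration = 20,
                        cooling_factor = 0.9,
                        initial_temperature = "auto", greedy = FALSE,
                        on_iteration = NULL, pilot_filter = is.finite,
                        pilot_accept = 0.3) {
  e_cur <- objective(init)
  if (!is.finite(e_cur)) abort("objective is not finite at the initial point")
  cur <- best <- init
  e_best <- e_cur
  n_eval <- 1L
  if (identical(initial_temperature, "auto")) {
    de <- numeric(0)
    for (k in 1:20) {
      cand <- propose_fn(cur, 1, 1)
      e <- objective(cand)
      n_eval <- n_eval + 1L
      if (is.finite(e) && pilot_filter(e) && e > e_cur) de <- c(de, e - e_cur)
    }
    t0 <- if (length(de)) -stats::median(de) / log(pilot_accept) else max(e_cur, 1)
  } else {
    t0 <- initial_temperature
  }
  temp <- t0
  accepted <- 0L
  tr <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    acc_it <- 0L
    for (m in seq_len(moves_per_iteration)) {
      cand <- propose_fn(cur, temp, t0)
      e <- objective(cand)
      n_eval <- n_eval + 1L
      take <- if (!is.finite(e)) {
        FALSE
      } else if (e <= e_cur) {
        TRUE
      } else if (greedy) {
        FALSE
      } else {
        stats::runif(1) < exp(-(e - e_cur) / temp)
      }
      if (take) {
        cur <- cand
        e_cur <- e
        acc_it <- acc_it + 1L
        if (e < e_best) { best <- cand; e_best <- e }
      }
    }
    accepted <- accepted + acc_it
    tr[[it]] <- tibble(iteration = it, temperature = temp,
                       E_current = e_cur, E_best = e_best,
                       acceptance = acc_it / moves_per_iteration)
    if (!is.null(on_iteration)) on_iteration(tr[[it]])
    temp <- temp * cooling_factor
  }
  list(best = best, best_error = e_best, trace = dplyr::bind_rows(tr),
       accepted = accepted, t0 = t0, n_evaluations = n_eval)
}

#' Fit model parameters to a clinical dataset by simulated annealing
#'
#' Minimizes the combined percent error of the simulated AP morphology,
#' APD restitution and CV restitution (optionally the upstroke interval)
#' against a target [clinical_dataset()]. Candidate parameter sets are
#' evaluated by running the S1-S2 cable protocol configured in `cfg`;
#' simulation blow-ups during a move are assigned infinite error and
#' rejected. The stimulus amplitude is calibrated once at the initial
#' parameters and held fixed so all candidates face the same protocol.
#'
#' @param target a [clinical_dataset()].
#' @param init initial `mm_params` (defaults to the bundled published set).
#' @param cfg a [fit_config()].
#' @param cable a [cable_config()].
#' @param verbose print one line per iteration?
#' @return An object of class `mm_fit`: list with `params` (best-ever),
#'   `errors` (error_breakdown at the best point), `trace`, `accepted`,
#'   `t0`, `seed` and config echoes.
#' @export
anneal <- function(target, init = default_parameters(), cfg = fit_config(),
                   cable = cable_config(), verbose = FALSE) {
  stopifnot(inherits(target, "clinical_dataset"))
  init <- validate_parameters(init)
  if (!is.null(cfg$seed)) {
    return(with_local_seed(cfg$seed,
                           anneal(target, init, modifyList2(cfg, seed = NULL),
                                  cable, verbose)))
  }
  if (is.null(cable$stim_amplitude)) {
    cable$stim_amplitude <- calibrate_stimulus(init, cable)
  }
  plan <- proposal_plan(unclass(init), cfg)
  s2_fit <- cfg$s2_fit %||% {
    cls <- sort(unique(target$di_cl_points$CL), decreasing = TRUE)
    cls <- cls[cls <= cfg$s1_cl]
    if (length(cls) > cfg$n_s2_fit) {
      cls[unique(round(seq(1, length(cls), length.out = cfg$n_s2_fit)))]
    } else {
      cls
    }
  }
  simulate <- function(p) {
    s1s2_restitution(p, cable, s1_cl = cfg$s1_cl, n_s1 = cfg$n_s1,
                     s2_list = s2_fit, keep_shapes = TRUE)
  }
  # blow-ups are rejected outright (infinite error); full protocol
  # failures (loss of S1 capture) score twice the uncovered penalty — a
  # finite, escapable error kept above any partially-covered fit so the
  # chain prefers staying on the excitable basin
  objective <- function(p) {
    tryCatch(
      error_components(simulate(p), target, cfg$weights,
                       cfg$uncovered_penalty, cfg$largest_s2_only,
                       cfg$di_extrapolation)$total,
      atriafit_blowup = function(e) Inf,
      error = function(e) 2 * cfg$uncovered_penalty
    )
  }
  prop <- function(cur, temp, t0) {
    propose_parameters(cur, temp, t0, cfg, plan)
  }
  logger <- if (verbose) {
    function(row) {
      message(sprintf("iter %2d  T=%8.3f  E_best=%7.3f%%  E_cur=%7.3f%%  acc=%.2f",
                      row$iteration, row$temperature, row$E_best,
                      row$E_current, row$acceptance))
    }
  } else {
    NULL
  }
  res <- sa_optimize(objective, init, prop,
                     n_iterations = cfg$n_iterations,
                     moves_per_iteration = cfg$moves_per_iteration,
                     cooling_factor = cfg$cooling_factor,
                     initial_temperature = cfg$initial_temperature,
                     on_iteration = logger,
                     pilot_filter = function(e) e < 2 * cfg$uncovered_penalty,
                     pilot_accept = cfg$pilot_accept)
  errors <- error_components(simulate(res$best), target, cfg$weights,
                             cfg$uncovered_penalty, cfg$largest_s2_only,
                             cfg$di_extrapolation)
  structure(list(params = res$best, errors = errors, trace = res$trace,
                 accepted = res$accepted, t0 = res$t0,
                 n_evaluations = res$n_evaluations, seed = cfg$seed,
                 config = cfg, cable = cable, init = init,
                 target_label = target$label),
            class = "mm_fit")
}

modifyList2 <- function(x, ...) {
  y <- utils::modifyList(unclass(x), list(...), keep.null = TRUE)
  class(y) <- class(x)
  y
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> target '%s': total error %.2f%% after %d iterations (%d evaluations)\n",
              x$target_label, x$errors$total, nrow(x$trace),
              x$n_evaluations))
  print(x$errors)
  invisible(x)
}

#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(term = names(x$params),
         estimate = as.numeric(x$params),
         init = as.numeric(x$init),
         fitted = !(names(x$params) %in% x$config$fit_mask))
}

#' @export
glance.mm_fit <- function(x, ...) {
  tibble(total_error = x$errors$total, e_morph = x$errors$e_morph,
         e_apd = x$errors$e_apd, e_cv = x$errors$e_cv,
         e_upstroke = x$errors$e_upstroke,
         iterations = nrow(x$trace), accepted = x$accepted,
         t0 = x$t0, n_evaluations = x$n_evaluations)
}

#' Save a fit result as JSON
#'
#' Writes the best parameters, error breakdown and annealing trace to a
#' single JSON file.
#'
#' @param fit an `mm_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "mm_fit"))
  jsonlite::write_json(list(
    params = as.list(unclass(fit$params)),
    errors = list(total = fit$errors$total, morph = fit$errors$e_morph,
                  apd = fit$errors$e_apd, cv = fit$errors$e_cv,
                  upstroke = fit$errors$e_upstroke),
    trace = fit$trace,
    accepted = fit$accepted,
    t0 = fit$t0,
    seed = fit$seed,
    target = fit$target_label
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
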