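#' Cable simulation configuration
#'
#' Settings for the homogeneous 1D monodomain cable: geometry, integration
#' steps, diffusion coefficient, stimulus site/shape and recording layout.
#' The default geometry is the 100-element cable with `dx = 0.02` cm and
#' `dt = 0.01` ms. The explicit scheme requires `D*dt/dx^2 < 0.5`.
#'
#' @param n_cells number of cells (>= 10).
#' @param dx spatial step, cm.
#' @param dt time step, ms.
#' @param D diffusion coefficient, cm^2/ms. Fixed during fitting by
#'   default; the conduction-velocity scale is carried by `tau_fi`.
#' @param stim_cells indices (1-based) of the stimulated cells.
#' @param stim_amplitude stimulus current in 1/ms, or `NULL` to
#'   auto-calibrate with [calibrate_stimulus()] at run time.
#' @param stim_duration stimulus pulse length, ms.
#' @param record_sites cell indices whose full-resolution traces are kept.
#' @param record_dt trace sampling cadence, ms.
#' @param cv_cells the two cells between which conduction velocity is
#'   measured (defaults to the central 1.0 cm, away from boundaries and
#'   stimulus foot).
#' @param measure_cell distal cell used for APD/morphology measurements.
#' @param act_threshold activation detection threshold (dimensionless
#'   voltage, upward crossing with sub-`dt` interpolation).
#' @param act_refractory detection refractory guard, ms.
#' @return A list of class `cable_config`.
#' @export
cable_config <- function(n_cells = 100, dx = 0.02, dt = 0.01, D = 0.001,
                         stim_cells = 1:3, stim_amplitude = NULL,
                         stim_duration = 2, record_sites = NULL,
                         record_dt = 1, cv_cells = c(25, 75),
                         measure_cell = 75, act_threshold = 0.2,
                         act_refractory = 50) {
  if (n_cells < 10) abort("n_cells must be >= 10")
  if (dx <= 0 || dt <= 0 || D <= 0) abort("dx, dt and D must be > 0")
  if (D * dt / dx^2 >= 0.5) {
    abort(sprintf("unstable configuration: D*dt/dx^2 = %.3f >= 0.5",
                  D * dt / dx^2))
  }
  if (any(stim_cells < 1 | stim_cells > n_cells)) {
    abort("stim_cells out of range")
  }
  record_sites <- sort(unique(c(record_sites, cv_cells, measure_cell)))
  structure(list(
    n_cells = n_cells, dx = dx, dt = dt, D = D, stim_cells = stim_cells,
    stim_amplitude = stim_amplitude, stim_duration = stim_duration,
    record_sites = record_sites, record_dt = record_dt, cv_cells = cv_cells,
    measure_cell = measure_cell, act_threshold = act_threshold,
    act_refractory = act_refractory
  ), class = "cable_config")
}

#' Discrete Laplacian with no-flux boundaries
#'
#' Second-difference Laplacian on a uniform 1D grid using mirror ghost
#' cells (the ghost value equals the first interior neighbour), so the net
#' discrete flux over the cable is exactly zero.
#'
#' @param u_values voltage vector (length >= 3).
#' @param dx grid spacing, cm.
#' @return Numeric vector of the same length, units 1/cm^2.
#' @export
laplacian_noflux <- function(u_values, dx) {
  n <- length(u_values)
  if (n < 3) abort("laplacian_noflux needs at least 3 values")
  left <- c(u_values[2], u_values[-n])
  right <- c(u_values[-1], u_values[n - 1])
  (left - 2 * u_values + right) / dx^2
}

#' Calibrate the stimulus amplitude
#'
#' Finds by bisection the smallest stimulus current (2-ms pulse by default,
#' factor-of-2 bracketing, 1% relative tolerance) that elicits a propagated
#' action potential at the distal measurement cell, and returns that
#' threshold times a safety factor of 2.
#'
#' @param params an [model_parameters()] object.
#' @param cfg a [cable_config()].
#' @param safety multiplicative safety factor on the threshold amplitude.
#' @return Stimulus amplitude in 1/ms.
#' @export
calibrate_stimulus <- function(params, cfg = cable_config(), safety = 2) {
  params <- validate_parameters(params)
  propagates <- function(amp) {
    rec <- cable_run_raw(params, cfg, amp = amp, stim_times = 10,
                         t_end = 10 + cfg$n_cells * cfg$dx / 0.005 + 50)
    length(rec$act[[cfg$measure_cell]]) > 0
  }
  amp <- 0.5
  n_try <- 0
  while (!propagates(amp)) {
    amp <- amp * 2
    n_try <- n_try + 1
    if (n_try > 8) abort("stimulus calibration failed: no capture up to amplitude 128/ms")
  }
  lo <- amp / 2
  hi <- amp
  if (lo > 0 && propagates(lo)) {
    # initial guess already supra-threshold: bracket downward
    while (propagates(lo) && lo > 1e-3) {
      hi <- lo
      lo <- lo / 2
    }
  }
  while ((hi - lo) / hi > 0.01) {
    mid <- (hi + lo) / 2
    if (propagates(mid)) hi <- mid else lo <- mid
  }
  hi * safety
}

# low-level cable call used by protocols: works on plain matrices/lists
cable_run_raw <- function(params, cfg, stim_times, t_end, t0 = 0,
                          state0 = NULL, amp = NULL, record_dt = NULL) {
  if (is.null(state0)) {
    rs <- as.numeric(resting_state(params))
    state0 <- matrix(rep(rs, each = cfg$n_cells), nrow = cfg$n_cells)
  }
  amp <- amp %||% cfg$stim_amplitude %||% calibrate_stimulus(params, cfg)
  record_dt <- record_dt %||% cfg$record_dt
  out <- mm_cable_run(
    as.numeric(params), state0, t0, t_end, cfg$dx, cfg$dt, cfg$D,
    as.numeric(sort(stim_times)), cfg$stim_duration, amp,
    as.integer(cfg$stim_cells - 1L), as.integer(cfg$record_sites - 1L),
    max(1L, as.integer(round(record_dt / cfg$dt))),
    cfg$act_threshold, cfg$act_refractory
  )
  out$amp <- amp
  out
}

#' Run a paced 1D cable simulation
#'
#' Integrates the monodomain equation `du/dt = D d2u/dx2 - J_ion + I_stim`
#' on a homogeneous cable with no-flux boundaries using explicit Euler.
#' Each entry of `stimulus_times` injects the stimulus current into the
#' configured stimulus cells for the configured duration. Activation times
#' (upward threshold crossings, linearly interpolated below the time step)
#' are recorded at every cell.
#'
#' @param params an [model_parameters()] object.
#' @param cfg a [cable_config()].
#' @param stimulus_times increasing stimulus onset times, ms.
#' @param t_end end of the simulation, ms.
#' @return An object of class `mm_recording`: list with `trace` (tibble
#'   `time`, `site`, `u` for the recorded sites), `activations` (tibble
#'   `site`, `time`), `state` (final cable state matrix), `stim_amplitude`
#'   and `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- cable_config(stim_amplitude = 0.5)
#' rec <- run_cable(model_parameters(), cfg, stimulus_times = 10, t_end = 500)
#' }
run_cable <- function(params, cfg = cable_config(), stimulus_times,
                      t_end) {
  params <- validate_parameters(params)
  if (is.unsorted(stimulus_times, strictly = TRUE) && length(stimulus_times) > 1) {
    abort("stimulus_times must be strictly increasing")
  }
  out <- cable_run_raw(params, cfg, stimulus_times, t_end)
  if (!isTRUE(out$ok)) {
    abort(sprintf("cable integration unstable at t = %.3f ms",
                  out$t_blowup %||% NA_real_),
          class = "atriafit_blowup")
  }
  new_mm_recording(out, cfg)
}

new_mm_recording <- function(out, cfg) {
  U <- out$U
  trace <- tibble(
    time = rep(out$time, times = length(cfg$record_sites)),
    site = rep(cfg$record_sites, each = length(out$time)),
    u = as.numeric(U)
  )
  act <- tibble(
    site = rep(seq_along(out$act), lengths(out$act)),
    time = unlist(out$act) %||% numeric(0)
  )
  structure(list(trace = trace, activations = act, state = out$state,
                 stim_amplitude = out$amp, config = cfg),
            class = "mm_recording")
}

#' @export
print.mm_recording <- function(x, ...) {
  cat(sprintf(
    "<mm_recording> %d-cell cable, %d recorded sites, %d activations, t in [%g, %g] ms\n",
    x$config$n_cells, length(x$config$record_sites),
    nrow(x$activations), min(x$trace$time), max(x$trace$time)))
  invisible(x)
}

# extract the trace of one site as a tibble(time, u)
site_trace <- function(rec_out, cfg, site) {
  j <- match(site, cfg$record_sites)
  if (is.na(j)) abort(sprintf("site %d was not recorded", site))
  tibble(time = rec_out$time, u = rec_out$U[, j])
}

#' Write a recording to CSV
#'
#' Writes the trace and activation tables of an `mm_recording` as two CSV
#' files (`<stem>_trace.csv`, `<stem>_activations.csv`) plus a JSON config
#' echo (`<stem>_config.json`).
#'
#' @param rec an `mm_recording`.
#' @param stem output path stem.
#' @return `stem`, invisibly.
#' @export
write_recording_csv <- function(rec, stem) {
  stopifnot(inherits(rec, "mm_recording"))
  utils::write.csv(rec$trace, paste0(stem, "_trace.csv"), row.names = FALSE)
  utils::write.csv(rec$activations, paste0(stem, "_activations.csv"),
                   row.names = FALSE)
  cfg <- rec$config
  jsonlite::write_json(cfg[setdiff(names(cfg), NULL)],
                       paste0(stem, "_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stem)
}
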