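#' Evaluate the ionic right-hand side
#'
#' Computes the total ionic rate and gate derivatives of the four-variable
#' minimal model at one or more states. The three phenomenological currents
#' are a fast inward current gated by `v` (depolarization), a slow outward
#' current (repolarization) and a slow inward current gated by `w*s`
#' (plateau). The Heaviside convention is `H(0) = 1`: a state exactly at a
#' threshold counts as supra-threshold.
#'
#' @param state a data frame (or single named vector/list) with columns
#'   `u`, `v`, `w`, `s`.
#' @param params an [model_parameters()] object.
#' @return A tibble with one row per input state and columns `J_ion` (total
#'   ionic rate, 1/ms; `du/dt = -J_ion + I_stim` pointwise), `dv`, `dw`,
#'   `ds` (1/ms).
#' @export
#' @examples
#' p <- model_parameters()
#' ionic_derivatives(data.frame(u = 0, v = 1, w = 1, s = 0), p)
ionic_derivatives <- function(state, params) {
  params <- validate_parameters(params)
  st <- as_state_matrix(state)
  check_state(st)
  d <- mm_derivs(as.numeric(params), st)
  if (!all(is.finite(d))) {
    abort("model blow-up: non-finite ionic derivatives",
          class = "atriafit_blowup", state = st[!stats::complete.cases(d), , drop = FALSE])
  }
  tibble(J_ion = d[, 1], dv = d[, 2], dw = d[, 3], ds = d[, 4])
}

as_state_matrix <- function(state) {
  if (is.data.frame(state)) {
    st <- as.matrix(state[, c("u", "v", "w", "s")])
  } else if (is.list(state) || (is.numeric(state) && !is.null(names(state)))) {
    st <- matrix(as.numeric(unlist(state)[c("u", "v", "w", "s")]), nrow = 1)
  } else {
    abort("state must be a data frame or named vector with u, v, w, s")
  }
  colnames(st) <- c("u", "v", "w", "s")
  storage.mode(st) <- "double"
  st
}

check_state <- function(st) {
  g <- st[, c("v", "w", "s"), drop = FALSE]
  if (any(g < -1e-9 | g > 1 + 1e-9)) abort("gates v, w, s must lie in [0, 1]")
  if (any(st[, "u"] < -0.5 | st[, "u"] > 2)) {
    abort("membrane potential outside guard range [-0.5, 2]",
          class = "atriafit_blowup")
  }
  invisible(st)
}

#' Quiescent resting state
#'
#' The model's resting fixed point: `u = u_o` with each gate at its
#' steady-state value evaluated at `u_o`. All derivatives vanish there, so
#' the state is invariant under unstimulated integration.
#'
#' @param params an [model_parameters()] object.
#' @return A one-row tibble with columns `u`, `v`, `w`, `s`.
#' @export
resting_state <- function(params) {
  params <- validate_parameters(params)
  u <- params[["u_o"]]
  H <- function(x) as.numeric(x >= 0)
  v_inf <- 1 - H(u - params[["theta_vminus"]])
  w_inf <- (1 - H(u - params[["theta_o"]])) * (1 - u / params[["tau_winf"]]) +
    H(u - params[["theta_o"]]) * params[["w_inf_star"]]
  s_inf <- (1 + tanh(params[["k_s"]] * (u - params[["u_s"]]))) / 2
  tibble(u = u, v = v_inf, w = min(max(w_inf, 0), 1), s = s_inf)
}

#' One explicit-Euler step of the point model
#'
#' Forward-Euler update of all four variables with an external stimulus
#' current added to `du/dt`. Gates are clipped to `[0, 1]` only when the
#' overshoot is below 1e-9; a larger excursion raises an instability error
#' naming the time step.
#'
#' @param state one-row data frame (or named vector) with `u`, `v`, `w`, `s`.
#' @param I_stim stimulus current in 1/ms (added to `du/dt`).
#' @param dt time step, ms (values above 0.05 ms are not recommended).
#' @param params an [model_parameters()] object.
#' @return A one-row tibble: the updated state.
#' @export
step_euler <- function(state, I_stim, dt, params) {
  stopifnot(dt > 0)
  st <- as_state_matrix(state)
  d <- ionic_derivatives(state, params)
  u <- st[, "u"] + dt * (-d$J_ion + I_stim)
  g <- cbind(v = st[, "v"] + dt * d$dv,
             w = st[, "w"] + dt * d$dw,
             s = st[, "s"] + dt * d$ds)
  if (any(g < -1e-9 | g > 1 + 1e-9)) {
    abort(sprintf("gate overshoot beyond tolerance at dt = %g ms", dt),
          class = "atriafit_blowup")
  }
  g <- pmin(pmax(g, 0), 1)
  if (any(!is.finite(u) | u < -0.5 | u > 2)) {
    abort(sprintf("membrane potential left guard range at dt = %g ms", dt),
          class = "atriafit_blowup")
  }
  tibble(u = as.numeric(u), v = as.numeric(g[, "v"]),
         w = as.numeric(g[, "w"]), s = as.numeric(g[, "s"]))
}

#' Integrate a single uncoupled cell
#'
#' Runs the point model with a train of identical stimulus pulses using the
#' compiled explicit-Euler integrator.
#'
#' @param params an [model_parameters()] object.
#' @param stimulus_times onset times of the stimulus pulses, ms.
#' @param t_end end of the run, ms.
#' @param dt time step, ms.
#' @param stim_amplitude stimulus current, 1/ms.
#' @param stim_duration pulse duration, ms.
#' @param record_dt sampling cadence of the returned trace, ms.
#' @param state0 optional initial state (defaults to [resting_state()]).
#' @return A tibble with columns `time`, `u`, `v`, `w`, `s`.
#' @export
run_cell <- function(params, stimulus_times = 0, t_end = 1000, dt = 0.01,
                     stim_amplitude = 0.6, stim_duration = 2,
                     record_dt = 0.1, state0 = NULL) {
  params <- validate_parameters(params)
  s0 <- if (is.null(state0)) resting_state(params) else state0
  s0 <- as.numeric(as_state_matrix(s0)[1, ])
  out <- mm_cell_run(as.numeric(params), s0, 0, t_end, dt,
                     as.numeric(sort(stimulus_times)), stim_duration,
                     stim_amplitude, max(1L, as.integer(round(record_dt / dt))))
  if (!isTRUE(out$ok)) {
    abort(sprintf("cell integration unstable (dt = %g ms, t = %g ms)",
                  dt, out$t_blowup %||% NA_real_),
          class = "atriafit_blowup")
  }
  tibble(time = out$time, u = out$u, v = out$v, w = out$w, s = out$s)
}
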