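# Shared, lazily built fixtures. The expensive cable-protocol objects are
# computed once per test session and reused across files.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# stimulus amplitude for the bundled default set on the default cable,
# calibrated once
default_amp <- function() {
  fixture("default_amp", function() {
    calibrate_stimulus(model_parameters(), cable_config())
  })
}

default_cable <- function() {
  cable_config(stim_amplitude = default_amp())
}

# full S1-S2 ladder protocol at the default parameters
default_s1s2 <- function() {
  fixture("default_s1s2", function() {
    s1s2_restitution(model_parameters(), default_cable())
  })
}

# noise-free model-truth synthetic patient on the default parameters
model_truth_dataset <- function() {
  fixture("model_truth_ds", function() {
    generate_patient(
      patient_spec("model_truth",
                   noise_sd = list(apd = 0, cv = 0, morph = 0),
                   truth_params = model_parameters(), seed = 7),
      default_cable()
    )
  })
}

# a single-cell paced AP trace at a slow cycle length
default_cell_trace <- function() {
  fixture("cell_trace", function() {
    run_cell(model_parameters(), stimulus_times = 10, t_end = 600,
             stim_amplitude = 0.6)
  })
}

# synthetic rigidly rotating field u = f(r) * cos(theta - omega t) on a
# square grid; the unique point with u = u_iso = 0 and du/dt = 0 is the
# rotation center
rotating_field <- function(n = 61, dx = 0.05, period = 200, frame_dt = 5,
                           t_end = 400) {
  cx <- (n - 1) / 2 * dx
  xs <- (seq_len(n) - 1) * dx
  grid_x <- matrix(xs, n, n)
  grid_y <- t(grid_x)
  r <- sqrt((grid_x - cx)^2 + (grid_y - cx)^2)
  th <- atan2(grid_y - cx, grid_x - cx)
  f <- r / (1 + r)
  times <- seq(0, t_end, by = frame_dt)
  omega <- 2 * pi / period
  frames <- vapply(times, function(t) f * cos(th - omega * t),
                   matrix(0, n, n))
  list(frames = frames, time = times, dx = dx, center = c(cx, cx),
       period = period)
}
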