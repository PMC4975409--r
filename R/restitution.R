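#' Detect activation times in a voltage trace
#'
#' Times of upward crossings of a fixed voltage threshold, linearly
#' interpolated between samples, with a refractory guard between
#' detections.
#'
#' @param trace data frame with columns `time` (ms, uniformly sampled) and
#'   `u` (dimensionless voltage).
#' @param threshold detection threshold.
#' @param refractory minimum spacing between detections, ms.
#' @return Numeric vector of activation times, ms.
#' @export
activation_times <- function(trace, threshold = 0.2, refractory = 50) {
  if (is.null(trace) || nrow(trace) == 0) abort("empty trace")
  t <- trace$time
  u <- trace$u
  up <- which(u[-length(u)] < threshold & u[-1] >= threshold)
  if (!length(up)) return(numeric(0))
  tc <- t[up] + (t[up + 1] - t[up]) * (threshold - u[up]) / (u[up + 1] - u[up])
  out <- tc[1]
  for (x in tc[-1]) if (x - out[length(out)] > refractory) out <- c(out, x)
  out
}

# beat window helpers: peak/baseline for the beat starting at `act`
beat_bounds <- function(trace, act, next_act = NULL) {
  t <- trace$time
  u <- trace$u
  t_hi <- next_act %||% max(t)
  pre <- u[t >= act - 50 & t <= act]
  baseline <- if (length(pre)) min(pre) else min(u[t <= act], u[1])
  win <- which(t >= act & t < t_hi)
  if (!length(win)) abort("beat window empty")
  ipk <- win[which.max(u[win])]
  list(baseline = baseline, peak = u[ipk], t_peak = t[ipk], win = win)
}

#' Action potential duration at 90% repolarization
#'
#' Duration from the activation time until the voltage first falls below
#' `baseline + 0.1 * (peak - baseline)`, where `peak` is the beat maximum
#' and `baseline` the pre-upstroke minimum, with sub-sample linear
#' interpolation.
#'
#' @param trace data frame with `time` and `u`; must span the full beat.
#' @param activation_time activation time of the beat, ms.
#' @param next_activation optional activation time of the following beat;
#'   repolarization must occur before it.
#' @return APD90 in ms.
#' @export
apd90 <- function(trace, activation_time, next_activation = NULL) {
  bb <- beat_bounds(trace, activation_time, next_activation)
  thr <- bb$baseline + 0.1 * (bb$peak - bb$baseline)
  t <- trace$time
  u <- trace$u
  idx <- which(t >= bb$t_peak)
  if (!is.null(next_activation)) idx <- idx[t[idx] < next_activation]
  dn <- idx[which(u[idx] >= thr & dplyr::lead(u)[idx] < thr)]
  dn <- dn[!is.na(dn)]
  if (!length(dn)) {
    abort("unresolved APD: no repolarization before next activation",
          class = "atriafit_unresolved_apd")
  }
  i <- dn[1]
  tc <- t[i] + (t[i + 1] - t[i]) * (thr - u[i]) / (u[i + 1] - u[i])
  tc - activation_time
}

#' Conduction velocity between two activation times
#'
#' @param t_a activation time at the proximal site, ms.
#' @param t_b activation time at the distal site, ms (must exceed `t_a`).
#' @param distance site separation, cm.
#' @return Conduction velocity in cm/s.
#' @export
conduction_velocity <- function(t_a, t_b, distance) {
  if (distance <= 0) abort("distance must be > 0")
  if (t_b <= t_a) {
    abort("retrograde or absent propagation: t_b <= t_a",
          class = "atriafit_no_propagation")
  }
  distance / (t_b - t_a) * 1000
}

#' Upstroke interval
#'
#' The time from 10% to 100% (peak) of the beat amplitude on the upstroke,
#' sub-sample interpolated. For noisy, non-monotone upstrokes the first
#' 10% crossing and the global beat peak are used.
#'
#' @inheritParams apd90
#' @param activation activation time of the beat, ms.
#' @return Interval in ms.
#' @export
upstroke_interval <- function(trace, activation, next_activation = NULL) {
  bb <- beat_bounds(trace, activation, next_activation)
  lvl <- bb$baseline + 0.1 * (bb$peak - bb$baseline)
  t <- trace$time
  u <- trace$u
  idx <- which(t >= activation - 20 & t <= bb$t_peak)
  if (length(idx) < 2) abort("beat contains no resolvable rising phase")
  cr <- idx[which(u[idx] < lvl & dplyr::lead(u)[idx] >= lvl)]
  cr <- cr[!is.na(cr)]
  if (!length(cr)) {
    # upstroke faster than sampling: at most one sample interval
    return(t[2] - t[1])
  }
  i <- cr[1]
  t10 <- t[i] + (t[i + 1] - t[i]) * (lvl - u[i]) / (u[i + 1] - u[i])
  bb$t_peak - t10
}

#' Normalize a beat to a morphology shape
#'
#' Min-max rescales the voltage of one beat to `[0, 1]` and rescales time
#' so the activation maps to 0 and the 90% repolarization point (APD90)
#' maps to 1. Samples earlier than `artifact_cutoff_ms` after activation
#' are masked, mirroring the removal of pacing artifacts from clinical
#' monophasic action potential recordings.
#'
#' @param segment data frame with `time`, `u` covering the beat from
#'   before activation to past 90% repolarization.
#' @param artifact_cutoff_ms length of the masked initial window, ms.
#' @param activation optional activation time; detected from the
#'   normalized trace when `NULL`.
#' @return An object of class `mm_morphology`: list with `grid` (tibble
#'   `t_norm`, `v_norm`, `masked`) and `artifact_cutoff` (normalized time).
#' @export
normalize_morphology <- function(segment, artifact_cutoff_ms = 10,
                                 activation = NULL) {
  rng <- range(segment$u)
  if (diff(rng) <= 0) abort("zero-amplitude segment cannot be normalized")
  seg <- tibble(time = segment$time,
                u = (segment$u - rng[1]) / diff(rng))
  act <- activation %||% {
    a <- activation_times(seg, threshold = 0.2)
    if (!length(a)) abort("no activation found in segment")
    a[1]
  }
  apd <- apd90(seg, act)
  keep <- seg$time >= act & seg$time <= act + apd + 1e-9
  t_norm <- (seg$time[keep] - act) / apd
  v <- seg$u[keep]
  # re-normalize on the retained window so the peak is exactly 1
  v <- (v - min(v)) / (max(v) - min(v))
  cutoff <- artifact_cutoff_ms / apd
  structure(list(
    grid = tibble(t_norm = t_norm, v_norm = v, masked = t_norm < cutoff),
    artifact_cutoff = cutoff, apd90 = apd
  ), class = "mm_morphology")
}

#' @export
print.mm_morphology <- function(x, ...) {
  cat(sprintf("<mm_morphology> %d samples, artifact cutoff %.3f (normalized time)\n",
              nrow(x$grid), x$artifact_cutoff))
  invisible(x)
}

# linear resampling onto the fixed 200-point comparison grid
resample_morphology <- function(shape, n = 200) {
  g <- seq(0, 1, length.out = n)
  v <- stats::approx(shape$grid$t_norm, shape$grid$v_norm, xout = g,
                     rule = 2)$y
  tibble(t_norm = g, v_norm = v, masked = g < shape$artifact_cutoff)
}

# first activation strictly after t at a given cell of a raw cable run
first_act_after <- function(raw, cell, t) {
  a <- raw$act[[cell]]
  a <- a[a > t]
  if (length(a)) a[1] else NA_real_
}

#' S1-S2 restitution protocol on a cable
#'
#' Paces `n_s1` conditioning beats at `s1_cl`, then delivers a single
#' premature S2 at each coupling interval of `s2_list`, measuring the S2
#' beat's APD90 and conduction velocity at the distal measurement cell.
#' The diastolic interval is the S2 coupling interval minus the APD90 of
#' the final S1 beat. The S1 train is integrated once and its end state
#' reused across S2 values. Failed captures are flagged, not dropped.
#'
#' When `s2_list` is `NULL` a clinical-style ladder is used: from `s1_cl`
#' down in 20 ms steps, refined to 10 ms steps below 300 ms, stopping at
#' loss of capture.
#'
#' @param params an [model_parameters()] object.
#' @param cfg a [cable_config()].
#' @param s1_cl S1 cycle length, ms (the clinical baseline is 500 ms).
#' @param n_s1 number of conditioning beats (>= 8).
#' @param s2_list S2 coupling intervals, ms, or `NULL` for the ladder.
#' @param artifact_cutoff_ms artifact mask passed to
#'   [normalize_morphology()].
#' @param keep_shapes capture the S2-beat morphologies?
#' @return An object of class `mm_s1s2`: list with `points` (tibble `S2`,
#'   `DI`, `APD`, `CV`, `captured`), `shapes` (named list of
#'   `mm_morphology`, one per captured S2), `apd_s1` (APD90 of the final
#'   conditioning beat) and `upstroke` (upstroke interval at the largest
#'   S2).
#' @export
s1s2_restitution <- function(params, cfg = cable_config(), s1_cl = 500,
                             n_s1 = 8, s2_list = NULL,
                             artifact_cutoff_ms = 10, keep_shapes = TRUE) {
  if (n_s1 < 8) abort("n_s1 must be >= 8")
  params <- validate_parameters(params)
  amp <- cfg$stim_amplitude %||% calibrate_stimulus(params, cfg)
  s1_times <- (seq_len(n_s1) - 1) * s1_cl
  t_last <- s1_times[n_s1]
  train <- cable_run_raw(params, cfg, s1_times, t_last + cfg$stim_duration,
                         amp = amp)
  if (!isTRUE(train$ok)) abort("S1 train unstable", class = "atriafit_blowup")
  n_capt <- length(train$act[[cfg$measure_cell]])
  # the final S1 beat has not reached the distal site yet at save time
  if (n_capt < n_s1 - 1) {
    abort(sprintf("S1 failure to capture: %d of %d beats detected distally",
                  n_capt, n_s1), class = "atriafit_protocol")
  }
  run_from_train <- function(stim_times, t_end) {
    cable_run_raw(params, cfg, stim_times, t_end,
                  t0 = t_last + cfg$stim_duration, state0 = train$state,
                  amp = amp, record_dt = min(cfg$record_dt, 1))
  }
  # the final S1 beat that anchors the DI bookkeeping: when the ladder
  # includes the degenerate S2 = s1_cl, that continuation contains the
  # full final S1 beat and is reused; otherwise a dedicated unstimulated
  # continuation is run
  s2_first <- if (is.null(s2_list)) s1_cl else max(s2_list)
  s2_cache <- NULL
  if (abs(s2_first - s1_cl) < 1e-9) {
    s2_cache <- run_from_train(t_last + s1_cl, t_last + s1_cl + 650)
    base <- s2_cache
  } else {
    base <- run_from_train(numeric(0), t_last + 900)
  }
  a_s1 <- first_act_after(base, cfg$measure_cell, t_last)
  if (is.na(a_s1)) abort("final S1 beat not detected", class = "atriafit_protocol")
  tr_base <- site_trace(base, cfg, cfg$measure_cell)
  a_s1_next <- first_act_after(base, cfg$measure_cell, t_last + s1_cl)
  apd_s1 <- apd90(tr_base, a_s1, a_s1_next)

  measure_s2 <- function(s2) {
    t_s2 <- t_last + s2
    raw <- if (!is.null(s2_cache) && abs(s2 - s1_cl) < 1e-9) {
      s2_cache
    } else {
      run_from_train(t_s2, t_s2 + 650)
    }
    tr <- site_trace(raw, cfg, cfg$measure_cell)
    a2 <- first_act_after(raw, cfg$measure_cell, t_s2)
    captured <- !is.na(a2) && (a2 - t_s2) <= s1_cl
    row <- tibble(S2 = s2, DI = s2 - apd_s1, APD = NA_real_, CV = NA_real_,
                  CL = s2, captured = captured)
    shape <- NULL
    upst <- NA_real_
    if (captured) {
      row$APD <- tryCatch(apd90(tr, a2), atriafit_unresolved_apd = function(e) NA_real_)
      ta <- first_act_after(raw, cfg$cv_cells[1], t_s2)
      tb <- first_act_after(raw, cfg$cv_cells[2], t_s2)
      if (!is.na(ta) && !is.na(tb) && tb > ta) {
        row$CV <- conduction_velocity(ta, tb, diff(cfg$cv_cells) * cfg$dx)
      }
      if (keep_shapes && !is.na(row$APD)) {
        seg <- dplyr::filter(tr, .data$time >= a2 - 20,
                             .data$time <= a2 + row$APD * 1.2 + 20)
        shape <- normalize_morphology(seg, artifact_cutoff_ms,
                                      activation = a2)
        upst <- upstroke_interval(tr, a2)
      }
    }
    list(row = row, shape = shape, upstroke = upst)
  }

  rows <- list()
  shapes <- list()
  upstrokes <- c()
  if (is.null(s2_list)) {
    ladder <- c(seq(s1_cl, 320, by = -20), seq(300, 100, by = -10))
    ladder <- ladder[ladder > 0]
    for (s2 in ladder) {
      m <- measure_s2(s2)
      rows[[length(rows) + 1]] <- m$row
      if (!is.null(m$shape)) {
        shapes[[as.character(s2)]] <- m$shape
        upstrokes[as.character(s2)] <- m$upstroke
      }
      if (!m$row$captured) break
    }
  } else {
    for (s2 in s2_list) {
      m <- measure_s2(s2)
      rows[[length(rows) + 1]] <- m$row
      if (!is.null(m$shape)) {
        shapes[[as.character(s2)]] <- m$shape
        upstrokes[as.character(s2)] <- m$upstroke
      }
    }
  }
  pts <- dplyr::bind_rows(rows)
  structure(list(points = pts, shapes = shapes, apd_s1 = apd_s1,
                 upstroke = if (length(upstrokes)) upstrokes[[1]] else NA_real_,
                 s1_cl = s1_cl, stim_amplitude = amp),
            class = "mm_s1s2")
}

#' @export
print.mm_s1s2 <- function(x, ...) {
  cat(sprintf("<mm_s1s2> S1 CL %g ms, %d S2 points (%d captured), APD(S1) = %.1f ms\n",
              x$s1_cl, nrow(x$points), sum(x$points$captured), x$apd_s1))
  invisible(x)
}

#' Decremental (dynamic) pacing protocol
#'
#' Replicates the clinical pacing ladder: at least 84 beats at each cycle
#' length of 500, 450, 400, 350 and 300 ms, then decrements of 10 ms until
#' capture failure (detected as a missing distal activation, i.e. 2:1
#' block). The cable state is carried from one cycle length to the next.
#' The last fully repolarized beat of each cycle length provides the
#' steady-state APD90, DI and CV.
#'
#' @param params an [model_parameters()] object.
#' @param cfg a [cable_config()].
#' @param n_beats beats per cycle length (>= 84).
#' @param cl_ladder the fixed upper rungs of the ladder, ms.
#' @param cl_step decrement below the last fixed rung, ms.
#' @param cl_min hard stop for the decremental phase, ms.
#' @return An object of class `mm_ladder`: list with `points` (tibble `CL`,
#'   `DI`, `APD`, `CV`, `captured`) and `ladder` (attempted cycle lengths).
#' @export
dynamic_pacing_protocol <- function(params, cfg = cable_config(),
                                    n_beats = 85,
                                    cl_ladder = c(500, 450, 400, 350, 300),
                                    cl_step = 10, cl_min = 120) {
  if (n_beats < 84) abort("n_beats must be >= 84")
  params <- validate_parameters(params)
  amp <- cfg$stim_amplitude %||% calibrate_stimulus(params, cfg)
  state <- NULL
  t0 <- 0
  rows <- list()
  attempted <- c()
  cls <- c(cl_ladder, seq(min(cl_ladder) - cl_step, cl_min, by = -cl_step))
  for (cl in cls) {
    attempted <- c(attempted, cl)
    stim <- t0 + (seq_len(n_beats) - 1) * cl
    t_end <- t0 + n_beats * cl
    raw <- cable_run_raw(params, cfg, stim, t_end, t0 = t0, state0 = state,
                         amp = amp, record_dt = min(cfg$record_dt, 1))
    if (!isTRUE(raw$ok)) {
      abort(sprintf("ladder unstable at CL %g ms", cl),
            class = "atriafit_blowup")
    }
    acts <- raw$act[[cfg$measure_cell]]
    captured <- length(acts) >= n_beats
    if (!captured) break  # 2:1 block: no points recorded at this CL
    tr <- site_trace(raw, cfg, cfg$measure_cell)
    # last beat whose repolarization is bounded by a following activation
    a_pen <- acts[length(acts) - 1]
    a_fin <- acts[length(acts)]
    apd <- apd90(tr, a_pen, a_fin)
    di <- cl - apd
    ta <- raw$act[[cfg$cv_cells[1]]]
    tb <- raw$act[[cfg$cv_cells[2]]]
    cv <- NA_real_
    if (length(ta) >= 2 && length(tb) >= 2) {
      ta_pen <- ta[length(ta) - 1]
      tb_pen <- tb[abs(tb - ta_pen) == min(abs(tb - ta_pen))][1]
      # distal activation of the same beat
      tb_pen <- tb[tb > ta_pen][1]
      if (!is.na(tb_pen)) {
        cv <- conduction_velocity(ta_pen, tb_pen, diff(cfg$cv_cells) * cfg$dx)
      }
    }
    rows[[length(rows) + 1]] <- tibble(CL = cl, DI = di, APD = apd, CV = cv,
                                       captured = TRUE)
    state <- raw$state
    t0 <- t_end
  }
  structure(list(points = dplyr::bind_rows(rows), ladder = attempted,
                 stim_amplitude = amp),
            class = "mm_ladder")
}

#' @export
print.mm_ladder <- function(x, ...) {
  cat(sprintf("<mm_ladder> %d cycle lengths attempted, %d with 1:1 capture\n",
              length(x$ladder), nrow(x$points)))
  invisible(x)
}
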