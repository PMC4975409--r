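#' 2D sheet configuration
#'
#' Square isotropic monodomain sheet with no-flux boundaries, paced by a
#' planar S1 from the left edge and a cross-field S2 over the lower-left
#' quadrant. The default geometry is 9.6 x 9.6 cm at `dx = 0.02` cm
#' (480 x 480 cells). The 2D explicit scheme requires `D*dt/dx^2 < 0.25`.
#'
#' @param side sheet edge length, cm.
#' @param dx spatial step, cm.
#' @param dt time step, ms.
#' @param D diffusion coefficient, cm^2/ms.
#' @param frame_dt interval between stored voltage frames, ms.
#' @param probe_xy matrix (or vector of length 2) of probe coordinates in
#'   cm; traces there are stored at `probe_dt` resolution.
#' @param probe_dt probe sampling cadence, ms.
#' @param s1_time S1 onset, ms.
#' @param s2_time S2 onset, ms, or `"auto"` to scan the S1 wake in 10 ms
#'   steps and keep the earliest sustained reentry.
#' @param s2_fraction fraction of the domain (per axis) covered by the S2
#'   quadrant.
#' @param stim_amplitude stimulus current 1/ms (`NULL`: calibrated on an
#'   equivalent cable).
#' @param stim_duration stimulus pulse, ms.
#' @param t_total run length, ms.
#' @return A list of class `grid2d_config`.
#' @export
grid2d_config <- function(side = 9.6, dx = 0.02, dt = 0.01, D = 0.001,
                          frame_dt = 1, probe_xy = NULL, probe_dt = 1,
                          s1_time = 5, s2_time = "auto", s2_fraction = 0.5,
                          stim_amplitude = NULL, stim_duration = 2,
                          t_total = 2000) {
  if (dx <= 0 || dt <= 0 || D <= 0) abort("dx, dt and D must be > 0")
  if (D * dt / dx^2 >= 0.25) {
    abort(sprintf("unstable 2D configuration: D*dt/dx^2 = %.3f >= 0.25",
                  D * dt / dx^2))
  }
  n <- round(side / dx)
  if (is.null(probe_xy)) probe_xy <- c(0.75 * side, 0.75 * side)
  probe_xy <- matrix(probe_xy, ncol = 2)
  structure(list(side = side, dx = dx, dt = dt, D = D, n = n,
                 frame_dt = frame_dt, probe_xy = probe_xy,
                 probe_dt = probe_dt, s1_time = s1_time, s2_time = s2_time,
                 s2_fraction = s2_fraction, stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration, t_total = t_total),
            class = "grid2d_config")
}

# 1D estimates of CV (cm/ms) and APD90 used to place the S2 in the S1 wake
estimate_wave_scales <- function(params, cfg) {
  ccfg <- cable_config(n_cells = 100, dx = cfg$dx, dt = cfg$dt, D = cfg$D,
                       stim_amplitude = cfg$stim_amplitude,
                       stim_duration = cfg$stim_duration)
  amp <- ccfg$stim_amplitude %||% calibrate_stimulus(params, ccfg)
  raw <- cable_run_raw(params, ccfg, stim_times = 5, t_end = 600, amp = amp)
  ta <- raw$act[[ccfg$cv_cells[1]]][1]
  tb <- raw$act[[ccfg$cv_cells[2]]][1]
  if (is.na(ta) || is.na(tb) || tb <= ta) {
    abort("S1 wave does not propagate at these parameters",
          class = "atriafit_protocol")
  }
  cv <- diff(ccfg$cv_cells) * ccfg$dx / (tb - ta)   # cm/ms
  tr <- site_trace(raw, ccfg, ccfg$measure_cell)
  apd <- apd90(tr, tb)
  list(cv = cv, apd = apd, amp = amp)
}

#' Run a 2D spiral-initiation simulation
#'
#' S1 launches a planar wave from the left edge; S2 stimulates the
#' lower-left quadrant at the configured time, creating a free wave end
#' that can curl into a spiral (cross-field initiation). Voltage frames
#' are stored at `frame_dt`; probe traces at full `probe_dt` resolution.
#'
#' With `s2_time = "auto"` the S2 onset is scanned in 10 ms steps across
#' the S1 repolarization wake (estimated from an equivalent 1D cable) and
#' the earliest timing that yields sustained reentry is kept.
#'
#' @param params an [model_parameters()] object.
#' @param cfg a [grid2d_config()].
#' @param s2_enabled set `FALSE` to deliver only the planar S1.
#' @return An object of class `mm_sheet`: list with `frames` (nx x ny x
#'   n_frames array), `frame_time`, `probes` (tibble `time`, `probe`,
#'   `u`), `s2_time`, `config`, and the final state fields.
#' @export
run_2d <- function(params, cfg = grid2d_config(), s2_enabled = TRUE) {
  params <- validate_parameters(params)
  n <- cfg$n
  if (!identical(cfg$s2_time, "auto") || !s2_enabled) {
    s2_time <- if (s2_enabled) cfg$s2_time else NA_real_
    return(run_2d_fixed(params, cfg, s2_time))
  }
  sc <- estimate_wave_scales(params, cfg)
  base <- cfg$s1_time + (cfg$side / 2) / sc$cv + sc$apd
  candidates <- base + seq(-30, 60, by = 10)
  for (s2 in candidates) {
    probe_cfg <- modifyList2(cfg, t_total = s2 + 500, frame_dt = 5,
                             stim_amplitude = sc$amp)
    trial <- run_2d_fixed(params, probe_cfg, s2)
    traj <- track_tips(trial)
    late <- traj$counts$n_tips[traj$counts$time > s2 + 300]
    if (length(late) && any(late > 0) && utils::tail(late, 1) > 0) {
      full <- modifyList2(cfg, stim_amplitude = sc$amp)
      return(run_2d_fixed(params, full, s2))
    }
  }
  warn("no sustained reentry found in the scanned S2 window; returning last trial")
  run_2d_fixed(params, modifyList2(cfg, stim_amplitude = sc$amp),
               utils::tail(candidates, 1))
}

run_2d_fixed <- function(params, cfg, s2_time) {
  n <- cfg$n
  rs <- as.numeric(resting_state(params))
  U0 <- matrix(rs[1], n, n); V0 <- matrix(rs[2], n, n)
  W0 <- matrix(rs[3], n, n); S0 <- matrix(rs[4], n, n)
  amp <- cfg$stim_amplitude %||% estimate_wave_scales(params, cfg)$amp
  stims <- list(list(t_on = cfg$s1_time, dur = cfg$stim_duration, amp = amp,
                     i0 = 0L, i1 = 2L, j0 = 0L, j1 = as.integer(n - 1)))
  if (!is.na(s2_time)) {
    q <- as.integer(round(n * cfg$s2_fraction)) - 1L
    stims <- c(stims, list(list(t_on = s2_time, dur = cfg$stim_duration,
                                amp = amp, i0 = 0L, i1 = q, j0 = 0L,
                                j1 = q)))
  }
  probes <- cbind(pmin(pmax(as.integer(round(cfg$probe_xy[, 1] / cfg$dx)), 0L), n - 1L),
                  pmin(pmax(as.integer(round(cfg$probe_xy[, 2] / cfg$dx)), 0L), n - 1L))
  out <- mm_sheet_run(as.numeric(params), U0, V0, W0, S0, cfg$dx, cfg$dt,
                      cfg$D, 0, cfg$t_total, stims,
                      max(1L, as.integer(round(cfg$frame_dt / cfg$dt))),
                      probes,
                      max(1L, as.integer(round(cfg$probe_dt / cfg$dt))))
  if (!isTRUE(out$ok)) {
    abort(sprintf("2D integration unstable at t = %.3f ms",
                  out$t_blowup %||% NA_real_), class = "atriafit_blowup")
  }
  np <- nrow(probes)
  probes_tb <- tibble(
    time = rep(out$probe_time, times = np),
    probe = rep(seq_len(np), each = length(out$probe_time)),
    u = as.numeric(out$probe_u)
  )
  structure(list(frames = out$frames, frame_time = out$frame_time,
                 probes = probes_tb, s2_time = s2_time,
                 stim_amplitude = amp, config = cfg,
                 final = list(u = out$U, v = out$v, w = out$w, s = out$s)),
            class = "mm_sheet")
}

#' @export
print.mm_sheet <- function(x, ...) {
  cat(sprintf("<mm_sheet> %dx%d cells (%.1f cm), %d frames, S2 at %s ms\n",
              dim(x$frames)[1], dim(x$frames)[2], x$config$side,
              dim(x$frames)[3],
              ifelse(is.na(x$s2_time), "-", format(x$s2_time))))
  invisible(x)
}

# Newton solve for the intersection of two bilinear surfaces with corner
# values a[1:4] = (00, 10, 01, 11), b likewise, inside the unit cell
bilinear_intersection <- function(a, b) {
  ax <- a[2] - a[1]; ay <- a[3] - a[1]; axy <- a[4] - a[2] - a[3] + a[1]
  bx <- b[2] - b[1]; by <- b[3] - b[1]; bxy <- b[4] - b[2] - b[3] + b[1]
  x <- 0.5; y <- 0.5
  for (k in 1:20) {
    fa <- a[1] + ax * x + ay * y + axy * x * y
    fb <- b[1] + bx * x + by * y + bxy * x * y
    j11 <- ax + axy * y; j12 <- ay + axy * x
    j21 <- bx + bxy * y; j22 <- by + bxy * x
    det <- j11 * j22 - j12 * j21
    if (!is.finite(det) || abs(det) < 1e-14) return(NULL)
    dx <- (fa * j22 - fb * j12) / det
    dy <- (j11 * fb - j21 * fa) / det
    x <- x - dx; y <- y - dy
    if (abs(dx) < 1e-10 && abs(dy) < 1e-10) break
  }
  if (x < -0.05 || x > 1.05 || y < -0.05 || y > 1.05) return(NULL)
  c(x = min(max(x, 0), 1), y = min(max(y, 0), 1))
}

#' Track spiral tips across a frame stack
#'
#' Detects spiral tips as the intersection points of the `u = u_iso`
#' isoline with the `du/dt = 0` contour (frame differencing), located by
#' bilinear interpolation inside each grid cell where both fields change
#' sign, then linked across frames by greedy nearest-neighbour matching
#' with a 0.3 cm gate.
#'
#' @param x an `mm_sheet`, or a 3D array of frames (then `dx` and
#'   `frame_time` must be given).
#' @param u_iso isopotential level used for the tip definition.
#' @param dx grid spacing, cm (taken from the sheet if available).
#' @param frame_time frame time stamps, ms.
#' @param gate linking gate distance, cm.
#' @return An object of class `mm_tip_trajectory`: list with `tips`
#'   (tibble `time`, `x`, `y`, `track`), `counts` (tibble `time`,
#'   `n_tips` per frame transition) and the frame metadata.
#' @export
track_tips <- function(x, u_iso = 0.5, dx = NULL, frame_time = NULL,
                       gate = 0.3) {
  if (inherits(x, "mm_sheet")) {
    frames <- x$frames
    dx <- x$config$dx
    frame_time <- x$frame_time
  } else {
    frames <- x
    if (is.null(dx) || is.null(frame_time)) {
      abort("dx and frame_time are required for a bare frame array")
    }
  }
  nf <- dim(frames)[3]
  if (nf < 2) abort("need at least 2 frames")
  nx <- dim(frames)[1]; ny <- dim(frames)[2]
  tips_list <- vector("list", nf - 1)
  counts <- integer(nf - 1)
  for (k in seq_len(nf - 1)) {
    G <- frames[, , k] - u_iso
    F <- frames[, , k + 1] - frames[, , k]
    sg <- G > 0
    sf <- F > 0
    cg <- sg[-nx, -ny] + sg[-1, -ny] + sg[-nx, -1] + sg[-1, -1]
    cf <- sf[-nx, -ny] + sf[-1, -ny] + sf[-nx, -1] + sf[-1, -1]
    cand <- which(cg %% 4 != 0 & cf %% 4 != 0, arr.ind = TRUE)
    if (nrow(cand)) {
      pts <- lapply(seq_len(nrow(cand)), function(q) {
        i <- cand[q, 1]; j <- cand[q, 2]
        a <- c(G[i, j], G[i + 1, j], G[i, j + 1], G[i + 1, j + 1])
        b <- c(F[i, j], F[i + 1, j], F[i, j + 1], F[i + 1, j + 1])
        p <- bilinear_intersection(a, b)
        if (is.null(p)) return(NULL)
        c((i - 1 + p[1]) * dx, (j - 1 + p[2]) * dx)
      })
      pts <- do.call(rbind, pts[!vapply(pts, is.null, logical(1))])
    } else {
      pts <- NULL
    }
    if (!is.null(pts) && nrow(pts)) {
      # merge duplicate detections from adjacent cells
      keep <- rep(TRUE, nrow(pts))
      if (nrow(pts) > 1) {
        d <- as.matrix(stats::dist(pts))
        for (q in 2:nrow(pts)) {
          if (any(d[q, seq_len(q - 1)][keep[seq_len(q - 1)]] < 1.5 * dx)) {
            keep[q] <- FALSE
          }
        }
      }
      pts <- pts[keep, , drop = FALSE]
      tips_list[[k]] <- tibble(time = frame_time[k], x = pts[, 1],
                               y = pts[, 2])
      counts[k] <- nrow(pts)
    }
  }
  tips <- dplyr::bind_rows(tips_list)
  tips$track <- link_tracks(tips, gate)
  structure(list(
    tips = tips,
    counts = tibble(time = frame_time[seq_len(nf - 1)], n_tips = counts),
    dx = dx, frame_dt = if (nf >= 2) frame_time[2] - frame_time[1] else NA
  ), class = "mm_tip_trajectory")
}

# greedy nearest-neighbour frame-to-frame linking
link_tracks <- function(tips, gate) {
  if (!nrow(tips)) return(integer(0))
  track <- integer(nrow(tips))
  next_id <- 1L
  times <- sort(unique(tips$time))
  prev_idx <- integer(0)
  for (t in times) {
    cur_idx <- which(tips$time == t)
    assigned <- rep(FALSE, length(cur_idx))
    if (length(prev_idx)) {
      d <- outer(seq_along(prev_idx), seq_along(cur_idx),
                 Vectorize(function(a, b) {
                   sqrt((tips$x[prev_idx[a]] - tips$x[cur_idx[b]])^2 +
                        (tips$y[prev_idx[a]] - tips$y[cur_idx[b]])^2)
                 }))
      used_prev <- rep(FALSE, length(prev_idx))
      repeat {
        m <- which(d == min(d), arr.ind = TRUE)[1, ]
        if (d[m[1], m[2]] > gate) break
        track[cur_idx[m[2]]] <- track[prev_idx[m[1]]]
        assigned[m[2]] <- TRUE
        used_prev[m[1]] <- TRUE
        d[m[1], ] <- Inf
        d[, m[2]] <- Inf
        if (all(used_prev) || all(assigned)) break
      }
    }
    for (b in which(!assigned)) {
      track[cur_idx[b]] <- next_id
      next_id <- next_id + 1L
    }
    prev_idx <- cur_idx
  }
  track
}

#' @export
print.mm_tip_trajectory <- function(x, ...) {
  cat(sprintf("<mm_tip_trajectory> %d tip detections in %d frames, %d tracks, max %d concurrent tips\n",
              nrow(x$tips), nrow(x$counts),
              length(unique(x$tips$track)),
              max(c(0, x$counts$n_tips))))
  invisible(x)
}

#' Spiral rotation period
#'
#' For a point-probe trace (data frame with `time`, `u`) the period is the
#' mean inter-activation interval over the final two-thirds of the trace;
#' for a tip trajectory it is `2*pi` divided by the mean angular velocity
#' of the longest track about its centroid. Returns `NA` (with a message)
#' when fewer than 3 activations / 2 full windings are available —
#' an unsustained rotor has no period.
#'
#' @param x a probe trace data frame or an `mm_tip_trajectory`.
#' @param ... passed to methods.
#' @return Period in ms (`NA_real_` if unsustained).
#' @export
rotation_period <- function(x, ...) UseMethod("rotation_period")

#' @param threshold activation threshold for probe traces.
#' @rdname rotation_period
#' @export
rotation_period.data.frame <- function(x, threshold = 0.2, ...) {
  t0 <- min(x$time) + diff(range(x$time)) / 3
  late <- x[x$time >= t0, ]
  acts <- activation_times(late, threshold = threshold)
  if (length(acts) < 3) {
    message("unsustained: fewer than 3 activations at the probe")
    return(NA_real_)
  }
  mean(diff(acts))
}

#' @rdname rotation_period
#' @export
rotation_period.mm_tip_trajectory <- function(x, ...) {
  if (!nrow(x$tips)) {
    message("unsustained: no tips")
    return(NA_real_)
  }
  spans <- x$tips |>
    dplyr::summarise(span = max(.data$time) - min(.data$time), n = dplyr::n(),
                     .by = "track")
  tr <- spans$track[which.max(spans$span)]
  tt <- x$tips[x$tips$track == tr, ]
  if (nrow(tt) < 5) {
    message("unsustained: longest track too short")
    return(NA_real_)
  }
  cx <- mean(tt$x); cy <- mean(tt$y)
  th <- atan2(tt$y - cy, tt$x - cx)
  dth <- diff(th)
  dth <- ifelse(dth > pi, dth - 2 * pi, ifelse(dth < -pi, dth + 2 * pi, dth))
  winding <- sum(dth)
  if (abs(winding) < 4 * pi) {
    message("unsustained: fewer than 2 full windings")
    return(NA_real_)
  }
  total_t <- max(tt$time) - min(tt$time)
  2 * pi * total_t / abs(winding)
}

#' Both rotation-period estimates for a sheet run
#'
#' @param sheet an `mm_sheet`.
#' @param traj optional precomputed `mm_tip_trajectory`.
#' @return Tibble with columns `method` (`"probe"`, `"tip"`) and
#'   `period_ms`.
#' @export
rotation_periods <- function(sheet, traj = NULL) {
  stopifnot(inherits(sheet, "mm_sheet"))
  traj <- traj %||% track_tips(sheet)
  pr <- sheet$probes[sheet$probes$probe == 1, c("time", "u")]
  tibble(method = c("probe", "tip"),
         period_ms = c(suppressMessages(rotation_period(as.data.frame(pr))),
                       suppressMessages(rotation_period(traj))))
}

#' Classify spiral-wave dynamics
#'
#' Rule-based classification of a run: `no_reentry` if no tips survive the
#' post-S2 transient; `breakup` if more than one tip is sustained for over
#' 200 ms; `terminated` if tips vanish before the end of the run after at
#' least one full rotation; otherwise `stable`.
#'
#' @param traj an `mm_tip_trajectory`.
#' @param run_length run length, ms.
#' @param s2_time S2 onset, ms (transient starts there).
#' @param transient settle time after S2 before classification, ms.
#' @return One of `"stable"`, `"breakup"`, `"no_reentry"`, `"terminated"`.
#' @export
classify_dynamics <- function(traj, run_length, s2_time = 0,
                              transient = 200) {
  stopifnot(inherits(traj, "mm_tip_trajectory"))
  cnt <- traj$counts[traj$counts$time > s2_time + transient, ]
  if (!nrow(cnt) || all(cnt$n_tips == 0)) return("no_reentry")
  # sustained multi-tip episodes
  multi <- rle(cnt$n_tips > 1)
  dtf <- traj$frame_dt %||% diff(cnt$time[1:2])
  if (any(multi$values & multi$lengths * dtf > 200)) return("breakup")
  last_tip_t <- max(cnt$time[cnt$n_tips > 0])
  if (last_tip_t < run_length - 2 * dtf) {
    rotated <- is.finite(suppressMessages(rotation_period(traj)))
    return(if (rotated) "terminated" else "no_reentry")
  }
  "stable"
}

#' Write a tip trajectory to CSV
#'
#' @param traj an `mm_tip_trajectory`.
#' @param stem output path stem; writes `<stem>_tips.csv` and
#'   `<stem>_counts.csv`.
#' @return `stem`, invisibly.
#' @export
write_trajectory_csv <- function(traj, stem) {
  stopifnot(inherits(traj, "mm_tip_trajectory"))
  utils::write.csv(traj$tips, paste0(stem, "_tips.csv"), row.names = FALSE)
  utils::write.csv(traj$counts, paste0(stem, "_counts.csv"),
                   row.names = FALSE)
  invisible(stem)
}
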