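#' Default parameters for adaptive gaze-event detection
#'
#' Canonical settings of the adaptive velocity-threshold algorithm for
#' 500 Hz data: Savitzky-Golay smoothing over 20 ms with polynomial order 2,
#' initial peak threshold 200 deg/s, data-driven threshold at
#' `mean + 6 SD` of the sub-threshold noise, minimum saccade duration 10 ms,
#' minimum fixation duration 40 ms, physiological velocity/acceleration caps
#' of 1000 deg/s and 100000 deg/s^2, a 40 ms post-saccadic glissade window,
#' and linear interpolation of invalid gaps shorter than 75 ms.
#'
#' @return named list of parameters.
#' @export
gaze_params <- function() {
  list(
    sg_window_s = 0.020, sg_order = 2,
    pt0 = 200, k = 6, tol = 1, pt_floor = 30,
    min_sacc_dur = 0.010, min_fix_dur = 0.040,
    v_max = 1000, a_max = 1e5,
    glissade_window_s = 0.040,
    max_gap_s = 0.075
  )
}

#' Data-driven peak-velocity threshold
#'
#' Iterates `PT <- mean + k * SD` of the velocity samples below the current
#' `PT`, starting from `pt0`, until the change falls below `tol`. When all
#' samples stay below the threshold the fixed point is the closed form
#' `mean + k * SD` of the whole sample.
#'
#' @param velocity numeric vector of speeds in deg/s (NA allowed, ignored).
#' @param pt0 initial threshold in deg/s.
#' @param k SD multiplier (default 6).
#' @param tol convergence tolerance in deg/s.
#' @return final threshold, with attribute `iterations`.
#' @export
adaptive_threshold <- function(velocity, pt0 = 200, k = 6, tol = 1) {
  v <- velocity[is.finite(velocity)]
  if (!any(v < pt0)) stop("adaptive_threshold: no velocity samples below pt0", call. = FALSE)
  pt <- pt0
  for (it in seq_len(100)) {
    sub <- v[v < pt]
    if (length(sub) == 0) { # nothing left below: previous value is the fixed point
      out <- pt
      attr(out, "iterations") <- it
      return(out)
    }
    s <- if (length(sub) < 2) 0 else stats::sd(sub)
    if (!is.finite(s)) s <- 0
    newpt <- mean(sub) + k * s
    if (abs(newpt - pt) < tol) {
      out <- newpt
      attr(out, "iterations") <- it
      return(out)
    }
    pt <- newpt
  }
  stop("adaptive_threshold: did not converge in 100 iterations", call. = FALSE)
}

# Savitzky-Golay smoothed derivative of order m, honouring sampling interval.
sg_deriv <- function(x, p, n, m, dt) {
  signal::sgolayfilt(x, p = p, n = n, m = m, ts = dt)
}

# Contiguous runs of TRUE in a logical vector -> matrix of (start, end).
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect fixations, saccades and glissades from gaze samples
#'
#' Adaptive velocity-threshold event detection: positions are smoothed with
#' a Savitzky-Golay filter and differentiated to angular velocity (per-axis
#' pixel pitch, Euclidean norm); implausible samples (velocity or
#' acceleration above physiological caps) are marked artifacts; a
#' data-driven peak threshold separates saccade peaks from fixation noise
#' ([adaptive_threshold()]); saccade onsets are traced back to the last
#' sample below an onset threshold (`mean + 3 SD` of the sub-threshold
#' noise) and offsets forward to a locally adapted threshold
#' (`0.7 * onset threshold + 0.3 * local noise term`); velocity wobbles
#' within 40 ms after a saccade offset become glissades; the remaining
#' intervals of at least the minimum fixation duration become fixations.
#' Invalid gaps shorter than 75 ms are linearly interpolated; longer gaps
#' split the recording and each piece is processed separately.
#'
#' @param samples data.frame with columns `t` (s), `x`, `y` (px) and
#'   optionally `valid` (logical).
#' @param geometry a [screen_geometry()].
#' @param params parameter list from [gaze_params()] (entries may be
#'   overridden).
#' @return data.frame of events: `kind` (fixation/saccade/glissade/artifact),
#'   `onset`, `offset` (s), `start_x`, `start_y`, `centroid_x`, `centroid_y`
#'   (fixations), `peak_vel_deg_s`.
#' @export
detect_events <- function(samples, geometry = screen_geometry(), params = gaze_params()) {
  p <- utils::modifyList(gaze_params(), params)
  stopifnot(is.data.frame(samples), all(c("t", "x", "y") %in% names(samples)))
  if (is.null(samples$valid)) samples$valid <- TRUE
  samples$valid <- samples$valid & is.finite(samples$x) & is.finite(samples$y)
  n <- nrow(samples)
  dt <- stats::median(diff(samples$t))
  fs <- 1 / dt
  if (sum(samples$valid) * dt < 0.2) {
    warning("detect_events: fewer than 200 ms of valid samples; returning no events")
    return(empty_events())
  }

  # --- gap handling: interpolate short invalid gaps, split on long ones ----
  x <- samples$x; y <- samples$y
  x[!samples$valid] <- NA; y[!samples$valid] <- NA
  gap_runs <- runs_of(!samples$valid)
  split_points <- integer(0)
  if (nrow(gap_runs) > 0) {
    for (gi in seq_len(nrow(gap_runs))) {
      len <- gap_runs[gi, "end"] - gap_runs[gi, "start"] + 1L
      if (len * dt < p$max_gap_s &&
          gap_runs[gi, "start"] > 1 && gap_runs[gi, "end"] < n) {
        idx <- gap_runs[gi, "start"]:gap_runs[gi, "end"]
        lo <- gap_runs[gi, "start"] - 1L; hi <- gap_runs[gi, "end"] + 1L
        w <- (idx - lo) / (hi - lo)
        x[idx] <- x[lo] + w * (x[hi] - x[lo])
        y[idx] <- y[lo] + w * (y[hi] - y[lo])
      } else {
        split_points <- c(split_points, gap_runs[gi, "start"]:gap_runs[gi, "end"])
      }
    }
  }
  chunk_id <- cumsum(seq_len(n) %in% c(1L, split_points + 1L))
  chunk_id[split_points] <- NA
  out <- lapply(stats::na.omit(unique(chunk_id)), function(ci) {
    idx <- which(!is.na(chunk_id) & chunk_id == ci)
    if (length(idx) * dt < 0.2) return(NULL)
    detect_events_chunk(samples$t[idx], x[idx], y[idx], fs, geometry, p)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0) return(empty_events())
  out[order(out$onset), , drop = FALSE]
}

empty_events <- function() {
  data.frame(kind = character(0), onset = numeric(0), offset = numeric(0),
             start_x = numeric(0), start_y = numeric(0),
             centroid_x = numeric(0), centroid_y = numeric(0),
             peak_vel_deg_s = numeric(0))
}

detect_events_chunk <- function(t, x, y, fs, geometry, p) {
  n <- length(t)
  dt <- 1 / fs
  nw <- round(p$sg_window_s * fs)
  if (nw %% 2 == 0) nw <- nw + 1L
  nw <- max(nw, p$sg_order + 2 + (p$sg_order %% 2)) # odd, > order
  if (n <= nw) return(NULL)

  dpp_x <- px_to_deg(1, "horizontal", geometry)
  dpp_y <- px_to_deg(1, "vertical", geometry)
  xs <- signal::sgolayfilt(x, p = p$sg_order, n = nw)
  ys <- signal::sgolayfilt(y, p = p$sg_order, n = nw)
  vx <- sg_deriv(x, p$sg_order, nw, 1, dt) * dpp_x
  vy <- sg_deriv(y, p$sg_order, nw, 1, dt) * dpp_y
  speed <- sqrt(vx^2 + vy^2)
  ax <- sg_deriv(x, p$sg_order, nw, 2, dt) * dpp_x
  ay <- sg_deriv(y, p$sg_order, nw, 2, dt) * dpp_y
  accel <- sqrt(ax^2 + ay^2)

  # raw central-difference speed: used only to report peak velocities, so
  # they are not attenuated by the segmentation filter
  vr_x <- c(0, diff(x, lag = 2) / (2 * dt), 0) * dpp_x
  vr_y <- c(0, diff(y, lag = 2) / (2 * dt), 0) * dpp_y
  speed_raw <- sqrt(vr_x^2 + vr_y^2)

  artifact <- speed > p$v_max | accel > p$a_max
  usable <- !artifact
  pt <- tryCatch(adaptive_threshold(speed[usable], p$pt0, p$k, p$tol),
                 error = function(e) NA_real_)
  if (is.na(pt)) return(NULL)
  pt <- max(pt, p$pt_floor) # physiological floor for near-noise-free data
  sub <- speed[usable & speed < pt]
  onset_thr <- max(mean(sub) + 3 * stats::sd(sub), p$pt_floor / 3)

  state <- rep("free", n) # free / saccade / glissade / artifact
  state[artifact] <- "artifact"
  peaks <- runs_of(speed > pt & usable)
  min_sacc <- max(2L, round(p$min_sacc_dur * fs))
  sacc <- list()
  if (nrow(peaks) > 0) {
    for (i in seq_len(nrow(peaks))) {
      # a genuine saccade stays above the peak threshold for several samples;
      # single-sample noise spikes are ignored
      if ((peaks[i, "end"] - peaks[i, "start"] + 1L) < 3L) next
      pk <- peaks[i, "start"] + which.max(speed[peaks[i, "start"]:peaks[i, "end"]]) - 1L
      # onset: last sample before the peak that falls below the onset threshold
      on <- peaks[i, "start"]
      while (on > 1 && speed[on - 1] >= onset_thr && state[on - 1] == "free") on <- on - 1L
      if (speed[on] >= onset_thr && on > 1) on <- max(1L, on - 1L)
      # offset: locally adapted threshold using pre-saccade noise
      loc_win <- max(1L, on - round(0.040 * fs)):max(1L, on - 1L)
      loc <- speed[loc_win][speed[loc_win] < pt]
      loc_term <- if (length(loc) >= 2) mean(loc) + 3 * stats::sd(loc) else onset_thr
      off_thr <- 0.7 * onset_thr + 0.3 * loc_term
      off <- peaks[i, "end"]
      while (off < n && speed[off + 1] > off_thr && state[off + 1] == "free") off <- off + 1L
      if (off < n) off <- off + 1L # first sample back below the offset threshold
      if ((off - on + 1L) < min_sacc) next
      if (any(state[on:off] != "free")) next
      state[on:off] <- "saccade"
      sacc[[length(sacc) + 1]] <- list(on = on, off = off, off_thr = off_thr)
    }
  }
  # glissades: wobbles within the glissade window after each saccade offset
  gl_w <- round(p$glissade_window_s * fs)
  for (s in sacc) {
    j0 <- s$off + 1L
    if (j0 > n) next
    j1 <- min(n, s$off + gl_w)
    win <- j0:j1
    over <- win[speed[win] > onset_thr & state[win] == "free"]
    if (length(over) == 0) next
    g_end <- max(over)
    while (g_end < n && speed[g_end + 1] > s$off_thr && state[g_end + 1] == "free") g_end <- g_end + 1L
    if (all(state[j0:g_end] == "free")) state[j0:g_end] <- "glissade"
  }

  # assemble events
  ev <- list()
  add <- function(kind, on, off, centroid = FALSE) {
    ev[[length(ev) + 1]] <<- data.frame(
      kind = kind, onset = t[on], offset = t[off],
      start_x = x[on], start_y = y[on],
      centroid_x = if (centroid) mean(xs[on:off]) else NA_real_,
      centroid_y = if (centroid) mean(ys[on:off]) else NA_real_,
      peak_vel_deg_s = max(speed_raw[on:off])
    )
  }
  for (kind in c("saccade", "glissade", "artifact")) {
    rr <- runs_of(state == kind)
    if (nrow(rr) > 0) for (i in seq_len(nrow(rr))) add(kind, rr[i, 1], rr[i, 2])
  }
  min_fix <- round(p$min_fix_dur * fs)
  rr <- runs_of(state == "free")
  if (nrow(rr) > 0) {
    for (i in seq_len(nrow(rr))) {
      if ((rr[i, 2] - rr[i, 1] + 1L) >= min_fix) add("fixation", rr[i, 1], rr[i, 2], centroid = TRUE)
    }
  }
  if (length(ev) == 0) return(NULL)
  do.call(rbind, ev)
}

#' Write / read gaze event tables
#' @param events event data.frame from [detect_events()].
#' @param path CSV path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_gaze_csv <- function(path) {
  df <- utils::read.csv(path)
  names(df)[names(df) == "t_s"] <- "t"
  names(df)[names(df) == "x_px"] <- "x"
  names(df)[names(df) == "y_px"] <- "y"
  df
}
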