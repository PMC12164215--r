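#' Generate a gaze scanpath with known ground-truth events
#'
#' Builds a gaze sample stream from a fixation plan. Fixation epochs are the
#' planned target positions plus isotropic Gaussian noise; between successive
#' targets the eye moves along a logistic position sigmoid (bell-shaped
#' velocity), whose duration follows the main-sequence rule
#' `21 ms + 2.2 ms/deg` of amplitude. The closed-form peak velocity of the
#' sigmoid, `amplitude * alpha / (4 * duration)` with shape constant
#' `alpha = 8`, is recorded in the returned truth table so detectors can be
#' scored against it.
#'
#' @param plan data.frame with columns `x_px`, `y_px`, `duration_s`: one row
#'   per planned fixation.
#' @param fs sampling rate in Hz (default 500).
#' @param noise_sd_deg isotropic fixation noise SD in degrees.
#' @param geometry a [screen_geometry()].
#' @param seed RNG seed.
#' @return list with `samples` (data.frame `t`, `x`, `y`, `valid`) and
#'   `events` (data.frame `kind`, `onset`, `offset`, `start_x`, `start_y`,
#'   `peak_vel_deg_s`), events non-overlapping and time-ordered.
#' @export
gen_gaze_scanpath <- function(plan, fs = 500, noise_sd_deg = 0.1,
                              geometry = screen_geometry(), seed = 1) {
  stopifnot(is.data.frame(plan), all(c("x_px", "y_px", "duration_s") %in% names(plan)))
  if (fs <= 0) stop("gen_gaze_scanpath: fs must be positive", call. = FALSE)
  if (any(plan$duration_s < 0.04)) {
    stop("gen_gaze_scanpath: planned fixations must last at least 40 ms", call. = FALSE)
  }
  if (any(plan$x_px < 0 | plan$x_px > geometry$width_px |
          plan$y_px < 0 | plan$y_px > geometry$height_px)) {
    stop("gen_gaze_scanpath: target off-screen", call. = FALSE)
  }
  set.seed(seed)
  # logistic shape constant: peak velocity = amp * alpha / (4 * dur); with the
  # main-sequence duration rule this saturates near 900 deg/s for very large
  # saccades, in the physiological range
  alpha <- 8
  dpp_x <- px_to_deg(1, "horizontal", geometry)
  dpp_y <- px_to_deg(1, "vertical", geometry)
  noise_px_x <- noise_sd_deg / dpp_x
  noise_px_y <- noise_sd_deg / dpp_y

  nfix <- nrow(plan)
  x <- numeric(0); y <- numeric(0)
  ev <- vector("list", 2 * nfix - 1)
  t_cursor <- 0 # start time of next segment, in samples
  for (i in seq_len(nfix)) {
    nf <- round(plan$duration_s[i] * fs)
    fx <- plan$x_px[i] + stats::rnorm(nf, sd = noise_px_x)
    fy <- plan$y_px[i] + stats::rnorm(nf, sd = noise_px_y)
    ev[[2 * i - 1]] <- data.frame(
      kind = "fixation",
      onset = t_cursor / fs, offset = (t_cursor + nf - 1) / fs,
      start_x = plan$x_px[i], start_y = plan$y_px[i],
      peak_vel_deg_s = NA_real_
    )
    x <- c(x, fx); y <- c(y, fy)
    t_cursor <- t_cursor + nf
    if (i < nfix) {
      dx <- plan$x_px[i + 1] - plan$x_px[i]
      dy <- plan$y_px[i + 1] - plan$y_px[i]
      amp <- sqrt((abs(dx) * dpp_x)^2 + (abs(dy) * dpp_y)^2)
      dur <- 0.021 + 0.0022 * amp
      ns <- max(2L, round(dur * fs))
      tt <- (seq_len(ns)) / (ns + 1) # interior points of (0, 1)
      sig <- 1 / (1 + exp(-alpha * (tt - 0.5)))
      sig <- (sig - sig[1]) / (sig[ns] - sig[1]) # pin ends to the targets
      x <- c(x, plan$x_px[i] + dx * sig)
      y <- c(y, plan$y_px[i] + dy * sig)
      ev[[2 * i]] <- data.frame(
        kind = "saccade",
        onset = t_cursor / fs, offset = (t_cursor + ns - 1) / fs,
        start_x = plan$x_px[i], start_y = plan$y_px[i],
        peak_vel_deg_s = amp * alpha / (4 * dur)
      )
      t_cursor <- t_cursor + ns
    }
  }
  n <- length(x)
  samples <- data.frame(t = (seq_len(n) - 1) / fs, x = x, y = y, valid = TRUE)
  events <- do.call(rbind, ev)
  list(samples = samples, events = events)
}

#' Default dyad frame layout for synthetic AOI tracks
#'
#' Places the two interactants in the left and right halves of the frame.
#' Each interactant has a fixed body ellipse (the body AOI, constant across
#' a dyad's segments) chosen large enough to contain the wandering head and
#' hand circles.
#'
#' @param width_px,height_px frame size in pixels.
#' @return list with `persons`: per person a list of body ellipse
#'   (`cx, cy, rx, ry`) and anchor points for head and two hands.
#' @export
dyad_layout <- function(width_px = 1920, height_px = 1080) {
  mk <- function(cx) {
    list(
      body = list(cx = cx, cy = height_px * 0.55, rx = width_px * 0.17, ry = height_px * 0.42),
      head = c(cx, height_px * 0.30),
      hand_l = c(cx - width_px * 0.07, height_px * 0.72),
      hand_r = c(cx + width_px * 0.07, height_px * 0.72)
    )
  }
  list(persons = list(p1 = mk(width_px * 0.27), p2 = mk(width_px * 0.73)),
       width_px = width_px, height_px = height_px)
}

# Smoothed random walk pulled toward an anchor, confined to the body ellipse
# (with a small margin so the drawn AOI circle itself stays inside).
ou_walk_confined <- function(n, anchor, body, wander_sd, margin = 0.9, rho = 0.98) {
  x <- numeric(n); y <- numeric(n)
  px <- anchor[1]; py <- anchor[2]
  for (t in seq_len(n)) {
    px <- anchor[1] + rho * (px - anchor[1]) + stats::rnorm(1, sd = wander_sd)
    py <- anchor[2] + rho * (py - anchor[2]) + stats::rnorm(1, sd = wander_sd)
    d <- sqrt(((px - body$cx) / body$rx)^2 + ((py - body$cy) / body$ry)^2)
    if (d > margin) { # project back onto the margin ellipse
      px <- body$cx + (px - body$cx) * margin / d
      py <- body$cy + (py - body$cy) * margin / d
    }
    x[t] <- px; y[t] <- py
  }
  cbind(x, y)
}

#' Generate dynamic AOI keypoint tracks for one dyad
#'
#' Head and hand AOI centres follow smoothed random walks (an
#' Ornstein-Uhlenbeck pull toward per-part anchor points) confined to each
#' interactant's body ellipse; the body regions themselves are static per
#' dyad. AOI diameters follow the study stimuli: 210 px heads, 140 px hands.
#'
#' @param n_frames number of frames.
#' @param fps frame rate.
#' @param layout a [dyad_layout()].
#' @param wander_sd_px per-frame random-walk innovation SD in pixels.
#' @param dyad_id identifier token.
#' @param seed RNG seed.
#' @return object of class `aoi_track`: list with `dyad_id`, `fps`,
#'   `n_frames`, `centers` (data.frame `frame, part, person, kind, x, y`),
#'   `bodies` (per-person ellipse), `head_diameter_px`, `hand_diameter_px`.
#' @export
gen_aoi_tracks <- function(n_frames, fps = 25, layout = dyad_layout(),
                           wander_sd_px = 2, dyad_id = "dyad", seed = 1) {
  if (n_frames <= 0) stop("gen_aoi_tracks: n_frames must be positive", call. = FALSE)
  set.seed(seed)
  rows <- list()
  for (pn in names(layout$persons)) {
    p <- layout$persons[[pn]]
    parts <- list(head = p$head, hand_l = p$hand_l, hand_r = p$hand_r)
    for (part in names(parts)) {
      tr <- ou_walk_confined(n_frames, parts[[part]], p$body, wander_sd_px)
      rows[[paste(pn, part)]] <- data.frame(
        frame = seq_len(n_frames), part = paste(pn, part, sep = "_"),
        person = pn, kind = if (part == "head") "head" else "hand",
        x = tr[, 1], y = tr[, 2]
      )
    }
  }
  structure(
    list(dyad_id = dyad_id, fps = fps, n_frames = as.integer(n_frames),
         centers = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         bodies = lapply(layout$persons, `[[`, "body"),
         head_diameter_px = 210, hand_diameter_px = 140),
    class = "aoi_track"
  )
}
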