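in_ellipse <- function(x, y, e) {
  ((x - e$cx) / e$rx)^2 + ((y - e$cy) / e$ry)^2 <= 1
}

#' Classify a fixation against the dynamic AOIs of one frame
#'
#' The fixation's starting point (its first-sample position) is tested
#' against the AOI geometry of the video frame containing the fixation
#' onset: circular head and hand AOIs at that frame's tracked centres
#' (membership = Euclidean distance <= radius, inclusive) and the static
#' per-person body regions. Any head or hand membership also counts as body
#' membership (nested-AOI rule). A fixation outside every AOI yields the
#' empty set.
#'
#' @param fixation one-row data.frame (or list) with `onset`, `start_x`,
#'   `start_y`.
#' @param track an `aoi_track` from [gen_aoi_tracks()] (or equivalent).
#' @param segment_start_t segment start time in seconds; the frame index is
#'   `floor((onset - segment_start_t) * fps)`, clamped to the track.
#' @return character vector, a subset of `c("head", "hand", "body")`.
#' @export
classify_fixation_aois <- function(fixation, track, segment_start_t = 0) {
  stopifnot(inherits(track, "aoi_track"))
  if (fixation$onset < segment_start_t) {
    stop("classify_fixation_aois: fixation onset precedes segment start", call. = FALSE)
  }
  fr <- floor((fixation$onset - segment_start_t) * track$fps) + 1L
  fr <- min(max(fr, 1L), track$n_frames)
  cen <- track$centers[track$centers$frame == fr, ]
  px <- fixation$start_x; py <- fixation$start_y
  d <- sqrt((cen$x - px)^2 + (cen$y - py)^2)
  r <- ifelse(cen$kind == "head", track$head_diameter_px / 2, track$hand_diameter_px / 2)
  hit <- d <= r
  out <- character(0)
  if (any(hit & cen$kind == "head")) out <- c(out, "head")
  if (any(hit & cen$kind == "hand")) out <- c(out, "hand")
  body_hit <- any(vapply(track$bodies, function(b) in_ellipse(px, py, b), logical(1)))
  if (length(out) > 0 || body_hit) out <- c(out, "body")
  out
}

#' Dwell-time proportions and saccade count for one segment
#'
#' Sums fixation durations per AOI class (a fixation contributes to every
#' AOI its start point falls on) and divides by the total duration of all
#' fixations regardless of location, so proportions are comparable across
#' observers with different overall fixation time. Also counts the saccade
#' events in the segment (for the saccade-rate model).
#'
#' @param events event data.frame from [detect_events()].
#' @param track an `aoi_track`.
#' @param segment_start_t segment start time (s).
#' @return list with `dwell` (named proportions for head, hand, body),
#'   `n_saccades`, and `total_fix_s`. If the segment has no fixation time
#'   the dwell entries are `NA` (undefined cell, to be dropped and logged).
#' @export
compute_dwell_proportions <- function(events, track, segment_start_t = 0) {
  fix <- events[events$kind == "fixation", , drop = FALSE]
  n_sacc <- sum(events$kind == "saccade")
  if (nrow(fix) == 0) {
    return(list(dwell = c(head = NA_real_, hand = NA_real_, body = NA_real_),
                n_saccades = n_sacc, total_fix_s = 0))
  }
  dur <- fix$offset - fix$onset
  tot <- sum(dur)
  if (tot <= 0) {
    return(list(dwell = c(head = NA_real_, hand = NA_real_, body = NA_real_),
                n_saccades = n_sacc, total_fix_s = 0))
  }
  acc <- c(head = 0, hand = 0, body = 0)
  for (i in seq_len(nrow(fix))) {
    cls <- classify_fixation_aois(fix[i, ], track, segment_start_t)
    for (a in cls) acc[a] <- acc[a] + dur[i]
  }
  list(dwell = acc / tot, n_saccades = n_sacc, total_fix_s = tot)
}

#' Aggregate per-segment dwell results to the modelling grain
#'
#' Takes per-segment dwell proportions and computes the median per
#' participant x dyad x condition x AOI — six values per participant for
#' each dyad when both synchrony conditions are present (three AOIs x two
#' conditions). Segment-level saccade counts are retained separately for
#' the Poisson model.
#'
#' @param records data.frame with columns `participant_id`, `group`,
#'   `dyad_id`, `dyad_type`, `condition`, `segment`, `head`, `hand`, `body`,
#'   `n_saccades` (one row per observed segment).
#' @return list with `dwell` (aggregated data.frame: participant_id, group,
#'   dyad_id, dyad_type, condition, aoi, dwell_prop) and `saccades` (the
#'   segment-grain records).
#' @export
aggregate_dwell <- function(records) {
  need <- c("participant_id", "dyad_id", "condition", "head", "hand", "body")
  if (!all(need %in% names(records))) {
    stop("aggregate_dwell: records lack required columns", call. = FALSE)
  }
  if (!all(records$condition %in% c("high", "low"))) {
    stop("aggregate_dwell: unknown condition label", call. = FALSE)
  }
  keep <- !is.na(records$head)
  dropped <- sum(!keep)
  if (dropped > 0) message(sprintf("aggregate_dwell: dropping %d undefined-dwell segments", dropped))
  rec <- records[keep, , drop = FALSE]
  long <- do.call(rbind, lapply(c("head", "hand", "body"), function(a) {
    data.frame(rec[c("participant_id", "dyad_id", "condition")],
               group = if ("group" %in% names(rec)) rec$group else NA,
               dyad_type = if ("dyad_type" %in% names(rec)) rec$dyad_type else NA,
               aoi = a, value = rec[[a]])
  }))
  agg <- stats::aggregate(value ~ participant_id + group + dyad_id + dyad_type + condition + aoi,
                          data = long, FUN = stats::median)
  names(agg)[names(agg) == "value"] <- "dwell_prop"
  one_cond <- stats::aggregate(condition ~ participant_id + dyad_id, data = agg,
                               FUN = function(z) length(unique(z)))
  if (any(one_cond$condition < 2)) {
    warning(sprintf("aggregate_dwell: %d participant-dyad cells have only one condition",
                    sum(one_cond$condition < 2)))
  }
  list(dwell = agg, saccades = rec)
}
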