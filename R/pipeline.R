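#' Trial filtering and rating aggregation
#'
#' Drops trials without a completed rating (no response within the 4-s
#' window), excludes participants who completed fewer than two thirds of the
#' `n_total` trials, and averages ratings per participant x dyad x
#' synchrony condition — two values per participant for each dyad when both
#' conditions survive.
#'
#' @param trials trial-level data.frame with `participant_id`, `group`,
#'   `dyad_id`, `dyad_type`, `condition`, `rating` (NA = missed).
#' @param n_total nominal number of trials per participant (default 64).
#' @return aggregated data.frame (`participant_id`, `group`, `dyad_id`,
#'   `dyad_type`, `condition`, `rating`), with attributes `excluded`
#'   (participant roster) and `n_dropped_trials`.
#' @export
prepare_behavioural_table <- function(trials, n_total = 64) {
  stopifnot(all(c("participant_id", "dyad_id", "condition", "rating") %in% names(trials)))
  done <- !is.na(trials$rating)
  n_dropped <- sum(!done)
  completed <- tapply(done, trials$participant_id, sum)
  excluded <- names(completed)[completed < (2 / 3) * n_total]
  keep <- done & !(trials$participant_id %in% excluded)
  surv <- trials[keep, , drop = FALSE]
  if (nrow(surv) == 0) stop("prepare_behavioural_table: no surviving participants", call. = FALSE)
  agg <- stats::aggregate(rating ~ participant_id + group + dyad_id + dyad_type + condition,
                          data = surv, FUN = mean)
  agg <- agg[order(agg$participant_id, agg$dyad_id, agg$condition), ]
  rownames(agg) <- NULL
  attr(agg, "excluded") <- excluded
  attr(agg, "n_dropped_trials") <- n_dropped
  agg
}

#' Group-level gaze behaviour parameters for the synthetic observers
#'
#' Generative gaze profiles: mean saccades per 10-s segment (ASD 17.7,
#' COMP 20.2 — the saccade-rate model's group predictions used as truth)
#' and the probability that a planned fixation targets a head, hand, body
#' or off-person location. The head probabilities differ between groups so
#' that head dwell is about 10 percentage points lower in the ASD group.
#'
#' @return named list per group.
#' @export
gaze_profiles <- function() {
  list(
    ASD  = list(sacc_rate = 17.7, p_target = c(head = 0.40, hand = 0.25, body = 0.25, out = 0.10)),
    COMP = list(sacc_rate = 20.2, p_target = c(head = 0.50, hand = 0.20, body = 0.20, out = 0.10))
  )
}

# Cut an aoi_track to a half-open frame window [start, end), reindexed to 1..W.
track_window <- function(track, start_frame, end_frame) {
  sel <- track$centers$frame >= start_frame & track$centers$frame < end_frame
  cen <- track$centers[sel, , drop = FALSE]
  cen$frame <- cen$frame - start_frame + 1L
  structure(
    list(dyad_id = track$dyad_id, fps = track$fps,
         n_frames = as.integer(end_frame - start_frame),
         centers = cen, bodies = track$bodies,
         head_diameter_px = track$head_diameter_px,
         hand_diameter_px = track$hand_diameter_px),
    class = "aoi_track")
}

# Sample one planned fixation target of a given kind at a given frame.
sample_target <- function(kind, track, frame, layout_wh = c(1920, 1080)) {
  cen <- track$centers[track$centers$frame == frame, ]
  if (kind %in% c("head", "hand")) {
    cand <- cen[cen$kind == kind, ]
    row <- cand[sample.int(nrow(cand), 1), ]
    r <- if (kind == "head") track$head_diameter_px / 2 else track$hand_diameter_px / 2
    ang <- stats::runif(1, 0, 2 * pi); rad <- stats::runif(1, 0, 0.4 * r)
    c(row$x + rad * cos(ang), row$y + rad * sin(ang))
  } else if (kind == "body") {
    b <- track$bodies[[sample.int(length(track$bodies), 1)]]
    for (i in 1:30) {
      ang <- stats::runif(1, 0, 2 * pi); rad <- sqrt(stats::runif(1)) * 0.85
      p <- c(b$cx + rad * b$rx * cos(ang), b$cy + rad * b$ry * sin(ang))
      d <- sqrt((cen$x - p[1])^2 + (cen$y - p[2])^2)
      rr <- ifelse(cen$kind == "head", track$head_diameter_px / 2, track$hand_diameter_px / 2)
      if (all(d > rr + 10)) return(p)
    }
    p
  } else { # off-person: screen centre strip between the two bodies
    c(stats::runif(1, layout_wh[1] * 0.46, layout_wh[1] * 0.54),
      stats::runif(1, layout_wh[2] * 0.1, layout_wh[2] * 0.9))
  }
}

# Build a fixation plan for one observer watching one segment.
plan_segment_gaze <- function(track_seg, profile, duration_s = 10, seed = 1) {
  set.seed(seed)
  n_sacc <- max(4L, min(35L, stats::rpois(1, profile$sacc_rate)))
  n_fix <- n_sacc + 1L
  kinds <- sample(names(profile$p_target), n_fix, replace = TRUE, prob = profile$p_target)
  frames_at <- pmax(1L, pmin(track_seg$n_frames,
                             round(seq(1, track_seg$n_frames, length.out = n_fix))))
  xy <- t(vapply(seq_len(n_fix), function(i) {
    sample_target(kinds[i], track_seg, frames_at[i])
  }, numeric(2)))
  # fixation durations fill the segment after saccade flight time
  amps_px <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  sacc_time <- sum(0.021 + 0.0022 * amps_px * 0.0279) # rough deg/px at this geometry
  budget <- max(0.2 * n_fix, duration_s - sacc_time)
  w <- stats::rgamma(n_fix, shape = 4)
  dur <- pmax(0.12, budget * w / sum(w))
  data.frame(x_px = pmin(pmax(xy[, 1], 5), 1915),
             y_px = pmin(pmax(xy[, 2], 5), 1075),
             duration_s = dur, kind = kinds)
}

#' Assemble the default study configuration
#'
#' All tunable knobs of [run_study()] in one list: generator sizes and
#' seeds, screen geometry, motion-energy threshold, cross-correlation
#' window/lag/step, selection k, gaze-detection parameters, AOI wander, the
#' generative effects, and sampler settings.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param n_observers_per_group observers per group `c(ASD, COMP)`.
#' @param n_frames frames per dyad video.
#' @param fps frame rate.
#' @param chains,draws,warmup sampler settings for all models.
#' @param rhat_max convergence tolerance passed to [fit_mixed_model()].
#' @param fit_models run the Bayesian models (disable to stop after the
#'   measurement stages).
#' @param mea_frames render pixel-flip frames and re-extract motion energy
#'   (round-trip demonstration) instead of using the generated series
#'   directly.
#' @return config list.
#' @export
study_config <- function(seed = 1, n_observers_per_group = c(6, 6),
                         n_frames = 7500, fps = 25,
                         chains = 2, draws = 1500, warmup = 1000,
                         rhat_max = 1.01, fit_models = TRUE, mea_frames = FALSE) {
  list(
    seed = as.integer(seed),
    n_observers_per_group = n_observers_per_group,
    n_frames = n_frames, fps = fps,
    geometry = screen_geometry(),
    mea_threshold = 10, mea_frames = mea_frames,
    window_s = 10, lag_s = 3, step_s = 1, k = 4,
    gaze = gaze_params(), gaze_fs = 500, gaze_noise_deg = 0.1,
    wander_sd_px = 2,
    design_effects = c(dyad_type_c = -3.87, ips_c = 0.83, group_c = 1.07,
                       "dyad_type_c:ips_c" = -0.06, "group_c:dyad_type_c" = 0.24),
    grand_mean = 55, sd_participant = 8, sd_dyad = 4, sigma = 10, miss_prob = 0.06,
    chains = chains, draws = draws, warmup = warmup, rhat_max = rhat_max,
    fit_models = fit_models
  )
}

#' Run the full synthetic study end-to-end
#'
#' Wires all stages together: simulate coupled dyad motion; (optionally)
#' render frames and re-extract motion energy; select balanced high/low
#' synchrony segments; simulate observers' gaze over the segments and detect
#' events; classify fixations against the dynamic AOIs and aggregate dwell;
#' generate and aggregate impression ratings; fit the confirmatory rating
#' and dwell models and the exploratory saccade-count (Poisson) and
#' gaze-predicts-rating models; and evaluate the preregistered hypothesis
#' list. Everything derives from `config$seed`, so two runs with the same
#' config are identical.
#'
#' @param config list from [study_config()].
#' @param outdir optional directory; when given, all tables are written as
#'   CSV and a JSON manifest records seeds and parameters.
#' @return list with `segments`, `trials`, `ratings` (aggregated),
#'   `gaze_records` (per segment), `dwell` (aggregated), `fits`,
#'   `hypotheses`, `manifest`.
#' @export
run_study <- function(config = study_config(), outdir = NULL) {
  if (sum(config$n_observers_per_group) == 0) {
    stop("run_study: empty study (zero observers)", call. = FALSE)
  }
  log_stage <- function(...) message(sprintf(...))

  ## --- stage 1: dyad motion ------------------------------------------------
  specs <- default_dyads(n_frames = config$n_frames, fps = config$fps,
                         seed = config$seed * 101L)
  dyads <- lapply(specs, function(sp) {
    d <- gen_coupled_motion(sp)
    d$dyad_type <- sp$dyad_type
    d
  })
  names(dyads) <- vapply(specs, `[[`, character(1), "dyad_id")
  log_stage("simulate: %d dyads x %d frames", length(dyads), config$n_frames)

  ## --- stage 2: motion energy (optional pixel round trip) ------------------
  if (isTRUE(config$mea_frames)) {
    roi <- matrix(TRUE, 32, 32)
    dyads <- lapply(dyads, function(d) {
      for (nm in c("a", "b")) {
        s <- d[[nm]]
        counts <- round(s$values * 100)
        counts[1] <- 0
        stopifnot(max(counts) <= sum(roi))
        raw <- motion_energy_series(counts, fps = s$fps, dyad_id = s$dyad_id,
                                    person_id = s$person_id, roi_area_px = sum(roi))
        frames <- gen_motion_frames(raw, frame_shape = dim(roi), roi_mask = roi,
                                    threshold = config$mea_threshold,
                                    seed = config$seed + nchar(s$dyad_id))
        mea <- compute_mea(frames, roi, threshold = config$mea_threshold,
                           fps = s$fps, dyad_id = s$dyad_id, person_id = s$person_id)
        d[[nm]] <- rescale_mea(mea)
      }
      d
    })
    log_stage("mea: frame round-trip re-extraction done")
  }

  ## --- stage 3: segment selection ------------------------------------------
  segments <- select_segments(dyads, window_s = config$window_s,
                              lag_s = config$lag_s, step_s = config$step_s,
                              k = config$k)
  segments$segment_id <- sprintf("%s_%s_%d", segments$dyad_id, segments$condition,
                                 stats::ave(seq_len(nrow(segments)),
                                            segments$dyad_id, segments$condition,
                                            FUN = seq_along))
  log_stage("select: %d segments (%d dyads x 2 conditions x k=%d)",
            nrow(segments), length(dyads), config$k)

  ## --- stage 4: ratings -----------------------------------------------------
  design <- study_design(
    n_observers_per_group = config$n_observers_per_group,
    dyads = specs, grand_mean = config$grand_mean, effects = config$design_effects,
    sd_participant = config$sd_participant, sd_dyad = config$sd_dyad,
    sigma = config$sigma, n_trials_per_cell = config$k,
    miss_prob = config$miss_prob, seed = config$seed * 7L)
  trials <- gen_ratings(design)
  seg_key <- sprintf("%s_%s_%d", trials$dyad_id, trials$condition, trials$trial)
  trials$segment_id <- seg_key
  ratings <- prepare_behavioural_table(trials, n_total = nrow(segments))
  log_stage("prepare: %d trials -> %d aggregated rating cells (%d excluded, %d missed)",
            nrow(trials), nrow(ratings), length(attr(ratings, "excluded")),
            attr(ratings, "n_dropped_trials"))

  ## --- stage 5: gaze + dwell ------------------------------------------------
  profiles <- gaze_profiles()
  tracks <- lapply(seq_along(specs), function(i) {
    gen_aoi_tracks(config$n_frames, fps = config$fps,
                   wander_sd_px = config$wander_sd_px,
                   dyad_id = specs[[i]]$dyad_id, seed = config$seed * 13L + i)
  })
  names(tracks) <- names(dyads)
  observers <- unique(trials[, c("participant_id", "group")])
  gaze_records <- list()
  for (oi in seq_len(nrow(observers))) {
    obs <- observers[oi, ]
    for (si in seq_len(nrow(segments))) {
      seg <- segments[si, ]
      tr_seg <- track_window(tracks[[seg$dyad_id]], seg$start_frame, seg$end_frame)
      seed_i <- (config$seed * 100003L + oi * 1009L + si) %% .Machine$integer.max
      plan <- plan_segment_gaze(tr_seg, profiles[[obs$group]],
                                duration_s = config$window_s, seed = seed_i)
      sp <- gen_gaze_scanpath(plan[, c("x_px", "y_px", "duration_s")],
                              fs = config$gaze_fs, noise_sd_deg = config$gaze_noise_deg,
                              geometry = config$geometry, seed = seed_i + 1L)
      ev <- detect_events(sp$samples, config$geometry, config$gaze)
      dw <- compute_dwell_proportions(ev, tr_seg, segment_start_t = 0)
      gaze_records[[length(gaze_records) + 1]] <- data.frame(
        participant_id = obs$participant_id, group = obs$group,
        dyad_id = seg$dyad_id, dyad_type = seg$dyad_type,
        condition = seg$condition, segment = seg$segment_id,
        head = dw$dwell[["head"]], hand = dw$dwell[["hand"]], body = dw$dwell[["body"]],
        n_saccades = dw$n_saccades, n_true_saccades = sum(sp$events$kind == "saccade"))
    }
  }
  gaze_records <- do.call(rbind, gaze_records)
  dwell_agg <- aggregate_dwell(gaze_records)
  log_stage("gaze/dwell: %d observer-segments -> %d aggregated dwell cells",
            nrow(gaze_records), nrow(dwell_agg$dwell))

  out <- list(segments = segments, trials = trials, ratings = ratings,
              gaze_records = gaze_records, dwell = dwell_agg$dwell,
              design = design)

  ## --- stage 6: models + hypotheses ----------------------------------------
  if (isTRUE(config$fit_models)) {
    ms <- function(outcome, fixed, random, likelihood = "gaussian", seed_off = 0,
                   thin = 1, warmup = config$warmup, draws = config$draws) {
      model_spec(outcome, fixed, random, likelihood = likelihood,
                 chains = config$chains, draws = draws,
                 warmup = warmup, thin = thin, seed = config$seed + seed_off)
    }
    fit_ratings <- fit_mixed_model(ratings, ms(
      "rating", ~ group_c * dyad_type_c * ips_c,
      list(participant_id = "1", dyad_id = "1"), seed_off = 11),
      rhat_max = config$rhat_max)

    dwell_tab <- dwell_agg$dwell
    dwell_tab$dwell_pct <- dwell_tab$dwell_prop * 100
    re_p <- c("1", "ips_c", "dyad_type_c", "aoi1", "aoi2",
              "ips_c:dyad_type_c", "ips_c:aoi1", "ips_c:aoi2",
              "dyad_type_c:aoi1", "dyad_type_c:aoi2")
    re_d <- c("1", "group_c", "ips_c", "aoi1", "aoi2",
              "group_c:ips_c", "group_c:aoi1", "group_c:aoi2",
              "ips_c:aoi1", "ips_c:aoi2")
    # the dwell model has many weakly-informed variance terms; it runs the
    # base samplers on long thinned chains
    fit_dwell <- fit_mixed_model(dwell_tab, ms(
      "dwell_pct", ~ group_c * dyad_type_c * ips_c * (aoi1 + aoi2),
      list(participant_id = re_p, dyad_id = re_d), seed_off = 12,
      thin = 5, warmup = max(config$warmup, 3000)),
      rhat_max = config$rhat_max)

    fit_sacc <- fit_mixed_model(gaze_records, ms(
      "n_saccades", ~ group_c * dyad_type_c * ips_c,
      list(participant_id = "1", dyad_id = "1"),
      likelihood = "poisson", seed_off = 13), rhat_max = config$rhat_max)

    gz <- merge(
      stats::aggregate(cbind(head, hand, body, n_saccades) ~ participant_id + dyad_id,
                       data = gaze_records, FUN = mean),
      stats::aggregate(rating ~ participant_id + dyad_id, data = ratings, FUN = mean))
    for (cc in c("head", "hand", "body", "n_saccades")) {
      gz[[paste0("z_", cc)]] <- as.numeric(scale(gz[[cc]]))
    }
    fit_gaze_rating <- fit_mixed_model(gz, ms(
      "rating", ~ z_head + z_hand + z_body + z_n_saccades,
      list(participant_id = "1", dyad_id = "1"), seed_off = 14),
      rhat_max = config$rhat_max)

    fits <- list(ratings = fit_ratings, dwell = fit_dwell,
                 saccades = fit_sacc, gaze_rating = fit_gaze_rating)
    out$fits <- fits
    out$hypotheses <- hypothesis_table(fits)
    log_stage("fit: 4 models sampled; %d hypotheses evaluated", nrow(out$hypotheses))
  }

  out$manifest <- list(
    package = "dyadsync", seed = config$seed,
    n_observers_per_group = config$n_observers_per_group,
    n_frames = config$n_frames, fps = config$fps,
    window_s = config$window_s, lag_s = config$lag_s, step_s = config$step_s,
    k = config$k, gaze = config$gaze, gaze_fs = config$gaze_fs,
    effects = as.list(config$design_effects),
    sampler = list(chains = config$chains, draws = config$draws, warmup = config$warmup))

  if (!is.null(outdir)) write_study_outputs(out, outdir)
  out
}

#' Preregistered hypothesis decision table
#'
#' One row per confirmatory hypothesis (directed, alpha = 0.05: dyad type,
#' synchrony, observer group, synchrony x dyad type, group x dyad type on
#' ratings) and the undirected dwell interactions (alpha = 0.025: group x
#' AOI, synchrony x AOI, dyad type x AOI), plus the exploratory saccade
#' group effect.
#'
#' @param fits named list with elements `ratings`, `dwell`, `saccades`.
#' @return data.frame of hypothesis results.
#' @export
hypothesis_table <- function(fits) {
  row <- function(model, label, ...) {
    cbind(data.frame(model = model, hypothesis = label), ...)
  }
  rbind(
    row("ratings", "dyad_type < 0 (mixed rated lower)",
        test_hypothesis(fits$ratings, "b_dyad_type_c", directed = TRUE, direction = "<")),
    row("ratings", "ips > 0 (high synchrony rated higher)",
        test_hypothesis(fits$ratings, "b_ips_c", directed = TRUE, direction = ">")),
    row("ratings", "group > 0 (observer-group difference)",
        test_hypothesis(fits$ratings, "b_group_c", directed = TRUE, direction = ">")),
    row("ratings", "ips:dyad_type < 0 (reduced synchrony effect in mixed dyads)",
        test_hypothesis(fits$ratings, "b_dyad_type_c:ips_c", directed = TRUE, direction = "<")),
    row("ratings", "group:dyad_type > 0 (reduced dyad-type effect in ASD observers)",
        test_hypothesis(fits$ratings, "b_group_c:dyad_type_c", directed = TRUE, direction = ">")),
    row("dwell", "group x AOI (head axis), undirected",
        test_hypothesis(fits$dwell, "b_group_c:aoi1", directed = FALSE)),
    row("dwell", "ips x AOI (head axis), undirected",
        test_hypothesis(fits$dwell, "b_ips_c:aoi1", directed = FALSE)),
    row("dwell", "dyad_type x AOI (head axis), undirected",
        test_hypothesis(fits$dwell, "b_dyad_type_c:aoi1", directed = FALSE)),
    row("saccades", "group < 0 (fewer saccades in ASD observers)",
        test_hypothesis(fits$saccades, "b_group_c", directed = TRUE, direction = "<"))
  )
}

write_study_outputs <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, nm) utils::write.csv(df, file.path(outdir, nm), row.names = FALSE)
  wr(out$segments, "segments.csv")
  wr(out$trials, "trials.csv")
  wr(out$ratings, "ratings_aggregated.csv")
  wr(out$gaze_records, "gaze_records.csv")
  wr(out$dwell, "dwell_aggregated.csv")
  if (!is.null(out$hypotheses)) wr(out$hypotheses, "hypotheses.csv")
  if (!is.null(out$fits)) {
    for (nm in names(out$fits)) {
      wr(posterior_summary(out$fits[[nm]]), sprintf("posterior_%s.csv", nm))
    }
  }
  jsonlite::write_json(out$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
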