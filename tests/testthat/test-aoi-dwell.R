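mk_track <- function(n_frames = 250, wander = 0, seed = 1) {
  gen_aoi_tracks(n_frames, fps = 25, wander_sd_px = wander, dyad_id = "d1", seed = seed)
}

test_that("AOI tracks have the requested length and honour zero wander", {
  tr <- mk_track(250, wander = 0)
  expect_equal(max(tr$centers$frame), 250)
  for (pp in unique(tr$centers$part)) {
    sub <- tr$centers[tr$centers$part == pp, ]
    expect_equal(nrow(sub), 250)
    expect_true(all(sub$x == sub$x[1] & sub$y == sub$y[1]))
  }
  expect_error(gen_aoi_tracks(0), "positive")
})

test_that("wandering head centres stay inside their body ellipse", {
  for (s in 1:100) {
    tr <- gen_aoi_tracks(100, wander_sd_px = 6, seed = s)
    heads <- tr$centers[tr$centers$kind == "head", ]
    for (pn in unique(heads$person)) {
      b <- tr$bodies[[pn]]
      h <- heads[heads$person == pn, ]
      expect_true(all(((h$x - b$cx) / b$rx)^2 + ((h$y - b$cy) / b$ry)^2 <= 1))
    }
  }
})

test_that("fixation start points classify by inclusive circle and nested body rule", {
  tr <- mk_track()
  head1 <- tr$centers[tr$centers$part == "p1_head" & tr$centers$frame == 1, ]
  # dead centre of a head AOI: head and (nested) body
  fx <- list(onset = 0, start_x = head1$x, start_y = head1$y)
  expect_setequal(classify_fixation_aois(fx, tr), c("head", "body"))
  # far corner: nothing
  fx2 <- list(onset = 0, start_x = 5, start_y = 5)
  expect_identical(classify_fixation_aois(fx2, tr), character(0))
  # exactly on the circle boundary is inside (inclusive rule)
  fx3 <- list(onset = 0, start_x = head1$x + 105, start_y = head1$y)
  expect_true("head" %in% classify_fixation_aois(fx3, tr))
  fx4 <- list(onset = 0, start_x = head1$x + 106, start_y = head1$y)
  expect_false("head" %in% classify_fixation_aois(fx4, tr))
  expect_error(classify_fixation_aois(list(onset = -1, start_x = 1, start_y = 1), tr),
               "precedes")
})

test_that("classification matches a brute-force geometric oracle on random points", {
  set.seed(21)
  tr <- gen_aoi_tracks(250, wander_sd_px = 3, seed = 9)
  for (i in 1:1000) {
    x <- runif(1, 0, 1920); y <- runif(1, 0, 1080)
    t0 <- runif(1, 0, 9.99)
    got <- classify_fixation_aois(list(onset = t0, start_x = x, start_y = y), tr)
    # oracle: direct point-in-circle / point-in-ellipse test at the onset frame
    fr <- min(max(floor(t0 * 25) + 1, 1), 250)
    cen <- tr$centers[tr$centers$frame == fr, ]
    want <- character(0)
    for (j in seq_len(nrow(cen))) {
      r <- if (cen$kind[j] == "head") 105 else 70
      if ((x - cen$x[j])^2 + (y - cen$y[j])^2 <= r^2) want <- c(want, cen$kind[j])
    }
    want <- unique(want)
    inbody <- any(vapply(tr$bodies, function(b) {
      ((x - b$cx) / b$rx)^2 + ((y - b$cy) / b$ry)^2 <= 1
    }, logical(1)))
    if (length(want) > 0 || inbody) want <- c(want, "body")
    expect_setequal(got, want)
  }
})

test_that("dwell proportions follow the event-by-event tally", {
  tr <- mk_track(wander = 0)
  head1 <- tr$centers[tr$centers$part == "p1_head" & tr$centers$frame == 1, ]
  ev <- data.frame(
    kind = c("fixation", "saccade", "fixation", "fixation"),
    onset = c(0.0, 0.21, 0.25, 0.50),
    offset = c(0.20, 0.24, 0.45, 0.70),
    start_x = c(head1$x, NA, 5, 5),
    start_y = c(head1$y, NA, 5, 5))
  out <- compute_dwell_proportions(ev, tr)
  expect_equal(out$n_saccades, 1)
  tot <- 0.20 + 0.20 + 0.20
  expect_equal(unname(out$dwell["head"]), 0.20 / tot)
  expect_gte(out$dwell[["body"]], out$dwell[["head"]])
  # all fixations off-AOI -> zero proportions
  ev2 <- ev
  ev2$start_x <- 5; ev2$start_y <- 5
  expect_equal(unname(compute_dwell_proportions(ev2, tr)$dwell), c(0, 0, 0))
  # no fixations -> undefined cell
  ev3 <- ev[ev$kind == "saccade", ]
  expect_true(all(is.na(compute_dwell_proportions(ev3, tr)$dwell)))
})

test_that("dwell proportions are invariant to uniform time rescaling", {
  set.seed(22)
  tr <- mk_track(wander = 2, seed = 5)
  ev <- data.frame(kind = "fixation",
                   onset = c(0, 1, 2, 3), offset = c(0.8, 1.7, 2.9, 3.4),
                   start_x = runif(4, 0, 1920), start_y = runif(4, 0, 1080))
  a <- compute_dwell_proportions(ev, tr)
  ev2 <- ev
  ev2$onset <- ev2$onset * 2; ev2$offset <- ev2$offset * 2
  # halve fps so the onset frames match after rescaling
  tr2 <- tr; tr2$fps <- tr$fps / 2
  b <- compute_dwell_proportions(ev2, tr2)
  expect_equal(a$dwell, b$dwell)
})

test_that("aggregation takes medians and yields six rows per participant-dyad", {
  rec <- expand.grid(participant_id = "s1", group = "ASD", dyad_id = "d1",
                     dyad_type = "mixed", condition = c("high", "low"),
                     segment = 1:4, stringsAsFactors = FALSE)
  rec$head <- 0.5
  rec$head[rec$condition == "high"] <- c(0.1, 0.2, 0.3, 0.4)
  rec$hand <- 0.1
  rec$body <- 0.9
  rec$n_saccades <- 20L
  out <- aggregate_dwell(rec)
  expect_equal(nrow(out$dwell), 6)
  med <- out$dwell$dwell_prop[out$dwell$aoi == "head" & out$dwell$condition == "high"]
  expect_equal(med, 0.25)
  # single-condition cells warn but survive
  rec2 <- rec[rec$condition == "high", ]
  expect_warning(out2 <- aggregate_dwell(rec2), "one condition")
  expect_equal(nrow(out2$dwell), 3)
  expect_error(aggregate_dwell(transform(rec, condition = "weird")), "condition")
})

test_that("nested-AOI invariant holds through aggregation", {
  set.seed(23)
  tr <- gen_aoi_tracks(250, wander_sd_px = 2, seed = 3)
  recs <- list()
  for (s in 1:8) {
    plan <- make_fix_plan(12, seed = s)
    sp <- gen_gaze_scanpath(plan, fs = 500, noise_sd_deg = 0.1, seed = s)
    ev <- detect_events(sp$samples, study_geom())
    dw <- compute_dwell_proportions(ev, tr)
    recs[[s]] <- data.frame(participant_id = sprintf("s%d", (s + 1) %/% 2),
                            group = "ASD", dyad_id = "d1", dyad_type = "mixed",
                            condition = rep(c("high", "low"), 4)[s], segment = s,
                            head = dw$dwell[["head"]], hand = dw$dwell[["hand"]],
                            body = dw$dwell[["body"]], n_saccades = dw$n_saccades)
  }
  out <- suppressWarnings(aggregate_dwell(do.call(rbind, recs)))
  wide <- reshape(out$dwell, idvar = c("participant_id", "dyad_id", "condition"),
                  timevar = "aoi", direction = "wide",
                  v.names = "dwell_prop")
  expect_true(all(wide$dwell_prop.head <= wide$dwell_prop.body + 1e-12))
  expect_true(all(wide$dwell_prop.hand <= wide$dwell_prop.body + 1e-12))
  expect_true(all(out$dwell$dwell_prop >= 0 & out$dwell$dwell_prop <= 1))
})
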