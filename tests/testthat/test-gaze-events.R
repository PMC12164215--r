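test_that("adaptive threshold reaches the closed-form fixed point", {
  # when every sample stays below the running threshold the fixed point is
  # mean + k * SD of the full sample
  for (s in 1:20) {
    set.seed(s)
    v <- abs(rnorm(4000, 20, 5))
    pt <- adaptive_threshold(v, pt0 = 500, k = 6, tol = 0.5)
    expect_equal(as.numeric(pt), mean(v) + 6 * sd(v), tolerance = 1e-10)
  }
  expect_identical(as.numeric(adaptive_threshold(rep(0, 100), pt0 = 200)), 0)
  expect_error(adaptive_threshold(c(300, 400), pt0 = 200), "below pt0")
})

test_that("adaptive threshold separates bimodal fixation/saccade velocities", {
  plan <- make_fix_plan(10, seed = 3)
  sp <- gen_gaze_scanpath(plan, fs = 500, noise_sd_deg = 0.1, seed = 3)
  g <- study_geom()
  # velocity as the detector computes it: Savitzky-Golay derivative
  vx <- signal::sgolayfilt(sp$samples$x, p = 2, n = 11, m = 1, ts = 1 / 500) *
    px_to_deg(1, "horizontal", g)
  vy <- signal::sgolayfilt(sp$samples$y, p = 2, n = 11, m = 1, ts = 1 / 500) *
    px_to_deg(1, "vertical", g)
  v <- sqrt(vx^2 + vy^2)
  pt <- adaptive_threshold(v, pt0 = 200, k = 6, tol = 1)
  truth_peaks <- sp$events$peak_vel_deg_s[sp$events$kind == "saccade"]
  expect_true(all(truth_peaks > pt))
})

test_that("scanpath generator produces the planned truth structure", {
  g <- study_geom()
  # single target, zero noise: constant samples, one fixation
  one <- gen_gaze_scanpath(data.frame(x_px = 600, y_px = 400, duration_s = 1),
                           fs = 500, noise_sd_deg = 0, seed = 1)
  expect_equal(nrow(one$samples), 500)
  expect_true(all(one$samples$x == 600 & one$samples$y == 400))
  expect_identical(one$events$kind, "fixation")
  # two targets 10 deg apart: fix-sacc-fix, closed-form peak above 100 deg/s
  x1 <- 700 + deg_to_px(10, "horizontal", g)
  two <- gen_gaze_scanpath(data.frame(x_px = c(700, x1), y_px = 540,
                                      duration_s = c(1, 1)),
                           fs = 500, noise_sd_deg = 0, seed = 2)
  expect_identical(two$events$kind, c("fixation", "saccade", "fixation"))
  pk <- two$events$peak_vel_deg_s[2]
  expect_gt(pk, 100)
  # main-sequence closed form: amp * alpha / (4 * (21 ms + 2.2 ms/deg * amp))
  expect_equal(pk, 10 * 8 / (4 * (0.021 + 0.0022 * 10)), tolerance = 0.01)
  # 20-fixation plan: 20 fixations and 19 saccades in the truth list
  sp <- gen_gaze_scanpath(make_fix_plan(20, seed = 4), fs = 500, seed = 4)
  expect_equal(sum(sp$events$kind == "fixation"), 20)
  expect_equal(sum(sp$events$kind == "saccade"), 19)
  # truth events are ordered and non-overlapping
  expect_true(all(diff(sp$events$onset) > 0))
  expect_true(all(sp$events$onset[-1] >= head(sp$events$offset, -1)))
  expect_error(gen_gaze_scanpath(data.frame(x_px = -50, y_px = 100, duration_s = 1)),
               "off-screen")
  expect_error(gen_gaze_scanpath(data.frame(x_px = 10, y_px = 10, duration_s = 0.01)),
               "40 ms")
})

test_that("a stationary noisy target yields exactly one fixation", {
  set.seed(13)
  g <- study_geom()
  sp <- gen_gaze_scanpath(data.frame(x_px = 960, y_px = 540, duration_s = 1),
                          fs = 500, noise_sd_deg = 0.1, seed = 13)
  ev <- detect_events(sp$samples, g)
  expect_equal(sum(ev$kind == "fixation"), 1)
  expect_equal(sum(ev$kind == "saccade"), 0)
})

test_that("detected fixations match generator truth within 10 ms", {
  g <- study_geom()
  total_matched <- 0; total_fix <- 0
  for (s in 1:20) {
    sp <- gen_gaze_scanpath(make_fix_plan(20, seed = s), fs = 500,
                            noise_sd_deg = 0.1, geometry = g, seed = s + 100)
    ev <- detect_events(sp$samples, g)
    tf <- sp$events[sp$events$kind == "fixation", ]
    df <- ev[ev$kind == "fixation", ]
    onerr <- vapply(tf$onset, function(o) min(abs(df$onset - o)), numeric(1))
    total_matched <- total_matched + sum(onerr <= 0.010)
    total_fix <- total_fix + nrow(tf)
  }
  expect_gte(total_matched / total_fix, 0.95)
})

test_that("noise-free scanpaths are segmented without error in saccade count", {
  g <- study_geom()
  for (s in 1:50) {
    sp <- gen_gaze_scanpath(make_fix_plan(8, seed = s), fs = 500,
                            noise_sd_deg = 0, geometry = g, seed = s)
    ev <- detect_events(sp$samples, g)
    expect_equal(sum(ev$kind == "saccade"), 7)
  }
})

test_that("detected peak velocity approximates the sigmoid's closed form", {
  g <- study_geom()
  x1 <- 700 + deg_to_px(10, "horizontal", g)
  sp <- gen_gaze_scanpath(data.frame(x_px = c(700, x1), y_px = 540,
                                     duration_s = c(1, 1)),
                          fs = 500, noise_sd_deg = 0, seed = 1)
  ev <- detect_events(sp$samples, g)
  truth <- sp$events$peak_vel_deg_s[sp$events$kind == "saccade"]
  got <- ev$peak_vel_deg_s[ev$kind == "saccade"]
  expect_length(got, 1)
  expect_lt(abs(got - truth) / truth, 0.15)
})

test_that("events are ordered, non-overlapping and respect duration minima", {
  g <- study_geom()
  p <- gaze_params()
  for (s in c(7, 23)) {
    sp <- gen_gaze_scanpath(make_fix_plan(15, seed = s), fs = 500,
                            noise_sd_deg = 0.15, geometry = g, seed = s)
    ev <- detect_events(sp$samples, g)
    expect_true(all(diff(ev$onset) > 0))
    expect_true(all(ev$onset[-1] >= head(ev$offset, -1)))
    dur <- ev$offset - ev$onset + 1 / 500
    expect_true(all(dur[ev$kind == "fixation"] >= p$min_fix_dur - 1e-9))
    expect_true(all(dur[ev$kind == "saccade"] >= p$min_sacc_dur - 1e-9))
  }
})

test_that("segmentation is invariant to a constant pixel shift", {
  g <- study_geom()
  sp <- gen_gaze_scanpath(make_fix_plan(10, seed = 31), fs = 500,
                          noise_sd_deg = 0.1, geometry = g, seed = 31)
  ev1 <- detect_events(sp$samples, g)
  shifted <- sp$samples
  shifted$x <- shifted$x + 57
  shifted$y <- shifted$y + 13
  ev2 <- detect_events(shifted, g)
  expect_equal(ev1$kind, ev2$kind)
  expect_equal(ev1$onset, ev2$onset)
  expect_equal(ev1$offset, ev2$offset)
  expect_equal(ev2$start_x, ev1$start_x + 57)
})

test_that("short invalid gaps are bridged, long gaps split the record", {
  g <- study_geom()
  sp <- gen_gaze_scanpath(make_fix_plan(8, seed = 41), fs = 500,
                          noise_sd_deg = 0.1, geometry = g, seed = 41)
  n <- nrow(sp$samples)
  # 40 ms blink inside a fixation: detection result keeps one fixation block
  sam <- sp$samples
  mid <- round(n / 2)
  sam$valid[mid:(mid + 19)] <- FALSE
  ev <- detect_events(sam, g)
  expect_gt(sum(ev$kind == "fixation"), 0)
  # all-invalid input: empty result with a warning
  sam2 <- sp$samples
  sam2$valid <- FALSE
  expect_warning(ev2 <- detect_events(sam2, g), "valid")
  expect_equal(nrow(ev2), 0)
})
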