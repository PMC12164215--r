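mk_series <- function(v, fps = 25, id = "d", person = "A") {
  motion_energy_series(v, fps = fps, dyad_id = id, person_id = person)
}

test_that("a series is perfectly synchronous with itself at lag zero", {
  v <- 2 + sin(seq(0, 20 * pi, length.out = 800))
  cc <- wlcc(mk_series(v), mk_series(v, person = "B"), window_s = 10, lag_s = 3)
  lag0 <- which(cc$lags == 0)
  expect_true(all(abs(cc$r[, lag0] - 1) < 1e-12))
})

test_that("a pure shift is located at the shifting lag for interior windows", {
  set.seed(5)
  n <- 2000
  a <- pmax(0, 4 + as.numeric(arima.sim(list(ar = 0.9), n)))
  b <- c(rep(mean(a), 30), a[1:(n - 30)]) # b lags a by 30 frames
  cc <- wlcc(mk_series(a), mk_series(b, person = "B"), window_s = 10, lag_s = 3)
  interior <- 5:(length(cc$window_starts) - 5)
  best <- cc$lags[apply(cc$r[interior, ], 1, which.max)]
  expect_true(all(best == 30))
})

test_that("wlcc matches the brute-force Pearson oracle within 1e-10", {
  set.seed(6)
  n <- 3000
  a <- pmax(0, 4 + as.numeric(arima.sim(list(ar = 0.95), n)))
  b <- pmax(0, 4 + as.numeric(arima.sim(list(ar = 0.95), n)))
  cc <- wlcc(mk_series(a), mk_series(b, person = "B"),
             window_s = 10, lag_s = 3, step_s = 1)
  want <- wlcc_oracle(a, b, W = 250, L = 75, step = 25)
  expect_equal(cc$window_starts, want$starts)
  expect_identical(unname(is.na(cc$r)), is.na(want$r))
  expect_lt(max(abs(cc$r - want$r), na.rm = TRUE), 1e-10)
})

test_that("zero-variance windows are undefined, not zero", {
  a <- c(rep(1, 300), 1 + abs(sin(1:700)))
  b <- abs(cos(1:1000)) + 1
  cc <- wlcc(mk_series(a), mk_series(b, person = "B"), window_s = 10, lag_s = 1)
  expect_true(all(is.na(cc$r[1, ]))) # first window: constant a slice
  expect_error(wlcc(mk_series(a[1:100]), mk_series(b, person = "B")), "length")
  expect_error(wlcc(mk_series(a[1:200]), mk_series(b[1:200], person = "B"),
                    window_s = 10, lag_s = 3), "longer than")
  expect_error(wlcc(mk_series(a[1:260]), mk_series(b[1:260], person = "B"),
                    window_s = 10, lag_s = 3), "fit inside")
})

test_that("swap symmetry holds on interior windows", {
  set.seed(8)
  a <- abs(rnorm(1500)) + 1
  b <- abs(rnorm(1500)) + 1
  ab <- wlcc(mk_series(a), mk_series(b, person = "B"), window_s = 4, lag_s = 2)
  ba <- wlcc(mk_series(b), mk_series(a, person = "B"), window_s = 4, lag_s = 2)
  # r_ab[w, tau] (a at w, b at w+tau) equals r_ba[w', -tau] with w' = w + tau
  step <- 25
  for (wi in 5:10) {
    for (tau in c(-50, -25, 25, 50)) {
      wj <- wi + tau / step
      expect_equal(unname(ab$r[wi, which(ab$lags == tau)]),
                   unname(ba$r[wj, which(ba$lags == -tau)]), tolerance = 1e-12)
    }
  }
})

test_that("peak synchrony takes the maximum absolute correlation", {
  expect_equal(as.numeric(peak_ips(c(0.2, 0.9, 0.5))), 0.9)
  p <- peak_ips(c(-0.95, 0.1), lags = c(-1, 0))
  expect_equal(as.numeric(p), 0.95)
  expect_equal(attr(p, "signed"), -0.95)
  expect_equal(attr(p, "lag"), -1)
  expect_equal(as.numeric(peak_ips(c(NA, 1, NA))), 1)
  expect_error(peak_ips(c(NA_real_, NA_real_)), "undefined")
})

test_that("peak synchrony is invariant under affine rescaling of either series", {
  set.seed(9)
  a <- abs(rnorm(600)) + 2
  b <- abs(rnorm(600)) + 2
  base <- wlcc(mk_series(a), mk_series(b, person = "B"), window_s = 8, lag_s = 2)
  scaled <- wlcc(mk_series(a * 3.7 + 1), mk_series(b, person = "B"), window_s = 8, lag_s = 2)
  for (w in seq_along(base$window_starts)) {
    expect_equal(as.numeric(peak_ips(base$r[w, ])),
                 as.numeric(peak_ips(scaled$r[w, ])), tolerance = 1e-12)
  }
})

test_that("segment selection returns a balanced, non-overlapping, motion-filtered set", {
  dyads <- make_test_dyads(n_frames = 4500, seed = 60)
  seg <- select_segments(dyads, window_s = 10, lag_s = 3, step_s = 1, k = 4)
  expect_equal(nrow(seg), 64)
  expect_equal(unname(table(seg$dyad_type, seg$condition)), matrix(16L, 2, 2))
  W <- 250
  for (d in unique(seg$dyad_id)) {
    sd_ <- seg[seg$dyad_id == d, ]
    expect_equal(nrow(sd_), 8)
    expect_true(all(sd_$end_frame - sd_$start_frame == W))
    o <- sd_[order(sd_$start_frame), ]
    expect_true(all(diff(o$start_frame) >= W)) # non-overlap
    # every selected segment's overall motion lies in the candidate [Q1, Q3]
    a <- dyads[[d]]$a$values; b <- dyads[[d]]$b$values
    starts <- seq(1, length(a) - W + 1, by = 25)
    motion <- vapply(starts, function(s) mean(a[s:(s + W - 1)] + b[s:(s + W - 1)]), numeric(1))
    qs <- quantile(motion, c(0.25, 0.75), names = FALSE)
    expect_true(all(sd_$overall_motion >= qs[1] & sd_$overall_motion <= qs[2]))
    # high-synchrony picks score above low-synchrony picks
    expect_gt(min(sd_$ips_peak[sd_$condition == "high"]),
              max(sd_$ips_peak[sd_$condition == "low"]))
  }
  expect_true(all(seg$ips_peak >= 0 & seg$ips_peak <= 1))
})

test_that("constant-motion dyads cannot be scored", {
  flat <- list(d1 = list(a = mk_series(rep(2, 1000), id = "d1"),
                         b = mk_series(rep(3, 1000), id = "d1", person = "B")))
  expect_error(select_segments(flat, window_s = 10, lag_s = 3), "d1")
})

test_that("epoch-wise coupling drives the high/low condition contrast", {
  for (s in c(1, 5, 11)) {
    n <- 4500
    cpl <- rep(rep(c(0.9, 0.1), length.out = 18), each = 250)
    sp <- dyad_spec(sprintf("d%d", s), "mixed", n_frames = n, coupling = cpl,
                    lag_frames = 5, noise_sd = 0.1, seed = s)
    d <- list(list(a = gen_coupled_motion(sp)$a, b = gen_coupled_motion(sp)$b))
    seg <- select_segments(d, k = 4)
    expect_gt(mean(seg$ips_peak[seg$condition == "high"]),
              mean(seg$ips_peak[seg$condition == "low"]))
  }
})
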