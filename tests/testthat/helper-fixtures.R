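# Shared fixture builders; everything is generated in code under fixed seeds.

study_geom <- function() screen_geometry()

# Fixation plan with a minimum inter-target separation (planned refixations
# in free viewing are degrees apart; sub-degree shifts are microsaccades and
# not part of the generative truth).
make_fix_plan <- function(n_fix = 20, seed = 1, min_sep_deg = 3,
                          dur_range = c(0.2, 0.6), geometry = study_geom()) {
  set.seed(seed)
  sep_px <- deg_to_px(min_sep_deg, "horizontal", geometry)
  pts <- matrix(NA_real_, n_fix, 2)
  pts[1, ] <- c(stats::runif(1, 200, 1700), stats::runif(1, 150, 900))
  for (i in 2:n_fix) {
    repeat {
      cand <- c(stats::runif(1, 200, 1700), stats::runif(1, 150, 900))
      if (sqrt(sum((cand - pts[i - 1, ])^2)) >= sep_px) break
    }
    pts[i, ] <- cand
  }
  data.frame(x_px = pts[, 1], y_px = pts[, 2],
             duration_s = stats::runif(n_fix, dur_range[1], dur_range[2]))
}

# Small dyad set for selection tests: shorter videos, fast to score.
make_test_dyads <- function(n_frames = 4500, seed = 50, coupling = 0.5) {
  specs <- default_dyads(n_frames = n_frames, coupling = coupling, seed = seed)
  dyads <- lapply(specs, function(sp) {
    d <- gen_coupled_motion(sp)
    d$dyad_type <- sp$dyad_type
    d
  })
  names(dyads) <- vapply(specs, `[[`, character(1), "dyad_id")
  dyads
}

# Brute-force per-window Pearson cross-correlation oracle (independent of
# the package implementation: plain double loop over windows and lags).
wlcc_oracle <- function(a, b, W, L, step) {
  n <- length(a)
  starts <- seq.int(1L, n - W + 1L, by = step)
  lags <- seq.int(-L, L)
  r <- matrix(NA_real_, length(starts), length(lags))
  for (i in seq_along(starts)) {
    s <- starts[i]
    for (j in seq_along(lags)) {
      bs <- s + lags[j]
      if (bs < 1 || bs + W - 1 > n) next
      xa <- a[s:(s + W - 1)]
      xb <- b[bs:(bs + W - 1)]
      if (stats::sd(xa) == 0 || stats::sd(xb) == 0) next
      r[i, j] <- sum((xa - mean(xa)) * (xb - mean(xb))) /
        ((W - 1) * stats::sd(xa) * stats::sd(xb))
    }
  }
  list(starts = starts, lags = lags, r = r)
}
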