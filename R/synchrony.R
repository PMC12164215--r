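#' Windowed-lagged cross-correlation of two motion-energy series
#'
#' Slides a window of `window_s` seconds along both series in steps of
#' `step_s` seconds and, within each window, computes the Pearson correlation
#' between partner A's values and partner B's values shifted by every lag in
#' `[-lag_s, +lag_s]` seconds (positive lag = B later than A). Cells where
#' the shifted window falls outside the series, or where either slice has
#' zero variance, are undefined (`NA`), not zero.
#'
#' @param a,b [motion_energy_series()] of equal length and fps.
#' @param window_s window size in seconds (default 10, the segment length).
#' @param lag_s maximum absolute lag in seconds (default 3).
#' @param step_s window step in seconds (default 1).
#' @return object of class `crosscorr_matrix`: list with `window_starts`
#'   (1-based frame indices), `lags` (frame offsets), `r` (windows x lags
#'   matrix of correlations) and `fps`.
#' @export
wlcc <- function(a, b, window_s = 10, lag_s = 3, step_s = 1) {
  stopifnot(inherits(a, "motion_energy_series"), inherits(b, "motion_energy_series"))
  if (length(a$values) != length(b$values)) stop("wlcc: series lengths differ", call. = FALSE)
  if (a$fps != b$fps) stop("wlcc: series fps differ", call. = FALSE)
  fps <- a$fps
  n <- length(a$values)
  W <- round(window_s * fps)
  L <- round(lag_s * fps)
  step <- max(1L, round(step_s * fps))
  if (W > n) stop("wlcc: window longer than series", call. = FALSE)
  if (W + L > n) stop("wlcc: window plus lag does not fit inside the series", call. = FALSE)
  starts <- seq.int(1L, n - W + 1L, by = step)
  lags <- seq.int(-L, L)
  r <- matrix(NA_real_, length(starts), length(lags),
              dimnames = list(NULL, as.character(lags)))
  av <- a$values; bv <- b$values
  off <- seq_len(W) - 1L
  for (i in seq_along(starts)) {
    s <- starts[i]
    bstarts <- s + lags
    ok <- bstarts >= 1L & (bstarts + W - 1L) <= n
    if (!any(ok)) next
    idx <- outer(off, bstarts[ok], "+")
    B <- matrix(bv[idx], nrow = W)
    r[i, ok] <- suppressWarnings(as.numeric(stats::cor(av[s + off], B)))
  }
  structure(list(window_starts = starts, lags = lags, r = r, fps = fps),
            class = "crosscorr_matrix")
}

#' Peak interpersonal synchrony of one window
#'
#' The synchrony of a window is summarised by the peak cross-correlation:
#' the maximum absolute Pearson correlation over all lags. The signed value
#' and the lag at which the peak occurs are attached as attributes.
#'
#' @param row numeric vector of correlations over lags (may contain `NA` for
#'   undefined cells); typically one row of a `crosscorr_matrix`.
#' @param lags optional lag values aligned with `row` (for the `lag`
#'   attribute).
#' @return peak |r| in [0, 1], with attributes `signed` (the correlation at
#'   the peak, keeping its sign) and `lag` (if `lags` supplied).
#' @export
peak_ips <- function(row, lags = NULL) {
  row <- as.numeric(row)
  if (all(is.na(row))) stop("peak_ips: synchrony undefined (no defined lag)", call. = FALSE)
  i <- which.max(abs(row))
  out <- abs(row[i])
  attr(out, "signed") <- row[i]
  if (!is.null(lags)) attr(out, "lag") <- lags[i]
  out
}

#' Select balanced high/low-synchrony stimulus segments
#'
#' Implements the stimulus-selection procedure: per dyad, enumerate candidate
#' 10-s segments at 1-s steps; score each candidate's overall motion (mean
#' over the segment of the two series' framewise sum) and its synchrony (peak
#' lagged cross-correlation, one window per candidate); drop candidates whose
#' overall motion lies outside the closed interquartile interval [Q1, Q3] of
#' that dyad's candidate distribution; then greedily pick the `k` candidates
#' with the highest peak synchrony (ties broken by earlier start), skipping
#' any candidate that overlaps an already-picked segment, and likewise the
#' `k` lowest. With 8 dyads and `k = 4` this yields 64 segments, 16 per
#' dyad-type x condition cell.
#'
#' @param dyads named list; each element a list with components `a` and `b`
#'   ([motion_energy_series()]) and optionally `dyad_type`.
#' @param window_s segment/window length in seconds (default 10).
#' @param lag_s maximum lag in seconds (default 3).
#' @param step_s candidate enumeration step in seconds (default 1).
#' @param k number of segments per condition per dyad (default 4).
#' @return data.frame with columns `dyad_id, dyad_type, start_frame,
#'   end_frame, overall_motion, ips_peak, ips_signed, condition`; intervals
#'   are half-open `[start_frame, end_frame)`.
#' @export
select_segments <- function(dyads, window_s = 10, lag_s = 3, step_s = 1, k = 4) {
  out <- lapply(dyads, function(d) {
    a <- d$a; b <- d$b
    dyad_id <- a$dyad_id
    dyad_type <- if (!is.null(d$dyad_type)) d$dyad_type else NA_character_
    cc <- wlcc(a, b, window_s = window_s, lag_s = lag_s, step_s = step_s)
    W <- round(window_s * a$fps)
    starts <- cc$window_starts
    motion <- vapply(starts, function(s) {
      idx <- s:(s + W - 1L)
      mean(a$values[idx] + b$values[idx])
    }, numeric(1))
    qs <- stats::quantile(motion, c(0.25, 0.75), names = FALSE)
    keep <- which(motion >= qs[1] & motion <= qs[2])
    peaks <- rep(NA_real_, length(starts))
    signed <- rep(NA_real_, length(starts))
    for (i in keep) {
      row <- cc$r[i, ]
      if (all(is.na(row))) next
      p <- peak_ips(row, cc$lags)
      peaks[i] <- as.numeric(p)
      signed[i] <- attr(p, "signed")
    }
    keep <- keep[!is.na(peaks[keep])]
    if (length(keep) < 2L * k) {
      stop(sprintf("select_segments: dyad %s has %d usable candidates, need %d",
                   dyad_id, length(keep), 2L * k), call. = FALSE)
    }
    pick_greedy <- function(order_idx, chosen) {
      picked <- integer(0)
      for (i in order_idx) {
        s <- starts[i]
        if (!any(abs(s - starts[c(chosen, picked)]) < W)) picked <- c(picked, i)
        if (length(picked) == k) break
      }
      picked
    }
    ord_hi <- keep[order(-peaks[keep], starts[keep])]
    hi <- pick_greedy(ord_hi, integer(0))
    ord_lo <- keep[order(peaks[keep], starts[keep])]
    lo <- pick_greedy(setdiff(ord_lo, hi), hi)
    if (length(hi) < k || length(lo) < k) {
      stop(sprintf("select_segments: dyad %s: could not place %d non-overlapping segments per condition",
                   dyad_id, k), call. = FALSE)
    }
    sel <- c(hi, lo)
    data.frame(
      dyad_id = dyad_id, dyad_type = dyad_type,
      start_frame = starts[sel], end_frame = starts[sel] + W,
      overall_motion = motion[sel], ips_peak = peaks[sel], ips_signed = signed[sel],
      condition = rep(c("high", "low"), each = k),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
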