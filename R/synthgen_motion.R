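#' Specification of one synthetic dyad
#'
#' Describes one simulated interacting pair: how long its motion-energy
#' series is, how strongly the two partners' movements are coupled and at
#' what lag, and which dyad-type cell of the design it belongs to.
#'
#' @param dyad_id identifier token.
#' @param dyad_type `"mixed"` (one autistic, one non-autistic interactant) or
#'   `"non-autistic"`.
#' @param n_frames number of video frames.
#' @param fps frame rate (frames/s); defaults to 25.
#' @param coupling lagged correlation between the partners' latent motion, in
#'   [0, 1]. May be a single value or a per-frame vector (epoch-varying
#'   coupling), each element in [0, 1].
#' @param lag_frames lag (in frames, >= 0) at which partner B follows A.
#' @param noise_sd SD of additive white measurement noise, in units of the
#'   latent process SD.
#' @param seed integer RNG seed for this dyad.
#' @return object of class `dyad_spec`.
#' @export
dyad_spec <- function(dyad_id, dyad_type = c("mixed", "non-autistic"),
                      n_frames = 7500, fps = 25, coupling = 0.5,
                      lag_frames = 0, noise_sd = 0.2, seed = 1) {
  dyad_type <- match.arg(dyad_type)
  if (any(!is.finite(coupling)) || !all(is.finite(c(n_frames, fps, lag_frames, noise_sd, seed)))) {
    stop("dyad_spec: non-finite parameter", call. = FALSE)
  }
  if (any(coupling < 0 | coupling > 1)) stop("dyad_spec: coupling must lie in [0, 1]", call. = FALSE)
  if (!(length(coupling) %in% c(1L, n_frames))) {
    stop("dyad_spec: coupling must be scalar or one value per frame", call. = FALSE)
  }
  if (lag_frames < 0 || lag_frames >= n_frames) stop("dyad_spec: need 0 <= lag_frames < n_frames", call. = FALSE)
  if (noise_sd < 0) stop("dyad_spec: noise_sd must be >= 0", call. = FALSE)
  structure(
    list(dyad_id = as.character(dyad_id), dyad_type = dyad_type,
         n_frames = as.integer(n_frames), fps = fps, coupling = coupling,
         lag_frames = as.integer(lag_frames), noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "dyad_spec"
  )
}

# Stationary AR(1) with unit marginal variance.
ar1_unit <- function(n, phi) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  innov <- stats::rnorm(n - 1, sd = sqrt(1 - phi^2))
  for (t in 2:n) x[t] <- phi * x[t - 1] + innov[t - 1]
  x
}

#' Generate a coupled pair of motion-energy series
#'
#' Partner A's latent motion is a stationary AR(1) (autocorrelation 0.95)
#' with unit variance; partner B's latent motion is
#' `coupling * A[t - lag] + sqrt(1 - coupling^2) * E[t]` with `E` an
#' independent AR(1) of the same autocorrelation, so the lagged Pearson
#' correlation of the latents equals `coupling` exactly. Both series are
#' then shifted by +4 SD and rectified at zero (motion energy is
#' non-negative; the shift makes rectification rare so the Pearson structure
#' is essentially preserved), with optional white measurement noise added
#' before rectification. The empirical lag-`lag_frames` correlation
#' approaches `coupling` as `n_frames` grows.
#'
#' @param spec a [dyad_spec()].
#' @return list with elements `a` and `b`, both [motion_energy_series()]
#'   (rescaled scale: values are latent motion in arbitrary non-negative
#'   units, not pixel counts).
#' @export
gen_coupled_motion <- function(spec) {
  stopifnot(inherits(spec, "dyad_spec"))
  n <- spec$n_frames
  phi <- 0.95
  set.seed(spec$seed)
  zA <- ar1_unit(n, phi)
  zE <- ar1_unit(n, phi)
  lag <- spec$lag_frames
  zAlag <- if (lag > 0) c(zA[seq_len(lag)], zA[seq_len(n - lag)]) else zA
  cpl <- spec$coupling
  zB <- cpl * zAlag + sqrt(1 - cpl^2) * zE
  if (spec$noise_sd > 0) {
    zA <- zA + stats::rnorm(n, sd = spec$noise_sd)
    zB <- zB + stats::rnorm(n, sd = spec$noise_sd)
  }
  a <- pmax(0, 4 + zA)
  b <- pmax(0, 4 + zB)
  list(
    a = motion_energy_series(a, fps = spec$fps, dyad_id = spec$dyad_id, person_id = "A"),
    b = motion_energy_series(b, fps = spec$fps, dyad_id = spec$dyad_id, person_id = "B")
  )
}

#' Render a motion-energy series as a synthetic frame sequence
#'
#' Builds grayscale frames whose motion energy, recomputed with
#' [compute_mea()] under the same ROI mask and threshold, reproduces the
#' input series exactly. At frame t, exactly `series$values[t]` ROI pixels
#' are toggled between intensity 0 and `threshold + 1`; a toggle in either
#' direction is one changed pixel, so the round trip is an identity by
#' construction. Frames are abstract pixel-flip stimuli, not renderings of
#' human outlines.
#'
#' @param series raw [motion_energy_series()] with non-negative integer
#'   values; `values[1]` must be 0 (a first frame has no predecessor).
#' @param frame_shape integer c(rows, cols) of each frame.
#' @param roi_mask logical matrix of shape `frame_shape`; defaults to the
#'   whole frame.
#' @param threshold intensity threshold the frames are built against.
#' @param seed RNG seed choosing which pixels flip.
#' @return list of integer matrices (frames).
#' @export
gen_motion_frames <- function(series, frame_shape = c(64, 64), roi_mask = NULL,
                              threshold = 10, seed = 1) {
  stopifnot(inherits(series, "motion_energy_series"))
  v <- series$values
  if (any(v != round(v))) stop("gen_motion_frames: series values must be integers (pixel counts)", call. = FALSE)
  if (v[1] != 0) stop("gen_motion_frames: first value must be 0", call. = FALSE)
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, frame_shape[1], frame_shape[2])
  roi <- which(roi_mask != 0)
  if (max(v) > length(roi)) {
    stop(sprintf("gen_motion_frames: series value %d exceeds ROI capacity %d",
                 max(v), length(roi)), call. = FALSE)
  }
  set.seed(seed)
  hi <- as.integer(threshold + 1)
  f <- matrix(0L, frame_shape[1], frame_shape[2])
  frames <- vector("list", length(v))
  frames[[1]] <- f
  for (t in seq_along(v)[-1]) {
    k <- v[t]
    if (k > 0) {
      flip <- sample(roi, k)
      f[flip] <- hi - f[flip] # toggle 0 <-> threshold+1
    }
    frames[[t]] <- f
  }
  frames
}
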