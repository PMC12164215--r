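#' Motion-energy series container
#'
#' A motion-energy series holds, for one interactant's region of interest
#' (ROI), the per-frame count of pixels whose intensity changed by more than
#' a threshold between consecutive frames ("raw"), or that count divided by
#' the ROI area ("rescaled", values in [0, 1]).
#'
#' @param values numeric vector of per-frame motion energy, `values[1] == 0`.
#' @param fps frame rate in frames per second.
#' @param dyad_id,person_id identifier tokens.
#' @param roi_area_px ROI size in pixels (needed to rescale).
#' @param rescaled logical; whether `values` are already divided by ROI area.
#' @return object of class `motion_energy_series`.
#' @export
motion_energy_series <- function(values, fps, dyad_id = "dyad", person_id = "p1",
                                 roi_area_px = NA_integer_, rescaled = FALSE) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("motion_energy_series: values must be finite and non-negative", call. = FALSE)
  }
  if (rescaled && any(values > 1)) {
    stop("motion_energy_series: rescaled values must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(values = values, fps = fps, dyad_id = dyad_id, person_id = person_id,
         roi_area_px = roi_area_px, rescaled = rescaled),
    class = "motion_energy_series"
  )
}

#' @export
length.motion_energy_series <- function(x) length(x$values)

#' @export
print.motion_energy_series <- function(x, ...) {
  cat(sprintf("<motion_energy_series> dyad %s / %s: %d frames @ %g fps (%s)\n",
              x$dyad_id, x$person_id, length(x$values), x$fps,
              if (x$rescaled) "rescaled" else "raw"))
  invisible(x)
}

#' Compute per-frame motion energy within a region of interest
#'
#' For each pair of consecutive grayscale frames, counts the ROI pixels whose
#' absolute intensity difference exceeds `threshold` (strictly). The first
#' frame has no predecessor and gets the value 0, keeping the series length
#' equal to the frame count.
#'
#' @param frames a list of numeric matrices (grayscale intensities, one per
#'   frame) or a 3-d array with dimensions (rows, cols, frames).
#' @param roi_mask logical or 0/1 matrix matching the frame shape; `TRUE`
#'   pixels belong to the ROI.
#' @param threshold intensity-difference threshold; default 10 on a 0-255
#'   scale, a conventional motion-energy setting.
#' @param fps frame rate recorded in the result.
#' @param dyad_id,person_id identifier tokens carried into the result.
#' @return raw [motion_energy_series()] of non-negative integers.
#' @export
compute_mea <- function(frames, roi_mask, threshold = 10, fps = 25,
                        dyad_id = "dyad", person_id = "p1") {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  if (!is.list(frames) || length(frames) == 0) {
    stop("compute_mea: frames must be a non-empty list of matrices", call. = FALSE)
  }
  if (threshold < 0) stop("compute_mea: threshold must be >= 0", call. = FALSE)
  shp <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), shp), logical(1)))) {
    stop("compute_mea: all frames must share one shape", call. = FALSE)
  }
  if (!identical(dim(roi_mask), shp)) {
    stop("compute_mea: roi_mask shape does not match frames", call. = FALSE)
  }
  roi <- which(roi_mask != 0)
  if (length(roi) == 0) stop("compute_mea: empty ROI", call. = FALSE)
  n <- length(frames)
  vals <- numeric(n)
  for (t in seq_len(n - 1L)) {
    d <- abs(frames[[t + 1L]][roi] - frames[[t]][roi])
    vals[t + 1L] <- sum(d > threshold)
  }
  motion_energy_series(vals, fps = fps, dyad_id = dyad_id, person_id = person_id,
                       roi_area_px = length(roi), rescaled = FALSE)
}

#' Rescale a raw motion-energy series by its ROI area
#'
#' Divides each changed-pixel count by the number of ROI pixels, yielding the
#' proportion of the ROI in motion per frame (in [0, 1]); this makes values
#' comparable across ROIs of different size. Refuses to rescale twice.
#'
#' @param series raw [motion_energy_series()] with known `roi_area_px`.
#' @return rescaled [motion_energy_series()].
#' @export
rescale_mea <- function(series) {
  stopifnot(inherits(series, "motion_energy_series"))
  if (isTRUE(series$rescaled)) {
    stop("rescale_mea: series is already rescaled", call. = FALSE)
  }
  if (is.na(series$roi_area_px) || series$roi_area_px <= 0) {
    stop("rescale_mea: ROI area unknown or empty", call. = FALSE)
  }
  motion_energy_series(series$values / series$roi_area_px, fps = series$fps,
                       dyad_id = series$dyad_id, person_id = series$person_id,
                       roi_area_px = series$roi_area_px, rescaled = TRUE)
}

#' Write / read motion-energy series tables
#'
#' Long CSV format with columns `frame, dyad, person, value` (plus `fps` and
#' `roi_area_px` repeated for round-tripping).
#'
#' @param series_list list of [motion_energy_series()].
#' @param path CSV file path.
#' @export
write_mea_csv <- function(series_list, path) {
  if (inherits(series_list, "motion_energy_series")) series_list <- list(series_list)
  df <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(frame = seq_along(s$values), dyad = s$dyad_id, person = s$person_id,
               value = s$values, fps = s$fps, roi_area_px = s$roi_area_px,
               rescaled = s$rescaled)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mea_csv
#' @param path CSV file path.
#' @return `read_mea_csv`: list of [motion_energy_series()].
#' @export
read_mea_csv <- function(path) {
  df <- utils::read.csv(path)
  keys <- unique(df[, c("dyad", "person")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$dyad == keys$dyad[i] & df$person == keys$person[i], ]
    sub <- sub[order(sub$frame), ]
    motion_energy_series(sub$value, fps = sub$fps[1], dyad_id = keys$dyad[i],
                         person_id = keys$person[i], roi_area_px = sub$roi_area_px[1],
                         rescaled = sub$rescaled[1])
  })
}
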