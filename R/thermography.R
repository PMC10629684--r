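#' Region-of-interest geometries
#'
#' An oval ROI (the ring of skin around the eye) is defined by an integer or
#' fractional centre and semi-axes in pixels; a line ROI (drawn across the
#' vertical centre of the bill, nare to tip) by its two endpoints. All
#' coordinates are 1-based (row, col) with origin at the top-left pixel.
#' Oval membership tests pixel centres against the ellipse inequality; line
#' ROIs are rasterized 8-connected (Bresenham), so the geometry is
#' deterministic and oracle-checkable.
#'
#' @param center Numeric `(row, col)` centre of the oval.
#' @param semi_axes Positive `(row, col)` semi-axes in pixels.
#' @return An object of class `vt_roi`.
#' @examples
#' roi_oval(c(20, 48), c(7, 7))
#' roi_line(c(34, 16), c(34, 35))
#' @export
roi_oval <- function(center, semi_axes) {
  stopifnot(length(center) == 2L, length(semi_axes) == 2L)
  if (any(semi_axes <= 0)) vt_abort("oval semi-axes must be positive.")
  structure(list(kind = "oval", center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes)), class = "vt_roi")
}

#' @rdname roi_oval
#' @param from,to Integer `(row, col)` endpoints of the line; must differ.
#' @export
roi_line <- function(from, to) {
  stopifnot(length(from) == 2L, length(to) == 2L)
  if (all(from == to)) vt_abort("line endpoints must be distinct.")
  structure(list(kind = "line", from = as.integer(from), to = as.integer(to)),
            class = "vt_roi")
}

# 8-connected Bresenham rasterization; returns a (row, col) matrix
rasterize_line <- function(from, to) {
  r0 <- from[1]; c0 <- from[2]; r1 <- to[1]; c1 <- to[2]
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  err <- dc - dr
  r <- r0; c <- c0
  pts <- matrix(integer(), 0, 2)
  repeat {
    pts <- rbind(pts, c(r, c))
    if (r == r1 && c == c1) break
    e2 <- 2 * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  pts
}

roi_pixel_indices <- function(roi, nrow, ncol) {
  if (roi$kind == "oval") {
    inside_rows <- roi$center[1] - roi$semi_axes[1] >= 0.5 &&
      roi$center[1] + roi$semi_axes[1] <= nrow + 0.5
    inside_cols <- roi$center[2] - roi$semi_axes[2] >= 0.5 &&
      roi$center[2] + roi$semi_axes[2] <= ncol + 0.5
    if (!inside_rows || !inside_cols) {
      vt_abort("ROI extends beyond the frame.", class = "vasotherm_roi_error")
    }
    which_oval(roi, nrow, ncol)
  } else {
    pts <- rasterize_line(roi$from, roi$to)
    if (any(pts[, 1] < 1 | pts[, 1] > nrow | pts[, 2] < 1 | pts[, 2] > ncol)) {
      vt_abort("ROI extends beyond the frame.", class = "vasotherm_roi_error")
    }
    (pts[, 2] - 1L) * nrow + pts[, 1]
  }
}

#' Read 16-bit thermal frames and attach sidecar timestamps
#'
#' Reads per-frame 16-bit single-channel TIFFs written by [write_frames()]
#' (or any camera export in that layout), preserving counts bit-exactly, and
#' attaches per-frame metadata from the sidecar table. Frames of any other
#' bit depth, and frames without a sidecar row, are rejected with the
#' offending frame identified.
#'
#' @param dir Directory containing `frames/` plus `sidecar.tsv` and
#'   `reference.tsv` (as written by [write_frames()]).
#' @return A list of class `vt_frames` with `frames` (integer count
#'   matrices, in sidecar order), `sidecar`, `reference` and `count_map`.
#' @export
read_frames <- function(dir) {
  sidecar <- readr::read_tsv(file.path(dir, "sidecar.tsv"),
                             show_col_types = FALSE)
  reference <- readr::read_tsv(file.path(dir, "reference.tsv"),
                               show_col_types = FALSE)
  files <- sort(list.files(file.path(dir, "frames"),
                           pattern = "\\.tiff?$", full.names = TRUE))
  if (length(files) != nrow(sidecar)) {
    vt_abort(sprintf("found %d frames but %d sidecar rows.",
                     length(files), nrow(sidecar)),
             class = "vasotherm_frame_error")
  }
  frames <- lapply(seq_along(files), function(i) {
    img <- tiff::readTIFF(files[i], as.is = TRUE, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (!is.null(bits) && bits != 16L) {
      vt_abort(sprintf("frame %d (%s) is %d-bit; expected 16-bit.",
                       i, basename(files[i]), bits),
               class = "vasotherm_frame_error")
    }
    if (length(dim(img)) != 2L) {
      vt_abort(sprintf("frame %d is not single-channel.", i),
               class = "vasotherm_frame_error")
    }
    storage.mode(img) <- "integer"
    img
  })
  structure(list(frames = frames, sidecar = sidecar, reference = reference,
                 count_map = count_map()),
            class = "vt_frames")
}

#' Maximum calibrated temperature within a region of interest
#'
#' Returns the maximum over all pixels whose centres satisfy the oval
#' inequality (or over the 8-connected rasterization of a line ROI), mapped
#' to deg C by the linear count model. Maxima are the field-standard
#' regional statistic here because motion blur against a cooler background
#' biases small-animal surface temperatures downward, never upward.
#'
#' @param frame Integer count matrix.
#' @param roi A [roi_oval()] or [roi_line()] lying inside the frame.
#' @param map Linear count-to-temperature map (default [count_map()]).
#' @return Maximum temperature in deg C (uncalibrated for camera bias).
#' @examples
#' f <- matrix(20000L, 32, 32)
#' extract_roi_max(f, roi_oval(c(16, 16), c(5, 5)))
#' @export
extract_roi_max <- function(frame, roi, map = count_map()) {
  stopifnot(is.matrix(frame), inherits(roi, "vt_roi"))
  idx <- roi_pixel_indices(roi, nrow(frame), ncol(frame))
  if (!length(idx)) {
    vt_abort("ROI contains no pixels.", class = "vasotherm_roi_error")
  }
  max(frame[idx]) * map$slope + map$offset
}

#' Mean reference-target temperature estimated by the camera, per minute
#'
#' For each frame, takes the mean temperature over the reference-target ROI
#' (the camera's estimate of the logger surface), then averages within each
#' logger minute. Minute `m` covers `[60 m, 60 (m + 1))` seconds.
#'
#' @param x A `vt_frames` object.
#' @param roi Reference ROI; defaults to the geometry recorded in the
#'   sidecar (`ref_row`, `ref_col`, `ref_a`, `ref_b`).
#' @return A tibble with columns `time_min` and `camera_est` (deg C).
#' @export
reference_estimates <- function(x, roi = NULL) {
  stopifnot(inherits(x, "vt_frames"))
  sc <- x$sidecar
  if (is.null(roi)) {
    roi <- roi_oval(c(sc$ref_row[1], sc$ref_col[1]), c(sc$ref_a[1], sc$ref_b[1]))
  }
  map <- x$count_map
  idx <- roi_pixel_indices(roi, nrow(x$frames[[1]]), ncol(x$frames[[1]]))
  est <- vapply(x$frames, function(f) mean(f[idx]) * map$slope + map$offset,
                numeric(1))
  tibble(time_min = floor(sc$time_s / 60), est = est) |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(camera_est = mean(.data$est), .groups = "drop")
}

#' Calibrate regional temperatures against a reference logger
#'
#' Applies, per observation, the offset between the temperature logged by
#' the in-scene reference logger and the camera's own estimate of the
#' logger surface for that minute: `corrected = raw + (logged - camera)`.
#' The single offset absorbs camera bias together with emissivity/gain
#' error; by construction the corrected camera estimate of the reference
#' equals the logged temperature. The offset is step-held across each
#' logger minute. Observations whose minute has no logger reading or no
#' camera estimate are flagged uncalibrated and excluded (their count is
#' reported in the `n_uncalibrated` attribute).
#'
#' @param raw_series Tibble with columns `time_s` and `temp` (raw deg C),
#'   e.g. from [extract_region_series()].
#' @param camera_ref Per-minute camera estimates from
#'   [reference_estimates()].
#' @param reference_log Tibble `time_min`, `temp_C`: the logger readings.
#' @return `raw_series` with `temp` corrected; attribute `n_uncalibrated`.
#' @export
calibrate <- function(raw_series, camera_ref, reference_log) {
  stopifnot(is.data.frame(raw_series),
            all(c("time_s", "temp") %in% names(raw_series)))
  corr <- dplyr::inner_join(reference_log, camera_ref, by = "time_min") |>
    dplyr::mutate(offset = .data$temp_C - .data$camera_est)
  minute <- floor(raw_series$time_s / 60)
  off <- corr$offset[match(minute, corr$time_min)]
  ok <- !is.na(off)
  out <- raw_series[ok, , drop = FALSE]
  out$temp <- out$temp + off[ok]
  attr(out, "n_uncalibrated") <- sum(!ok)
  out
}

#' Extract a calibrated regional temperature series from frames
#'
#' Convenience wrapper running [extract_roi_max()] over every frame for one
#' region, attaching the position index and quality flag from the sidecar,
#' and applying reference calibration. Rows retain the sidecar ordering.
#'
#' @param x A `vt_frames` object.
#' @param region `"eye"` or `"bill"`; ROI geometry is taken from the
#'   sidecar (the oval for the eye, the per-frame line for the bill).
#' @param calibrated Apply [calibrate()] using the bundled reference log
#'   (default `TRUE`).
#' @return A tibble of class `vt_temps`: `time_s`, `region`, `temp`,
#'   `position_index`, `quality`.
#' @export
extract_region_series <- function(x, region = c("eye", "bill"),
                                  calibrated = TRUE) {
  stopifnot(inherits(x, "vt_frames"))
  region <- match.arg(region)
  sc <- x$sidecar
  map <- x$count_map
  nr <- nrow(x$frames[[1]]); nc <- ncol(x$frames[[1]])
  temp <- numeric(nrow(sc))
  if (region == "eye") {
    roi <- roi_oval(c(sc$eye_row[1], sc$eye_col[1]), c(sc$eye_a[1], sc$eye_b[1]))
    idx <- roi_pixel_indices(roi, nr, nc)
    for (i in seq_along(x$frames)) {
      temp[i] <- max(x$frames[[i]][idx]) * map$slope + map$offset
    }
  } else {
    for (i in seq_along(x$frames)) {
      roi <- roi_line(c(sc$bill_row[i], sc$bill_col0[i]),
                      c(sc$bill_row[i], sc$bill_col1[i]))
      idx <- roi_pixel_indices(roi, nr, nc)
      temp[i] <- max(x$frames[[i]][idx]) * map$slope + map$offset
    }
  }
  out <- tibble(
    time_s = sc$time_s, region = region, temp = temp,
    position_index = measure_position_index(sc), quality = sc$quality
  )
  if (calibrated) {
    cam <- reference_estimates(x)
    cal <- calibrate(out, cam, x$reference)
    out <- cal
  }
  class(out) <- c("vt_temps", class(out))
  out
}

#' Position index of each frame
#'
#' The apparent bill length in pixels, recorded for every temperature
#' measurement as a covariate absorbing camera-subject distance and
#' head-angle deviation from profile. Constant within a frame, so the same
#' value attaches to both regions measured from it.
#'
#' @param sidecar Sidecar tibble (or one row of it) with column `bill_px`.
#' @return Numeric vector of bill lengths (px); missing or non-positive
#'   values are returned as `NA` with a warning, so the affected
#'   observations can be flagged.
#' @export
measure_position_index <- function(sidecar) {
  px <- as.numeric(sidecar$bill_px)
  bad <- !is.finite(px) | px <= 0
  if (any(bad)) {
    rlang::warn(sprintf("%d frame(s) with missing/non-positive bill length; flagged NA.",
                        sum(bad)))
    px[bad] <- NA_real_
  }
  px
}

#' Drop quality-flagged observations
#'
#' Removes rows whose `quality` flag is `FALSE` (out-of-focus or
#' off-profile frames). The number of dropped rows is recorded in the
#' `n_dropped` attribute.
#'
#' @param series A `vt_temps` tibble with a logical `quality` column.
#' @return The filtered series.
#' @export
quality_filter <- function(series) {
  stopifnot(is.data.frame(series), "quality" %in% names(series))
  out <- series[series$quality, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!series$quality)
  out
}

#' Trailing rolling-maximum filter
#'
#' Replaces each temperature by the maximum over observations in the
#' trailing window `(t - window, t]`, suppressing one-sided (negative)
#' error from motion blur: a momentary cold dip between warm neighbours is
#' replaced by the preceding maximum. Output timestamps are unchanged; the
#' filter is idempotent and never decreases a value.
#'
#' @param series Data frame with columns `time_s` and `temp`, sorted by
#'   time (unsorted input is rejected).
#' @param window Window width in seconds (default 5).
#' @return The series with `temp` replaced by its trailing windowed max.
#' @examples
#' s <- tibble::tibble(time_s = 1:5, temp = c(36, 35, 36.2, 33, 36.1))
#' rolling_max_filter(s)$temp
#' @export
rolling_max_filter <- function(series, window = 5) {
  stopifnot(is.data.frame(series),
            all(c("time_s", "temp") %in% names(series)))
  check_number(window, "window", lower = 0, strict_lower = TRUE)
  t <- series$time_s
  if (is.unsorted(t)) {
    vt_abort("series must be time-sorted.", class = "vasotherm_sort_error")
  }
  x <- series$temp
  n <- length(t)
  if (n) {
    start <- findInterval(t - window, t) + 1L
    out <- numeric(n)
    for (i in seq_len(n)) out[i] <- max(x[start[i]:i])
    series$temp <- out
  }
  series
}
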