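#' Detect R peaks in a uniformly sampled ECG trace
#'
#' Finds local maxima that cross an adaptive amplitude threshold, enforcing a
#' minimum separation between successive detections. The threshold is the
#' median of the trace plus `threshold_frac` of the median-to-maximum span, a
#' rule robust to baseline wander; a flat or everywhere-subthreshold trace
#' yields an empty beat series rather than an error.
#'
#' @param ecg Data frame with columns `time_ms` and `value`, uniformly
#'   sampled (non-uniform sampling is rejected).
#' @param min_separation_ms Minimum time between detections (must be > 0);
#'   when two candidate peaks fall closer, the larger is kept.
#' @param threshold_frac Fraction of the median-to-maximum span used for the
#'   adaptive threshold (default 0.5).
#' @return A tibble of class `vt_beats` with column `beat_ms`, strictly
#'   increasing.
#' @examples
#' b <- simulate_beat_series(
#'   simulate_autonomic_state(protocol(run_end = 10), synthetic_truth(), 1),
#'   synthetic_truth(), 1
#' )
#' ecg <- render_ecg(b, snr_db = 20)
#' nrow(detect_r_peaks(ecg, min_separation_ms = 40))
#' @export
detect_r_peaks <- function(ecg, min_separation_ms = 40, threshold_frac = 0.5) {
  stopifnot(is.data.frame(ecg), all(c("time_ms", "value") %in% names(ecg)))
  check_number(min_separation_ms, "min_separation_ms", lower = 0,
               strict_lower = TRUE)
  t <- ecg$time_ms; v <- ecg$value
  if (length(t) >= 3L) {
    dt <- diff(t)
    if (max(dt) - min(dt) > 1e-6 * median(dt)) {
      vt_abort("ECG must be uniformly sampled.", class = "vasotherm_ecg_error")
    }
  }
  med <- median(v); mx <- max(v)
  empty <- tibble(beat_ms = numeric())
  class(empty) <- c("vt_beats", class(empty))
  if (mx <= med) return(empty)               # flat signal: no peaks
  thr <- med + threshold_frac * (mx - med)

  n <- length(v)
  is_peak <- v > thr &
    v >= c(-Inf, v[-n]) & v > c(v[-1], -Inf)  # local maximum (ties keep first)
  cand <- which(is_peak)
  if (!length(cand)) return(empty)

  # enforce min separation, keeping the larger of clashing peaks
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || t[i] - t[keep[length(keep)]] >= min_separation_ms) {
      keep <- c(keep, i)
    } else if (v[i] > v[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  # refine each peak by parabolic interpolation over its 3-point neighbourhood
  beat <- vapply(keep, function(i) {
    if (i <= 1L || i >= n) return(t[i])
    denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
    if (denom >= 0) return(t[i])
    t[i] + 0.5 * (v[i - 1L] - v[i + 1L]) / denom * (t[2] - t[1])
  }, numeric(1))
  out <- tibble(beat_ms = beat)
  class(out) <- c("vt_beats", class(out))
  out
}

#' Compute R-R intervals from a beat series
#'
#' Each interval is stamped at the time of its terminating beat.
#'
#' @param beats Data frame with column `beat_ms` (strictly increasing), or a
#'   numeric vector of beat times in ms. Fewer than 2 beats is an error.
#' @return A tibble of class `vt_rri` with columns `t` (ms), `rri` (ms) and
#'   `removed` (logical, all `FALSE`).
#' @examples
#' compute_rri(c(0, 100, 200))
#' @export
compute_rri <- function(beats) {
  beat_ms <- if (is.data.frame(beats)) beats$beat_ms else as.numeric(beats)
  if (length(beat_ms) < 2L) {
    vt_abort("need at least 2 beats to form an R-R interval.",
             class = "vasotherm_rri_error")
  }
  check_strictly_increasing(beat_ms, "beat_ms")
  out <- tibble(
    t = beat_ms[-1L],
    rri = diff(beat_ms),
    removed = FALSE
  )
  class(out) <- c("vt_rri", class(out))
  out
}

#' Flag gap and spike artifacts in an R-R interval series
#'
#' Telemetry dropouts produce intervals spanning several missed beats
#' (too long) and spurious detections produce implausibly short ones. An
#' interval is flagged removed when it falls outside
#' `[low_mult, high_mult]` times the local median over a window of
#' neighbouring intervals. Flagging is non-destructive (rows are kept,
#' `removed` is set) and monotone: already-removed points are never
#' reinstated. A physiologically clean series passes unchanged.
#'
#' @param rri A [compute_rri()] series.
#' @param low_mult,high_mult Acceptance band as multiples of the local
#'   median; require `0 < low_mult < 1 < high_mult`.
#' @param window_beats Width (in intervals, including self) of the local
#'   median window; must be >= 3 (odd recommended).
#' @return The series with updated `removed` flags.
#' @examples
#' rri <- compute_rri(c(0, 100, 200, 3200, 3300, 3400))
#' remove_gap_artifacts(rri)$removed
#' @export
remove_gap_artifacts <- function(rri, low_mult = 0.5, high_mult = 2,
                                 window_beats = 11) {
  stopifnot(inherits(rri, "vt_rri") || is.data.frame(rri))
  if (!(low_mult > 0 && low_mult < 1 && high_mult > 1)) {
    vt_abort("need 0 < low_mult < 1 < high_mult.")
  }
  if (window_beats < 3) {
    vt_abort("`window_beats` must be at least 3.")
  }
  n <- nrow(rri)
  if (n == 0L) return(rri)
  half <- floor(window_beats / 2)
  x <- rri$rri
  loc_med <- vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    median(x[idx])
  }, numeric(1))
  bad <- x < low_mult * loc_med | x > high_mult * loc_med
  rri$removed <- rri$removed | bad
  rri
}

#' Instantaneous heart rate from retained R-R intervals
#'
#' @param rri A [compute_rri()] series; non-positive intervals are rejected.
#' @return A tibble with columns `t` (ms) and `hr` (beats/min), one row per
#'   retained (non-removed) interval: `hr = 60000 / rri`.
#' @examples
#' instantaneous_heart_rate(compute_rri(c(0, 100, 200)))
#' @export
instantaneous_heart_rate <- function(rri) {
  stopifnot(is.data.frame(rri), all(c("t", "rri", "removed") %in% names(rri)))
  if (any(rri$rri <= 0)) {
    vt_abort("R-R intervals must be positive.", class = "vasotherm_rri_error")
  }
  kept <- rri[!rri$removed, , drop = FALSE]
  tibble(t = kept$t, hr = 60000 / kept$rri)
}

#' Rolling coefficient-of-variation heart-rate variability
#'
#' At each retained interval time `t`, computes `sd / mean` of the retained
#' intervals falling in the trailing window `(t - window, t]`, using the
#' sample (n-1) standard deviation. A value is emitted only when at least
#' `min_points` intervals fall in the window; removed intervals never enter
#' any window. Trailing alignment means no future data is used, so the
#' estimate at stressor onset reflects only the baseline.
#'
#' @param rri A [compute_rri()] (optionally artifact-flagged) series.
#' @param window Window width in ms (default 2000: a 2 s rolling window).
#' @param min_points Minimum intervals per window (default 3; below 3 a CV
#'   is statistically meaningless).
#' @return A tibble of class `vt_hrv` with columns `t` (ms) and `cv`
#'   (dimensionless).
#' @examples
#' rri <- compute_rri(cumsum(c(0, rep(c(90, 110), 50))))
#' head(rolling_cv_hrv(rri))
#' @export
rolling_cv_hrv <- function(rri, window = 2000, min_points = 3) {
  stopifnot(is.data.frame(rri), all(c("t", "rri", "removed") %in% names(rri)))
  check_number(window, "window", lower = 0, strict_lower = TRUE)
  check_number(min_points, "min_points", lower = 2)
  kept <- rri[!rri$removed, , drop = FALSE]
  t <- kept$t; x <- kept$rri
  if (any(x <= 0)) {
    vt_abort("R-R intervals must be positive.", class = "vasotherm_rri_error")
  }
  n <- length(t)
  if (n == 0L) {
    out <- tibble(t = numeric(), cv = numeric())
    class(out) <- c("vt_hrv", class(out))
    return(out)
  }
  # trailing window (t - window, t]: first index via binary search
  start <- findInterval(t - window, t) + 1L   # first t[j] > t[i] - window
  cv <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- start[i]
    if (i - j + 1L >= min_points) {
      w <- x[j:i]
      cv[i] <- sd(w) / mean(w)
    }
  }
  out <- tibble(t = t, cv = cv)
  out <- out[!is.na(out$cv), , drop = FALSE]
  class(out) <- c("vt_hrv", class(out))
  out
}

#' Censor onset artifact spikes in a heart-rate-variability trace
#'
#' When a rolling window straddles the sharp heart-rate rise at stressor
#' onset, the mixture of slow and fast intervals inflates the coefficient of
#' variation, producing a spurious HRV spike. Points within the guard
#' interval `[onset, onset + guard)` whose value exceeds the baseline mean
#' are removed; everything else is untouched. The operation never adds
#' points and is idempotent.
#'
#' @param hrv A [rolling_cv_hrv()] trace (columns `t`, `cv`).
#' @param baseline_mean Mean HRV over the baseline period of the same run.
#' @param onset Stressor onset time (ms).
#' @param guard Guard width in ms (default 10000: the first 10 s); must be
#'   non-negative.
#' @return The trace with offending rows dropped.
#' @examples
#' tr <- tibble::tibble(t = c(5000, 12000), cv = c(0.05, 0.05))
#' censor_onset_spikes(tr, baseline_mean = 0.03, onset = 0)
#' @export
censor_onset_spikes <- function(hrv, baseline_mean, onset, guard = 10000) {
  stopifnot(is.data.frame(hrv), all(c("t", "cv") %in% names(hrv)))
  check_number(baseline_mean, "baseline_mean")
  if (guard < 0) vt_abort("`guard` must be non-negative.")
  spike <- hrv$t >= onset & hrv$t < onset + guard & hrv$cv > baseline_mean
  hrv[!spike, , drop = FALSE]
}

#' Linearly interpolate a point series onto a regular grid
#'
#' Interpolates between retained points onto a grid of spacing `step`
#' starting at the first point; values at original sample times that fall on
#' the grid are reproduced exactly, and no extrapolation occurs beyond the
#' first or last point. Grid cells falling inside a gap between consecutive
#' points wider than `max_gap` are set `NA` rather than bridged, so multi-
#' second telemetry dropouts are not papered over with fabricated values
#' (`max_gap = Inf` interpolates across every gap).
#'
#' @param series Data frame whose first two columns are time (ms) and value
#'   (e.g. a `vt_hrv` trace); at least 2 points.
#' @param step Grid step in ms (default 1: one value per millisecond).
#' @param max_gap Widest gap (ms) across which to interpolate
#'   (default 2000).
#' @param kind Label stored on the result (`"hrv"` or `"heart_rate"`).
#' @return A tibble of class `vt_uniform` with columns `t` (ms) and `value`;
#'   attributes `t0`, `step` and `kind`.
#' @examples
#' interpolate_to_grid(tibble::tibble(t = c(0, 1000), v = c(100, 200)),
#'                     step = 500)
#' @export
interpolate_to_grid <- function(series, step = 1, max_gap = 2000,
                                kind = "hrv") {
  stopifnot(is.data.frame(series), ncol(series) >= 2L)
  check_number(step, "step", lower = 0, strict_lower = TRUE)
  t <- series[[1L]]; v <- series[[2L]]
  if (length(t) < 2L) {
    vt_abort("need at least 2 points to interpolate.",
             class = "vasotherm_interp_error")
  }
  check_strictly_increasing(t, "time")
  grid <- seq(t[1L], t[length(t)], by = step)
  val <- approx(t, v, xout = grid, method = "linear", ties = "ordered")$y
  if (is.finite(max_gap)) {
    gaps <- which(diff(t) > max_gap)
    for (g in gaps) {
      inside <- grid > t[g] & grid < t[g + 1L]
      val[inside] <- NA_real_
    }
  }
  out <- tibble(t = grid, value = val)
  class(out) <- c("vt_uniform", class(out))
  attr(out, "t0") <- grid[1L]
  attr(out, "step") <- step
  attr(out, "kind") <- kind
  out
}
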