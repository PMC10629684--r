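#' Simulate an R-peak beat series from an autonomic state trajectory
#'
#' Generates strictly increasing beat (R-wave) times whose local mean R-R
#' interval is `60000 / HR(s)` ms, where `HR(s)` interpolates linearly from
#' `hr_baseline` at activation 0 to `hr_stress` at activation 1, and whose
#' local dispersion is set so the coefficient of variation of intervals
#' tracks `cv_baseline -> cv_stress`. Optional telemetry artifacts are
#' injected afterwards: dropped beats (each surviving interval then spans a
#' gap) at rate `truth$gap_rate`, and spurious extra detections at rate
#' `truth$spike_rate`.
#'
#' All beat times are milliseconds relative to stressor onset, so baseline
#' beats are negative; the series spans `[baseline_start, run_end]` of the
#' state's protocol window.
#'
#' @param state A [simulate_autonomic_state()] trajectory.
#' @param truth A [synthetic_truth()]; negative rates or CVs are rejected at
#'   construction time.
#' @param seed Integer seed; the series is bit-reproducible given it.
#' @return A tibble of class `vt_beats` with column `beat_ms`.
#' @examples
#' pr <- protocol(run_end = 120)
#' st <- simulate_autonomic_state(pr, synthetic_truth(), seed = 1)
#' b <- simulate_beat_series(st, synthetic_truth(), seed = 1)
#' head(b)
#' @export
simulate_beat_series <- function(state, truth, seed) {
  stopifnot(inherits(state, "vt_state"), inherits(truth, "vt_truth"))
  set.seed(seed)

  t_grid <- state$t
  step <- attr(state, "step") %||% (t_grid[2] - t_grid[1])
  hr_grid <- truth$hr_baseline + (truth$hr_stress - truth$hr_baseline) * state$s
  cv_grid <- truth$cv_baseline + (truth$cv_stress - truth$cv_baseline) * state$s

  t0_ms <- t_grid[1] * 1000
  t_end_ms <- t_grid[length(t_grid)] * 1000
  # generous upper bound on beat count for pre-drawing normals
  n_max <- ceiling((t_end_ms - t0_ms) / (60000 / truth$hr_stress)) + 64L
  z <- rnorm(n_max)

  beats <- numeric(n_max)
  t_cur <- t0_ms
  i <- 0L
  ng <- length(t_grid)
  while (TRUE) {
    idx <- floor((t_cur / 1000 - t_grid[1]) / step) + 1
    idx <- min(max(idx, 1), ng)
    mu <- 60000 / hr_grid[idx]
    rri <- mu * (1 + cv_grid[idx] * z[i + 1L])
    rri <- max(rri, 0.2 * mu)            # truncation keeps intervals positive
    t_cur <- t_cur + rri
    if (t_cur > t_end_ms) break
    i <- i + 1L
    beats[i] <- t_cur
  }
  beats <- beats[seq_len(i)]

  # telemetry artifacts
  if (truth$gap_rate > 0 && length(beats) > 2L) {
    drop <- runif(length(beats)) < truth$gap_rate
    beats <- beats[!drop]
  }
  if (truth$spike_rate > 0 && length(beats) > 2L) {
    spike_at <- which(runif(length(beats) - 1L) < truth$spike_rate)
    if (length(spike_at)) {
      frac <- runif(length(spike_at), 0.2, 0.8)
      extra <- beats[spike_at] + frac * diff(beats)[spike_at]
      beats <- sort(c(beats, extra))
    }
  }

  out <- tibble(beat_ms = beats)
  class(out) <- c("vt_beats", class(out))
  attr(out, "seed") <- seed
  out
}

#' Render a sampled ECG trace from beat times
#'
#' Places a Gaussian R-wave kernel at every beat and adds white noise at a
#' chosen signal-to-noise ratio, producing the uniformly sampled raw trace
#' expected by [detect_r_peaks()]. Useful for validating peak detection
#' against known beat positions.
#'
#' @param beats A `vt_beats` tibble (or numeric vector of beat times, ms).
#' @param sample_rate_hz Sampling rate of the rendered trace (default 1000).
#' @param kernel_sd_ms Width of the Gaussian R wave (default 3 ms).
#' @param snr_db Signal-to-noise ratio in dB; `Inf` for a noise-free trace.
#' @param seed Seed for the additive noise.
#' @return A tibble with columns `time_ms` and `value`.
#' @export
render_ecg <- function(beats, sample_rate_hz = 1000, kernel_sd_ms = 3,
                       snr_db = Inf, seed = 1) {
  beat_ms <- if (is.data.frame(beats)) beats$beat_ms else as.numeric(beats)
  check_number(sample_rate_hz, "sample_rate_hz", lower = 0, strict_lower = TRUE)
  step <- 1000 / sample_rate_hz
  t <- seq(floor(min(beat_ms)) - 20, ceiling(max(beat_ms)) + 20, by = step)
  v <- numeric(length(t))
  half <- ceiling(4 * kernel_sd_ms / step)
  for (b in beat_ms) {
    ic <- round((b - t[1]) / step) + 1
    idx <- max(1, ic - half):min(length(t), ic + half)
    v[idx] <- v[idx] + exp(-((t[idx] - b)^2) / (2 * kernel_sd_ms^2))
  }
  if (is.finite(snr_db)) {
    set.seed(seed)
    noise_sd <- sqrt(mean(v^2) / 10^(snr_db / 10))
    v <- v + rnorm(length(v), sd = noise_sd)
  }
  tibble(time_ms = t, value = v)
}
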