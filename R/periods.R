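#' Analysis period definitions
#'
#' The four periods of the capture-and-handling protocol, on the
#' onset-relative clock: baseline (-60 to 0 s), stressor (0 to 180 s),
#' 15 min (840 to 900 s) and 30 min (1740 to 1800 s). Membership is
#' half-open `[start, end)`, so 0 s belongs to the stressor and 180 s to no
#' period. Baseline, 15 min and 30 min are reduced to a single summary per
#' run; the stressor period keeps multiple readings (it is where most of
#' the surface-temperature dynamics occur).
#'
#' @return A tibble with columns `label`, `start`, `end`, `keep_multiple`.
#' @examples
#' period_definitions()
#' @export
period_definitions <- function() {
  tibble(
    label = c("baseline", "stressor", "min15", "min30"),
    start = c(-60, 0, 840, 1740),
    end = c(0, 180, 900, 1800),
    keep_multiple = c(FALSE, TRUE, FALSE, FALSE)
  )
}

#' Assign times to analysis periods
#'
#' Half-open `[start, end)` membership; a time outside every period maps to
#' `NA`. Overlapping definitions are rejected.
#'
#' @param t Numeric vector of times (s, onset-relative).
#' @param defs Period definitions, as from [period_definitions()].
#' @return Character vector of period labels (or `NA`).
#' @examples
#' assign_period(c(-30, 870, 500))
#' @export
assign_period <- function(t, defs = period_definitions()) {
  stopifnot(is.data.frame(defs),
            all(c("label", "start", "end") %in% names(defs)))
  if (any(defs$start >= defs$end)) vt_abort("period start must precede end.")
  o <- order(defs$start)
  if (any(defs$end[o][-nrow(defs)] > defs$start[o][-1L])) {
    vt_abort("period definitions overlap.", class = "vasotherm_period_error")
  }
  out <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(defs))) {
    out[t >= defs$start[i] & t < defs$end[i]] <- defs$label[i]
  }
  out
}

#' Reduce the values of one period to its summary statistic
#'
#' Cardiac variables (heart rate, HRV) are reduced by the mean; regional
#' temperatures by the maximum (the most accurate measurement, since errors
#' are one-sided negative). A temperature summary is suppressed (`NA`) when
#' fewer than `min_raw` measurements existed before filtering, because too
#' few frames cannot adequately represent the period; `n_raw` is counted
#' before rolling-max filtering and before quality exclusion within the
#' period's own inclusion rule (quality-rejected frames were never
#' measurements).
#'
#' @param values Numeric values falling in the period (after filtering).
#' @param reducer `"mean"` (cardiac) or `"max"` (temperature).
#' @param n_raw Number of measurements before filtering.
#' @param min_raw Inclusion threshold applied to temperature periods
#'   (default 5).
#' @return A one-row tibble with `value`, `n_raw` and `included`.
#' @examples
#' summarize_period(c(36.1, 36.9, 36.4, 36.2, 36.0), "max", n_raw = 5)
#' summarize_period(c(500, 600), "mean", n_raw = 2)
#' @export
summarize_period <- function(values, reducer = c("mean", "max"), n_raw,
                             min_raw = 5) {
  reducer <- match.arg(reducer)
  check_number(n_raw, "n_raw", lower = 0)
  needs_min <- reducer == "max"
  if (needs_min && n_raw >= min_raw && length(values) == 0L) {
    vt_abort("no values supplied for a period recorded with n_raw >= 5.",
             class = "vasotherm_period_error")
  }
  included <- if (needs_min) n_raw >= min_raw else n_raw >= 1
  value <- if (!included || length(values) == 0L) {
    NA_real_
  } else if (reducer == "mean") {
    mean(values)
  } else {
    max(values)
  }
  tibble(value = value, n_raw = n_raw, included = included)
}

#' Match temperature observations with synchronous covariates
#'
#' Joins every quality-retained temperature observation in the baseline and
#' stressor periods with the heart-rate-variability value at its exact
#' millisecond grid cell, the activity signal at its timestamp, and the air
#' temperature for its logger minute (step-held). Observations falling in a
#' censored HRV gap (missing grid cell) or outside the HRV span are dropped
#' and counted in the `n_dropped_join` attribute, so exclusion bookkeeping
#' reconciles exactly.
#'
#' @param temps A calibrated, quality-filtered, rolling-max-filtered
#'   `vt_temps` tibble (columns `time_s`, `region`, `temp`,
#'   `position_index`).
#' @param hrv A [interpolate_to_grid()] `vt_uniform` HRV series (ms grid).
#' @param activity Data frame with columns `t` (s) and `activity` (e.g. the
#'   state trajectory, or the transmitter's movement channel).
#' @param air_log Tibble `time_min`, `temp_C`: per-minute air temperatures.
#' @param meta Named list of run metadata: `run_id`, `individual_id`,
#'   `sex`, `run_order`, `round`.
#' @param defs Period definitions; only rows assigned to `keep_periods`
#'   enter the table.
#' @param keep_periods Periods eligible for modelling (default baseline and
#'   stressor).
#' @return A tibble of class `vt_obs` (the observation table): `t`,
#'   `period`, `region`, `temp`, `hrv`, `activity`, `position_index`,
#'   `air_temp`, `sex`, `individual_id`, `run_id`, `run_order`, `round`.
#' @export
match_synchronous <- function(temps, hrv, activity, air_log, meta,
                              defs = period_definitions(),
                              keep_periods = c("baseline", "stressor")) {
  stopifnot(is.data.frame(temps), inherits(hrv, "vt_uniform"))
  t0 <- attr(hrv, "t0"); step <- attr(hrv, "step")
  period <- assign_period(temps$time_s, defs)
  keep <- !is.na(period) & period %in% keep_periods
  obs <- temps[keep, , drop = FALSE]
  period <- period[keep]

  t_ms <- obs$time_s * 1000
  idx <- round((t_ms - t0) / step) + 1
  in_span <- idx >= 1 & idx <= nrow(hrv) &
    abs((idx - 1) * step + t0 - t_ms) <= step / 2
  hrv_val <- rep(NA_real_, nrow(obs))
  hrv_val[in_span] <- hrv$value[idx[in_span]]

  act <- approx(activity$t, activity$activity, xout = obs$time_s,
                rule = 1)$y
  air <- air_log$temp_C[match(floor(obs$time_s / 60), air_log$time_min)]

  ok <- !is.na(hrv_val) & !is.na(act) & !is.na(air) &
    !is.na(obs$position_index)
  out <- tibble(
    t = obs$time_s[ok],
    period = period[ok],
    region = obs$region[ok],
    temp = obs$temp[ok],
    hrv = hrv_val[ok],
    activity = act[ok],
    position_index = obs$position_index[ok],
    air_temp = air[ok],
    sex = meta$sex,
    individual_id = meta$individual_id,
    run_id = meta$run_id,
    run_order = meta$run_order,
    round = meta$round
  )
  attr(out, "n_dropped_join") <- sum(!ok)
  attr(out, "n_candidates") <- nrow(obs)
  class(out) <- c("vt_obs", class(out))
  out
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the values with replacement `B` times, computes the mean of
#' each resample, and returns the percentile interval of the resampled
#' means. Reproducible under a fixed seed.
#'
#' @param values Numeric vector (at least 2 values; identical values give a
#'   degenerate interval at their common value).
#' @param B Number of resamples (default 10000); below 100 a warning is
#'   issued.
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed set before resampling.
#' @return A named numeric vector `c(low, high)`.
#' @examples
#' bootstrap_ci(rnorm(30), B = 1000, seed = 1)
#' @export
bootstrap_ci <- function(values, B = 10000, level = 0.95, seed = NULL) {
  if (length(values) == 0L) {
    vt_abort("cannot bootstrap an empty sample.",
             class = "vasotherm_boot_error")
  }
  check_number(B, "B", lower = 1)
  check_number(level, "level", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (B < 100) rlang::warn("B < 100 resamples: interval will be unstable.")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  means <- rowMeans(matrix(values[sample.int(n, n * B, replace = TRUE)],
                           nrow = B))
  alpha <- (1 - level) / 2
  q <- quantile(means, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}
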