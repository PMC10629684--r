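# Independent brute-force oracles used to check the package's rolling
# statistics, ROI geometry and averaging arithmetic. These deliberately use
# naive O(n * w) / exhaustive-scan implementations.

# trailing-window CV: sd/mean over (t - window, t], sample sd, >= min_points
oracle_rolling_cv <- function(t, x, window = 2000, min_points = 3) {
  out_t <- numeric(0)
  out_cv <- numeric(0)
  for (i in seq_along(t)) {
    in_win <- t > t[i] - window & t <= t[i]
    w <- x[in_win]
    if (length(w) >= min_points) {
      out_t <- c(out_t, t[i])
      out_cv <- c(out_cv, stats::sd(w) / mean(w))
    }
  }
  list(t = out_t, cv = out_cv)
}

# trailing-window maximum over (t - window, t]
oracle_rolling_max <- function(t, x, window = 5) {
  vapply(seq_along(t), function(i) max(x[t > t[i] - window & t <= t[i]]),
         numeric(1))
}

# documented count encoding, restated independently: counts = (T + 50) * 400
temp_to_counts_test <- function(temp_c) {
  as.integer(round((temp_c + 50) * 400))
}

# exhaustive oval maximum: scan every pixel of the frame
oracle_oval_max <- function(frame, center, semi, map = count_map()) {
  best <- -Inf
  for (r in seq_len(nrow(frame))) {
    for (c in seq_len(ncol(frame))) {
      if (((r - center[1]) / semi[1])^2 + ((c - center[2]) / semi[2])^2 <= 1) {
        best <- max(best, frame[r, c])
      }
    }
  }
  best * map$slope + map$offset
}

# local-median artifact rule, written independently of the implementation
oracle_gap_flags <- function(rri, low = 0.5, high = 2, window = 11) {
  n <- length(rri)
  half <- floor(window / 2)
  flags <- logical(n)
  for (i in seq_len(n)) {
    idx <- max(1, i - half):min(n, i + half)
    m <- stats::median(rri[idx])
    flags[i] <- rri[i] < low * m | rri[i] > high * m
  }
  flags
}

# build a minimal state trajectory by hand (bypassing the simulator) so
# closed-form drives can be evaluated at chosen activation histories
manual_state <- function(t, s, activity = 0, step = t[2] - t[1]) {
  out <- tibble::tibble(t = t, s = s,
                        activity = rep_len(activity, length(t)))
  class(out) <- c("vt_state", class(out))
  attr(out, "step") <- step
  out
}

# hand-built model table for averaging arithmetic tests
fake_model_table <- function(aics, term_sets, estimates, ses = NULL) {
  if (is.null(ses)) ses <- lapply(estimates, function(e) rep(1, length(e)))
  tibble::tibble(
    model_id = seq_along(aics),
    AIC = aics,
    terms = term_sets,
    coefs = lapply(seq_along(aics), function(i) {
      tibble::tibble(term = term_sets[[i]],
                     estimate = estimates[[i]], se = ses[[i]])
    }),
    converged = TRUE
  )
}

# simulate a plain mixed-model table directly (no imaging/cardiac chain):
# y = intercept + X beta + individual effect + AR/exp noise
simulate_obs_table <- function(n_individuals = 4, n_per = 50,
                               beta = c(hrv = 0, activity = 0,
                                        position_index = 0, air_temp = 0,
                                        sex = 0),
                               sd_individual = 0, sd_resid = 0.3,
                               corr_range = 0, region = "bill",
                               dt = 2, seed = 1, center_groups = FALSE) {
  # center_groups demeans the noise within each individual, realising a
  # between-group residual variance of exactly zero (the degenerate
  # mixed-model limit, where the variance estimate must hit the boundary)
  set.seed(seed)
  rows <- lapply(seq_len(n_individuals), function(i) {
    # irregular sampling, as for quality-filtered frames
    t <- sort(stats::runif(n_per, 0, n_per * dt))
    eps <- if (corr_range > 0) {
      # exponentially correlated residuals from the exact covariance
      cv <- sd_resid^2 * exp(-abs(outer(t, t, "-")) / corr_range)
      as.numeric(t(chol(cv)) %*% stats::rnorm(n_per))
    } else {
      stats::rnorm(n_per, 0, sd_resid)
    }
    if (center_groups) eps <- eps - mean(eps)
    sex <- if (i %% 2 == 0) "male" else "female"
    hrv <- stats::runif(n_per, 0.01, 0.03)
    activity <- stats::rexp(n_per)
    position_index <- stats::runif(n_per, 19, 21)
    air_temp <- stats::rnorm(n_per, 20.8, 0.1)
    y <- 37 + beta["hrv"] * hrv + beta["activity"] * activity +
      beta["position_index"] * position_index +
      beta["air_temp"] * air_temp +
      beta["sex"] * (sex == "male") +
      stats::rnorm(1, 0, sd_individual) + eps
    tibble::tibble(
      t = t, period = "stressor", region = region, temp = y,
      hrv = hrv, activity = activity, position_index = position_index,
      air_temp = air_temp, sex = sex,
      individual_id = sprintf("bird%02d", i),
      run_id = sprintf("bird%02d_r1", i), run_order = 1L, round = 1L
    )
  })
  dplyr::bind_rows(rows)
}

# tiny protocol whose stressor machinery is over quickly; used where only
# the baseline matters or where frame counts must stay small
tiny_protocol <- function(run_end = 70, frame_rate = 2, ...) {
  protocol(capture_time = 1, injection_time = 2, release_time = 3,
           room_exit = 4, run_end = run_end, frame_rate = frame_rate, ...)
}
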