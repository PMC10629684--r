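test_that("R-R intervals are interval arithmetic stamped at the closing beat", {
  r <- compute_rri(c(0, 100, 200))
  expect_equal(r$t, c(100, 200))
  expect_equal(r$rri, c(100, 100))
  expect_false(any(r$removed))

  # n beats -> n - 1 intervals
  b <- cumsum(c(0, runif(49, 80, 120)))
  expect_equal(nrow(compute_rri(b)), 49)

  # a single 107.8 ms interval is 556.6 beats/min instantaneous HR
  r2 <- compute_rri(c(0, 107.8))
  expect_equal(instantaneous_heart_rate(r2)$hr, 60000 / 107.8)
  expect_equal(round(60000 / 107.8, 1), 556.6)

  expect_error(compute_rri(100), class = "vasotherm_rri_error")
  expect_error(compute_rri(c(0, 100, 90)))
})

test_that("R-peak detection recovers simulated beats and degrades safely", {
  st <- manual_state(seq(0, 30, 0.1), s = 0)
  beats <- simulate_beat_series(st, synthetic_truth(), seed = 4)
  ecg <- render_ecg(beats, snr_db = 20, seed = 1)
  det <- detect_r_peaks(ecg, min_separation_ms = 40)
  expect_equal(nrow(det), nrow(beats))
  expect_lt(max(abs(det$beat_ms - beats$beat_ms)), 2)

  # determinism on identical traces
  expect_identical(detect_r_peaks(ecg, 40), det)

  # flat trace: empty series, not an error
  flat <- tibble::tibble(time_ms = 0:999, value = 0)
  expect_equal(nrow(detect_r_peaks(flat, 40)), 0)

  # non-uniform sampling is rejected
  bad <- tibble::tibble(time_ms = c(0, 1, 3, 6), value = rnorm(4))
  expect_error(detect_r_peaks(bad, 40), class = "vasotherm_ecg_error")
})

test_that("gap-artifact flagging matches the local-median oracle", {
  # documented example: ~100 ms series with one 3000 ms dropout interval
  set.seed(1)
  rri_v <- rnorm(60, 100, 3)
  rri_v[30] <- 3000
  beats <- cumsum(c(0, rri_v))
  flagged <- remove_gap_artifacts(compute_rri(beats))
  expect_true(flagged$removed[30])
  expect_equal(sum(flagged$removed), 1)

  # oracle equivalence on series with random gap and spike artifacts
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(80, 100, 3)
    n_art <- sample(0:4, 1)
    pos <- sample(seq_along(x), n_art)
    x[pos] <- sample(c(10, 20, 2500, 4000), n_art, replace = TRUE)
    r <- tibble::tibble(t = cumsum(x), rri = x, removed = FALSE)
    got <- remove_gap_artifacts(r)
    expect_equal(got$removed, oracle_gap_flags(x))
  }

  # physiological series at CV 0.03: no removals at defaults
  st <- manual_state(seq(0, 120, 0.1), s = 0)
  clean <- compute_rri(simulate_beat_series(st, synthetic_truth(), seed = 6))
  expect_equal(sum(remove_gap_artifacts(clean)$removed), 0)

  # flagging is non-destructive and monotone
  pre <- clean
  pre$removed[5] <- TRUE
  out <- remove_gap_artifacts(pre)
  expect_equal(nrow(out), nrow(pre))
  expect_equal(out$t, pre$t)
  expect_true(out$removed[5])

  expect_error(remove_gap_artifacts(clean, window_beats = 2))
  expect_error(remove_gap_artifacts(clean, low_mult = 1.5))
})

test_that("instantaneous heart rate converts retained intervals only", {
  r <- tibble::tibble(t = c(100, 200, 300), rri = c(100, 60000, 100),
                      removed = c(FALSE, FALSE, TRUE))
  hr <- instantaneous_heart_rate(r)
  expect_equal(hr$hr, c(600, 1))        # 100 ms -> 600; 60000 ms -> 1
  expect_equal(nrow(hr), 2)             # removed point absent
  r$rri[1] <- -5
  expect_error(instantaneous_heart_rate(r), class = "vasotherm_rri_error")
})

test_that("rolling CV equals the trailing-window oracle", {
  expect_equal(formals(rolling_cv_hrv)$window, 2000)

  # constant intervals: CV identically zero wherever defined
  const <- compute_rri(seq(0, 10000, by = 100))
  cv0 <- rolling_cv_hrv(const)
  expect_true(all(cv0$cv == 0))

  # alternating 90/110 over 10 s against the brute-force oracle
  alt <- compute_rri(cumsum(c(0, rep(c(90, 110), 50))))
  got <- rolling_cv_hrv(alt)
  want <- oracle_rolling_cv(alt$t, alt$rri)
  expect_equal(got$t, want$t)
  expect_equal(got$cv, want$cv, tolerance = 1e-12)

  # random series property, including removed-point exclusion
  for (s in 1:25) {
    set.seed(s)
    x <- rnorm(150, 100, 5)
    r <- tibble::tibble(t = cumsum(x), rri = x,
                        removed = runif(150) < 0.1)
    got <- rolling_cv_hrv(r)
    kept <- r[!r$removed, ]
    want <- oracle_rolling_cv(kept$t, kept$rri)
    expect_equal(got$t, want$t)
    expect_equal(got$cv, want$cv, tolerance = 1e-12)
  }
})

test_that("baseline rolling CV recovers the configured generator CV", {
  # across seeds, the baseline-period mean CV sits within 3 Monte-Carlo
  # standard errors of cv_baseline
  tr <- synthetic_truth()
  means <- vapply(1:50, function(s) {
    st <- manual_state(seq(-60, 1, 0.1), s = 0)
    rri <- compute_rri(simulate_beat_series(st, tr, seed = s))
    cv <- rolling_cv_hrv(rri)
    mean(cv$cv[cv$t >= -60000 & cv$t < 0])
  }, numeric(1))
  mc_se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - tr$cv_baseline), 3 * mc_se + 0.002)
})

test_that("onset-spike censoring removes exactly the guarded exceedances", {
  hrv <- tibble::tibble(
    t = c(-5000, 5000, 5000, 12000, 9000),
    cv = c(0.05, 0.05, 0.01, 0.05, 0.02)
  )[order(c(-5000, 5000, 5000, 12000, 9000)), ]
  out <- censor_onset_spikes(hrv, baseline_mean = 0.03, onset = 0)
  # removed: the 0.05 at 5 s; kept: baseline point (before onset), the
  # 0.01 at 5 s (below baseline), 0.02 at 9 s, and 0.05 at 12 s (outside)
  expect_equal(nrow(out), 4)
  expect_false(any(out$t >= 0 & out$t < 10000 & out$cv > 0.03))
  expect_true(all(c(-5000, 12000) %in% out$t))

  # idempotent and never adds points
  expect_identical(censor_onset_spikes(out, 0.03, 0), out)
  expect_lte(nrow(out), nrow(hrv))

  expect_error(censor_onset_spikes(hrv, 0.03, 0, guard = -1))
})

test_that("grid interpolation is linear, exact at samples, and gap-safe", {
  expect_equal(formals(interpolate_to_grid)$step, 1)

  pts <- tibble::tibble(t = c(0, 1000), v = c(100, 200))
  g <- interpolate_to_grid(pts, step = 500, max_gap = Inf)
  expect_equal(g$value[g$t == 500], 150)
  expect_equal(g$value[g$t == 0], 100)
  expect_equal(g$value[g$t == 1000], 200)
  expect_equal(range(g$t), c(0, 1000))   # no extrapolation

  # cells inside a gap wider than max_gap are missing, not interpolated
  pts2 <- tibble::tibble(t = c(0, 1000, 8000, 9000), v = c(1, 2, 3, 4))
  g2 <- interpolate_to_grid(pts2, step = 100, max_gap = 2000)
  inside <- g2$t > 1000 & g2$t < 8000
  expect_true(all(is.na(g2$value[inside])))
  expect_true(all(!is.na(g2$value[!inside])))
  # original sample values reproduced exactly
  expect_equal(g2$value[match(pts2$t, g2$t)], pts2$v)

  expect_error(interpolate_to_grid(pts, step = 0))
  expect_error(interpolate_to_grid(pts[1, ]),
               class = "vasotherm_interp_error")
})
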