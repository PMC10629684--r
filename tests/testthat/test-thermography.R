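make_small_run_frames <- function(seed = 1, ...) {
  tr <- synthetic_truth(usable_fraction = 1, ...)
  pr <- tiny_protocol(run_end = 8, frame_rate = 1, baseline_start = -4)
  st <- manual_state(seq(-4, 8, 0.1), s = 0)
  simulate_thermal_frames(st, tr, pr, seed = seed, run_offset = 0)
}

test_that("frames round-trip through 16-bit TIFF bit-exactly", {
  fr <- make_small_run_frames()
  dir <- withr::local_tempdir()
  write_frames(fr, dir)
  back <- read_frames(dir)
  expect_equal(length(back$frames), nrow(back$sidecar))
  # bit-exact counts (readTIFF attaches format attributes; compare content)
  expect_true(all(mapply(function(a, b) {
    identical(dim(a), dim(b)) && identical(as.vector(a), as.vector(b))
  }, back$frames, fr$frames)))
  expect_equal(back$sidecar$time_s, fr$sidecar$time_s)

  # an 8-bit frame is rejected with its identity
  tiff::writeTIFF(matrix(0.5, 4, 4), file.path(dir, "frames", "frame_00001.tiff"),
                  bits.per.sample = 8L)
  expect_error(read_frames(dir), class = "vasotherm_frame_error")

  # frame/sidecar count mismatch is rejected
  dir2 <- withr::local_tempdir()
  write_frames(fr, dir2)
  file.remove(file.path(dir2, "frames", "frame_00002.tiff"))
  expect_error(read_frames(dir2), class = "vasotherm_frame_error")
})

test_that("ROI maximum honours containment and matches exhaustive scans", {
  map <- count_map()
  f <- matrix(temp_to_counts_test(20), 32, 40)
  # hottest pixel inside the oval is returned
  f[16, 20] <- temp_to_counts_test(35)
  roi <- roi_oval(c(16, 20), c(5, 5))
  expect_equal(extract_roi_max(f, roi), 35)
  # hotter pixel outside the oval is ignored; second-hottest inside wins
  f[2, 2] <- temp_to_counts_test(50)
  expect_equal(extract_roi_max(f, roi), 35)

  # line ROI: max over the 8-connected rasterization
  f2 <- matrix(temp_to_counts_test(20), 32, 40)
  f2[10, 5:24] <- temp_to_counts_test(30)
  f2[10, 15] <- temp_to_counts_test(33)
  f2[11, 15] <- temp_to_counts_test(45)   # adjacent to, not on, the line
  expect_equal(extract_roi_max(f2, roi_line(c(10, 5), c(10, 24))), 33)

  # exhaustive oracle over random scenes and oval geometries
  for (s in 1:200) {
    set.seed(s)
    f3 <- matrix(sample.int(60000, 20 * 24, replace = TRUE), 20, 24)
    ctr <- c(runif(1, 6, 14), runif(1, 7, 17))
    semi <- c(runif(1, 2, 5), runif(1, 2, 6))
    got <- extract_roi_max(f3, roi_oval(ctr, semi))
    expect_equal(got, oracle_oval_max(f3, ctr, semi))
  }

  # ROI outside frame or empty pixel set is rejected
  expect_error(extract_roi_max(f, roi_oval(c(2, 2), c(5, 5))),
               class = "vasotherm_roi_error")
  expect_error(extract_roi_max(f, roi_oval(c(16.5, 20.5), c(0.4, 0.4))),
               class = "vasotherm_roi_error")
})

test_that("ROI maximum ignores every exterior pixel", {
  set.seed(7)
  for (s in 1:20) {
    f <- matrix(sample.int(50000, 18 * 18, replace = TRUE), 18, 18)
    roi <- roi_oval(c(9, 9), c(4, 4))
    base <- extract_roi_max(f, roi)
    # perturb a random exterior pixel to the global maximum
    repeat {
      r <- sample(18, 1); c <- sample(18, 1)
      if (((r - 9) / 4)^2 + ((c - 9) / 4)^2 > 1) break
    }
    f[r, c] <- 65535L
    expect_equal(extract_roi_max(f, roi), base)
  }
})

test_that("reference calibration corrects additive camera error", {
  # offset arithmetic: logger 20.0, camera sees 19.0, raw 35.9 -> 36.9
  raw <- tibble::tibble(time_s = 30, temp = 35.9)
  cam <- tibble::tibble(time_min = 0, camera_est = 19.0)
  log <- tibble::tibble(time_min = 0, temp_C = 20.0)
  expect_equal(calibrate(raw, cam, log)$temp, 36.9)

  # zero bias: identity
  cam0 <- tibble::tibble(time_min = 0, camera_est = 20.0)
  expect_equal(calibrate(raw, cam0, log)$temp, 35.9)

  # missing reference minute: observation excluded and counted
  raw2 <- tibble::tibble(time_s = c(30, 90), temp = c(35.9, 36.2))
  out <- calibrate(raw2, cam, log)
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_uncalibrated"), 1)

  # generator bias is recovered up to count quantization
  fr <- make_small_run_frames(seed = 3, camera_bias = -0.7, temp_noise_sd = 0,
                              activity_effect = 0)
  eye_raw <- extract_region_series(fr, "eye", calibrated = FALSE)
  expect_lt(max(abs(eye_raw$temp - (fr$sidecar$true_eye - 0.7))), 0.0026)
  eye_cal <- extract_region_series(fr, "eye", calibrated = TRUE)
  expect_lt(max(abs(eye_cal$temp - fr$sidecar$true_eye)), 0.0026)
})

test_that("quality filtering drops exactly the flagged rows", {
  s <- tibble::tibble(time_s = 1:6, temp = 30 + 1:6,
                      quality = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  out <- quality_filter(s)
  expect_equal(nrow(out), 4)
  expect_equal(attr(out, "n_dropped"), 2)
  all_true <- quality_filter(dplyr::mutate(s, quality = TRUE))
  expect_equal(nrow(all_true), 6)
  all_false <- quality_filter(dplyr::mutate(s, quality = FALSE))
  expect_equal(nrow(all_false), 0)
})

test_that("rolling maximum is a trailing idempotent envelope", {
  expect_equal(formals(rolling_max_filter)$window, 5)

  # monotone non-decreasing series unchanged
  mono <- tibble::tibble(time_s = 1:10, temp = cumsum(runif(10)))
  expect_equal(rolling_max_filter(mono)$temp, mono$temp)

  # single cold dip within the window replaced by the preceding maximum
  dip <- tibble::tibble(time_s = c(0, 2, 4), temp = c(36.5, 33.0, 36.2))
  expect_equal(rolling_max_filter(dip)$temp, c(36.5, 36.5, 36.5))

  # oracle match and pointwise dominance on random series; a second
  # application can only extend maxima forward, never lower anything
  for (s in 1:25) {
    set.seed(s)
    d <- tibble::tibble(time_s = sort(runif(60, 0, 120)),
                        temp = rnorm(60, 36, 0.5))
    once <- rolling_max_filter(d)
    expect_equal(once$temp, oracle_rolling_max(d$time_s, d$temp))
    expect_true(all(once$temp >= d$temp))
    expect_true(all(rolling_max_filter(once)$temp >= once$temp))
    expect_equal(once$time_s, d$time_s)
  }

  # with every gap wider than the window the filter is the identity, and
  # therefore idempotent
  sparse <- tibble::tibble(time_s = seq(0, 120, by = 7),
                           temp = rnorm(18, 36, 0.5))
  expect_equal(rolling_max_filter(sparse), sparse)
  expect_equal(rolling_max_filter(rolling_max_filter(sparse)), sparse)

  expect_error(rolling_max_filter(tibble::tibble(time_s = c(2, 1),
                                                 temp = c(1, 2))),
               class = "vasotherm_sort_error")
})

test_that("position index is the frame's bill length, shared across regions", {
  fr <- make_small_run_frames(seed = 5)
  px <- measure_position_index(fr$sidecar)
  expect_equal(px, as.numeric(fr$sidecar$bill_px))
  expect_true(all(px >= 19 & px <= 21))

  eye <- extract_region_series(fr, "eye")
  bill <- extract_region_series(fr, "bill")
  expect_equal(eye$position_index, bill$position_index)

  bad <- fr$sidecar
  bad$bill_px[2] <- 0
  expect_warning(px2 <- measure_position_index(bad))
  expect_true(is.na(px2[2]))
})
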