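#' Default scene layout for synthetic thermal frames
#'
#' Frame geometry for the synthetic radiometric scene: an oval eye-ring ROI
#' of ~150 pixels, a horizontal bill line of 19-21 pixels, and a disc-shaped
#' reference target (an insulated contact logger taped to the cage front).
#' Coordinates are 1-based (row, col) with origin at the top-left pixel.
#'
#' @param nrow,ncol Frame dimensions in pixels.
#' @return A named list with frame dimensions and the three ROI definitions.
#' @export
default_scene <- function(nrow = 64, ncol = 96) {
  list(
    nrow = nrow, ncol = ncol,
    eye = roi_oval(center = c(20, 48), semi_axes = c(7, 7)),
    bill_row = 34, bill_col0 = 16, bill_len_range = c(19L, 21L),
    reference = roi_oval(center = c(52, 78), semi_axes = c(6, 6)),
    background_offset = -2   # cage background sits below air temperature
  )
}

#' Linear count-to-temperature mapping of the synthetic camera
#'
#' 16-bit counts encode temperature as `counts = (T_degC + 50) * 400`,
#' clamped to `[0, 65535]`: a -50 to +113.8 deg C span at 0.0025 deg C
#' resolution, comfortably beyond any scene temperature.
#'
#' @return A list with `slope` and `offset` such that
#'   `T_degC = counts * slope + offset`.
#' @export
count_map <- function() {
  list(slope = 1 / 400, offset = -50)
}

temp_to_counts <- function(temp_c) {
  m <- pmin(pmax(round((temp_c + 50) * 400), 0), 65535)
  storage.mode(m) <- "integer"
  m
}

#' Simulate a sequence of radiometric thermal frames with sidecar metadata
#'
#' Renders one 16-bit grayscale frame per camera tick over the protocol
#' window. Each frame contains (i) an eye-ring ROI whose true maximum
#' temperature is `teye_baseline - beta_eye * d_eye(t) -
#' activity_effect * activity(t) + noise`, where the eye drive is
#' proportional to activation with a partial mid-stressor recovery dip;
#' (ii) a bill ROI whose drive either integrates activation over the
#' stressor (`bill_drive = "cumulative"`, a consistent drop throughout
#' handling that recovers with time constant `bill_tau`) or tracks
#' activation directly (`"proportional"`); and (iii) a reference-target
#' region rendered at the logged reference temperature. The camera bias
#' `truth$camera_bias` is added to every pixel, so downstream reference
#' calibration should remove it exactly (up to count quantization).
#'
#' The per-minute reference log emulates an independent contact logger:
#' readings are the room air temperature plus slow drift. The sidecar table
#' carries, per frame: timestamp, quality flag (a Bernoulli draw with
#' success probability `truth$usable_fraction`, emulating frames where the
#' head is sharp and in profile), the rendered bill length in pixels
#' (position index, drawn from the configured range as camera-distance /
#' head-angle variation), serialized ROI geometry, and ground-truth scene
#' temperatures (`true_eye`, `true_bill`, `true_ref`) for validation.
#'
#' @param state A [simulate_autonomic_state()] trajectory covering the
#'   protocol window.
#' @param truth A [synthetic_truth()].
#' @param protocol A [protocol()]; `frame_rate` sets the camera tick.
#' @param seed Integer seed.
#' @param scene Scene layout from [default_scene()]; frames too small to
#'   contain the ROIs are rejected.
#' @param run_offset Per-run baseline temperature offset (deg C). `NULL`
#'   (default) draws one from `N(0, truth$run_offset_sd)`.
#' @return A list of class `vt_frames`: `frames` (list of integer count
#'   matrices), `sidecar` (tibble), `reference` (tibble `time_min`,
#'   `temp_C`), `count_map`, `scene`, `run_offset`.
#' @examples
#' pr <- protocol(run_end = 30, frame_rate = 1)
#' st <- simulate_autonomic_state(pr, synthetic_truth(), seed = 1)
#' fr <- simulate_thermal_frames(st, synthetic_truth(), pr, seed = 1)
#' length(fr$frames)
#' @export
simulate_thermal_frames <- function(state, truth, protocol, seed,
                                    scene = default_scene(),
                                    run_offset = NULL) {
  stopifnot(inherits(state, "vt_state"), inherits(truth, "vt_truth"),
            inherits(protocol, "vt_protocol"))
  validate_scene(scene)
  set.seed(seed)

  if (is.null(run_offset)) {
    run_offset <- rnorm(1, 0, truth$run_offset_sd)
  }

  t_frames <- seq(protocol$baseline_start, protocol$run_end,
                  by = 1 / protocol$frame_rate)
  n <- length(t_frames)

  # reference logger: one reading per minute covering the run
  minutes <- seq(floor(protocol$baseline_start / 60),
                 floor(protocol$run_end / 60))
  logged <- protocol$air_temperature +
    cumsum(rnorm(length(minutes), 0, 0.03))
  reference <- tibble(time_min = minutes, temp_C = logged)

  # interpolate latent signals at frame times
  s_f <- approx(state$t, state$s, xout = t_frames, rule = 2)$y
  act_f <- approx(state$t, state$activity, xout = t_frames, rule = 2)$y

  d_eye <- eye_drive(t_frames, s_f)
  d_bill <- bill_drive_profile(t_frames, state, protocol, truth)

  eps_eye <- rnorm(n, 0, truth$temp_noise_sd)
  eps_bill <- rnorm(n, 0, truth$temp_noise_sd)

  true_eye <- truth$teye_baseline - truth$beta_eye * d_eye -
    truth$activity_effect * act_f + run_offset + eps_eye
  true_bill <- truth$tbill_baseline - truth$beta_bill * d_bill -
    truth$activity_effect * act_f + run_offset + eps_bill
  frame_min <- floor(t_frames / 60)
  true_ref <- logged[match(frame_min, minutes)]

  bill_len <- sample(seq(scene$bill_len_range[1], scene$bill_len_range[2]),
                     n, replace = TRUE)
  quality <- runif(n) < truth$usable_fraction

  # precompute pixel index sets; bill mask depends on drawn length
  eye_idx <- oval_indices(scene$eye, scene$nrow, scene$ncol)
  ref_idx <- oval_indices(scene$reference, scene$nrow, scene$ncol)
  eye_profile <- oval_profile(scene$eye, scene$nrow, scene$ncol)

  bg <- protocol$air_temperature + scene$background_offset
  bias <- truth$camera_bias

  frames <- vector("list", n)
  for (i in seq_len(n)) {
    m <- matrix(bg, scene$nrow, scene$ncol)
    # eye: hottest at centre, cooling outward so the max sits at true_eye
    m[eye_idx] <- true_eye[i] - eye_profile
    # bill: uniform along the drawn line
    cols <- scene$bill_col0:(scene$bill_col0 + bill_len[i] - 1L)
    m[cbind(rep(scene$bill_row, length(cols)), cols)] <- true_bill[i]
    # reference target: uniform at the logged temperature
    m[ref_idx] <- true_ref[i]
    frames[[i]] <- temp_to_counts(m + bias)
  }

  sidecar <- tibble(
    frame_id = seq_len(n),
    time_s = t_frames,
    quality = quality,
    bill_px = bill_len,
    eye_row = scene$eye$center[1], eye_col = scene$eye$center[2],
    eye_a = scene$eye$semi_axes[1], eye_b = scene$eye$semi_axes[2],
    bill_row = scene$bill_row, bill_col0 = scene$bill_col0,
    bill_col1 = scene$bill_col0 + bill_len - 1L,
    ref_row = scene$reference$center[1], ref_col = scene$reference$center[2],
    ref_a = scene$reference$semi_axes[1], ref_b = scene$reference$semi_axes[2],
    true_eye = true_eye, true_bill = true_bill, true_ref = true_ref
  )

  structure(
    list(frames = frames, sidecar = sidecar, reference = reference,
         count_map = count_map(), scene = scene, run_offset = run_offset,
         seed = seed),
    class = "vt_frames"
  )
}

# eye drive: proportional to activation with a partial recovery dip
# centred ~40 s into the stressor
eye_drive <- function(t, s) {
  dip <- 1 - 0.7 * exp(-((t - 40) / 12)^2)
  pmax(s * ifelse(t >= 0, dip, 1), 0)
}

# bill drive: either integrates activation over the stressor and then decays
# (cumulative vasomotor drop), or tracks activation directly
bill_drive_profile <- function(t_frames, state, protocol, truth) {
  if (truth$bill_drive == "proportional") {
    return(approx(state$t, state$s, xout = t_frames, rule = 2)$y)
  }
  step <- attr(state, "step") %||% (state$t[2] - state$t[1])
  s_pos <- ifelse(state$t >= 0 & state$t <= protocol$room_exit, state$s, 0)
  cum <- cumsum(s_pos) * step / (protocol$room_exit - protocol$stressor_onset)
  cum <- pmin(cum, 1)
  d <- approx(state$t, cum, xout = t_frames, rule = 2)$y
  post <- t_frames > protocol$room_exit
  if (any(post)) {
    d_exit <- max(cum[state$t <= protocol$room_exit])
    d[post] <- d_exit * exp(-(t_frames[post] - protocol$room_exit) / truth$bill_tau)
  }
  d
}

validate_scene <- function(scene) {
  eye <- scene$eye; ref <- scene$reference
  inside <- function(roi) {
    roi$center[1] - roi$semi_axes[1] >= 1 &&
      roi$center[1] + roi$semi_axes[1] <= scene$nrow &&
      roi$center[2] - roi$semi_axes[2] >= 1 &&
      roi$center[2] + roi$semi_axes[2] <= scene$ncol
  }
  bill_ok <- scene$bill_row >= 1 && scene$bill_row <= scene$nrow &&
    scene$bill_col0 >= 1 &&
    scene$bill_col0 + max(scene$bill_len_range) - 1 <= scene$ncol
  if (!inside(eye) || !inside(ref) || !bill_ok) {
    vt_abort("frame dimensions too small to contain the scene ROIs.",
             class = "vasotherm_scene_error")
  }
  invisible(scene)
}

oval_indices <- function(roi, nrow, ncol) {
  which_oval(roi, nrow, ncol)
}

# linear index set of pixels whose centres satisfy the ellipse inequality
which_oval <- function(roi, nrow, ncol) {
  r <- seq_len(nrow); c <- seq_len(ncol)
  rr <- matrix(r, nrow, ncol)
  cc <- matrix(c, nrow, ncol, byrow = TRUE)
  inside <- ((rr - roi$center[1]) / roi$semi_axes[1])^2 +
    ((cc - roi$center[2]) / roi$semi_axes[2])^2 <= 1
  which(inside)
}

# radial cooling profile over the oval's pixels (same order as which_oval):
# 0 at the centre pixel so the ROI maximum equals the rendered temperature
oval_profile <- function(roi, nrow, ncol) {
  lin <- which_oval(roi, nrow, ncol)
  rc <- cbind((lin - 1L) %% nrow + 1L, (lin - 1L) %/% nrow + 1L)
  d <- sqrt(((rc[, 1] - roi$center[1]) / roi$semi_axes[1])^2 +
              ((rc[, 2] - roi$center[2]) / roi$semi_axes[2])^2)
  0.8 * d^2
}

#' Write synthetic frames and sidecars to disk
#'
#' Persists a [simulate_thermal_frames()] result in its on-disk interchange
#' form: per-frame 16-bit grayscale TIFFs under `frames/`, plus `sidecar.tsv`
#' and `reference.tsv`.
#'
#' @param x A `vt_frames` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(x, dir) {
  stopifnot(inherits(x, "vt_frames"))
  frame_dir <- file.path(dir, "frames")
  dir.create(frame_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(x$frames)) {
    path <- file.path(frame_dir, sprintf("frame_%05d.tiff", i))
    tiff::writeTIFF(x$frames[[i]] / 65535, path, bits.per.sample = 16L)
  }
  readr::write_tsv(x$sidecar, file.path(dir, "sidecar.tsv"))
  readr::write_tsv(x$reference, file.path(dir, "reference.tsv"))
  invisible(dir)
}
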