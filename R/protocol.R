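#' Capture-and-handling protocol timeline
#'
#' Describes one experimental run on a clock whose origin (0 s) is stressor
#' onset: the experimenter entering the room. The default event times follow
#' a 30-minute capture-and-handling protocol in which the bird is captured
#' ~22 s after onset, injected ~70 s, released from the hand ~87 s, and the
#' experimenter leaves the room at 180 s; recording spans one minute of
#' baseline before onset to 30 minutes after.
#'
#' @param baseline_start Start of recording, seconds relative to stressor
#'   onset (negative; default -60).
#' @param stressor_onset Always 0 s; retained as an explicit field so that
#'   downstream period definitions can refer to it.
#' @param capture_time,injection_time,release_time Handling event times (s).
#' @param room_exit Time the experimenter leaves the room (s, default 180);
#'   the end of the stressor period.
#' @param run_end End of recording (s, default 1800).
#' @param frame_rate Thermal camera frame rate (frames/s, default 7.5).
#' @param air_temperature Room air temperature (deg C, default 20.8).
#'
#' @return An object of class `vt_protocol` (a named list).
#' @examples
#' protocol(run_end = 600, frame_rate = 1)
#' @export
protocol <- function(baseline_start = -60, stressor_onset = 0,
                     capture_time = 22.3, injection_time = 70.5,
                     release_time = 87.1, room_exit = 180,
                     run_end = 1800, frame_rate = 7.5,
                     air_temperature = 20.8) {
  p <- list(
    baseline_start = baseline_start, stressor_onset = stressor_onset,
    capture_time = capture_time, injection_time = injection_time,
    release_time = release_time, room_exit = room_exit,
    run_end = run_end, frame_rate = frame_rate,
    air_temperature = air_temperature
  )
  for (nm in names(p)) check_number(p[[nm]], nm)
  ok <- baseline_start < 0 && 0 <= capture_time &&
    capture_time < injection_time && injection_time < release_time &&
    release_time <= room_exit && room_exit < run_end
  if (!ok) {
    vt_abort(paste(
      "invalid protocol ordering: need baseline_start < 0 <= capture_time <",
      "injection_time < release_time <= room_exit < run_end"
    ), class = "vasotherm_protocol_error")
  }
  check_number(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  structure(p, class = "vt_protocol")
}

#' @export
print.vt_protocol <- function(x, ...) {
  cat("<vt_protocol>\n")
  cat(sprintf("  recording: %g to %g s (onset at 0 s)\n",
              x$baseline_start, x$run_end))
  cat(sprintf("  events: capture %g s, injection %g s, release %g s, room exit %g s\n",
              x$capture_time, x$injection_time, x$release_time, x$room_exit))
  cat(sprintf("  frames: %g Hz; air %g degC\n", x$frame_rate, x$air_temperature))
  invisible(x)
}

#' Ground-truth parameters for the synthetic generator
#'
#' Collects every parameter of the synthetic cardiac/thermal generator,
#' together with the seed, so that recovery tests can compare pipeline
#' estimates against known truth. Defaults are calibrated to the acute-stress
#' response of a small passerine: baseline heart rate ~557 beats/min rising
#' to ~875 beats/min under handling; heart-rate variability (2 s rolling CV
#' of R-R intervals) dropping 0.03 -> 0.01; eye-ring surface temperature
#' 36.9 deg C with a ~1 deg C vasoconstrictive drop; bill surface temperature
#' 38.9 deg C with a cumulative ~4 deg C drop over a 180 s stressor.
#'
#' @param hr_baseline,hr_stress Heart rate (beats/min) at rest and at full
#'   sympathetic activation. Must satisfy `hr_stress > hr_baseline`.
#' @param cv_baseline,cv_stress Coefficient of variation of R-R intervals at
#'   rest and at full activation. Must satisfy `cv_stress < cv_baseline`.
#' @param teye_baseline,tbill_baseline Resting maximum regional surface
#'   temperatures (deg C).
#' @param beta_eye,beta_bill Coupling of surface temperature on sympathetic
#'   activation (deg C drop per unit activation).
#' @param camera_bias Systematic camera error injected into every rendered
#'   pixel (deg C); the reference-target calibration should remove it.
#' @param activity_effect Temperature drop per unit activity signal
#'   (deg C; motion blur depresses apparent maxima).
#' @param temp_noise_sd SD of per-observation temperature noise (deg C).
#' @param run_offset_sd SD of the per-run (per-bird) baseline temperature
#'   offset (deg C); gives the random-intercept structure its variance.
#' @param gap_rate,spike_rate Per-beat probabilities of a dropped beat
#'   (telemetry gap) and of an inserted spurious detection.
#' @param usable_fraction Fraction of thermal frames in which the head is
#'   sharp and in profile, i.e. marked quality-usable.
#' @param recovery_tau Exponential recovery time constant of sympathetic
#'   activation after the stressor ends (s).
#' @param bill_tau Recovery time constant of the bill's cumulative vasomotor
#'   drive (s); slower than the eye's, so the bill stays cool longer.
#' @param bill_drive `"cumulative"` integrates activation over the stressor
#'   (consistent drop throughout handling); `"proportional"` makes the bill
#'   track activation directly, which gives the temperature--HRV relation a
#'   well-defined structural slope for recovery benchmarks.
#' @param seed Integer seed recorded with every generated dataset.
#'
#' @return An object of class `vt_truth` (a named list).
#' @examples
#' synthetic_truth(seed = 1)
#' @export
synthetic_truth <- function(hr_baseline = 556.7, hr_stress = 875,
                            cv_baseline = 0.03, cv_stress = 0.01,
                            teye_baseline = 36.9, tbill_baseline = 38.9,
                            beta_eye = 1, beta_bill = 4,
                            camera_bias = -0.7, activity_effect = 0.3,
                            temp_noise_sd = 0.2, run_offset_sd = 0.3,
                            gap_rate = 0, spike_rate = 0,
                            usable_fraction = 0.03,
                            recovery_tau = 300, bill_tau = 450,
                            bill_drive = c("cumulative", "proportional"),
                            seed = NULL) {
  bill_drive <- match.arg(bill_drive)
  tr <- list(
    hr_baseline = hr_baseline, hr_stress = hr_stress,
    cv_baseline = cv_baseline, cv_stress = cv_stress,
    teye_baseline = teye_baseline, tbill_baseline = tbill_baseline,
    beta_eye = beta_eye, beta_bill = beta_bill,
    camera_bias = camera_bias, activity_effect = activity_effect,
    temp_noise_sd = temp_noise_sd, run_offset_sd = run_offset_sd,
    gap_rate = gap_rate, spike_rate = spike_rate,
    usable_fraction = usable_fraction,
    recovery_tau = recovery_tau, bill_tau = bill_tau,
    bill_drive = bill_drive, seed = seed
  )
  num <- setdiff(names(tr), c("bill_drive", "seed"))
  for (nm in num) check_number(tr[[nm]], nm)
  if (hr_stress <= hr_baseline) vt_abort("`hr_stress` must exceed `hr_baseline`.")
  if (cv_stress > cv_baseline) vt_abort("`cv_stress` must not exceed `cv_baseline`.")
  check_number(cv_baseline, "cv_baseline", lower = 0)
  check_number(cv_stress, "cv_stress", lower = 0)
  check_number(gap_rate, "gap_rate", lower = 0, upper = 1)
  check_number(spike_rate, "spike_rate", lower = 0, upper = 1)
  check_number(usable_fraction, "usable_fraction", lower = 0, upper = 1)
  check_number(temp_noise_sd, "temp_noise_sd", lower = 0)
  check_number(run_offset_sd, "run_offset_sd", lower = 0)
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
      vt_abort("`seed` must be a single integer.")
    }
    tr$seed <- as.integer(seed)
  }
  structure(tr, class = "vt_truth")
}

#' @export
print.vt_truth <- function(x, ...) {
  cat("<vt_truth>\n")
  cat(sprintf("  HR %g -> %g beats/min; CV %g -> %g\n",
              x$hr_baseline, x$hr_stress, x$cv_baseline, x$cv_stress))
  cat(sprintf("  T_eye %g degC (beta %g); T_bill %g degC (beta %g, %s drive)\n",
              x$teye_baseline, x$beta_eye, x$tbill_baseline, x$beta_bill,
              x$bill_drive))
  cat(sprintf("  camera bias %g degC; seed %s\n", x$camera_bias,
              if (is.null(x$seed)) "<unset>" else x$seed))
  invisible(x)
}

#' Serialise and restore a ground-truth record
#'
#' Writes every generator parameter, including the seed, to a YAML key-value
#' file so a downstream recovery analysis can reload the exact generating
#' conditions. A record without a seed is refused: without it the dataset is
#' not reproducible and truth comparison is meaningless.
#'
#' @param truth A [synthetic_truth()] object with a non-null seed.
#' @param path File path to write to / read from.
#' @return `write_truth_record()` returns `path` invisibly;
#'   `read_truth_record()` returns a `vt_truth` identical to the one written.
#' @examples
#' tr <- synthetic_truth(seed = 42)
#' p <- tempfile(fileext = ".yaml")
#' write_truth_record(tr, p)
#' identical(read_truth_record(p), tr)
#' @export
write_truth_record <- function(truth, path) {
  stopifnot(inherits(truth, "vt_truth"))
  if (is.null(truth$seed)) {
    vt_abort("truth record must carry a seed.", class = "vasotherm_truth_error")
  }
  yaml::write_yaml(unclass(truth), path)
  invisible(path)
}

#' @rdname write_truth_record
#' @export
read_truth_record <- function(path) {
  rec <- yaml::read_yaml(path)
  do.call(synthetic_truth, rec)
}
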