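#' Simulate the latent autonomic state of one run
#'
#' Produces the latent sympathetic-activation trajectory `s(t)` in [0, 1]
#' driving both the cardiac and the thermal generators, plus a non-negative
#' activity (movement) signal. Activation follows a logistic rise at stressor
#' onset reaching 90% of its ceiling 15 s after onset, holds near 1 while the
#' experimenter is in the room, and recovers exponentially (time constant
#' `truth$recovery_tau`) after `protocol$room_exit`. Activity is a shot-noise
#' process: Poisson-timed movement bursts with exponentially decaying
#' kernels, whose rate is elevated while the bird is being handled.
#'
#' @param protocol A [protocol()].
#' @param truth A [synthetic_truth()].
#' @param seed Integer seed; the trajectory is bit-reproducible given it.
#' @param step Grid step in seconds (default 0.1).
#' @return A tibble of class `vt_state` with columns `t` (s), `s`
#'   (activation, dimensionless) and `activity`.
#' @examples
#' st <- simulate_autonomic_state(protocol(run_end = 300), synthetic_truth(), seed = 1)
#' range(st$s)
#' @export
simulate_autonomic_state <- function(protocol, truth, seed, step = 0.1) {
  stopifnot(inherits(protocol, "vt_protocol"), inherits(truth, "vt_truth"))
  check_number(step, "step", lower = 0, strict_lower = TRUE)
  set.seed(seed)

  t <- seq(protocol$baseline_start, protocol$run_end, by = step)
  s <- activation_profile(t, protocol, truth)

  # activity: Poisson bursts, rate elevated during handling, kernel decay 2 s
  base_rate <- 0.02                     # bursts / s at rest
  stress_rate <- 0.30                   # bursts / s while handled
  handled <- t >= 0 & t < protocol$room_exit
  rate <- ifelse(handled, stress_rate, base_rate)
  events <- rbinom(length(t), 1L, pmin(rate * step, 1))
  amp <- stats::rexp(length(t))
  kernel_tau <- 2
  decay <- exp(-step / kernel_tau)
  activity <- numeric(length(t))
  acc <- 0
  for (i in seq_along(t)) {
    acc <- acc * decay + events[i] * amp[i]
    activity[i] <- acc
  }

  out <- tibble(t = t, s = s, activity = activity)
  class(out) <- c("vt_state", class(out))
  attr(out, "step") <- step
  attr(out, "seed") <- seed
  out
}

# deterministic activation shape shared by the generators:
# logistic rise (midpoint 9 s, 90% at 15 s), exponential recovery after exit
activation_profile <- function(t, protocol, truth) {
  t_mid <- 9
  tau_l <- (15 - t_mid) / log(9)        # plogis((15 - t_mid)/tau_l) = 0.9
  s <- stats::plogis((t - t_mid) / tau_l)
  post <- t > protocol$room_exit
  if (any(post)) {
    s_exit <- stats::plogis((protocol$room_exit - t_mid) / tau_l)
    s[post] <- s_exit * exp(-(t[post] - protocol$room_exit) / truth$recovery_tau)
  }
  s
}
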