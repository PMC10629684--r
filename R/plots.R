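#' Plot a processed run: heart rate, HRV and regional temperatures
#'
#' Draws the synchronized response traces of one run (a Fig.-style summary
#' of the acute-stress response): instantaneous heart rate, rolling-CV
#' heart-rate variability, and the calibrated regional temperature
#' observations, all on the onset-relative clock.
#'
#' @param run A [simulate_run()] result.
#' @param max_points Downsample cap per trace, for plotting speed.
#' @return A ggplot (patchwork stack when the patchwork package is
#'   installed, otherwise a faceted single plot).
#' @export
plot_run <- function(run, max_points = 2000) {
  card <- process_cardiac(run$beats)
  hr <- instantaneous_heart_rate(card$rri)
  thin <- function(d) {
    if (nrow(d) > max_points) d[seq(1, nrow(d), length.out = max_points), ]
    else d
  }
  hr_d <- thin(tibble(t = hr$t / 1000, value = hr$hr, what = "heart rate (beats/min)"))
  hrv_d <- thin(tibble(t = card$hrv$t / 1000, value = card$hrv$cv,
                       what = "HRV (rolling CV of RRI)"))
  temps <- dplyr::bind_rows(lapply(c("eye", "bill"), function(rg) {
    s <- quality_filter(extract_region_series(run$thermal, rg))
    tibble(t = s$time_s, value = s$temp,
           what = paste0("T_", rg, " (deg C)"))
  }))
  d <- dplyr::bind_rows(hr_d, hrv_d, temps)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(0, run$protocol$room_exit),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~what, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time relative to stressor onset (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Coefficient plot of a model-averaging result
#'
#' Forest plot of the full- and conditional-averaged coefficients with
#' their 95% CIs (intercept omitted).
#'
#' @param object An [average_models()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vt_model_average
#' @export
autoplot.vt_model_average <- function(object, ...) {
  cf <- object$coefficients
  cf <- cf[cf$term != "(Intercept)", , drop = FALSE]
  d <- dplyr::bind_rows(
    tibble(term = cf$term, estimate = cf$full_avg,
           low = cf$ci_full_low, high = cf$ci_full_high, flavour = "full"),
    tibble(term = cf$term, estimate = cf$cond_avg,
           low = cf$ci_cond_low, high = cf$ci_cond_high,
           flavour = "conditional")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term,
                                  colour = .data$flavour)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$low, xmax = .data$high),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "averaged coefficient (deg C per unit)", y = NULL,
                  colour = "average") +
    ggplot2::theme_minimal()
}

#' Recovery benchmark plot
#'
#' Per-replicate full-average HRV coefficients with CIs, against the
#' structural slope.
#'
#' @param object A [recover_coupling()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vt_recovery
#' @export
autoplot.vt_recovery <- function(object, ...) {
  r <- object$replicates
  ggplot2::ggplot(r, ggplot2::aes(x = .data$rep, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = object$true_slope, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             size = 0.2) +
    ggplot2::labs(x = "replicate", y = "averaged HRV coefficient") +
    ggplot2::theme_minimal()
}
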