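#' Tidy a fitted temperature--HRV mixed model
#'
#' @param x A [fit_mixed_model()] result.
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect coefficient.
#' @method tidy vt_fit
#' @export
tidy.vt_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.vt_fit
#' @method glance vt_fit
#' @export
glance.vt_fit <- function(x, ...) {
  tibble(
    logLik = x$logLik, AIC = x$AIC, df = x$k,
    converged = x$converged, correlation = x$spec$correlation,
    corr_param = x$corr_param
  )
}

#' Tidy a model-averaging result
#'
#' @param x An [average_models()] result.
#' @param which `"full"` or `"conditional"`: which averaged coefficient
#'   flavour populates `estimate`/`conf.low`/`conf.high` (both are kept in
#'   the dedicated columns either way).
#' @param ... Unused.
#' @return A tibble with one row per averaged term.
#' @method tidy vt_model_average
#' @export
tidy.vt_model_average <- function(x, which = c("full", "conditional"), ...) {
  which <- match.arg(which)
  cf <- x$coefficients
  if (which == "full") {
    dplyr::mutate(cf, estimate = .data$full_avg, std.error = .data$se_full,
                  conf.low = .data$ci_full_low, conf.high = .data$ci_full_high)
  } else {
    dplyr::mutate(cf, estimate = .data$cond_avg, std.error = .data$se_cond,
                  conf.low = .data$ci_cond_low, conf.high = .data$ci_cond_high)
  }
}

#' @rdname tidy.vt_model_average
#' @method glance vt_model_average
#' @export
glance.vt_model_average <- function(x, ...) {
  ret <- x$models[x$models$retained, , drop = FALSE]
  tibble(
    n_models = nrow(x$models),
    n_retained = nrow(ret),
    n_uninformative = sum(x$models$uninformative),
    min_AIC = min(x$models$AIC, na.rm = TRUE),
    top_terms = ret$terms_label[which.min(ret$AIC)],
    weight_sum = sum(ret$weight)
  )
}

#' Tidy a recovery benchmark
#'
#' @param x A [recover_coupling()] result.
#' @param ... Unused.
#' @return The per-replicate tibble (`tidy`) or the one-row summary
#'   (`glance`).
#' @method tidy vt_recovery
#' @export
tidy.vt_recovery <- function(x, ...) {
  x$replicates
}

#' @rdname tidy.vt_recovery
#' @method glance vt_recovery
#' @export
glance.vt_recovery <- function(x, ...) {
  x$summary
}
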