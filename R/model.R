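#' Specification of the temperature--HRV mixed model
#'
#' Defines one candidate model: the response region, the fixed-effect
#' terms, the random-intercept nesting, and the residual temporal
#' correlation structure. The full model regresses regional maximum surface
#' temperature on heart-rate variability (the variable of interest) plus
#' activity, position index, air temperature and sex; random intercepts are
#' nested as run order within individual (optionally within experimental
#' round); residual correlation is defined on the observation time within
#' the innermost grouping (AR1 on observation order).
#'
#' @param response `"eye"` or `"bill"`.
#' @param fixed Character subset of
#'   `c("hrv", "activity", "position_index", "air_temp", "sex")`.
#' @param random Nesting levels, outermost first: a subset (in order) of
#'   `c("round", "individual", "run_order")`.
#' @param correlation One of `"none"`, `"AR1"`, `"linear"`, `"Gaussian"`,
#'   `"exponential"`.
#' @return An object of class `vt_model_spec`.
#' @examples
#' model_spec("bill")
#' @export
model_spec <- function(response = c("eye", "bill"),
                       fixed = c("hrv", "activity", "position_index",
                                 "air_temp", "sex"),
                       random = c("individual", "run_order"),
                       correlation = c("exponential", "none", "AR1",
                                       "linear", "Gaussian")) {
  response <- match.arg(response)
  correlation <- match.arg(correlation)
  all_fixed <- c("hrv", "activity", "position_index", "air_temp", "sex")
  if (!all(fixed %in% all_fixed)) {
    vt_abort(sprintf("unknown fixed term(s): %s",
                     paste(setdiff(fixed, all_fixed), collapse = ", ")))
  }
  all_random <- c("round", "individual", "run_order")
  if (!all(random %in% all_random) || length(random) < 1L) {
    vt_abort("`random` must be a non-empty ordered subset of round/individual/run_order.")
  }
  random <- all_random[all_random %in% random]   # enforce the fixed nesting order
  structure(list(response = response, fixed = fixed, random = random,
                 correlation = correlation),
            class = "vt_model_spec")
}

random_formula <- function(spec) {
  cols <- c(round = "round", individual = "individual_id",
            run_order = "run_order")[spec$random]
  as.formula(paste0("~ 1 | ", paste(cols, collapse = "/")))
}

correlation_structure <- function(correlation) {
  switch(correlation,
    none = NULL,
    AR1 = nlme::corAR1(form = ~ 1),
    linear = nlme::corLin(form = ~ t),
    Gaussian = nlme::corGaus(form = ~ t),
    exponential = nlme::corExp(form = ~ t)
  )
}

fixed_formula <- function(fixed) {
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  as.formula(paste("temp ~", rhs))
}

#' Fit one linear mixed-effects model of temperature on HRV
#'
#' Fits the specified model by maximum likelihood (so AICs are comparable
#' across fixed-effect sets during dredging) with nested random intercepts
#' and, optionally, a residual temporal correlation structure defined on
#' the observation time within the innermost group. Non-convergent or
#' singular fits are returned flagged (`converged = FALSE`) rather than
#' thrown, so the dredge can drop them with a log entry.
#'
#' @param table An observation table ([match_synchronous()] output, or rows
#'   bound over runs); rows of other regions are dropped, then
#'   complete-case filtering is applied to the model variables. At least 2
#'   individuals are required.
#' @param spec A [model_spec()].
#' @return An object of class `vt_fit`: coefficient tibble (`term`,
#'   `estimate`, `se`), `logLik`, `AIC`, `k`, `converged`, `corr_param`,
#'   the fitted `nlme::lme` object (`fit`), and the spec.
#' @export
fit_mixed_model <- function(table, spec) {
  stopifnot(inherits(spec, "vt_model_spec"))
  dat <- as.data.frame(table[table$region == spec$response, , drop = FALSE])
  vars <- unique(c("temp", spec$fixed, "t",
                   c(round = "round", individual = "individual_id",
                     run_order = "run_order")[spec$random]))
  dat <- dat[complete.cases(dat[, vars, drop = FALSE]), , drop = FALSE]
  if (length(unique(dat$individual_id)) < 2L) {
    vt_abort("need at least 2 individuals to fit the mixed model.",
             class = "vasotherm_fit_error")
  }
  dat$sex <- factor(dat$sex)
  dat$individual_id <- factor(dat$individual_id)
  if ("round" %in% names(dat)) dat$round <- factor(dat$round)
  if ("run_order" %in% names(dat)) dat$run_order <- factor(dat$run_order)

  lme_try <- function(opt) {
    tryCatch(
      nlme::lme(
        fixed = fixed_formula(spec$fixed),
        random = random_formula(spec),
        correlation = correlation_structure(spec$correlation),
        data = dat, method = "ML",
        control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                   niterEM = 50, opt = opt,
                                   tolerance = 1e-9)
      ),
      error = function(e) e
    )
  }
  fit <- lme_try("nlminb")
  if (inherits(fit, "error")) fit <- lme_try("optim")
  if (inherits(fit, "error")) {
    return(structure(list(
      fit = NULL, spec = spec, terms = spec$fixed,
      coefficients = tibble(term = character(), estimate = numeric(),
                            se = numeric()),
      logLik = NA_real_, AIC = NA_real_, k = NA_integer_,
      converged = FALSE, corr_param = NA_real_,
      message = conditionMessage(fit)
    ), class = "vt_fit"))
  }

  est <- nlme::fixef(fit)
  se <- sqrt(diag(vcov(fit)))
  ll <- as.numeric(logLik(fit))
  k <- attr(logLik(fit), "df")
  corr_param <- if (spec$correlation == "none") NA_real_ else {
    cs <- fit$modelStruct$corStruct
    as.numeric(coef(cs, unconstrained = FALSE))[1]
  }
  structure(list(
    fit = fit, spec = spec, terms = spec$fixed,
    coefficients = tibble(term = names(est), estimate = unname(est),
                          se = unname(se)),
    logLik = ll, AIC = -2 * ll + 2 * k, k = k,
    converged = TRUE, corr_param = corr_param, message = NULL
  ), class = "vt_fit")
}

#' @export
print.vt_fit <- function(x, ...) {
  cat(sprintf("<vt_fit> %s ~ %s | correlation: %s | %s\n",
              x$spec$response,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
              x$spec$correlation,
              if (x$converged) sprintf("AIC %.2f", x$AIC) else "NOT CONVERGED"))
  if (x$converged) print(x$coefficients)
  invisible(x)
}

#' Select the residual correlation structure of the full model
#'
#' Fits the full model once per candidate structure and returns the spec
#' whose fit attains the lowest AIC; ties go to the first candidate in the
#' documented order. Candidates that fail to converge are skipped; if all
#' fail, the structure falls back to `"none"` with a warning.
#'
#' @param table Observation table.
#' @param full_spec A [model_spec()] with the full fixed-effect set.
#' @param candidates Structures to compare, in tie-break order.
#' @return The winning `vt_model_spec`; attribute `aic` carries the
#'   candidate AICs.
#' @export
select_correlation_structure <- function(table, full_spec,
                                         candidates = c("AR1", "linear",
                                                        "Gaussian",
                                                        "exponential")) {
  fits <- lapply(candidates, function(cs) {
    sp <- full_spec; sp$correlation <- cs
    fit_mixed_model(table, sp)
  })
  aics <- vapply(fits, function(f) if (f$converged) f$AIC else NA_real_,
                 numeric(1))
  names(aics) <- candidates
  if (all(is.na(aics))) {
    rlang::warn("no candidate correlation structure converged; using 'none'.")
    out <- full_spec; out$correlation <- "none"
    attr(out, "aic") <- aics
    return(out)
  }
  best <- which(aics == min(aics, na.rm = TRUE))[1]   # tie: first in order
  out <- full_spec; out$correlation <- candidates[best]
  attr(out, "aic") <- aics
  out
}

#' Fit all fixed-effect subsets (dredge)
#'
#' Fits every subset of the full model's fixed terms (including the
#' intercept-only model; `2^p` models for `p` candidate terms) with the
#' selected random and correlation structure, each by maximum likelihood.
#' Non-convergent subsets are kept in the table, flagged, and excluded
#' from averaging.
#'
#' @param table Observation table.
#' @param full_spec A [model_spec()]; its `fixed` set defines the candidate
#'   terms.
#' @return An object of class `vt_model_set`: `models` (list of [fit_mixed_model()]
#'   results), `table` (tibble: `model_id`, `terms`, `AIC`, `converged`)
#'   and `spec`.
#' @export
dredge_fixed_effects <- function(table, full_spec) {
  p <- length(full_spec$fixed)
  subsets <- lapply(seq_len(2^p) - 1L, function(mask) {
    full_spec$fixed[bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0]
  })
  models <- lapply(subsets, function(fx) {
    sp <- full_spec; sp$fixed <- fx
    fit_mixed_model(table, sp)
  })
  tab <- tibble(
    model_id = seq_along(models),
    terms = lapply(models, `[[`, "terms"),
    AIC = vapply(models, `[[`, numeric(1), "AIC"),
    converged = vapply(models, `[[`, logical(1), "converged")
  )
  structure(list(models = models, table = tab, spec = full_spec),
            class = "vt_model_set")
}

#' @export
print.vt_model_set <- function(x, ...) {
  cat(sprintf("<vt_model_set> %d models (%d converged)\n",
              length(x$models), sum(x$table$converged)))
  invisible(x)
}

# normalise averaging input to a tibble(model_id, AIC, terms, coefs)
as_model_table <- function(models) {
  if (inherits(models, "vt_model_set")) models <- models$models
  if (is.data.frame(models)) {
    stopifnot(all(c("AIC", "terms", "coefs") %in% names(models)))
    if (!"model_id" %in% names(models)) models$model_id <- seq_len(nrow(models))
    if (!"converged" %in% names(models)) models$converged <- TRUE
    return(models)
  }
  stopifnot(is.list(models), length(models) >= 1L)
  tibble(
    model_id = seq_along(models),
    AIC = vapply(models, `[[`, numeric(1), "AIC"),
    terms = lapply(models, `[[`, "terms"),
    coefs = lapply(models, `[[`, "coefficients"),
    converged = vapply(models, `[[`, logical(1), "converged")
  )
}

#' Average a model set by Akaike weights
#'
#' Retains converged models within `delta_keep` AIC of the best model,
#' drops uninformative models (a model containing a strictly nested,
#' retained, simpler model plus extra terms while sitting within
#' `uninformative_delta` AIC of it adds parameters without explanatory
#' gain), renormalises Akaike weights `w_i ~ exp(-Delta_i / 2)` over the
#' retained set, and averages each coefficient two ways: the conditional
#' average over models containing its term, and the full average treating
#' the coefficient as 0 in models lacking it (so
#' `full = conditional x summed weight`). Standard errors use the
#' model-averaging variance formula including between-model variance;
#' 95% CIs are normal-theory.
#'
#' @param models A [dredge_fixed_effects()] set, a list of [fit_mixed_model()]
#'   fits, or a tibble with columns `AIC`, `terms` (list), `coefs` (list of
#'   `term`/`estimate`/`se` tibbles).
#' @param delta_keep Retain models within this AIC of the top model
#'   (default 6).
#' @param uninformative_delta AIC window for the uninformative-model rule
#'   (default 2).
#' @param level Confidence level for the averaged-coefficient intervals.
#' @return An object of class `vt_model_average` with elements
#'   `coefficients` (per-term tibble) and `models` (per-model tibble with
#'   `delta`, `weight`, `retained`, `uninformative`).
#' @export
average_models <- function(models, delta_keep = 6, uninformative_delta = 2,
                           level = 0.95) {
  tab <- as_model_table(models)
  tab <- tab[order(tab$model_id), , drop = FALSE]
  conv <- tab[tab$converged & is.finite(tab$AIC), , drop = FALSE]
  if (nrow(conv) == 0L) {
    vt_abort("no converged models to average.", class = "vasotherm_avg_error")
  }
  best <- min(conv$AIC)
  conv$delta <- conv$AIC - best
  conv$retained <- conv$delta <= delta_keep

  # uninformative-model exclusion: scan retained models from simplest up
  idx <- which(conv$retained)
  idx <- idx[order(lengths(conv$terms[idx]), conv$AIC[idx])]
  kept <- logical(nrow(conv))
  uninformative <- logical(nrow(conv))
  for (i in idx) {
    trm <- conv$terms[[i]]
    drop_it <- FALSE
    for (j in which(kept)) {
      sub <- conv$terms[[j]]
      if (length(sub) < length(trm) && all(sub %in% trm) &&
          abs(conv$AIC[i] - conv$AIC[j]) <= uninformative_delta) {
        drop_it <- TRUE
        break
      }
    }
    if (drop_it) uninformative[i] <- TRUE else kept[i] <- TRUE
  }
  conv$uninformative <- uninformative
  conv$retained <- kept
  if (!any(kept)) {
    vt_abort("all candidate models were excluded.",
             class = "vasotherm_avg_error")
  }

  ret <- conv[kept, , drop = FALSE]
  w <- exp(-ret$delta / 2)
  ret$weight <- w / sum(w)

  all_terms <- unique(unlist(lapply(ret$coefs, `[[`, "term")))
  z <- qnorm(1 - (1 - level) / 2)
  coef_rows <- lapply(all_terms, function(tm) {
    has <- vapply(ret$coefs, function(cf) tm %in% cf$term, logical(1))
    est <- vapply(ret$coefs[has], function(cf) cf$estimate[cf$term == tm],
                  numeric(1))
    se <- vapply(ret$coefs[has], function(cf) cf$se[cf$term == tm],
                 numeric(1))
    w_in <- ret$weight[has]
    sw <- sum(w_in)
    cond <- sum(w_in * est) / sw
    full <- sum(w_in * est)                       # absent models contribute 0
    se_cond <- sqrt(sum((w_in / sw) * (se^2 + (est - cond)^2)))
    # absent models contribute estimate 0 with SE 0 to the full average
    se_full <- sqrt(sum(w_in * (se^2 + (est - full)^2)) +
                      sum(ret$weight[!has] * full^2))
    tibble(
      term = tm, full_avg = full, cond_avg = cond,
      se_full = se_full, se_cond = se_cond,
      ci_full_low = full - z * se_full, ci_full_high = full + z * se_full,
      ci_cond_low = cond - z * se_cond, ci_cond_high = cond + z * se_cond,
      sum_weight = sw
    )
  })
  coefficients <- dplyr::bind_rows(coef_rows)

  model_tbl <- conv |>
    dplyr::mutate(
      terms_label = vapply(.data$terms, function(x) {
        if (length(x)) paste(x, collapse = "+") else "(intercept)"
      }, character(1)),
      weight = ifelse(.data$retained,
                      ret$weight[match(.data$model_id, ret$model_id)], 0)
    ) |>
    dplyr::select("model_id", "terms_label", "AIC", "delta", "weight",
                  "retained", "uninformative")

  structure(list(coefficients = coefficients, models = model_tbl,
                 delta_keep = delta_keep,
                 uninformative_delta = uninformative_delta, level = level),
            class = "vt_model_average")
}

#' @export
print.vt_model_average <- function(x, ...) {
  cat(sprintf("<vt_model_average> %d retained of %d models\n",
              sum(x$models$retained), nrow(x$models)))
  print(x$coefficients)
  invisible(x)
}

#' Variance inflation factors for the fixed-effect design
#'
#' For each fixed-effect design column, regresses it on the remaining
#' columns and reports `VIF = 1 / (1 - R^2)`; values below 3 indicate no
#' collinearity concern. A constant column has an undefined regression and
#' is reported as infinite and flagged.
#'
#' @param table Observation table.
#' @param spec A [model_spec()] naming the response region and the fixed
#'   terms to check.
#' @param threshold Pass/fail threshold (default 3).
#' @return A tibble with columns `term`, `vif`, `pass`.
#' @export
vif_check <- function(table, spec, threshold = 3) {
  dat <- as.data.frame(table[table$region == spec$response, , drop = FALSE])
  dat$sex <- if ("sex" %in% names(dat)) factor(dat$sex)
  mm <- model.matrix(fixed_formula(spec$fixed), data = dat)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  vifs <- vapply(seq_len(ncol(mm)), function(j) {
    xj <- mm[, j]
    if (stats::var(xj) == 0) return(Inf)
    others <- mm[, -j, drop = FALSE]
    fit <- stats::lm.fit(cbind(1, others), xj)
    r2 <- 1 - sum(fit$residuals^2) / sum((xj - mean(xj))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble(term = colnames(mm), vif = vifs, pass = vifs < threshold)
}
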