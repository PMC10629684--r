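test_that("degenerate mixed model reproduces ordinary least squares", {
  tab <- simulate_obs_table(
    n_individuals = 4, n_per = 50,
    beta = c(hrv = 150, activity = -0.3, position_index = 0.05,
             air_temp = 0, sex = -0.2),
    sd_individual = 0, sd_resid = 0.3, seed = 5, center_groups = TRUE
  )
  sp <- model_spec("bill", random = "individual", correlation = "none")
  fit <- fit_mixed_model(tab, sp)
  expect_true(fit$converged)
  ols <- lm(temp ~ hrv + activity + position_index + air_temp + sex,
            data = dplyr::mutate(tab, sex = factor(sex)))
  expect_equal(fit$coefficients$estimate,
               unname(coef(ols))[match(fit$coefficients$term,
                                       names(coef(ols)))],
               tolerance = 1e-6)

  # determinism: identical refit
  fit2 <- fit_mixed_model(tab, sp)
  expect_equal(fit$coefficients, fit2$coefficients)
  expect_equal(fit$AIC, fit2$AIC)

  # AIC identity
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$k)

  # fewer than 2 individuals is rejected
  one <- tab[tab$individual_id == "bird01", ]
  expect_error(fit_mixed_model(one, sp), class = "vasotherm_fit_error")
})

test_that("the fitted HRV slope recovers a known coupling within 3 SE", {
  k <- 200
  tab <- simulate_obs_table(
    n_individuals = 6, n_per = 80,
    beta = c(hrv = k, activity = -0.3, position_index = 0,
             air_temp = 0, sex = 0),
    sd_individual = 0.3, sd_resid = 0.3, seed = 7
  )
  fit <- fit_mixed_model(tab, model_spec("bill", random = "individual",
                                         correlation = "none"))
  est <- fit$coefficients[fit$coefficients$term == "hrv", ]
  expect_lt(abs(est$estimate - k), 3 * est$se)
})

test_that("correlation-structure selection finds exponential residuals", {
  sp <- model_spec("bill", random = "individual")
  wins <- vapply(1:25, function(s) {
    tab <- simulate_obs_table(n_individuals = 4, n_per = 60,
                              corr_range = 5, sd_resid = 0.3, seed = s)
    select_correlation_structure(tab, sp)$correlation
  }, character(1))
  expect_gte(mean(wins == "exponential"), 0.8)

  # white-noise residuals: structure choice is inconsequential (typical
  # candidate AIC spread below 2; occasional larger spreads are chance
  # overfitting of a correlation range, so the assertion is on the median)
  spreads <- vapply(1:10, function(s) {
    tab <- simulate_obs_table(n_individuals = 4, n_per = 60,
                              corr_range = 0, sd_resid = 0.3, seed = 100 + s)
    aic <- attr(select_correlation_structure(tab, sp), "aic")
    diff(range(aic, na.rm = TRUE))
  }, numeric(1))
  expect_lt(median(spreads), 2)

  # a single-candidate list returns that structure
  tab1 <- simulate_obs_table(seed = 1)
  one <- select_correlation_structure(tab1, sp, candidates = "AR1")
  expect_equal(one$correlation, "AR1")
})

test_that("dredging fits every fixed-effect subset consistently", {
  tab <- simulate_obs_table(
    n_individuals = 4, n_per = 40,
    beta = c(hrv = 150, activity = 0, position_index = 0, air_temp = 0,
             sex = 0),
    sd_individual = 0.2, sd_resid = 0.3, seed = 3
  )
  full <- model_spec("bill", random = "individual", correlation = "none")
  set <- dredge_fixed_effects(tab, full)
  expect_equal(length(set$models), 32)
  expect_equal(sort(lengths(set$table$terms)),
               sort(unlist(lapply(0:5, function(k) rep(k, choose(5, k))))))
  # the refitted full model reproduces the selection-stage AIC
  full_idx <- which(lengths(set$table$terms) == 5)
  refit <- fit_mixed_model(tab, full)
  expect_equal(set$table$AIC[full_idx], refit$AIC)
})

test_that("the top dredged model retains a strongly active predictor", {
  hits <- vapply(1:50, function(s) {
    tab <- simulate_obs_table(
      n_individuals = 3, n_per = 30,
      beta = c(hrv = 200, activity = 0, position_index = 0, air_temp = 0,
               sex = 0),
      sd_individual = 0.2, sd_resid = 0.3, seed = 200 + s
    )
    set <- dredge_fixed_effects(
      tab, model_spec("bill", random = "individual", correlation = "none"))
    ok <- set$table$converged
    top <- which.min(set$table$AIC[ok])
    "hrv" %in% set$table$terms[ok][[top]]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("model averaging follows the Akaike-weight arithmetic", {
  expect_equal(formals(average_models)$delta_keep, 6)
  expect_equal(formals(average_models)$uninformative_delta, 2)

  # singleton set: full = conditional = the model's coefficients
  single <- fake_model_table(
    aics = 100, term_sets = list(c("(Intercept)", "hrv")),
    estimates = list(c(37, 150))
  )
  avg1 <- average_models(single)
  hrv1 <- avg1$coefficients[avg1$coefficients$term == "hrv", ]
  expect_equal(hrv1$full_avg, 150)
  expect_equal(hrv1$cond_avg, 150)
  expect_equal(hrv1$sum_weight, 1)

  # two models, term only in A: full = w_A x conditional
  two <- fake_model_table(
    aics = c(100, 101),
    term_sets = list(c("(Intercept)", "hrv", "activity"), "(Intercept)"),
    estimates = list(c(37, 150, -0.3), 37)
  )
  avg2 <- average_models(two, uninformative_delta = 0)  # keep both models
  w_a <- avg2$models$weight[avg2$models$model_id == 1]
  hrv2 <- avg2$coefficients[avg2$coefficients$term == "hrv", ]
  expect_equal(hrv2$cond_avg, 150)
  expect_equal(hrv2$full_avg, w_a * 150)
  expect_equal(hrv2$sum_weight, w_a)
  expect_equal(sum(avg2$models$weight), 1, tolerance = 1e-12)

  # delta_keep: a model 7 AIC off the top is discarded
  far <- fake_model_table(
    aics = c(100, 107),
    term_sets = list(c("(Intercept)", "hrv"), c("(Intercept)", "activity")),
    estimates = list(c(37, 150), c(37, -1))
  )
  avg3 <- average_models(far)
  expect_equal(sum(avg3$models$retained), 1)

  # uninformative rule: a superset within 2 AIC of its nested model drops
  nested <- fake_model_table(
    aics = c(100, 101.5, 104),
    term_sets = list(c("(Intercept)", "hrv"),
                     c("(Intercept)", "hrv", "activity"),
                     c("(Intercept)", "hrv", "air_temp")),
    estimates = list(c(37, 150), c(37, 149, -0.2), c(37, 151, 0.5))
  )
  avg4 <- average_models(nested)
  m <- avg4$models
  expect_true(m$uninformative[m$model_id == 2])
  expect_false(m$retained[m$model_id == 2])
  expect_true(m$retained[m$model_id == 1])
  expect_true(m$retained[m$model_id == 3])   # 4 AIC off: informative, kept

  expect_error(average_models(fake_model_table(NA_real_, list("x"),
                                               list(1))),
               class = "vasotherm_avg_error")
})

test_that("full averages shrink toward zero exactly by the summed weight", {
  set.seed(42)
  terms_pool <- c("hrv", "activity", "position_index", "air_temp")
  for (rep in 1:20) {
    n_m <- sample(2:6, 1)
    term_sets <- lapply(seq_len(n_m), function(i) {
      c("(Intercept)", sample(terms_pool, sample(0:4, 1)))
    })
    tabm <- fake_model_table(
      aics = runif(n_m, 100, 105),
      term_sets = term_sets,
      estimates = lapply(term_sets, function(ts) rnorm(length(ts), 0, 5))
    )
    avg <- average_models(tabm, uninformative_delta = 0)
    cf <- avg$coefficients
    expect_equal(sum(avg$models$weight), 1, tolerance = 1e-12)
    expect_true(all(abs(cf$full_avg) <= abs(cf$cond_avg) + 1e-12))
    expect_equal(cf$full_avg, cf$cond_avg * cf$sum_weight)
    always_in <- abs(cf$sum_weight - 1) < 1e-12
    expect_equal(cf$full_avg[always_in], cf$cond_avg[always_in])
  }
})

test_that("variance inflation factors diagnose collinearity", {
  tab <- simulate_obs_table(n_individuals = 4, n_per = 100, seed = 13)
  sp <- model_spec("bill")
  v <- vif_check(tab, sp)
  expect_true(all(v$vif < 2))
  expect_true(all(v$pass))

  # duplicated covariate: VIF diverges and is flagged
  dup <- dplyr::mutate(tab, activity = hrv)
  v2 <- vif_check(dup, sp)
  expect_true(all(is.infinite(v2$vif[v2$term %in% c("hrv", "activity")])))
  expect_false(any(v2$pass[v2$term %in% c("hrv", "activity")]))

  # constant column: infinite and flagged
  cst <- dplyr::mutate(tab, air_temp = 20.8)
  v3 <- vif_check(cst, sp)
  expect_true(is.infinite(v3$vif[v3$term == "air_temp"]))
})
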