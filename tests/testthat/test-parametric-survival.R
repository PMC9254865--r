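test_that("exponential fit equals the closed-form MLE and AIC identity", {
  fit <- fit_parametric(ipd_exponential_closed_form(), "exponential")
  expect_equal(unname(fit$params[["rate"]]), 0.2, tolerance = 1e-10)
  expect_equal(fit$loglik, 20 * log(0.2) - 20, tolerance = 1e-10)
  expect_equal(fit$aic, 2 - 2 * (20 * log(0.2) - 20), tolerance = 1e-10)
  expect_equal(fit$bic, log(30) - 2 * fit$loglik, tolerance = 1e-10)
  # the in-package censored log-likelihood agrees with the fit's own value
  expect_equal(censored_loglik(ipd_exponential_closed_form(), fit$fn),
               fit$loglik, tolerance = 1e-10)
})

test_that("AIC/BIC identities hold exactly for every fitted family", {
  fn <- calibrate_weibull_from_median(9.2, 1.2)
  sim <- simulate_arm_ipd(fn, fn, 150, 30, 6, seed = 2)
  fits <- fit_all_families(sim$pfs)
  for (f in fits) {
    if (!f$converged) next
    expect_equal(f$aic, 2 * f$n_params - 2 * f$loglik, tolerance = 1e-12)
    expect_equal(f$bic, f$n_params * log(f$n_obs) - 2 * f$loglik,
                 tolerance = 1e-12)
    # numerical maximizer agrees with the closed-form likelihood evaluation
    expect_equal(censored_loglik(sim$pfs, f$fn), f$loglik, tolerance = 1e-6)
  }
})

test_that("Weibull parameters are recovered within 10% under 20% censoring", {
  truth <- surv_fn("weibull", c(shape = 1.2, scale = 13.27))
  set.seed(31)
  u <- runif(1000)
  t_ev <- survival_quantile(truth, u)
  cens <- quantile(t_ev, 0.8)  # administrative cut at the 80th percentile
  ipd <- tibble::tibble(time_months = pmin(t_ev, cens),
                        event = as.integer(t_ev <= cens))
  fit <- fit_parametric(ipd, "weibull")
  expect_true(fit$converged)
  expect_equal(unname(fit$params[["shape"]]), 1.2, tolerance = 0.1)
  expect_equal(unname(fit$params[["scale"]]), 13.27, tolerance = 0.1)
})

test_that("zero-event data are refused, and the MLE is a local optimum", {
  expect_error(
    fit_parametric(tibble::tibble(time_months = c(1, 2), event = c(0L, 0L)),
                   "weibull"),
    "no events")

  fn <- calibrate_weibull_from_median(9.2, 1.2)
  sim <- simulate_arm_ipd(fn, fn, 200, 30, 6, seed = 3)
  fit <- fit_parametric(sim$pfs, "weibull")
  ll_hat <- censored_loglik(sim$pfs, fit$fn)
  set.seed(99)
  for (i in 1:100) {
    pert <- fit$params * exp(runif(2, -0.1, 0.1))
    ll <- censored_loglik(sim$pfs, surv_fn("weibull", pert))
    expect_lte(ll, ll_hat + 1e-8)
  }
})

test_that("criterion selection prefers the minimum, fewer parameters, fixed order", {
  mk <- function(family, ll) {
    params <- switch(family,
                     exponential = c(rate = 0.1),
                     weibull = c(shape = 1.1, scale = 10),
                     gompertz = c(shape = 0.01, rate = 0.05),
                     loglogistic = c(shape = 1.2, scale = 10),
                     lognormal = c(meanlog = 2, sdlog = 1))
    psmcea:::new_psm_fit(family, params, ll, n_obs = 100, n_events = 50,
                         converged = TRUE)
  }
  # AICs 100, 98, 103 -> the 98 fit
  f1 <- mk("weibull", -(100 - 4) / 2)
  f2 <- mk("loglogistic", -(98 - 4) / 2)
  f3 <- mk("lognormal", -(103 - 4) / 2)
  expect_identical(select_distribution(list(f1, f2, f3), "aic")$family,
                   "loglogistic")
  # exact tie: exponential (1 parameter) beats Weibull (2)
  fe <- mk("exponential", -(98 - 2) / 2)
  fw <- mk("weibull", -(98 - 4) / 2)
  expect_identical(select_distribution(list(fw, fe), "aic")$family,
                   "exponential")
  # non-converged fits are never selected
  bad <- psmcea:::new_psm_fit("gompertz", c(shape = NA, rate = NA), -Inf,
                              100, 50, FALSE)
  expect_identical(select_distribution(list(bad, f2), "bic")$family,
                   "loglogistic")
  expect_error(select_distribution(list(bad), "aic"), "no converged")
})

test_that("exponential data select a family that nests the truth", {
  fn <- surv_fn("exponential", c(rate = log(2) / 9.2))
  sim <- simulate_arm_ipd(fn, fn, 2000, 60, 0, seed = 8)
  best <- select_distribution(fit_all_families(sim$os), "bic")
  expect_true(best$family %in% c("exponential", "weibull", "gengamma"))
})

test_that("closed-form survival evaluation matches defining properties", {
  fns <- list(
    surv_fn("exponential", c(rate = 0.1)),
    surv_fn("weibull", c(shape = 1.3, scale = 12)),
    surv_fn("gompertz", c(shape = 0.05, rate = 0.04)),
    surv_fn("gompertz", c(shape = -0.05, rate = 0.04)),
    surv_fn("gengamma", c(mu = 2.2, sigma = 0.8, Q = 0.5)),
    surv_fn("gengamma", c(mu = 2.2, sigma = 0.8, Q = 1e-9)),
    surv_fn("loglogistic", c(shape = 1.5, scale = 9.2)),
    surv_fn("lognormal", c(meanlog = 2.3, sdlog = 0.7)))
  grid <- seq(0, 120, length.out = 1000)
  for (fn in fns) {
    s <- survival_at(fn, grid)
    expect_identical(s[1], 1)
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
    # quantile inverts survival away from plateaus
    p <- c(0.9, 0.5, 0.2)
    q <- survival_quantile(fn, p)
    ok <- is.finite(q)
    expect_equal(survival_at(fn, q[ok]), p[ok], tolerance = 1e-6)
  }
  # exponential with rate ln2/13.27 halves at 13.27 months
  expect_equal(survival_at(surv_fn("exponential", c(rate = log(2) / 13.27)),
                           13.27), 0.5, tolerance = 1e-12)
  expect_equal(survival_at(surv_fn("exponential", c(rate = 0.0522)), 13.27),
               0.5, tolerance = 1e-3)
  # log-logistic scale is the median by construction
  expect_equal(survival_at(surv_fn("loglogistic",
                                   c(shape = 1, scale = 9.2)), 9.2), 0.5)
  expect_error(surv_fn("weibull", c(shape = -1, scale = 2)), "must be > 0")
})

test_that("proportional-hazards shifts scale the cumulative hazard exactly", {
  base <- calibrate_weibull_from_median(9.2, 1.2)
  expect_equal(survival_at(apply_hazard_ratio(base, 1), 1:30),
               survival_at(base, 1:30))

  hr <- apply_hazard_ratio(base, 0.39)
  expect_identical(survival_at(hr, 0), 1)
  # S = 0.5 at the median maps to 0.5^0.39
  expect_equal(survival_at(hr, 9.2), 0.5^0.39, tolerance = 1e-12)
  expect_equal(survival_at(hr, 9.2), 0.7631296, tolerance = 1e-6)
  grid <- seq(0.5, 60, by = 0.5)
  expect_equal(cumulative_hazard_at(hr, grid),
               0.39 * cumulative_hazard_at(base, grid), tolerance = 1e-12)
  expect_true(all(diff(survival_at(hr, grid)) <= 0))

  # exponential median scales as 1/HR, consistent with the trial's
  # 23.9 vs 9.2 month pair up to the proportional-hazards approximation
  exp_base <- surv_fn("exponential", c(rate = log(2) / 9.2))
  med <- survival_quantile(apply_hazard_ratio(exp_base, 0.39), 0.5)
  expect_equal(med, 9.2 / 0.39, tolerance = 1e-9)
  expect_equal(med, 23.5897436, tolerance = 1e-6)

  expect_error(apply_hazard_ratio(base, 0), "positive")
})
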