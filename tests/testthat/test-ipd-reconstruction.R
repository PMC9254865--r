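test_that("curve sanitation enforces monotone survival from the origin", {
  raw <- tibble::tibble(time_months = c(0, 1, 2), survival = c(1, 0.8, 0.82))
  out <- sanitize_curve(raw)
  expect_equal(out$survival, c(1, 0.8, 0.8))

  mono <- tibble::tibble(time_months = c(0, 2, 5), survival = c(1, 0.7, 0.4))
  expect_equal(sanitize_curve(mono), mono)
  expect_equal(sanitize_curve(sanitize_curve(raw)), sanitize_curve(raw))

  # missing origin is inserted
  no0 <- sanitize_curve(tibble::tibble(time_months = 1, survival = 0.9))
  expect_equal(no0$time_months, c(0, 1))
  expect_equal(no0$survival, c(1, 0.9))

  # duplicate times keep the last value; out-of-range values are clamped
  dup <- sanitize_curve(tibble::tibble(time_months = c(0, 1, 1),
                                       survival = c(1, 0.9, 0.85)))
  expect_equal(dup$survival, c(1, 0.85))
  clamped <- sanitize_curve(tibble::tibble(time_months = c(0, 1),
                                           survival = c(1.2, -0.1)))
  expect_equal(clamped$survival, c(1, 0))

  expect_error(sanitize_curve(tibble::tibble(time_months = -1, survival = 1)),
               "negative")
})

test_that("single-interval reconstruction matches the brute-force allocation", {
  curve <- tibble::tibble(time_months = c(0, 1), survival = c(1, 0.5))
  risk <- tibble::tibble(time_months = c(0, 2), n_risk = c(10L, 5L))
  ipd <- reconstruct_ipd(curve, risk)

  # brute-force oracle: d events at t=1 plus c interval censorings with
  # d + c = 5 leaving 5 at risk at t=2; product-limit 1 - d/10 must hit 0.5
  grid <- expand.grid(d = 0:5)
  grid$err <- abs((1 - grid$d / 10) - 0.5)
  best_d <- grid$d[which.min(grid$err)]
  expect_identical(best_d, 5L)

  expect_equal(sum(ipd$event == 1), 5)
  expect_equal(unique(ipd$time_months[ipd$event == 1]), 1)
  expect_equal(sum(ipd$event == 0), 5)
  expect_equal(unique(ipd$time_months[ipd$event == 0]), 2)
})

test_that("a flat curve over a shrinking risk set yields censorings only", {
  curve <- tibble::tibble(time_months = c(0, 6), survival = c(1, 1))
  risk <- tibble::tibble(time_months = c(0, 6), n_risk = c(100L, 80L))
  ipd <- reconstruct_ipd(curve, risk)
  expect_equal(sum(ipd$event == 1), 0)
  expect_equal(nrow(ipd), 100)
  expect_equal(sum(ipd$event == 0 & ipd$time_months < 6), 20)
})

test_that("product-limit estimation reproduces hand-computed step values", {
  ipd <- tibble::tibble(time_months = c(1, 2), event = c(1L, 0L))
  km <- km_estimate(ipd)
  expect_equal(eval_step_curve(km, 1), 0.5)

  none <- km_estimate(tibble::tibble(time_months = c(1, 2), event = c(0L, 0L)))
  expect_equal(none$survival, 1)

  km4 <- km_estimate(ipd_four())
  expect_equal(eval_step_curve(km4, 3), 0.375)
})

test_that("reconstruction round-trips synthetic artifacts within 0.02 sup-norm", {
  fn_pfs <- calibrate_weibull_from_median(9.2, 1.2)
  fn_os <- calibrate_weibull_from_median(40, 1)
  sim <- simulate_arm_ipd(fn_pfs, fn_os, n = 300, max_followup_months = 36,
                          accrual_months = 12, seed = 20)
  for (ep in c("pfs", "os")) {
    art <- emit_km_artifacts(sim[[ep]], seq(0, 36, 3))
    rec <- reconstruct_ipd(art$curve, art$risk)
    expect_identical(nrow(rec), sum(art$risk$n_risk[art$risk$time_months == 0]))
    km_rec <- km_estimate(rec)
    at <- art$curve$time_months
    sup <- max(abs(eval_step_curve(km_rec, at) -
                     eval_step_curve(art$curve, at)))
    expect_lt(sup, 0.02)
    # at-risk counts reproduced exactly at every published time
    n_at <- vapply(art$risk$time_months,
                   function(g) sum(rec$time_months >= g), numeric(1))
    expect_equal(n_at, as.numeric(art$risk$n_risk))
    # deterministic: no randomness anywhere in the reconstruction
    expect_identical(rec, reconstruct_ipd(art$curve, art$risk))
  }
})

test_that("inconsistent published inputs are rejected with context", {
  curve <- tibble::tibble(time_months = c(0, 1), survival = c(1, 0.5))
  risk_up <- tibble::tibble(time_months = c(0, 2), n_risk = c(10L, 12L))
  expect_error(reconstruct_ipd(curve, risk_up), "increase")

  dead <- tibble::tibble(time_months = c(0, 1), survival = c(1, 0))
  risk_alive <- tibble::tibble(time_months = c(0, 2), n_risk = c(10L, 5L))
  expect_error(reconstruct_ipd(dead, risk_alive), "survival reaches 0")
})

test_that("a published total event count constrains the tail", {
  # curve keeps dropping after the last risk time; the stated total caps it
  curve <- tibble::tibble(time_months = c(0, 1, 3),
                          survival = c(1, 0.5, 0.25))
  risk <- tibble::tibble(time_months = c(0, 2), n_risk = c(10L, 5L))
  free <- reconstruct_ipd(curve, risk)
  capped <- reconstruct_ipd(curve, risk, total_events = 6)
  expect_gt(sum(free$event), 6)
  expect_equal(sum(capped$event), 6)
  expect_equal(nrow(capped), 10)
})
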