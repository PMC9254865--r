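results_pair <- function(c0, q0, c1, q1) {
  tibble::tibble(strategy = c("ref", "cmp"), cost = c(c0, c1),
                 qaly = c(q0, q1))
}

test_that("incremental table reproduces ratio arithmetic and dominance labels", {
  # reported incremental pair: 1,253,130 RMB for 0.47 QALYs
  tab <- icer_table(results_pair(762572, 2.13, 762572 + 1253130, 2.60), "ref")
  expect_equal(tab$delta_cost, 1253130)
  expect_equal(tab$delta_qaly, 0.47, tolerance = 1e-12)
  expect_equal(tab$icer, 1253130 / 0.47, tolerance = 1e-9)
  expect_equal(tab$icer, 2666234.04, tolerance = 1e-6)

  expect_equal(icer_table(results_pair(0, 0, 100, 0.5), "ref")$icer, 200)

  dom <- icer_table(results_pair(1, 0, 0, 0.1), "ref")
  expect_identical(dom$label, "dominant")
  dominated <- icer_table(results_pair(0, 0.1, 1, 0), "ref")
  expect_identical(dominated$label, "dominated")
  zero <- icer_table(results_pair(0, 0.5, 10, 0.5), "ref")
  expect_true(is.na(zero$icer))

  expect_error(icer_table(results_pair(0, 0, 1, 1), "nope"), "reference")
  expect_error(
    icer_table(tibble::tibble(strategy = c("a", "a"), cost = 1:2,
                              qaly = 1:2), "a"), "duplicate")
})

test_that("incremental deltas negate under swapping comparator and reference", {
  res <- results_pair(10, 1, 30, 1.5)
  fwd <- icer_table(res, "ref")
  bwd <- icer_table(res, "cmp")
  expect_equal(fwd$delta_cost, -bwd$delta_cost)
  expect_equal(fwd$delta_qaly, -bwd$delta_qaly)
  expect_equal(fwd$icer, bwd$icer)
})

test_that("net monetary benefit follows wtp * qaly - cost", {
  res <- tibble::tibble(strategy = "sun", cost = 762572, qaly = 2.13)
  expect_equal(net_monetary_benefit(res, 217341)$nmb, -299635.67,
               tolerance = 1e-9)
  expect_equal(net_monetary_benefit(res, 0)$nmb, -res$cost)
  expect_equal(
    net_monetary_benefit(tibble::tibble(cost = 0, qaly = 1), 5e5)$nmb, 5e5)
})

test_that("moment matching reproduces the hand-computed gamma and beta shapes", {
  g <- moment_match(179.18, 143.34, 215.02, "gamma")
  expect_equal(g$sd, 18.2857142857, tolerance = 1e-9)
  expect_equal(g$shape, 96.0185636963, tolerance = 1e-6)
  expect_equal(g$scale, 1.86609748264, tolerance = 1e-6)

  b <- moment_match(0.82, 0.656, 0.984, "beta")
  expect_equal(b$sd, 0.0836734693878, tolerance = 1e-9)
  expect_equal(b$alpha + b$beta, 20.0819512195, tolerance = 1e-6)
  expect_equal(b$alpha, 16.4672, tolerance = 1e-4)
})

test_that("PSA draws are deterministic, leave fixed parameters alone, and
           recover the base means", {
  ptab <- param_table(fixture_config())
  d1 <- sample_psa_parameters(ptab, 4000, seed = 123)
  d2 <- sample_psa_parameters(ptab, 4000, seed = 123)
  expect_identical(d1, d2)

  expect_true(all(d1$discount_rate == 0.05))  # marked fixed, never sampled

  for (i in seq_len(nrow(ptab))) {
    p <- ptab[i, ]
    if (p$dist == "fixed") next
    se <- (p$high - p$low) / 3.92 / sqrt(4000)
    expect_lt(abs(mean(d1[[p$name]]) - p$base), 3 * se + 1e-12)
    if (p$dist == "beta") {
      expect_true(all(d1[[p$name]] > 0 & d1[[p$name]] < 1))
    } else {
      expect_true(all(d1[[p$name]] > 0))
    }
  }
})

test_that("the PSA fast path agrees with the full valuation route", {
  cfg <- fixture_config()
  psa <- run_psa(cfg, n_iter = 25, seed = 77, wtp_grid = c(0, 5e5, 1e6))
  traces <- psmcea:::build_traces(cfg)
  draws <- sample_psa_parameters(param_table(cfg), 25, seed = 77)
  for (i in c(1, 13, 25)) {
    params <- unlist(draws[i, ])
    slow <- psmcea:::evaluate_strategies(cfg, traces, params)$results
    fast <- dplyr::filter(psa$samples, .data$iteration == i) |>
      dplyr::arrange(match(.data$strategy, slow$strategy))
    expect_equal(fast$cost, slow$cost, tolerance = 1e-9)
    expect_equal(fast$qaly, slow$qaly, tolerance = 1e-9)
  }
})

test_that("CEAC probabilities partition, and degenerate PSA is deterministic", {
  cfg <- fixture_config()
  psa <- run_psa(cfg, n_iter = 400, seed = 5, wtp_grid = seq(0, 1e6, 2e5))
  sums <- psa$ceac |>
    dplyr::summarise(s = sum(.data$probability), .by = "wtp")
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-12)
  # at wtp = 0 the decision is cost-minimization: the reference is cheapest
  # at base, so it wins the plurality of iterations
  at0 <- dplyr::filter(psa$ceac, .data$wtp == 0)
  expect_gt(at0$probability[at0$strategy == "sunitinib"], 0.5)
  expect_equal(at0$probability[at0$strategy == "lenv_pemb"], 0)
  # quadrant shares partition too
  expect_equal(rowSums(psa$quadrants[, 3:6]), rep(1, 2), tolerance = 1e-12)

  # all-fixed parameter table: every iteration identical, CEAC in {0, 1}
  cfg_fixed <- cfg
  cfg_fixed$parameters <- lapply(cfg$parameters, function(p) {
    p$dist <- "fixed"; p
  })
  cfg_fixed <- validate_model_config(unclass(cfg_fixed))
  dpsa <- run_psa(cfg_fixed, n_iter = 10, seed = 1, wtp_grid = c(0, 1e6))
  spread <- dpsa$samples |>
    dplyr::summarise(v = max(.data$cost) - min(.data$cost), .by = "strategy")
  expect_equal(spread$v, rep(0, 3))
  expect_true(all(dpsa$ceac$probability %in% c(0, 1)))
})

test_that("one-way sensitivity orders parameters by ICER swing", {
  cfg <- fixture_config()
  dsa <- one_way_dsa(cfg, "lenv_pemb", "sunitinib",
                     parameters = c("price_pembrolizumab", "u_pfs",
                                    "u_pd", "fu_urine", "disc_ae_lenv_pemb"))
  expect_true(all(diff(dsa$width) <= 0))
  # a parameter with no effect on the pair collapses to zero width and sorts last
  expect_identical(dsa$parameter[nrow(dsa)], "disc_ae_lenv_pemb")
  expect_equal(dsa$width[nrow(dsa)], 0)
  # comparator-only price: ICER strictly increasing in the price
  pem <- dplyr::filter(dsa, .data$parameter == "price_pembrolizumab")
  expect_lt(pem$icer_low, pem$icer_base)
  expect_gt(pem$icer_high, pem$icer_base)
  expect_error(one_way_dsa(cfg, parameters = "nope"), "unknown parameter")
})

test_that("pembrolizumab price scenarios are affine in price; horizons accumulate", {
  cfg <- fixture_config()
  sc <- run_scenarios(cfg, horizons = c(5, 10),
                      price_scales = c(1, 0.75, 0.5, 0.25, 0))
  # unchanged price leaves the ICER at base
  base_icer <- sc$price$icer[sc$price$price_scale == 1]
  expect_equal(sc$price$icer_reduction_vs_base[sc$price$price_scale == 1], 0)
  # equal price steps give equal ICER steps (affine to machine precision)
  fit <- stats::lm(icer ~ price, data = sc$price)
  expect_equal(unname(summary(fit)$r.squared), 1, tolerance = 1e-12)
  # longer horizon can only add QALYs and life-years
  wide <- tidyr::pivot_wider(sc$horizon[, c("strategy", "horizon_years", "qaly")],
                             names_from = "horizon_years",
                             values_from = "qaly")
  expect_true(all(wide$`10` >= wide$`5`))
  expect_error(run_scenarios(cfg, horizons = -1), "horizons")
})

test_that("subgroup hazard ratios act monotonically on the comparator", {
  cfg <- fixture_config()
  sg <- run_subgroup(cfg, tibble::tibble(
    label = c("null", "better_os", "best_os"),
    hr_pfs = c(1, 1, 1), hr_os = c(1, 0.8, 0.5)))
  res <- sg$results
  # unit hazard ratios: identical curves, so life-years match the reference
  # exactly while QALYs still differ through the arm-specific utilities
  null_row <- dplyr::filter(res, .data$label == "null")
  expect_equal(null_row$ly[null_row$strategy == "lenv_pemb"],
               null_row$ly[null_row$strategy == "sunitinib"],
               tolerance = 1e-12)
  expect_gt(null_row$qaly[null_row$strategy == "lenv_pemb"],
            null_row$qaly[null_row$strategy == "sunitinib"])
  # lower OS hazard ratio -> more comparator QALYs, monotonically
  q <- res |>
    dplyr::filter(.data$strategy == "lenv_pemb") |>
    dplyr::arrange(match(.data$label, c("null", "better_os", "best_os"))) |>
    dplyr::pull("qaly")
  expect_true(all(diff(q) > 0))
  expect_error(run_subgroup(cfg, tibble::tibble(label = "x", hr_pfs = -1,
                                                hr_os = 1)), "> 0")
})
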