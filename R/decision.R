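#' Incremental cost-effectiveness table
#'
#' Pairwise comparison of each strategy against the reference: incremental
#' cost, incremental QALYs and their ratio. When the signs disagree the ICER
#' is replaced by a dominance label (`dominant`: cheaper and more
#' effective; `dominated`: dearer and less effective); a zero QALY
#' difference leaves the ICER undefined.
#'
#' @param results Tibble with columns `strategy`, `cost`, `qaly` (and
#'   optionally `ly`), one row per strategy.
#' @param reference Name of the reference strategy.
#' @return Tibble with `comparator`, `reference`, `delta_cost`,
#'   `delta_qaly`, `icer`, `label`.
#' @export
icer_table <- function(results, reference) {
  if (anyDuplicated(results$strategy)) {
    abort("icer_table: duplicate strategy names")
  }
  if (!reference %in% results$strategy) {
    abort(sprintf("icer_table: reference '%s' not among results", reference))
  }
  if (nrow(results) < 2) abort("icer_table: need at least two strategies")
  ref <- filter(results, .data$strategy == reference)
  results |>
    filter(.data$strategy != reference) |>
    transmute(
      comparator = .data$strategy,
      reference = reference,
      delta_cost = .data$cost - ref$cost,
      delta_qaly = .data$qaly - ref$qaly,
      icer = ifelse(.data$delta_qaly == 0, NA_real_,
                    .data$delta_cost / .data$delta_qaly),
      label = case_when(
        .data$delta_qaly > 0 & .data$delta_cost < 0 ~ "dominant",
        .data$delta_qaly < 0 & .data$delta_cost > 0 ~ "dominated",
        .data$delta_qaly == 0 ~ "undefined",
        TRUE ~ ""))
}

#' Net monetary benefit
#'
#' `wtp * qaly - cost` per strategy row; maximizing NMB is equivalent to the
#' ICER-versus-threshold decision rule.
#'
#' @param results Tibble with `qaly` and `cost` columns.
#' @param wtp Willingness-to-pay threshold (RMB per QALY, >= 0).
#' @return `results` with an `nmb` column appended.
#' @export
net_monetary_benefit <- function(results, wtp) {
  if (wtp < 0) abort("net_monetary_benefit: wtp must be >= 0")
  mutate(results, nmb = wtp * .data$qaly - .data$cost)
}

pair_icer <- function(results, comparator, reference) {
  icer_table(results, reference) |>
    filter(.data$comparator == !!comparator) |>
    pull("icer")
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the model with each parameter set to its low and then high bound
#' (all others at base) and records the ICER of the chosen pair. Entries are
#' sorted by the absolute ICER swing, the tornado-plot order. Varying the
#' discount rate rebuilds the traces; all other parameters only re-price the
#' fixed traces.
#'
#' @param config A validated config.
#' @param comparator,reference Strategy names for the ICER pair (defaults:
#'   lenvatinib-plus-pembrolizumab vs the config reference).
#' @param parameters Optional character vector restricting which parameters
#'   to vary (unknown names are an error).
#' @return Tibble `parameter`, `low`, `high`, `icer_low`, `icer_high`,
#'   `icer_base`, `width`, sorted by decreasing width.
#' @export
one_way_dsa <- function(config, comparator = "lenv_pemb",
                        reference = config$reference,
                        parameters = NULL) {
  ptab <- param_table(config)
  if (!is.null(parameters)) {
    missing <- setdiff(parameters, ptab$name)
    if (length(missing) > 0) {
      abort(sprintf("one_way_dsa: unknown parameter(s): %s",
                    paste(missing, collapse = ", ")))
    }
    ptab <- filter(ptab, .data$name %in% parameters)
  }
  base <- param_base(config)
  curves <- resolve_curves(config)
  traces_base <- build_traces(config, curves)
  icer_base <- pair_icer(evaluate_strategies(config, traces_base)$results,
                         comparator, reference)
  run_at <- function(pname, value) {
    p <- base
    p[[pname]] <- value
    traces <- if (pname == "discount_rate") {
      build_traces(config, curves, discount_rate = value)
    } else {
      traces_base
    }
    pair_icer(evaluate_strategies(config, traces, p)$results,
              comparator, reference)
  }
  pmap(ptab, function(name, base, low, high, dist) {
    tibble(parameter = name, low = low, high = high,
           icer_low = run_at(name, low), icer_high = run_at(name, high))
  }) |>
    list_rbind() |>
    mutate(icer_base = icer_base,
           width = abs(.data$icer_high - .data$icer_low)) |>
    arrange(desc(.data$width))
}

#' Sample parameter draws for probabilistic sensitivity analysis
#'
#' Moment-matched sampling: each range is read as a 95% interval, so
#' `sd = (high - low) / 3.92`; cost parameters draw from a gamma with
#' `shape = mean^2/sd^2`, `scale = sd^2/mean`; bounded quantities draw from
#' a beta with `alpha + beta = mean(1-mean)/sd^2 - 1` and
#' `alpha = mean (alpha+beta)`. Parameters marked `fixed` (the discount
#' rate) are not sampled and stay at base. Deterministic given the seed.
#'
#' @param ptab Parameter table ([param_table()]).
#' @param n Number of iterations.
#' @param seed Integer seed.
#' @return Tibble of `n` rows, one column per parameter.
#' @export
sample_psa_parameters <- function(ptab, n, seed = 1L) {
  set.seed(seed)
  draws <- map(seq_len(nrow(ptab)), function(i) {
    p <- ptab[i, ]
    sd <- (p$high - p$low) / 3.92
    if (p$dist == "fixed" || sd == 0) return(rep(p$base, n))
    if (p$dist == "gamma") {
      if (p$base <= 0) abort(sprintf("gamma parameter '%s' needs mean > 0", p$name))
      shape <- p$base^2 / sd^2
      rgamma(n, shape = shape, scale = sd^2 / p$base)
    } else {
      if (p$base <= 0 || p$base >= 1) {
        abort(sprintf("beta parameter '%s' needs mean in (0, 1)", p$name))
      }
      nu <- p$base * (1 - p$base) / sd^2 - 1
      if (nu <= 0) {
        abort(sprintf("beta parameter '%s' has too wide a range", p$name))
      }
      rbeta(n, shape1 = p$base * nu, shape2 = (1 - p$base) * nu)
    }
  })
  as_tibble(setNames(draws, ptab$name))
}

#' Moment-matched distribution parameters
#'
#' The gamma/beta shapes implied by a base value and a range read as a 95%
#' interval; exposed for auditing the PSA.
#'
#' @param base,low,high Base value and range.
#' @param dist `"gamma"` or `"beta"`.
#' @return Named list: `sd` plus `shape`/`scale` (gamma) or
#'   `alpha`/`beta` (beta).
#' @export
moment_match <- function(base, low, high, dist = c("gamma", "beta")) {
  dist <- match.arg(dist)
  sd <- (high - low) / 3.92
  if (dist == "gamma") {
    list(sd = sd, shape = base^2 / sd^2, scale = sd^2 / base)
  } else {
    nu <- base * (1 - base) / sd^2 - 1
    list(sd = sd, alpha = base * nu, beta = (1 - base) * nu)
  }
}

# Vectorized per-iteration costing on fixed traces: with the survival curves
# held at base, cost and QALY are simple arithmetic in the sampled
# parameters and the discounted occupancy aggregates.
psa_strategy_samples <- function(config, strategy_name, agg, draws) {
  s <- config$strategies[[strategy_name]]
  col <- function(p) draws[[p]]
  daily <- Reduce(`+`, map(s$oral %||% list(),
                           function(o) col(o$price_param) * o$units_per_day),
                  accumulate = FALSE, right = FALSE) %||% 0
  if (length(daily) == 1 && daily == 0) daily <- rep(0, nrow(draws))
  infusion <- if (!is.null(s$infusion)) {
    col(s$infusion$price_param) * s$infusion$mg_per_administration
  } else rep(0, nrow(draws))
  drug <- infusion + daily * config$model$cycle_length_days *
    (s$dosed_day_fraction %||% 1)
  subs <- col(s$subsequent_cost_param)
  prop <- col(s$subsequent_prop_param)
  fu <- Reduce(`+`, map(unlist(config$followup_params), col))
  mg <- Reduce(`+`, map(unlist(config$management_params), col))
  inc <- unlist(s$ae_incidence %||% list())
  ae_cost <- if (length(inc) > 0) {
    Reduce(`+`, map(names(inc), function(a) {
      inc[[a]] * col(config$ae_cost_params[[a]])
    }))
  } else rep(0, nrow(draws))
  ae_loss <- col("ae_disutility") * min(sum(inc), 1) *
    config$model$ae_duration_weeks * 7 / 365.25
  tibble(
    strategy = strategy_name,
    cost = drug * agg$A_pfs +
      (prop * subs + (1 - prop) * col("bsc_cost")) * agg$A_pd +
      (fu + mg) * agg$A_alive +
      col("terminal_care_cost") * agg$D + ae_cost,
    qaly = col(s$u_pfs_param) * agg$Y_pfs + col("u_pd") * agg$Y_pd - ae_loss)
}

#' Probabilistic sensitivity analysis with CEAC
#'
#' Monte Carlo over the cost and utility parameters (gamma/beta
#' moment-matched draws; survival curves fixed at the base calibration and
#' the discount rate fixed, so the traces are constant across iterations).
#' Produces per-iteration cost/QALY pairs per strategy, the
#' cost-effectiveness acceptability curve (probability of maximal net
#' monetary benefit across the WTP grid), pairwise CEACs against the
#' reference, and incremental cost-effectiveness-plane quadrant shares.
#'
#' @param config A validated config.
#' @param n_iter Number of Monte Carlo iterations (default 10000).
#' @param seed Integer seed; results are bit-reproducible given the seed.
#' @param wtp_grid WTP thresholds (RMB/QALY); default 0 to 1,000,000 in
#'   10,000 steps.
#' @return List with `samples` (iteration, strategy, cost, qaly), `ceac`
#'   (wtp, strategy, probability; probabilities sum to 1 at each wtp),
#'   `pairwise_ceac` (comparator vs reference), `quadrants`, `n_iter`,
#'   `n_failed`.
#' @export
run_psa <- function(config, n_iter = 10000, seed = 1L,
                    wtp_grid = seq(0, 1e6, by = 1e4)) {
  if (n_iter < 1) abort("run_psa: n_iter must be >= 1")
  traces <- build_traces(config)
  aggs <- map(traces, trace_aggregates)
  draws <- sample_psa_parameters(param_table(config), n_iter, seed)
  ok <- stats::complete.cases(draws)
  if (mean(!ok) > 0.01) abort("run_psa: more than 1% of iterations failed")
  n_failed <- sum(!ok)
  draws <- draws[ok, ]
  samples <- list_rbind(imap(aggs, function(agg, nm) {
    psa_strategy_samples(config, nm, agg, draws) |>
      mutate(iteration = seq_len(nrow(draws)), .before = 1)
  }))

  wide_q <- matrix(samples$qaly, ncol = length(aggs))
  wide_c <- matrix(samples$cost, ncol = length(aggs))
  strategies <- names(aggs)
  ceac <- list_rbind(map(wtp_grid, function(w) {
    nmb <- w * wide_q - wide_c
    winner <- max.col(nmb, ties.method = "first")
    tibble(wtp = w, strategy = strategies,
           probability = tabulate(winner, length(strategies)) / nrow(nmb))
  }))

  ref_idx <- match(config$reference, strategies)
  comp_idx <- setdiff(seq_along(strategies), ref_idx)
  pairwise <- list_rbind(map(comp_idx, function(ci) {
    dq <- wide_q[, ci] - wide_q[, ref_idx]
    dc <- wide_c[, ci] - wide_c[, ref_idx]
    list_rbind(map(wtp_grid, function(w) {
      tibble(comparator = strategies[ci], reference = config$reference,
             wtp = w, probability = mean(w * dq - dc > 0))
    }))
  }))
  quadrants <- list_rbind(map(comp_idx, function(ci) {
    dq <- wide_q[, ci] - wide_q[, ref_idx]
    dc <- wide_c[, ci] - wide_c[, ref_idx]
    tibble(comparator = strategies[ci], reference = config$reference,
           ne_more_costly_more_effective = mean(dq > 0 & dc > 0),
           se_dominant = mean(dq > 0 & dc <= 0),
           nw_dominated = mean(dq <= 0 & dc > 0),
           sw_less_costly_less_effective = mean(dq <= 0 & dc <= 0))
  }))
  list(samples = samples, ceac = ceac, pairwise_ceac = pairwise,
       quadrants = quadrants, n_iter = n_iter, n_failed = n_failed)
}

#' CEAC crossing threshold
#'
#' First WTP value on the grid at which a pairwise CEAC reaches a target
#' probability.
#'
#' @param pairwise_ceac Tibble from [run_psa()]`$pairwise_ceac`.
#' @param comparator Strategy name.
#' @param level Target probability (default 0.5).
#' @return WTP value, or `NA` if never reached.
#' @export
ceac_crossing <- function(pairwise_ceac, comparator, level = 0.5) {
  d <- pairwise_ceac |>
    filter(.data$comparator == !!comparator) |>
    arrange(.data$wtp)
  idx <- which(d$probability >= level)
  if (length(idx) == 0) NA_real_ else d$wtp[idx[1]]
}

#' Scenario analyses: model horizon and pembrolizumab price
#'
#' Two scenario sets. Horizon: the model is re-run with 5-, 10- and 20-year
#' horizons (curves unchanged), reporting per-strategy results and, for
#' horizons beyond 5 years, the share of total discounted cost accrued in
#' the first 5 years. Price: the first-line pembrolizumab acquisition price
#' is scaled (100%, 75%, 50%, 25%, 0% by default) and the comparator ICER
#' recorded; with QALYs unchanged the ICER is affine in the price.
#'
#' @param config A validated config.
#' @param horizons Horizons in years.
#' @param price_scales Multipliers applied to the pembrolizumab price.
#' @param comparator Strategy whose infusion price is scaled.
#' @return List with tibbles `horizon` and `price`.
#' @export
run_scenarios <- function(config, horizons = c(5, 10, 20),
                          price_scales = c(1, 0.75, 0.5, 0.25, 0),
                          comparator = "lenv_pemb") {
  if (any(horizons <= 0)) abort("run_scenarios: horizons must be > 0")
  curves <- resolve_curves(config)
  horizon_tbl <- list_rbind(map(horizons, function(h) {
    traces <- build_traces(config, curves, horizon_years = h)
    ev <- evaluate_strategies(config, traces)
    share <- map_dbl(ev$valuations, function(v) {
      if (h <= 5) return(NA_real_)
      sum(v$cycle_costs[v$t_end <= 5 + 1e-9]) / sum(v$cycle_costs)
    })
    ev$results |>
      mutate(horizon_years = h,
             cost_share_first_5yr = unname(share[.data$strategy]),
             icer_vs_ref = map_dbl(.data$strategy, function(s) {
               if (s == config$reference) NA_real_
               else pair_icer(ev$results, s, config$reference)
             }))
  }))

  base <- param_base(config)
  price_param <- config$strategies[[comparator]]$infusion$price_param
  if (is.null(price_param)) {
    abort(sprintf("run_scenarios: strategy '%s' has no infusion price to scale",
                  comparator))
  }
  traces <- build_traces(config, curves)
  price_tbl <- list_rbind(map(price_scales, function(sc) {
    p <- base
    p[[price_param]] <- base[[price_param]] * sc
    icer <- pair_icer(evaluate_strategies(config, traces, p)$results,
                      comparator, config$reference)
    tibble(price_scale = sc, price = p[[price_param]], icer = icer)
  })) |>
    mutate(icer_reduction_vs_base = .data$icer[.data$price_scale == 1] -
             .data$icer)
  list(horizon = horizon_tbl, price = price_tbl)
}

#' Subgroup analysis through hazard ratios
#'
#' Assumes every subgroup shares the reference-arm baseline curves; the
#' comparator's curves are the reference curves raised to the
#' subgroup-specific PFS and OS hazard ratios, and the full valuation is
#' re-run.
#'
#' @param config A validated config.
#' @param subgroups Tibble (or data frame) with columns `label`, `hr_pfs`,
#'   `hr_os` (both > 0).
#' @param comparator Strategy whose curves are replaced.
#' @return List with `results` (per subgroup and strategy) and
#'   `incremental` (per subgroup, comparator vs reference).
#' @export
run_subgroup <- function(config, subgroups, comparator = "lenv_pemb") {
  subgroups <- as_tibble(subgroups)
  if (any(subgroups$hr_pfs <= 0 | subgroups$hr_os <= 0)) {
    abort("run_subgroup: hazard ratios must be > 0")
  }
  curves <- resolve_curves(config)
  ref_cv <- curves[[config$reference]]
  if (is.null(ref_cv)) abort("run_subgroup: reference curves missing")
  out <- map(seq_len(nrow(subgroups)), function(i) {
    sg <- subgroups[i, ]
    cv <- curves
    cv[[comparator]] <- list(pfs = apply_hazard_ratio(ref_cv$pfs, sg$hr_pfs),
                             os = apply_hazard_ratio(ref_cv$os, sg$hr_os))
    ev <- evaluate_strategies(config, build_traces(config, cv))
    list(results = mutate(ev$results, label = sg$label, .before = 1),
         incremental = icer_table(ev$results, config$reference) |>
           filter(.data$comparator == !!comparator) |>
           mutate(label = sg$label, .before = 1))
  })
  list(results = list_rbind(map(out, "results")),
       incremental = list_rbind(map(out, "incremental")))
}
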