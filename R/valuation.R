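#' Cost and utility inputs for one treatment strategy
#'
#' Bundles everything needed to price a strategy on a trace: first-line
#' acquisition costs (a daily oral component, an optional per-cycle infusion
#' component, and the fraction of days actually dosed for intermittent
#' schedules such as sunitinib's 4-weeks-on/2-weeks-off), per-cycle
#' subsequent-therapy and best-supportive-care costs in the progressed
#' state, per-cycle follow-up and hospital-management costs for alive
#' patients, a one-off terminal-care cost at death, grade >= 3
#' adverse-event management costs and disutility applied once at model
#' entry, and the health-state utilities.
#'
#' @param name Strategy label.
#' @param daily_drug_cost Oral acquisition cost per dosed day (RMB).
#' @param infusion_cost_per_cycle Infusion acquisition cost per cycle (RMB).
#' @param dosed_day_fraction Fraction of days dosed (e.g. 28/42 for the
#'   sunitinib schedule); steady-state averaging over the cycle.
#' @param subsequent_cost_per_cycle Subsequent-therapy cost per cycle in the
#'   progressed state (RMB).
#' @param subsequent_proportion Share of progressed patients receiving
#'   subsequent therapy; the remainder accrue best supportive care.
#' @param bsc_cost_per_cycle Best-supportive-care cost per cycle (RMB).
#' @param followup_cost_per_cycle,management_cost_per_cycle Per-cycle costs
#'   applied to all alive patients (RMB).
#' @param terminal_care_cost One-off end-of-life cost (RMB).
#' @param u_pfs,u_pd Health-state utilities in `[0, 1]`; a warning is
#'   issued if `u_pfs < u_pd`.
#' @param ae_profile Tibble with columns `ae`, `incidence` (grade >= 3, in
#'   `[0, 1]`) and `unit_cost` (RMB).
#' @param ae_disutility Utility decrement per adverse event episode.
#' @param ae_duration_weeks Duration of the adverse-event disutility
#'   (default 4 weeks).
#' @param discontinuation_prob_ae Probability of treatment discontinuation
#'   due to adverse events. Carried for sensitivity analyses; not applied in
#'   the base case (see the methods vignette).
#' @return A `psm_strategy` list.
#' @export
strategy_inputs <- function(name,
                            daily_drug_cost = 0,
                            infusion_cost_per_cycle = 0,
                            dosed_day_fraction = 1,
                            subsequent_cost_per_cycle = 0,
                            subsequent_proportion = 0,
                            bsc_cost_per_cycle = 0,
                            followup_cost_per_cycle = 0,
                            management_cost_per_cycle = 0,
                            terminal_care_cost = 0,
                            u_pfs = 1, u_pd = 1,
                            ae_profile = tibble(ae = character(),
                                                incidence = numeric(),
                                                unit_cost = numeric()),
                            ae_disutility = 0,
                            ae_duration_weeks = 4,
                            discontinuation_prob_ae = 0) {
  costs <- c(daily_drug_cost = daily_drug_cost,
             infusion_cost_per_cycle = infusion_cost_per_cycle,
             subsequent_cost_per_cycle = subsequent_cost_per_cycle,
             bsc_cost_per_cycle = bsc_cost_per_cycle,
             followup_cost_per_cycle = followup_cost_per_cycle,
             management_cost_per_cycle = management_cost_per_cycle,
             terminal_care_cost = terminal_care_cost)
  neg <- names(costs)[costs < 0]
  if (length(neg) > 0) {
    abort(sprintf("strategy_inputs: negative cost in field(s): %s",
                  paste(neg, collapse = ", ")))
  }
  unit <- c(dosed_day_fraction = dosed_day_fraction,
            subsequent_proportion = subsequent_proportion,
            u_pfs = u_pfs, u_pd = u_pd,
            discontinuation_prob_ae = discontinuation_prob_ae)
  bad <- names(unit)[unit < 0 | unit > 1]
  if (length(bad) > 0) {
    abort(sprintf("strategy_inputs: field(s) outside [0, 1]: %s",
                  paste(bad, collapse = ", ")))
  }
  if (u_pfs < u_pd) {
    warn(sprintf("strategy_inputs('%s'): u_pfs < u_pd is unusual", name))
  }
  if (nrow(ae_profile) > 0 &&
      (any(ae_profile$incidence < 0 | ae_profile$incidence > 1) ||
       any(ae_profile$unit_cost < 0))) {
    abort("strategy_inputs: ae_profile incidences must be in [0, 1], costs >= 0")
  }
  if (ae_disutility < 0 || ae_duration_weeks < 0) {
    abort("strategy_inputs: ae_disutility and ae_duration_weeks must be >= 0")
  }
  structure(list(name = name,
                 daily_drug_cost = daily_drug_cost,
                 infusion_cost_per_cycle = infusion_cost_per_cycle,
                 dosed_day_fraction = dosed_day_fraction,
                 subsequent_cost_per_cycle = subsequent_cost_per_cycle,
                 subsequent_proportion = subsequent_proportion,
                 bsc_cost_per_cycle = bsc_cost_per_cycle,
                 followup_cost_per_cycle = followup_cost_per_cycle,
                 management_cost_per_cycle = management_cost_per_cycle,
                 terminal_care_cost = terminal_care_cost,
                 u_pfs = u_pfs, u_pd = u_pd,
                 ae_profile = as_tibble(ae_profile),
                 ae_disutility = ae_disutility,
                 ae_duration_weeks = ae_duration_weeks,
                 discontinuation_prob_ae = discontinuation_prob_ae),
            class = "psm_strategy")
}

#' First-line acquisition cost for one cycle
#'
#' Infusion component plus oral component; intermittent schedules enter as
#' the dosed-day fraction of the cycle (steady-state averaging, e.g. 28/42
#' for sunitinib). Applied only to the progression-free share of the cohort
#' (the weighting happens in [accumulate_strategy()]).
#'
#' @param inputs A [strategy_inputs()].
#' @param cycle_index Cycle number (>= 1); present for schedule patterns,
#'   the base-case cost is cycle-invariant.
#' @param cycle_length_days Days per cycle.
#' @return Cost in RMB for that cycle.
#' @export
cycle_drug_cost <- function(inputs, cycle_index = 1, cycle_length_days = 21) {
  stopifnot(inherits(inputs, "psm_strategy"))
  if (any(cycle_index < 1)) abort("cycle_drug_cost: cycle_index must be >= 1")
  rep(inputs$infusion_cost_per_cycle +
        inputs$daily_drug_cost * cycle_length_days * inputs$dosed_day_fraction,
      length(cycle_index))
}

#' One-off adverse-event burden at model entry
#'
#' Expected grade >= 3 adverse-event management cost
#' (`sum(incidence * unit_cost)`) and QALY loss
#' (`disutility * min(sum(incidence), 1) * duration`), both applied once
#' when treatment starts.
#'
#' @param inputs A [strategy_inputs()].
#' @return Named list `ae_cost` (RMB) and `ae_qaly_loss` (years).
#' @export
one_off_event_burden <- function(inputs) {
  stopifnot(inherits(inputs, "psm_strategy"))
  prof <- inputs$ae_profile
  if (nrow(prof) == 0) return(list(ae_cost = 0, ae_qaly_loss = 0))
  list(
    ae_cost = sum(prof$incidence * prof$unit_cost),
    ae_qaly_loss = inputs$ae_disutility * min(sum(prof$incidence), 1) *
      inputs$ae_duration_weeks * 7 / 365.25)
}

#' Attach costs and utilities to a trace
#'
#' Accumulates discounted costs and outcomes over the trace: first-line
#' drug cost weighted by progression-free occupancy; subsequent therapy
#' (for the recipient share) and best supportive care (for the rest)
#' weighted by progressed occupancy; follow-up and management costs for all
#' alive patients; terminal care for incident deaths; the adverse-event
#' burden once at entry. QALYs weight time by the state utilities, life
#' years use utility 1.
#'
#' @param trace A [build_trace()] result.
#' @param inputs A [strategy_inputs()].
#' @return List with `costs` (one-row tibble of discounted components and
#'   `total`), `outcomes` (one-row tibble `ly`, `qaly`,
#'   `ly_undiscounted`), and `cycle_costs` (per-cycle discounted cost,
#'   entry burden on cycle 1).
#' @export
accumulate_strategy <- function(trace, inputs) {
  stopifnot(inherits(trace, "psm_trace"), inherits(inputs, "psm_strategy"))
  cld <- attr(trace, "cycle_length_days")
  dt <- trace$t_end - trace$t_start
  disc <- trace$discount_factor

  drug <- cycle_drug_cost(inputs, trace$cycle, cld)
  burden <- one_off_event_burden(inputs)

  per_cycle <- list(
    first_line = drug * trace$occ_pfs * disc,
    subsequent = inputs$subsequent_proportion *
      inputs$subsequent_cost_per_cycle * trace$occ_pd * disc,
    bsc = (1 - inputs$subsequent_proportion) * inputs$bsc_cost_per_cycle *
      trace$occ_pd * disc,
    followup = inputs$followup_cost_per_cycle *
      (trace$occ_pfs + trace$occ_pd) * disc,
    management = inputs$management_cost_per_cycle *
      (trace$occ_pfs + trace$occ_pd) * disc,
    terminal = inputs$terminal_care_cost * trace$incident_deaths * disc)

  comp <- c(map_dbl(per_cycle, sum), ae = burden$ae_cost)
  costs <- as_tibble(as.list(comp)) |>
    mutate(strategy = inputs$name, total = sum(comp), .before = 1)

  qaly <- sum(dt * disc * (inputs$u_pfs * trace$occ_pfs +
                             inputs$u_pd * trace$occ_pd)) -
    burden$ae_qaly_loss
  outcomes <- tibble(
    strategy = inputs$name,
    ly = sum(dt * disc * (trace$occ_pfs + trace$occ_pd)),
    qaly = qaly,
    ly_undiscounted = sum(dt * (trace$occ_pfs + trace$occ_pd)))

  cycle_costs <- Reduce(`+`, per_cycle)
  cycle_costs[1] <- cycle_costs[1] + burden$ae_cost
  list(costs = costs, outcomes = outcomes, cycle_costs = cycle_costs,
       t_end = trace$t_end)
}
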