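#' Cycle grid for the partitioned survival engine
#'
#' Defines the discrete cycle boundaries, in years, on which state occupancy
#' is evaluated. The default 21-day cycle matches the pembrolizumab
#' administration schedule that the per-cycle costs are keyed to; the last
#' boundary is the first cycle end at or beyond the horizon.
#'
#' @param cycle_length_days Positive cycle length in days (default 21).
#' @param horizon_years Positive model horizon in years (default 5).
#' @return A `psm_cycle_grid` with boundary times and cycle length.
#' @export
cycle_grid <- function(cycle_length_days = 21, horizon_years = 5) {
  if (cycle_length_days <= 0) abort("cycle_grid: cycle length must be > 0")
  if (horizon_years <= 0) abort("cycle_grid: horizon must be > 0")
  dt <- cycle_length_days / 365.25
  n <- ceiling(horizon_years / dt - 1e-9)
  structure(list(cycle_length_days = cycle_length_days,
                 horizon_years = horizon_years,
                 cycle_length_years = dt,
                 boundaries = (0:n) * dt,
                 n_cycles = n),
            class = "psm_cycle_grid")
}

#' Discount factor
#'
#' Present-value weight `(1 + rate)^(-t)` for an annual discount rate.
#'
#' @param t_years Nonnegative time in years.
#' @param rate Annual discount rate (> -1).
#' @return Positive discount factors.
#' @export
discount_factor <- function(t_years, rate) {
  if (rate <= -1) abort("discount_factor: rate must be > -1")
  (1 + rate)^(-t_years)
}

curve_time <- function(fn, t_years) {
  if (fn$time_unit == "months") t_years * 12 else t_years
}

#' Build the three-state occupancy trace
#'
#' The partitioned-survival core: per cycle, state occupancy is read
#' directly off the PFS and OS curves at the cycle midpoint (the mid-cycle
#' evaluation is equivalent to a half-cycle correction):
#' `occ_pfs = min(S_pfs, S_os)`, `occ_dead = 1 - S_os`, and the progressed
#' share is the band between the curves, so the three occupancies sum to 1
#' exactly by construction. Incident deaths per cycle are the drop in OS
#' across the cycle boundaries; discounting is applied at the midpoint time.
#' Where digitization or extrapolation makes the PFS curve cross above OS,
#' PFS is clamped to OS with a warning (the progressed share is never
#' negative).
#'
#' @param s_pfs,s_os [surv_fn()] curves (any time unit).
#' @param grid A [cycle_grid()].
#' @param discount_rate Annual discount rate in `[0, 1]`.
#' @return A tibble of class `psm_trace` with columns `cycle`, `t_start`,
#'   `t_end`, `t_mid_years`, `occ_pfs`, `occ_pd`, `occ_dead`,
#'   `incident_deaths`, `discount_factor`.
#' @export
build_trace <- function(s_pfs, s_os, grid = cycle_grid(),
                        discount_rate = 0.05) {
  stopifnot(inherits(s_pfs, "psm_survfn"), inherits(s_os, "psm_survfn"),
            inherits(grid, "psm_cycle_grid"))
  if (discount_rate < 0 || discount_rate > 1) {
    abort("build_trace: discount_rate must be in [0, 1]")
  }
  b <- grid$boundaries
  t_start <- b[-length(b)]
  t_end <- b[-1]
  t_mid <- (t_start + t_end) / 2
  sp <- survival_at(s_pfs, curve_time(s_pfs, t_mid))
  so <- survival_at(s_os, curve_time(s_os, t_mid))
  n_cross <- sum(sp > so + 1e-12)
  if (n_cross > 0) {
    warn(sprintf(
      "build_trace: PFS exceeded OS at %d cycle midpoint(s); clamped", n_cross))
  }
  occ_pfs <- pmin(sp, so)
  so_bound <- survival_at(s_os, curve_time(s_os, b))
  out <- tibble(
    cycle = seq_along(t_mid),
    t_start = t_start, t_end = t_end, t_mid_years = t_mid,
    occ_pfs = occ_pfs,
    occ_pd = so - occ_pfs,
    occ_dead = 1 - so,
    incident_deaths = so_bound[-length(so_bound)] - so_bound[-1],
    discount_factor = discount_factor(t_mid, discount_rate))
  attr(out, "cycle_length_days") <- grid$cycle_length_days
  attr(out, "discount_rate") <- discount_rate
  attr(out, "horizon_years") <- grid$horizon_years
  class(out) <- c("psm_trace", class(out))
  out
}

# discounted occupancy aggregates reused by valuation and the PSA fast path
trace_aggregates <- function(trace) {
  dt <- trace$t_end - trace$t_start
  disc <- trace$discount_factor
  list(
    A_pfs = sum(trace$occ_pfs * disc),          # discounted PFS cycle-weight
    A_pd = sum(trace$occ_pd * disc),
    A_alive = sum((trace$occ_pfs + trace$occ_pd) * disc),
    D = sum(trace$incident_deaths * disc),      # discounted incident deaths
    Y_pfs = sum(dt * disc * trace$occ_pfs),     # discounted years in PFS
    Y_pd = sum(dt * disc * trace$occ_pd),
    LY_undisc = sum(dt * (trace$occ_pfs + trace$occ_pd)))
}
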