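#' Summary statistics of a three-arm trial
#'
#' Collects the published summary statistics that the synthetic-data
#' generator is calibrated to: per-arm PFS medians, PFS and OS hazard ratios
#' against the reference arm, the discounted life-year anchor for the
#' reference OS curve, and the accrual/follow-up window that produces
#' administrative right-censoring. The defaults are the CLEAR-like study
#' conditions: PFS medians 23.9 / 14.7 / 9.2 months, HR_PFS 0.39 / 0.65 and
#' HR_OS 0.66 / 1.15 versus sunitinib, 355 patients per arm.
#'
#' @param arm_names Character labels; the reference arm must be included.
#' @param reference Name of the reference arm (hazard ratios are 1 there).
#' @param n_per_arm Patients per arm.
#' @param pfs_median_months Named (per-arm) positive medians, months.
#' @param pfs_hr_vs_ref,os_hr_vs_ref Named per-arm hazard ratios vs the
#'   reference; the reference entry must equal 1.
#' @param os_anchor_ly Discounted life-years over the 5-year horizon that the
#'   reference OS exponential is calibrated to.
#' @param accrual_months,max_followup_months Uniform accrual window and
#'   maximum follow-up (months); `max_followup_months >= accrual_months`.
#' @return A `psm_trial_summary` list.
#' @export
trial_summary <- function(arm_names = c("lenv_pemb", "lenv_ever", "sunitinib"),
                          reference = "sunitinib",
                          n_per_arm = 355,
                          pfs_median_months = c(lenv_pemb = 23.9,
                                                lenv_ever = 14.7,
                                                sunitinib = 9.2),
                          pfs_hr_vs_ref = c(lenv_pemb = 0.39,
                                            lenv_ever = 0.65,
                                            sunitinib = 1),
                          os_hr_vs_ref = c(lenv_pemb = 0.66,
                                           lenv_ever = 1.15,
                                           sunitinib = 1),
                          os_anchor_ly = 2.83,
                          accrual_months = 12,
                          max_followup_months = 36) {
  if (!reference %in% arm_names) {
    abort("trial_summary: reference arm must be one of arm_names")
  }
  if (n_per_arm < 1) abort("trial_summary: n_per_arm must be >= 1")
  for (v in list(pfs_median_months, pfs_hr_vs_ref, os_hr_vs_ref)) {
    if (!all(arm_names %in% names(v))) {
      abort("trial_summary: per-arm vectors must name every arm")
    }
    if (any(v[arm_names] <= 0)) abort("trial_summary: medians and HRs must be > 0")
  }
  if (pfs_hr_vs_ref[[reference]] != 1 || os_hr_vs_ref[[reference]] != 1) {
    abort("trial_summary: reference-arm hazard ratios must equal 1")
  }
  if (accrual_months < 0 || max_followup_months < accrual_months) {
    abort("trial_summary: need max_followup_months >= accrual_months >= 0")
  }
  structure(list(arm_names = arm_names, reference = reference,
                 n_per_arm = as.integer(n_per_arm),
                 pfs_median_months = pfs_median_months[arm_names],
                 pfs_hr_vs_ref = pfs_hr_vs_ref[arm_names],
                 os_hr_vs_ref = os_hr_vs_ref[arm_names],
                 os_anchor_ly = os_anchor_ly,
                 accrual_months = accrual_months,
                 max_followup_months = max_followup_months),
            class = "psm_trial_summary")
}

#' Simulate individual patient data for one arm
#'
#' Draws jointly consistent PFS and OS records by inverse-transform sampling
#' from true parametric curves. A single uniform draw per patient feeds both
#' endpoint quantiles (comonotone coupling) and the PFS time is then clipped
#' to the OS time, which guarantees the partitioned-survival constraint
#' `PFS <= OS` in the truth data. Administrative censoring occurs at
#' `max_followup_months` minus a uniform accrual offset, shared by both
#' endpoints of a patient.
#'
#' @param spec_pfs,spec_os True [surv_fn()] curves in months.
#' @param n Number of patients (>= 1).
#' @param max_followup_months Maximum administrative follow-up, months.
#' @param accrual_months Uniform accrual window, months (0 disables).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return List with tibbles `pfs` and `os` (columns `time_months`, `event`),
#'   plus the seed used.
#' @export
simulate_arm_ipd <- function(spec_pfs, spec_os, n,
                             max_followup_months = 36,
                             accrual_months = 12,
                             seed = 1L) {
  stopifnot(inherits(spec_pfs, "psm_survfn"), inherits(spec_os, "psm_survfn"))
  if (!is.numeric(n) || n < 1) abort("simulate_arm_ipd: n must be >= 1")
  if (max_followup_months <= 0) {
    abort("simulate_arm_ipd: max_followup_months must be > 0")
  }
  n <- as.integer(n)
  set.seed(seed)
  u <- runif(n)
  t_os <- survival_quantile(spec_os, u)
  t_pfs <- pmin(survival_quantile(spec_pfs, u), t_os)
  c_time <- max_followup_months -
    runif(n, 0, min(accrual_months, max_followup_months * 0.999))
  mk <- function(t) tibble(time_months = pmin(t, c_time),
                           event = as.integer(t <= c_time))
  list(pfs = mk(t_pfs), os = mk(t_os), seed = seed)
}

#' Emit digitized-curve and risk-table artifacts from simulated IPD
#'
#' Produces the two artifacts a digitization workflow would yield from a
#' published figure: the product-limit (Kaplan-Meier) estimate sampled at
#' every step time, and the number still at risk on a reporting grid.
#'
#' @param ipd Tibble with `time_months` and `event` columns.
#' @param risk_grid_months Strictly increasing grid starting at 0.
#' @return List with `curve` (tibble `time_months`, `survival`, first row
#'   `(0, 1)`) and `risk` (tibble `time_months`, `n_risk`).
#' @export
emit_km_artifacts <- function(ipd, risk_grid_months = seq(0, 36, by = 3)) {
  check_ipd(ipd)
  if (length(risk_grid_months) < 1 || risk_grid_months[1] != 0 ||
      is.unsorted(risk_grid_months, strictly = TRUE)) {
    abort("emit_km_artifacts: risk grid must start at 0 and strictly increase")
  }
  curve <- km_estimate(ipd)
  risk <- tibble(
    time_months = risk_grid_months,
    n_risk = vapply(risk_grid_months,
                    function(g) sum(ipd$time_months >= g), integer(1)))
  list(curve = curve, risk = risk)
}

#' Build true curves for every arm of a summary
#'
#' Reference PFS is a Weibull calibrated to the published median; reference
#' OS is an exponential anchored to the discounted life-year target;
#' comparator curves are proportional-hazards shifts of the reference by the
#' published hazard ratios.
#'
#' @param summary A [trial_summary()].
#' @param pfs_shape Weibull shape for the reference PFS curve.
#' @param horizon_years,cycle_length_days,discount_rate Grid settings for the
#'   OS anchor calibration.
#' @return Named list (per arm) of lists with `pfs` and `os` curves.
#' @export
true_curves_from_summary <- function(summary, pfs_shape = 1.2,
                                     horizon_years = 5,
                                     cycle_length_days = 21,
                                     discount_rate = 0.05) {
  stopifnot(inherits(summary, "psm_trial_summary"))
  ref <- summary$reference
  ref_pfs <- calibrate_weibull_from_median(
    summary$pfs_median_months[[ref]], shape = pfs_shape)
  ref_os <- calibrate_exponential_to_discounted_ly(
    summary$os_anchor_ly, horizon_years, cycle_length_days, discount_rate)
  out <- map(summary$arm_names, function(arm) {
    list(pfs = apply_hazard_ratio(ref_pfs, summary$pfs_hr_vs_ref[[arm]]),
         os = apply_hazard_ratio(ref_os, summary$os_hr_vs_ref[[arm]]))
  })
  setNames(out, summary$arm_names)
}
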