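# psmcea

A partitioned survival cost-utility model for first-line therapy in
advanced renal cell carcinoma (RCC), from a Chinese health-system
perspective: lenvatinib + pembrolizumab and lenvatinib + everolimus versus
sunitinib. The package is for health economists and HTA analysts who want a
reproducible, testable version of this class of analysis — from
survival-curve evidence all the way to probabilistic sensitivity analysis —
rather than a spreadsheet or a point-and-click model.

## The model

A three-state partitioned survival model (progression-free, progressed,
dead) reads state occupancy directly off the endpoint curves instead of
transition probabilities:

```
occ_PF(t)   = min(S_PFS(t), S_OS(t))
occ_dead(t) = 1 − S_OS(t)
occ_PD(t)   = S_OS(t) − min(S_PFS(t), S_OS(t))
```

evaluated at the midpoints of 21-day cycles over a 5-year horizon
(half-cycle correction), discounted at 5%/year. Discounted costs (drug
acquisition while progression-free, subsequent therapy or best supportive
care while progressed, follow-up/management while alive, terminal care at
death, one-off adverse-event burden) and utility-weighted QALYs accumulate
per strategy; strategies are compared by the incremental
cost-effectiveness ratio ICER = ΔCost/ΔQALY against a willingness-to-pay
threshold of 1–3× GDP per capita (217,341 RMB), equivalently by net
monetary benefit NMB = WTP × QALY − Cost.

Around that core the package provides the full evidence pipeline:

* **synthetic trial data** calibrated to published medians and hazard
  ratios (`trial_summary()`, `simulate_arm_ipd()`, `emit_km_artifacts()`);
* **pseudo-IPD reconstruction** from digitized Kaplan–Meier coordinates
  plus number-at-risk tables, a deterministic Guyot-style inversion
  (`sanitize_curve()`, `reconstruct_ipd()`, `km_estimate()`);
* **parametric extrapolation**: six families fitted by right-censored
  maximum likelihood with AIC/BIC selection and proportional-hazards
  shifts (`fit_parametric()`, `select_distribution()`,
  `apply_hazard_ratio()`);
* **decision analysis**: incremental tables, one-way (tornado) sensitivity,
  10,000-draw PSA with CEAC, horizon/price scenarios and hazard-ratio
  subgroups (`icer_table()`, `one_way_dsa()`, `run_psa()`,
  `run_scenarios()`, `run_subgroup()`), plus `ggplot2` helpers
  (`plot_trace()`, `plot_tornado()`, `plot_ceac()`, `plot_ce_plane()`) and
  an end-to-end artifact writer (`run_pipeline()`).

See the methods vignette (`vignettes/partitioned-survival-cua.Rmd`) for the
model assumptions, the surrogate calibration and every numerical choice.

## Worked example

```r
library(psmcea)

cfg <- psm_example_config()   # shipped surrogate calibration
bc  <- run_base_case(cfg)
bc
#> Partitioned survival cost-utility analysis (base case)
#>   horizon 5 years, 21-day cycles, 5.0% discount, reference 'sunitinib'
#> # A tibble: 3 × 5
#>   strategy     ly  qaly ly_undiscounted     cost
#>   <chr>     <dbl> <dbl>           <dbl>    <dbl>
#> 1 sunitinib  2.83  1.93            3.12  538452.
#> 2 lenv_ever  2.66  1.96            2.93  596158.
#> 3 lenv_pemb  3.27  2.45            3.63 1673705.
#>
#> Incremental analysis vs reference:
#> # A tibble: 2 × 6
#>   comparator reference delta_cost delta_qaly     icer label
#>   <chr>      <chr>          <dbl>      <dbl>    <dbl> <chr>
#> 1 lenv_ever  sunitinib     57706.     0.0326 1770499. ""
#> 2 lenv_pemb  sunitinib   1135252.     0.520  2181730. ""
```

Reading the output: over 5 discounted years, lenvatinib + pembrolizumab
adds 0.52 QALYs over sunitinib at an extra 1.14 million RMB — an ICER of
about 2.18 million RMB/QALY, more than three times the 652,023 RMB/QALY
upper threshold, so neither combination is cost-effective at Chinese
prices. The tornado confirms the PFS utility and the pembrolizumab price as
the dominant drivers:

```r
one_way_dsa(cfg, "lenv_pemb", "sunitinib")[1:3, ]
#> # A tibble: 3 × 7
#>   parameter               low    high icer_low icer_high icer_base    width
#> 1 u_pfs                 0.656   0.984 5362672.  1369433.  2181730. 3993240.
#> 2 u_pfs_sunitinib       0.584   0.876 1726490.  2963016.  2181730. 1236526.
#> 3 price_pembrolizumab 143.34  215.02  1730810.  2632650.  2181730.  901840.
```

`run_psa(cfg, n_iter = 10000, seed = 1)` yields the CEAC: the pembrolizumab
combination is never cost-effective below 1,000,000 RMB/QALY, while the
everolimus combination's pairwise acceptability against sunitinib stays in
the 40% range over the upper half of that grid.

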