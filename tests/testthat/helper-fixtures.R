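# shared fixtures built in code; the shipped config is cached per test run
fixture_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- psm_example_config()
    cfg
  }
})

fixture_base_case <- local({
  bc <- NULL
  function() {
    if (is.null(bc)) bc <<- run_base_case(fixture_config())
    bc
  }
})

# tiny hand-made IPD: events at 1 and 3 months, censored at 2 and 4
ipd_four <- function() {
  tibble::tibble(time_months = c(1, 2, 3, 4), event = c(1L, 0L, 1L, 0L))
}

# exponential-family IPD with closed-form MLE rate 0.2 = 20 / 100
ipd_exponential_closed_form <- function() {
  tibble::tibble(time_months = c(rep(3, 20), rep(4, 10)),
                 event = c(rep(1L, 20), rep(0L, 10)))
}
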