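#' Sanitize a digitized Kaplan-Meier curve
#'
#' Digitized coordinates carry clicking noise: survival values can tick
#' upward, times can repeat, and the origin may be missing. This enforces
#' the defining properties of a survival curve: values are clamped to
#' `[0, 1]`, duplicate times keep the last value, monotonicity is restored
#' by a running minimum, and `(0, 1)` is prepended if absent. The operation
#' is idempotent.
#'
#' @param curve Data frame with columns `time_months` and `survival`.
#' @return A sanitized tibble with the same columns.
#' @export
sanitize_curve <- function(curve) {
  if (!is.data.frame(curve) || nrow(curve) == 0) {
    abort("sanitize_curve: curve must be a nonempty data frame")
  }
  if (!all(c("time_months", "survival") %in% names(curve))) {
    abort("sanitize_curve: need columns 'time_months' and 'survival'")
  }
  if (any(curve$time_months < 0)) {
    abort("sanitize_curve: negative times are not valid")
  }
  out <- curve |>
    as_tibble() |>
    select("time_months", "survival") |>
    mutate(survival = pmin(pmax(.data$survival, 0), 1)) |>
    arrange(.data$time_months) |>
    group_by(.data$time_months) |>
    slice_tail(n = 1) |>
    ungroup()
  if (out$time_months[1] != 0) {
    out <- bind_rows(tibble(time_months = 0, survival = 1), out)
  }
  out$survival[1] <- 1  # everyone at risk and event-free at the origin
  out |> mutate(survival = cummin(.data$survival))
}

#' Evaluate a step survival curve
#'
#' Right-continuous step interpolation of a digitized curve (the value at a
#' step time is the post-drop value).
#'
#' @param curve Tibble with `time_months`, `survival`.
#' @param t Times at which to read the curve.
#' @return Survival values.
#' @export
eval_step_curve <- function(curve, t) {
  approx(curve$time_months, curve$survival, xout = t,
         method = "constant", f = 0, rule = 2)$y
}

# Real-valued event allocation for one risk interval.
# Walks the digitized steps with `c_cens` censor times interleaved at
# equally spaced quantiles, tracking a fractional at-risk count; returns the
# per-step (real) event counts implied by the KM ratios.
alloc_interval <- function(step_t, step_s, c_cens, n_enter, s_enter, t0, t1) {
  cens_t <- if (c_cens > 0) t0 + seq_len(c_cens) / (c_cens + 1) * (t1 - t0)
            else numeric(0)
  ev <- data.frame(t = c(step_t, cens_t),
                   kind = rep(c(1L, 0L), c(length(step_t), length(cens_t))),
                   s = c(step_s, rep(NA_real_, length(cens_t))))
  ev <- ev[order(ev$t, -ev$kind), , drop = FALSE]  # event before censor at ties
  n_cur <- n_enter
  s_cur <- s_enter
  d <- numeric(length(step_t))
  k <- 0L
  for (i in seq_len(nrow(ev))) {
    if (ev$kind[i] == 1L) {
      k <- k + 1L
      if (n_cur > 1e-12 && s_cur > 0) {
        d[k] <- n_cur * max(0, 1 - ev$s[i] / s_cur)
        s_cur <- max(ev$s[i], 0)
        n_cur <- n_cur - d[k]
      }
    } else {
      n_cur <- max(n_cur - 1, 0)
    }
  }
  list(d = d, n_exit = n_cur)
}

# Largest-remainder apportionment of `total` integer events across steps,
# proportional to the real-valued allocation `d`.
apportion <- function(d, total) {
  if (total <= 0) return(integer(length(d)))
  if (sum(d) <= 0) {
    out <- integer(length(d))
    if (length(d) > 0) out[length(d)] <- total  # degenerate: pile on last step
    return(out)
  }
  raw <- d / sum(d) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Reconstruct pseudo individual patient data from a digitized curve
#'
#' Inverts the product-limit estimator: published Kaplan-Meier coordinates
#' plus the number-at-risk table are combined into per-patient
#' `(time, event)` records whose KM estimate tracks the digitized curve and
#' whose at-risk counts match the published table exactly at every risk
#' time. Within each risk interval the censor count is iterated to the
#' unique value consistent with the at-risk decline, censor times are placed
#' at equally spaced quantiles (deterministic), and integer event counts are
#' assigned across digitized steps by largest-remainder apportionment. After
#' the last risk entry no censoring is assumed, unless `total_events` is
#' given, in which case the residual events are balanced to match it and the
#' remainder is censored.
#'
#' @param curve Digitized curve, sanitized with [sanitize_curve()] first
#'   (done internally if needed); columns `time_months`, `survival`.
#' @param risk Risk table; columns `time_months` (first entry 0, strictly
#'   increasing) and `n_risk` (nonincreasing).
#' @param total_events Optional published total event count used to
#'   constrain the tail beyond the last risk time.
#' @return Tibble of records `time_months`, `event` (class includes
#'   `psm_pseudo_ipd`); the record count equals the published `n_risk` at
#'   time 0.
#' @references Guyot-style reconstruction from published survival curves and
#'   at-risk tables.
#' @export
reconstruct_ipd <- function(curve, risk, total_events = NULL) {
  curve <- sanitize_curve(curve)
  if (!is.data.frame(risk) || nrow(risk) == 0 ||
      !all(c("time_months", "n_risk") %in% names(risk))) {
    abort("reconstruct_ipd: risk table needs columns 'time_months', 'n_risk'")
  }
  risk <- arrange(as_tibble(risk), .data$time_months)
  if (risk$time_months[1] != 0) {
    abort("reconstruct_ipd: risk table must start at time 0")
  }
  if (any(diff(risk$n_risk) > 0)) {
    abort("reconstruct_ipd: at-risk counts increase over time")
  }
  zero_t <- curve$time_months[which(curve$survival <= 0)[1]]
  if (!is.na(zero_t) && any(risk$time_months > zero_t & risk$n_risk > 0)) {
    abort(sprintf(
      "reconstruct_ipd: survival reaches 0 at t=%g but later at-risk counts are positive",
      zero_t))
  }

  steps <- filter(curve, .data$time_months > 0)
  ev_t <- c(); ev_n <- c(); cs_t <- c(); cs_n <- c()
  n_cur <- risk$n_risk[1]
  s_hat <- 1
  J <- nrow(risk)

  for (j in seq_len(max(J - 1, 0))) {
    t0 <- risk$time_months[j]; t1 <- risk$time_months[j + 1]
    n0 <- n_cur; n1 <- risk$n_risk[j + 1]
    in_iv <- steps$time_months >= t0 & steps$time_months < t1
    st <- steps$time_months[in_iv]; ss <- steps$survival[in_iv]

    # iterate the censor count to the value consistent with the at-risk drop
    c_cens <- max(0L, n0 - n1 - as.integer(round(
      sum(alloc_interval(st, ss, 0L, n0, s_hat, t0, t1)$d))))
    for (iter in seq_len(10000L)) {
      d_real <- alloc_interval(st, ss, c_cens, n0, s_hat, t0, t1)$d
      c_new <- max(0L, n0 - n1 - as.integer(round(sum(d_real))))
      if (c_new == c_cens) break
      c_cens <- c_new
    }
    d_int <- apportion(d_real, n0 - n1 - c_cens)

    # final integer bookkeeping pass (event before censor at ties)
    if (length(st) > 0) {
      keep <- d_int > 0
      ev_t <- c(ev_t, st[keep]); ev_n <- c(ev_n, d_int[keep])
      for (k in which(keep)) {
        if (n_cur > 0) s_hat <- s_hat * (1 - d_int[k] / n_cur)
        n_cur <- n_cur - d_int[k]
      }
    }
    if (c_cens > 0) {
      q <- t0 + seq_len(c_cens) / (c_cens + 1) * (t1 - t0)
      cs_t <- c(cs_t, q); cs_n <- c(cs_n, rep(1L, c_cens))
      n_cur <- n_cur - c_cens
    }
    stopifnot(n_cur == n1)
  }

  # tail beyond the last risk entry
  t_last <- risk$time_months[J]
  tail_steps <- filter(steps, .data$time_months >= t_last)
  if (nrow(tail_steps) > 0 && n_cur > 0) {
    d_real <- alloc_interval(tail_steps$time_months, tail_steps$survival,
                             0L, n_cur, s_hat, t_last,
                             max(tail_steps$time_months))$d
    budget <- if (!is.null(total_events)) {
      max(0L, as.integer(total_events) - sum(ev_n))
    } else {
      as.integer(round(sum(d_real)))
    }
    d_int <- apportion(d_real, min(budget, n_cur))
    keep <- d_int > 0
    ev_t <- c(ev_t, tail_steps$time_months[keep])
    ev_n <- c(ev_n, d_int[keep])
    n_cur <- n_cur - sum(d_int)
  }
  if (n_cur > 0) {
    # survivors administratively censored at end of observation
    end_t <- max(t_last, curve$time_months[nrow(curve)])
    cs_t <- c(cs_t, end_t); cs_n <- c(cs_n, n_cur)
  }

  out <- bind_rows(
    tibble(time_months = rep(ev_t, ev_n), event = 1L),
    tibble(time_months = rep(cs_t, cs_n), event = 0L)) |>
    arrange(.data$time_months, desc(.data$event))
  stopifnot(nrow(out) == risk$n_risk[1])
  class(out) <- c("psm_pseudo_ipd", class(out))
  out
}

#' Product-limit (Kaplan-Meier) estimate of pseudo-IPD
#'
#' Standard product-limit step function, computed with
#' [survival::survfit()] and returned as a tidy step curve beginning at
#' `(0, 1)` with one row per distinct event time.
#'
#' @param ipd Tibble with `time_months` and `event`.
#' @return Tibble with `time_months` and `survival`.
#' @export
km_estimate <- function(ipd) {
  check_ipd(ipd)
  df <- as.data.frame(ipd)
  sf <- survival::survfit(survival::Surv(time_months, event) ~ 1, data = df)
  drop <- sf$n.event > 0
  tibble(time_months = c(0, sf$time[drop]),
         survival = c(1, sf$surv[drop]))
}

#' Median of a Kaplan-Meier step curve
#'
#' First time at which the curve falls to 0.5 or below (`NA` if it never
#' does within the observed range).
#'
#' @param curve Tibble with `time_months`, `survival`.
#' @return Median time (months) or `NA`.
#' @export
km_median <- function(curve) {
  idx <- which(curve$survival <= 0.5)
  if (length(idx) == 0) return(NA_real_)
  curve$time_months[idx[1]]
}
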