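# Discount rates and per-period schedules for each numeraire.
#
# Two compounding conventions are carried throughout. "approx_subtractive"
# reproduces the usual printed arithmetic in which rates combine by addition
# and subtraction (r_s - gk_h, r_h + gk_h, ...). "exact_multiplicative"
# combines the same ingredients as growth factors, (1+a)/(1+b) - 1, which is
# what makes the numeraire-equivalence identities hold to machine precision.

#' One-period forward rates and cumulative discount factors
#'
#' A `rate_schedule` carries per-period one-period forward rates `r[t]` and
#' the cumulative discount factors `D[t] = prod_{s<=t} 1/(1+r[s])`: the value
#' at decision time of one unit accruing at the end of period `t`.
#'
#' @param rates A single rate (recycled over the horizon) or a vector of
#'   per-period forward rates, each > -1.
#' @param T Horizon in periods; defaults to `length(rates)`.
#' @param factors Optional explicit discount factors (internal use); when
#'   supplied they must be consistent with `rates` by construction.
#' @return An object of class `rate_schedule` with fields `rates`, `factors`
#'   and `T`.
#' @export
rate_schedule <- function(rates, T = length(rates), factors = NULL) {
  if (length(rates) == 1L) rates <- rep(rates, T)
  if (length(rates) != T || T < 1L) {
    stop("`rates` must have length T >= 1", call. = FALSE)
  }
  if (any(!is.finite(rates)) || any(rates <= -1)) {
    stop("forward rates must be finite and > -1", call. = FALSE)
  }
  if (is.null(factors)) factors <- cumprod(1 / (1 + rates))
  structure(list(rates = rates, factors = factors, T = T),
            class = "rate_schedule")
}

#' @export
print.rate_schedule <- function(x, ...) {
  cat(sprintf("<rate_schedule> T = %d periods\n", x$T))
  print(tibble::tibble(t = seq_len(x$T), rate = x$rates, factor = x$factors))
  invisible(x)
}

#' Ramsey social discount rate for consumption
#'
#' `r_c = delta + eta * g_c`: pure time preference plus a wealth effect that
#' down-weights consumption accruing to (richer) future beneficiaries.
#'
#' @param delta Pure time preference rate, >= 0.
#' @param eta Inequality-aversion / wealth-effect weight, > 0.
#' @param g_c Expected real consumption growth per period.
#' @return The consumption discount rate.
#' @examples
#' ramsey_rate(0, 1, 0.03) # conservative scenario: r_c = g_c
#' ramsey_rate(0, 2, 0.03) # alternative scenario: r_c = 2 g_c
#' @export
ramsey_rate <- function(delta, eta, g_c) {
  if (!is.finite(delta) || delta < 0) stop("`delta` must be >= 0", call. = FALSE)
  if (!is.finite(eta) || eta <= 0) stop("`eta` must be > 0", call. = FALSE)
  delta + eta * g_c
}

#' Social time preference rate for health
#'
#' Revealed time preference for health based on the rate at which the
#' principal can borrow or save and expected growth in the health
#' opportunity-cost threshold: `r_h = r_s - gk_h` (approximate) or
#' `(1 + r_s)/(1 + gk_h) - 1` (exact).
#'
#' @param r_s Principal's real borrowing/saving rate.
#' @param gk_h Expected growth rate of the threshold, > -1.
#' @param convention Compounding convention.
#' @return The health discount rate.
#' @export
health_rate <- function(r_s, gk_h,
                        convention = c("exact_multiplicative",
                                       "approx_subtractive")) {
  convention <- match.arg(convention)
  if (!is.finite(gk_h) || gk_h <= -1) stop("`gk_h` must be > -1", call. = FALSE)
  if (!is.finite(r_s)) stop("`r_s` must be finite", call. = FALSE)
  if (convention == "approx_subtractive") r_s - gk_h
  else (1 + r_s) / (1 + gk_h) - 1
}

#' Dual (differential) discount rates
#'
#' The single constant rates that fold expected parameter growth into
#' discounting, as used when reporting ICERs or when discounting equivalent
#' health effects against a consumption-rate benchmark:
#'
#' * `icer_costs`: rate for health-care costs against health discounted at
#'   `r_h` — `r_h + gk_h` (approximate) or `(1+r_h)(1+gk_h) - 1` (exact);
#' * `consumption_health`: rate for health effects against consumption
#'   discounted at `r_c` — `r_c - gV_h` or `(1+r_c)/(1+gV_h) - 1`;
#' * `consumption_costs`: rate for health-care costs in the same framing —
#'   `r_c - gV_h + gk_h` or `(1+r_c)(1+gk_h)/(1+gV_h) - 1`.
#'
#' Dual discounting embeds parameter growth in the discount rate; the
#' extensive tables, which account for that growth explicitly, are the
#' recommended primary output.
#'
#' @param base_rate `r_h` for `icer_costs`, `r_c` for the consumption modes.
#' @param gk_h Growth rate of the health opportunity-cost threshold.
#' @param gV_h Growth rate of the consumption value of health.
#' @param mode One of `"icer_costs"`, `"consumption_health"`,
#'   `"consumption_costs"`.
#' @param convention Compounding convention.
#' @return The dual discount rate.
#' @export
dual_cost_rate <- function(base_rate, gk_h = 0, gV_h = 0,
                           mode = c("icer_costs", "consumption_health",
                                    "consumption_costs"),
                           convention = c("exact_multiplicative",
                                          "approx_subtractive")) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  if (any(!is.finite(c(base_rate, gk_h, gV_h))) || gk_h <= -1 || gV_h <= -1) {
    stop("rates must be finite with growth rates > -1", call. = FALSE)
  }
  if (convention == "approx_subtractive") {
    switch(mode,
      icer_costs = base_rate + gk_h,
      consumption_health = base_rate - gV_h,
      consumption_costs = base_rate - gV_h + gk_h
    )
  } else {
    switch(mode,
      icer_costs = (1 + base_rate) * (1 + gk_h) - 1,
      consumption_health = (1 + base_rate) / (1 + gV_h) - 1,
      consumption_costs = (1 + base_rate) * (1 + gk_h) / (1 + gV_h) - 1
    )
  }
}

#' Dual discount schedule anchored at the period-1 parameter base
#'
#' Builds the per-period schedule implied by a dual rate. Parameter paths
#' have their base value in period 1 (`x[t] = x[1](1+g)^(t-1)`), so under the
#' exact convention the growth adjustment applies from period 2 onward:
#' `D[t] = (1+base)^(-t) * (1+gV_h)^(t-1) / (1+gk_h)^(t-1)` (per mode). This
#' anchoring makes discounting a parameter-scaled series at the base rate
#' identical to discounting the unscaled series under the dual schedule times
#' the period-1 parameter — and hence makes the ICER comparison against the
#' period-1 threshold an exact restatement of the net-health decision. Under
#' the approximate convention the flat printed dual rate applies from
#' period 1.
#'
#' @inheritParams dual_cost_rate
#' @param T Horizon in periods.
#' @return A [rate_schedule()].
#' @export
dual_schedule <- function(base_rate, T, gk_h = 0, gV_h = 0,
                          mode = c("icer_costs", "consumption_health",
                                   "consumption_costs"),
                          convention = c("exact_multiplicative",
                                         "approx_subtractive")) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  if (convention == "approx_subtractive") {
    return(rate_schedule(dual_cost_rate(base_rate, gk_h, gV_h, mode,
                                        convention), T = T))
  }
  step <- dual_cost_rate(base_rate, gk_h, gV_h, mode, convention)
  rates <- c(base_rate, rep(step, T - 1L))[seq_len(T)]
  adj <- switch(mode,
    icer_costs = 1 / (1 + gk_h),
    consumption_health = (1 + gV_h),
    consumption_costs = (1 + gV_h) / (1 + gk_h)
  )
  t_ <- seq_len(T)
  factors <- (1 + base_rate)^(-t_) * adj^(t_ - 1)
  rate_schedule(rates, T = T, factors = factors)
}

#' Declining term structure from growth scenarios
#'
#' Persistent uncertainty about consumption growth induces a precautionary,
#' horizon-declining consumption discount rate. Each growth scenario `g_i`
#' (probability `p_i`) implies a Ramsey rate `r_i = delta + eta * g_i`; the
#' certainty-equivalent discount factor at term `t` is
#' `F(t) = sum_i p_i (1 + r_i)^(-t)` and the annualised term rate is
#' `R(t) = F(t)^(-1/t) - 1`. `R(t)` declines with `t` towards the lowest
#' scenario rate.
#'
#' @param scenarios Data frame with columns `g` and `p` (probabilities > 0
#'   summing to 1).
#' @param delta Pure time preference rate.
#' @param eta Wealth-effect weight.
#' @param T Horizon in periods.
#' @return A [rate_schedule()] whose factors are `F(t)`, with the annualised
#'   term rates available as `attr(, "term_rates")` and the scenario rates as
#'   `attr(, "scenario_rates")`.
#' @export
declining_schedule <- function(scenarios, delta = 0, eta = 1, T) {
  scenarios <- as.data.frame(scenarios)
  if (!all(c("g", "p") %in% names(scenarios)) || nrow(scenarios) < 1L) {
    stop("`scenarios` needs columns `g` and `p` and >= 1 row", call. = FALSE)
  }
  if (any(scenarios$p <= 0) || abs(sum(scenarios$p) - 1) > 1e-8) {
    stop("scenario probabilities must be > 0 and sum to 1", call. = FALSE)
  }
  r_i <- vapply(scenarios$g, function(g) ramsey_rate(delta, eta, g),
                numeric(1))
  t_ <- seq_len(T)
  F_t <- vapply(t_, function(t) sum(scenarios$p * (1 + r_i)^(-t)), numeric(1))
  fwd <- c(1, F_t[-T]) / F_t - 1
  sched <- rate_schedule(fwd, T = T, factors = F_t)
  attr(sched, "term_rates") <- F_t^(-1 / t_) - 1
  attr(sched, "scenario_rates") <- r_i
  sched
}

#' Annualised term rates of a schedule
#'
#' `R(t) = D(t)^(-1/t) - 1`, the constant rate that reproduces the cumulative
#' discount factor at term `t`.
#'
#' @param schedule A [rate_schedule()].
#' @return Numeric vector of length `T`.
#' @export
term_rates <- function(schedule) {
  stopifnot(inherits(schedule, "rate_schedule"))
  schedule$factors^(-1 / seq_len(schedule$T)) - 1
}

#' Overlay a catastrophic hazard on a schedule
#'
#' A per-period probability `p_cat` of a truly catastrophic event, after
#' which no project effects are received, multiplies each discount factor by
#' the survival probability `(1 - p_cat)^t`; equivalently each forward rate
#' becomes `(1 + r[t])/(1 - p_cat) - 1`. Only non-recoverable events belong
#' here (at most 0.1% per period); recoverable shocks belong in macro or
#' project-specific risk.
#'
#' @param schedule A [rate_schedule()].
#' @param p_cat Per-period hazard in [0, 1).
#' @return The adjusted [rate_schedule()].
#' @export
apply_catastrophic_hazard <- function(schedule, p_cat) {
  stopifnot(inherits(schedule, "rate_schedule"))
  if (!is.finite(p_cat) || p_cat < 0 || p_cat >= 1) {
    stop("`p_cat` must lie in [0, 1)", call. = FALSE)
  }
  if (p_cat == 0) return(schedule)
  rates <- (1 + schedule$rates) / (1 - p_cat) - 1
  factors <- schedule$factors * (1 - p_cat)^seq_len(schedule$T)
  rate_schedule(rates, T = schedule$T, factors = factors)
}

#' Apply an additive project risk premium
#'
#' Projects whose payoffs are correlated with realised consumption growth
#' carry a signed additive premium on every forward rate: positive for
#' procyclical projects (payoffs shrink in downturns), negative for
#' countercyclical ones (insurance value raises the present value).
#'
#' @param schedule A [rate_schedule()].
#' @param beta_premium Signed additive premium; every adjusted forward rate
#'   must remain > -1.
#' @return The adjusted [rate_schedule()].
#' @export
risk_adjusted_schedule <- function(schedule, beta_premium) {
  stopifnot(inherits(schedule, "rate_schedule"))
  if (!is.finite(beta_premium)) {
    stop("`beta_premium` must be finite", call. = FALSE)
  }
  if (beta_premium == 0) return(schedule)
  rates <- schedule$rates + beta_premium
  if (any(rates <= -1)) {
    stop("risk adjustment drives a forward rate below -100%", call. = FALSE)
  }
  rate_schedule(rates, T = schedule$T)
}

#' Consumption discount schedule implied by a discounting specification
#'
#' Builds the schedule for equivalent-consumption streams: a flat Ramsey rate
#' for a point growth assessment, or the certainty-equivalent declining
#' schedule for a growth scenario set; then overlays the catastrophic hazard
#' and the project risk premium if present. A point-growth schedule beyond 30
#' periods triggers an advisory that growth uncertainty (a scenario set, and
#' hence declining rates) should be considered.
#'
#' @param discount A [discount_spec()].
#' @param T Horizon in periods.
#' @return A [rate_schedule()].
#' @export
consumption_schedule <- function(discount, T) {
  stopifnot(inherits(discount, "discount_spec"))
  if (!is.null(discount$scenarios)) {
    sched <- declining_schedule(discount$scenarios, discount$delta,
                                discount$eta, T)
  } else {
    if (is.null(discount$g_c)) {
      stop("discount spec has neither a point g_c nor a scenario set",
           call. = FALSE)
    }
    if (T > 30L) {
      warning("horizon exceeds 30 periods with a point growth assessment; ",
              "consider a growth scenario set (declining term structure) ",
              "to reflect persistent growth uncertainty", call. = FALSE)
    }
    sched <- rate_schedule(ramsey_rate(discount$delta, discount$eta,
                                       discount$g_c), T = T)
  }
  sched <- apply_catastrophic_hazard(sched, discount$p_cat)
  risk_adjusted_schedule(sched, discount$beta_premium)
}
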