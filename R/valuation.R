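# Present values, decision statistics, country and global NPVs.

#' Present value of a per-period series under a schedule
#'
#' `sum_t series[t] * D[t]`, with `D` the schedule's cumulative discount
#' factors (end-of-period accrual).
#'
#' @param series Numeric vector, one value per period.
#' @param schedule A [rate_schedule()] of matching horizon.
#' @return A scalar present value.
#' @examples
#' present_value(c(100, 100), rate_schedule(0, T = 2)) # 200
#' @export
present_value <- function(series, schedule) {
  stopifnot(inherits(schedule, "rate_schedule"))
  if (length(series) != schedule$T) {
    stop(sprintf("series length %d does not match schedule horizon %d",
                 length(series), schedule$T), call. = FALSE)
  }
  sum(series * schedule$factors)
}

# multiply factors by (num/den)^(t-1): converts a consumption schedule into
# the matched schedule for a numeraire whose parameter grows geometrically
# from its period-1 base.
adjust_schedule_growth <- function(schedule, num = 1, den = 1) {
  if (num == 1 && den == 1) return(schedule)
  t_ <- seq_len(schedule$T)
  factors <- schedule$factors * (num / den)^(t_ - 1)
  rates <- c(1, factors[-schedule$T]) / factors - 1
  rate_schedule(rates, T = schedule$T, factors = factors)
}

#' Adopt/reject decision from discounted net health benefit
#'
#' Discounts the per-period net health benefit (health gained minus health
#' displaced by health-care costs) at the health time-preference schedule and
#' reads the verdict off its sign. No numerical indifference band is applied:
#' the verdict is `"indifferent"` only at an exact zero.
#'
#' @param stream An [effect_stream()].
#' @param params A [parameter_path()] of matching length.
#' @param schedule A [rate_schedule()] for the health numeraire (rate `r_h`).
#' @return A list with `verdict` (`"adopt"`, `"reject"` or `"indifferent"`)
#'   and `pv_net_health`.
#' @export
decision_net_health <- function(stream, params, schedule) {
  pv <- present_value(net_health_benefit(stream, params), schedule)
  verdict <- if (pv > 0) "adopt" else if (pv < 0) "reject" else "indifferent"
  list(verdict = verdict, pv_net_health = pv)
}

#' ICER with dual discounting and threshold comparison
#'
#' Reports the incremental cost-effectiveness ratio with health effects
#' discounted at the health rate `r_h` and health-care costs at the dual rate
#' that folds in expected threshold growth, then compares the ratio against
#' the period-1 threshold `k_h1`. Under the exact convention the dual
#' schedule is anchored at the period-1 base (see [dual_schedule()]), so for
#' geometric threshold paths the verdict is an exact restatement of
#' [decision_net_health()]. When the discounted health effect is negative the
#' ratio is labelled with its cost-effectiveness-plane quadrant rather than
#' read as a bare ratio. ICERs are reported alongside — never instead of —
#' the extensive tables.
#'
#' @inheritParams decision_net_health
#' @param discount A [discount_spec()] supplying `r_s` and the convention.
#' @param growth A [growth_spec()] supplying `gk_h`.
#' @return A list with `icer`, `pv_health`, `pv_cost`, `k_h1`, `quadrant`,
#'   `verdict` and the rates used.
#' @export
icer_dual <- function(stream, params, discount, growth = growth_spec()) {
  stopifnot(inherits(discount, "discount_spec"), inherits(growth, "growth_spec"))
  if (is.null(discount$r_s)) {
    stop("ICER reporting needs the principal's rate `r_s` in the discount spec",
         call. = FALSE)
  }
  validate_stream(stream)
  check_lengths(stream, params)
  conv <- discount$convention
  r_h <- health_rate(discount$r_s, growth$gk_h, conv)
  h_sched <- rate_schedule(r_h, T = stream$T)
  c_sched <- dual_schedule(r_h, T = stream$T, gk_h = growth$gk_h,
                           mode = "icer_costs", convention = conv)
  pv_h <- present_value(stream$delta_h, h_sched)
  pv_c <- present_value(stream$delta_c_h, c_sched)
  if (pv_h == 0) {
    stop("discounted health effect is zero: the ICER is undefined; report ",
         "net benefits (extensive tables) instead", call. = FALSE)
  }
  k_h1 <- params$k_h[1L]
  quadrant <- if (pv_h > 0 && pv_c >= 0) {
    "NE (more effective, more costly)"
  } else if (pv_h > 0) {
    "SE (more effective, cost saving: dominant)"
  } else if (pv_c >= 0) {
    "NW (less effective, more costly: dominated)"
  } else {
    "SW (less effective, cost saving)"
  }
  nb <- pv_h - pv_c / k_h1
  verdict <- if (nb > 0) "adopt" else if (nb < 0) "reject" else "indifferent"
  list(
    icer = pv_c / pv_h, pv_health = pv_h, pv_cost = pv_c, k_h1 = k_h1,
    quadrant = quadrant, verdict = verdict,
    r_h = r_h,
    r_cost = dual_cost_rate(r_h, gk_h = growth$gk_h, mode = "icer_costs",
                            convention = conv),
    convention = conv
  )
}

#' Country-specific appraisal and net present value
#'
#' The full appraisal of one country's effect stream: the extensive
#' period-by-period table, present values in each numeraire under its
#' matched schedule, the net-health decision and dual-rate ICER where the
#' principal's rate is available, and the country NPV — the sum of the
#' discounted equivalent-consumption effects under the country's consumption
#' schedule.
#'
#' @param stream An [effect_stream()].
#' @param context A [country_context()] for the same country.
#' @return An object of class `appraisal_result` with fields `npv`, `table`
#'   (the [extensive_table()]), `pv` (per-numeraire present values),
#'   `decision`, `icer` (or `NULL`), `schedule`, `convention`, `currency`
#'   and parameter provenance metadata.
#' @examples
#' s <- effect_stream("A", delta_h = 10, delta_c_h = 5000, delta_c_c = 200)
#' ctx <- country_context("A", k_h1 = 1000, V_h1 = 3000,
#'                        growth = growth_spec(g_c = 0.03),
#'                        discount = discount_spec(eta = 1))
#' npv_country(s, ctx)
#' @export
npv_country <- function(stream, context) {
  stopifnot(inherits(context, "country_context"))
  validate_stream(stream)
  T_ <- stream$T
  params <- context_parameters(context, T_)
  tbl <- extensive_table(stream, params)
  cons_sched <- consumption_schedule(context$discount, T_)
  npv <- present_value(tbl$eq_consumption, cons_sched)

  conv <- context$discount$convention
  growth_known <- is.null(context$parameters)
  pv <- list(consumption = npv, health = NA_real_, resource = NA_real_)
  if (growth_known) {
    g <- context$growth
    if (conv == "approx_subtractive" && !is.null(context$discount$g_c) &&
        is.null(context$discount$scenarios)) {
      r_c <- ramsey_rate(context$discount$delta, context$discount$eta,
                         context$discount$g_c)
      h_sched <- rate_schedule(dual_cost_rate(r_c, gV_h = g$gV_h,
                                              mode = "consumption_health",
                                              convention = conv), T = T_)
      x_sched <- rate_schedule(dual_cost_rate(r_c, gk_h = g$gk_h, gV_h = g$gV_h,
                                              mode = "consumption_costs",
                                              convention = conv), T = T_)
    } else {
      h_sched <- adjust_schedule_growth(cons_sched, num = 1 + g$gV_h)
      x_sched <- adjust_schedule_growth(cons_sched, num = 1 + g$gV_h,
                                        den = 1 + g$gk_h)
    }
    pv$health <- present_value(tbl$eq_health, h_sched)
    pv$resource <- present_value(tbl$eq_resource, x_sched)
  }

  decision <- NULL
  icer <- NULL
  if (!is.null(context$discount$r_s) && growth_known) {
    r_h <- health_rate(context$discount$r_s, context$growth$gk_h, conv)
    rh_sched <- rate_schedule(r_h, T = T_)
    decision <- decision_net_health(stream, params, rh_sched)
    pv$net_health <- decision$pv_net_health
    rs_sched <- rate_schedule(context$discount$r_s, T = T_)
    pv$resource_benefit <- present_value(tbl$resource_benefit, rs_sched)
    pv$resource_cost <- present_value(tbl$resource_cost, rs_sched)
    icer <- tryCatch(
      icer_dual(stream, params, context$discount, context$growth),
      error = function(e) NULL
    )
  }

  structure(
    list(
      country_id = stream$country_id, npv = npv, table = tbl, pv = pv,
      decision = decision, icer = icer, schedule = cons_sched,
      convention = conv, currency = context$currency,
      parameters = list(
        k_h1 = params$k_h[1L], k_c1 = params$k_c[1L], V_h1 = params$V_h[1L],
        growth = if (growth_known) unclass(context$growth) else NULL,
        discount = unclass(context$discount)
      ),
      accrual = "end-of-period"
    ),
    class = "appraisal_result"
  )
}

#' @export
print.appraisal_result <- function(x, ...) {
  cat(sprintf("<appraisal_result> country %s (%s, %s discounting)\n",
              x$country_id, x$currency, x$convention))
  cat(sprintf("  NPV (consumption numeraire): %.6g %s\n", x$npv, x$currency))
  if (!is.na(x$pv$health)) {
    cat(sprintf("  PV equivalent health: %.6g; PV equivalent resources: %.6g\n",
                x$pv$health, x$pv$resource))
  }
  if (!is.null(x$decision)) {
    cat(sprintf("  net-health decision: %s (PV net health %.6g)\n",
                x$decision$verdict, x$decision$pv_net_health))
  }
  if (!is.null(x$icer)) {
    cat(sprintf("  ICER: %.6g vs k_h1 = %.6g [%s] -> %s\n",
                x$icer$icer, x$icer$k_h1, x$icer$quadrant, x$icer$verdict))
  }
  cat(sprintf("  (extensive table: %d periods; effects accrue %s)\n",
              nrow(x$table), x$accrual))
  invisible(x)
}

#' Global net present value across countries
#'
#' Country effects are converted to equivalent consumption and discounted at
#' each country's own consumption rate; the global NPV is the unweighted sum
#' of the country-specific NPVs — not the sum of effects discounted at a
#' common rate. All countries must share one declared currency label; mixed
#' labels are refused (no exchange-rate conversion is performed).
#'
#' @param project A [project()].
#' @param contexts A list of [country_context()] objects (named by country
#'   id, or carrying their own ids).
#' @return An object of class `global_npv`: a list with `global` (the scalar
#'   sum), `by_country` (a tibble of country NPVs), `results` (the full
#'   [npv_country()] objects) and `currency`.
#' @export
npv_global <- function(project, contexts) {
  stopifnot(inherits(project, "project"))
  if (inherits(contexts, "country_context")) contexts <- list(contexts)
  ids <- vapply(contexts, function(cx) cx$id, character(1))
  names(contexts) <- ids
  missing <- setdiff(names(project), ids)
  if (length(missing) > 0) {
    stop("no country context for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  currencies <- unique(vapply(contexts[names(project)],
                              function(cx) cx$currency, character(1)))
  if (length(currencies) > 1) {
    stop("cannot sum NPVs across currencies: ",
         paste(currencies, collapse = ", "),
         "; declare a common currency label", call. = FALSE)
  }
  results <- lapply(names(project), function(id) {
    npv_country(project[[id]], contexts[[id]])
  })
  names(results) <- names(project)
  npvs <- vapply(results, function(r) r$npv, numeric(1))
  structure(
    list(
      global = sum(npvs),
      by_country = tibble::tibble(country = names(npvs), npv = unname(npvs)),
      results = results,
      currency = currencies
    ),
    class = "global_npv"
  )
}

#' @export
print.global_npv <- function(x, ...) {
  cat(sprintf("<global_npv> %d countries, currency %s\n",
              nrow(x$by_country), x$currency))
  print(x$by_country)
  cat(sprintf("Global net present value: %.6g %s\n", x$global, x$currency))
  invisible(x)
}
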