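# Period-by-period column algebra: project effects expressed as net health,
# equivalent health-care resources and equivalent consumption.

check_lengths <- function(stream, params) {
  if (params$T != stream$T) {
    stop(sprintf("parameter path length %d does not match stream horizon %d",
                 params$T, stream$T), call. = FALSE)
  }
}

#' Health opportunity loss of health-care expenditure
#'
#' The health forgone elsewhere when health-care expenditure is displaced:
#' each period's incremental cost divided by that period's opportunity-cost
#' threshold, `delta_c_h[t] / k_h[t]`. A cost saving (negative cost) yields a
#' health gain (negative loss).
#'
#' @param delta_c_h Per-period incremental health-care costs.
#' @param k_h Per-period health opportunity-cost thresholds, all > 0.
#' @return Numeric vector in health units.
#' @export
health_opportunity_loss <- function(delta_c_h, k_h) {
  if (any(!is.finite(k_h)) || any(k_h <= 0)) {
    stop("k_h must be finite and > 0 in every period: health opportunity ",
         "cost must be finite and positive", call. = FALSE)
  }
  if (length(delta_c_h) != length(k_h)) {
    stop("delta_c_h and k_h must have equal length", call. = FALSE)
  }
  delta_c_h / k_h
}

#' Net health benefit per period
#'
#' Health gained net of the health displaced by the project's health-care
#' costs: `delta_h[t] - delta_c_h[t] / k_h[t]`.
#'
#' @param stream An [effect_stream()].
#' @param params A [parameter_path()] of matching length.
#' @return Numeric vector in health units.
#' @export
net_health_benefit <- function(stream, params) {
  validate_stream(stream)
  check_lengths(stream, params)
  stream$delta_h - health_opportunity_loss(stream$delta_c_h, params$k_h)
}

#' Net consumption cost per period
#'
#' Consumption costs plus the consumption (net production) displaced by the
#' project's health-care costs: `delta_c_c[t] + k_c[t] * delta_c_h[t]`.
#'
#' @inheritParams net_health_benefit
#' @return Numeric vector in currency units (positive = cost).
#' @export
net_consumption_cost <- function(stream, params) {
  validate_stream(stream)
  check_lengths(stream, params)
  if (any(params$k_c < 0)) stop("k_c must be >= 0", call. = FALSE)
  stream$delta_c_c + params$k_c * stream$delta_c_h
}

#' Health effects as equivalent health-care resources
#'
#' Values health benefits as the health-care expenditure that would have been
#' required to deliver them (`k_h[t] * delta_h[t]`); costs stay in resource
#' units unchanged.
#'
#' @inheritParams net_health_benefit
#' @return A list with numeric vectors `benefit` (`k_h * delta_h`) and `cost`
#'   (`delta_c_h`).
#' @export
equivalent_resources <- function(stream, params) {
  validate_stream(stream)
  check_lengths(stream, params)
  if (any(params$k_h <= 0)) stop("k_h must be > 0", call. = FALSE)
  list(benefit = params$k_h * stream$delta_h, cost = stream$delta_c_h)
}

#' Consumption value of health gained and health displaced
#'
#' Values the health benefits (`V_h[t] * delta_h[t]`) and the health
#' opportunity losses (`V_h[t] * delta_c_h[t] / k_h[t]`) at the consumption
#' value of health.
#'
#' @inheritParams net_health_benefit
#' @return A list with numeric vectors `benefit` and `cost` in currency units.
#' @export
consumption_value_columns <- function(stream, params) {
  validate_stream(stream)
  check_lengths(stream, params)
  if (any(params$V_h <= 0)) stop("V_h must be > 0", call. = FALSE)
  list(
    benefit = params$V_h * stream$delta_h,
    cost = params$V_h * health_opportunity_loss(stream$delta_c_h, params$k_h)
  )
}

#' Net project effect in the consumption numeraire
#'
#' Values the net health benefit at the consumption value of health and
#' subtracts the net consumption cost:
#' `V_h * (delta_h - delta_c_h / k_h) - (delta_c_c + k_c * delta_c_h)`.
#' Positive values are net consumption-equivalent benefits.
#'
#' @inheritParams net_health_benefit
#' @return Numeric vector in currency units.
#' @export
equivalent_consumption_effect <- function(stream, params) {
  params$V_h * net_health_benefit(stream, params) -
    net_consumption_cost(stream, params)
}

#' Net project effect in the health numeraire
#'
#' The net health benefit minus the net consumption cost converted into
#' health units at the consumption value of health; equals
#' [equivalent_consumption_effect()] divided by `V_h`, period by period.
#'
#' @inheritParams net_health_benefit
#' @return Numeric vector in health units.
#' @export
equivalent_health_effect <- function(stream, params) {
  net_health_benefit(stream, params) -
    net_consumption_cost(stream, params) / params$V_h
}

#' Net project effect in the health-care-resource numeraire
#'
#' The equivalent health effect revalued as the health-care expenditure that
#' would deliver it: `k_h[t] * equivalent_health_effect[t]`.
#'
#' @inheritParams net_health_benefit
#' @return Numeric vector in currency (health-care resource) units.
#' @export
equivalent_resource_effect <- function(stream, params) {
  params$k_h * equivalent_health_effect(stream, params)
}

#' Shadow price expenditure in another constrained public sector
#'
#' Converts displaced expenditure in another constrained public sector `x`
#' into consumption units using the sector's value-to-opportunity-cost ratio
#' `V_x/k_x`. Absent sector-specific estimates, resource allocation across
#' sectors under an overall public-expenditure constraint is expected to
#' equalise this ratio, so `V_h/k_h` is the default shadow price.
#'
#' @param delta_c_x Per-period incremental sector-x expenditure.
#' @param ratio Per-period `V_x/k_x` ratio (> 0); if `NULL`, computed as
#'   `V_h / k_h` from `params`.
#' @param params Optional [parameter_path()] used for the default ratio.
#' @return Numeric vector: consumption value of the displaced expenditure.
#' @export
shadow_price_other_sector <- function(delta_c_x, ratio = NULL, params = NULL) {
  if (is.null(ratio)) {
    if (is.null(params)) {
      stop("supply `ratio` or `params` (for the default V_h/k_h)",
           call. = FALSE)
    }
    ratio <- params$V_h / params$k_h
  }
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("shadow-price ratio must be finite and > 0", call. = FALSE)
  }
  if (length(ratio) == 1L) ratio <- rep(ratio, length(delta_c_x))
  if (length(ratio) != length(delta_c_x)) {
    stop("ratio and delta_c_x must have equal length", call. = FALSE)
  }
  ratio * delta_c_x
}

#' Extensive period-by-period accounting table
#'
#' The recommended primary output of an appraisal: every effect of the
#' project, period by period, alongside its representation in each numeraire
#' — health gained and health displaced, net health benefit, equivalent
#' health-care resources, consumption values of health gained/displaced, net
#' consumption cost, and the net effect expressed in the consumption, health
#' and resource numeraires. Every derived column can be recomputed from the
#' raw input columns it sits next to.
#'
#' @inheritParams net_health_benefit
#' @return A tibble of class `extensive_table`, one row per period.
#' @export
extensive_table <- function(stream, params) {
  validate_stream(stream)
  check_lengths(stream, params)
  res <- equivalent_resources(stream, params)
  cv <- consumption_value_columns(stream, params)
  tbl <- tibble::tibble(
    t = seq_len(stream$T),
    delta_h = stream$delta_h,
    delta_c_h = stream$delta_c_h,
    delta_c_c = stream$delta_c_c,
    k_h = params$k_h,
    k_c = params$k_c,
    V_h = params$V_h,
    health_gained = stream$delta_h,
    health_loss = health_opportunity_loss(stream$delta_c_h, params$k_h),
    net_health_benefit = net_health_benefit(stream, params),
    resource_benefit = res$benefit,
    resource_cost = res$cost,
    consumption_value_gained = cv$benefit,
    consumption_value_lost = cv$cost,
    net_consumption_cost = net_consumption_cost(stream, params),
    eq_consumption = equivalent_consumption_effect(stream, params),
    eq_health = equivalent_health_effect(stream, params),
    eq_resource = equivalent_resource_effect(stream, params)
  )
  class(tbl) <- c("extensive_table", class(tbl))
  tbl
}
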