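# Domain types for per-period project effect streams and parameter paths.
# Periods are 1-based: t = 1 is the first period after the decision, and all
# effects accrue at the end of their period.

#' Per-period effect stream for one country
#'
#' Bundles the three time streams a project appraisal needs for one country:
#' incremental health effects (QALYs gained or DALYs averted), incremental
#' health-care costs and incremental consumption costs, all in real units.
#'
#' @param country_id Character scalar identifying the country/jurisdiction.
#' @param delta_h Numeric vector of per-period incremental health effects.
#'   Positive values are health improvements for both metrics.
#' @param delta_c_h Numeric vector of per-period incremental health-care costs
#'   (real currency units; positive = cost).
#' @param delta_c_c Numeric vector of per-period incremental consumption costs
#'   (real currency units; negative values are consumption benefits). A scalar
#'   is recycled to the horizon.
#' @param health_metric Either `"QALY_gained"` or `"DALY_averted"`; recorded as
#'   metadata only, both are sign-equivalent health improvements.
#'
#' @return An object of class `effect_stream` with fields `country_id`, `T`
#'   (horizon in periods), `delta_h`, `delta_c_h`, `delta_c_c` and
#'   `health_metric`.
#' @examples
#' effect_stream("A", delta_h = c(2, 3), delta_c_h = c(100, 100))
#' @export
effect_stream <- function(country_id, delta_h, delta_c_h,
                          delta_c_c = 0,
                          health_metric = c("QALY_gained", "DALY_averted")) {
  health_metric <- match.arg(health_metric)
  T_ <- length(delta_h)
  if (length(delta_c_c) == 1L) delta_c_c <- rep(as.numeric(delta_c_c), T_)
  if (length(delta_c_h) == 1L && T_ > 1L) {
    delta_c_h <- rep(as.numeric(delta_c_h), T_)
  }
  stream <- structure(
    list(
      country_id = as.character(country_id)[1L],
      T = T_,
      delta_h = as.numeric(delta_h),
      delta_c_h = as.numeric(delta_c_h),
      delta_c_c = as.numeric(delta_c_c),
      health_metric = health_metric
    ),
    class = "effect_stream"
  )
  validate_stream(stream)
}

#' Validate an effect stream
#'
#' Checks that the three series share the stated horizon, that all values are
#' finite, and that the horizon is at least one period. All violations are
#' reported at once, each naming the offending series and period.
#'
#' @param stream An [effect_stream()].
#' @return The stream, invisibly unchanged, if valid; otherwise an error
#'   listing every violation.
#' @export
validate_stream <- function(stream) {
  if (!inherits(stream, "effect_stream")) {
    stop("`stream` must be an effect_stream", call. = FALSE)
  }
  problems <- character(0)
  T_ <- stream$T
  if (!is.numeric(T_) || length(T_) != 1L || is.na(T_) || T_ < 1L) {
    problems <- c(problems, "horizon T must be an integer >= 1")
  }
  for (nm in c("delta_h", "delta_c_h", "delta_c_c")) {
    x <- stream[[nm]]
    if (length(x) != T_) {
      problems <- c(problems, sprintf(
        "length mismatch: %s has length %d, expected T = %d",
        nm, length(x), T_
      ))
    }
    bad <- which(!is.finite(x))
    if (length(bad) > 0) {
      problems <- c(problems, sprintf(
        "non-finite value in %s at period %s", nm,
        paste(bad, collapse = ", ")
      ))
    }
  }
  if (length(problems) > 0) {
    stop("invalid effect stream:\n  - ",
         paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  stream
}

#' @export
print.effect_stream <- function(x, ...) {
  cat(sprintf("<effect_stream> country %s, T = %d periods (%s)\n",
              x$country_id, x$T, x$health_metric))
  print(tibble::tibble(
    t = seq_len(x$T), delta_h = x$delta_h,
    delta_c_h = x$delta_c_h, delta_c_c = x$delta_c_c
  ))
  invisible(x)
}

#' Geometric parameter path from a base value and growth rate
#'
#' Realises a "base plus growth" parameter specification as an explicit
#' per-period path: `v[t] = base * (1 + g)^(t - 1)`, so the value in period 1
#' equals the stated base.
#'
#' @param base Positive starting value (period 1).
#' @param g Per-period real growth rate, greater than -1.
#' @param T Integer horizon, at least 1.
#' @return Numeric vector of length `T`.
#' @examples
#' path_from_growth(100, 0.02, 3) # 100, 102, 104.04
#' @export
path_from_growth <- function(base, g, T) {
  if (!is.numeric(base) || length(base) != 1L || !is.finite(base) || base <= 0) {
    stop("`base` must be a single positive finite number", call. = FALSE)
  }
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= -1) {
    stop("`g` must be a single finite growth rate > -1", call. = FALSE)
  }
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T < 1) {
    stop("`T` must be an integer >= 1", call. = FALSE)
  }
  base * (1 + g)^(seq_len(T) - 1)
}

#' Growth rates for the value parameters
#'
#' Collects the per-period real growth rates that drive the parameter paths:
#' consumption growth `g_c`, growth of the health opportunity-cost threshold
#' `gk_h`, and the income elasticity of demand for health, which sets the
#' growth of the consumption value of health to `elasticity_V * g_c`. The
#' consumption opportunity cost of health-care expenditure grows at `g_kc`,
#' by default at the same rate as consumption.
#'
#' @param g_c Real consumption growth rate per period.
#' @param gk_h Real growth rate of the health opportunity-cost threshold.
#' @param elasticity_V Income elasticity of demand for health (>= 0); the
#'   conservative default of 1 makes the consumption value of health grow at
#'   `g_c`, the alternative scenario uses 1.5.
#' @param g_kc Growth rate of the consumption opportunity cost per unit of
#'   health-care expenditure; defaults to `g_c`.
#' @return An object of class `growth_spec` with the above fields plus the
#'   derived `gV_h = elasticity_V * g_c`.
#' @export
growth_spec <- function(g_c = 0, gk_h = 0, elasticity_V = 1, g_kc = g_c) {
  rates <- c(g_c = g_c, gk_h = gk_h, g_kc = g_kc)
  if (any(!is.finite(rates)) || any(rates <= -1)) {
    stop("growth rates must be finite and > -1", call. = FALSE)
  }
  if (!is.finite(elasticity_V) || elasticity_V < 0) {
    stop("`elasticity_V` must be finite and >= 0", call. = FALSE)
  }
  gV_h <- elasticity_V * g_c
  if (gV_h <= -1) stop("implied V_h growth must be > -1", call. = FALSE)
  structure(
    list(g_c = g_c, gk_h = gk_h, elasticity_V = elasticity_V,
         g_kc = g_kc, gV_h = gV_h),
    class = "growth_spec"
  )
}

#' Per-period value-parameter paths
#'
#' Holds the three per-period value parameters of the appraisal: the health
#' opportunity-cost threshold `k_h` (currency per health unit), the
#' consumption opportunity cost per unit of health-care expenditure `k_c`
#' (dimensionless), and the consumption value of a health unit `V_h`
#' (currency per health unit).
#'
#' @param k_h Numeric vector of per-period thresholds, all strictly positive.
#' @param k_c Numeric vector of per-period consumption opportunity costs,
#'   all non-negative.
#' @param V_h Numeric vector of per-period consumption values of health,
#'   all strictly positive.
#' @return An object of class `parameter_path` of common length `T`.
#' @seealso [parameter_path_from_growth()] to build paths from base values
#'   and a [growth_spec()].
#' @export
parameter_path <- function(k_h, k_c, V_h) {
  lens <- c(length(k_h), length(k_c), length(V_h))
  if (length(unique(lens)) != 1L || lens[1] < 1L) {
    stop("k_h, k_c and V_h must share a common length T >= 1", call. = FALSE)
  }
  if (any(!is.finite(k_h)) || any(k_h <= 0)) {
    stop("k_h must be finite and > 0 in every period", call. = FALSE)
  }
  if (any(!is.finite(V_h)) || any(V_h <= 0)) {
    stop("V_h must be finite and > 0 in every period", call. = FALSE)
  }
  if (any(!is.finite(k_c)) || any(k_c < 0)) {
    stop("k_c must be finite and >= 0 in every period", call. = FALSE)
  }
  structure(
    list(k_h = as.numeric(k_h), k_c = as.numeric(k_c),
         V_h = as.numeric(V_h), T = lens[1]),
    class = "parameter_path"
  )
}

#' Build parameter paths from base values and growth rates
#'
#' @param k_h1 Base (period-1) health opportunity-cost threshold, > 0.
#' @param V_h1 Base consumption value of a health unit, > 0.
#' @param k_c1 Base consumption opportunity cost per unit of health-care
#'   expenditure; the conservative default is 1 (one dollar of health-care
#'   expenditure displaces one dollar of net production).
#' @param growth A [growth_spec()].
#' @param T Integer horizon.
#' @return A [parameter_path()] with `k_h` growing at `gk_h`, `V_h` at
#'   `elasticity_V * g_c` and `k_c` at `g_kc`.
#' @export
parameter_path_from_growth <- function(k_h1, V_h1, k_c1 = 1,
                                       growth = growth_spec(), T = 1) {
  stopifnot(inherits(growth, "growth_spec"))
  k_c <- if (k_c1 == 0) rep(0, T) else path_from_growth(k_c1, growth$g_kc, T)
  parameter_path(
    k_h = path_from_growth(k_h1, growth$gk_h, T),
    k_c = k_c,
    V_h = path_from_growth(V_h1, growth$gV_h, T)
  )
}

#' @export
print.parameter_path <- function(x, ...) {
  cat(sprintf("<parameter_path> T = %d periods\n", x$T))
  print(tibble::tibble(t = seq_len(x$T), k_h = x$k_h, k_c = x$k_c, V_h = x$V_h))
  invisible(x)
}

#' Multi-country project
#'
#' @param ... One or more [effect_stream()] objects (or a single list of
#'   them); country ids must be unique.
#' @return An object of class `project`: a named list of streams keyed by
#'   country id.
#' @export
project <- function(...) {
  streams <- list(...)
  if (length(streams) == 1L && !inherits(streams[[1L]], "effect_stream")) {
    streams <- streams[[1L]]
  }
  if (length(streams) < 1L) stop("a project needs >= 1 country", call. = FALSE)
  ok <- vapply(streams, inherits, logical(1), "effect_stream")
  if (!all(ok)) stop("all project components must be effect_streams", call. = FALSE)
  ids <- vapply(streams, function(s) s$country_id, character(1))
  if (anyDuplicated(ids)) {
    stop("country ids must be unique: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(streams) <- ids
  structure(streams, class = "project")
}

#' @export
print.project <- function(x, ...) {
  cat(sprintf("<project> %d countr%s: %s\n", length(x),
              if (length(x) == 1) "y" else "ies",
              paste(names(x), collapse = ", ")))
  invisible(x)
}
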