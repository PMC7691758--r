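# Discounting specifications, default parameter profiles and country contexts.

#' Named default parameter profiles
#'
#' Two scenario bundles for the judgement parameters of the framework. The
#' conservative profile uses a consumption opportunity cost of health-care
#' expenditure of 1, an income elasticity of demand for health of 1, an
#' inequality-aversion weight of 1 and zero pure time preference (so the
#' consumption discount rate equals consumption growth). The alternative
#' profile raises the income elasticity to 1.5 and the inequality-aversion
#' weight to 2. Both carry the catastrophic-hazard bound (0.1% per period)
#' and the 30-period horizon advisory threshold.
#'
#' @param name `"conservative"` or `"alternative"`.
#' @return A list with elements `k_c`, `elasticity_V`, `eta`, `delta`,
#'   `p_cat`, `p_cat_bound` and `horizon_advisory`.
#' @export
defaults_profile <- function(name = c("conservative", "alternative")) {
  name <- match.arg(name)
  base <- list(
    k_c = 1, elasticity_V = 1, eta = 1, delta = 0, p_cat = 0,
    p_cat_bound = 0.001, horizon_advisory = 30L, profile = name
  )
  if (name == "alternative") {
    base$elasticity_V <- 1.5
    base$eta <- 2
  }
  base
}

#' Discounting specification
#'
#' Collects everything needed to build discount schedules for a country: the
#' Ramsey ingredients (pure time preference `delta`, inequality-aversion
#' weight `eta`, consumption growth as a point value or a scenario set), the
#' principal's real borrowing/saving rate `r_s`, an optional per-period
#' catastrophic hazard, an optional additive project risk premium, and the
#' compounding convention.
#'
#' @param delta Pure time preference rate, >= 0 (default 0: zero pure time
#'   preference for social choices).
#' @param eta Inequality-aversion / wealth-effect weight, > 0.
#' @param g_c Point estimate of real consumption growth per period. Ignored
#'   when `scenarios` is supplied.
#' @param scenarios Optional data frame with columns `g` (growth rate) and
#'   `p` (probability, summing to 1) describing growth uncertainty; induces a
#'   declining term structure of consumption rates.
#' @param r_s Principal's real borrowing/saving rate (e.g. real yield on
#'   government bonds); required for health / resource numeraire discounting.
#' @param p_cat Per-period probability of a truly catastrophic,
#'   non-recoverable event, in [0, 1). A warning is issued above 0.001.
#' @param beta_premium Additive project risk premium (signed; negative for
#'   countercyclical projects).
#' @param convention `"exact_multiplicative"` (default; growth adjustments
#'   compound exactly so numeraire equivalences hold to machine precision) or
#'   `"approx_subtractive"` (rates combined by addition/subtraction).
#' @return An object of class `discount_spec`.
#' @export
discount_spec <- function(delta = 0, eta = 1, g_c = NULL, scenarios = NULL,
                          r_s = NULL, p_cat = 0, beta_premium = 0,
                          convention = c("exact_multiplicative",
                                         "approx_subtractive")) {
  convention <- match.arg(convention)
  if (!is.finite(delta) || delta < 0) {
    stop("`delta` must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(eta) || eta <= 0) {
    stop("`eta` must be finite and > 0", call. = FALSE)
  }
  if (!is.null(scenarios)) {
    scenarios <- as.data.frame(scenarios)
    if (!all(c("g", "p") %in% names(scenarios)) || nrow(scenarios) < 1L) {
      stop("`scenarios` needs columns `g` and `p` and >= 1 row", call. = FALSE)
    }
    if (any(scenarios$p <= 0) || abs(sum(scenarios$p) - 1) > 1e-8) {
      stop("scenario probabilities must be > 0 and sum to 1", call. = FALSE)
    }
    if (any(scenarios$g <= -1)) {
      stop("scenario growth rates must be > -1", call. = FALSE)
    }
  }
  if (!is.null(g_c) && (!is.finite(g_c) || g_c <= -1)) {
    stop("`g_c` must be finite and > -1", call. = FALSE)
  }
  if (!is.null(r_s) && !is.finite(r_s)) {
    stop("`r_s` must be finite", call. = FALSE)
  }
  if (!is.finite(p_cat) || p_cat < 0 || p_cat >= 1) {
    stop("`p_cat` must lie in [0, 1)", call. = FALSE)
  }
  if (p_cat > 0.001) {
    warning("p_cat exceeds 0.001; catastrophic hazards should reflect only ",
            "truly non-recoverable events (<= 0.1% per period)",
            call. = FALSE)
  }
  if (!is.finite(beta_premium)) {
    stop("`beta_premium` must be finite", call. = FALSE)
  }
  structure(
    list(delta = delta, eta = eta, g_c = g_c, scenarios = scenarios,
         r_s = r_s, p_cat = p_cat, beta_premium = beta_premium,
         convention = convention),
    class = "discount_spec"
  )
}

#' Country context: value parameters plus discounting policy
#'
#' Associates a country id with its value-parameter paths and its discounting
#' specification. Parameters may be given either as explicit per-period paths
#' (`parameters = parameter_path(...)`) or, the usual case, as period-1 base
#' values plus a [growth_spec()], from which paths of any horizon are built
#' on demand.
#'
#' @param id Country identifier.
#' @param k_h1,V_h1,k_c1 Base (period-1) parameter values; used when
#'   `parameters` is not supplied. `k_c1` defaults to 1.
#' @param growth A [growth_spec()]; drives the parameter paths and, when the
#'   discount spec carries no growth of its own, the Ramsey wealth effect.
#' @param discount A [discount_spec()]. If its `g_c` is `NULL` and it has no
#'   scenario set, consumption growth is taken from `growth` so a single
#'   growth assessment feeds every parameter consistently.
#' @param parameters Optional explicit [parameter_path()] (overrides the
#'   base-plus-growth construction; the path must cover any appraised
#'   horizon).
#' @param shadow_ratio_x Optional consumption value per unit of expenditure
#'   in another constrained public sector; defaults to `V_h/k_h` when shadow
#'   pricing is requested.
#' @param currency Currency label attached to this country's monetary
#'   streams; global aggregation refuses to sum mismatched labels.
#' @return An object of class `country_context`.
#' @export
country_context <- function(id, k_h1 = NULL, V_h1 = NULL, k_c1 = 1,
                            growth = growth_spec(),
                            discount = discount_spec(),
                            parameters = NULL,
                            shadow_ratio_x = NULL,
                            currency = "INT$") {
  stopifnot(inherits(growth, "growth_spec"), inherits(discount, "discount_spec"))
  if (is.null(parameters)) {
    if (is.null(k_h1) || is.null(V_h1)) {
      stop("supply either `parameters` or base values `k_h1` and `V_h1`",
           call. = FALSE)
    }
    if (!is.finite(k_h1) || k_h1 <= 0) stop("`k_h1` must be > 0", call. = FALSE)
    if (!is.finite(V_h1) || V_h1 <= 0) stop("`V_h1` must be > 0", call. = FALSE)
    if (!is.finite(k_c1) || k_c1 < 0) stop("`k_c1` must be >= 0", call. = FALSE)
  } else {
    stopifnot(inherits(parameters, "parameter_path"))
  }
  if (is.null(discount$g_c) && is.null(discount$scenarios)) {
    discount$g_c <- growth$g_c
  }
  if (!is.null(shadow_ratio_x) &&
      (any(!is.finite(shadow_ratio_x)) || any(shadow_ratio_x <= 0))) {
    stop("`shadow_ratio_x` must be finite and > 0", call. = FALSE)
  }
  structure(
    list(id = as.character(id)[1L], k_h1 = k_h1, V_h1 = V_h1, k_c1 = k_c1,
         growth = growth, discount = discount, parameters = parameters,
         shadow_ratio_x = shadow_ratio_x, currency = currency),
    class = "country_context"
  )
}

#' Materialise a context's parameter paths over a horizon
#'
#' @param context A [country_context()].
#' @param T Horizon in periods.
#' @return A [parameter_path()] of length `T`. Explicit paths are truncated
#'   to `T` and must cover it; base-plus-growth contexts are expanded.
#' @export
context_parameters <- function(context, T) {
  stopifnot(inherits(context, "country_context"))
  if (!is.null(context$parameters)) {
    p <- context$parameters
    if (p$T < T) {
      stop(sprintf("parameter path for %s covers %d periods but %d are needed",
                   context$id, p$T, T), call. = FALSE)
    }
    idx <- seq_len(T)
    return(parameter_path(p$k_h[idx], p$k_c[idx], p$V_h[idx]))
  }
  parameter_path_from_growth(context$k_h1, context$V_h1, context$k_c1,
                             context$growth, T)
}

#' @export
print.country_context <- function(x, ...) {
  cat(sprintf("<country_context> %s (currency %s)\n", x$id, x$currency))
  if (is.null(x$parameters)) {
    cat(sprintf("  bases: k_h = %g, V_h = %g, k_c = %g\n",
                x$k_h1, x$V_h1, x$k_c1))
    cat(sprintf("  growth: g_c = %g, gk_h = %g, elasticity_V = %g\n",
                x$growth$g_c, x$growth$gk_h, x$growth$elasticity_V))
  } else {
    cat(sprintf("  explicit parameter path, T = %d\n", x$parameters$T))
  }
  d <- x$discount
  g <- if (!is.null(d$scenarios)) {
    sprintf("%d growth scenarios", nrow(d$scenarios))
  } else {
    sprintf("g_c = %g", d$g_c %||% NA_real_)
  }
  cat(sprintf("  discount: delta = %g, eta = %g, %s, convention = %s\n",
              d$delta, d$eta, g, d$convention))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
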