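# Random-case generators for property-style tests. Streams span all four
# cost-effectiveness quadrants; parameters stay in realistic ranges.

rand_stream <- function(id = "X", T = sample(1:10, 1)) {
  effect_stream(
    id,
    delta_h = stats::runif(T, -5, 20),
    delta_c_h = stats::runif(T, -2000, 10000),
    delta_c_c = stats::runif(T, -1000, 2000)
  )
}

rand_growth <- function() {
  growth_spec(
    g_c = stats::runif(1, 0, 0.05),
    gk_h = stats::runif(1, 0, 0.05),
    elasticity_V = stats::runif(1, 0.5, 2),
    g_kc = stats::runif(1, 0, 0.05)
  )
}

# r_s chosen so the principal's revealed health rate is consistent with the
# Ramsey consumption rate: (1+r_s)/(1+gk_h) = (1+r_c)/(1+gV_h). Under this
# condition the health-framed and consumption-framed decisions coincide.
rand_context <- function(id = "X", convention = "exact_multiplicative",
                         consistent_r_s = TRUE) {
  g <- rand_growth()
  eta <- stats::runif(1, 1, 2)
  delta <- stats::runif(1, 0, 0.01)
  r_c <- delta + eta * g$g_c
  r_s <- if (consistent_r_s) {
    (1 + r_c) * (1 + g$gk_h) / (1 + g$gV_h) - 1
  } else {
    stats::runif(1, 0, 0.08)
  }
  country_context(
    id,
    k_h1 = stats::runif(1, 500, 5000),
    V_h1 = stats::runif(1, 1000, 20000),
    k_c1 = stats::runif(1, 0, 2),
    growth = g,
    discount = discount_spec(delta = delta, eta = eta, r_s = r_s,
                             convention = convention)
  )
}

rand_params <- function(T) {
  parameter_path(
    k_h = stats::runif(T, 500, 5000),
    k_c = stats::runif(T, 0, 2),
    V_h = stats::runif(T, 1000, 20000)
  )
}
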