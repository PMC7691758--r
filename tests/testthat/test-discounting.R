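test_that("Ramsey rule combines time preference and the wealth effect", {
  expect_equal(ramsey_rate(0, 1, 0.03), 0.03)
  expect_equal(ramsey_rate(0, 2, 0.03), 0.06)
  expect_equal(ramsey_rate(0.01, 1.5, 0.02), 0.04)
  expect_error(ramsey_rate(-0.01, 1, 0.02), ">= 0")
  expect_error(ramsey_rate(0, 0, 0.02), "> 0")
})

test_that("health rate nets threshold growth off the principal's rate", {
  expect_equal(health_rate(0.05, 0.02, "approx_subtractive"), 0.03)
  expect_equal(health_rate(0.05, 0.02, "exact_multiplicative"),
               1.05 / 1.02 - 1)
  expect_equal(health_rate(0.05, 0, "approx_subtractive"), 0.05)
  expect_equal(health_rate(0.05, 0, "exact_multiplicative"), 0.05)
  expect_error(health_rate(0.05, -1.1), "> -1")
})

test_that("dual cost rates fold parameter growth into discounting", {
  expect_equal(dual_cost_rate(0.03, gk_h = 0.02, mode = "icer_costs",
                              convention = "approx_subtractive"), 0.05)
  expect_equal(dual_cost_rate(0.03, gk_h = 0.02, mode = "icer_costs",
                              convention = "exact_multiplicative"),
               1.03 * 1.02 - 1)
  expect_equal(dual_cost_rate(0.03, gV_h = 0.03, mode = "consumption_health",
                              convention = "approx_subtractive"), 0)
  expect_equal(dual_cost_rate(0.03, gk_h = 0.01, gV_h = 0.03,
                              mode = "consumption_costs",
                              convention = "approx_subtractive"),
               0.03 - 0.03 + 0.01)
  expect_equal(dual_cost_rate(0.03, gk_h = 0.01, gV_h = 0.03,
                              mode = "consumption_costs",
                              convention = "exact_multiplicative"),
               1.03 * 1.01 / 1.03 - 1)
})

test_that("rate schedules accumulate discount factors multiplicatively", {
  sched <- rate_schedule(0.03, T = 3)
  expect_equal(sched$factors, 1.03^-(1:3))
  expect_error(rate_schedule(c(0.03, -1.5)), "> -1")
  mixed <- rate_schedule(c(0.05, 0.01))
  expect_equal(mixed$factors, c(1 / 1.05, 1 / (1.05 * 1.01)))
})

test_that("a degenerate scenario set reduces to the flat Ramsey schedule", {
  sched <- declining_schedule(data.frame(g = 0.03, p = 1), delta = 0,
                              eta = 1, T = 10)
  expect_equal(attr(sched, "term_rates"), rep(0.03, 10))
  expect_equal(sched$rates, rep(0.03, 10))
  expect_equal(sched$factors, 1.03^-(1:10))
})

test_that("growth uncertainty produces declining certainty-equivalent rates", {
  scen <- data.frame(g = c(0.01, 0.05), p = c(0.5, 0.5))
  sched <- declining_schedule(scen, delta = 0, eta = 1, T = 500)
  R <- attr(sched, "term_rates")
  F1 <- 0.5 / 1.01 + 0.5 / 1.05
  expect_equal(R[1], 1 / F1 - 1)
  expect_equal(round(R[1], 4), 0.0296)
  expect_true(all(diff(R) <= 1e-15))     # non-increasing in term
  expect_lt(R[1], 0.03)                  # below the mean rate (Jensen)
  expect_gt(R[500], 0.01)                # approaches the minimum from above
  expect_lt(R[500] - 0.01, 0.1 * (R[1] - 0.01))
})

test_that("declining-schedule properties hold for random scenario sets", {
  set.seed(201)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    p <- runif(n)
    p <- p / sum(p)
    scen <- data.frame(g = runif(n, -0.01, 0.07), p = p)
    delta <- runif(1, 0, 0.01)
    eta <- runif(1, 1, 2)
    sched <- declining_schedule(scen, delta, eta, T = 500)
    R <- attr(sched, "term_rates")
    r_i <- delta + eta * scen$g
    expect_true(all(diff(R) <= 1e-12))
    expect_lte(R[1], sum(scen$p * r_i) + 1e-12)
    expect_gte(R[500], min(r_i) - 1e-12)
  }
})

test_that("long-term rates converge towards the lowest scenario rate", {
  # two-scenario sets with balanced probabilities and a material rate
  # spread: convergence in t is O(log(1/p_min)/t), so near-degenerate
  # scenario weights or spreads close to zero converge only at terms far
  # beyond any appraisal horizon
  set.seed(203)
  for (i in 1:20) {
    g_lo <- runif(1, 0, 0.01)
    scen <- data.frame(g = c(g_lo, g_lo + runif(1, 0.035, 0.06)),
                       p = local({ p <- runif(1, 0.4, 0.6); c(p, 1 - p) }))
    eta <- runif(1, 1, 2)
    sched <- declining_schedule(scen, delta = 0, eta = eta, T = 500)
    R <- attr(sched, "term_rates")
    r_min <- eta * g_lo
    expect_gte(R[500], r_min)
    expect_lt(R[500] - r_min, 0.1 * (R[1] - r_min))
  }
})

test_that("declining schedules reject invalid scenario sets", {
  expect_error(declining_schedule(data.frame(g = numeric(0), p = numeric(0)),
                                  T = 5), ">= 1 row")
  expect_error(declining_schedule(data.frame(g = 0.02, p = 0.7), T = 5),
               "sum to 1")
  expect_error(declining_schedule(data.frame(g = c(0.02, 0.03),
                                             p = c(1.2, -0.2)), T = 5),
               "> 0 and sum to 1")
})

test_that("catastrophic hazards multiply in survival probabilities", {
  flat <- rate_schedule(0.03, T = 5)
  expect_identical(apply_catastrophic_hazard(flat, 0), flat)
  hz <- apply_catastrophic_hazard(flat, 0.001)
  expect_equal(hz$rates, rep(1.03 / 0.999 - 1, 5))
  expect_equal(hz$factors, flat$factors * 0.999^(1:5))
  zero <- apply_catastrophic_hazard(rate_schedule(0, T = 1), 0.001)
  expect_equal(zero$factors[1], 0.999)
  expect_error(apply_catastrophic_hazard(flat, 1), "\\[0, 1\\)")
})

test_that("risk premia shift every forward rate additively", {
  flat <- rate_schedule(0.03, T = 4)
  expect_identical(risk_adjusted_schedule(flat, 0), flat)
  up <- risk_adjusted_schedule(flat, 0.01)
  expect_equal(up$rates, rep(0.04, 4))
  down <- risk_adjusted_schedule(flat, -0.01)
  expect_equal(down$rates, rep(0.02, 4))
  expect_true(all(down$factors > flat$factors)) # countercyclical raises PV
  expect_error(risk_adjusted_schedule(flat, -1.5), "below -100%")
})

test_that("hazard and premium compose by their exact formulas", {
  r <- 0.03; p <- 0.001; b <- 0.01
  base <- rate_schedule(r, T = 3)
  hz_then_prem <- risk_adjusted_schedule(apply_catastrophic_hazard(base, p), b)
  prem_then_hz <- apply_catastrophic_hazard(risk_adjusted_schedule(base, b), p)
  expect_equal(hz_then_prem$rates, rep((1 + r) / (1 - p) - 1 + b, 3))
  expect_equal(prem_then_hz$rates, rep((1 + r + b) / (1 - p) - 1, 3))
})

test_that("parameter-scaled discounting is proportional to dual-rate discounting", {
  set.seed(202)
  for (i in 1:50) {
    T <- sample(1:10, 1)
    delta_h <- runif(T, -5, 20)
    r_s <- runif(1, 0, 0.08)
    gk_h <- runif(1, 0, 0.05)
    k_h1 <- runif(1, 500, 5000)
    k_path <- path_from_growth(k_h1, gk_h, T)
    lhs <- present_value(k_path * delta_h, rate_schedule(r_s, T = T))
    r_h <- health_rate(r_s, gk_h, "exact_multiplicative")
    rhs <- (k_h1 / (1 + gk_h)) *
      present_value(delta_h, rate_schedule(r_h, T = T))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("point-growth schedules beyond 30 periods trigger the advisory", {
  d <- discount_spec(g_c = 0.03)
  expect_warning(consumption_schedule(d, 31), "30 periods")
  expect_silent(consumption_schedule(d, 30))
  scen <- discount_spec(scenarios = data.frame(g = c(0.01, 0.05),
                                               p = c(0.5, 0.5)))
  expect_silent(consumption_schedule(scen, 60))
})

test_that("discount specs flag hazards above the catastrophic bound", {
  expect_warning(discount_spec(g_c = 0.03, p_cat = 0.002), "0.001")
  expect_silent(discount_spec(g_c = 0.03, p_cat = 0.001))
})

test_that("the consumption schedule layers hazard and premium over the base", {
  d <- discount_spec(eta = 2, g_c = 0.02, p_cat = 0.001, beta_premium = 0.005)
  sched <- suppressWarnings(consumption_schedule(d, 3))
  expect_equal(sched$rates, rep(1.04 / 0.999 - 1 + 0.005, 3))
})
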