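worked_context <- function(g_c = 0.03, eta = 1, delta = 0, r_s = 0.05) {
  country_context("A", k_h1 = 1000, V_h1 = 3000,
                  growth = growth_spec(g_c = g_c),
                  discount = discount_spec(delta = delta, eta = eta,
                                           r_s = r_s))
}

test_that("present value discounts end-of-period accruals", {
  expect_equal(present_value(c(100, 100), rate_schedule(0, T = 2)), 200)
  expect_equal(present_value(100, rate_schedule(0.03, T = 1)), 100 / 1.03)
  expect_equal(present_value(rep(0, 5), rate_schedule(0.07, T = 5)), 0)
  expect_error(present_value(c(1, 2), rate_schedule(0, T = 3)),
               "does not match")
})

test_that("country NPV discounts the equivalent-consumption stream", {
  s <- effect_stream("A", 10, 5000, 200)
  res <- npv_country(s, worked_context())
  expect_equal(res$npv, 9800 / 1.03)
  expect_s3_class(res$table, "extensive_table")
  expect_equal(res$table$eq_consumption, 9800)

  res0 <- npv_country(s, worked_context(g_c = 0))
  expect_equal(res0$npv, 9800)

  null <- effect_stream("A", 0, 0, 0)
  expect_equal(npv_country(null, worked_context())$npv, 0)
})

test_that("country NPV equals the sum of discounted per-period contributions", {
  set.seed(301)
  for (i in 1:20) {
    s <- rand_stream("A")
    ctx <- rand_context("A")
    res <- npv_country(s, ctx)
    sched <- consumption_schedule(ctx$discount, s$T)
    expect_equal(res$npv,
                 sum(res$table$eq_consumption * sched$factors),
                 tolerance = 1e-12)
  }
})

test_that("net-health verdicts follow the sign of the discounted benefit", {
  p <- parameter_path(1000, 1, 3000)
  sched <- rate_schedule(0.03, T = 1)
  expect_equal(decision_net_health(effect_stream("A", 10, 5000, 0), p,
                                   sched)$verdict, "adopt")
  expect_equal(decision_net_health(effect_stream("A", 10, 10000, 0), p,
                                   sched)$verdict, "indifferent")
  expect_equal(decision_net_health(effect_stream("A", 4, 5000, 0), p,
                                   sched)$verdict, "reject")
})

test_that("single-period ICERs compare against the period-1 threshold", {
  s <- effect_stream("A", 10, 5000, 0)
  d0 <- discount_spec(g_c = 0, r_s = 0)
  res <- icer_dual(s, parameter_path(1000, 1, 3000), d0)
  expect_equal(res$icer, 500)
  expect_equal(res$verdict, "adopt")
  expect_match(res$quadrant, "NE")
  res2 <- icer_dual(s, parameter_path(400, 1, 3000), d0)
  expect_equal(res2$icer, 500)
  expect_equal(res2$verdict, "reject")
})

test_that("undefined ICERs point the user to net-benefit reporting", {
  s <- effect_stream("A", 0, 5000, 0)
  expect_error(icer_dual(s, parameter_path(1000, 1, 3000),
                         discount_spec(g_c = 0, r_s = 0)),
               "net benefits")
})

test_that("dominance quadrants are labelled rather than read as bare ratios", {
  d0 <- discount_spec(g_c = 0, r_s = 0)
  p <- parameter_path(1000, 1, 3000)
  dom <- icer_dual(effect_stream("A", 5, -2000, 0), p, d0)
  expect_match(dom$quadrant, "dominant")
  expect_equal(dom$verdict, "adopt")
  dtd <- icer_dual(effect_stream("A", -5, 2000, 0), p, d0)
  expect_match(dtd$quadrant, "dominated")
  expect_equal(dtd$verdict, "reject")
})

test_that("ICER and net-health verdicts coincide under exact compounding", {
  set.seed(302)
  for (i in 1:40) {
    T <- sample(1:10, 1)
    s <- effect_stream("A", runif(T, -5, 20), runif(T, -2000, 10000), 0)
    gk_h <- runif(1, 0, 0.05)
    r_s <- runif(1, 0, 0.08)
    k_h1 <- runif(1, 500, 5000)
    g <- growth_spec(g_c = 0.03, gk_h = gk_h)
    params <- parameter_path_from_growth(k_h1, 3000, 1, g, T)
    d <- discount_spec(g_c = 0.03, r_s = r_s,
                       convention = "exact_multiplicative")
    r_h <- health_rate(r_s, gk_h, "exact_multiplicative")
    dec <- decision_net_health(s, params, rate_schedule(r_h, T = T))
    ic <- icer_dual(s, params, d, g)
    expect_equal(ic$verdict, dec$verdict)
    if (ic$pv_health > 0) {
      expect_equal(ic$verdict,
                   if (ic$icer < k_h1) "adopt"
                   else if (ic$icer > k_h1) "reject" else "indifferent")
    }
  }
})

test_that("global NPV sums country NPVs and preserves the breakdown", {
  sA <- effect_stream("A", c(10, 8), c(5000, 4000), c(200, 100))
  sB <- effect_stream("B", c(-2, 1), c(1000, -500), c(0, 50))
  sC <- effect_stream("C", c(3, 3), c(9000, 9000), c(400, 400))
  proj <- project(sA, sB, sC)
  ctxs <- list(
    country_context("A", 1000, 3000, growth = growth_spec(0.03),
                    discount = discount_spec(eta = 1)),
    country_context("B", 800, 2000, growth = growth_spec(0.02, gk_h = 0.01),
                    discount = discount_spec(eta = 2)),
    country_context("C", 1500, 5000, growth = growth_spec(0.04),
                    discount = discount_spec(delta = 0.01, eta = 1.5))
  )
  res <- npv_global(proj, ctxs)
  expect_equal(res$global, sum(res$by_country$npv))

  # brute-force per-term oracle for the three-country sum
  oracle <- 0
  specs <- list(
    list(s = sA, k = 1000, V = 3000, g = 0.03, gk = 0, el = 1,
         eta = 1, del = 0),
    list(s = sB, k = 800, V = 2000, g = 0.02, gk = 0.01, el = 1,
         eta = 2, del = 0),
    list(s = sC, k = 1500, V = 5000, g = 0.04, gk = 0, el = 1,
         eta = 1.5, del = 0.01)
  )
  for (sp in specs) {
    r_c <- sp$del + sp$eta * sp$g
    for (t in 1:2) {
      k_ht <- sp$k * (1 + sp$gk)^(t - 1)
      V_ht <- sp$V * (1 + sp$el * sp$g)^(t - 1)
      k_ct <- 1 * (1 + sp$g)^(t - 1)
      eq <- V_ht * (sp$s$delta_h[t] - sp$s$delta_c_h[t] / k_ht) -
        (sp$s$delta_c_c[t] + k_ct * sp$s$delta_c_h[t])
      oracle <- oracle + eq / (1 + r_c)^t
    }
  }
  expect_equal(res$global, oracle, tolerance = 1e-12)

  # order invariance
  res_rev <- npv_global(project(sC, sB, sA), rev(ctxs))
  expect_equal(res_rev$global, res$global, tolerance = 1e-12)

  # additivity under stream splitting
  one <- npv_global(project(sA), ctxs[1])
  half <- effect_stream("A", sA$delta_h / 2, sA$delta_c_h / 2,
                        sA$delta_c_c / 2)
  expect_equal(2 * npv_global(project(half), ctxs[1])$global, one$global,
               tolerance = 1e-12)
})

test_that("aggregation refuses missing contexts and mixed currencies", {
  sA <- effect_stream("A", 1, 1)
  sB <- effect_stream("B", 1, 1)
  ctxA <- country_context("A", 1000, 3000, growth = growth_spec(0.03))
  expect_error(npv_global(project(sA, sB), list(ctxA)), "B")
  ctxB <- country_context("B", 1000, 3000, growth = growth_spec(0.03),
                          currency = "ZMW")
  expect_error(npv_global(project(sA, sB), list(ctxA, ctxB)),
               "currenc")
})

test_that("all present values reduce to column sums at zero rates", {
  set.seed(303)
  s <- rand_stream("A", T = 6)
  ctx <- country_context("A", 1000, 3000, growth = growth_spec(0),
                         discount = discount_spec(r_s = 0))
  res <- npv_country(s, ctx)
  expect_equal(res$npv, sum(res$table$eq_consumption))
  expect_equal(res$pv$health, sum(res$table$eq_health))
  expect_equal(res$pv$resource, sum(res$table$eq_resource))
  expect_equal(res$pv$net_health, sum(res$table$net_health_benefit))
})
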