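test_that("nationwide budget impact is the undiscounted product", {
  expect_identical(nwbi(35000, 1e6), 35e9)
  expect_identical(nwbi(9050, 20000), 181e6)
  expect_identical(nwbi(750, 1), 750)
  # linear in both arguments
  expect_identical(nwbi(2 * 35000, 1e6), 2 * nwbi(35000, 1e6))
  expect_identical(nwbi(35000, 3e6), 3 * nwbi(35000, 1e6))
  expect_error(nwbi(0, 10), "positive")
  expect_error(nwbi(100, -1), "positive")
})

test_that("analytic expenditure matches the closed-form average for both worked examples", {
  m1 <- ranibizumab_model()
  e1 <- total_expenditure(m1, 20000)
  expect_lt(abs(e1$average_per_patient - 7705), 1)          # published 7,705 EUR
  expect_equal(e1$total, e1$average_per_patient * 20000, tolerance = 1e-12)
  expect_equal(average_cost(m1, 20000), e1$average_per_patient, tolerance = 1e-12)

  m2 <- sofosbuvir_model()
  e2 <- total_expenditure(m2, 60000)
  expect_lt(abs(e2$average_per_patient - 14969), 1)         # published 14,969 EUR
  expect_equal(average_cost(m2, 60000), e2$average_per_patient, tolerance = 1e-12)
})

test_that("average cost is bracketed by the last price and the full price", {
  set.seed(21)
  for (i in 1:25) {
    m <- pv_model(runif(1, 500, 5e4), 10^runif(1, -7, -3))
    n <- runif(1, 10, 2e5)
    avg <- average_cost(m, n)
    expect_gte(avg, price_at(m, n))
    expect_lte(avg, m$f_price)
    expect_equal(avg, total_expenditure(m, n)$average_per_patient,
                 tolerance = 1e-12)
  }
  flat <- pv_model(1234, 0)
  expect_identical(average_cost(flat, 5000), 1234)
})

test_that("trapezoid totals bound the analytic total from above and converge at O(step^2)", {
  m <- ranibizumab_model()
  ana <- total_expenditure(m, 20000)$total
  t1 <- total_expenditure(m, 20000, method = "trapezoid", step = 1)$total
  expect_lt(abs(t1 - ana), 0.01)
  for (step in c(1, 50, 400, 5000, 20000)) {
    tt <- total_expenditure(m, 20000, method = "trapezoid", step = step)$total
    expect_gte(tt, ana)
  }
  # single panel has the textbook closed form
  one <- total_expenditure(m, 20000, method = "trapezoid", step = 20000)$total
  expect_equal(one, 20000 * (m$f_price + price_at(m, 20000)) / 2, tolerance = 1e-12)
  # halving the step cuts the error ~4x
  e_h <- total_expenditure(m, 20000, method = "trapezoid", step = 200)$total - ana
  e_h2 <- total_expenditure(m, 20000, method = "trapezoid", step = 100)$total - ana
  expect_gt(e_h / e_h2, 3.8)
  expect_lt(e_h / e_h2, 4.2)
})

test_that("a partial final trapezoid panel is handled exactly", {
  m <- sofosbuvir_model()
  # step does not divide n: grid must still end at n, not short of it
  t_part <- total_expenditure(m, 50001, method = "trapezoid", step = 1000)
  ana <- total_expenditure(m, 50001)$total
  expect_gte(t_part$total, ana)
  # relative error ~ (k*step)^2 / 12 ~ 1.2e-4 at this step
  expect_lt(abs(t_part$total - ana) / ana, 3e-4)
  expect_error(total_expenditure(m, 100, method = "trapezoid", step = 0), "step")
  expect_error(total_expenditure(m, 100, method = "trapezoid", step = 101), "step")
})

test_that("analytic total grows with population and shrinks with faster decay", {
  m <- pv_model(10000, 5e-5)
  ns <- c(1e3, 1e4, 5e4, 2e5)
  totals <- vapply(ns, function(n) total_expenditure(m, n)$total, numeric(1))
  expect_true(all(diff(totals) > 0))
  ks <- c(1e-6, 1e-5, 1e-4, 1e-3)
  tot_k <- vapply(ks, function(k) total_expenditure(pv_model(10000, k), 5e4)$total,
                  numeric(1))
  expect_true(all(diff(tot_k) < 0))
})

test_that("the budget solver inverts the forward expenditure", {
  # feed the sofosbuvir model's own total back through the solver
  m2 <- sofosbuvir_model()
  cap <- total_expenditure(m2, 60000)$total
  sol <- solve_decay_for_budget(37500, 60000, cap)
  expect_equal(sol$decay_k, m2$decay_k, tolerance = 1e-8)
  expect_lt(abs(total_expenditure(sol, 60000)$total - cap) / cap, 1e-10)

  # identity on decay_k across the realistic rate range
  for (k in 10^seq(-7, -3, length.out = 9)) {
    m <- pv_model(20000, k)
    cap <- total_expenditure(m, 80000)$total
    sol <- solve_decay_for_budget(20000, 80000, cap)
    expect_equal(sol$decay_k, k, tolerance = 1e-8)
    expect_lt(abs(total_expenditure(sol, 80000)$total - cap) / cap, 1e-10)
  }
})

test_that("a cap at or above the undiscounted budget needs no decay", {
  sol <- solve_decay_for_budget(100, 1000, 100 * 1000)
  expect_identical(sol$decay_k, 0)
  expect_true(isTRUE(attr(sol, "no_discount_needed")))
  expect_error(solve_decay_for_budget(100, 1000, 0), "positive")
  expect_error(solve_decay_for_budget(100, 1000, -5), "positive")
})

test_that("tier schedules conserve the continuous model's expenditure", {
  m <- sofosbuvir_model()
  # single band reduces to the closed-form average
  one <- tier_schedule(m, 60000)
  expect_equal(one$price_eur, average_cost(m, 60000), tolerance = 1e-12)
  # multi-band schedule conserves the analytic total
  ts <- tier_schedule(m, c(10000, 25000, 42000, 60000))
  expect_equal(sum((ts$upper - ts$lower) * ts$price_eur),
               total_expenditure(m, 60000)$total, tolerance = 1e-9)
  # tier prices decrease with volume
  expect_true(all(diff(ts$price_eur) < 0))
  # a flat model prices every tier at the full price
  flat <- pv_model(800, 0)
  expect_true(all(tier_schedule(flat, c(100, 200))$price_eur == 800))
  expect_error(tier_schedule(m, c(200, 100)), "ascending")
  expect_error(tier_schedule(m, c(0, 100)), "ascending|above 0")
})

test_that("agreements derive their budget impact on construction", {
  a <- pv_agreement("ranibizumab", ranibizumab_model(), tot_pt = 20000)
  expect_identical(a$nwbi, 9050 * 20000)
  expect_error(pv_agreement("x", ranibizumab_model(), tot_pt = 0), "positive")
})
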