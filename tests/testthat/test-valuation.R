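test_that("state values combine utilities, multipliers and costs as specified", {
  p <- base_params()
  v <- state_values(p, "surgery")
  expect_equal(unname(v$utility["LLL"]), 0.7 * 0.888)      # 0.6216
  expect_equal(unname(v$utility["LLComp"]), 0.8 * 0.888)
  expect_equal(unname(v$utility["ULL"]), 0.8 * 0.944)
  expect_equal(unname(v$utility["ULComp"]), 0.75 * 0.944)
  expect_equal(unname(v$utility["NormalLife_LLLOnly"]), 0.888)
  expect_equal(unname(v$utility["NormalLife_Full"]), 0.944)
  expect_equal(unname(v$utility["Death"]), 0)
  expect_equal(unname(v$cost),
               c(28539, 6275, 10834, 6275, 0, 0, 0))
  vn <- state_values(p, "no_treatment")
  expect_equal(unname(vn$utility), c(0.711, 0))
  expect_equal(unname(vn$cost), c(0, 0))
})

test_that("the baseline multiplier-base variant scales u_base instead", {
  p <- base_params(multiplier_base = "baseline")
  v <- state_values(p, "surgery")
  expect_equal(unname(v$utility["LLL"]), 0.7 * 0.711)
  expect_equal(unname(v$utility["ULL"]), 0.8 * 0.711)
  # lifelong utilities unaffected by the choice
  expect_equal(unname(v$utility["NormalLife_Full"]), 0.944)
})

test_that("unit multipliers restore the full post-stage utilities", {
  p <- base_params(m_lll = 1, m_ull = 1, m_llc = 1, m_ulc = 1)
  v <- state_values(p, "surgery")
  expect_equal(unname(v$utility["LLL"]), p$u_lll)
  expect_equal(unname(v$utility["ULComp"]), p$u_full)
})

test_that("discount factors follow the exponent law", {
  expect_equal(discount_factor(0, 0:10), rep(1, 11))
  expect_equal(discount_factor(0.03, 1), 1 / 1.03)
  expect_equal(discount_factor(0.03, 2) * discount_factor(0.03, 3),
               discount_factor(0.03, 5), tolerance = 1e-15)
  expect_error(discount_factor(-0.1, 1), "non-negative")
})

test_that("accumulation matches closed forms", {
  # one-cycle identity: a single undiscounted normal-life cycle
  s <- model_states("no_treatment")
  one <- matrix(c(0, 1, 0, 1), 2, byrow = TRUE, dimnames = list(s, s))
  tr <- run_trace(no_treatment_init(), list(one))
  vals <- list(utility = c(NormalLife = 0.711, Death = 0),
               cost = c(NormalLife = 0, Death = 0))
  acc <- accumulate_trace(tr, vals, r_cost = 0, r_health = 0)
  expect_equal(unname(acc["qalys"]), 0.711)
  expect_equal(unname(acc["cost"]), 0)
  # geometric series: dp = 0.2, u = 1, r = 0 over 500 cycles -> 1/0.2
  mats <- replicate(500, no_treatment_matrix(0.2), simplify = FALSE)
  tr <- run_trace(no_treatment_init(), mats)
  vals$utility <- c(NormalLife = 1, Death = 0)
  acc <- accumulate_trace(tr, vals, r_cost = 0, r_health = 0)
  expect_equal(unname(acc["qalys"]), 1 / 0.2, tolerance = 1e-9)
})

test_that("QALYs are bounded by the horizon and decrease with discounting", {
  lt <- gompertz_makeham_table()
  fit <- ll_model(base_params(), lt)
  expect_true(all(fit$qalys <= 91))
  fit_r0 <- ll_model(base_params(r_health = 0), lt)
  expect_true(all(fit_r0$qalys > fit$qalys))
})

test_that("utilities and costs are separable", {
  lt <- gompertz_makeham_table()
  f1 <- ll_model(base_params(), lt)
  # changing utilities leaves costs untouched
  f2 <- ll_model(base_params(u_lll = 0.5, u_full = 0.6, m_lll = 0.2), lt)
  expect_identical(f1$costs, f2$costs)
  # changing costs leaves QALYs untouched
  f3 <- ll_model(base_params(c_lll = 1, c_ull = 2, c_comp = 3), lt)
  expect_identical(f1$qalys, f3$qalys)
})

test_that("a null intervention is economically equivalent to no treatment", {
  p <- base_params(u_lll = 0.711, u_full = 0.711,
                   m_lll = 1, m_ull = 1, m_llc = 1, m_ulc = 1,
                   c_lll = 0, c_ull = 0, c_comp = 0, surg_dp = 0)
  fit <- ll_model(p, gompertz_makeham_table())
  expect_equal(unname(fit$qalys["surgery"]), unname(fit$qalys["no_treatment"]),
               tolerance = 1e-10)
  expect_equal(unname(diff(fit$costs)), 0)
})

test_that("comparison reproduces desk arithmetic and flags degeneracies", {
  cmp <- cea_compare(c(no_treatment = 21.243, surgery = 27.197),
                     c(no_treatment = 0, surgery = 49480), wtp = 25000)
  expect_equal(cmp$delta_qaly, 5.954)
  expect_equal(round(cmp$icer), 8310)
  # identical strategies: undefined ICER, no dominance
  same <- cea_compare(c(a = 20, b = 20), c(a = 100, b = 100))
  expect_true(is.na(same$icer))
  expect_identical(same$dominance, "none")
  # NMB arithmetic
  nm <- cea_compare(c(a = 0, b = 20), c(a = 0, b = 0), wtp = 25000)
  expect_equal(unname(nm$nmb["b"]), 500000)
  # dominance flags
  dom <- cea_compare(c(a = 10, b = 12), c(a = 100, b = 50))
  expect_identical(dom$dominance, "comparator dominant")
  expect_true(is.finite(dom$icer) == FALSE || dom$icer < 0)
})

test_that("NMB ranking agrees with ICER-vs-threshold whenever QALYs are gained", {
  lt <- gompertz_makeham_table()
  fit <- ll_model(base_params(), lt)
  expect_gt(fit$delta_qaly, 0)
  for (lambda in c(2000, fit$icer * 0.9, fit$icer * 1.1, 40000)) {
    cmp <- cea_compare(fit$qalys, fit$costs, wtp = lambda)
    surgery_preferred <- cmp$nmb["surgery"] > cmp$nmb["no_treatment"]
    expect_identical(unname(surgery_preferred), lambda > fit$icer)
  }
})
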