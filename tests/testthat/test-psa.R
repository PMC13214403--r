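test_that("beta method-of-moments recovers the requested moments", {
  ab <- beta_from_moments(0.711, 0.266)
  expect_equal(unname(ab), c(1.3538, 0.5503), tolerance = 1e-4)
  # the moments come back out of the shape parameters
  m <- ab[1] / sum(ab)
  v <- ab[1] * ab[2] / (sum(ab)^2 * (sum(ab) + 1))
  expect_equal(unname(m), 0.711, tolerance = 1e-12)
  expect_equal(unname(sqrt(v)), 0.266, tolerance = 1e-12)
  # feasibility boundary: sd^2 = mean(1-mean) is rejected, not truncated
  expect_error(beta_from_moments(0.5, 0.5), "infeasible beta moments")
  expect_error(beta_from_moments(1.2, 0.1), "in \\(0, 1\\)")
  # small-sd limit concentrates at the mean
  ab2 <- beta_from_moments(0.5, 1e-4)
  expect_equal(unname(ab2[1] / sum(ab2)), 0.5)
  expect_gt(sum(ab2), 1e6)
})

test_that("beta from effective sample size follows the definition", {
  expect_equal(unname(beta_from_ess(0.8, 50)), c(40, 10))
  expect_equal(unname(beta_from_ess(0.1, 50)), c(5, 45))
  expect_error(beta_from_ess(0, 50), "in \\(0, 1\\)")
  expect_error(beta_from_ess(0.5, 0), "> 0")
})

test_that("gamma from coefficient of variation follows the definition", {
  sh <- gamma_from_cv(28539, 0.30)
  expect_equal(unname(sh["shape"]), 1 / 0.09, tolerance = 1e-12)
  expect_equal(unname(sh["scale"]), 2568.51, tolerance = 1e-10)
  expect_equal(unname(gamma_from_cv(100, 1)["shape"]), 1)  # exponential
  expect_error(gamma_from_cv(-5, 0.3), "> 0")
})

test_that("distribution builders recover target moments in large samples", {
  set.seed(7)
  n <- 1e6
  # beta, moment-matched
  ab <- beta_from_moments(0.711, 0.266)
  x <- rbeta(n, ab[1], ab[2])
  expect_lt(abs(mean(x) - 0.711), 4 * 0.266 / sqrt(n))
  expect_equal(sd(x), 0.266, tolerance = 0.01)
  # beta, effective sample size
  ab <- beta_from_ess(0.8, 50)
  sd_true <- sqrt(0.8 * 0.2 / 51)
  x <- rbeta(n, ab[1], ab[2])
  expect_lt(abs(mean(x) - 0.8), 4 * sd_true / sqrt(n))
  # gamma, CV-parameterised: sd/mean ~ cv
  sh <- gamma_from_cv(28539, 0.30)
  x <- rgamma(n, shape = sh[1], scale = sh[2])
  expect_lt(abs(mean(x) - 28539), 4 * 28539 * 0.3 / sqrt(n))
  expect_equal(sd(x) / mean(x), 0.30, tolerance = 0.01)
})

test_that("a fully fixed PSA reproduces the deterministic base case", {
  p <- base_params(n_cycles = 40L)
  lt <- gompertz_makeham_table()
  specs <- psa_distributions(p, quiet = TRUE)
  fixed <- lapply(names(specs), function(nm) list(family = "fixed",
                                                  value = p[[nm]]))
  names(fixed) <- names(specs)
  psa <- run_psa(p, lt, n_iter = 5, seed = 1, specs = fixed)
  fit <- ll_model(p, lt)
  for (i in 1:5) {
    expect_equal(psa$qalys[i, ], fit$qalys, tolerance = 1e-14)
    expect_equal(psa$costs[i, ], fit$costs, tolerance = 1e-14)
  }
})

test_that("the PSA is bitwise reproducible from its seed", {
  p <- base_params(n_cycles = 30L)
  lt <- gompertz_makeham_table()
  a <- suppressMessages(run_psa(p, lt, n_iter = 25, seed = 99))
  b <- suppressMessages(run_psa(p, lt, n_iter = 25, seed = 99))
  expect_identical(a$qalys, b$qalys)
  expect_identical(a$costs, b$costs)
  expect_identical(a$samples, b$samples)
  c2 <- suppressMessages(run_psa(p, lt, n_iter = 25, seed = 100))
  expect_false(identical(a$samples, c2$samples))
})

test_that("sampled draws respect their supports and approximate their means", {
  p <- base_params()
  lt <- gompertz_makeham_table()
  psa <- suppressMessages(run_psa(p, lt, n_iter = 1000, seed = 3))
  expect_identical(psa$n_iter, 1000L)
  expect_identical(nrow(psa$samples), 1000L)
  u_cols <- c("u_base", "u_lll", "u_full", "m_lll", "m_ull", "m_llc", "m_ulc",
              "p_ll_comp", "p_ul_comp", "p_withdraw")
  expect_true(all(psa$samples[, u_cols] >= 0 & psa$samples[, u_cols] <= 1))
  expect_true(all(psa$samples[, c("c_lll", "c_ull", "c_comp")] > 0))
  expect_true(all(psa$qalys >= 0) && all(psa$costs >= 0))
  # marginal means within 4 * implied sd / sqrt(n) of the spec means
  implied_sd <- c(u_base = 0.266, u_lll = 0.111, u_full = 0.078,
                  m_lll = sqrt(0.7 * 0.3 / 51), m_ull = sqrt(0.8 * 0.2 / 51),
                  m_llc = sqrt(0.8 * 0.2 / 51), m_ulc = sqrt(0.75 * 0.25 / 51),
                  p_ll_comp = sqrt(0.8 * 0.2 / 51),
                  p_ul_comp = sqrt(0.1 * 0.9 / 51),
                  p_withdraw = sqrt(0.1 * 0.9 / 51),
                  c_lll = 28539 * 0.3, c_ull = 10834 * 0.3,
                  c_comp = 6275 * 0.3)
  means <- c(u_base = 0.711, u_lll = 0.888, u_full = 0.944,
             m_lll = 0.7, m_ull = 0.8, m_llc = 0.8, m_ulc = 0.75,
             p_ll_comp = 0.8, p_ul_comp = 0.1, p_withdraw = 0.1,
             c_lll = 28539, c_ull = 10834, c_comp = 6275)
  for (nm in names(means)) {
    expect_lt(abs(mean(psa$samples[, nm]) - means[[nm]]),
              4 * implied_sd[[nm]] / sqrt(1000))
  }
})

test_that("shrinking all dispersions collapses the PSA onto the base case", {
  p <- base_params(u_base_sd = 1e-4, u_lll_sd = 1e-4, u_full_sd = 1e-4,
                   n_cycles = 40L)
  lt <- gompertz_makeham_table()
  specs <- psa_distributions(p, ess = 1e7, cost_cv = 1e-4, quiet = TRUE)
  psa <- run_psa(p, lt, n_iter = 50, seed = 5, specs = specs)
  fit <- ll_model(p, lt)
  s <- summary(psa)
  expect_equal(unname(s$mean_qalys), unname(fit$qalys), tolerance = 1e-3)
  expect_equal(unname(s$mean_costs), unname(fit$costs), tolerance = 1e-2)
})

test_that("summary statistics satisfy their defining identities", {
  p <- base_params(n_cycles = 30L)
  lt <- gompertz_makeham_table()
  psa <- suppressMessages(run_psa(p, lt, n_iter = 200, seed = 11))
  s <- summary(psa)
  # ICER of means is the ratio of mean increments
  expect_equal(s$icer, s$delta_cost / s$delta_qaly, tolerance = 1e-12)
  # mean NMB linearity: mean(lambda*E - C) = lambda*mean(E) - mean(C)
  lambda <- 25000
  per_iter <- lambda * psa$qalys - psa$costs
  expect_equal(unname(colMeans(per_iter)), unname(s$mean_nmb),
               tolerance = 1e-9)
  # a single iteration summarises to itself
  one <- suppressMessages(run_psa(p, lt, n_iter = 1, seed = 2))
  s1 <- summary(one)
  expect_equal(unname(s1$mean_qalys), unname(one$qalys[1, ]))
})
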