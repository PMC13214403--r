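psa_fixture <- function(n_iter = 200, seed = 17, n_cycles = 30L) {
  suppressMessages(run_psa(base_params(n_cycles = n_cycles),
                           gompertz_makeham_table(),
                           n_iter = n_iter, seed = seed))
}

test_that("CEAC limits follow costs at lambda = 0 and QALYs as lambda grows", {
  psa <- psa_fixture()
  cc <- ceac(psa, wtp = c(0, 1e9))
  # surgery always costs more, so the zero-cost strategy wins every
  # iteration at lambda = 0
  expect_equal(cc$p_no_treatment[1L], 1)
  # at enormous lambda the choice follows QALYs alone
  dq <- psa$qalys[, "surgery"] - psa$qalys[, "no_treatment"]
  expect_equal(cc$p_surgery[2L], mean(dq > 0))
  # probabilities sum to one across strategies at every lambda
  vc <- voi_curves(psa, seq(0, 50000, 2500))
  expect_equal(vc$p_surgery + vc$p_no_treatment, rep(1, nrow(vc)))
})

test_that("CEAC agrees with an explicit per-iteration argmax oracle", {
  psa <- psa_fixture(n_iter = 50, seed = 23)
  grid <- seq(0, 40000, 1000)
  cc <- ceac(psa, grid)
  for (j in seq_along(grid)) {
    wins <- 0L
    for (i in seq_len(psa$n_iter)) {
      nmb_nt <- grid[j] * psa$qalys[i, "no_treatment"] - psa$costs[i, "no_treatment"]
      nmb_s <- grid[j] * psa$qalys[i, "surgery"] - psa$costs[i, "surgery"]
      if (nmb_s > nmb_nt) wins <- wins + 1L   # ties to the reference
    }
    expect_identical(cc$p_surgery[j], wins / psa$n_iter)
  }
})

test_that("the frontier switches strategy exactly at the ICER of means", {
  psa <- psa_fixture()
  s <- summary(psa)
  grid <- sort(c(seq(0, 50000, 500), s$icer * c(0.999, 1.001)))
  cf <- ceaf(psa, grid)
  expect_true(all(cf$frontier_strategy[grid < s$icer] == "no_treatment"))
  expect_true(all(cf$frontier_strategy[grid > s$icer] == "surgery"))
  # the frontier reports the acceptability of the expected-value-optimal
  # strategy, so it never exceeds the upper CEAC envelope
  cc <- ceac(psa, grid)
  expect_true(all(cf$frontier_p <= pmax(cc$p_surgery, cc$p_no_treatment) + 1e-12))
})

test_that("EVPI is non-negative, zero without uncertainty, and kinked at the crossing", {
  psa <- psa_fixture(n_iter = 1000, seed = 29, n_cycles = 90L)
  grid <- seq(0, 50000, 500)
  ev <- evpi(psa, grid)
  expect_true(all(ev$evpi >= 0))
  # degenerate PSA: all iterations identical -> EVPI identically zero
  p <- base_params(n_cycles = 30L)
  specs <- lapply(psa_distributions(p, quiet = TRUE), function(sp) sp)
  fixed <- lapply(names(specs), function(nm) list(family = "fixed", value = p[[nm]]))
  names(fixed) <- names(specs)
  degen <- run_psa(p, gompertz_makeham_table(), n_iter = 10, seed = 1,
                   specs = fixed)
  expect_equal(evpi(degen, grid)$evpi, rep(0, length(grid)), tolerance = 1e-9)
  # the slope change (largest second difference) localises at the
  # expected-NMB crossing, i.e. the ICER of means
  s <- summary(psa)
  d2 <- abs(diff(diff(ev$evpi)))
  kink_at <- grid[which.max(d2) + 1L]
  expect_lt(abs(kink_at - s$icer), 1000)
})

test_that("VOI curves are difference-based and scale-equivariant", {
  psa <- psa_fixture(n_iter = 100, seed = 31)
  grid <- seq(0, 30000, 1500)
  base <- voi_curves(psa, grid)
  # adding a constant cost to both strategies changes nothing
  shifted <- psa
  shifted$costs <- psa$costs + 5000
  sh <- voi_curves(shifted, grid)
  expect_equal(sh$p_surgery, base$p_surgery)
  expect_equal(sh$evpi, base$evpi)
  expect_identical(sh$frontier_strategy, base$frontier_strategy)
  # multiplying costs by k and lambda by k preserves CEAC and scales EVPI by k
  k <- 3
  scaled <- psa
  scaled$costs <- psa$costs * k
  sc <- voi_curves(scaled, grid * k)
  expect_equal(sc$p_surgery, base$p_surgery)
  expect_equal(sc$evpi, k * base$evpi, tolerance = 1e-9)
})

test_that("the grid is validated", {
  psa <- psa_fixture(n_iter = 20, seed = 2)
  expect_error(ceac(psa, c(0, 0, 500)), "strictly increasing")
  expect_error(ceac(psa, c(-100, 0)), "non-negative")
})
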