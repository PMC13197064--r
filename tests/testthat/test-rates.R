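p_low <- levan_presets()$low

test_that("Monod growth rate has the right limits and shape", {
  expect_identical(growth_rate(p_low, 0), 0)
  expect_equal(growth_rate(p_low, p_low$Ks), p_low$mu_max / 2)
  # saturation: fitted low-regime value recovered at overwhelming sucrose
  expect_equal(growth_rate(p_low, 1e6 * p_low$Ks), 0.2454, tolerance = 1e-5)
  expect_lt(abs(growth_rate(p_low, 1e9 * p_low$Ks) - p_low$mu_max),
            1e-6 * p_low$mu_max)
  # monotone non-decreasing in S
  S <- seq(0, 2000, length.out = 200)
  expect_true(all(diff(growth_rate(p_low, S)) >= 0))
  expect_true(all(growth_rate(p_low, S) <= p_low$mu_max))
  expect_error(growth_rate(p_low, -1), "S_reactor")
})

test_that("hydrolysis rate is single-substrate Michaelis-Menten", {
  expect_identical(hydrolysis_rate(p_low, 0), 0)
  expect_equal(hydrolysis_rate(p_low, p_low$KM_hyd), p_low$vmax_hyd / 2)
  p <- kinetic_params(mu_max = 0.2, Ks = 5, kd = 0, Y_XS = 0.02, alpha = 18,
                      vmax_hyd = 2, KM_hyd = 10, vmax_trans1 = 6.42,
                      KM_trans1 = 7000, KM_trans2 = 5e4,
                      vmax_levdeg = 0.03, KM_levdeg = 100, t_levdeg_onset = 18)
  expect_equal(hydrolysis_rate(p, 30), 1.5)
  expect_true(all(hydrolysis_rate(p_low, seq(0, 1e5, length.out = 50)) <=
                    p_low$vmax_hyd))
  expect_error(hydrolysis_rate(p_low, -0.1), "S_reactor")
})

test_that("transfructosylation rate reduces correctly at its limits", {
  expect_identical(transfructosylation_rate(p_low, 0, 0), 0)
  expect_identical(transfructosylation_rate(p_low, 0, 50), 0)
  # F = 0 collapses to the sucrose-only Michaelis-Menten term
  S <- c(1, 10, 100, 1000)
  mm <- p_low$vmax_trans1 * (S / p_low$KM_trans1) / (1 + S / p_low$KM_trans1)
  expect_equal(transfructosylation_rate(p_low, S, 0), mm)
  # saturation to the shared fitted maximum rate
  expect_equal(transfructosylation_rate(p_low, 1e9, 0), 6.42, tolerance = 1e-5)
  # bounded by the larger vmax for any inputs
  grid <- expand.grid(S = c(0, 5, 50, 500, 5000), F = c(0, 5, 50, 500))
  r <- transfructosylation_rate(p_low, grid$S, grid$F)
  expect_true(all(r >= 0 & r <= max(p_low$vmax_trans1, p_low$vmax_trans2)))
  expect_error(transfructosylation_rate(p_low, 10, -1), "Fru")
})

test_that("levan degradation is Heaviside-gated with a 67% degradable pool", {
  expect_identical(levan_degradation_rate(p_low, 100, p_low$t_levdeg_onset - 1), 0)
  expect_identical(levan_degradation_rate(p_low, 0, p_low$t_levdeg_onset + 1), 0)
  # half-saturation when the degradable pool 0.67*L equals KM
  L_half <- p_low$KM_levdeg / (1 - p_low$degradable_fraction_complement)
  expect_equal(levan_degradation_rate(p_low, L_half, p_low$t_levdeg_onset + 1),
               p_low$vmax_levdeg / 2)
  expect_error(levan_degradation_rate(p_low, -1, 10), "Levan")
})

test_that("the ODE right-hand side matches a term-by-term hand evaluation", {
  state <- c(X = 1, E = 20, S_cell = 50, Glc = 30, Fru = 10,
             S_reactor = 100, Levan = 5)
  t <- 20  # past the low-regime onset, so the degradation gate is open
  p <- p_low
  out <- ode_rhs(t, state, p)

  # independent arithmetic, straight from the rate laws
  mu <- 0.2454 * 100 / (5 + 100)
  v1 <- mu * 1 / 0.020
  E_pool <- 18.19 * 1
  v3 <- 1.0 * 100 / (30 + 100)
  v4 <- (6.42 * 100 / 7000 + 6.42 * 10 * 100 / 5e4) /
    (1 + 100 / 7000 + 10 * 100 / 5e4)
  v5 <- 0.03 * (0.67 * 5) / (100 + 0.67 * 5)
  expect_equal(unname(out[[1]]),
               c((mu - 0.008) * 1,
                 18.19 * mu * 1,
                 v1,
                 (v3 + v4) * E_pool,
                 (v3 - v4 + v5) * E_pool,
                 -v1 - (v3 + v4) * E_pool,
                 (v4 - v5) * E_pool))
  expect_equal(out[[2]][["mu"]], mu)
  expect_equal(out[[2]][["v5"]], v5)
})

test_that("zero biomass freezes the whole system", {
  state <- c(X = 0, E = 0, S_cell = 0, Glc = 5, Fru = 5,
             S_reactor = 100, Levan = 5)
  out <- ode_rhs(50, state, p_low)
  expect_equal(unname(out[[1]]), rep(0, 7))
})

test_that("glucosyl-moiety balance holds identically in the right-hand side", {
  # the glucose derivative must equal total enzymatic sucrose consumption
  for (S in c(10, 100, 700)) {
    state <- c(X = 0.8, E = 10, S_cell = 0, Glc = 1, Fru = 25,
               S_reactor = S, Levan = 40)
    out <- ode_rhs(30, state, p_low)
    rates <- out[[2]]
    expect_equal(out[[1]][["Glc"]], rates[["v3_vol"]] + rates[["v4_vol"]])
  }
})

test_that("the as-printed variant omits the enzyme pool on hydrolysis", {
  state <- c(X = 1, E = 20, S_cell = 0, Glc = 0, Fru = 10,
             S_reactor = 100, Levan = 5)
  pooled <- ode_rhs(2, state, p_low, equations = "pooled")
  printed <- ode_rhs(2, state, p_low, equations = "as_printed")
  v3 <- pooled[[2]][["v3"]]
  E_pool <- pooled[[2]][["E_pool"]]
  expect_equal(printed[[1]][["Glc"]] - pooled[[1]][["Glc"]],
               v3 - v3 * E_pool)
  # growth terms are unaffected
  expect_equal(printed[[1]][["X"]], pooled[[1]][["X"]])
})

test_that("non-finite states are rejected", {
  state <- c(X = 1, E = 0, S_cell = 0, Glc = 0, Fru = NaN,
             S_reactor = 100, Levan = 0)
  expect_error(ode_rhs(1, state, p_low), "non-finite")
})
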