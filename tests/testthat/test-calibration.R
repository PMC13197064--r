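presets <- levan_presets()

test_that("nrmse matches its closed forms and a direct recomputation", {
  expect_equal(nrmse(c(1, 5, 9), c(1, 5, 9)), 0)
  # constant offset 1 over observed range 10 -> 10%
  expect_equal(nrmse(c(1, 11), c(0, 10)), 10)
  set.seed(42)
  obs <- runif(20, 0, 50)
  sim <- obs + rnorm(20)
  expect_equal(nrmse(sim, obs), nrmse_oracle(sim, obs))
  # alternative normalisers
  expect_equal(nrmse(sim, obs, "mean"),
               100 * sqrt(mean((sim - obs)^2)) / mean(obs))
})

test_that("nrmse is invariant to affine rescaling of the measurement unit", {
  set.seed(7)
  obs <- runif(15, 1, 30)
  sim <- obs * (1 + rnorm(15, 0, 0.05))
  for (k in c(0.001, 1, 180.16)) {
    expect_equal(nrmse(k * sim + 3, k * obs + 3), nrmse(sim, obs))
  }
})

test_that("nrmse guards its preconditions and names the offending series", {
  expect_error(nrmse(1:3, 1:4), "equal length")
  expect_error(nrmse(1, 1), "at least 2")
  expect_error(nrmse(c(1, 2), c(5, 5), species = "glucose"), "glucose")
})

test_that("noiseless data generated from the truth is a fixed point of the fit", {
  obs <- generate_timecourses(conditions = 100, replicates = 1,
                              noise = noise_model(cv = 0), seed = 1)
  fit <- fit_parameters(obs, presets$low, free = c("mu_max", "alpha"),
                        n_starts = 1, seed = 1)
  expect_lt(fit$sse, 1e-6)
  expect_equal(fit$params$mu_max, presets$low$mu_max, tolerance = 1e-6)
  expect_equal(fit$params$alpha, presets$low$alpha, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("fitting is deterministic given data, start and seed", {
  obs <- generate_timecourses(conditions = 100, replicates = 1, seed = 5)
  f1 <- fit_parameters(obs, presets$low, free = "mu_max", n_starts = 2, seed = 9)
  f2 <- fit_parameters(obs, presets$low, free = "mu_max", n_starts = 2, seed = 9)
  expect_identical(f1$params$mu_max, f2$params$mu_max)
  expect_identical(f1$sse, f2$sse)
})

test_that("held-fixed parameters are untouched and errors are guarded", {
  obs <- generate_timecourses(conditions = 100, replicates = 1, seed = 2)
  fit <- fit_parameters(obs, presets$low, free = "mu_max", n_starts = 1, seed = 1)
  for (nm in c("Ks", "kd", "alpha", "vmax_hyd", "KM_trans1")) {
    expect_identical(fit$params[[nm]], presets$low[[nm]])
  }
  expect_error(fit_parameters(obs, presets$low, free = character(0)), "free")
  expect_error(fit_parameters(obs[0, ], presets$low), "observations")
  expect_error(fit_parameters(obs, presets$low, free = "nonexistent"),
               "unknown")
})

test_that("tidy and glance summarise a fit", {
  obs <- generate_timecourses(conditions = 100, replicates = 1, seed = 3)
  fit <- fit_parameters(obs, presets$low, free = "mu_max", n_starts = 1, seed = 1)
  tb <- tidy(fit)
  expect_true(tb$fitted[tb$parameter == "mu_max"])
  expect_false(tb$fitted[tb$parameter == "Ks"])
  g <- glance(fit)
  expect_true(all(c("sse", "nrmse_average_pct", "converged") %in% names(g)))
  expect_gte(g$nrmse_average_pct, 0)
})

test_that("a zero perturbation produces exactly zero deviations", {
  sc <- sensitivity_scan(presets$low, 100, perturbation = 0,
                         parameters = c("mu_max", "alpha"),
                         report_times = seq(0, 48, by = 6), horizon = 48)
  expect_true(all(sc$nrmse_pct[!sc$failed] == 0, na.rm = TRUE))
})

test_that("the scan reports two perturbed runs per parameter and ranks them", {
  pars <- c("mu_max", "Ks", "alpha", "vmax_hyd")
  # halving the hydrolysis capacity pushes the printed fructose balance
  # below zero; the simulator clips and warns, which is expected here
  sc <- suppressWarnings(
    sensitivity_scan(presets$high, 250, parameters = pars,
                     report_times = seq(0, 72, by = 6), horizon = 72))
  # bookkeeping: one row per species per direction per parameter
  runs <- unique(sc[, c("parameter", "direction")])
  expect_equal(nrow(runs), 2 * length(pars))
  rk <- attr(sc, "ranking")
  expect_setequal(rk$parameter, pars)
  # enzyme yield is among the most influential for levan at high sucrose
  lev <- sc[sc$species == "levan" & !sc$failed, ]
  by_par <- tapply(lev$nrmse_pct, lev$parameter, mean)
  expect_true("alpha" %in% names(sort(by_par, decreasing = TRUE))[1:2])
})

test_that("failed perturbed runs are recorded per cell, not fatal", {
  # a 150% downward perturbation makes Ks negative: that cell must be
  # flagged as failed while the upward cell still reports deviations
  sc <- sensitivity_scan(presets$low, 100, perturbation = 1.5,
                         parameters = "Ks",
                         report_times = seq(0, 24, by = 6), horizon = 24)
  expect_true(all(sc$failed[sc$direction == "minus"]))
  expect_false(any(sc$failed[sc$direction == "plus"]))
  expect_true(all(is.finite(sc$nrmse_pct[sc$direction == "plus"])))
})
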