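presets <- levan_presets()

# small helper: a linear chain EX_A -> (A -> B) -> (B -> C) -> EX_C
chain_model <- function(uptake = 1) {
  S <- matrix(c(1, 0, 0,
                -1, 1, 0,
                0, -1, 1,
                0, 0, -1),
              nrow = 3, dimnames = list(c("A", "B", "C"),
                                        c("EX_A", "R1", "R2", "EX_C")))
  stoich_model(S, lb = c(uptake, 0, 0, 0), ub = c(uptake, 10, 10, 10),
               biomass_id = "EX_C", uptake_id = "EX_A",
               levansucrase_id = NA)
}

test_that("the toy network loads with its documented shape and is feasible", {
  m <- generate_toy_gem()
  expect_equal(length(m$rxns), 13)
  expect_equal(m$biomass_id, "BIOMASS")
  expect_equal(m$levansucrase_id, "LVS_SYN")
  # positive growth and levansucrase flux are simultaneously attainable
  m2 <- m
  m2$lb["EX_suc"] <- m2$ub["EX_suc"] <- 10
  m2$lb["BIOMASS"] <- 0.5
  m2$lb["LVS_SYN"] <- 0.01
  sol <- solve_min_total_flux(m2)
  expect_gte(sol$flux[sol$reaction == "BIOMASS"], 0.5 - 1e-9)
  expect_gte(sol$flux[sol$reaction == "LVS_SYN"], 0.01 - 1e-9)
})

test_that("every internal metabolite balances: a strictly positive flux exists", {
  m <- generate_toy_gem()
  m2 <- m
  m2$ub["EX_aa"] <- 10           # open the supplement so all 13 can carry flux
  m2$lb[] <- 0.001               # demand strictly positive flux everywhere
  m2$lb["EX_suc"] <- m2$ub["EX_suc"] <- 5
  sol <- solve_min_total_flux(m2)
  expect_true(all(sol$flux >= 0.001 - 1e-9))
  expect_lt(max(abs(m$S %*% sol$flux[match(m$rxns, sol$reaction)])), 1e-9)
})

test_that("levansucrase synthesis depends on the amino-acid precursor", {
  m <- generate_toy_gem()
  m2 <- m
  m2$lb["EX_suc"] <- m2$ub["EX_suc"] <- 5
  # close both precursor routes: supplement exchange and internal synthesis
  m2$ub["EX_aa"] <- 0
  m2$ub["AASYN"] <- 0
  m2$lb["BIOMASS"] <- m2$ub["BIOMASS"] <- 0
  sol <- maximize_flux(m2, "LVS_SYN")
  expect_equal(sol$flux[sol$reaction == "LVS_SYN"], 0, tolerance = 1e-10)
})

test_that("the toy network is pinned against accidental edits", {
  m <- generate_toy_gem()
  fingerprint <- rlang::hash(list(m$S, m$lb, m$ub, m$obj, m$biomass_id,
                                  m$uptake_id, m$levansucrase_id))
  expect_identical(fingerprint, "7d0f149ce053f77eb06a67f550065027")
})

test_that("SBML round-trips the network exactly", {
  m <- generate_toy_gem()
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f)
  expect_equal(m2$S, m$S)
  expect_equal(m2$lb, m$lb)
  expect_equal(m2$ub, m$ub)
  expect_equal(m2$obj, m$obj)
  expect_identical(m2$rxns, m$rxns)
  expect_identical(m2$biomass_id, m$biomass_id)
  expect_identical(m2$levansucrase_id, m$levansucrase_id)
  # write the read-back model again: byte-identical documents
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("the packaged SBML fixture file loads to the generated network", {
  f <- system.file("extdata", "toy_network_sbml.xml", package = "levansim")
  expect_true(nzchar(f))
  m <- read_sbml(f)
  ref <- generate_toy_gem()
  expect_equal(m$S, ref$S)
  expect_equal(m$lb, ref$lb)
  expect_identical(m$levansucrase_id, ref$levansucrase_id)
})

test_that("a missing designated reaction is reported with candidates", {
  m <- generate_toy_gem(augmented = FALSE)
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  expect_error(read_sbml(f, designations = list(biomass = "BIOMASS",
                                                uptake = "EX_suc",
                                                levansucrase = "LVS_SYN")),
               "LVS_SYN")
  expect_error(read_sbml("no/such/file.xml"), "not found")
})

test_that("augmentation adds the configured drain and inverts cleanly", {
  m0 <- generate_toy_gem(augmented = FALSE)
  m1 <- augment_levansucrase(m0, composition = c(aa = -2, atp = -1))
  # one mmol of synthesis drains exactly the configured stoichiometry
  col <- m1$S[, "LVS_SYN"]
  expect_equal(col[["aa"]], -2)
  expect_equal(col[["atp"]], -1)
  expect_equal(col[["lvs"]], 1)
  expect_equal(sum(col != 0), 3)
  # augment then delete restores the original at the id level
  m2 <- deaugment_levansucrase(m1)
  expect_equal(m2$S, m0$S)
  expect_identical(m2$rxns, m0$rxns)
  expect_equal(m2$lb, m0$lb)
  # double augmentation and unknown metabolites are rejected
  expect_error(augment_levansucrase(m1), "already")
  expect_error(augment_levansucrase(m0, composition = c(thr = -1)), "thr")
  expect_error(augment_levansucrase(m0, composition = c(aa = 2)), "negative")
})

test_that("coupling fixes biomass, uptake and enzyme fluxes as equalities", {
  p <- presets$transition
  # saturating sucrose: mu ~ mu_max = 0.2454, uptake = mu / 0.015 ~ 16.36
  cc <- coupling_constraints(p, S_reactor = 1e9)
  expect_equal(cc$mu_Monod, 0.2454, tolerance = 1e-6)
  expect_equal(cc$sucrose_uptake_flux, 16.36, tolerance = 1e-3)
  m <- generate_toy_gem()
  cm <- apply_coupling(m, cc)
  sol <- solve_min_total_flux(cm)
  expect_equal(sol$flux[sol$reaction == "BIOMASS"], cc$mu_Monod,
               tolerance = 1e-9)
  expect_equal(sol$flux[sol$reaction == "EX_suc"], cc$sucrose_uptake_flux,
               tolerance = 1e-9)
  expect_equal(sol$flux[sol$reaction == "LVS_SYN"],
               cc$alpha * cc$mu_Monod / cc$levansucrase_MW, tolerance = 1e-12)
})

test_that("zero growth pins biomass and levansucrase fluxes at zero", {
  cc <- coupling_constraints(presets$low, S_reactor = 0)
  expect_equal(cc$mu_Monod, 0)
  m <- generate_toy_gem()
  cm <- apply_coupling(m, cc)
  sol <- solve_min_total_flux(cm)
  expect_true(all(abs(sol$flux) < 1e-12))
})

test_that("an infeasible coupling names the binding constraint", {
  m <- generate_toy_gem()
  m$ub["UPT"] <- 0.01  # starve the network so the uptake pin cannot be met
  cc <- coupling_constraints(presets$transition, S_reactor = 1e9)
  expect_error(apply_coupling(m, cc), "binding constraint: '(EX_suc|BIOMASS)'")
})

test_that("minimal total flux on a chain equals its length times the demand", {
  sol <- solve_min_total_flux(chain_model(uptake = 1))
  expect_equal(sol$flux, rep(1, 4))
  expect_equal(attr(sol, "total_flux"), 4)
})

test_that("parsimonious FBA routes demand through the shorter branch", {
  # A -> C via one reaction or via two; both satisfy the same demand
  S <- matrix(c(1, 0, 0,
                -1, 0, 1,
                -1, 1, 0,
                0, -1, 1,
                0, 0, -1),
              nrow = 3, dimnames = list(c("A", "B", "C"),
                                        c("EX_A", "SHORT", "L1", "L2", "EX_C")))
  m <- stoich_model(S, lb = c(1, 0, 0, 0, 0), ub = c(1, 10, 10, 10, 10),
                    biomass_id = "EX_C", uptake_id = "EX_A")
  sol <- solve_min_total_flux(m)
  v <- setNames(sol$flux, sol$reaction)
  expect_equal(v[["SHORT"]], 1)
  expect_equal(v[["L1"]], 0)
  expect_equal(v[["L2"]], 0)
  # independent check: enumeration of the two basic routings
  expect_equal(attr(sol, "total_flux"), enumerate_min_total_flux(m))
})

test_that("contradictory equality bounds are reported as infeasible", {
  m <- chain_model(uptake = 1)
  m$lb["EX_C"] <- m$ub["EX_C"] <- 2
  expect_error(solve_min_total_flux(m), "infeasible")
})

test_that("flux-sums match the half-sum definition and normalise to uptake", {
  sol <- solve_min_total_flux(chain_model(uptake = 1))
  fs <- flux_sum(sol)
  expect_equal(fs$flux_sum[fs$metabolite == "B"], 1)
  expect_equal(fs$flux_sum_normalized[fs$metabolite == "A"], 1)
  # random bounded network solution vs direct half-sum recomputation
  m <- generate_toy_gem()
  cc <- coupling_constraints(presets$low, S_reactor = 500)
  sol2 <- solve_min_total_flux(apply_coupling(m, cc))
  fs2 <- flux_sum(sol2, normalize = FALSE)
  v <- setNames(sol2$flux, sol2$reaction)[m$rxns]
  manual <- 0.5 * apply(abs(m$S %*% diag(v)), 1, sum)
  expect_equal(fs2$flux_sum, unname(manual))
  # zero uptake cannot be normalised
  m0 <- chain_model(uptake = 0)
  s0 <- solve_min_total_flux(m0)
  expect_error(flux_sum(s0), "zero")
})

test_that("activity classes reproduce the four canonical patterns", {
  mk <- function(fluxes) {
    tibble::tibble(reaction = paste0("R", seq_along(fluxes)), flux = fluxes)
  }
  sols <- list(low = mk(c(1e-7, 0.5, 0.5, 0, 0.3)),
               transition = mk(c(1e-8, 0.5, 0, 0.4, 0)),
               high = mk(c(0, 0.5, 0, 0.4, 0.3)))
  cls <- classify_activity(sols, threshold = 1e-6)
  expect_equal(cls$category,
               c("inactive_all", "active_all", "active_low_only",
                 "active_transition_high", "other"))
  # threshold semantics: magnitudes strictly below it are inactive
  expect_false(cls$active_low[1])
  expect_error(classify_activity(sols[c("low", "high")]), "low")
  sols$high <- mk(c(0.1, 0.1))
  expect_error(classify_activity(sols), "mismatched")
})
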