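#' Specific growth rate (Monod kinetics)
#'
#' `mu = mu_max * S / (Ks + S)`: saturable dependence of growth on the
#' reactor sucrose concentration.
#'
#' @param p a [kinetic_params()] object.
#' @param S_reactor reactor sucrose concentration, mM (vectorised).
#' @return Specific growth rate, 1/h.
#' @export
growth_rate <- function(p, S_reactor) {
  check_nonneg(S_reactor, "S_reactor")
  p$mu_max * S_reactor / (p$Ks + S_reactor)
}

#' Specific sucrose hydrolysis rate of levansucrase
#'
#' Single-substrate Michaelis--Menten in reactor sucrose, bounded above by
#' `vmax_hyd`. Units: mmol sucrose per mg levansucrase per h.
#'
#' @inheritParams growth_rate
#' @return Specific rate, mmol/(mg h).
#' @export
hydrolysis_rate <- function(p, S_reactor) {
  check_nonneg(S_reactor, "S_reactor")
  p$vmax_hyd * S_reactor / (p$KM_hyd + S_reactor)
}

#' Specific transfructosylation rate of levansucrase
#'
#' Two-term rate with sucrose as the fructosyl donor and free fructose as
#' an additional acceptor:
#' `(vmax1*S/KM1 + vmax2*F*S/KM2) / (1 + S/KM1 + F*S/KM2)`.
#' With `F = 0` it reduces to single-substrate Michaelis--Menten in S.
#'
#' @inheritParams growth_rate
#' @param Fru free fructose concentration, mM (vectorised).
#' @return Specific rate, mmol/(mg h).
#' @export
transfructosylation_rate <- function(p, S_reactor, Fru) {
  check_nonneg(S_reactor, "S_reactor")
  check_nonneg(Fru, "Fru")
  d1 <- S_reactor / p$KM_trans1
  d2 <- Fru * S_reactor / p$KM_trans2
  (p$vmax_trans1 * d1 + p$vmax_trans2 * d2) / (1 + d1 + d2)
}

#' Specific levan degradation rate of levansucrase
#'
#' Michaelis--Menten in the degradable levan pool
#' `L* = Levan - dfc * Levan` (by default 67% of the polymer), gated by a
#' Heaviside step at `t_levdeg_onset`: the rate is identically zero before
#' the onset.
#'
#' @inheritParams growth_rate
#' @param Levan levan concentration, mM fructosyl equivalents (vectorised).
#' @param t time, h.
#' @return Specific rate, mmol/(mg h).
#' @export
levan_degradation_rate <- function(p, Levan, t) {
  check_nonneg(Levan, "Levan")
  check_nonneg(t, "t")
  Lstar <- (1 - p$degradable_fraction_complement) * Levan
  gate <- as.numeric(t >= p$t_levdeg_onset)
  gate * p$vmax_levdeg * Lstar / (p$KM_levdeg + Lstar)
}

check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(paste0("`", name, "` must be finite and >= 0"))
  }
  invisible(x)
}

#' Instantaneous rate vector at a state
#'
#' Evaluates mu, the growth-linked sucrose consumption v1 (mmol/(L h)),
#' the levansucrase synthesis rate v2 (mg/(L h)), the specific enzymatic
#' rates v3--v5 (mmol/(mg h)) and their volumetric equivalents after
#' multiplication by the enzyme pool `E_pool = alpha * X` (mmol/(L h)).
#'
#' @param state named numeric vector or one-row data frame with `X` (gDW/L),
#'   `Glc`, `Fru`, `S_reactor`, `Levan` (mM).
#' @param p a [kinetic_params()] object.
#' @param t time, h.
#' @return Named list with `mu`, `v1`, `v2`, `v3`, `v4`, `v5`,
#'   `v3_vol`, `v4_vol`, `v5_vol`, `E_pool`.
#' @export
rate_vector <- function(state, p, t) {
  s <- as.list(state)
  mu <- growth_rate(p, s$S_reactor)
  v1 <- mu * s$X / p$Y_XS
  v2 <- p$alpha * mu * s$X
  E_pool <- p$alpha * s$X
  v3 <- hydrolysis_rate(p, s$S_reactor)
  v4 <- transfructosylation_rate(p, s$S_reactor, s$Fru)
  v5 <- levan_degradation_rate(p, s$Levan, t)
  list(mu = mu, v1 = v1, v2 = v2, v3 = v3, v4 = v4, v5 = v5,
       v3_vol = v3 * E_pool, v4_vol = v4 * E_pool, v5_vol = v5 * E_pool,
       E_pool = E_pool)
}

#' Right-hand side of the fermentation ODE system
#'
#' State: biomass `X` (gDW/L), integrated levansucrase `E` (mg/L),
#' cumulative growth-consumed sucrose `S_cell` (mM, positive bookkeeping
#' integral of v1), and glucose, fructose, reactor sucrose and levan (mM).
#' The default (`equations = "pooled"`) multiplies all three specific
#' enzymatic rates by the enzyme pool `alpha * X`;
#' `equations = "as_printed"` leaves the hydrolysis rate without the
#' enzyme-pool factor, reproducing the literal published text for
#' comparison.
#'
#' @param t time, h.
#' @param state named numeric state vector
#'   (`X`, `E`, `S_cell`, `Glc`, `Fru`, `S_reactor`, `Levan`).
#' @param p a [kinetic_params()] object.
#' @param equations `"pooled"` (default) or `"as_printed"`.
#' @return List of the derivative vector and a named vector of rates,
#'   in the form deSolve expects.
#' @export
ode_rhs <- function(t, state, p, equations = c("pooled", "as_printed")) {
  equations <- match.arg(equations)
  if (any(!is.finite(state))) abort("non-finite state in ode_rhs")
  # numerical guard: adaptive steps may transiently undershoot zero
  S <- max(state[["S_reactor"]], 0)
  Fr <- max(state[["Fru"]], 0)
  L <- max(state[["Levan"]], 0)
  X <- state[["X"]]

  mu <- p$mu_max * S / (p$Ks + S)
  v1 <- mu * X / p$Y_XS
  E_pool <- p$alpha * X
  v3 <- p$vmax_hyd * S / (p$KM_hyd + S)
  d1 <- S / p$KM_trans1
  d2 <- Fr * S / p$KM_trans2
  v4 <- (p$vmax_trans1 * d1 + p$vmax_trans2 * d2) / (1 + d1 + d2)
  Lstar <- (1 - p$degradable_fraction_complement) * L
  H <- as.numeric(t >= p$t_levdeg_onset)
  v5 <- H * p$vmax_levdeg * Lstar / (p$KM_levdeg + Lstar)

  v3_term <- if (equations == "pooled") v3 * E_pool else v3
  dX <- (mu - p$kd) * X
  dE <- p$alpha * mu * X
  dS_cell <- v1
  dGlc <- v3_term + v4 * E_pool
  dFru <- v3_term + (-v4 + v5) * E_pool
  dLevan <- (v4 - v5) * E_pool
  dS_reactor <- -v1 - v3_term - v4 * E_pool

  list(c(X = dX, E = dE, S_cell = dS_cell, Glc = dGlc, Fru = dFru,
         S_reactor = dS_reactor, Levan = dLevan),
       c(mu = mu, v1 = v1, v2 = dE, v3 = v3, v4 = v4, v5 = v5,
         v3_vol = v3 * E_pool, v4_vol = v4 * E_pool, v5_vol = v5 * E_pool,
         E_pool = E_pool))
}
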