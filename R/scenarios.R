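#' Hydrolysis-to-transfructosylation ratio of a trajectory
#'
#' Instantaneous ratio of the volumetric hydrolysis and
#' transfructosylation rates, `v3_vol / v4_vol`. Points where the
#' transfructosylation rate is zero are masked (`NA`), not interpolated.
#'
#' @param traj a `levan_trajectory`.
#' @return Tibble (`time`, `ht`).
#' @export
ht_ratio <- function(traj) {
  stopifnot(inherits(traj, "levan_trajectory"))
  tibble(time = traj$time,
         ht = ifelse(traj$v4_vol > 0, traj$v3_vol / traj$v4_vol, NA_real_))
}

#' Conversion-weighted average H/T ratio
#'
#' Summarises a trajectory's hydrolysis/transfructosylation balance as the
#' ratio of cumulative fluxes, `integral(v3_vol) / integral(v4_vol)`
#' (trapezoidal). This weights the instantaneous ratio by conversion
#' activity, so the numerically degenerate tail after sucrose exhaustion
#' (where both rates vanish but their ratio stays finite) does not
#' dominate the average.
#'
#' @param traj a `levan_trajectory`.
#' @return Scalar average H/T ratio.
#' @export
ht_average <- function(traj) {
  stopifnot(inherits(traj, "levan_trajectory"))
  cumH <- trapz(traj$time, traj$v3_vol)
  cumT <- trapz(traj$time, traj$v4_vol)
  if (cumT <= 0) return(NA_real_)
  cumH / cumT
}

trapz <- function(x, y) sum(0.5 * (y[-1] + head(y, -1)) * diff(x))

#' Levansucrase-yield (alpha) perturbation sweep
#'
#' Re-simulates the batch model at each supplied enzyme yield, all else
#' equal, and summarises levan output, biomass and the H/T balance —
#' the in-silico analogue of down-/up-regulating the levansucrase gene.
#'
#' @param p baseline [kinetic_params()].
#' @param initial_sucrose condition, g/L.
#' @param alphas levansucrase yields to sweep, mg/gDW.
#' @param ... passed to [simulate_batch()].
#' @return A `levan_scenario` object: `summary` tibble (`alpha`,
#'   `max_levan`, `max_biomass`, `ht_average`, plus fold changes vs the
#'   baseline alpha) and `trajectories` (named list).
#' @export
run_alpha_perturbation <- function(p, initial_sucrose,
                                   alphas = c(22.5, 45, 184.1), ...) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(alphas <= 0)) abort("alphas must be > 0")
  trajs <- lapply(alphas, function(a) {
    pp <- p
    pp$alpha <- a
    simulate_batch(pp, initial_sucrose, ...)
  })
  names(trajs) <- paste0("alpha_", alphas)
  summ <- dplyr::bind_rows(lapply(seq_along(alphas), function(i) {
    tr <- trajs[[i]]
    tibble(alpha = alphas[i],
           max_levan = max(mM_to_gL(tr$Levan, "levan")),
           max_biomass = max(tr$X),
           max_levansucrase = max(tr$E),
           ht_average = ht_average(tr))
  }))
  base_lev <- summ$max_levan[which.min(abs(summ$alpha - p$alpha))]
  if (length(base_lev) && base_lev > 0) {
    summ$levan_fold_vs_base <- summ$max_levan / base_lev
  }
  structure(list(scenario = "alpha_perturbation",
                 inputs = list(alphas = alphas,
                               initial_sucrose = initial_sucrose),
                 summary = summ, trajectories = trajs),
            class = "levan_scenario")
}

#' @export
print.levan_scenario <- function(x, ...) {
  cat("<levan_scenario>", x$scenario, "\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' Plot an alpha-perturbation scenario
#'
#' @param object a `levan_scenario` from [run_alpha_perturbation()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.levan_scenario <- function(object, ...) {
  if (is.null(object$trajectories)) {
    abort("this scenario has no trajectories to plot")
  }
  df <- dplyr::bind_rows(lapply(names(object$trajectories), function(nm) {
    out <- trajectory_to_gL(object$trajectories[[nm]])
    out$run <- nm
    out
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$run)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time [h]", y = "concentration [g/L]", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Amino-acid supplementation scenario
#'
#' Switches the objective to maximising levansucrase synthesis (the growth
#' equality is replaced by a lower bound at a configured fraction of the
#' coupled growth rate, avoiding the degenerate zero-growth optimum),
#' solves the baseline (closed supplement exchange) and the supplemented
#' model, and reports the fold change of the levansucrase and biomass
#' fluxes.
#'
#' @param m a coupled-ready `stoich_model` (designations set).
#' @param cc [coupling_constraints()].
#' @param exchange_id supplement exchange reaction id.
#' @param supply_bound upper bound opened on the supplement exchange,
#'   mmol/(gDW h).
#' @param growth_floor_frac growth lower bound as a fraction of the
#'   coupled growth rate (default 0.5).
#' @return A `levan_scenario` with a one-row `summary`
#'   (`levansucrase_fold`, `biomass_fold`, baseline and supplemented
#'   fluxes) and both `flux_solution`s.
#' @export
run_supplementation <- function(m, cc, exchange_id, supply_bound,
                                growth_floor_frac = 0.5) {
  stopifnot(inherits(m, "stoich_model"), inherits(cc, "coupling_constraints"))
  if (!exchange_id %in% m$rxns) {
    abort(paste0("exchange '", exchange_id, "' not found"))
  }
  if (supply_bound < 0) abort("supply_bound must be >= 0")
  base <- apply_coupling(m, cc, probe = FALSE)
  # free the enzyme flux (it becomes the objective) and floor the growth
  base$lb[m$levansucrase_id] <- 0
  base$ub[m$levansucrase_id] <- 1000
  base$lb[m$biomass_id] <- growth_floor_frac * cc$mu_Monod
  base$ub[m$biomass_id] <- 1000

  supp <- base
  supp$ub[exchange_id] <- max(supp$ub[exchange_id], supply_bound)

  sol0 <- maximize_flux(base, m$levansucrase_id)
  sol1 <- maximize_flux(supp, m$levansucrase_id)
  f0 <- sol0$flux[sol0$reaction == m$levansucrase_id]
  f1 <- sol1$flux[sol1$reaction == m$levansucrase_id]
  b0 <- sol0$flux[sol0$reaction == m$biomass_id]
  b1 <- sol1$flux[sol1$reaction == m$biomass_id]
  if (f0 <= 0) abort("baseline levansucrase flux is zero: fold change undefined")
  structure(list(scenario = "supplementation",
                 inputs = list(exchange_id = exchange_id,
                               supply_bound = supply_bound,
                               growth_floor_frac = growth_floor_frac),
                 summary = tibble(levansucrase_flux_base = f0,
                                  levansucrase_flux_suppl = f1,
                                  biomass_flux_base = b0,
                                  biomass_flux_suppl = b1,
                                  levansucrase_fold = f1 / f0,
                                  biomass_fold = b1 / max(b0, 1e-12)),
                 solutions = list(baseline = sol0, supplemented = sol1)),
            class = "levan_scenario")
}

#' Reaction knockdown scenario
#'
#' Caps one reaction's flux, re-solves the minimal-total-flux problem and
#' reports per-reaction flux deltas with a branch-point redirection flag
#' (increased / decreased / unchanged at the activity threshold).
#'
#' @param m a `stoich_model` with coupling-ready designations.
#' @param cc [coupling_constraints()].
#' @param reaction_id reaction to knock down.
#' @param new_upper_bound flux cap, mmol/(gDW h); 0 is a knockout.
#' @param threshold redirection threshold, mmol/(gDW h).
#' @return A `levan_scenario` with `summary` = per-reaction tibble
#'   (`reaction`, `flux_base`, `flux_kd`, `delta`, `change`) and both
#'   solutions; attribute-level totals in `inputs`.
#' @export
run_knockdown <- function(m, cc, reaction_id, new_upper_bound,
                          threshold = 1e-6) {
  stopifnot(inherits(m, "stoich_model"))
  if (!reaction_id %in% m$rxns) {
    abort(paste0("reaction '", reaction_id, "' not found"))
  }
  if (new_upper_bound < 0) abort("new_upper_bound must be >= 0")
  base_m <- apply_coupling(m, cc)
  sol0 <- solve_min_total_flux(base_m)
  kd_m <- base_m
  kd_m$ub[reaction_id] <- new_upper_bound
  kd_m$lb[reaction_id] <- min(kd_m$lb[reaction_id], new_upper_bound)
  sol1 <- solve_min_total_flux(kd_m)
  delta <- sol1$flux - sol0$flux
  change <- ifelse(abs(delta) < threshold, "unchanged",
                   ifelse(delta > 0, "increased", "decreased"))
  structure(list(scenario = "knockdown",
                 inputs = list(reaction_id = reaction_id,
                               new_upper_bound = new_upper_bound,
                               total_flux_base = attr(sol0, "total_flux"),
                               total_flux_kd = attr(sol1, "total_flux")),
                 summary = tibble(reaction = sol0$reaction,
                                  flux_base = sol0$flux, flux_kd = sol1$flux,
                                  delta = delta, change = change),
                 solutions = list(baseline = sol0, knockdown = sol1)),
            class = "levan_scenario")
}
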