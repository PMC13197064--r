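#' Coupling constraints from the dynamic model
#'
#' Evaluates the three linker quantities passed from the kinetic model to
#' the stoichiometric model at a snapshot time (default 9 h,
#' mid-exponential phase): the Monod growth rate, the specific sucrose
#' uptake flux `mu / Y_XS` (mmol/(gDW h)), and the levansucrase yield
#' `alpha` (mg/gDW). The enzyme-yield equality needs a molar conversion;
#' the levansucrase molecular weight (default 53,000 mg/mmol, a
#' SacB-class protein) is configurable since no conversion is published.
#'
#' @param p a [kinetic_params()] object.
#' @param traj optional `levan_trajectory` from which the snapshot sucrose
#'   concentration is read; if omitted, `S_reactor` must be given.
#' @param snapshot_time snapshot, h.
#' @param S_reactor reactor sucrose at the snapshot, mM (used when no
#'   trajectory is supplied).
#' @param levansucrase_MW molecular weight, mg/mmol.
#' @return An object of class `coupling_constraints` with fields
#'   `mu_Monod`, `sucrose_uptake_flux`, `alpha`, `levansucrase_MW`,
#'   `snapshot_time`.
#' @export
coupling_constraints <- function(p, traj = NULL, snapshot_time = 9,
                                 S_reactor = NULL, levansucrase_MW = 53000) {
  stopifnot(inherits(p, "kinetic_params"))
  if (levansucrase_MW <= 0) abort("levansucrase_MW must be > 0")
  if (is.null(S_reactor)) {
    if (is.null(traj)) abort("supply a trajectory or S_reactor")
    S_reactor <- approx(traj$time, traj$S_reactor, xout = snapshot_time,
                        rule = 2)$y
  }
  mu <- growth_rate(p, S_reactor)
  structure(list(mu_Monod = mu,
                 sucrose_uptake_flux = mu / p$Y_XS,
                 alpha = p$alpha,
                 levansucrase_MW = levansucrase_MW,
                 snapshot_time = snapshot_time),
            class = "coupling_constraints")
}

#' @export
print.coupling_constraints <- function(x, ...) {
  cat(sprintf(paste0("<coupling_constraints> t = %g h: mu = %.4g 1/h, ",
                     "uptake = %.4g mmol/(gDW h), alpha = %.4g mg/gDW\n"),
              x$snapshot_time, x$mu_Monod, x$sucrose_uptake_flux, x$alpha))
  invisible(x)
}

#' Inject the coupling constraints into a stoichiometric model
#'
#' Fixes the biomass flux to the Monod growth rate, the sucrose uptake
#' flux to `mu / Y_XS`, and the levansucrase synthesis flux to
#' `alpha * mu / MW` (mmol/(gDW h)). Constraints are fixed bounds
#' (lb = ub) by default; `relax = TRUE` applies them as upper bounds only,
#' for feasibility diagnosis.
#'
#' @param m a [stoich_model()] with designated reactions (including the
#'   levansucrase synthesis pseudo-reaction).
#' @param cc a [coupling_constraints()] object.
#' @param relax apply as `<=` bounds instead of equalities.
#' @param probe if `TRUE` (default) check feasibility of the coupled model
#'   and report the binding constraint on failure.
#' @return The constrained `stoich_model`.
#' @export
apply_coupling <- function(m, cc, relax = FALSE, probe = TRUE) {
  stopifnot(inherits(m, "stoich_model"), inherits(cc, "coupling_constraints"))
  if (is.na(m$levansucrase_id)) {
    abort("model lacks a levansucrase synthesis reaction; augment it first")
  }
  lvs_flux <- cc$alpha * cc$mu_Monod / cc$levansucrase_MW
  targets <- c(setNames(cc$mu_Monod, m$biomass_id),
               setNames(cc$sucrose_uptake_flux, m$uptake_id),
               setNames(lvs_flux, m$levansucrase_id))
  m2 <- m
  for (id in names(targets)) {
    m2$ub[id] <- targets[[id]]
    m2$lb[id] <- if (relax) 0 else targets[[id]]
  }
  if (probe && !relax) {
    if (!fba_feasible(m2)) {
      # pin each constraint alone on the unconstrained model: the first one
      # the network cannot satisfy by itself is the binding constraint
      for (id in names(targets)) {
        malone <- m
        malone$lb[id] <- malone$ub[id] <- targets[[id]]
        if (!fba_feasible(malone)) {
          abort(paste0("coupled model infeasible; binding constraint: '",
                       id, "' fixed at ", signif(targets[[id]], 6)))
        }
      }
      abort(paste0("coupled model infeasible; the constraints are jointly ",
                   "binding (each is satisfiable alone)"))
    }
  }
  m2
}

# --- LP machinery ----------------------------------------------------------

# Split reversible reactions into irreversible forward/backward pairs.
split_irreversible <- function(m) {
  fwd_ub <- pmax(m$ub, 0)
  fwd_lb <- pmax(m$lb, 0)
  rev_idx <- which(m$lb < 0)
  S <- m$S
  Ssp <- cbind(S, -S[, rev_idx, drop = FALSE])
  back_ub <- -pmin(m$lb[rev_idx], 0)
  back_lb <- pmax(-m$ub[rev_idx], 0)
  list(S = Ssp,
       lb = c(fwd_lb, back_lb), ub = c(fwd_ub, back_ub),
       n_fwd = ncol(S), rev_idx = rev_idx,
       names = c(m$rxns, if (length(rev_idx)) paste0(m$rxns[rev_idx], "__rev")))
}

# Dense two-phase primal simplex with Bland's anti-cycling rule:
# min c'x s.t. A x = b, x >= 0. Flux-balance problems are small here
# (tens of variables) but routinely degenerate (b = 0, pinned fluxes), so
# Bland's rule matters.
lp_simplex <- function(cvec, A, b, tol = 1e-9, max_iter = 10000) {
  m <- nrow(A)
  n <- ncol(A)
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  Tb <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)

  run_phase <- function(Tb, basis, cost, allowed) {
    for (it in seq_len(max_iter)) {
      cb <- cost[basis]
      red <- cost[allowed] - as.vector(crossprod(cb, Tb[, allowed, drop = FALSE]))
      ent <- allowed[red < -tol]
      if (!length(ent)) return(list(Tb = Tb, basis = basis, status = "optimal"))
      j <- min(ent)  # Bland: smallest eligible index
      col <- Tb[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(status = "unbounded"))
      ratios <- Tb[pos, ncol(Tb)] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + tol]
      r <- cand[which.min(basis[cand])]  # Bland tie-break on leaving index
      Tb[r, ] <- Tb[r, ] / Tb[r, j]
      other <- setdiff(seq_len(m), r)
      Tb[other, ] <- Tb[other, , drop = FALSE] -
        outer(Tb[other, j], Tb[r, ])
      basis[r] <- j
    }
    list(status = "iteration_limit")
  }

  # phase 1: drive the artificial variables out
  ph1 <- run_phase(Tb, basis, c(rep(0, n), rep(1, m)), seq_len(n + m))
  if (!identical(ph1$status, "optimal")) return(list(status = ph1$status))
  Tb <- ph1$Tb
  basis <- ph1$basis
  if (sum(Tb[basis > n, ncol(Tb)]) > 1e-7) return(list(status = "infeasible"))
  drop_rows <- integer(0)
  for (r in which(basis > n)) {
    piv <- which(abs(Tb[r, seq_len(n)]) > tol)
    if (length(piv)) {
      j <- piv[1]
      Tb[r, ] <- Tb[r, ] / Tb[r, j]
      other <- setdiff(seq_len(m), r)
      Tb[other, ] <- Tb[other, , drop = FALSE] - outer(Tb[other, j], Tb[r, ])
      basis[r] <- j
    } else {
      drop_rows <- c(drop_rows, r)  # redundant constraint
    }
  }
  if (length(drop_rows)) {
    Tb <- Tb[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
    m <- nrow(Tb)
  }

  ph2 <- run_phase(Tb, basis, c(cvec, rep(0, length(ph1$basis))), seq_len(n))
  if (!identical(ph2$status, "optimal")) return(list(status = ph2$status))
  x <- numeric(n)
  real <- ph2$basis <= n
  x[ph2$basis[real]] <- ph2$Tb[real, ncol(ph2$Tb)]
  list(status = "optimal", x = x, value = sum(cvec * x))
}

# Solve min/max c'v s.t. S v = 0, lb <= v <= ub over the split variables.
# Lower bounds are shifted out (v = lb + y), upper bounds become explicit
# slack rows, pinned fluxes (lb == ub) are substituted into the RHS.
solve_lp_split <- function(sp, objective, maximise = FALSE) {
  n <- ncol(sp$S)
  lb <- unname(sp$lb)
  ub <- unname(sp$ub)
  fixed <- which(abs(ub - lb) < 1e-12)
  free <- setdiff(seq_len(n), fixed)
  nf <- length(free)
  # metabolite rows in the shifted variables y = v_free - lb_free:
  # S_free y = -S lb  (pinned fluxes sit at lb == ub)
  A <- sp$S[, free, drop = FALSE]
  b <- -as.vector(sp$S %*% lb)
  # slack rows y_i + s_i = ub_i - lb_i
  span <- ub[free] - lb[free]
  A_full <- rbind(cbind(A, matrix(0, nrow(A), nf)),
                  cbind(diag(nf), diag(nf)))
  b_full <- c(b, span)
  sign <- if (maximise) -1 else 1
  cvec <- c(sign * objective[free], rep(0, nf))
  res <- lp_simplex(cvec, A_full, b_full)
  if (res$status != "optimal") return(list(status = res$status))
  v <- lb
  v[free] <- lb[free] + res$x[seq_len(nf)]
  list(status = "optimal", v = v,
       value = sum(objective * v))
}

fba_feasible <- function(m) {
  sp <- split_irreversible(m)
  out <- solve_lp_split(sp, rep(1, ncol(sp$S)))
  identical(out$status, "optimal")
}

recombine_fluxes <- function(sp, v) {
  net <- v[seq_len(sp$n_fwd)]
  if (length(sp$rev_idx)) {
    net[sp$rev_idx] <- net[sp$rev_idx] - v[sp$n_fwd + seq_along(sp$rev_idx)]
  }
  net
}

#' Minimal-total-flux (parsimonious) flux distribution
#'
#' Converts all reversible reactions to irreversible forward/backward
#' pairs, minimises the total flux `sum_j |flux_j|` over the split
#' variables subject to the steady-state constraint `S v = 0` and the flux
#' bounds, and recombines to net fluxes.
#'
#' @param m a `stoich_model` (typically after [apply_coupling()]).
#' @return A `flux_solution`: tibble (`reaction`, `flux`) with attributes
#'   `total_flux`, `status`, `model`.
#' @export
solve_min_total_flux <- function(m) {
  stopifnot(inherits(m, "stoich_model"))
  sp <- split_irreversible(m)
  out <- solve_lp_split(sp, rep(1, ncol(sp$S)))
  if (out$status == "infeasible") {
    abort("minimal-total-flux problem is infeasible under the given bounds")
  }
  if (out$status != "optimal") {
    abort("LP did not converge (iteration limit)")
  }
  net <- recombine_fluxes(sp, out$v)
  resid <- max(abs(m$S %*% net))
  if (resid > 1e-9) {
    abort(sprintf("steady-state violation %.3g exceeds 1e-9", resid))
  }
  sol <- tibble(reaction = m$rxns, flux = net)
  structure(sol, class = c("flux_solution", class(sol)),
            total_flux = sum(out$v), status = "optimal", model = m)
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> total |flux| = %.6g (%s)\n",
              attr(x, "total_flux"), attr(x, "status")))
  NextMethod()
}

#' Maximise a single reaction's flux
#'
#' Linear FBA with the objective placed on one reaction.
#'
#' @param m a `stoich_model`.
#' @param reaction_id reaction to maximise.
#' @return A `flux_solution` with attribute `objective_value`.
#' @export
maximize_flux <- function(m, reaction_id) {
  stopifnot(inherits(m, "stoich_model"))
  if (!reaction_id %in% m$rxns) abort(paste0("reaction '", reaction_id,
                                             "' not found"))
  sp <- split_irreversible(m)
  objective <- as.numeric(sp$names == reaction_id)
  if (reaction_id %in% m$rxns[sp$rev_idx]) {
    objective[sp$names == paste0(reaction_id, "__rev")] <- -1
  }
  out <- solve_lp_split(sp, objective, maximise = TRUE)
  if (out$status != "optimal") abort(paste0("FBA ", out$status))
  net <- recombine_fluxes(sp, out$v)
  sol <- tibble(reaction = m$rxns, flux = net)
  structure(sol, class = c("flux_solution", class(sol)),
            total_flux = sum(abs(net)), status = "optimal", model = m,
            objective_value = out$value)
}

#' Flux-sum turnover per metabolite
#'
#' The flux-sum of metabolite i is half the stoichiometry-weighted sum of
#' absolute fluxes around it, `Phi_i = 0.5 * sum_j |S_ij * v_j|`; the
#' normalised variant divides by the sucrose uptake flux so turnovers are
#' comparable across conditions.
#'
#' @param sol a `flux_solution`.
#' @param m the `stoich_model` the solution was computed on (defaults to
#'   the model stored in the solution).
#' @param normalize divide by the sucrose uptake flux (default `TRUE`).
#' @return Tibble (`metabolite`, `flux_sum`, and `flux_sum_normalized` if
#'   requested).
#' @export
flux_sum <- function(sol, m = attr(sol, "model"), normalize = TRUE) {
  stopifnot(inherits(sol, "flux_solution"), inherits(m, "stoich_model"))
  v <- setNames(sol$flux, sol$reaction)[m$rxns]
  phi <- 0.5 * rowSums(abs(m$S * rep(v, each = nrow(m$S))))
  out <- tibble(metabolite = m$mets, flux_sum = unname(phi))
  if (normalize) {
    upt <- abs(v[[m$uptake_id]])
    if (upt <= 0) abort("sucrose uptake flux is zero: cannot normalise")
    out$flux_sum_normalized <- out$flux_sum / upt
  }
  out
}

#' Classify reaction activity across sucrose regimes
#'
#' A reaction is inactive in a condition when `|flux| < threshold`
#' (default 1e-6 mmol/(gDW h)). Categories follow the four canonical
#' patterns: (i) active in all conditions, (ii) active only at low,
#' (iii) active at transition and high, (iv) inactive everywhere; any
#' other pattern is labelled `"other"`.
#'
#' @param solutions named list of `flux_solution`s with elements `low`,
#'   `transition`, `high`.
#' @param threshold activity threshold, mmol/(gDW h).
#' @return Tibble (`reaction`, `active_low`, `active_transition`,
#'   `active_high`, `category`).
#' @export
classify_activity <- function(solutions, threshold = 1e-6) {
  need <- c("low", "transition", "high")
  if (!all(need %in% names(solutions))) {
    abort("solutions must be a named list with low, transition, high")
  }
  rxns <- solutions$low$reaction
  for (s in need) {
    if (!identical(sort(solutions[[s]]$reaction), sort(rxns))) {
      abort("mismatched reaction sets across conditions")
    }
  }
  act <- vapply(need, function(s) {
    v <- setNames(solutions[[s]]$flux, solutions[[s]]$reaction)[rxns]
    abs(v) >= threshold
  }, logical(length(rxns)))
  category <- apply(act, 1, function(a) {
    if (all(a)) "active_all"
    else if (a[1] && !a[2] && !a[3]) "active_low_only"
    else if (!a[1] && a[2] && a[3]) "active_transition_high"
    else if (!any(a)) "inactive_all"
    else "other"
  })
  tibble(reaction = rxns,
         active_low = unname(act[, "low"]),
         active_transition = unname(act[, "transition"]),
         active_high = unname(act[, "high"]),
         category = unname(category))
}
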