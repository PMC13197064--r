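#' Normalised root-mean-squared error
#'
#' `100 * RMSE / norm`, where the normaliser is by default the observed
#' range (`max(obs) - min(obs)`); mean- and max-normalised variants are
#' selectable. Expressed as a percentage.
#'
#' @param simulated,observed equal-length numeric series (>= 2 points).
#' @param normalization `"range"` (default), `"mean"` or `"max"`.
#' @param species optional label used in error messages.
#' @return NRMSE in percent.
#' @examples
#' nrmse(c(1, 11), c(0, 10)) # constant offset 1 over range 10 -> 10
#' @export
nrmse <- function(simulated, observed,
                  normalization = c("range", "mean", "max"),
                  species = "series") {
  normalization <- match.arg(normalization)
  if (length(simulated) != length(observed)) {
    abort("simulated and observed must have equal length")
  }
  if (length(observed) < 2) abort("need at least 2 points")
  norm <- switch(normalization,
                 range = diff(range(observed)),
                 mean = mean(observed),
                 max = max(observed))
  if (!is.finite(norm) || norm <= 0) {
    abort(paste0("zero or invalid ", normalization, " of observed series '",
                 species, "': NRMSE undefined"))
  }
  100 * sqrt(mean((simulated - observed)^2)) / norm
}

#' Per-species and condition-level NRMSE of a simulation against data
#'
#' @param traj a `levan_trajectory`.
#' @param obs observed time course in long format (`time`, `species`,
#'   `value`, measurement units), as produced by [generate_timecourses()].
#' @param normalization see [nrmse()].
#' @return Tibble with one row per species plus the unweighted average
#'   (`species == "average"`).
#' @export
nrmse_table <- function(traj, obs, normalization = "range") {
  sim <- trajectory_to_gL(traj)
  sp <- unique(obs$species)
  per <- vapply(sp, function(s) {
    o <- obs[obs$species == s, ]
    si <- sim[sim$species == s, ]
    sim_at <- approx(si$time, si$value, xout = o$time, rule = 2)$y
    nrmse(sim_at, o$value, normalization = normalization, species = s)
  }, numeric(1))
  tibble(species = c(sp, "average"),
         nrmse_pct = c(per, mean(per)))
}

#' Fit kinetic parameters to observed time courses
#'
#' Least-squares calibration of the batch model against one or more
#' observed time courses of a single regime. The objective is the sum of
#' squared errors over all species on the measurement grid, in measurement
#' units (g/L, gDW/L). Optimisation is bounded Levenberg--Marquardt
#' (`minpack.lm::nls.lm`) on log-transformed parameters (all fitted
#' parameters are strictly positive), with seeded multi-start.
#'
#' @param obs long-format observations: columns `condition` (g/L initial
#'   sucrose), `time`, `species`, `value`; optionally `replicate`.
#' @param p0 starting [kinetic_params()].
#' @param free character vector of parameter names to fit. Default frees
#'   the growth-side parameters and the degradation onset while holding the
#'   enzyme-activity constants fixed.
#' @param lower,upper named bound vectors for the free parameters (natural
#'   scale). Defaults: `p0/10` and `p0*10`.
#' @param n_starts number of multi-start runs (first start is `p0`).
#' @param seed master seed; start-specific seeds derive from it.
#' @param X0,horizon passed to [simulate_batch()].
#' @param rtol,atol solver tolerances used during fitting.
#' @return A `levan_fit` object: fitted parameter set, SSE, per-species
#'   NRMSE, convergence info. Has [tidy()] and [glance()] methods.
#' @export
fit_parameters <- function(obs, p0, free = c("mu_max", "Ks", "kd", "Y_XS",
                                             "alpha", "t_levdeg_onset"),
                           lower = NULL, upper = NULL,
                           n_starts = 10, seed = 1,
                           X0 = 0.05, horizon = 120,
                           rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(p0, "kinetic_params"))
  if (length(free) == 0) abort("free must name at least one parameter")
  if (nrow(obs) == 0) abort("no observations supplied")
  bad <- setdiff(free, setdiff(names(p0), "regime"))
  if (length(bad)) abort(paste("unknown parameters:", paste(bad, collapse = ", ")))

  start0 <- unlist(p0[free])
  if (is.null(lower)) lower <- start0 / 10
  if (is.null(upper)) upper <- start0 * 10
  lower <- pmax(lower[free], 1e-12)
  upper <- upper[free]
  if (any(!is.finite(c(lower, upper)))) abort("bounds must be finite")

  conds <- sort(unique(obs$condition))
  obs_split <- lapply(conds, function(cc) {
    o <- obs[obs$condition == cc, c("time", "species", "value")]
    dplyr::arrange(o, .data$species, .data$time)
  })

  residual_fun <- function(logpar) {
    pars <- exp(logpar)
    p <- p0
    p[free] <- as.list(pars)
    unlist(lapply(seq_along(conds), function(i) {
      tr <- tryCatch(
        simulate_batch(p, conds[i], X0 = X0, horizon = horizon,
                       report_times = sort(unique(obs_split[[i]]$time)),
                       rtol = rtol, atol = atol),
        error = function(e) NULL)
      o <- obs_split[[i]]
      if (is.null(tr)) return(rep(1e3, nrow(o)))
      sim <- trajectory_to_gL(tr)
      simw <- tidyr::pivot_wider(sim, names_from = "species",
                                 values_from = "value")
      sim_at <- mapply(function(tm, sp) {
        simw[[sp]][match(tm, simw$time)]
      }, o$time, o$species)
      sim_at - o$value
    }))
  }

  starts <- withr::with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      if (i == 1) return(log(start0))
      st <- log(start0) + rnorm(length(start0), 0, 0.3)
      pmin(pmax(st, log(lower)), log(upper))
    })
  })

  runs <- lapply(starts, function(st) {
    tryCatch(
      minpack.lm::nls.lm(par = st, fn = residual_fun,
                         lower = log(lower), upper = log(upper),
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0) {
    abort("all optimisation starts failed; check data and bounds")
  }
  sses <- vapply(runs, function(r) sum(r$fvec^2), numeric(1))
  best <- runs[[which.min(sses)]]

  fitted <- p0
  fitted[free] <- as.list(exp(best$par))
  fitted$regime <- p0$regime
  class(fitted) <- "kinetic_params"

  nr <- dplyr::bind_rows(lapply(seq_along(conds), function(i) {
    tr <- simulate_batch(fitted, conds[i], X0 = X0, horizon = horizon,
                         report_times = sort(unique(obs_split[[i]]$time)),
                         rtol = rtol, atol = atol)
    tab <- nrmse_table(tr, obs_split[[i]])
    tab$condition <- conds[i]
    tab
  }))

  structure(list(
    params = fitted, free = free,
    sse = min(sses),
    nrmse = nr,
    nrmse_average = mean(nr$nrmse_pct[nr$species == "average"]),
    n_iterations = best$niter,
    converged = best$info %in% 1:4,
    n_starts = n_starts,
    bounds = list(lower = lower, upper = upper),
    seed = seed,
    obs = obs
  ), class = "levan_fit")
}

#' @export
print.levan_fit <- function(x, ...) {
  cat(sprintf("<levan_fit> %d free parameter(s), SSE = %.4g, avg NRMSE = %.2f%%, %s\n",
              length(x$free), x$sse, x$nrmse_average,
              if (x$converged) "converged" else "NOT converged"))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.levan_fit <- function(x, ...) {
  tb <- tidy(x$params)
  tb$fitted <- tb$parameter %in% x$free
  tb
}

#' @exportS3Method generics::glance
glance.levan_fit <- function(x, ...) {
  tibble(sse = x$sse, nrmse_average_pct = x$nrmse_average,
         n_free = length(x$free), n_iterations = x$n_iterations,
         converged = x$converged, n_starts = x$n_starts, seed = x$seed)
}

#' Plot a fit against its calibration data
#'
#' @param object a `levan_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.levan_fit <- function(object, ...) {
  obs <- object$obs
  sims <- dplyr::bind_rows(lapply(unique(obs$condition), function(cc) {
    tr <- simulate_batch(object$params, cc,
                         report_times = seq(0, max(obs$time), by = 1))
    out <- trajectory_to_gL(tr)
    out$condition <- cc
    out
  }))
  ggplot2::ggplot(sims, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = obs, alpha = 0.6, size = 0.8) +
    ggplot2::facet_grid(species ~ condition, scales = "free_y") +
    ggplot2::labs(x = "time [h]", y = "concentration [g/L]") +
    ggplot2::theme_minimal()
}

#' Global sensitivity scan by parameter perturbation
#'
#' Perturbs each parameter by `+/- perturbation` (default 50%) holding the
#' others fixed, re-simulates, and reports the per-species NRMSE of the
#' perturbed trajectory against the baseline, ranking parameters by mean
#' deviation across species.
#'
#' @param p a [kinetic_params()] object.
#' @param initial_sucrose condition to simulate, g/L.
#' @param perturbation relative perturbation (0.5 = +/-50%).
#' @param parameters parameters to scan; defaults to all numeric ones.
#' @param ... passed to [simulate_batch()].
#' @return Tibble (`parameter`, `direction`, `species`, `nrmse_pct`,
#'   `failed`) with an attribute `ranking` (parameters ordered by mean
#'   deviation, most influential first).
#' @export
sensitivity_scan <- function(p, initial_sucrose, perturbation = 0.5,
                             parameters = NULL, ...) {
  stopifnot(inherits(p, "kinetic_params"))
  if (is.null(parameters)) {
    parameters <- setdiff(names(p), c("regime", "degradable_fraction_complement"))
  }
  base_tr <- simulate_batch(p, initial_sucrose, ...)
  base_gl <- trajectory_to_gL(base_tr)

  rows <- list()
  for (par in parameters) {
    for (dir in c(-1, 1)) {
      pp <- p
      pp[[par]] <- p[[par]] * (1 + dir * perturbation)
      label <- if (dir < 0) "minus" else "plus"
      res <- tryCatch({
        validate_kinetic_params(pp)
        tr <- simulate_batch(pp, initial_sucrose, ...)
        gl <- trajectory_to_gL(tr)
        sp <- unique(base_gl$species)
        vals <- vapply(sp, function(s) {
          b <- base_gl$value[base_gl$species == s]
          v <- gl$value[gl$species == s]
          if (diff(range(b)) <= 0) return(NA_real_)
          nrmse(v, b, species = s)
        }, numeric(1))
        tibble(parameter = par, direction = label, species = sp,
               nrmse_pct = vals, failed = FALSE)
      }, error = function(e) {
        tibble(parameter = par, direction = label, species = NA_character_,
               nrmse_pct = NA_real_, failed = TRUE)
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  rk <- out %>%
    dplyr::filter(!.data$failed) %>%
    dplyr::group_by(.data$parameter) %>%
    dplyr::summarise(mean_dev = mean(.data$nrmse_pct, na.rm = TRUE)) %>%
    dplyr::arrange(dplyr::desc(.data$mean_dev))
  attr(out, "ranking") <- rk
  out
}
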