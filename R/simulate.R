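#' Simulate a batch fermentation
#'
#' Integrates the fermentation ODE system from inoculation to `horizon`
#' with deSolve's `lsoda`. The Heaviside switch of levan degradation is
#' handled exactly by splitting the integration at `t_levdeg_onset`, so the
#' discontinuity never falls inside an adaptive step. States are reported in
#' mM (biomass in gDW/L, levansucrase in mg/L) together with the
#' instantaneous rate vector at each reported time.
#'
#' @param p a [kinetic_params()] object.
#' @param initial_sucrose initial sucrose concentration, g/L.
#' @param X0 inoculum biomass, gDW/L. Default 0.05.
#' @param horizon simulation horizon, h.
#' @param report_times times at which to report, h. Defaults to a 0.5 h
#'   grid over the horizon.
#' @param rtol,atol solver tolerances.
#' @param equations `"pooled"` or `"as_printed"`, see [ode_rhs()].
#' @param clip_tol negative undershoots smaller than this (mM) are clipped
#'   silently; larger undershoots are clipped with a warning.
#' @return A `levan_trajectory`: a tibble with columns `time`, the seven
#'   states, `mu`, `v1`..`v5`, `v3_vol`, `v4_vol`, `v5_vol`, `E_pool`, with
#'   the parameter set and condition stored as attributes.
#' @examples
#' tr <- simulate_batch(levan_presets()$low, initial_sucrose = 100)
#' summarize_production(tr, initial_sucrose = 100)
#' @export
simulate_batch <- function(p, initial_sucrose, X0 = 0.05, horizon = 120,
                           report_times = NULL,
                           rtol = 1e-8, atol = 1e-10,
                           equations = "pooled", clip_tol = 1e-6) {
  stopifnot(inherits(p, "kinetic_params"))
  if (initial_sucrose <= 0) abort("initial_sucrose must be > 0 (g/L)")
  if (horizon <= 0) abort("horizon must be > 0")
  if (rtol <= 0 || atol <= 0) abort("solver tolerances must be > 0")
  if (is.null(report_times)) report_times <- seq(0, horizon, by = 0.5)
  report_times <- sort(unique(report_times))
  if (min(report_times) < 0 || max(report_times) > horizon) {
    abort("report_times must lie within [0, horizon]")
  }

  y0 <- c(X = X0, E = 0, S_cell = 0, Glc = 0, Fru = 0,
          S_reactor = gL_to_mM(initial_sucrose, "sucrose"), Levan = 0)

  onset <- p$t_levdeg_onset
  segs <- if (onset > 0 && onset < horizon) {
    list(c(0, onset), c(onset, horizon))
  } else {
    list(c(0, horizon))
  }

  state <- y0
  rows <- list()
  for (seg in segs) {
    tt <- sort(unique(c(seg[1], report_times[report_times >= seg[1] &
                                               report_times <= seg[2]], seg[2])))
    out <- tryCatch(
      deSolve::lsoda(state, tt, func = ode_rhs, parms = p,
                     equations = equations, rtol = rtol, atol = atol),
      error = function(e) abort(paste0("ODE solver failed in segment [",
                                       seg[1], ", ", seg[2], "] h: ",
                                       conditionMessage(e)))
    )
    if (attr(out, "istate")[1] < 0) {
      abort(paste0("ODE solver did not complete segment [", seg[1], ", ",
                   seg[2], "] h; last valid time ", max(out[, "time"]), " h"))
    }
    state <- out[nrow(out), names(y0)]
    rows[[length(rows) + 1]] <- out
  }
  res <- do.call(rbind, lapply(rows, as.data.frame))
  res <- res[!duplicated(res$time), , drop = FALSE]
  res <- res[res$time %in% report_times, , drop = FALSE]

  conc <- c("S_cell", "Glc", "Fru", "S_reactor", "Levan", "X", "E")
  worst <- min(unlist(res[conc]), 0)
  if (worst < -clip_tol) {
    warn(sprintf(
      "state undershoot of %.3g mM clipped to zero (solver tolerance?)", worst))
  }
  res[conc] <- lapply(res[conc], function(v) pmax(v, 0))

  out <- tibble::as_tibble(res)
  structure(out,
            class = c("levan_trajectory", class(out)),
            params = p,
            initial_sucrose = initial_sucrose,
            X0 = X0,
            equations = equations)
}

#' @export
print.levan_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<levan_trajectory> %s regime, %g g/L initial sucrose, %g-%g h\n",
              p$regime, attr(x, "initial_sucrose"),
              min(x$time), max(x$time)))
  NextMethod()
}

#' Convert a trajectory to measurement units
#'
#' Returns the five measured species in the units the instruments report:
#' biomass in gDW/L, sucrose/glucose/fructose/levan in g/L, in long (tidy)
#' format.
#'
#' @param traj a `levan_trajectory`.
#' @return Tibble with columns `time`, `species`, `value`.
#' @export
trajectory_to_gL <- function(traj) {
  tibble(
    time = rep(traj$time, 5),
    species = rep(c("biomass", "sucrose", "glucose", "fructose", "levan"),
                  each = nrow(traj)),
    value = c(traj$X,
              mM_to_gL(traj$S_reactor, "sucrose"),
              mM_to_gL(traj$Glc, "glucose"),
              mM_to_gL(traj$Fru, "fructose"),
              mM_to_gL(traj$Levan, "levan"))
  )
}

#' Export a trajectory as tidy or wide CSV
#'
#' @param traj a `levan_trajectory`.
#' @param path output file.
#' @param format `"tidy"` (time, variable, value, unit) or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("tidy", "wide")) {
  format <- match.arg(format)
  if (format == "wide") {
    utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  } else {
    units <- c(X = "gDW/L", E = "mg/L", S_cell = "mM", Glc = "mM",
               Fru = "mM", S_reactor = "mM", Levan = "mM", mu = "1/h",
               v1 = "mmol/(L h)", v2 = "mg/(L h)",
               v3 = "mmol/(mg h)", v4 = "mmol/(mg h)", v5 = "mmol/(mg h)",
               v3_vol = "mmol/(L h)", v4_vol = "mmol/(L h)",
               v5_vol = "mmol/(L h)", E_pool = "mg/L")
    long <- tidyr::pivot_longer(as.data.frame(traj), -"time",
                                names_to = "variable", values_to = "value")
    long$unit <- units[long$variable]
    utils::write.csv(long, path, row.names = FALSE)
  }
  invisible(path)
}

#' Plot a simulated trajectory
#'
#' Concentration panels (measurement units) plus the volumetric enzymatic
#' rates.
#'
#' @param object a `levan_trajectory`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.levan_trajectory <- function(object, ...) {
  conc <- trajectory_to_gL(object)
  rates <- tibble(
    time = rep(object$time, 3),
    species = rep(c("hydrolysis", "transfructosylation", "degradation"),
                  each = nrow(object)),
    value = c(object$v3_vol, object$v4_vol, object$v5_vol)
  )
  conc$panel <- "concentration [g/L]"
  rates$panel <- "rate [mmol/(L h)]"
  df <- rbind(conc, rates)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time [h]", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
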