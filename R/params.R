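#' Kinetic parameter set for the batch fermentation model
#'
#' Bundles every rate-law constant of the extracellular levan synthesis
#' model for one sucrose regime: Monod growth (`mu_max`, `Ks`), first-order
#' death (`kd`), biomass yield on sucrose (`Y_XS`), the growth-associated
#' levansucrase yield (`alpha`), and the Michaelis--Menten constants of the
#' three levansucrase-mediated reactions (hydrolysis, two-term
#' transfructosylation, levan degradation) plus the degradation onset time.
#'
#' @param mu_max maximum specific growth rate, 1/h.
#' @param Ks Monod half-saturation for sucrose, mM.
#' @param kd death constant, 1/h.
#' @param Y_XS biomass yield on sucrose, gDW/mmol.
#' @param alpha levansucrase yield on biomass, mg/gDW.
#' @param vmax_hyd maximum hydrolysis rate, mmol/(mg h).
#' @param KM_hyd hydrolysis Michaelis constant, mM.
#' @param vmax_trans1,vmax_trans2 maximum transfructosylation rates for the
#'   sucrose-only and fructose-acceptor terms, mmol/(mg h). The two share a
#'   single fitted value by default.
#' @param KM_trans1 Michaelis constant of the sucrose-only term, mM.
#' @param KM_trans2 constant of the fructose x sucrose product term, mM^2.
#' @param vmax_levdeg maximum levan degradation rate, mmol/(mg h).
#' @param KM_levdeg levan degradation Michaelis constant, mM.
#' @param t_levdeg_onset Heaviside onset time of levan degradation, h.
#' @param degradable_fraction_complement fraction of levan resistant to
#'   degradation; the saturating substrate is
#'   `(1 - degradable_fraction_complement) * Levan`.
#' @param regime regime label: `"low"`, `"transition"`, `"high"` or
#'   `"custom"`.
#'
#' @return An object of class `kinetic_params` (named list).
#' @seealso [levan_presets()], [select_regime()]
#' @export
kinetic_params <- function(mu_max, Ks, kd, Y_XS, alpha,
                           vmax_hyd, KM_hyd,
                           vmax_trans1, vmax_trans2 = vmax_trans1,
                           KM_trans1, KM_trans2,
                           vmax_levdeg, KM_levdeg, t_levdeg_onset,
                           degradable_fraction_complement = 0.33,
                           regime = "custom") {
  p <- list(
    mu_max = mu_max, Ks = Ks, kd = kd, Y_XS = Y_XS, alpha = alpha,
    vmax_hyd = vmax_hyd, KM_hyd = KM_hyd,
    vmax_trans1 = vmax_trans1, vmax_trans2 = vmax_trans2,
    KM_trans1 = KM_trans1, KM_trans2 = KM_trans2,
    vmax_levdeg = vmax_levdeg, KM_levdeg = KM_levdeg,
    t_levdeg_onset = t_levdeg_onset,
    degradable_fraction_complement = degradable_fraction_complement,
    regime = regime
  )
  validate_kinetic_params(p)
  structure(p, class = "kinetic_params")
}

validate_kinetic_params <- function(p) {
  num <- setdiff(names(p), "regime")
  vals <- unlist(p[num])
  if (any(!is.finite(vals))) {
    abort("all kinetic parameters must be finite numbers")
  }
  if (any(vals[c("mu_max", "kd", "alpha", "vmax_hyd", "vmax_trans1",
                 "vmax_trans2", "vmax_levdeg", "t_levdeg_onset")] < 0)) {
    abort("rate constants, alpha and the degradation onset must be >= 0")
  }
  if (any(vals[c("Ks", "KM_hyd", "KM_trans1", "KM_trans2", "KM_levdeg")] <= 0)) {
    abort("half-saturation constants must be > 0")
  }
  if (vals["Y_XS"] <= 0) abort("Y_XS must be > 0")
  dfc <- vals["degradable_fraction_complement"]
  if (dfc < 0 || dfc >= 1) {
    abort("degradable_fraction_complement must be in [0, 1)")
  }
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params> regime:", x$regime, "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kinetic_params <- function(x, ...) {
  units <- param_units()
  nm <- names(units)
  tibble(
    parameter = nm,
    value = unname(vapply(x[nm], as.numeric, numeric(1))),
    unit = unname(units)
  )
}

param_units <- function() {
  c(mu_max = "1/h", Ks = "mM", kd = "1/h", Y_XS = "gDW/mmol",
    alpha = "mg/gDW", vmax_hyd = "mmol/(mg h)", KM_hyd = "mM",
    vmax_trans1 = "mmol/(mg h)", vmax_trans2 = "mmol/(mg h)",
    KM_trans1 = "mM", KM_trans2 = "mM^2",
    vmax_levdeg = "mmol/(mg h)", KM_levdeg = "mM",
    t_levdeg_onset = "h", degradable_fraction_complement = "1")
}

# Shared constants across regimes. mu_max, alpha and vmax_trans are reported
# fitted values; the remaining constants are not published and are package
# choices fixed so the presets reproduce the qualitative batch behaviour
# (see the methods vignette). They are placeholders, not authoritative.
.shared_kinetics <- list(
  Ks = 5, kd = 0.008,
  vmax_hyd = 1.0, KM_hyd = 30,
  vmax_trans1 = 6.42, vmax_trans2 = 6.42,
  KM_trans1 = 7000, KM_trans2 = 5e4,
  vmax_levdeg = 0.03, KM_levdeg = 100
)

#' Packaged parameter presets for the three sucrose regimes
#'
#' Returns the three condition-specific parameter sets: `low` (fitted at
#' 100 g/L initial sucrose: alpha = 18.19 mg/gDW, mu_max = 0.2454 1/h),
#' `high` (250 g/L: alpha = 45, mu_max = 0.1) and `transition` (200 g/L:
#' alpha = 45, mu_max = 0.2454, Y_XS = 0.015 gDW/mmol). The maximum
#' transfructosylation rate (6.42 mmol/(mg h)) is shared by all regimes.
#' Constants not published for this system (Ks, kd, hydrolysis/degradation
#' constants, onset times) are package defaults chosen to reproduce the
#' qualitative batch dynamics; treat them as non-authoritative.
#'
#' @return Named list of three [kinetic_params()] objects:
#'   `low`, `transition`, `high`.
#' @export
levan_presets <- function() {
  list(
    low = do.call(kinetic_params, c(.shared_kinetics, list(
      mu_max = 0.2454, alpha = 18.19, Y_XS = 0.020,
      t_levdeg_onset = 18, regime = "low"))),
    transition = do.call(kinetic_params, c(.shared_kinetics, list(
      mu_max = 0.2454, alpha = 45, Y_XS = 0.015,
      t_levdeg_onset = 24, regime = "transition"))),
    high = do.call(kinetic_params, c(.shared_kinetics, list(
      mu_max = 0.1, alpha = 45, Y_XS = 0.012,
      t_levdeg_onset = 36, regime = "high")))
  )
}

#' Pick (or interpolate) the parameter set for an initial sucrose level
#'
#' Initial sucrose at or below 100 g/L uses the low-regime fit, at or above
#' 250 g/L the high-regime fit. Inside the transition band the
#' condition-specific transition fit is returned at 200 g/L; elsewhere each
#' parameter is linearly interpolated between the low and high presets.
#'
#' @param initial_sucrose initial sucrose concentration, g/L.
#' @param presets preset list as returned by [levan_presets()].
#' @return A [kinetic_params()] object.
#' @export
select_regime <- function(initial_sucrose, presets = levan_presets()) {
  if (!is.numeric(initial_sucrose) || initial_sucrose <= 0) {
    abort("initial_sucrose must be a positive number (g/L)")
  }
  if (initial_sucrose <= 100) return(presets$low)
  if (initial_sucrose >= 250) return(presets$high)
  if (abs(initial_sucrose - 200) < 1e-8) return(presets$transition)
  interpolate_params(presets$low, presets$high,
                     (initial_sucrose - 100) / 150)
}

#' Linear interpolation between two parameter sets
#'
#' @param p_low,p_high [kinetic_params()] endpoints.
#' @param weight interpolation weight in `[0, 1]`; 0 returns `p_low`.
#' @return A [kinetic_params()] object with `regime = "interpolated"`.
#' @export
interpolate_params <- function(p_low, p_high, weight) {
  stopifnot(weight >= 0, weight <= 1)
  nm <- setdiff(names(p_low), "regime")
  vals <- lapply(nm, function(k) (1 - weight) * p_low[[k]] + weight * p_high[[k]])
  names(vals) <- nm
  do.call(kinetic_params, c(vals, list(regime = "interpolated")))
}

#' Read and write parameter sets as JSON or YAML
#'
#' Serialized field names carry explicit units (e.g. `mu_max_per_h`,
#' `Ks_mM`) so files are self-describing.
#'
#' @param p a [kinetic_params()] object.
#' @param path file path; format chosen from the extension
#'   (`.json`, `.yml`/`.yaml`).
#' @return `read_params()` returns a [kinetic_params()] object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "kinetic_params"))
  nm <- setdiff(names(p), "regime")
  out <- setNames(lapply(nm, function(k) p[[k]]), serial_names()[nm])
  out$regime <- p$regime
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sn <- serial_names()
  back <- setNames(names(sn), sn)
  vals <- raw[names(raw) %in% names(back)]
  names(vals) <- back[names(vals)]
  do.call(kinetic_params, c(vals, list(regime = raw$regime %||% "custom")))
}

serial_names <- function() {
  c(mu_max = "mu_max_per_h", Ks = "Ks_mM", kd = "kd_per_h",
    Y_XS = "Y_XS_gDW_per_mmol", alpha = "alpha_mg_per_gDW",
    vmax_hyd = "vmax_hyd_mmol_per_mg_h", KM_hyd = "KM_hyd_mM",
    vmax_trans1 = "vmax_trans1_mmol_per_mg_h",
    vmax_trans2 = "vmax_trans2_mmol_per_mg_h",
    KM_trans1 = "KM_trans1_mM", KM_trans2 = "KM_trans2_mM2",
    vmax_levdeg = "vmax_levdeg_mmol_per_mg_h", KM_levdeg = "KM_levdeg_mM",
    t_levdeg_onset = "t_levdeg_onset_h",
    degradable_fraction_complement = "degradable_fraction_complement")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
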