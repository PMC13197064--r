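#' Measurement noise model for synthetic time courses
#'
#' Multiplicative lognormal noise with a per-species coefficient of
#' variation (default 3%, the scale suggested by the replicate standard
#' deviations of the production summary table) and a detection floor.
#' Additive Gaussian noise is selectable.
#'
#' @param cv coefficient of variation (single value or named per species).
#' @param floor detection floor in measurement units (g/L); values below
#'   it are clipped to the floor.
#' @param type `"lognormal"` (multiplicative, default) or `"additive"`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.03, floor = 0, type = c("lognormal", "additive")) {
  type <- match.arg(type)
  if (any(cv < 0) || floor < 0) abort("cv and floor must be >= 0")
  structure(list(cv = cv, floor = floor, type = type), class = "noise_model")
}

#' Generate synthetic fermentation time courses
#'
#' Simulates each condition with its regime-specific parameter set
#' (via [select_regime()]), samples the trajectory on the experimental
#' grid (6, 12, 18, 24, 30, 36, 48, 60, 72, 96, 120 h), and applies the
#' noise model. Lognormal noise is mean-preserving
#' (`meanlog = -sdlog^2/2`), so the expected value of each noisy point is
#' the model value. Deterministic under a fixed seed.
#'
#' @param conditions initial sucrose concentrations, g/L.
#' @param replicates replicates per condition.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param presets preset list (see [levan_presets()]).
#' @param times sampling grid, h.
#' @param X0 inoculum, gDW/L.
#' @return Long tibble (`condition`, `replicate`, `time`, `species`,
#'   `value`) in measurement units, with the generating parameters in the
#'   `params` attribute.
#' @export
generate_timecourses <- function(conditions = c(50, 100, 200, 250, 300),
                                 replicates = 3,
                                 noise = noise_model(),
                                 seed = 1,
                                 presets = levan_presets(),
                                 times = c(6, 12, 18, 24, 30, 36, 48, 60, 72, 96, 120),
                                 X0 = 0.05) {
  if (replicates < 1) abort("replicates must be >= 1")
  stopifnot(inherits(noise, "noise_model"))
  params_used <- list()
  out <- withr::with_seed(seed, {
    dplyr::bind_rows(lapply(conditions, function(cc) {
      p <- select_regime(cc, presets)
      params_used[[as.character(cc)]] <<- p
      tr <- simulate_batch(p, cc, X0 = X0, horizon = max(times),
                           report_times = times)
      clean <- trajectory_to_gL(tr)
      dplyr::bind_rows(lapply(seq_len(replicates), function(r) {
        v <- apply_noise(clean$value, clean$species, noise)
        tibble(condition = cc, replicate = r, time = clean$time,
               species = clean$species, value = v)
      }))
    }))
  })
  attr(out, "params") <- params_used
  attr(out, "seed") <- seed
  out
}

apply_noise <- function(values, species, noise) {
  cv <- if (is.null(names(noise$cv))) {
    rep(noise$cv, length(values))
  } else {
    unname(noise$cv[species])
  }
  noisy <- if (noise$type == "lognormal") {
    sdlog <- sqrt(log(1 + cv^2))
    values * exp(rnorm(length(values), -sdlog^2 / 2, sdlog))
  } else {
    values + rnorm(length(values), 0, cv * values)
  }
  pmax(noisy, noise$floor)
}

#' Write/read observed time courses as CSV
#'
#' Long format: `condition`, `replicate`, `time`, `species`, `value`.
#'
#' @param obs observation tibble.
#' @param path file path.
#' @return `read_timecourses()` returns the tibble; `write_timecourses()`
#'   returns `path` invisibly.
#' @export
write_timecourses <- function(obs, path) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourses
#' @export
read_timecourses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "time", "species", "value")
  if (!all(need %in% names(df))) {
    # wide dialect: species as columns
    idc <- intersect(c("condition", "replicate", "time"), names(df))
    df <- tidyr::pivot_longer(df, -all_of(idc),
                              names_to = "species", values_to = "value")
  }
  tibble::as_tibble(df)
}

#' Build the packaged toy stoichiometric network
#'
#' A mass-balanced 13-reaction network shaped like the core of hexose
#' metabolism so every coupling and scenario operation is exercisable
#' without the published genome-scale model: sucrose supply and uptake
#' into a glucose-6-phosphate node that branches into glycolysis (PGI
#' analogue) and the oxidative pentose phosphate route (G6PDH analogue,
#' returning via a non-oxidative lump), respiration and maintenance for
#' energy balance, an amino-acid precursor (with a closed supplement
#' exchange), a biomass drain, and the levansucrase synthesis
#' pseudo-reaction with its secretion exchange. PGI is reversible so the
#' irreversible-splitting path of the LP is exercised.
#'
#' Reactions: `EX_suc` (sucrose supply), `UPT` (suc_e -> 2 g6p), `PGI`
#' (g6p <-> f6p), `G6PDH` (g6p -> rp), `NOPPP` (rp -> f6p), `GLYC`
#' (f6p -> 2 pyr + 2 atp), `RESP` (pyr -> 3 atp), `ATPM` (atp sink),
#' `AASYN` (pyr + rp + atp -> aa), `EX_aa` (supplement, closed), `LVS_SYN`
#' (2 aa + atp -> lvs), `EX_lvs`, `BIOMASS` (pyr + aa + 2 atp -> ).
#'
#' @param augmented include the levansucrase synthesis pseudo-reaction
#'   (default `TRUE`); with `FALSE` the network is returned without it,
#'   ready for [augment_levansucrase()].
#' @return A [stoich_model()].
#' @export
generate_toy_gem <- function(augmented = TRUE) {
  mets <- c("suc_e", "g6p", "f6p", "rp", "pyr", "aa", "atp")
  rxn <- list(
    EX_suc = c(suc_e = 1),
    UPT    = c(suc_e = -1, g6p = 2),
    PGI    = c(g6p = -1, f6p = 1),
    G6PDH  = c(g6p = -1, rp = 1),
    NOPPP  = c(rp = -1, f6p = 1),
    GLYC   = c(f6p = -1, pyr = 2, atp = 2),
    RESP   = c(pyr = -1, atp = 3),
    ATPM   = c(atp = -1),
    AASYN  = c(pyr = -1, rp = -1, atp = -1, aa = 1),
    EX_aa  = c(aa = 1),
    BIOMASS = c(pyr = -1, aa = -1, atp = -2)
  )
  S <- matrix(0, length(mets), length(rxn),
              dimnames = list(mets, names(rxn)))
  for (j in seq_along(rxn)) S[names(rxn[[j]]), j] <- rxn[[j]]
  lb <- setNames(rep(0, length(rxn)), names(rxn))
  ub <- setNames(rep(1000, length(rxn)), names(rxn))
  lb["PGI"] <- -1000
  ub["EX_aa"] <- 0  # supplement closed by default
  m <- stoich_model(S, lb = lb, ub = ub,
                    biomass_id = "BIOMASS", uptake_id = "EX_suc")
  if (augmented) {
    m <- augment_levansucrase(m, composition = c(aa = -2, atp = -1))
  }
  m
}
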