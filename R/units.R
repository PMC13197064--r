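#' Molar masses used for unit conversion
#'
#' Internal model state is in mM (levan in fructosyl-monomer equivalents);
#' measurements are in g/L. Conversion uses sucrose 342.30, glucose and
#' fructose 180.16, and the levan fructosyl monomer 162.14 g/mol
#' (anhydro-fructose unit in the polymer).
#'
#' @format Named numeric vector, g/mol.
#' @export
levan_molar_masses <- c(
  sucrose  = 342.30,
  glucose  = 180.16,
  fructose = 180.16,
  levan    = 162.14
)

#' Convert a concentration between g/L and mM
#'
#' @param x numeric concentrations.
#' @param species one of `"sucrose"`, `"glucose"`, `"fructose"`, `"levan"`.
#'   Levan is counted in fructosyl-monomer equivalents.
#' @return numeric vector, converted concentrations.
#' @examples
#' gL_to_mM(100, "sucrose") # 292.1 mM
#' @export
gL_to_mM <- function(x, species) {
  species <- match.arg(species, names(levan_molar_masses))
  x * 1000 / levan_molar_masses[[species]]
}

#' @rdname gL_to_mM
#' @export
mM_to_gL <- function(x, species) {
  species <- match.arg(species, names(levan_molar_masses))
  x * levan_molar_masses[[species]] / 1000
}
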