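# Physical constants (CODATA-consistent) in internal units.

#' Physical constants used by bilff
#'
#' @format Named list:
#' \describe{
#'   \item{ke}{Coulomb constant e^2/(4 pi eps0), kJ mol^-1 Angstrom e^-2.}
#'   \item{kB}{Boltzmann constant, kJ mol^-1 K^-1.}
#'   \item{avogadro}{Avogadro constant, mol^-1.}
#'   \item{bar}{1 bar in kJ mol^-1 Angstrom^-3.}
#'   \item{atm}{1 atm in kJ mol^-1 Angstrom^-3.}
#'   \item{time_unit_fs}{Internal time unit in fs.}
#' }
#' @export
bilff_constants <- list(
  ke  = 1389.35457644382,       # kJ mol^-1 A e^-2
  kB  = 0.008314462618153,      # kJ mol^-1 K^-1
  avogadro = 6.02214076e23,     # mol^-1
  bar = 6.02214076e-5,          # 1e5 Pa * 1e-30 m^3/A^3 * NA / 1000
  atm = 6.101933e-5,            # 1.01325 bar
  time_unit_fs = 100            # internal time unit
)

# Standard atomic weights (IUPAC 2021 abridged), g/mol.
.atomic_weights <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  F = 18.998, Cl = 35.45, Na = 22.990, K = 39.098, M = 0.0
)

#' Standard atomic weight of an element
#'
#' @param element character vector of element symbols ("M" denotes a massless
#'   virtual site).
#' @return numeric vector, g/mol.
#' @export
atomic_weight <- function(element) {
  w <- .atomic_weights[element]
  if (anyNA(w)) {
    stop("unknown element(s): ", paste(unique(element[is.na(w)]), collapse = ", "))
  }
  unname(w)
}
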