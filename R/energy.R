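# Energy and force evaluation (OPLS functional form).

# flatten a bilff_system into the argument list the compiled engine expects
.engine_args <- function(sys) {
  a <- sys$atoms
  list(
    q = a$q, sigma = a$sigma, epsilon = a$epsilon, mass = a$mass,
    virtual = as.integer(a$virtual), mol_id = as.integer(a$mol_id),
    sp_i = sys$special$i, sp_j = sys$special$j, sp_f = sys$special$f,
    b_i = sys$bonds$i, b_j = sys$bonds$j, b_l0 = sys$bonds$l0, b_kl = sys$bonds$kl,
    a_i = sys$angles$i, a_j = sys$angles$j, a_k = sys$angles$k,
    a_theta0 = sys$angles$theta0, a_ktheta = sys$angles$ktheta,
    d_i = sys$dihedrals$i, d_j = sys$dihedrals$j, d_k = sys$dihedrals$k,
    d_l = sys$dihedrals$l, d_v1 = sys$dihedrals$V1, d_v2 = sys$dihedrals$V2,
    d_v3 = sys$dihedrals$V3, d_v4 = sys$dihedrals$V4,
    c_i = sys$constraints$i, c_j = sys$constraints$j, c_d = sys$constraints$d,
    vs_idx = sys$vsites$idx, vs_o = sys$vsites$o, vs_h1 = sys$vsites$h1,
    vs_h2 = sys$vsites$h2, vs_gamma = sys$vsites$gamma
  )
}

#' Nonbonded interaction options
#'
#' @param method electrostatics treatment: `"cutoff"` (truncated
#'   minimum-image Coulomb, for testing and isolated systems), `"dsf"`
#'   (damped shifted-force Coulomb, the default for condensed-phase runs) or
#'   `"ewald"` (real + reciprocal space, tinfoil boundary).
#' @param rc_lj Lennard-Jones cutoff radius in pm (default 800 pm).
#' @param rc_coul real-space Coulomb cutoff in pm.
#' @param alpha damping/splitting parameter, 1/Angstrom.
#' @param kmax Ewald reciprocal-space cutoff (integer shell radius).
#' @param lj_tail logical, analytic mean-field LJ tail correction.
#' @return list of class `bilff_nb_options`.
#' @export
nb_options <- function(method = c("dsf", "cutoff", "ewald"),
                       rc_lj = 800, rc_coul = rc_lj, alpha = 0.25,
                       kmax = 8, lj_tail = FALSE) {
  method <- match.arg(method)
  structure(list(method = method, rc_lj = rc_lj / 100, rc_coul = rc_coul / 100,
                 alpha = alpha, kmax = as.integer(kmax), lj_tail = lj_tail),
            class = "bilff_nb_options")
}

.check_cutoff_box <- function(sys, opts) {
  if (sys$box > 0) {
    rc <- max(opts$rc_lj, opts$rc_coul)
    if (sys$box < 2 * rc)
      stop(sprintf(paste0("box edge (%.0f pm) must exceed twice the cutoff ",
                          "(2 x %.0f pm) for the minimum-image convention"),
                   100 * sys$box, 100 * rc))
  }
  invisible(TRUE)
}

#' Harmonic bond energy
#'
#' `U = kl (l - l0)^2` (no 1/2 prefactor).
#'
#' @param l bond length, Angstrom.
#' @param p parameter row with `l0` (Angstrom) and `kl` (kJ mol-1 A-2).
#' @return energy in kJ/mol.
#' @export
bond_energy <- function(l, p) {
  stopifnot(all(l > 0))
  p$kl * (l - p$l0)^2
}

#' Harmonic angle energy
#'
#' `U = ktheta (theta - theta0)^2` with `theta0` given in degrees and `theta`
#' in radians.
#'
#' @param theta angle in radians.
#' @param p parameter row with `theta0` (degrees) and `ktheta` (kJ mol-1 rad-2).
#' @return energy in kJ/mol.
#' @export
angle_energy <- function(theta, p) {
  stopifnot(all(theta >= 0), all(theta <= pi + 1e-12))
  p$ktheta * (theta - p$theta0 * pi / 180)^2
}

#' OPLS torsion energy
#'
#' Four-term Fourier series
#' `U = V1/2 (1+cos phi) + V2/2 (1-cos 2 phi) + V3/2 (1+cos 3 phi) + V4/2 (1-cos 4 phi)`.
#'
#' @param phi dihedral angle in radians.
#' @param p parameter row with `V1`..`V4` in kJ/mol.
#' @return energy in kJ/mol.
#' @export
torsion_energy <- function(phi, p) {
  0.5 * (p$V1 * (1 + cos(phi)) + p$V2 * (1 - cos(2 * phi)) +
         p$V3 * (1 + cos(3 * phi)) + p$V4 * (1 - cos(4 * phi)))
}

#' Nonbonded energy of a configuration
#'
#' Lennard-Jones (geometric combining rules, truncated at the LJ cutoff) and
#' electrostatics by truncation, damped shifted force or Ewald summation,
#' with the force field's 1-2/1-3/1-4 exclusion factors applied to both
#' terms.
#'
#' @param sys a `bilff_system` with positions.
#' @param opts [nb_options()].
#' @return list with `lj` and `coulomb` energies (kJ/mol).
#' @export
nonbonded_energy <- function(sys, opts = nb_options()) {
  r <- total_energy_forces(sys, opts)
  list(lj = r$lj, coulomb = r$coulomb)
}

#' Total potential energy and analytic forces
#'
#' Evaluates the full potential (bond + angle + torsion + LJ + Coulomb) and
#' its analytic gradient for a periodic (or isolated, `box <= 0`) system.
#'
#' @param sys a `bilff_system` with positions.
#' @param opts [nb_options()].
#' @return `bilff_energy` object: energy terms in kJ/mol, `forces` (N x 3,
#'   kJ mol-1 A-1), and the scalar interaction `virial`.
#' @export
total_energy_forces <- function(sys, opts = nb_options()) {
  stopifnot(!is.null(sys$pos))
  .check_cutoff_box(sys, opts)
  r <- cpp_energy_forces(.engine_args(sys), sys$pos, sys$box,
                         unclass(opts))
  structure(r, class = "bilff_energy")
}

#' @export
print.bilff_energy <- function(x, ...) {
  cat("bilff energy report (kJ/mol)\n")
  for (t in c("bond", "angle", "torsion", "lj", "coulomb", "total"))
    cat(sprintf("  %-8s %14.4f\n", t, x[[t]]))
  invisible(x)
}

#' Minimize a configuration (steepest descent, capped displacement)
#'
#' @param sys a `bilff_system` with positions.
#' @param ff unused placeholder kept for call symmetry; may be NULL.
#' @param opts [nb_options()].
#' @param steps maximum iterations.
#' @param max_disp maximum per-component displacement per step, Angstrom.
#' @param ftol force-infinity-norm convergence threshold, kJ mol-1 A-1.
#' @return the system with relaxed positions.
#' @export
minimize_system <- function(sys, ff = NULL, opts = nb_options(method = "cutoff"),
                            steps = 500, max_disp = 0.1, ftol = 1.0) {
  stopifnot(!is.null(sys$pos))
  r <- cpp_minimize(.engine_args(sys), sys$pos, sys$box, unclass(opts),
                    as.integer(steps), max_disp, ftol)
  sys$pos <- r$pos
  attr(sys, "min_energy") <- r$energy
  sys
}
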