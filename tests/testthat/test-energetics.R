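# Energy terms, analytic forces, exclusions, Ewald, invariances.

test_that("bond, angle and torsion energies follow their closed forms", {
  ff <- load_bilff()
  b <- lookup_bond(ff, "NA", "NR")
  expect_equal(bond_energy(1.344, b), 0)
  expect_equal(bond_energy(1.444, b), 3199.2 * 0.1^2, tolerance = 1e-10)
  expect_equal(bond_energy(2, list(l0 = 1, kl = 0)), 0)
  a <- lookup_angle(ff, "O2", "CO", "O2")
  expect_equal(angle_energy(126 * pi / 180, a), 0)
  expect_equal(angle_energy(131 * pi / 180, a), 735.9 * (5 * pi / 180)^2,
               tolerance = 1e-10)
  # even about theta0
  expect_equal(angle_energy((126 + 7) * pi / 180, a),
               angle_energy((126 - 7) * pi / 180, a))
  t1 <- lookup_torsion(ff, "CA", "CA", "CO", "O2")
  expect_equal(torsion_energy(0, t1), 0)
  expect_equal(torsion_energy(pi / 2, t1), 8.000, tolerance = 1e-10)
  t2 <- lookup_torsion(ff, "NA", "CW", "CW", "NA")
  expect_equal(torsion_energy(pi / 2, t2), 65.0, tolerance = 1e-10)
})

test_that("Lennard-Jones and Coulomb pair identities hold", {
  at_sigma <- raw_system(rbind(c(0, 0, 0), c(3, 0, 0)), box = 0,
                         sigma = 3, epsilon = 0.7, mass = 1)
  expect_equal(nonbonded_energy(at_sigma, nb_options("cutoff", rc_lj = 2000))$lj, 0,
               tolerance = 1e-12)
  at_min <- raw_system(rbind(c(0, 0, 0), c(2^(1 / 6) * 3, 0, 0)), box = 0,
                       sigma = 3, epsilon = 0.7, mass = 1)
  expect_equal(nonbonded_energy(at_min, nb_options("cutoff", rc_lj = 2000))$lj,
               -0.7, tolerance = 1e-12)
  charges <- raw_system(rbind(c(0, 0, 0), c(5, 0, 0)), box = 0,
                        q = c(1, -1), epsilon = 0, mass = 1)
  expect_equal(nonbonded_energy(charges, nb_options("cutoff", rc_coul = 2000))$coulomb,
               -bilff_constants$ke / 5, tolerance = 1e-10)
  # overlapping atoms
  clash <- raw_system(rbind(c(0, 0, 0), c(0.005, 0, 0)), box = 0,
                      sigma = 3, epsilon = 0.7, mass = 1)
  expect_error(nonbonded_energy(clash, nb_options("cutoff")), "overlapping")
})

test_that("analytic forces match central-difference gradients for every term class", {
  ff <- ff_full()
  # jittered cation: bonds + angles + torsions + intramolecular 1-4 nonbonded
  sys <- vacuum_molecule("EMTr", ff, jitter = 0.08, seed = 7)
  for (method in c("cutoff", "dsf")) {
    opts <- nb_options(method, rc_lj = 900)
    e <- total_energy_forces(sys, opts)
    g <- num_grad(sys, opts)
    expect_lt(max(abs(e$forces + g)) / max(abs(g)), 1e-5)
    expect_lt(max(abs(colSums(e$forces))), 1e-8)
  }
  # random periodic charged LJ system, all three electrostatics methods
  set.seed(11)
  sysr <- raw_system(matrix(runif(30, 0, 10), 10, 3), box = 20,
                     q = rep(c(0.3, -0.3), 5), sigma = 3, epsilon = 0.5,
                     mass = 10)
  for (method in c("cutoff", "dsf", "ewald")) {
    opts <- nb_options(method, rc_lj = 900, alpha = 0.35, kmax = 10)
    e <- total_energy_forces(sysr, opts)
    g <- num_grad(sysr, opts)
    expect_lt(max(abs(e$forces + g)) / max(abs(g)), 1e-5)
  }
  # rigid water pair with virtual sites
  compw <- composition(TIP4PEW = 2, box_edge = 3000)
  w <- bilff:::.template_coords("TIP4PEW")
  sysw <- build_system(compw, ff,
                       pos = rbind(w, sweep(w, 2, c(3, 0.5, 0.3), `+`)))
  e <- total_energy_forces(sysw, nb_options("dsf"))
  g <- num_grad(sysw, nb_options("dsf"))
  expect_lt(max(abs(e$forces + g)) / max(abs(g)), 1e-5)
})

test_that("1-2/1-3 pairs are fully excluded and 1-4 scaling is symmetric", {
  ff <- ff_full()
  sys <- vacuum_molecule("OAc", ff)
  sp <- sys$special
  d <- function(i, j) sqrt(sum((sys$pos[i, ] - sys$pos[j, ])^2))
  # direct Coulomb sum with the exclusion factors reproduces the engine
  ke <- bilff_constants$ke
  q <- sys$atoms$q
  e_manual <- 0
  n <- nrow(sys$pos)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    f <- 1
    hit <- sp$i == i & sp$j == j
    if (any(hit)) f <- sp$f[hit]
    e_manual <- e_manual + f * ke * q[i] * q[j] / d(i, j)
  }
  e <- nonbonded_energy(sys, nb_options("cutoff", rc_lj = 4000, rc_coul = 4000))
  expect_equal(e$coulomb, e_manual, tolerance = 1e-10)
  # zeroing all 1-4 factors removes every nonbonded contribution of a small
  # molecule whose pairs are all within 3 bonds
  ff0 <- load_bilff(extra = bilff_extdata("oac_synthetic.prm"),
                    exclusion_policy = c(0, 0, 0))
  sys0 <- vacuum_molecule("OAc", ff0)
  e0 <- nonbonded_energy(sys0, nb_options("cutoff", rc_lj = 4000, rc_coul = 4000))
  expect_equal(e0$coulomb, 0, tolerance = 1e-12)
  expect_equal(e0$lj, 0, tolerance = 1e-12)
})

test_that("Ewald reproduces the rock-salt Madelung energy and is alpha-independent", {
  a <- 5.64
  sys <- nacl_crystal(a)
  madelung <- 1.7475645946
  e_exact <- -4 * madelung * bilff_constants$ke / (a / 2)
  e1 <- nonbonded_energy(sys, nb_options("ewald", rc_lj = 281, rc_coul = 281,
                                         alpha = 1.4, kmax = 14))$coulomb
  expect_equal(e1, e_exact, tolerance = 1e-3 / abs(e_exact))
  e2 <- nonbonded_energy(sys, nb_options("ewald", rc_lj = 281, rc_coul = 281,
                                         alpha = 1.25, kmax = 14))$coulomb
  expect_equal(e1, e2, tolerance = 1e-5)
})

test_that("Ewald agrees with the direct sum for a dilute periodic pair", {
  # two opposite charges far from their images: direct minimum-image sum is a
  # good reference
  sys <- raw_system(rbind(c(0, 0, 0), c(4, 0, 0)), box = 60, q = c(1, -1),
                    epsilon = 0, mass = 1)
  e_direct <- -bilff_constants$ke / 4
  e_ew <- nonbonded_energy(sys, nb_options("ewald", rc_lj = 2500, rc_coul = 2500,
                                           alpha = 0.2, kmax = 10))$coulomb
  # periodic-image contribution of the dipole array is O(ke p^2 / L^3)
  expect_equal(e_ew, e_direct, tolerance = 2e-3)
})

test_that("energy is invariant under rigid translation and rotation", {
  ff <- ff_full()
  set.seed(21)
  comp <- composition(EMTr = 2, OBz = 2, box_edge = 4000)
  sys <- pack_system(build_system(comp, ff), ff, seed = 3, relax_steps = 20)
  opts <- nb_options("dsf")
  e0 <- total_energy_forces(sys, opts)$total
  # translation (periodic wrap handled by minimum image)
  st <- sys; st$pos <- sweep(sys$pos, 2, c(7.3, -2.1, 11.9), `+`)
  expect_equal(total_energy_forces(st, opts)$total, e0, tolerance = 1e-9)
  # rotation about the box center (non-periodic evaluation)
  sysv <- sys; sysv$box <- 0
  e0v <- total_energy_forces(sysv, nb_options("cutoff", rc_lj = 1e5,
                                              rc_coul = 1e5))$total
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  sr <- sysv; sr$pos <- sysv$pos %*% R
  expect_equal(total_energy_forces(sr, nb_options("cutoff", rc_lj = 1e5,
                                                  rc_coul = 1e5))$total,
               e0v, tolerance = 1e-9)
})

test_that("the cutoff method refuses a box smaller than twice the cutoff", {
  sys <- raw_system(matrix(runif(30), 10, 3), box = 10, mass = 1)
  expect_error(total_energy_forces(sys, nb_options("cutoff", rc_lj = 800)),
               "twice the cutoff")
})
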