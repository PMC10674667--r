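# Molecule templates: multiplicities, charge closure, term enumeration,
# molar masses, density arithmetic.

test_that("templates have the correct atom multiplicities", {
  emtr <- build_molecule("EMTr")
  tab <- table(emtr$atoms$type)
  expect_equal(as.integer(tab[c("NA", "NR", "CW", "HCW", "C1", "H1", "CE", "HC")]),
               c(2L, 1L, 2L, 2L, 2L, 5L, 1L, 3L))
  obz <- build_molecule("OBz")
  tab2 <- table(obz$atoms$type)
  expect_equal(as.integer(tab2[c("CO", "O2", "C1", "C2", "C3", "C4", "H2", "H3", "H4")]),
               c(1L, 2L, 1L, 2L, 2L, 1L, 2L, 2L, 1L))
  expect_error(build_molecule("nonsense"), "unknown species")
})

test_that("ionic charge closure is exactly +/-0.82 e and water is neutral", {
  ff <- ff_full()
  expect_equal(template_charge(build_molecule("EMTr"), ff), 0.82, tolerance = 1e-9)
  expect_equal(template_charge(build_molecule("OBz"), ff), -0.82, tolerance = 1e-9)
  expect_equal(template_charge(build_molecule("OAc"), ff), -0.82, tolerance = 1e-9)
  expect_equal(template_charge(build_molecule("EMIm"), ff), 0.82, tolerance = 1e-9)
  expect_equal(template_charge(build_molecule("TIP4PEW"), ff), 0, tolerance = 1e-12)
})

test_that("bonded-term enumeration matches a brute-force graph oracle", {
  ff <- ff_full()
  for (species in c("EMTr", "OBz", "OAc", "EMIm")) {
    tpl <- build_molecule(species)
    terms <- enumerate_bonded_terms(tpl, ff)
    oracle <- brute_terms(tpl$bonds, nrow(tpl$atoms))
    got_ang <- canon_set(lapply(seq_len(nrow(terms$angles)), function(r)
      as.integer(terms$angles[r, c("i", "j", "k")])))
    exp_ang <- canon_set(oracle$angles)
    expect_identical(got_ang, exp_ang)
    got_dih <- canon_set(lapply(seq_len(nrow(terms$dihedrals)), function(r)
      as.integer(terms$dihedrals[r, c("i", "j", "k", "l")])))
    exp_dih <- canon_set(oracle$dihedrals)
    expect_identical(got_dih, exp_dih)
  }
})

test_that("benzoate contains the expected key terms and the ring angle appears once", {
  ff <- ff_full()
  obz <- enumerate_bonded_terms(build_molecule("OBz"), ff)
  # two CO-O2 bonds at the published parameters
  co_o2 <- obz$bonds[obz$bonds$l0 == 1.282, ]
  expect_equal(nrow(co_o2), 2)
  # exactly one O2-CO-O2 angle
  expect_equal(sum(obz$angles$theta0 == 126.0), 1)
  emtr <- enumerate_bonded_terms(build_molecule("EMTr"), ff)
  # NA-NR-NA ring angle exactly once
  expect_equal(sum(emtr$angles$theta0 == 104.4), 1)
  # diatomic toy: one bond, nothing else
  toy <- build_molecule("OAc")
  toy$atoms <- toy$atoms[1:2, ]
  toy$bonds <- matrix(c(1, 2), 1)
  t2 <- enumerate_bonded_terms(toy, ff)
  expect_equal(c(nrow(t2$bonds), nrow(t2$angles), nrow(t2$dihedrals)),
               c(1L, 0L, 0L))
})

test_that("a term without parameters is an error naming the class tuple", {
  ff <- load_bilff()   # no acetate classes merged
  expect_error(enumerate_bonded_terms(build_molecule("OAc"), ff), "CO|CT")
})

test_that("molar masses match standard atomic weights", {
  ff <- ff_full()
  expect_equal(molar_mass(build_molecule("EMTr"), ff), 112.16, tolerance = 1e-3)
  expect_equal(molar_mass(build_molecule("OBz"), ff), 121.11, tolerance = 1e-3)
  expect_equal(molar_mass(build_molecule("TIP4PEW"), ff), 18.015, tolerance = 1e-3)
})

test_that("density arithmetic reproduces every published composition row", {
  # composition / box edge (pm) / printed density (g/cm^3)
  rows <- list(
    list(c(EMTr = 36, OAc = 36), 2121, 1.072),
    list(c(EMIm = 36, OBz = 36), 2319, 1.114),
    list(c(EMTr = 27, OBz = 27, TIP4PEW = 81), 2319, 1.033),
    list(c(EMTr = 128, OAc = 128), 3198, 1.113),
    list(c(EMTr = 81, OAc = 81, TIP4PEW = 243), 3027, 1.092),
    list(c(EMIm = 128, OBz = 128), 3550, 1.103),
    list(c(EMIm = 81, OBz = 81, TIP4PEW = 243), 3286, 1.086),
    list(c(EMTr = 128, OBz = 128), 3529, 1.128),
    list(c(EMTr = 81, OBz = 81, TIP4PEW = 243), 3271, 1.105))
  ff <- ff_full()
  for (r in rows) {
    comp <- do.call(composition, c(as.list(r[[1]]), list(box_edge = r[[2]])))
    expect_equal(system_density(comp, ff), r[[3]], tolerance = 0.002 / r[[3]])
  }
  # empty box
  expect_equal(system_density(composition(box_edge = 1000), ff), 0)
})
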