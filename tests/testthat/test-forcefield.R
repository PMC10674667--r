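# Parameter library: table lookups, combining rules, closures, serialization.

test_that("embedded parameter tables resolve the published values", {
  ff <- load_bilff()
  expect_equal(lookup_type(ff, "OBz", "O2")$q, -0.550)
  expect_equal(lookup_type(ff, "OBz", "O2")$sigma, 2.80)
  expect_equal(lookup_type(ff, "OBz", "O2")$epsilon, 0.8786)
  expect_equal(lookup_type(ff, "EMTr", "HCW")$q, 0.191)
  expect_equal(lookup_type(ff, "EMTr", "HCW")$sigma, 1.48)
  b <- lookup_bond(ff, "NA", "NR")
  expect_equal(b$l0, 1.344)
  expect_equal(b$kl, 3199.2)
  expect_equal(lookup_angle(ff, "O2", "CO", "O2")$ktheta, 735.9)
  expect_equal(lookup_torsion(ff, "CA", "CA", "CO", "O2")$V2, 8.000)
  expect_equal(lookup_torsion(ff, "NA", "CW", "CW", "NA")$V2, 65.0)
})

test_that("alias types of the cation resolve to the charge-closing set", {
  ff <- load_bilff()
  expect_equal(lookup_type(ff, "EMTr", "CM")$q, lookup_type(ff, "EMTr", "C1")$q)
  expect_equal(lookup_type(ff, "EMTr", "HM")$q, lookup_type(ff, "EMTr", "H1")$q)
  expect_equal(lookup_type(ff, "EMTr", "HE")$q, lookup_type(ff, "EMTr", "HC")$q)
  expect_error(lookup_type(ff, "EMTr", "XX"), "unknown atom type")
})

test_that("bonded lookups are symmetric under tuple reversal", {
  ff <- ff_full()
  for (r in seq_len(nrow(ff$bonds))) {
    expect_identical(lookup_bond(ff, ff$bonds$class1[r], ff$bonds$class2[r]),
                     lookup_bond(ff, ff$bonds$class2[r], ff$bonds$class1[r]))
  }
  for (r in seq_len(nrow(ff$angles))) {
    expect_identical(
      lookup_angle(ff, ff$angles$class1[r], ff$angles$class2[r], ff$angles$class3[r]),
      lookup_angle(ff, ff$angles$class3[r], ff$angles$class2[r], ff$angles$class1[r]))
  }
  for (r in seq_len(nrow(ff$torsions))) {
    expect_identical(
      lookup_torsion(ff, ff$torsions$class1[r], ff$torsions$class2[r],
                     ff$torsions$class3[r], ff$torsions$class4[r]),
      lookup_torsion(ff, ff$torsions$class4[r], ff$torsions$class3[r],
                     ff$torsions$class2[r], ff$torsions$class1[r]))
  }
})

test_that("geometric combining rule and its arithmetic examples", {
  ff <- load_bilff()
  hcw <- lookup_type(ff, "EMTr", "HCW")
  o2 <- lookup_type(ff, "OBz", "O2")
  same <- combine_lj(hcw, hcw)
  expect_equal(unname(same["sigma"]), 1.48)
  expect_equal(unname(same["epsilon"]), 0.1260)
  cross <- combine_lj(hcw, o2)
  expect_equal(unname(cross["sigma"]), sqrt(1.48 * 2.80), tolerance = 1e-12)
  expect_equal(unname(cross["epsilon"]), sqrt(0.1260 * 0.8786), tolerance = 1e-12)
  expect_error(combine_lj(hcw, list(sigma = NA, epsilon = 1, type = "bad")),
               "missing Lennard-Jones")
})

test_that("serialization round trip reproduces the parameter set", {
  ff <- ff_full()
  f <- tempfile(fileext = ".prm")
  write_forcefield(ff, f)
  back <- read_forcefield(f)
  for (tab in c("types", "bonds", "angles", "torsions")) {
    num <- vapply(ff[[tab]], is.numeric, TRUE)
    expect_equal(as.matrix(back[[tab]][, num]), as.matrix(ff[[tab]][, num]),
                 tolerance = 1e-9, ignore_attr = TRUE)
    chr <- !num
    expect_identical(as.matrix(back[[tab]][, chr]), as.matrix(ff[[tab]][, chr]))
  }
})

test_that("merging rejects conflicting redefinitions and accepts identical ones", {
  ff <- load_bilff()
  extra <- list(types = NULL,
                bonds = data.frame(class1 = "NA", class2 = "NR",
                                   l0 = 1.5, kl = 1000),
                angles = NULL, torsions = NULL)
  expect_error(merge_forcefield(ff, extra), "merge conflict")
  same <- list(types = NULL,
               bonds = data.frame(class1 = "NR", class2 = "NA",
                                  l0 = 1.344, kl = 3199.2),
               angles = NULL, torsions = NULL)
  expect_silent(ff2 <- merge_forcefield(ff, same))
  expect_equal(nrow(ff2$bonds), nrow(ff$bonds))
})

test_that("parameter validation enforces the type invariants", {
  ff <- load_bilff()
  ff$types$sigma[1] <- -1
  expect_error(validate_forcefield <- bilff:::validate_forcefield(ff), "sigma")
})
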