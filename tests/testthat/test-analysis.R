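# Trajectory analyses against fixtures with known statistical structure.

test_that("ideal-gas RDF is flat at 1 and frozen pair occupies a single bin", {
  tr <- make_fixture(fixture_spec("ideal_gas", frames = 200, box = 2000,
                                  seed = 4, n = 300))
  g <- rdf(tr, 1:300, 1:300, bin_width = 10)
  inside <- g$r > 100          # skip the few-count innermost shells
  expect_true(all(abs(g$g[inside] - 1) < 0.05))
  tr2 <- make_fixture(fixture_spec("frozen_pair", frames = 5, box = 5000, d = 300))
  g2 <- rdf(tr2, 1, 2, bin_width = 10)
  occupied <- which(g2$g > 0)
  expect_length(occupied, 1)
  expect_lt(abs(g2$r[occupied] - 300), 10)
})

test_that("first_peak finds a synthetic peak and rejects monotone curves", {
  tr <- make_fixture(fixture_spec("gaussian_shell", frames = 400, box = 4000,
                                  r0 = 200, sd = 10, n_t = 30, seed = 9))
  g <- rdf(tr, 1, 2:31, bin_width = 5)
  pk <- first_peak(g, smooth = 3)
  expect_lt(abs(pk$r_peak - 200), 10)
  expect_false(is.na(pk$r_min))
  mono <- structure(data.frame(r = 1:100, g = seq(0, 2, length.out = 100)),
                    class = c("bilff_rdf", "data.frame"), rho = 0.01)
  expect_error(first_peak(mono), "no peak")
})

test_that("coordination number matches the ideal-gas closed form within 1%", {
  tr <- make_fixture(fixture_spec("ideal_gas", frames = 200, box = 2000,
                                  seed = 4, n = 300))
  g <- rdf(tr, 1:300, 1:300, bin_width = 10)
  rho <- attr(g, "rho")
  for (R_pm in c(400, 600)) {
    expect_equal(coordination_number(g, R_pm),
                 4 / 3 * pi * (R_pm / 100)^3 * rho,
                 tolerance = 0.01)
  }
  # g = 0 everywhere integrates to 0
  g0 <- g; g0$g[] <- 0
  expect_equal(coordination_number(g0, 600), 0)
})

test_that("distance-angle distribution puts collinear mass at 0 and right angles at 90", {
  mk <- function(acc_pos) {
    p0 <- rbind(c(0, 0, 0), c(1, 0, 0), acc_pos)
    sys <- raw_system(p0, box = 0, mol_id = c(1, 1, 2))
    bilff:::.as_traj(sys, matrix(as.vector(t(p0)), 1), 1000, 0)
  }
  lin <- cdf_distance_angle(mk(c(3, 0, 0)), don = 1, hyd = 2, acc = 3)
  expect_equal(sum(lin$counts), 1)
  expect_lt(lin$angle[which(colSums(lin$counts) > 0)], 5)
  perp <- cdf_distance_angle(mk(c(1, 2, 0)), don = 1, hyd = 2, acc = 3)
  expect_equal(perp$angle[which(colSums(perp$counts) > 0)], 90, tolerance = 0.05)
  expect_error(cdf_distance_angle(mk(c(3, 0, 0)), don = 1, hyd = 2,
                                  acc = integer(0)), "length")
})

test_that("SDF conserves counts, is flat for uniform targets and peaked for rigid ones", {
  # all targets on a tight shell: everything inside the grid
  tr <- make_fixture(fixture_spec("gaussian_shell", frames = 60, box = 4000,
                                  r0 = 250, sd = 20, n_t = 25, seed = 12))
  top <- tr$topology
  top$atoms$species[1:3] <- "REF"
  top$atoms$label[1:3] <- c("A1", "A2", "A3")
  top$atoms$mol_id[1:3] <- 1L
  tr$topology <- top
  s <- sdf(tr, "REF", c("A1", "A2", "A3"), target = 4:26,
           extent = 600, resolution = 60)
  vox_nm3 <- (60 / 1000)^3
  expect_equal(sum(s$density) * vox_nm3, 23, tolerance = 0.05)
  # rigid co-moving target: single-voxel spike
  n <- 5
  pos <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(3, 3, 0))
  fm <- do.call(rbind, lapply(seq_len(n), function(k) {
    shift <- c(k, 2 * k, 0.5 * k)
    as.vector(t(sweep(pos, 2, shift, `+`)))
  }))
  sys <- raw_system(pos, box = 0)
  sys$atoms$species <- c("REF", "REF", "REF", "T")
  sys$atoms$label <- c("A1", "A2", "A3", "T")
  sys$atoms$mol_id <- c(1L, 1L, 1L, 2L)
  trr <- bilff:::.as_traj(sys, fm, 1000, 0)
  trr$topology <- sys
  s2 <- sdf(trr, "REF", c("A1", "A2", "A3"), target = 4,
            extent = 500, resolution = 50)
  expect_equal(sum(s2$density > 0), 1)
  expect_error(sdf(trr, "REF", c("A1", "A1", "A1"), target = 4), "collinear")
})

test_that("telegraph fixture recovers the breakage rate within 10%", {
  for (k_off in c(0.1, 0.5, 2.0)) {
    # scale window/rate so each series holds many events
    dt_fs <- if (k_off < 0.3) 500 else 100
    tr <- make_fixture(fixture_spec("telegraph_hbond", frames = 4000,
                                    dt = dt_fs, seed = 3, n_pairs = 60,
                                    k_on = k_off, k_off = k_off))
    pr <- attr(tr, "pairs")
    lt <- hbond_lifetimes(tr, pr$don, pr$hyd, pr$acc)
    expect_equal(lt$tau_continuous, 1 / k_off, tolerance = 0.10)
  }
})

test_that("continuous lifetime never exceeds the intermittent lifetime", {
  for (seed in 1:4) {
    tr <- make_fixture(fixture_spec("telegraph_hbond", frames = 2000, dt = 200,
                                    seed = seed, n_pairs = 40,
                                    k_on = 0.3 * seed, k_off = 0.6 / seed))
    pr <- attr(tr, "pairs")
    lt <- hbond_lifetimes(tr, pr$don, pr$hyd, pr$acc)
    expect_lte(lt$tau_continuous, lt$tau_intermittent)
  }
})

test_that("a permanent bond is censored at the window length", {
  tr <- make_fixture(fixture_spec("telegraph_hbond", frames = 200, dt = 100,
                                  seed = 1, n_pairs = 5, k_on = 100, k_off = 1e-9))
  pr <- attr(tr, "pairs")
  lt <- hbond_lifetimes(tr, pr$don, pr$hyd, pr$acc)
  expect_true(lt$censored["continuous"])
  window_ps <- (200 %/% 2) * 0.1
  expect_equal(lt$tau_continuous, window_ps, tolerance = 0.05)
})

test_that("no bonds under the criterion is an explicit error", {
  tr <- make_fixture(fixture_spec("telegraph_hbond", frames = 50, dt = 100,
                                  seed = 1, n_pairs = 3))
  pr <- attr(tr, "pairs")
  expect_error(hbond_lifetimes(tr, pr$don, pr$hyd, pr$acc,
                               hbond_criterion(rmax = 50)), "no hydrogen bonds")
})

test_that("Brownian fixture recovers its diffusion coefficient within 10%", {
  tr <- make_fixture(fixture_spec("brownian", frames = 500, dt = 1000,
                                  D = 20, n = 60, seed = 8))
  d <- diffusion(tr, 1:60)
  expect_equal(d$D, 20, tolerance = 0.10)
  expect_gt(d$r_squared, 0.99)
  # frozen particles do not diffuse
  frz <- make_fixture(fixture_spec("frozen_pair", frames = 100, box = 4000))
  d0 <- diffusion(frz, 1:2)
  expect_equal(d0$D, 0, tolerance = 1e-10)
})

test_that("analyses are invariant under rigid translation and particle relabeling", {
  tr <- make_fixture(fixture_spec("ideal_gas", frames = 50, box = 2000,
                                  seed = 6, n = 100))
  g0 <- rdf(tr, 1:50, 51:100, bin_width = 20)
  # rigid translation of every frame
  trt <- tr
  shift <- rep(c(5, -3, 9), 100)
  trt$frames <- sweep(tr$frames, 2, rep(shift, 1), `+`)
  gt <- rdf(trt, 1:50, 51:100, bin_width = 20)
  expect_equal(gt$g, g0$g, tolerance = 1e-12)
  # relabeling within the identical target set
  perm <- c(51:100)[sample(50)]
  gp <- rdf(tr, 1:50, perm, bin_width = 20)
  expect_equal(gp$g, g0$g, tolerance = 1e-12)
})

test_that("derive_hbond_criterion brackets the first peak of a synthetic bond", {
  tr <- make_fixture(fixture_spec("telegraph_hbond", frames = 1000, dt = 100,
                                  seed = 2, n_pairs = 40, k_on = 1, k_off = 1))
  pr <- attr(tr, "pairs")
  cr <- derive_hbond_criterion(tr, pr$don, pr$hyd, pr$acc)
  # bonded state sits at 200 pm, unbonded at 600 pm: the cutoff separates them
  expect_gt(cr$rmax, 200)
  expect_lt(cr$rmax, 600)
})
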