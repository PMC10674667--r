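# Integrator, thermostats, barostat, SHAKE, protocol determinism.

test_that("NVE conserves energy and linear momentum (symplectic integrator)", {
  dimer <- raw_system(rbind(c(0, 0, 0), c(3.5, 0, 0)), box = 0,
                      sigma = 3.4, epsilon = 0.996, mass = 39.95)
  cfg <- integrator(dt = 0.5, thermostat = "none", save_every = 100, seed = 2)
  v0 <- matrix(c(0.01, 0, 0, -0.01, 0, 0), 2, 3, byrow = TRUE)
  tr <- integrate_nvt(dimer, nb_options("cutoff", rc_lj = 1500), cfg, 10000,
                      vel = v0)
  E <- tr$epot + tr$ekin
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-4)
  # total momentum stays zero
  m <- dimer$atoms$mass
  p_end <- colSums(tr$final$vel * m)
  expect_lt(max(abs(p_end)), 1e-10)
})

test_that("Langevin and Nose-Hoover thermostats hold the target temperature", {
  fluid <- lj_fluid()
  cfg <- integrator(dt = 2, thermostat = "langevin", tau_t = 200,
                    temperature = 350, seed = 3, save_every = 50)
  tr <- integrate_nvt(fluid, nb_options("cutoff", rc_lj = 1000), cfg, 25000)
  expect_equal(mean(tr$temperature[-(1:100)]), 350, tolerance = 0.05)
  cfg2 <- integrator(dt = 2, thermostat = "nosehoover", tau_t = 100,
                     temperature = 350, seed = 3, save_every = 50)
  tr2 <- integrate_nvt(fluid, nb_options("cutoff", rc_lj = 1000), cfg2, 25000)
  expect_equal(mean(tr2$temperature[-(1:100)]), 350, tolerance = 0.02)
})

test_that("the barostat reproduces the ideal-gas equation of state", {
  set.seed(9)
  ig <- raw_system(matrix(runif(192, 0, 40), 64, 3), box = 40,
                   sigma = 1, epsilon = 0, q = 0, mass = 20)
  cfg <- integrator(dt = 10, thermostat = "langevin", tau_t = 500,
                    temperature = 300, barostat = TRUE, tau_p = 2000,
                    pressure = 10, seed = 4, save_every = 20)
  tr <- integrate_npt(ig, nb_options("cutoff", rc_lj = 500, rc_coul = 500),
                      cfg, 20000)
  v_pred <- 64 * bilff_constants$kB * 300 / (10 * bilff_constants$bar)
  v_mean <- mean(tr$box[-(1:500)]^3)
  expect_equal(v_mean, v_pred, tolerance = 0.10)
  # barostat off: box never moves
  cfg$barostat <- FALSE
  tr2 <- integrate_nvt(ig, nb_options("cutoff", rc_lj = 500, rc_coul = 500),
                       cfg, 200)
  expect_true(all(tr2$box == 40))
})

test_that("SHAKE restores perturbed rigid water and detects infeasibility", {
  ff <- ff_full()
  comp <- composition(TIP4PEW = 1, box_edge = 3000)
  sys <- build_system(comp, ff, pos = bilff:::.template_coords("TIP4PEW"))
  # already satisfied: unchanged
  p0 <- shake_constrain(sys)
  expect_equal(p0[1:3, ], sys$pos[1:3, ], tolerance = 1e-9)
  # perturbed by 1 pm: restored to the targets
  p <- sys$pos; p[2, 1] <- p[2, 1] + 0.01
  pc <- shake_constrain(sys, p)
  expect_equal(sqrt(sum((pc[1, ] - pc[2, ])^2)), 0.9572, tolerance = 1e-6)
  expect_equal(sqrt(sum((pc[1, ] - pc[3, ])^2)), 0.9572, tolerance = 1e-6)
  # triangle-inequality violation cannot converge
  bad <- sys
  bad$constraints$d <- c(1, 1, 3)
  expect_error(shake_constrain(bad, sys$pos, maxit = 100), "SHAKE did not converge")
})

test_that("rigid water stays rigid through thermostatted dynamics", {
  ff <- ff_full()
  comp <- composition(TIP4PEW = 8, box_edge = 2000)
  sys <- pack_system(build_system(comp, ff), ff, seed = 5, relax_steps = 50)
  cfg <- integrator(dt = 1, thermostat = "langevin", tau_t = 100,
                    temperature = 300, seed = 6, save_every = 100)
  tr <- integrate_nvt(sys, nb_options("dsf"), cfg, 2000)
  p <- tr$final$pos
  for (m in seq_len(8)) {
    o <- 4 * (m - 1)
    expect_equal(sqrt(sum((p[o + 1, ] - p[o + 2, ])^2)), 0.9572, tolerance = 1e-6)
    expect_equal(sqrt(sum((p[o + 2, ] - p[o + 3, ])^2)),
                 2 * 0.9572 * sin(104.52 / 2 * pi / 180), tolerance = 1e-6)
  }
})

test_that("zero steps returns the configuration unchanged", {
  sys <- raw_system(matrix(runif(30, 0, 10), 10, 3), box = 20, mass = 1,
                    epsilon = 0.1, sigma = 2)
  tr <- integrate_nvt(sys, nb_options("cutoff"), integrator(temperature = 100),
                      steps = 0)
  expect_equal(frame_pos(tr, 1), sys$pos)
  expect_equal(n_frames(tr), 1)
})

test_that("identical seeds give identical trajectories", {
  fluid <- lj_fluid(27, spacing = 5, box = 25)
  cfg <- integrator(dt = 2, thermostat = "langevin", tau_t = 100,
                    temperature = 200, seed = 42, save_every = 25)
  opts <- nb_options("cutoff", rc_lj = 1000)
  tr1 <- integrate_nvt(fluid, opts, cfg, 500)
  tr2 <- integrate_nvt(fluid, opts, cfg, 500)
  expect_identical(tr1$frames, tr2$frames)
  cfg$seed <- 43
  tr3 <- integrate_nvt(fluid, opts, cfg, 500)
  expect_false(identical(tr1$frames, tr3$frames))
})

test_that("the staged protocol logs its phases in order and is reproducible", {
  ff <- ff_full()
  comp <- composition(EMTr = 2, OAc = 2, box_edge = 4000)
  run1 <- run_protocol(comp, ff, seed = 7, temperature = 350,
                       t_scramble = 0.05, t_npt = 0, t_damp = 0.05,
                       t_prod = 0.1, save_every = 20)
  st <- attr(run1, "stages")
  expect_identical(st$stage, c("pack", "scramble", "damp", "production"))
  run2 <- run_protocol(comp, ff, seed = 7, temperature = 350,
                       t_scramble = 0.05, t_npt = 0, t_damp = 0.05,
                       t_prod = 0.1, save_every = 20)
  expect_identical(run1$frames, run2$frames)
})

test_that("an exploding configuration aborts with a diagnostic", {
  clashing <- raw_system(rbind(c(0, 0, 0), c(0.2, 0, 0)), box = 0,
                         sigma = 3, epsilon = 5, mass = 0.1)
  cfg <- integrator(dt = 50, thermostat = "none", temperature = 10, save_every = 1)
  expect_error(
    integrate_nvt(clashing, nb_options("cutoff", rc_lj = 1500), cfg, 1000,
                  vel = matrix(0, 2, 3)),
    "blow-up|overlapping")
})
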