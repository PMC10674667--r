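# bilff

All-atom force-field modelling of triazolium- and benzoate-based ionic
liquids in R.

Ionic liquids built from 1-ethyl-3-methyl-1,2,3-triazolium ([EMTr]+) and
carboxylate anions (acetate [OAc]-, benzoate [OBz]-) dissolve cellulose at
mild conditions, and their performance is governed by a dense network of
ionic hydrogen bonds. Simulating that microstructure classically requires a
force field whose charges and radii were tuned against first-principles
reference data. `bilff` packages such a parameter set together with
everything needed to use and scrutinize it on a single workstation:

* the **parameter library** (atom types with partial charges and
  Lennard-Jones parameters; bond/angle/torsion constants keyed by atom
  class; scaled ionic charges of ±0.82 e) plus hand-curated molecule
  templates and a documented plain-text parameter-file format for
  additional species ([OAc]-, [EMIm]+, TIP4P-EW water),
* an **energy/force engine** for the OPLS-AA functional form with geometric
  combining rules — truncated, damped-shifted-force (DSF) and Ewald
  electrostatics, analytic forces, exclusion handling, all in compiled
  code,
* a compact **MD engine**: velocity Verlet at 0.5 fs with Berendsen,
  Langevin and Nosé–Hoover thermostats, an isotropic barostat, SHAKE/RATTLE
  rigid water with a virtual charge site, seeded packing and a staged
  equilibration protocol,
* the **analysis suite** used in force-field validation: radial
  distribution functions and peak metrics, coordination numbers, combined
  distance–angle distributions, spatial distribution functions,
  intermittent/continuous hydrogen-bond lifetimes, and self-diffusion from
  mean squared displacements,
* seeded **synthetic fixtures** (ideal gas, frozen pair, telegraph
  hydrogen bond, Brownian walkers, Gaussian shell) that give every
  estimator an exact oracle,
* readers/writers for extended XYZ, PDB, LAMMPS data ("full" style),
  Gaussian cube and YAML run configs, and a thin command-line front end
  (`inst/scripts/bilff`).

The model is the OPLS-AA form

    U = sum k_l (l - l0)^2 + sum k_theta (theta - theta0)^2
      + sum_n V_n/2 [1 +/- cos(n phi)]
      + sum_{i<j} f_ij { 4 eps_ij [ (sig_ij/r)^12 - (sig_ij/r)^6 ]
                         + ke q_i q_j / r }

with geometric means for both `sig_ij` and `eps_ij`, harmonic terms without
the 1/2 prefactor, OPLS exclusions (f12 = f13 = 0, f14 = 0.5) and net ionic
charges scaled to ±0.82 e. See the methods vignette
(`vignettes/bilff-methods.Rmd`) for the full account.

## Worked example

```r
library(bilff)

ff <- load_bilff(extra = bilff_extdata("oac_synthetic.prm"))
ff
#> BILFF force field (OPLS-AA form, geometric combining rules)
#>   21 atom types over species: EMTr, OBz, OAc
#>   12 bond, 18 angle, 22 torsion parameter rows
#>   1-2/1-3/1-4 scaling: 0.0 / 0.0 / 0.5

template_charge(build_molecule("EMTr"), ff)   # scaled net ionic charge
#> [1] 0.82

# 36 ion pairs of [EMTr][OAc] in a 2121 pm box: density bookkeeping
comp <- composition(EMTr = 36, OAc = 36, box_edge = 2121)
system_density(comp, ff)                      # g/cm^3
#> [1] 1.072589

# pack the box (seeded, internal) and evaluate energy and forces
sys <- pack_system(build_system(comp, ff), ff, seed = 1)
total_energy_forces(sys, nb_options("dsf"))
#> bilff energy report (kJ/mol)
#>   bond          1309.2776
#>   angle         5019.4619
#>   torsion       1326.7456
#>   lj            6182.0378
#>   coulomb     -14810.2316
#>   total         -972.7088
```

The packed configuration is a relaxed lattice start, not an equilibrated
liquid — hence the positive bonded/LJ terms; `run_protocol()` takes it
through scramble/NpT/production stages:

```r
tr <- run_protocol(comp, ff, seed = 1, temperature = 350,
                   opts = nb_options(lj_tail = TRUE),
                   t_scramble = 2, t_npt = 10, t_damp = 1, t_prod = 15)
hcw <- select_atoms(tr$topology, species = "EMTr", type = "HCW")
o2  <- select_atoms(tr$topology, species = "OAc", type = "O2")
g <- rdf(tr, hcw, o2, bin_width = 5)     # pm-resolved g(r)
first_peak(g, min_height = 1)            # ring-H...O hydrogen-bond peak
plot(g)
```

On a 24-ion-pair box this reproduces the characteristic ring-proton⋯oxygen
hydrogen-bond peak near 195–200 pm with g(r) ≈ 5.

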