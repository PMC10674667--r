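---
title: "Modelling triazolium and benzoate ionic liquids with bilff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling triazolium and benzoate ionic liquids with bilff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`bilff` is a self-contained toolkit for classical all-atom simulations of
cellulose-dissolving ionic liquids built from the
1-ethyl-3-methyl-1,2,3-triazolium cation ([EMTr]+) and the benzoate anion
([OBz]-), with pluggable parameter files for acetate ([OAc]-),
1-ethyl-3-methylimidazolium ([EMIm]+) and TIP4P-EW water. The potential is
the OPLS-AA functional form

$$
U = \sum_{\mathrm{bonds}} k_l (l - l_0)^2
  + \sum_{\mathrm{angles}} k_\theta (\theta - \theta_0)^2
  + \sum_{\mathrm{dihedrals}} \sum_{n=1}^{4} \frac{V_n}{2}
      \left[1 \pm \cos(n\phi)\right]
  + \sum_{i<j} \left\{ 4\epsilon_{ij}\left[
      \left(\tfrac{\sigma_{ij}}{r_{ij}}\right)^{12} -
      \left(\tfrac{\sigma_{ij}}{r_{ij}}\right)^{6}\right]
      + \frac{q_i q_j e^2}{4\pi\epsilon_0 r_{ij}} \right\} f_{ij}
$$

with *geometric* combining rules for both $\sigma$ and $\epsilon$, harmonic
bonded terms **without** the $1/2$ prefactor, and the four-term OPLS Fourier
torsion. Note the harmonic convention: published force constants are used
verbatim, so $U = k_l (l - l_0)^2$, not $\tfrac{1}{2} k_l (l-l_0)^2$.

The net ionic charge is scaled to $\pm 0.82\,e$, a widely used mean-field
surrogate for electronic polarization in ionic-liquid force fields. The
embedded charge set closes these sums *exactly*: the cation types
(2 NA, 1 NR, 2 CW, 2 HCW, 2 C1, 5 H1, 1 CE, 3 HC) total $+0.820\,e$ and the
benzoate types (CO, 2 O2, 6 aromatic C, 5 aromatic H) total $-0.820\,e$.
The alias types CM/HM/HE that appear in structure drawings resolve to
C1/H1/HC; this is the unique assignment under which the charge sums close.

### Exclusion policy

$f_{ij}$ is not part of the published table set; `bilff` adopts the OPLS-AA
convention $f_{12}=f_{13}=0$, $f_{14}=0.5$ applied to both Lennard-Jones and
Coulomb terms (configurable through `load_bilff(exclusion_policy = ...)`).
Pairs are classified by shortest bond-graph distance, so fused and aromatic
rings are handled correctly, and rigid-water constraints/virtual-site
attachments count as graph edges (all water intramolecular pairs are
excluded).

### What is embedded and what is not

Only the parameters printed for [EMTr]+ and [OBz]- are embedded. The full
acetate and imidazolium sets belong to earlier releases of the force-field
family and are *not* reproduced here; the package ships synthetic stand-in
files (`oac_synthetic.prm`, `emim_synthetic.prm`) that honour the few
documented values (acetate O charge $-0.66\,e$; imidazolium ring-proton
charge $+0.150\,e$, $\sigma = 1.62$ Å) and close the net charge at
$\pm0.82\,e$, with OPLS-AA-style values elsewhere. Results obtained with the
stand-ins demonstrate the machinery; they are not a substitute for the
published sets. TIP4P-EW water uses the standard published model (rigid
geometry, negative charge on the massless M site at 0.125 Å on the
bisector).

## Electrostatics

Three treatments are implemented behind one switch (`nb_options()`):

* `cutoff` — truncated minimum-image Coulomb; for testing and isolated
  systems only.
* `dsf` — damped shifted-force Coulomb (Fennell–Gezelter), default
  $\alpha = 0.25$ Å$^{-1}$ at the 800 pm cutoff. Energy and force go
  smoothly to zero at the cutoff; this is the default for condensed-phase
  dynamics.
* `ewald` — classical Ewald summation (real + reciprocal space, tinfoil
  boundary) with exact handling of the scaled intramolecular pairs.

The Ewald path is validated against the closed-form Madelung energy of rock
salt (agreement to $\sim 10^{-4}$ kJ/mol at converged settings) and by
$\alpha$-independence. The reduced demonstration runs use DSF rather than
per-step Ewald: at the package's intended single-workstation scale the
pairwise kernel is several times faster, and for the homogeneous,
charge-neutral boxes studied here DSF is an established production-quality
approximation. Ewald remains available for reference energies. Inside the
MD loop the DSF kernel is evaluated from an 8192-point table on an $r^2$
grid (interpolation error $\lesssim 10^{-5}$ relative); the one-shot energy
evaluator always uses the analytic kernel.

A mean-field Lennard-Jones tail correction (energy and virial) beyond the
cutoff is available and switched **off** by default; constant-pressure runs
should enable it (`nb_options(lj_tail = TRUE)`), since tail-less truncation
at 800 pm biases the pressure of these liquids upward by several hundred
bar and correspondingly underestimates NpT densities.

## Dynamics

Velocity-Verlet integration (default timestep 0.5 fs) with

* Berendsen thermostat (used only for the 500 K scramble stage; the printed
  1 fs coupling is aggressive by design),
* Langevin thermostat (BAOA-type splitting; momentum re-zeroed
  deterministically every `com_every` steps because the noise does not
  conserve it),
* Nosé–Hoover chains of length 2 (100 fs coupling by default; the chain
  length is the package's choice, the published protocol does not state
  one),
* an isotropic Nosé–Hoover-style barostat (2000 fs coupling, default
  1.01325 bar — the published protocol never states the target pressure, so
  1 atm is assumed).

Rigid water is maintained by SHAKE (positions) and RATTLE (velocities); the
M charge site is a massless virtual site whose force is redistributed onto
O/H each step.

**Pressure.** The instantaneous pressure uses the *molecular* (centre-of-
mass) virial, $PV = \tfrac{2}{3}K_{\mathrm{com}} + \tfrac{1}{3}\left[W +
\sum_i \mathbf{F}_i\cdot(\mathbf{R}_{\mathrm{com}(i)} -
\mathbf{r}_i)\right]$, in which all intramolecular force contributions
(bonded terms, constraint forces, virtual-site transmission) cancel
identically. This formulation is exact for flexible, constrained and
virtual-site molecules alike; the pairwise virial $W$ is verified against a
numerical volume derivative, and the barostat reproduces the ideal-gas
equation of state to better than 1%.

**Packing.** Box construction is internal and seeded: molecules are relaxed
in vacuum, placed on a jittered lattice with uniformly random orientations
(robust at liquid density), and residual contacts are removed with a
capped-displacement minimizer. Random insertion with a 2 Å overlap
rejection is available as an alternative (`method = "random"`), but the
lattice method is the default because rejection sampling stalls at
realistic liquid densities.

The staged protocol (`run_protocol()`) is: pack → 500 K NVT scramble
(Berendsen) → NpT at the target temperature (Nosé–Hoover thermostat +
barostat) → short Langevin damping → NVT production (Nosé–Hoover). All
stage durations and couplings are configurable; a fixed master seed makes
the whole pipeline bit-reproducible.

## Analyses

* **RDF** — shell-volume/ideal-density normalized minimum-image histogram
  (default 1 pm bins; results in pm). The normalization density excludes,
  per observer, the self pair and optionally same-molecule targets, so an
  ideal gas gives exactly $g = 1$ in expectation. Non-periodic (cluster)
  input is normalized to the analysis sphere instead and then carries
  relative structure only.
* **Peak metrics** — `first_peak()` smooths with a short running mean
  (default 3 bins, never stored) and reports the first local maximum and
  the following minimum, the conventional coordination bound.
* **Coordination number** — $n = 4\pi\rho\int_0^{r_{\min}} g(r) r^2 dr$ by
  midpoint quadrature; matches the ideal-gas closed form to < 0.1%.
* **CDF** — 2D histogram over the H⋯acceptor distance and the deviation
  from donor–H⋯acceptor linearity (0° = linear bond).
* **SDF** — target density in an orthonormal molecule-fixed frame built
  from three anchor atoms, reported in nm$^{-3}$; exportable as a Gaussian
  cube file.
* **Hydrogen-bond lifetimes** — per-pair indicator series under a geometric
  criterion. The *intermittent* lifetime integrates the normalized
  autocorrelation $C(t) = \langle h(0)h(t)\rangle / \langle h\rangle$
  (re-formation allowed) with a single-exponential tail fit beyond the
  window; finite trajectories cannot sample the very long intermittent
  lifetimes of neat ionic liquids directly, so window-limited values are
  lower bounds and a non-decaying tail is flagged as censored rather than
  extrapolated. The *continuous* lifetime integrates the survival
  probability of an uninterrupted bond, estimated from run lengths with
  trajectory-end censoring handled in the denominator; on a two-state
  telegraph fixture it recovers $1/k_{\mathrm{off}}$ to within the sampling
  error (~1% at $10^4$ events) and $S(t) \le C(t)$ holds pointwise, so the
  continuous lifetime never exceeds the intermittent one.
* **Diffusion** — Einstein relation with all time origins, lags up to 50%
  of the window and a fit over the 20–100% portion of the lag range;
  engine coordinates are stored unwrapped so no image bookkeeping is
  needed.

### The hydrogen-bond criterion

The default criterion (H⋯O ≤ 300 pm, deviation ≤ 30°) brackets the first
peak of strong ionic hydrogen bonds. For *continuous* lifetimes this
default is deliberately conservative and, in these weakly directional
C–H⋯O systems, breaks bonds on every librational excursion: the measured
continuous lifetime is then dominated by angular flicker. Because published
criteria for these systems are defined from the first maximum of the
underlying distributions, the package provides
`derive_hbond_criterion()`, which sets the distance cutoff at the first RDF
minimum and the angular cutoff at the smallest angle containing 90% of the
close-contact angular mass. The reduced-scale checks use this derived
criterion with a 100 fs analysis stride; both choices are exposed as
options, not hard-coded.

## Synthetic fixtures

`make_fixture()` generates seeded trajectories with known statistics:
uniform ideal gas (flat RDF, Poisson voxel counts), a frozen pair (single
occupied RDF bin), a two-state telegraph hydrogen bond with prescribed
on/off rates (known continuous lifetime), Brownian walkers with a
prescribed diffusion coefficient, and a Gaussian radial shell (known peak
position). These are the oracles for the analysis layer; what they do *not*
emulate is the coupling of real liquids — momentum conservation,
collectivity, long-range order — so passing fixture tests validates the
estimators, not the force field. The force field itself is validated by the
exact desk-scale identities (charge closure, density arithmetic of the
published compositions) and the reduced-scale runs below.

## Problem sizes and expectations at reduced scale

The published validation runs are 128-ion-pair, 10 ns simulations. The
package's self-checks instead use 24 ion pairs of [EMTr][OAc] (~28 ps of
staged dynamics) and 18 ion pairs + 54 waters of aqueous [EMTr][OBz]
(~21 ps), sizes chosen for a single-CPU workflow. Tolerance bands for these
stochastic reproductions were fixed before the runs were first measured:
RDF first-peak position ±15%, peak height ±30%, cation coordination
±0.4, continuous lifetime within [1, 10] ps, NpT density within the 3%
used for density comparisons.

At these settings the hydrogen-bond microstructure reproduces well: the
ring-proton⋯acetate-oxygen RDF peaks near 195–200 pm with $g \approx 5$,
the aqueous benzoate system peaks near 200 pm with $g \approx 2$–2.5, and
the continuous lifetime lands at 2–3 ps. Two observables sit outside their
bands and are reported honestly rather than re-tuned: the NpT density of
the reduced [EMTr][OAc] box converges to ~1.00–1.05 g/cm³ against the
published 1.11 (the synthetic acetate stand-in carries unoptimized OPLS-AA
Lennard-Jones radii — and tuning $\sigma$ against density is precisely the
optimization the published acetate set went through — compounded by DSF
electrostatics and 24-pair finite size), and the aqueous cation
coordination fluctuates around 1.0–1.4 between seeds at this system size.

## Numerical choices and degenerate inputs

* Internal units: Å, amu, e, kJ/mol with a 100 fs time unit, making the
  unit system self-consistent (no conversion constants inside the
  integrator). The Coulomb constant is fixed at
  $e^2/4\pi\epsilon_0 = 1389.35457644382$ kJ mol$^{-1}$ Å e$^{-2}$.
* Interfaces follow the field's conventions: pm for structural distances,
  ps for lifetimes, $10^{-11}$ m² s$^{-1}$ for diffusion, fs for timesteps.
* Overlapping atoms (r < 1 pm) and energy overflow abort with diagnostics;
  SHAKE non-convergence (e.g. triangle-inequality-violating constraints)
  reports the worst violation; cutoff runs refuse boxes smaller than twice
  the cutoff; monotone RDFs raise a "no peak" error instead of returning a
  boundary artifact.
* A Verlet neighbour list (1 Å skin, rebuilt every 10 steps) accelerates
  the MD pair loop; it is bypassed automatically when the listing radius
  would exceed half the box.

## Known limitations

* No improper torsions: aromatic planarity is maintained by the large ring
  $V_2$ terms alone, as in the published parameter set.
* The barostat requires pairwise electrostatics (cutoff/DSF); the Ewald
  reciprocal-space virial is not implemented.
* PPPM, GPU kernels and replica exchange are out of scope; multi-ns
  production runs are possible in principle but slow in this engine.
* Atom typing is template-based; arbitrary molecules are not auto-typed.
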