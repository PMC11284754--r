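---
title: "Methods: coarse-grained membrane wrapping of spiked nanostars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained membrane wrapping of spiked nanostars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`starwrap` simulates receptor-mediated wrapping (the first step of
endocytosis) of a rigid nanoparticle by a lipid bilayer, using an
implicit-solvent coarse-grained model in reduced Lennard-Jones units:
sigma (length), epsilon (energy), tau (time), with all bead masses 1
and kB = 1. Comparing the simulated bilayer thickness with real
membranes maps sigma to roughly 1 nm.

## Lipids

Each lipid is three beads: one head and two tail beads, the
widely used implicit-solvent parameterization in which a broad
attraction between tail beads substitutes for the hydrophobic effect,
so no solvent particles are needed. Within a lipid:

* consecutive beads are joined by FENE bonds,
  `U = -1/2 K1 rmax^2 log(1 - (r/rmax)^2)` with `K1 = 30 eps` and
  maximum extension `rmax = 1.5 sigma`;
* the three beads carry a harmonic angle
  `U = K2 (theta - theta0)^2`, `K2 = 10 eps`, `theta0 = 180 deg`,
  keeping the lipid straight.

A note on `rmax`: the source parameterization calls 1.5 sigma the
"equilibrium bond length" of the FENE bond, but a FENE potential
diverges at that radius and has no finite-energy minimum there. We
follow the convention of the underlying lipid model, where 1.5 sigma
is the divergence (maximum-extension) radius; the actual bond length
equilibrates near 0.97 sigma against the repulsive core.

Nonbonded interactions follow a per-bead-kind pair table:

| pair | potential | parameters |
|---|---|---|
| head-head, head-tail | WCA | b = 0.95 sigma |
| tail-tail | WCA core + cos attraction | b = 1 sigma, wc = 1.5 sigma |
| particle/ligand vs lipid beads | WCA | b = 1 sigma |
| receptor vs lipid beads | WCA | b = 0.95 sigma (receptors are heads) |
| intra-particle pairs | none | rigid body |

The WCA potential is the purely repulsive cut-and-shifted
Lennard-Jones, zero beyond `2^(1/6) b`. The tail attraction is
`-eps` out to contact and `-eps cos^2(pi (r - rc)/(2 wc))` over a
width `wc = 1.5 sigma`; this width controls the membrane phase
behavior, and at temperature 1 eps/kB the bilayer is a stable fluid.
The printed "WCA cutoff of 1.5 sigma" in the source is read as this
attraction width `wc`, consistent with the parameter table; a WCA
cutoff is fixed at `2^(1/6) b` by definition.

**Bonded-pair convention.** The reference simulations were run in
LAMMPS, whose FENE bond style requires 1-2 pair exclusion
(`special_bonds 0 1 1`) with the bond itself carrying a WCA core of
sigma = 1. We adopt the same convention: directly bonded beads
interact through FENE + a WCA core with b = 1 sigma, and are excluded
from the pair table. 1-3 pairs interact normally (their separation is
beyond every WCA cutoff in practice). This choice matters at the
0.1-sigma level for the bilayer thickness, because the head-tail bond
length depends on which repulsive core acts inside the bond.

## Ligand-receptor adhesion

Half of the lipid heads, chosen uniformly at random, are receptors; a
subset of particle surface beads are ligands. Bound ligand-receptor
pairs interact by a Morse potential
`U = eps_LR ((1 - e^(-alpha (r - r0)))^2 - 1)` with dissociation
energy `eps_LR = 30 eps`, equilibrium length `r0 = 1 sigma`, and
`alpha = 1 / sigma` (the source prints alpha with units of length;
dimensional analysis requires inverse length, so we use 1/sigma and
flag the reading here). Bonds are explicit and stochastic:

* an unbound ligand and unbound receptor within 1.3 sigma form a bond
  with 50% probability per check;
* a bond breaks with certainty when stretched beyond 4 sigma (the
  Morse evaluation is cut off at the same distance);
* valence is one bond per ligand and per receptor; candidate pairs
  are processed in randomized order so the constraint is never
  violated.

The check cadence is not stated in the source; with p = 0.5 per check,
per-step checks make formation effectively instantaneous, so the
interval is a visible parameter (`bond_check_interval`, default 10
steps = 0.1 tau) recorded in run metadata.

Unbound ligand-receptor pairs still repel via WCA (the parameter
table lists both WCA and Morse for this pair); the Morse term acts
only on currently bonded pairs, and the engine counts one Morse
evaluation per bond per step as a bookkeeping invariant.

## Dynamics

Langevin dynamics at `T = 1 eps/kB` with damping `gamma = 1/tau` and
timestep `dt = 0.01 tau`, integrated with the Gronbech-Jensen/Farago
(GJF) scheme, whose configurational sampling and half-step velocity
estimator are unbiased at finite dt (a plain velocity-Verlet full-step
velocity overestimates the kinetic temperature by a few percent at
this timestep against the stiff FENE/WCA bonds). Kinetic temperature
is therefore reported from the half-step displacements. Random thermal
kicks use variance-matched uniform deviates, the standard trick in
production MD engines: only the first two moments of the noise enter
the fluctuation-dissipation balance, and velocities become Gaussian by
the central limit theorem within a few 1/gamma. Equipartition and free
diffusion are verified in the test suite against the exact
Ornstein-Uhlenbeck expectations.

**Zero-tension barostat.** The source names a Nose-Hoover barostat
with pressure damping 1 tau imposing zero tension in the membrane
plane. We implement the same contract with a weak-coupling
(Berendsen-style) area rescale: the instantaneous lateral tension is
measured from the Kirkwood virial,
`Gamma A = (sum m vz^2 + Wzz) - (sum m(vx^2+vy^2) + Wlat)/2`,
and the box area is rescaled every 10 steps using the tension
averaged over the interval,
`dA/A = -(10 dt) (mean Gamma - Gamma_target) / (tauP KA)` (clamped to
1% per rescale), with `KA` an order-of-magnitude estimate of the area
compressibility (20 eps/sigma^2) that sets only the relaxation rate.
The averaging matters: rescaling every step against the instantaneous
(noisy) tension does work correlated with the fluctuations and was
measured to heat the membrane by ~5%; the interval average removes
the correlation and the thermostat holds 1.00 eps/kB.
The fixed point (zero mean tension, stationary area) is identical to
the Nose-Hoover target and is what every observable in scope depends
on; the extended-Lagrangian fluctuation spectrum of a true
Nose-Hoover chain is not. Lz is never rescaled; the box is periodic
in X and Y only and open in Z, so no interaction crosses the Z
boundary.

**Rigid particle.** The nanoparticle moves as one rigid body
(mobile and thermostatted by default, with a frozen mode as a
sensitivity flag, since the source does not state the particle's
equation of motion). Forces and torques on all particle beads are
summed; translation uses the total mass, rotation a scalar (isotropic)
moment of inertia, adequate for these nearly spherical shells; the
rotation itself is applied with an exact Rodrigues rotation so
intra-particle distances are preserved to floating-point precision
(audited at 1e-8 sigma in the tests). Langevin friction and noise act
on the body's six degrees of freedom with coefficients summed over its
beads. When the barostat rescales the box, only the body's center of
mass is remapped, preserving its shape.

**Neighbor lists.** Verlet lists with per-pair-kind radii (short for
WCA-only pairs, the full attraction range for tail pairs, the bond
capture radius for receptor-ligand pairs) and a 0.9-sigma skin,
rebuilt on a half-skin displacement trigger from a cell grid.
Correctness is enforced by an oracle test: total nonbonded energy
from the neighbor-list path must equal a deliberately naive all-pairs
O(N^2) evaluation in R to 1e-10 on small systems. In the inner force
loop the smooth tail-attraction force is linearly tabulated in r^2
(4096 bins, error ~1e-7 eps/sigma); energies are always evaluated
from the exact expressions, which is why the oracle comparison holds
at 1e-10.

# The particles

Spiked nanostars are bead shells: a core sphere (radius 7 sigma) plus
tips (length 5 sigma, basal radius 3 sigma, apex radius 1.5 sigma),
maximum radial extent 12 sigma; comparison spheres have radius 12
sigma, the same maximum extent. Beads are laid out with a
deterministic Fibonacci (golden-angle) lattice on the core and on
concentric rings along the tip cones, targeting a homogeneous
1-sigma spacing (the WCA diameter, so the shell is impenetrable to
lipids). The exact surface algorithm of the source is in its
supplement and unavailable; the Fibonacci scheme satisfies the stated
property (even spacing) and is used for surface beads, tip axes, and
patch centers alike. With 35 tips of 3-sigma basal radius on a
7-sigma core the tip bases necessarily overlap; tip flank beads are
trimmed at the midline between adjacent tips with 1.6 bead-spacings of
clearance, so every tip remains a distinct connected component - the
spiky silhouette survives, and a single-linkage clustering test
recovers exactly the nominal tip count.

Ligands on stars are confined to the outermost 3 sigma of the
12-sigma extent (tips only), drawn per tip uniformly at random under
a seed. Ligands on spheres form `n_patches` disjoint patches around
Fibonacci-distributed centers; patches claim their nearest unclaimed
beads in index order, which makes equidistant ties deterministic
(lowest patch index wins). The layout series compared in the source
(56x5, 40x7, 35x8, 28x10, 20x14, 14x20, 10x28 patches x
ligands/patch against a 35-tip star with 8 ligands/tip) all carry
exactly 280 ligands, so adhesion energy budgets are identical and
only geometry differs.

**Patch separation metric.** The source tabulates a "separation
distance" per layout (2.8-5.6 sigma) without defining the metric.
`patch_separation()` reports three variants; the mean
nearest-neighbor chord between patch centers comes closest,
reproducing the published column within ~10% across all seven
layouts (2.54-5.65 sigma here), but since the metric is undefined in
the source only the ordering across layouts (monotone in patch
count) is treated as a testable contract.

# Observables

* **Wrapping fraction**: |sum of bonded Morse energies| normalized by
  `N_ligands * eps_LR` (its value if every ligand were bound at the
  well minimum), clamped to [0, 1].
* **Wrapping time T_w**: the source defines completion as the
  fraction "attaining one", which a thermal system approaches but
  never holds; we declare completion when the (lightly smoothed)
  fraction stays at or above a threshold (default 0.9) for a hold
  time (default 100 tau), both config-exposed and recorded. Traces
  that never complete map to N/A, and group ratios
  (sphere T_w / star T_w) propagate N/A as in the published table.
  The energy-based fraction is primary; bond counts are emitted
  alongside (the source is ambiguous between the two, and they are
  proportional at the default parameters).
* **Membrane thickness**: heads are binned on a 0.5-sigma XY grid;
  leaflet = sign of the z-component of the tail2-to-head vector;
  per-bin mean head heights are differenced (upper - lower); empty
  bins are filled by linear interpolation along rows then columns and
  flagged, never silently; the map's mean +/- sd is reported. At the
  equilibrium area per lipid (~1.18 sigma^2) most 0.25-sigma^2 bins
  hold no head in a single frame, so interpolation is a designed-in
  part of the estimator, as in the source.
* **Vesicle membership**: lipids within the interaction range of any
  particle bead, closed under tail-tail contact clustering - the set
  over which lipid displacement is measured "in the final vesicle".
* **Lipid displacement**: mean |x(t + 100 tau) - x(t)| of head beads
  over a lipid set, on unwrapped coordinates maintained by the
  integrator (a periodic jump in input coordinates is detected and
  refused rather than silently reconstructed).
* **Transwell permeability** (utility): Papp = (V/(A C0)) (dC/dt)
  with the published chamber constants as defaults (V = 750 uL,
  A = 0.3 cm^2, C0 = 0.5 mg/mL, dt = 4 h), in cm/s.

# The synthetic world and what green tests establish

There is no external input data: the membrane builder and particle
generators *are* the data generators, and their defaults are the
published system (10,452 lipids in a 77 x 77 sigma box at area per
lipid 1.1345 sigma^2 - the printed numbers imply it - 50% receptors,
280 ligands, five replicas of 1e4 tau). The `reduced` preset
(~1,600 lipids, ~30-sigma box, particle scaled to 6-sigma maximum
radius, 2e3-tau horizon) exists so that property suites run on one
CPU core.

Scale choices in the shipped tests, and why:

* The thickness acceptance run uses a 26 x 26-lipid-per-leaflet
  bilayer (1,352 lipids, 28.3-sigma box): lateral size only enters
  through undulation amplitudes, which are small at these sizes, and
  the run fits a single-CPU time budget.
* The wrapping-order experiment in the test suite is a micro-scale
  analog (4-sigma maximum-radius particles, 968 lipids, fixed
  72-ligand budget) of the published layout series. Particles below
  roughly twice the bilayer thickness cannot be fully engulfed (the
  membrane cannot bend at radii smaller than its own thickness), so
  at this scale the completion analog is the propagation of binding
  across ligand sites: with small patch separations the membrane's
  thermal fluctuations reach the next site and binding spreads;
  beyond a critical separation (~4 sigma center-to-center here) the
  particle stays pinned to its first site for the whole run - the
  same mechanism the published table reports as "N/A" layouts. The
  particle is inserted with one ligand site facing the membrane
  (otherwise sparse layouts may simply never attach: no force acts
  before the first bond). The full published protocol is available
  through `uptake_experiment()` with the `paper` preset and is an
  hours-to-days computation; its quantitative T_w ratios are not
  reproduced at desk scale, and the tests assert only the orderings
  (denser patches spread faster; overly sparse layouts stall;
  star-contact lipids are at least as mobile as sphere-contact
  ones).

A green suite therefore establishes: correct potentials and forces,
a thermodynamically sound integrator/thermostat/barostat, valence-safe
bond kinetics with the stated rates, the stated particle geometry and
ligand budgets, and the qualitative shape-dependence of wrapping at
micro scale. It does not establish the full-scale quantitative uptake
ratios, lipid hydrodynamics (there is no solvent), membrane
electrostatics, or any property of the real silica particles.

# Numerical choices and degenerate inputs

* dt = 0.01 tau with FENE K1 = 30 is the stability limit's
  comfortable side; a FENE bond reaching its divergence radius aborts
  the run with the step index (the signature of too large a step).
* The barostat clamps per-step area changes at 1% and aborts if the
  box falls below 4 sigma (collapse guard).
* Empty thickness leaflets, empty projection masks, fewer than two
  ligand sites, and zero-ligand wrapping fractions raise errors
  rather than NaN.
* Ligand placement with a shell too sparse names the deficient tip.
  Tip placement at `ligand_depth = 0` is an error: an empty ligand
  set can never wrap.
* Replica seeds derive deterministically from the master seed (kept
  below 2^31); identical configs and seeds give bit-identical
  trajectories on the same build.

# Known limitations

* The barostat is weak-coupling, not extended-Lagrangian: area
  *fluctuation spectra* should not be interpreted quantitatively.
* The rigid body uses a scalar moment of inertia; rotational
  diffusion anisotropy of strongly aspherical particles is
  approximate (shape preservation is exact).
* The published "sep. dist" column and the absolute T_w ratios are
  not reproduced at desk scale (see above); orderings are.
* One particle per box; no particle-particle interactions, pore
  structure, or silica chemistry.
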