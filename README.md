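# starwrap

Coarse-grained simulation of membrane wrapping of spiked nanostars.

`starwrap` is an R package (with Rcpp compute kernels) for studying
how nanoparticle shape and ligand placement control receptor-mediated
wrapping — the first step of endocytosis — using an implicit-solvent
coarse-grained model. It is aimed at people modelling nanoparticle
uptake: given a particle geometry (a spiked "nanostar" or a sphere
with ligand patches), it simulates a three-bead-lipid bilayer wrapping
the particle and measures how fast and how completely that happens.

## The model in brief

All quantities are in reduced Lennard-Jones units (σ, ε, τ; the
equilibrated bilayer thickness maps σ ≈ 1 nm).

* **Lipids** (1 head + 2 tail beads): FENE bonds
  U = −½K₁r²ₘₐₓ ln(1 − (r/rₘₐₓ)²) with K₁ = 30 ε, rₘₐₓ = 1.5 σ;
  harmonic angle U = K₂(θ − θ₀)², K₂ = 10 ε, θ₀ = 180°;
  WCA excluded volume (b = 0.95 σ for heads, 1 σ for tails) and a
  cosine-squared tail attraction of depth ε and width w_c = 1.5 σ
  standing in for the hydrophobic effect.
* **Particles**: rigid bead shells. Stars: 7 σ core + 5 σ tips
  (basal radius 3 σ, apex 1.5 σ, maximum extent 12 σ); spheres:
  radius 12 σ. Ligands sit on the outermost 3 σ of star tips, or in
  evenly distributed patches on spheres; the published layout series
  all carry exactly 280 ligands.
* **Adhesion**: reversible ligand–receptor Morse bonds,
  U = ε_LR[(1 − e^(−α(r−r₀)))² − 1], ε_LR = 30 ε, r₀ = 1 σ,
  α = 1 σ⁻¹; bonds form with 50% probability inside 1.3 σ, break
  beyond 4 σ, one bond per ligand and per receptor (valence
  constraint). Half the lipid heads are receptors.
* **Dynamics**: Langevin thermostat (T = 1 ε/k_B, γ = 1 τ⁻¹,
  dt = 0.01 τ), zero-tension barostat in the membrane plane, rigid
  particle motion, periodic X/Y, open Z.
* **Observables**: wrapping fraction (bonded Morse energy over its
  maximum), wrapping time (sustained-threshold crossing), binned
  membrane thickness maps, vesicle membership, windowed lipid
  displacement, patch separation, projection solidity, and a
  transwell P_app utility.

See `vignettes/membrane-wrapping-methods.Rmd` for the full model
description, design decisions and limitations.

## Worked example

Equilibrate a small bilayer and measure its thickness:

```r
library(starwrap)

bil <- build_bilayer(20, 20)              # 800 lipids, ~21.3 sigma box
bil <- assign_receptors(bil, 0.5, seed = 1)
eq  <- equilibrate_bilayer(bil, tau = 1000,
                           cfg = integrator_config(seed = 11))
tail(eq$obs[c("time", "temperature", "area", "tension")], 2)
#>      time temperature     area   tension
#> 999   999   0.9763531 463.2610 -5.925256
#> 1000 1000   0.9965419 467.8926 -1.000268
membrane_thickness(eq$state)
#> <thickness_map> 43 x 43 bins (0.503 x 0.503 sigma): thickness
#>   4.483 +/- 0.538 sigma (1762 interpolated bins)
```

The temperature sits at the 1 ε/k_B target, the box area relaxes
under the zero-tension barostat to ~1.17 σ² per lipid, and the
thickness of this snapshot is 4.48 σ — matching the published
coarse-grained value 4.51 ± 0.04 σ, which is what anchors the
σ ≈ 1 nm mapping. (The per-bin SD reflects membrane undulations and
single-frame bin noise; time-averaging over a further 10³ τ, as the
acceptance script does, gives 4.48 ± 0.03 σ at this system size.)

Wrap a particle:

```r
star <- build_particle(nanoparticle_spec("star"), seed = 1)  # 35 tips, 280 ligands
traces <- run_wrapping(star,
                       membrane = list(n_lipids_x = 78, n_lipids_y = 67,
                                       area_per_lipid = 1.1345,
                                       receptor_fraction = 0.5,
                                       equilibration_tau = 1000),
                       horizon_tau = 1e4, replicas = 5, master_seed = 1)
sapply(traces, wrapping_time)     # tau per replica; NA = never wrapped
```

(The full published scale above is an hours-to-days computation; use
`default_config("reduced")` scales for desk runs.)

## Command line

```sh
inst/cli/starwrap build-particle --shape star --out star.xyz
inst/cli/starwrap run --config my.cfg --replicas 5 --seed 1 --out runs/
inst/cli/starwrap layouts --config my.cfg --dry-run
inst/cli/starwrap analyze --checkpoint runs/replica-01.chk
inst/cli/starwrap report --out runs/
```

Configs are flat `section.key = value` text files; every output
directory receives the materialized config so runs can be reproduced
exactly (same config + seed ⇒ bit-identical trajectories).

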