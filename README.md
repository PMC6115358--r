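# sorpflex

Hybrid GCMC/MD simulation of water sorption in deformable nanoporous
polymers, with the analysis stack needed to dissect sorption-induced
swelling and its hysteresis: hydrogen-bond networks and energies, pore size
distributions, and moisture-dependent mechanics.

## The science

Hydrophilic amorphous polymers (cellulose and its relatives, many membrane
and barrier materials) take up water from humid air and swell; both the
moisture content *m* (grams of water per gram of dry host) and the volume
strain ε<sub>V</sub> = V/V₀ − 1 are hysteretic between adsorption and
desorption, down to very low humidity. Neither sorption in a rigid
framework nor deformation at fixed composition reproduces this: the
coupling is the mechanism. `sorpflex` samples the osmotic ensemble
(μ, σ, T) directly by alternating

* **grand canonical Monte Carlo** on rigid three-site (SPC/E) water —
  insertions, deletions, displacements, rotations against an ideal-vapor
  reservoir at chemical potential μ − μ₀ = k<sub>B</sub>T ln RH, activity
  z = P/(k<sub>B</sub>T) anchored at the model's saturation pressure
  P₀ = 1017 Pa (300 K); and
* **constant-stress molecular dynamics** (velocity Verlet, SHAKE/RATTLE
  rigid water, Nose-Hoover thermostat, anisotropic weak-coupling barostat)
  that lets the polymer host relax mechanically between exchange blocks.

Isotherm branches chain configurations from point to point, which is what
makes history dependence observable. The analysis layer classifies hydrogen
bonds as water–water, host–water and host–host with the geometric criterion
(O···O < 0.35 nm, donor angle < 30°), computes pair-isolation bond energies
(LJ + bare Coulomb between the two isolated partners), radial distribution
functions, inscribed-sphere pore size distributions, and undrained bulk
moduli from volumetric tensile tests. A built-in generator produces every
input: bulk water boxes, slit pores, harmonic solids and an amorphous
bead-spring "cellulose surrogate" host whose repeat units carry hydroxyl
donor/acceptor sites.

Interactions are Lennard-Jones 12-6 (Lorentz–Berthelot) plus damped
shifted-force Coulomb (α = 2 nm⁻¹, r<sub>c</sub> = 0.9 nm by default), all
parameters loaded from plain-text forcefield files (`spce.ff`,
`surrogate_host.ff`). Internal units are nm, ps, K, e, kJ/mol. See the
methods vignette (`vignettes/sorption-swelling-methods.Rmd`) for the model,
its assumptions and all numerical choices.

## A worked example

```r
library(sorpflex)

# the reservoir: 50% relative humidity at 300 K
res <- reservoir_spec(T = 300, RH = 0.5)
res$mu_offset      # -1.729 kJ/mol  (= kB T ln 0.5)
res$activity       #  1.228e-04 molecules/nm^3

# a hydrogen-bonded water dimer and its pair-isolation energy
dimer <- make_fixture("two_molecule", r_oo = 0.28)
rec <- detect_hbonds(dimer)
rec                       # one WW bond: donor O 1, H 2, acceptor 4
hb_energy(dimer, rec[1, ])   # 6.72 kcal/mol binding

# pore size distribution of a 1.2 nm slit pore, probe radius 0.1 nm
psd <- compute_psd(make_fixture("slit_pore", gap = 1.2), probe = 0.1, seed = 1)
psd_mode(psd)             # 1.025 nm, the geometric value gap - 2 r_probe

# capillary critical-point shift for a 0.3 nm pore: far above ambient,
# so sub-nanometer pores fill reversibly and cannot cause the hysteresis
capillary_shift(D = 0.3)  # 2415 K
```

The full sorption experiment is three calls: `grow_chains()` +
`relax_host()` to prepare a dry host, `run_isotherm()` for each branch, and
`branch_table()` to tabulate RH, m, ε<sub>V</sub> and the hydrogen-bond
columns. `run_fixed_volume_control()` produces the frozen/flexible
constant-volume control sweeps, and `tensile_test()` + `bulk_modulus()` the
mechanical response at any stored point. A thin command-line wrapper
(`inst/cli/sorpflex`) exposes `build`, `relax`, `isotherm`, `controls`,
`analyze-hb`, `psd`, `tensile` and `report` over TOML-style configs, and
every run writes a manifest with seeds and forcefield checksums.

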