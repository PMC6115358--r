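---
title: "Hybrid GCMC/MD simulation of water sorption in deformable polymer hosts"
author: "sorpflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid GCMC/MD simulation of water sorption in deformable polymer hosts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the method

Soft nanoporous polymers such as amorphous cellulose take up water from the
vapor phase and swell as they do so, and both the moisture content and the
volume strain are history dependent: the desorption branch of the isotherm
lies above the adsorption branch down to very low humidity. Neither a rigid
framework (plain grand canonical Monte Carlo) nor fixed-composition dynamics
reproduces this; the coupling between sorption and deformation is the
mechanism itself.

`sorpflex` implements the osmotic-ensemble strategy for this problem: the
state of the system is sampled at fixed water chemical potential $\mu$,
external stress $\sigma$ and temperature $T$ by alternating

1. a block of grand canonical Monte Carlo moves on water only (insertion,
   deletion, displacement, rotation against an ideal-vapor reservoir), and
2. a block of molecular dynamics in the isothermal--isostress (N$\sigma$T)
   ensemble in which the polymer host and the sorbed water relax
   mechanically, each orthorhombic box length coupling independently to the
   external stress.

The reservoir is parameterized by relative humidity through the ideal-vapor
relation $\mu - \mu_0 = k_\mathrm{B} T \ln \mathrm{RH}$, with the absolute
activity anchored at the model's saturation pressure ($P_0 = 1017$ Pa for the
rigid three-site water model at 300 K), so insertion weights use
$z = P/(k_\mathrm{B}T)$ directly. An isotherm branch chains configurations:
each humidity inherits the final configuration of the previous one, which is
what makes history dependence observable.

## Interaction model

Sites interact through Lennard-Jones 12-6 potentials with Lorentz--Berthelot
mixing plus Coulomb interactions evaluated with the damped shifted-force
method (damping $\alpha = 2\,\mathrm{nm^{-1}}$, cutoff $r_c = 0.9$ nm by
default; both energy and force go continuously to zero at the cutoff). This
real-space electrostatics was chosen over a reciprocal-space sum because the
desk-scale systems targeted here are small, the method is pairwise (so the
same kernel serves MD forces, MC insertion energies and virial stresses
consistently), and the mechanisms of interest -- hydrogen-bond competition
and swelling -- are short-ranged; the choice is recorded in every run
manifest. Long-range dispersion tail corrections are likewise omitted and
documented.

Water is the rigid three-site SPC/E model; its geometry and parameters are
read from the shipped `spce.ff` file, never hard-coded. Rigidity is enforced
by constraint projection (SHAKE for positions, RATTLE for velocities) on
each three-site group, which permits ordinary 1--2 fs time steps without
stiff intramolecular springs. The constraint virial enters the pressure
through the position-stage multipliers only; we verified on a free rigid
rotor gas that this reproduces the exact molecular pressure, while adding
the velocity-stage multipliers double-counts it.

Host molecules use generic class-I terms: harmonic bonds
$E = k (r - r_0)^2$, harmonic angles $E = k(\theta - \theta_0)^2$ and an
optional cosine-polynomial torsion. The angle force is regularized by
flooring $\sin\theta$ at 0.05, because a harmonic-in-$\theta$ angle has a
singular gradient at collinearity; the energy is unaffected.

Units are nm, ps, K, e, kJ/mol and g/mol internally ($k_\mathrm{B} =
0.0083144621$ kJ/mol/K); pascals appear only at the I/O boundary.

## Thermostat and barostat

Temperature is controlled by a Nose--Hoover thermostat (relaxation time 0.5
ps, as is conventional for condensed-phase water) with a Langevin thermostat
available for stiff start-ups: freshly grown chains and freshly inserted
waters can carry strained contacts, and every hybrid block therefore begins
with a short, strongly damped settling pass at a quarter step before the
production integrator runs.

Constant-stress dynamics uses an anisotropic weak-coupling barostat: each
box length relaxes independently toward its target stress with a relaxation
time of 2 ps, positions rescaled per molecule center of mass so constrained
geometries are untouched. We deliberately use weak coupling rather than an
extended-Lagrangian cell: at $10^2$--$10^3$ sites a dynamical cell rings
strongly and can destabilize the repeated velocity randomization of hybrid
GCMC/MD chaining, and nothing in the analysis consumes equilibrium volume
*fluctuations* -- only mean volumes, which weak coupling reproduces (bulk
rigid-water density at 0 Pa and 300 K comes out at 0.99 g/cm^3 here,
within the accepted bracket for the model). The barostat relaxation time is
a declared choice; the source material for this class of simulations does
not state one.

## The surrogate host

The built-in generator produces an amorphous bead-spring polymer whose
repeat unit is three sites: a backbone bead (CB), a hydroxyl oxygen (OH,
donor and acceptor) and a hydroxyl hydrogen (HO, donor). One repeat unit
stands for one hydroxyl-bearing segment of a polysaccharide chain -- about a
third of a glucopyranose ring, 87 g/mol -- so "per repeat unit"
normalizations read "per hydroxyl site", and the moisture-content scale per
unit mass matches the hydroxyl density of cellulose-like polymers.

The parameters in `surrogate_host.ff` were calibrated once against the
qualitative portrait of that material class and then frozen:

* hydroxyl charges O $-0.85$, H $+0.50$ (backbone $+0.35$ for neutrality):
  strong enough that the dry matrix is held together by an
  inter-chain hydrogen-bond network, and that water competes for those
  bonds -- the mechanism under study. OPLS-strength hydroxyl charges left
  the surrogate nearly hydrophobic at desk scale because each unit carries
  only one hydroxyl;
* a small Lennard-Jones core on the hydroxyl hydrogen: with a bare point
  charge, an exposed donor H can collapse onto an acceptor oxygen
  (a well-known failure mode of class-I forcefields with unshielded
  hydrogens);
* backbone beads of $\sigma = 0.36$ nm bonded at 0.36 nm with moderate
  angular stiffness: chains are flexible enough to densify, and the dry
  void network is smaller than a water molecule, so measurable uptake has
  to pry chains apart (larger beads left water-sized intrinsic porosity and
  sorption became volume-neutral).

Chains are grown as self-avoiding random walks at 1.2 g/cm^3, then relaxed
by N$\sigma$T dynamics at 300 K and zero stress. The dry reference volume
$V_0$ for strain bookkeeping is the time-averaged volume over the last third
of that relaxation, not an instantaneous box volume -- at these sizes the
instantaneous volume fluctuates by about a percent, which is the same order
as the swelling signal itself. Three independent realizations (different
growth seeds) are generated and observables averaged, with the standard
deviation over realizations as the error estimate.

## Hydrogen-bond analysis

A hydrogen bond is detected geometrically from a donor O--H and an acceptor
O on different molecules. Two distance conventions are implemented and
recorded in outputs: donor-O...acceptor below the cutoff (`O_to_O`,
default), or H...acceptor below the cutoff (`O_to_H`); the angular cut can
be taken at the donor oxygen (H--O$_d$...O$_a$ angle, default) or at the
hydrogen (deviation from O$_d$--H...O$_a$ linearity). The default pairing
(O...O < 0.35 nm with donor angle < 30 degrees) is the standard
liquid-water convention and is the one that reproduces the textbook bulk
coordination of ~3.6 hydrogen bonds per molecule for SPC/E water at 300 K;
the literal O-to-H reading gives ~4.1 with the same cutoffs. Counts are
classified water-water (WW), host-water (CW) and host-host (CC), normalized
per water molecule (WW, CW) or per repeat unit (CC). Note one bookkeeping
subtlety: `summarize_hbonds()` reports *bond counts* per water
($n^{WW}/N_w$), while "hydrogen bonds per molecule" in the bulk-water sense
counts each molecule's participations, i.e. $2n^{WW}/N_w$; `bulk_hb_count()`
reports the latter.

Bond energies use pair isolation: the two bonded molecules are kept, all
others removed, and the full intermolecular energy (Lennard-Jones plus
*bare* Coulomb, no damping or cutoff) is evaluated and averaged over bonds
and frames, reported as a positive binding magnitude in kcal/mol.

Cohesive energies of bulk water are reported with the SPC/E
self-polarization correction (5.22 kJ/mol per molecule, read from the
parameter file) subtracted by default: the raw configurational energy of
SPC/E is about $-45$ kJ/mol here, and the model's definition includes the
polarization term precisely so that its cohesive energy lands on the
experimental scale of ~41 kJ/mol. `bulk_cohesive_energy(run,
polarization_correction = FALSE)` returns the raw value.

## Texture and mechanics

The pore size distribution is the stochastic largest-inscribed-sphere
construction: candidate sphere centers are scattered in the box, each
assigned the largest radius that avoids all sites inflated by the probe van
der Waals radius (0.1 nm by default); for random void test points the
largest covering sphere defines the local pore diameter. Sphere radii are
capped at half the smallest box length. This replaces a
constrained-optimization formulation of the same geometric quantity; on a
slit pore of gap $g$ the mode is $g - 2r_\mathrm{probe}$ as it must be.

The volumetric tensile test dilates the box isotropically so the volume
strain follows a linear ramp (default 0 to 0.1) under NVT dynamics at fixed
moisture content; the virial tension is recorded continuously and the
undrained bulk modulus is the least-squares slope over the small-strain
window (default $\varepsilon_V \in [0, 0.02]$ -- the linear-regime bound is
not fixed by the source material and is exposed as a parameter). For stiff,
nearly harmonic systems the discrete ramp excites ringing; the Langevin
thermostat option damps it, and the implementation recovers the analytic
modulus $2k/(3a)$ of a simple-cubic nearest-neighbour-spring lattice to
within a few percent.

## Numerical choices and degenerate inputs

* Minimum image on each periodic axis; components lie in $(-L/2, L/2]$ with
  ties resolved toward $+L/2$.
* Nonbonded exclusions: 1--2, 1--3 and all intra-rigid-group pairs.
* Neighbour list with 0.15 nm skin rebuilt every 10 steps.
* Overlapping interacting sites (r < 1e-6 nm) raise an error rather than
  returning infinities; GCMC treats hard overlaps as zero acceptance.
* Deletion attempts on a dry system are flagged rejections, not errors;
  RH = 0 is handled as the dry limit (no insertions) rather than a numeric
  chemical potential.
* A hybrid point that fails to converge within its block budget is kept and
  flagged, never silently dropped.

## Problem sizes and what the tests do (and do not) show

The shipped validation suite runs at deliberately small sizes chosen as
representative desk-scale conditions: bulk-water benchmarks use 216
molecules (the smallest cube count whose ambient-density box admits the 0.9
nm cutoff) with 20 ps equilibration and 50 ps production at 2 fs; the
sorption-mechanism experiments use three realizations of a 24-unit
surrogate host over a five-point humidity grid, with 10,000 GCMC attempts
and 0.4 ps of N$\sigma$T dynamics per block.

At this scale the suite demonstrates the *mechanism*: deformable-host
sorption is history dependent while frozen fixed-volume controls are not,
swollen hosts adsorb more than unswollen ones, the raw water-water bond
count grows superlinearly with moisture content, and stiffness degrades
with hydration. It does not reproduce cluster-scale magnitudes: the
surrogate swells by a few percent, not tens of percent, and with a swelling
signal of the same order as the volume fluctuations of a 100-site box, the
strain-moisture relationship is far noisier than the corresponding
cluster-scale result; the strain--moisture collapse statistic in the
acceptance suite is reported honestly at whatever value the frozen
conditions deliver. Real amorphous polymers also differ in ways the
surrogate does not attempt to capture: chemical heterogeneity, chain
entanglement at realistic lengths, glassy relaxation times far beyond
nanoseconds, and multilayer adsorption at high humidity.

## Limitations

* Electrostatics is real-space damped shifted-force only; no reciprocal
  sum. Absolute pressures of strongly polar systems carry the corresponding
  truncation bias (the bulk-water density check brackets it).
* The barostat is weak-coupling: volume *fluctuations* are not canonical
  and must not be used for compressibility estimates; use the tensile test
  for moduli.
* GCMC insertions are unbiased; at high densities uptake equilibration
  relies on the alternating MD, and deeply bound waters desorb slowly --
  frozen-host control sweeps therefore use large Monte Carlo blocks.
* Class-II cross terms of the reference forcefield family for
  polysaccharides are not implemented; the host forcefield is a generic
  class-I surrogate, declared in the run manifest.
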