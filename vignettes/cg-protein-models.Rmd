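---
title: "Coarse-grained protein models by force matching: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained protein models by force matching: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mscg)
```

## The model

`mscg` implements a solvent-free, sidechain-centric coarse-grained (CG)
protein model. Each residue contributes one backbone site fixed at the
C-alpha position and up to four typed sidechain sites, each the mass center
of two or three heavy atoms (single-heavy-atom sidechains such as alanine
are a documented exception). Sites carry one of five interaction types —
backbone, apolar, polar, positive, negative — so the nonbonded model
consists of 15 pair potentials. Bonded structure (bonds, two distinct
backbone-neighbour angles per sidechain, a sequence-independent backbone
angle term, sequence-dependent backbone pseudo-torsions and planarity
impropers for Trp/Tyr rings) is derived by Boltzmann inversion of
coordinate distributions; nonbonded interactions are derived by multiscale
coarse-graining (MS-CG) force matching, a variational least-squares
projection of mapped reference forces onto a linear-spline basis in pair
distance. Because the CG potential is an approximation to the many-body
potential of mean force at the mapping resolution, it is smoother than the
underlying atomistic surface; transition temperatures in the CG ensemble
are correspondingly depressed, and native-state simulations are run at
0.6 T_f, with T_f defined as the maximum of the heat-capacity curve from
replica-exchange folding runs.

## Mapping scheme

The per-residue heavy-atom groupings are shipped as a plain-text file
(`inst/extdata/mapping_default.txt`) and are user-overridable. The grouping
rules the file must satisfy are enforced by `validate_mapping_scheme()`:
no atom in more than one site, at most four sidechain sites per residue, at
most three heavy atoms per site, C-alpha reserved for the backbone site.
The specific groupings (e.g. Leu CB+CG / CD1+CD2 apolar; Arg CB+CG+CD
apolar, NE+CZ and NH1+NH2 positive; Trp split into three apolar ring groups
plus the polar CD1+NE1+CE2 group) are a best-effort reconstruction
constrained by those rules, not a published table — treat them as a
sensible default. Site masses include bonded hydrogens by default
(`include_hydrogens = FALSE` switches to heavy atoms only); the backbone
site carries the C-alpha atom alone for position, force and mass, leaving
amide and carbonyl atoms unmapped, which is a deliberate model limitation
(no explicit backbone hydrogen bonding). Terminal residues carry no special
sites or charges.

## Boltzmann inversion

Distributions are histogrammed with defaults of 0.002 nm (bonds), 2°
(angles) and 5° (torsions). Inversion applies the Jacobian volume factors
r² and sin θ; torsions use none. Empty bins are marked *unsupported* and
excluded from fits — no pseudo-counts are added, so barrier heights are
never fabricated from zero counts. All potentials are min-shifted to zero
before fitting or serialization. Polynomial fits (harmonic or quartic) are
count-weighted least squares on a centered basis; when the RMS residual
exceeds a threshold (default 1 kJ/mol — the "where appropriate" criterion
is not specified anywhere, so this is our operational choice) the fit is
flagged `use_table`, signalling that a custom tabulated term should be used
instead. The torsion library stores one fourth-order cosine series per
ordered middle-residue pair (400 entries for the 20 standard amino acids).
The statistical-potential scale factor (default 0.54) multiplies every
coefficient; pure multiplication scales V − min V by exactly the factor and
is the identity at scale 1, which is why it was chosen over rescaling a
min-shifted copy (the two differ only by an additive constant and are
force-identical). The cosine basis is symmetric about φ = 0; an optional
sine extension exists for asymmetric source statistics.

## Force matching

The solver accumulates normal equations per block (the full design matrix
is never materialised across blocks), with each in-range, non-excluded pair
contributing hat-function weights times the unit separation vector to both
partner sites with opposite signs — Newton's third law is structural.
Blocks are solved by a minimum-norm pseudoinverse; knots unsampled in a
block are rank-deficient directions, resolved to zero and masked. Block
solutions are combined by frame-count-weighted means with standard errors
over blocks (the weighting of unequal blocks is unstated in the source
protocol; count-weighting is our choice). A half-data convergence check
reports per-pair max/RMS deviations over knots sampled in both halves.
Defaults: knots every 0.02 nm over (0.2, 2.0] nm, blocks of 2000 frames.
Frames supplied to the solver must contain nonbonded forces only; a
`subtract_bonded` hook exists for data where bonded contributions must be
removed first.

## Tabulated potentials

Force curves are integrated from the cutoff inward (trapezoid), smoothed
with a cubic smoothing spline whose force column is the exact negative
spline derivative, and optionally switched linearly to zero over
1.0–1.2 nm (like-charge pairs). The soft-core stand-in builder uses the
Mie(9,6) form, which preserves the published (r_min, ε) pairs exactly while
having one lower repulsive order than 12-6 LJ; the functional form is
pluggable. Numerical choices that departed from first intent during
implementation:

* **Grid spacing 0.001 nm** (not 0.002): the internal consistency invariant
  (force equal to the central finite difference of −V within 10⁻³ of the
  maximum force) is unattainable at 0.002 nm for the steep Mie cores —
  the O(h²) finite-difference error is ≈1.25×10⁻³ of max |f| there
  irrespective of capping. At 0.001 nm it passes with a 0.37 margin.
* **Inner cap V_max = 100 kJ/mol** with linear force continuation below the
  cap radius: an integrator-safety wall (≈40 kT at 300 K). The cap point is
  a deliberate slope kink and is excluded from the finite-difference check.
* Tables are zeroed at the 1.2 nm MD cutoff, distinct from the 2 nm
  force-matching range.

The MD engine treats the *force* column as primary: pair energies are
computed as exact integrals of the linearly interpolated force, so forces
are exact negative gradients of the energy by construction (verified to
10⁻⁴ relative against central differences in the test suite). The V column
is authoritative for serialization and reporting.

## Dynamics

Langevin dynamics uses the BAOAB splitting, chosen for configurational
accuracy at the 2 fs step and because it reduces exactly to velocity Verlet
at zero friction, enabling energy-conservation tests. Exclusions follow the
bond graph: pairs closer than `min_separation = 3` bonds (1-2, 1-3) do not
interact nonbondedly; the source protocol is ambiguous between "at least
three" and "more than three" bonds, so 4 is available as an option. The
neighbor structure is a Verlet pair list with a 0.3 nm skin rebuilt on the
half-skin displacement criterion rather than a cell list: at the system
sizes this package targets (≤ ~600 CG sites) the cell-list constant factor
is irrelevant, and the contract — interactions exact within the cutoff at
every step — is identical. Position restraints are harmonic with a default
constant of 1000 kJ mol⁻¹ nm⁻² (no published value exists). Site masses sum
member atoms plus hydrogens; masses affect kinetics only, not equilibrium
sampling, and absolute CG timescales are not meaningful in this model. No
bond constraints are applied at the CG level. Units are nm, ps, K, kJ/mol,
amu internally; Å appears only at I/O boundaries (PDB, pair-minima file,
RMSD reports).

## Replica exchange

Ladders are exponential between the configured endpoints (default
100–700 K), giving constant neighbor temperature ratios. Exchange attempts
run in alternating even/odd neighbor sweeps at a fixed step interval
(decoupled from the timestep); the Metropolis criterion
min{1, exp[(β_i − β_j)(U_i − U_j)]} uses the most recent recorded
potential energy, which the driver guarantees is current by requiring the
exchange interval to be a multiple of the recording stride. Accepted swaps
exchange configurations between temperature slots with velocities rescaled
by √(T_new/T_old). Whether the source protocol attempted all neighbor
pairs or one random pair per interval is unstated; alternating sweeps are
our choice. Acceptance is reported per pair against the 20–40% band; pairs
with no attempts are undefined, not zero. The driver is sequential and
deterministic under a master seed.

## Analysis

The heat capacity is configurational, C_v = Var(U)/(k_B T²), with block
averaging (≥5 blocks) for uncertainties and the first 20% of each series
discarded as equilibration (both configurable; the estimator is the
implicit-solvent REMD convention — adding kinetic terms shifts every point
by N_dof k_B/2 and moves no peak, and a flag exists for it). T_f ties are
reported, not silently broken. RMSD uses the Kabsch superposition with a
proper rotation (det +1) on a fit selection, evaluated over a measure
selection, reported in Å. ΔD_RMSD is RMSD-from-open minus
RMSD-from-closed (negative = open-like), antisymmetric under swapping
references. The nonbonded C-alpha RDF counts intramolecular pairs separated
by ≥3 bonds plus all intermolecular pairs, shell-volume and density
normalised, minimum-image under a periodic box. For adenylate-kinase-style
per-domain reports, domain residue ranges default to NMP 30–67, LID
118–160, CORE elsewhere — an external convention, user-overridable.

## What the synthetic generators establish — and what they do not

The fixtures module provides exact oracles: fluids whose stored forces are
evaluated analytically from a known pair law (overdamped Brownian sampling;
only equilibrium structure matters for force-matching tests), i.i.d.
rejection samplers for bonded coordinates, ideal-geometry toy peptides
(0.38 nm consecutive C-alpha spacing) and synthetic stand-in structures
built from real benchmark sequences. Force laws come in two flavours:
piecewise-linear (inside the spline span, isolating estimation error —
recovery must be exact) and Mie (outside the span, including basis
approximation error). A green test therefore establishes correctness of
the estimators and the simulator against known ground truth. It does *not*
establish that the shipped soft-core tables reproduce the original
force-matched potentials (those were never published in tabulated form;
the builder is an explicit stand-in honouring only the published minima),
nor that folding-simulation observables (transition temperatures, native
RMSDs) match the published values — those depend on the original tables
and are out of reach from the publication alone. Real experimental
structures are likewise not bundled: benchmark-sequence tests use
synthetic idealised geometries and are labelled as such.

## Known limitations

* No explicit backbone hydrogen bonding or multi-site backbone option; the
  single C-alpha site trades hydrogen-bond geometry for sidechain detail.
* No long-range electrostatics; all interactions are cut off at 1.2 nm.
* Termini are not specially charged or capped.
* The torsion library's database-derived coefficients are user input (or
  fit from supplied distributions); the package ships only the fitting
  machinery, the 0.54 scaling and a synthetic stand-in for tests.
* Single chain per topology; intermolecular analyses accept multiple
  molecules only through explicit molecule ids.
* Absolute timescales in CG dynamics are not physical.
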