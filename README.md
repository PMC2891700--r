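# mscg: multiscale coarse-grained protein models by force matching

`mscg` builds and simulates a five-site-type coarse-grained (CG) protein
model of the kind used to study folding energy landscapes and large
conformational transitions. It is aimed at structural/computational
biophysicists who want a transparent, fully testable R implementation of the
whole pipeline:

1. **CG mapping** — one backbone site per residue at the C-alpha position,
   plus up to four sidechain sites per residue placed at the mass centers of
   2–3 heavy-atom functional groups, each typed as *apolar*, *polar*,
   *positive* or *negative*. No atom belongs to more than one site.
2. **Bonded potentials by Boltzmann inversion** — from coordinate
   distributions p observed in reference simulations:
   V(r) = −kT ln[p(r)/r²], V(θ) = −kT ln[p(θ)/sin θ], V(φ) = −kT ln p(φ),
   fit to harmonic/quartic polynomials or fourth-order cosine series. The
   20×20 sequence-dependent backbone-torsion library carries a global
   scale factor (default 0.54). A single sequence-independent quartic serves
   every backbone angle.
3. **Nonbonded potentials by force matching (MS-CG)** — the variational
   projection of mapped reference forces onto a linear-spline basis in pair
   distance (range < 2 nm), solved per block of configurations in
   least-squares sense and block-averaged; force curves are integrated and
   smoothed with a cubic spline into tabulated potentials.
4. **Soft-core stand-in tables** — a Mie(9,6) form
   V(r) = ε[2(r_min/r)⁹ − 3(r_min/r)⁶] built from the shipped pair-minima
   parameter file (15 site-type pairs), softer-cored than a 12-6 LJ with the
   same minimum; like-charge pairs are switched linearly to zero over
   1.0–1.2 nm.
5. **Langevin CG-MD** — BAOAB integration (2 fs step, 2 ps inverse friction,
   1.2 nm cutoff, nonbonded pairs separated by ≥ 3 bonds), tabulated forces
   with energies that are exact integrals of the interpolated force, optional
   position restraints and periodic box. Compiled (Rcpp) inner loop.
6. **Replica exchange (REMD)** — exponential temperature ladders
   (T_i = T_min (T_max/T_min)^(i/(n−1)), default 100–700 K), Metropolis
   swaps in alternating even/odd neighbor sweeps, full occupancy
   bookkeeping and acceptance reports against the 20–40% band.
7. **Landscape analysis** — C_v(T) from potential-energy fluctuations with
   the transition temperature T_f at its maximum (native-state runs at
   0.6 T_f), Kabsch RMSD with fit/measure selections, the ΔD_RMSD
   open-minus-closed reaction coordinate, mass-weighted radius of gyration
   (absolute or native-relative), and the nonbonded C-alpha RDF.
8. **Synthetic fixtures** — oracle fluids with exactly known pair forces,
   Boltzmann samplers for bonded coordinates, idealised toy peptides and
   synthetic stand-in structures, giving every stage an independent test
   oracle without any external data.

## Worked example

```r
library(mscg)

## the 15 soft-core pair potentials from the shipped parameter file
ff <- table2_forcefield()
pn <- ff$tables[["negative|positive"]]
i  <- which.min(pn$V)
sprintf("positive-negative minimum: r = %.2f A, depth = %.2f kJ/mol",
        nm_to_ang(pn$r[i]), -(min(pn$V) + mie96(1.2, 0.32, 9.6)))
#> "positive-negative minimum: r = 3.20 A, depth = 9.60 kJ/mol"

## map a 12-residue Trp-zipper sequence (synthetic stand-in structure)
cfg <- map_structure(synthetic_structure("SWTWENGKWTWK"))
table(cfg$site_type)
#>   apolar backbone negative    polar positive
#>       16       12        1        8        2

## low-temperature CG-MD of a 15-mer: the chain compacts
tp     <- toy_peptide("AAAAAAAAAAAAAAA")
bonded <- default_bonded_terms(tp$topology)
sim    <- sim_config(temperature = 150, seed = 1, stride = 200)
traj   <- run_cg_md(tp$topology, ff$tables, bonded, sim, 2e5, tp$positions)
rg <- frame_metric(traj$positions,
                   function(p) radius_of_gyration(p, tp$topology$sites$mass))
sprintf("Rg: start %.2f nm -> mean %.2f nm at 150 K", rg[1], mean(rg[-(1:250)]))
#> "Rg: start 1.43 nm -> mean 0.57 nm at 150 K"
```

The first number reproduces the strongest attractive minimum of the
parameter table (a salt-bridge-like positive–negative contact at 3.2 Å,
9.6 kJ/mol deep); the site-type counts reflect the mapping rules (one
backbone site per residue, tryptophan splitting into three apolar ring
sites plus one polar NE1-bearing site); the Rg drop shows the force field's
characteristic low-temperature compaction of an extended chain.

## Vignette

`vignettes/cg-protein-models.Rmd` documents the model assumptions, the
tunable parameters with units and defaults, what the synthetic generators do
and do not emulate, the numerical choices, and known limitations.
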