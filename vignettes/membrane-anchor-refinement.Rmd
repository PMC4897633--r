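---
title: "Restrained ensemble refinement of the alpha-synuclein membrane anchor: models and methods"
author: "memanchor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restrained ensemble refinement of the alpha-synuclein membrane anchor: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memanchor)
```

## What this package models

The N-terminal ~30 residues of alpha-synuclein form an amphipathic helix on
acidic lipid bilayers and anchor the protein to synaptic-vesicle-like
membranes. Characterising that anchor experimentally rests on solid-state NMR
chemical shifts of the assigned region (residues 6–25), used as
replica-averaged restraints on a simulated ensemble, followed by analyses of
the refined ensemble: a free-energy surface over (Cα RMSD to an ideal helix,
dipole moment), per-residue helix populations and fluctuations, salt-bridge
and hydrophobic contact maps, and — once the peptide is placed on a bilayer —
helix tilt, per-residue insertion depth, sidechain–lipid interactions, and
paramagnetic relaxation enhancement (PRE) profiles for doxyl-labelled lipids.

`memanchor` implements that entire workflow at desk scale. The all-atom
explicit-solvent machinery of the original protocol is out of scope; in its
place stands a coarse, fully documented torsion-space model whose purpose is
to make every stage of the pipeline runnable, testable, and verifiable
against known ground truth. Synthetic-data generators produce ensembles,
bilayers, placements and shift tables with planted parameters, so each
analysis can be checked by parameter recovery rather than by eye.

## The coarse peptide model

Each residue carries five sites: backbone N, CA, C, O and a single sidechain
centroid SC placed along the Cβ direction at a residue-specific distance
(glycine's centroid coincides with CA). Geometry is built by sequential
internal-coordinate (NeRF) placement with fixed bond lengths and angles and
ω = 180°, so a conformation is fully specified by its (φ, ψ) torsions. The
torsion↔Cartesian round trip is exact to numerical precision; consecutive
CA–CA distances are 3.80 Å; the φ of residue 1 is a gauge freedom (there is
no preceding carbonyl) and is carried as metadata.

The *ideal helix* is defined numerically as (φ, ψ) = (−57°, −47°) at every
residue — the source protocol never defines it, so the package fixes the
textbook values. The resulting build has a rise of ≈1.56 Å per residue and a
CA helix radius of ≈2.3 Å.

Charge classes are formal: Lys/Arg +1, Asp/Glu −1, His neutral, and the
N-terminal amine counts as a positive charge carried on the backbone N of
residue 1. Hydrophobic residues are {A, V, L, I, M, F}.

## Scalar descriptors

* **Cα RMSD** uses a least-squares (Kabsch) superposition on the CA atoms of
  the selected range only; the default range is the assigned region 6–25.
* **Dipole moment** is |Σ qᵢ(rᵢ − o)| in e·nm with formal charges. The 6–25
  selection is not net-neutral, so the origin matters: the default origin is
  the centre of mass of the selected residues' sites (unit masses). Whether
  the original analysis used force-field partial charges or formal charges is
  not stated anywhere; formal charges are the default and the charge table is
  an argument, so either convention can be supplied.
* **Radius of gyration** is the RMS distance of all sites to their centroid,
  unit masses.
* **SASA** is Shrake–Rupley sphere sampling with 960 deterministic
  golden-spiral points per site, probe 1.4 Å, and radii N 1.55, CA 2.0,
  C 1.70, O 1.52 Å plus the per-residue centroid radius. A single isolated
  sphere reproduces 4π(r+p)² to well within the 2 % sampling tolerance.
* **Dihedral RMSD** uses circular differences.

## The toy shift predictor

An empirical shift predictor is substituted by a documented two-term model:

δ(res, atom) = δ_coil(aa, atom) + w(φ, ψ) · Δδ_helix(atom),

with w = exp(−[(φ+57)² + (ψ+47)²]/(2s²)), s = 25°, and helix increments
(+2.6, −0.4, +1.9) ppm for (CA, CB, C). The coil table contains generic
random-coil backbone-carbon values. Glycine is assigned a nominal pseudo-CB
coil value (46 ppm): real glycine has no CB, but the coarse model keeps the
full residue × {CA, CB, C} grid so the default assigned-region table has
20 × 3 = 60 entries. This is a deliberate fiction of the stand-in predictor,
not a claim about glycine spectroscopy. A "perturbed" predictor variant
(different increments, width and coil offsets) is packaged so that
back-calculation validation can use a predictor other than the restraining
one, mirroring cross-validation against an independent shift predictor.

## Replica-averaged restraints

The restraint is a flat-bottom harmonic on the across-replica mean of the
predicted shifts:

E = k · Σⱼ max(0, |δ̄ⱼ − δ_exp,ⱼ| − εⱼ)²,

with k = 10 kJ·mol⁻¹·ppm⁻² and εⱼ defaulting to the per-nucleus uncertainty
of the shift table. The exact functional form used by the source protocol is
in supplementary material that is not available; the flat-bottom harmonic on
the replica mean is the standard published form for this family of methods
and both k and ε are configurable. Only the replica *mean* is restrained:
compensating deviations in different replicas cost nothing, which is the
defining property of replica averaging (it enforces the measurement as an
ensemble average, not per conformation), and is tested as an exact identity.
Residues without assigned shifts (1–5, 26–30) contribute no restraint.

## The coarse physical potential

Three terms, each individually testable:

1. **Torsion basins.** Two Gaussian wells per residue: a helical basin at
   (−57, −47) with depth 5.5 kJ/mol and width 30°, and an extended basin at
   (−140, 135) with depth 3 kJ/mol and width 45°.
2. **Helix cooperativity.** −J Σᵢ gᵢgᵢ₊₁ with gᵢ a Gaussian helical-state
   weight (width 30°) and J = 6 kJ/mol. Isolated per-residue basins cannot
   reproduce the cooperative, run-forming character of helix formation that
   hydrogen bonding provides in the real chain; the Ising-like
   nearest-neighbour coupling restores it, so that partially helical
   ensembles consist of helical *segments* rather than scattered helical
   residues. The depths and J were calibrated once, by unrestrained and
   restrained pilot runs, so that (i) the unrestrained ensemble is clearly
   sub-helical (helix population ≈ 0.2) and (ii) restrained refinement
   against shifts from a 70 %-helical ensemble equilibrates inside the
   restraint's flat bottom. They are model constants of the package, not
   fitting dials; all are arguments to `energy_params()`.
3. **Excluded volume.** A soft-sphere penalty k_rep(r₀ − r)² for r < r₀
   between CA–CA and SC–SC site pairs of residues at least two apart
   (r₀ = sum of site radii, k_rep = 10 kJ·mol⁻¹·Å⁻²). It is finite
   everywhere, monotone in overlap, and cheap enough for Monte Carlo.

Term weights let tests switch parts off; a flat potential (`w_torsion = 0`,
`w_repulsion = 0`) yields uniform torsion marginals, which is tested by χ².

## The sampler

Four replicas evolve in lockstep through annealing cycles of 100 ps at
278 K (the collection segment), 100 ps heating to 350 K, 100 ps at 350 K and
a 300 ps cooling ramp — temperatures ramp linearly in segment time. "ps" is
a nominal bookkeeping unit: one ps is `steps_per_ps` (default 10) MC sweeps,
and one sweep proposes one Gaussian single-angle (φ or ψ) move per residue
(width 15°, adapted toward 30–50 % acceptance during the discard horizon and
frozen afterwards). Moves are accepted by Metropolis on
E_phys + E_restraint at the current temperature; the restraint couples the
replicas through its mean, and there is no replica exchange. Torsion moves
are pivot moves — the chain suffix rotates rigidly — so only the pair
energies that straddle the pivot need recomputation; coordinates are
re-canonicalised from torsions once per cycle so rotation round-off cannot
accumulate. Starting conformations draw torsions uniformly. Per-replica RNG
streams are distinct xorshift64* generators seeded from the master seed, so
runs are bit-reproducible and independent of R's RNG state.

Frames are collected only from hold-low segments, every `frame_interval_ps`
(default 10 ps), after a discard horizon rounded *up* to whole cycles. The
default schedule reproduces the protocol arithmetic exactly: 417 cycles of
600 ps = 250.2 ns per replica, and with a 50 ns discard (84 cycles), a 10 ps
interval and 4 replicas, (417 − 84) × 10 × 4 = 13320 collected
conformations. The 10 ps interval is the unique simple choice that
reproduces that frame count and is flagged as an inference in
`annealing_schedule()`'s defaults.

Sampler correctness is tested directly: on a 2-residue system with the
cooperativity switched off the stationary (φ, ψ) distribution matches a
fine-grid Boltzmann enumeration within total variation 0.05, and detailed
balance holds by construction (symmetric proposals).

## Ensemble analyses

* **FES.** Per-frame (RMSD to ideal helix, dipole) over residues 6–25,
  binned 40 × 40 over the observed ranges padded 5 %. Occupied bins get
  F = −kT ln(n/n_max), so the most populated bin sits at 0 and F ≥ 0
  everywhere; the figure convention that colours basins increasingly
  *negative* is the same quantity with the sign flipped, which is documented
  rather than imitated. Unoccupied bins are NA, never 0. Basins are local
  minima under 8-neighbour steepest descent; minima capturing < 1 % of
  frames are dropped as histogram noise. Two bins with a count ratio of e
  are separated by exactly kT (2.3114 kJ/mol at 278 K), which the tests
  assert to machine precision in the realised counts.
* **Helix population.** A residue is helical in a frame iff (φ, ψ) lies in
  the window φ ∈ [−100, −30], ψ ∈ [−77, −17] *and* belongs to a run of ≥ 4
  consecutive in-window residues. This is a dihedral substitute for an
  H-bond-based secondary-structure assignment, which a model without
  explicit hydrogen-bond donors cannot support. The run filter matters
  quantitatively: an ensemble whose residues are 70 % helical by state
  measures ≈ 0.64 by this instrument, because short runs are discarded. For
  that reason every recovery comparison in the package compares
  *estimator to estimator* — the refined ensemble's helix population against
  the ground-truth ensemble's helix population — never a population against
  a nominal state fraction.
* **RMSF.** Frames are superposed on an iteratively refined mean structure
  (three passes); RMSF is the per-residue RMS deviation of CA positions.
  Superposition absorbs six rigid-body degrees of freedom, shrinking an
  isotropic-jitter RMSF by √(1 − 6/3N); the tests account for this.
* **Contacts.** Salt bridges: centroid distance ≤ 5.0 Å between sidechain
  charged groups ((positive, negative) pairs, |i−j| ≥ 2; the N-terminal
  amine uses the backbone N of residue 1). Hydrophobic contacts: same
  cutoff over hydrophobic pairs. In the coarse model the "charged-group
  centre of mass" *is* the sidechain centroid. One caveat discovered during
  verification: on the built ideal helix, same-face (i, i+3)/(i, i+4)
  centroid pairs sit at 6.3–6.9 Å, so at the 5.0 Å group cutoff their
  occupancy is zero — sidechains are extended objects and their centroids
  are farther apart than their closest heavy atoms. The helical-face
  geometry is therefore verified at a centroid-scale cutoff (7 Å) in the
  tests, while 5.0 Å remains the default wherever the group-distance
  convention applies.

## The coarse bilayer and topology analyses

`build_bilayer()` lays lipids (headgroup P, glycerol, 18 chain carbons) on a
jittered 8 Å lattice, split evenly across leaflets, with species assigned to
the 5:3:2 DOPE:DOPS:DOPC molar ratio by largest remainder. The carbon depth
profile is piecewise linear through |z| anchors C5 = 12.5 Å, C10 = 7.5 Å,
C16 = 2.5 Å (P at 19 Å), strictly decreasing toward the midplane. Two
percent of lipids (at least one) carry a doxyl label.

* **Surface fit:** least-squares plane through the P atoms within 10 Å of
  any protein atom on the proximal leaflet; the midplane is the mean P
  height of both leaflets; the normal points toward the protein.
* **Tilt:** angle between the helix axis (first principal component of the
  CA trace, oriented N→C) and its in-plane projection; positive when the
  N-terminal end is deeper; computed per frame and averaged. Whether the
  original analysis averaged per-frame tilts or used an average structure is
  not stated; per-frame is adopted.
* **Depth:** signed distance of the SC centroid (CA for glycine) from the
  midplane along the normal, positive toward the proximal leaflet.
* **Contacts and energies:** lipid sites within 5.0 Å of the SC centroid
  (the centroid stands in for "sidechain heavy atoms" — a documented
  coarsening), and 12-6 Lennard-Jones plus Coulomb sums truncated at 0.9 nm
  with documented per-class parameters (DOPS headgroup −1 e; formal protein
  charges; f = 138.935 kJ·nm·mol⁻¹·e⁻²). Because constructed placements are
  not energy-minimised, pair distances are floored at 0.9 σ (LJ) and 2 Å
  (Coulomb) so occasional overlaps cannot dominate frame averages; the
  attractive region is untouched.
* **PRE:** r_eff = ⟨min over labels r⁻⁶⟩⁻¹ᐟ⁶ over frames from the SC
  centroid to the doxyl site of each labelled lipid at the chosen carbon
  (or headgroup P); attenuation A = 1/(1 + (r_eff/R_c)⁻⁶) with R_c = 13 Å;
  residues with A < 0.5 are flagged broadened. This effective-distance
  sigmoid replaces full relaxation theory, whose correlation times the
  coarse model cannot supply. Because only ~2 % of lipids are labelled, a
  *static* placement almost never sits near a label; physically, PRE
  averages over fast lateral diffusion of lipids and peptide. The
  `scatter_placements()` generator therefore produces placement ensembles
  scattered laterally over the patch, and the r⁻⁶ frame average then
  carries the depth information, reproducing the expected ordering: a C5
  label (12.5 Å) broadens more of a peptide whose residues sit at 9–17 Å
  than a C10 label (7.5 Å) does.

## Synthetic data and what passing tests mean

`generate_helical_ensemble()` assigns helical/coil states by a two-state
Markov chain with stationary fraction h and mean helical run length 8 (so
the ≥ 4-run criterion is exercised realistically; when the requested h makes
that persistence unattainable the entry probability saturates and the exit
probability is adjusted to keep h stationary). Helical torsions are
N((−57, −47), 10°); coil torsions are uniform over the torus. Shifts are
synthesised as ensemble-mean predictions plus i.i.d. Gaussian noise
(default 0.3 ppm; the sigma column records the noise level, floored at 1e−6
for noise-free tables). Placements are parameterised by the reported
topology (tilt 12°, F4 at 8.9 Å) used as *construction parameters*.

These generators emulate the statistical structure of the study's inputs —
not the physics of lipid membranes or the spectroscopy of shift prediction.
Passing tests demonstrate that the pipeline's estimators recover planted
parameters under the model's own assumptions (correct bookkeeping, correct
formulas, correct statistical behaviour); they do not validate the coarse
force field against real membrane-bound ensembles, and no quantity computed
here should be read as a new physical prediction.

## Problem sizes and numerical choices

The verification runs use desk-scale sizes chosen for statistical adequacy:
2000-frame truth ensembles; a 150-cycle fixed-temperature toy run
(~60k samples) for the Boltzmann comparison; 100-cycle refinements
(discard 18 ns, 2800 collected frames) for parameter recovery, where
first-third/last-third helicity agreement confirms equilibration; 400-lipid
bilayers and 80-frame placement ensembles for topology. The full
417-cycle protocol is exercised through its arithmetic
(`schedule_accounting()`), which reproduces the printed totals exactly.

Other numerical choices: angles wrap to (−180°, 180°]; the Metropolis RNG
never consumes R's stream (generators restore `.Random.seed`);
`rmsd_ca` requires ≥ 3 residues; the FES of a degenerate (single-point)
ensemble returns a single-bin grid with a warning rather than an error;
tilt requires an elongated CA trace (first PC singular value at least twice
the second) and errors on degenerate blobs; placements accept tilt only in
[0°, 90°] (hard bounds, no clamping) and reject placements that clash with
more than half the lipids.

## Interfaces

All analysis results are tibbles; sampled and projected objects support
`tidy()`, `glance()` and `autoplot()`. Ensembles serialise to multi-model
PDB (MODEL/ENDMDL, atoms N/CA/C/O/SC, 1-based residues; the gauge φ₁ rides
in a REMARK so torsions round-trip), bilayers to PDB with species DPE/DPS/
DPC and carbons C01–C18; shift tables are TSV with header
`residue atom shift sigma`; restraint and residue-parameter configurations
are YAML. The package is a library: its exported functions and
`scripts/acceptance.R` are the operational interface, and no shell
entry point is shipped.

## Known limitations

* The coarse model has no hydrogens, rotamers, or H-bonds; secondary
  structure is dihedral-defined.
* The bilayer is a flat static patch: no curvature (the vesicle geometry is
  not modelled), no lipid dynamics, no periodic boundaries.
* The membrane-coupled term is not part of refinement; membrane analyses
  are post-hoc on constructed placements.
* PRE is an effective-distance model, not Solomon–Bloembergen relaxation.
* The toy predictor ignores ring currents, H-bonding and sequence context
  beyond the residue's own coil value.
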