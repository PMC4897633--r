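# memanchor

Chemical-shift-restrained ensemble refinement and membrane topology of the
α-synuclein membrane-anchor region (residues 1–30), at desk scale.

α-Synuclein binds synaptic-vesicle-like membranes through its N-terminal
~30 residues, which fold into an amphipathic helix on acidic
DOPE:DOPS:DOPC (5:3:2) bilayers. The experimental route to its structure
uses solid-state NMR chemical shifts of the assigned region (residues 6–25)
as *replica-averaged restraints* on a simulated ensemble: M = 4 replicas
evolve together and a flat-bottom harmonic penalises the deviation of their
**mean** back-calculated shifts from experiment,

> E = k · Σⱼ max(0, |δ̄ⱼ − δ_exp,ⱼ| − εⱼ)² ,  δ̄ⱼ = (1/M) Σₘ δⱼ(xₘ),

so the measurement is enforced as an ensemble average, not per
conformation. The refined ensemble is then characterised by a free-energy
surface F = −kT ln(n/n_max) over (Cα-RMSD to an ideal helix, dipole
moment), per-residue helix populations and RMSF, salt-bridge and
hydrophobic contact occupancies (5.0 Å group cutoff), and — on the
membrane — helix tilt, per-residue insertion depth along the bilayer
normal, sidechain–lipid Lennard-Jones/Coulomb energies (0.9 nm cutoff) and
PRE attenuation profiles for doxyl spin labels at lipid carbons 5/10/16.

`memanchor` implements the full workflow with a coarse, documented
torsion-space peptide model (5 sites/residue), a four-replica
simulated-annealing Metropolis sampler (278–350 K cycles, collection at
278 K only), a toy torsion→shift predictor standing in for an empirical
one, a coarse two-leaflet bilayer builder, and synthetic-data generators
with planted ground truth that make every stage testable without
experimental trajectories. It is aimed at method developers and students
who want a verifiable, self-contained implementation of the
restrained-refinement + membrane-topology pipeline, not at production
structure determination. See the vignette
(`vignettes/membrane-anchor-refinement.Rmd`) for the models, parameters and
their rationale.

## Worked example

```r
library(memanchor)

chain <- alpha_syn_chain()
chain
#> <ma_chain> 30 residues: MDVFMKGLSKAKEGVVAAAEKTKQGVAEAA

# the full protocol's bookkeeping: 417 cycles of 600 ps, 50 ns discarded,
# frames every 10 ps from the 278 K segments of 4 replicas
str(schedule_accounting(annealing_schedule(n_cycles = 417), n_replicas = 4))
#> List of 4
#>  $ cycle_ps              : num 600
#>  $ total_ns_per_replica  : num 250
#>  $ discarded_cycles      : int 84
#>  $ collected_frames_total: num 13320

# synthetic restraints from a 70%-helical ground-truth ensemble
truth  <- generate_helical_ensemble(chain, n_frames = 500, h = 0.7, seed = 1)
shifts <- synthesize_shifts(truth, noise_sd = 0.3, seed = 2)

# a short restrained refinement (30 annealing cycles, 6 ns discard)
fit <- run_replica_annealing(chain, shifts, sampler_config(seed = 3),
                             annealing_schedule(n_cycles = 30, discard_ns = 6))
glance(fit)
#> # A tibble: 1 × 7
#>   n_frames n_cycles n_replicas discarded_cycles mean_acceptance final_e_physical
#>      <int>    <int>      <int>            <int>           <dbl>            <dbl>
#> 1      800       30          4               10           0.504            -142.

mean(helix_population(fit$ensemble)$helix_fraction[6:25])
#> [1] 0.58    # vs 0.63 measured on the truth ensemble by the same criterion

fes <- project_fes(fit$ensemble)   # autoplot(fes) draws the surface
glance(fes)$main_basin_rmsd
#> [1] 4.14    # Å; the unrestrained control's main basin sits higher

# membrane topology on a constructed placement (tilt 12°, F4 at 8.9 Å)
bl     <- build_bilayer(400, seed = 4, label = "C5")
placed <- place_peptide(build_ideal_helix(chain), bl, tilt = 12,
                        anchor_depth = 8.9, anchor_residue = 4)
helix_tilt_angle(placed, fit_membrane_surface(bl, placed))
#> [1] 11.6    # degrees, recovered from the fitted membrane plane

scat <- scatter_placements(build_ideal_helix(chain), bl, 60, 12, 8.9, 4, seed = 5)
sum(pre_attenuation(scat, bl, "C5")$broadened)
#> [1] 25      # residues PRE-broadened by a carbon-5 doxyl label
```

The numbers mean: the refinement run collected 800 conformations at a ~50 %
Metropolis acceptance; restraining to the synthetic shifts raised the 6–25
helix population to 0.58, close to the 0.63 the same helix criterion
measures on the generating ensemble; the free-energy surface's main basin
sits at 4.1 Å RMSD from the ideal helix (lower than an unrestrained
control); a peptide placed at the reported topology (12° tilt, F4 centroid
8.9 Å above the midplane) gives back 11.6° from the fitted membrane
surface; and a carbon-5 doxyl label broadens 25 of 30 residues, while a
deeper carbon-10 label broadens far fewer — the depth ordering the PRE
experiment encodes.

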