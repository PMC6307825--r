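# rnadynr

Analysis of multi-model structure ensembles of protein–RNA complexes:
NOE restraint validation, interface contact occupancies, backbone
plasticity and conformational entropy, collective variables for
sampling comparison, solute-tempering replica planning, and free-energy
estimation from bidirectional non-equilibrium work.

## Who this is for

Researchers who simulate or model protein–RNA complexes — RRM-domain
recognition of pre-miRNA loops being the archetype — and need to answer,
from a coordinate ensemble rather than a single structure:

* does my ensemble satisfy the experimental NOE upper bounds, and which
  conformers agree best ("NOE-adapted" representative ensembles)?
* which interface hydrogen bonds and stacking contacts are actually
  populated, and at what occupancy per trajectory?
* where is the backbone plastic — fluctuations vs genuine Ramachandran
  transitions — and how does conformational entropy change on binding
  or mutation?
* how do two simulations compare in a collective-variable plane
  (fraction of native contacts Q vs DRID)?
* what ΔG does a set of forward/reverse alchemical work values imply,
  and what ΔΔG for a mutation via the thermodynamic cycle?

## The models at the core

**NOE ensemble averaging.** For a restraint with upper bound r_NOE, the
ensemble-effective distance over N_f frames is the r⁻⁶ generalized mean

    ⟨r⟩ = ( (1/N_f) Σ_f r_f⁻⁶ )^(−1/6),

with pseudo-atom groups combined by per-frame r⁻⁶ summation; violated
iff r_NOE < ⟨r⟩. Frames with fewest violations (best 10%) are clustered
and their medoids form the NOE-adapted ensemble.

**Contacts.** H-bond: d(D,A) ≤ 0.35 nm and ∠(D–H–A) ≥ 135°. Stacking:
ring-centre distance < 0.5 nm and plane angle < 30°. Occupancy is
reported per trajectory; geometry statistics pool the frames where the
interaction is present.

**Backbone dynamics.** Per-residue circular standard deviation of
ω = φ+ψ, with residues tagged F (fluctuation), t (short transitions)
or T (long transitions, minority-basin occupancy ≥ 30%); first-order
dihedral-histogram entropy S = −R Σ p ln p and TΔS differences with
block-bootstrap errors.

**Collective variables.** DRID = (1/3N) Σᵢ ‖vₙ(·,i) − v₀(·,i)‖ over
per-anchor (μ, √m₂, ∛m₃) features of inverse anchor distances;
Q = (1/N) Σ 1/(1 + exp[β(r − λr⁰)]) with β = 50 nm⁻¹, λ = 1.8; joint
2-D Gaussian KDE maps of (Q, DRID).

**REST2 planning.** Geometric ladders λᵢ = λ_min^(i/(n−1)) and
partial-scaling regions (mutated nucleotides + flanking phosphates +
protein shell within 0.5 nm).

**Free energy.** The Crooks-theorem maximum-likelihood (Bennett-type)
estimator solves

    Σ_F 1/(1+exp(M+(W_F−ΔG)/kT)) = Σ_R 1/(1+exp(−M+(ΔG+W_R)/kT)),

M = ln(n_F/n_R), by bracketed root search, with seeded bootstrap errors
and an overlap diagnostic; ΔΔG = ΔG_complex − ΔG_free.

Every generator in the package plants its ground truth (occupancies by
exact frame counts, work samples satisfying the Crooks relation in
expectation, cluster mixtures with recorded labels), so the whole
pipeline is testable end-to-end without external data.

## Worked example

```r
library(rnadynr)

# a 100-frame synthetic complex with planted interface interactions
cx <- make_complex_ensemble(100,
  hbonds = list(list(occupancy = 0.70, label = "N1-H...O2"),
                list(occupancy = 0.95, label = "N3-H...OP1")),
  stacks = list(list(d = 0.35, theta = 10, label = "F126/G30")),
  seed = 42)

occupancy_table(list(md1 = cx$ensemble),
                hbonds = cx$truth$hbond_specs,
                stacks = cx$truth$stack_specs)
#>        label  type mean_distance_nm sd_distance_nm mean_angle_deg sd_angle_deg occ_md1
#> 1  N1-H...O2 hbond             0.29              0            165            0      70
#> 2 N3-H...OP1 hbond             0.29              0            165            0      95
#> 3   F126/G30 stack             0.35              0             10            0     100

# NOE validation against a restraint table with known status
fx <- make_noe_fixture(cx$ensemble, 8, 2, margin = 0.05, seed = 43)
violation_report(cx$ensemble, fx$restraints)
#> <noe_report: 10 restraints, 80.0% satisfied, 2 violations (0 > 0.05 nm, 0 > 0.3 nm)>

# mutation ddG from bidirectional work values (planted -2.0 / -0.8)
ws_co <- make_work_samples(-2.0, 0.5, 2000, 2000, 298, seed = 44)
ws_s  <- make_work_samples(-0.8, 0.5, 2000, 2000, 298, seed = 45)
dg_co <- crooks_mle(ws_co, seed = 1)
#> <crooks_mle: dG = -2.000 +/- 0.008 kcal/mol (n_F = 2000, n_R = 2000, overlap = 0.67)>
dg_s  <- crooks_mle(ws_s, seed = 1)
dd <- thermo_cycle_ddg(dg_co, dg_s)
sprintf("ddG = %.2f +/- %.2f kcal/mol", dd$ddg_kcal_mol, dd$stderr_kcal_mol)
#> "ddG = -1.20 +/- 0.01 kcal/mol"

geometric_ladder(8, 0.6)
#> <lambda_ladder: 8 replicas, 1 -> 0.6 (ratio 0.9296)>
```

The occupancy table recovers the planted 70% / 95% occupancies exactly
(occupancy is planted by frame counting), the NOE report flags exactly
the two restraints constructed to be violated, and the Crooks estimator
recovers the planted free energies within its bootstrap error, giving
the planted binding ΔΔG of −1.2 kcal/mol.

`run_pipeline(default_run_config(seed = 1))` runs every stage on
bundled synthetic fixtures and writes TSV/JSON outputs plus a manifest
with input hashes and seeds; reruns with the same seeds are
byte-identical.

## Documentation

The methods vignette
(`vignettes/ensemble-validation-methods.Rmd`) describes each model,
its assumptions, the tunable parameters and defaults, what the
synthetic generators do and do not emulate, and known limitations.
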