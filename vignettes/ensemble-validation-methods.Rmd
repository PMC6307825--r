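---
title: "Validating protein-RNA structure ensembles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating protein-RNA structure ensembles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnadynr)
```

# Scope

`rnadynr` analyses multi-model coordinate ensembles of protein-RNA
complexes — the kind produced by molecular dynamics simulations or
deposited as NMR structure bundles — and answers three families of
questions:

1. **Agreement with NMR data.** Does the ensemble satisfy NOE
   upper-bound distance restraints, and which conformers agree best?
2. **Interface and backbone dynamics.** Which hydrogen bonds and
   stacking contacts are populated, how plastic is the backbone, and how
   does conformational entropy differ between states?
3. **Sampling and energetics.** How do two simulations compare in the
   collective-variable plane, how should a solute-tempering replica
   ladder be laid out, and what free-energy difference do bidirectional
   non-equilibrium work values imply?

The package does not run simulations. Its inputs are coordinate
ensembles (multi-model PDB), restraint tables (TSV), and work-value
tables (TSV); everything downstream of those files is in scope.

All lengths are **nanometres** internally; PDB files are converted from
and to Angstrom at the I/O boundary. Angles are degrees, energies
kcal/mol, with the gas constant `R = 1.9872e-3 kcal/(mol K)`.

# NOE back-calculation and the NOE-adapted ensemble

An NOE restraint carries an upper bound `r_NOE` on the effective
distance between two proton groups. Because NOE intensity scales as
`r^-6`, the ensemble-effective distance is the generalized mean

    <r> = ( (1/N_f) * sum_f r_f^-6 )^(-1/6)

over the `N_f` frames. For pseudo-atom groups (methyls, degenerate
aromatic protons) the per-frame distance is itself the `r^-6`-summed
effective distance over all cross pairs. This convention follows the
physics of the averaged observable; a minimum-distance alternative is
available via `group_mode = "min"` because some restraint lists are
calibrated that way. A restraint is violated iff `r_NOE < <r>`.

The per-restraint violation magnitude is always reported as the
non-negative excess `<r> - r_NOE`. The *average violation* summary is
emitted in two explicitly labelled conventions — averaged over the
violated restraints only and over all restraints — because the
literature is inconsistent about the denominator and the operand order;
reporting both removes the ambiguity.

The **NOE-adapted ensemble** generalises "which conformers agree best
with the data": frames are ranked by per-frame violation count (the
single-frame `r^-6` average reduces to the plain effective distance),
the best 10% retained (ties broken by total violation magnitude, then
frame order, so results are reproducible), and the retained frames
clustered by k-means; the per-cluster medoids, ordered by cluster
population, are the representative ensemble. `k = 20` is the
conventional deliverable size; the bundled demonstrations use smaller
`k` purely because their fixtures are smaller.

# Contact occupancies

Hydrogen bonds and stacking interactions are *declared*, not
auto-perceived: interface studies report curated contact lists, and
automatic donor/acceptor perception on coarse or non-standard topologies
is a common source of silent errors. The geometric criteria are the
standard trajectory-analysis ones:

* H-bond present: donor-acceptor heavy-atom distance <= 0.35 nm **and**
  donor-H-acceptor angle >= 135 degrees. A missing hydrogen is an error,
  never a silent heavy-atom-only fallback.
* Stack present: ring-centre distance < 0.5 nm **and** the folded angle
  between best-fit ring planes < 30 degrees. Ring normals have
  arbitrary sign, so the plane angle is `acos(|n1 . n2|)`, always in
  [0, 90] degrees.

Ring centres are unweighted centres of geometry by default: ring atoms
(C/N) have near-equal masses, so the distinction from a true centre of
mass is far below the 0.5 nm criterion; a mass-weighted variant is
available behind a flag. Occupancy is reported **per trajectory**
(`100 * present-frames / total-frames`, never pooled across
trajectories), while geometry means and standard deviations pool the
present frames of all trajectories — the usual table convention, since
geometry is a property of the formed interaction and occupancy a
property of each simulation.

# Backbone plasticity and conformational entropy

Local backbone plasticity is measured on the Ramachandran angle sum
`omega = wrap(phi + psi)` as the circular standard deviation
`sqrt(-2 ln Rbar)` (degrees), where `Rbar` is the mean resultant
length. The sum of the two angles is used because compensating
phi/psi "crankshaft" fluctuations cancel in omega, while genuine basin
changes do not. The dispersion measure is deliberately pluggable: the
circular standard deviation is one defensible choice among several
dispersion statistics in use.

Residues are tagged by region occupancy on the Ramachandran plane:

* `F` (fluctuation): every non-modal region occupied at or below the
  noise floor (default 1%);
* `T` (long transitions): pooled minority-region occupancy >= 30%;
* `t` (short transitions): anything between.

The default region map is three rectangles (beta, alpha, left-handed
alpha) plus a catch-all. Published region boundaries vary; the map is a
plain configurable list, and the defaults are conventional
secondary-structure basins. Minority occupancy is **pooled** over all
non-modal regions rather than per-region: a residue that splits 15%/15%
between two minor basins spends 30% of its time away from its modal
basin, which is the quantity the tag is meant to capture.

Conformational entropy uses first-order dihedral histograms:
`S = -R sum_b p_b ln p_b` per angle over 10-degree right-closed bins on
(-180, 180], summed over a residue's angles. This is a *comparative*
measure: it ignores correlations between angles (no
mutual-information corrections) and its absolute value depends on the
bin width, but differences between two states of the same residue at
the same binning are meaningful. `TdS = T (S_a - S_b)` is exactly
antisymmetric under state swap; its uncertainty comes from a block
bootstrap (contiguous blocks of 10% of frames) because trajectory
samples are serially correlated and a naive bootstrap would understate
the error.

# Collective variables

**DRID** (distribution of reciprocal interatomic distances)
summarises a conformation by, for each anchor atom (CA and P atoms),
the mean, the square root of the second central moment, and the cube
root of the third central moment of its inverse distances to all other
anchors. The cube root is *signed* so negative skew survives. The
distance between a frame and a reference is

    DRID = (1/(3N)) * sum_i || v_n(., i) - v_0(., i) ||

with the Euclidean norm of each anchor's 3-feature difference. This
prefactor is implemented exactly as written; it averages per-anchor
norms rather than taking a global vector norm, and tests pin this
choice down against brute-force evaluation.

**Q**, the fraction of native contacts, uses the smoothed logistic form

    Q = (1/N) * sum_(i,j) 1 / (1 + exp(beta * (r_ij - lambda * r0_ij)))

over heavy-atom contact pairs defined in a reference structure
(cross-pairs below 0.45 nm). The defaults are `lambda = 1.8` and
`beta = 50 nm^-1` (= 5 A^-1). A beta on the order of a length rather
than an inverse length is dimensionally impossible in this functional
form, so the inverse-length convention standard for this CV is the
default; beta is an ordinary argument for anyone wanting a different
smoothing.

Sampling maps are joint 2-D Gaussian KDEs of (Q, DRID) per frame with
Scott's bandwidth per dimension, evaluated on a regular grid and
normalised to integrate to 1 (checked to 1e-3 in tests). A
zero-variance dimension is an error with a suggestion to jitter,
rather than a silently degenerate map.

# Clustering

Conformational clustering superposes all frames onto the **first
frame** (Kabsch, det-corrected against reflections) over the chosen
selection and runs k-means on the flattened selected coordinates. This
is the standard practical approximation to RMSD-metric clustering —
true pairwise RMSD after per-pair superposition is not a vector-space
metric, so exact k-means in that metric is not defined. Initialisation
is seeded k-means++ with 10 restarts keeping the best inertia, <= 500
Lloyd iterations; results are deterministic given the seed. The first
frame (rather than an iterated mean structure) is the superposition
reference because it is reproducible and the choice only perturbs the
embedding by a rigid transform per frame.

Cluster representatives are **medoids**: the member with the lowest
cumulative pairwise superposed RMSD to all other members, ties broken
by lowest frame index.

The interface selection used for clustering mirrors the usual
definition: all atoms of the named nucleotides plus all atoms of every
protein residue with at least one heavy atom within 0.45 nm of any
heavy atom of those nucleotides, in the reference frame.

# REST2 planning

A solute-tempering ladder scales solute-solute interactions by
`lambda`, solute-solvent by `lambda^1/2`, and leaves solvent-solvent
unscaled, which effectively heats only the solute
(`T_eff = T / lambda`). The ladder is geometric:
`lambda_i = lambda_min^(i/(n-1))`, giving a constant neighbour ratio —
the spacing that roughly equalises exchange probabilities. Stated
setups of 8 replicas down to `lambda = 0.6` and 16 replicas down to
0.7 are reproduced exactly by construction.

For partial scaling, the scaled region is the mutated nucleotides,
their flanking phosphate groups, and every whole protein residue with a
heavy atom within 0.5 nm of the nucleotides. "Flanking phosphates" is
interpreted as both the residue's own 5' phosphate and the 3'-side
phosphate carried by the following residue (configurable to 3'-only or
none, since the phrase is ambiguous in common usage). Shell membership
is residue-level (any heavy atom), matching how such regions are
reported.

# Free energy from bidirectional work

The Crooks fluctuation theorem,
`P_F(W) / P_R(-W) = exp[(W - dG)/kT]`, implies a maximum-likelihood
(Bennett-type) estimator for `dG` given forward works `W_F` (A to B)
and reverse works `W_R` (B to A):

    sum_F 1/(1 + exp(M + (W_F - dG)/kT)) =
    sum_R 1/(1 + exp(-M + (dG + W_R)/kT)),   M = ln(n_F/n_R).

The residual is monotone in `dG`, so the root is found by bracketed
search over `[min(-W_R), max(W_F)]` to a residual tolerance of 1e-10.
If the bracket contains no sign change — the signature of
non-overlapping work distributions — estimation **refuses** with the
histogram-overlap diagnostic in the error, because any number produced
in that regime would be an extrapolation. In the zero-dissipation limit
(all `W_F = c`, all `W_R = -c`) the estimator returns `c` exactly and
coincides with the Jarzynski exponential average.

Uncertainties come from a seeded bootstrap over work values (default
1000 resamples), resampling each direction independently; replicate ids
are preserved by the reader for hierarchical schemes. A
Gaussian-intersection estimator (crossing point of normal fits to
`P_F(W)` and `P_R(-W)`; midpoint of means at equal variance) is
provided as a cross-check, never as the primary estimator.

The binding effect of a mutation uses the thermodynamic cycle
`ddG = dG_complex - dG_free`, errors combined in quadrature; negative
`ddG` means the mutation favours binding.

# Synthetic ensembles and what the tests do (and do not) show

Every fixture is generated by seeded code with planted ground truth:

* **Complex ensembles** place each declared H-bond at 0.29 nm / 165
  degrees in exactly `round(occupancy * n_frames)` frames (broken at
  0.60 nm otherwise) and each stacking pair at its exact planted
  geometry, on a minimal two-chain scaffold of named atoms. Occupancy
  is planted by frame counting, not probabilistically, so recovery
  assertions are exact. The scaffold is geometry only — no chemistry,
  no solvent, no force field.
* **Dihedral fixtures** draw wrapped-normal angles around Ramachandran
  modes, with exact planted minority-state counts for two-state
  residues.
* **Work samples** use the Gaussian pair `W_F ~ N(dG + s^2/2kT, s^2)`,
  `W_R ~ N(-dG + s^2/2kT, s^2)`, which satisfies the Crooks relation
  exactly in expectation.
* **Cluster mixtures** build k rigid conformers at pairwise superposed
  RMSD of at least the requested separation and add isotropic noise;
  separations below 4x the noise are flagged as unidentifiable.
* **NOE fixtures** set bounds to the back-calculated `<r> +/- margin`,
  so satisfaction status and violation magnitude are known by
  construction.

Passing these tests demonstrates that the estimators compute their
definitions correctly and recover planted truth under clean,
well-separated conditions. It does **not** demonstrate robustness to
the pathologies of real trajectories — force-field bias, incomplete
convergence, overlapping conformational basins, pseudo-atom bookkeeping
mismatches in legacy restraint lists — which no synthetic fixture can
stand in for.

# Numerical choices and degenerate inputs

* Right-closed histogram bins on (-180, 180], and bin widths that must
  divide 360, make entropies deterministic and exactly
  shift-invariant.
* Kabsch uses SVD with the determinant correction; the quaternion
  method serves as an independent oracle in tests.
* Exact boundary values: H-bond criteria are inclusive (<= 0.35 nm,
  >= 135 degrees), stacking criteria exclusive (< 0.5 nm, < 30
  degrees), as conventionally implemented; tests probe both sides of
  each boundary.
* Degenerate geometry (zero-length angle arms, collinear dihedral
  triples, collinear rings, coincident DRID anchors) raises errors
  rather than returning NaN.
* `i == j` distance is defined as 0; descending residue ranges select
  nothing and are flagged, not errors.
* k-means ties and medoid ties break deterministically (best inertia;
  lowest frame index).

The bundled pipeline demonstration (`run_pipeline()`) uses 60-frame
complexes, 200-500-frame dihedral series, 100-2000 work values per
direction and 30-60-frame mixtures — sizes chosen so the planted
effects are unambiguous while a full run stays interactive on a
laptop; every stage scales to real trajectory sizes linearly in frames.

# Known limitations

* No periodic-boundary imaging: inputs must be whole-molecule
  (NMR-style) ensembles.
* Entropy is first-order; correlated torsions inflate it.
* k-means in superposed coordinate space is an approximation to
  RMSD-metric clustering, and k is a required input (no automatic
  selection).
* The NOE reader resolves named atoms only; pseudo-atom equivalence
  bookkeeping (methyl rotations, aromatic flips) is the caller's
  responsibility via multi-atom groups.
* Exchange acceptance rates for a REST2 ladder cannot be predicted
  without energies from real simulations; the planner reports the
  ladder and region only.
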