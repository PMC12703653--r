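---
title: "Modelling degrader ternary complexes with protaconf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling degrader ternary complexes with protaconf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protaconf)
```

## The model

A heterobifunctional degrader is treated as three units: a warhead bound
to the protein of interest (POI), an E3-recruiting group bound to the E3
ligase, and a flexible linker. The package's central assumption is that
at the moment of ternary-complex (TC) formation the two binding moieties
retain their monomer-bound geometries, so the TC geometry is a function
of the linker torsions alone. Conformational sampling is therefore
torsion-only: ring geometries and all bond lengths/angles are kept from
the input structure, and only acyclic single bonds between non-terminal
heavy atoms rotate (amide C–N bonds are excluded by default, since their
rotational barrier makes non-planar states rare).

### Torsion preferences

For each rotatable-bond class, observed dihedrals are summarised by a
kernel density estimate with a wrapped Gaussian kernel on (−180°, 180°],
evaluated on a 1° grid. Local maxima of the density are the
representative angles; each peak's probability is the density mass of
its basin of attraction (the arc between adjacent local minima), so
probabilities sum to one by construction. Peaks closer than one
bandwidth to a stronger peak merge into it. Defaults: bandwidth 10°, at
most 10 peaks per bond. Rules are keyed by 4-atom dihedral SMARTS
patterns and assigned first-match-wins, with a mandatory `*` fallback
(anti/gauche, 0.5/0.25/0.25) so every free bond has a rule.

The shipped library is fitted from *synthetic* observation files
bundled under `inst/extdata/torsion_obs/` that emulate common linker
chemotypes (ether, alkyl, amide-adjacent, aryl–alkyl). They are
generated wrapped-normal mixtures, not crystallographic survey data, and
are meant as a working default: a production user should fit
`read_torsion_library()`-format rules from their own observations.

### Deterministic depth-first enumeration

Free bonds are enumerated depth-first in a fixed bond order; at each
node the rule's angles are tried in descending probability (ties:
smaller absolute angle first, then positive before negative). Branches
are cut when

* any heavy-atom pair at graph distance ≥ 4 bonds comes closer than
  `clash_factor` (default 0.6) times the sum of van der Waals radii —
  checked only over pairs whose relative geometry is already fixed at
  that depth, so no branch is cut that a deeper rotation could rescue;
* the running probability product falls below `min_probability`
  (default 1e-6);
* a completed conformer lies within `similarity_rmsd` (default 0.5 Å,
  superposed heavy-atom RMSD, symmetry-blind for speed) of a kept one.

There is no stochastic step anywhere, so ensembles are bit-reproducible
and the first emitted conformer always carries the maximal probability
product. The similarity rejection implements the "diverse conformers"
requirement as an on-the-fly filter rather than a post-hoc clustering
pass; this is a deliberate design choice — it keeps emission order (and
hence ranks) well defined.

The protein-bound fragment geometries enter twice: first their internal
torsions are copied onto the degrader (`apply_bound_torsions`), then the
matched atoms are registered as constrained fragments whose bonds (all
four torsion-defining atoms inside the fragment) are excluded from
sampling. Every emitted conformer reproduces each fragment's internal
distance matrix to < 1e-6 Å; the test suite checks this across a
500-conformer ensemble.

### Assembly and scoring

Monomer complexes are placed by MCS + Kabsch. The MCS is a connected
maximum common subgraph on heavy atoms requiring element and bond-order
equality (ring/chain distinction off); the Kabsch superposition is the
standard SVD solution with the determinant correction, so only proper
rotations occur. Clash- and surface-scores count inter-unit heavy-atom
pairs in the [0, 2) Å and [2, 4) Å shells respectively — half-open
boundaries, so no pair is double-counted — summed over POI↔E3,
POI↔degrader and E3↔degrader pairs, minus the same counts inside each
isolated monomer complex (protein against its own ligand), floored at
zero. Which pairs enter the count is genuinely ambiguous in the
underlying method description; counting all inter-unit pairs makes the
baseline subtraction meaningful and is switchable to `protein_only`.
Hydrogens are excluded from all scoring.

Raw counts are min–max normalised per ensemble onto [1, 10] (constant
ensembles map to 1, the *best* end, so a uniformly clash-free ensemble
is not penalised). The plausibility window keeps models with clash
≤ 1.1 and surface ≤ 1.2, the range observed for experiment-like TC
geometries.

### Reduction and the compromise-score

Window-passing models are aligned on the E3 Cα set of the lowest-clash
model (ties: lower rank). The POI orientation feature is the
concatenation of the three unit principal axes of its heavy-atom inertia
tensor, eigenvalue-ascending. Eigenvectors have a sign ambiguity; each
axis is flipped so its largest-magnitude component is positive, and
near-degenerate spectra (two eigenvalues within 1e-6 relative) are
flagged. k is chosen by maximum mean silhouette over a candidate range
(default 2–50), with near-ties broken toward the elbow (largest second
difference of within-cluster inertia); clustering is k-means with
k-means++ seeding, 10 seeded restarts, best inertia kept.

Representatives maximise the compromise-score
`S = 1 − (w_clash · S_clash + w_surface · (1 − S_surface))` on
[0, 1]-rescaled scores (ties: lower raw clash, then lower rank). The
weights are optimised on the simplex by maximising the mean log-density
of the selected representatives under per-axis reference densities
(Gaussian KDE on [0, 1] with boundary reflection, bandwidth 0.05),
minus `α (w_clash² + w_surface²)` with α = 0.1. "Similarity to the
reference distributions" is not operationalised in the source method;
mean log-density of the selected representatives is this package's
choice, stated here deliberately. The optimiser is a deterministic
101-point grid scan with golden-section refinement inside the best
cell — the objective is piecewise constant in w (representative switches)
plus a smooth penalty, so gradient methods are inappropriate. In a
prospective run with no experimental reference scores, the unit scores
of the window-passing models themselves form the reference density; any
user-supplied score table can replace it.

### Evaluation

`pp_rmsd` first builds a residue map per chain role by global sequence
alignment (match +1, mismatch −1, linear gap −2; identity < 30% warns,
supporting homolog references), then superposes the model on the
reference using E3 Cα only and measures the RMSD over all mapped Cα of
both proteins with no re-fitting. Plain per-atom RMSD is used (no
chain-length weighting; the method source leaves this open).
`rank_models_by_ppRMSD` applies the plausibility window, takes up to
`top_n` models by ascending lig_RMSD and reports the best pp_RMSD, its
rank, and the count under 10 Å.

## What the synthetic systems do and do not show

`make_toy_degrader` builds a fluorobenzene and a pyridine cap joined by
an alternating C/O ether linker, embedded by a small deterministic
distance-geometry routine; the first and last two chain atoms belong to
the frozen cap fragments, leaving exactly `n_linker_bonds` free bonds,
so enumeration counts are known in closed form. `make_toy_protein`
builds Cα + sidechain-centroid pseudo-residues along a helix or a
seeded globular walk around the ligand. These systems give exact,
hand-checkable oracles for every stage (fragmentation bookkeeping,
enumeration counts, placement RMSDs, contact counts, clustering
recovery), which is what the tests exercise.

They do not show chemical realism: no real torsion statistics, no
protein folds, no binding-site shape complementarity, and contact counts
far sparser than a real interface. Passing tests therefore demonstrate
the correctness of the machinery, not predictive accuracy on real
degrader systems — the latter depends on the quality of the torsion
library and the rigid-monomer assumption, both inherited limitations.

## Numerical choices

* Angles live on (−180°, 180°]; KDE grids are 1°, trapezoid-integrated.
* Torsion driving is exact (dihedral reset to target within 1e-6°);
  distal-side rotation only, so internal coordinates elsewhere are
  untouched.
* Kabsch uses base `svd` with the sign correction; degenerate inputs
  (< 3 points, collinear) are errors.
* lig_RMSD minimises over element- and bond-order-preserving graph
  automorphisms (found via coloured LAD isomorphism, capped at 10,000).
* The problem sizes in tests and the acceptance script — toy degraders
  with 1–4 free bonds, 8-residue pseudo-proteins, ensembles of ≤ 500
  conformers, 10,000-sample torsion fits — were chosen as the smallest
  sizes at which every contract is non-trivially exercised.

## Known limitations

* Rigid monomers: no induced fit, side-chain repacking or energy
  refinement; scores are purely geometric.
* The SMARTS/SMILES support is a documented subset (organic-subset
  elements, bond symbols, branches, ring closures, anchor maps); logic
  operators and recursive SMARTS are rejected, and aromaticity is not a
  matching constraint (use explicit `-`/`:` bonds to discriminate).
* SDF charge blocks are not written; neutral molecules round-trip
  exactly.
* `embed_from_smiles` is a convenience for linker-sized molecules, not
  a general conformer generator; fused-ring systems may embed poorly.
* The `--threads` option is accepted for interface compatibility but
  runs the serial search; the output contract (serial emission order)
  is what any parallel implementation would have to reproduce anyway.
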