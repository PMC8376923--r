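---
title: "Enumeration, clustering and population fitting: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumeration, clustering and population fitting: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confenum)
```

This vignette is the package's account of its science: the models behind
each stage, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, the numerical choices, and the known
limitations. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## From likelihood maps to torsion boxes

Chemical-shift-based predictors emit, per residue, a likelihood over the
324 voxels (20° × 20°) of the Ramachandran plane. `normalize_map()` rescales
a map to a probability distribution; `select_voxels()` keeps voxels with
probability strictly above a threshold (default 0.01, i.e. about 3× the
uniform level of 1/324 ≈ 0.003); `boxes_from_voxels()` groups the selection
into 8-connected components and returns each component's bounding
rectangle as a `TorsionBox`.

Design choices made here:

* **Automatic boxes.** Where a human would draw boxes over the selected
  voxels by eye, the package uses component bounding rectangles — a
  reproducible rule — and accepts hand-written box tables in the same text
  format as an escape hatch. Auto boxes never extend beyond their
  component's bounding rectangle.
* **Toroidal topology.** Ramachandran maps are periodic; components are
  merged across the ±180° seam on both axes. A seam-crossing box is written
  with its upper limit past 180° (e.g. φ ∈ [160, 200] means
  [160, 180] ∪ [−180, −160]), which downstream code interprets
  periodically.
* **Missing maps.** A residue whose map is absent or entirely below
  threshold is an error unless the configuration explicitly copies another
  residue's boxes (`copy_from`); nothing is defaulted silently.

## Torsions as distances, and the branch-and-prune tree

For ideal bond lengths and angles, a backbone dihedral is in one-to-one
correspondence (up to sign) with the distance between the first and fourth
atoms of its defining chain: φ(i) with C(i−1)···C(i), ψ(i) with
N(i)···N(i+1), and the fixed ω with CA(i)···CA(i+1). The correspondence

d² = r₁² + r₂² + r₃² − 2r₁r₂cosθ₁ − 2r₂r₃cosθ₂ + 2r₁r₃(cosθ₁cosθ₂ − sinθ₁sinθ₂cosω)

is strictly monotone in |ω| on (0°, 180°), so a torsion box maps to a
distance interval. Atoms are placed by trilateration from three already
placed references; two of the three distances are exact (a bond and an
angle-derived 1–3 distance) and at most one is an interval. The sign
ambiguity of the torsion (mirror solutions of the trilateration) is
resolved by measuring the realized dihedral and checking membership of the
(periodically interpreted) box with a small angular slack (default 2°),
which mirrors the 0.05 Å widening of the distance bounds.

The default build order is backbone-plus-decorations: per residue N, CA, C
(and CB right after C), with each carbonyl O placed once the next residue's
N exists, because O's third reference distance (to that N) is fixed by the
planar peptide group. CB and O are placed from three exact distances; their
mirror candidates are disambiguated by improper-angle targets:

* CA chirality: the torsion CA–N–C–CB, target −33.84° for L-residues,
  derived from the ideal tetrahedral angles in the parameter file; a
  D-configuration flips its sign and is pruned.
* Peptide planarity: the torsion O–CA–C–N(i+1), target 180°.

The improper tolerance defaults to 5°: far smaller than the ~68° separation
between the two chirality candidates, far larger than the numerical error
of exact placements. Pairs separated by two bonds or fewer are excluded
from the clash check (the standard nonbonded exclusion); the van der Waals
scaling of 0.7 compensates for enumerating at ideal geometry without any
relaxation.

Interval discretization: bounds widened by 0.05 Å, then
`min(4, max(1, floor(width / 0.1)))` equal sub-intervals sampled at their
midpoints — small intervals are never over-sampled, wide ones are capped at
4 branches. Near ω = ±180° the +180/−180 torsion aliases describe the same
geometry; candidates are deduplicated on the wrapped circle.

One dummy alanine residue is appended at each terminus so that the first
real residue's φ and the last one's ψ are defined; dummy torsions are fixed
at extended values (φ = −139°, ψ = 135°, chosen to keep the dummies' steric
footprint minimal and reproducible), dummies take part in pruning and are
stripped from saved conformations. Alanine is used because it is the
smallest residue that still carries a Cβ.

Leaves are gated: a conformation is saved only when its Kabsch-aligned Cα
RMSD to the *most recently saved* one exceeds the gate (default 2 Å); the
all-saved comparison is available as an option. Saving stops at the cap
(default 10⁹) and the result is flagged incomplete. Branch order is
deterministic — distance samples ascending, positive torsion before
negative — so identical inputs give identical output.

The correctness argument for the enumerator is a bijection test: on small
fragments the saved set must coincide, conformation by conformation and in
traversal order, with an independent construction that builds every sampled
torsion combination in Cartesian space and applies the same pruning rules.

## Conformer encoding, SOM and U-matrix

Conformers are encoded from their Cα–Cα distance matrix D by the row
covariance C_ij = (1/n) Σ_k (d_ik − d̄_i)(d_jk − d̄_j); the four largest
eigenvalues and their eigenvectors form a vector of length 4(n+1). (Note
that reading the covariance as a doubly summed product of row sums
factorizes to zero identically; the row-covariance reading is the only one
that yields informative eigenvectors, and is what is implemented.) The
encoding is invariant under rigid motion and blind to chirality — two
mirror-image conformers encode identically, which is acceptable here
because the enumerator only emits L-configurations. Eigenvector signs are
fixed by making each vector's largest-magnitude component positive.

The map is a periodic (toroidal) 2D Kohonen lattice. The training
schedule is the package's own declared choice: neurons initialized uniformly within the inputs'
per-coordinate range, 2 epochs over shuffled inputs, learning rate 0.5 →
0.05 linear, Gaussian neighbourhood with radius max(rows, cols)/2 → 1
exponential; every piece is a function argument. The U-matrix is the mean
code-vector distance to the 8 toroidal neighbours; representatives are the
first-assigned conformations of occupied local minima (entry ≤ all
neighbours, < at least one). "First" is resolved as the lowest input index
of the best-matching-unit assignment computed after training, which makes
the extraction deterministic. If no minimum is occupied, the lowest-U occupied
neuron serves as fallback (logged). Clustering triggers only above 1000
conformations (strictly), leaving small sets untouched.

Map size matters relative to occupancy: minima of a map much larger than
the input set tend to fall on unoccupied neurons. The 100×100 production
default matches set sizes in the 10⁴–10⁶ range; the tests use 8×8–20×20
maps with hundreds of inputs, which keeps occupied minima plentiful at desk
scale.

## Assembly and domain attachment

Consecutive fragments share 3 residues. The downstream fragment is
superposed onto the upstream one over the shared backbone atoms
(N, CA, C, O); the *switch atom* is the overlap backbone atom whose two
copies are closest after superposition (ties toward the earlier atom in
build order); the merged chain takes the upstream atoms through the switch
atom and the downstream ones after it. Merges with any non-neighbouring Cα
pair under 1 Å are rejected. Counters per step satisfy
N_saved = N_trials − N_clashes with N_trials the product of the two set
sizes, and chains assemble left to right with clustering between steps.

Domain attachment scans a lattice spanning the linker's Cα bounding box
widened by the domain's radius of gyration, keeping points strictly within
R_g of the downstream anchor's Cα and strictly beyond 2 Å of every linker
Cα. At each point the domain is rotated by the minimal rotation aligning
its anchor vector (Cα of the two shared residues) with the linker's, then
translated by the mean of the two anchor displacement vectors. Acceptance:
fewer than 3 cross Cα pairs under 1 Å *and* mean anchor Cα–Cα distance
under 6 Å. Grid spacing (2 Å default) and the spin about the aligned axis
(one vector alignment leaves a free rotation; a configurable number of spin
angles, default 8, can be scanned) are package choices where the procedure
left freedom. The second domain is carried over from a reference complex:
superpose the complex on the partial model over a stated backbone range,
translate the second domain by the bridge residue's Cα displacement, accept
under 50 atom–atom clashes at 1 Å. The molecular-dynamics relaxation and
energy filtering that a full structural study would run afterwards are out
of scope; an optional steric-only filter stands in, and knot detection is
not attempted.

## Maximum-entropy populations

Populations w on the simplex minimize χ²/2 − θS with
χ² = Σ_j ((Σ_i w_i y_ij − o_j)/σ_j)² and S = −Σ_i w_i ln(w_i/w⁰_i) ≤ 0.
θ (default 10) trades data fit against adherence to the reference weights
w⁰ (uniform by default); as θ → 0⁺ the solution approaches
simplex-constrained least squares, as θ → ∞ it returns w⁰. σ comes from the
observed profile when present, else 1.

The optimizer works in softmax coordinates (simplex constraints exact,
iterates interior): mirror descent with backtracking to approach the
optimum, then damped Newton with the analytic Hessian. The second-order
polish matters: the χ² term's design matrix can have a condition number of
10⁷ or worse on realistic curve sets, where first-order methods stall far
from the optimum. If a random start still ends above the reference point's
objective, the fit restarts from w⁰, so the reported objective never
exceeds objective(w⁰).

The two-round protocol runs 10 fits from uniform-random simplex starts,
keeps conformers whose population summed over the runs exceeds 0.01, refits
10 times on the kept set, and reports per-conformer mean ± sd (means
renormalized; deviation from 1 below 10⁻⁶) plus mean χ² and S. Duplicate
predicted profiles make only their summed population identifiable; with
θ = 0 the run-to-run scatter (sd) exposes the degeneracy, while θ > 0
resolves it toward equal split — both behaviours are tested.

Fit quality uses RMS, Pearson R, and Q = rms(calc − obs)/rms(obs), the
standard NMR normalized-deviation convention; plain rms normalization is
available.
Greedy ensemble selection adds, at each step, the candidate maximizing the
equal-weight ensemble's R, and emits the full RMS/R/Q trajectory: whether
to stop where R peaks or where RMS/Q bottom out is left to the caller,
since a correlation is normally maximized while the source procedure
described selecting at a minimum.

## The synthetic generator: what it emulates, what it does not

`synthetic_scenario()` plants per-residue torsion distributions (mixtures
of isotropic Gaussians on the torus; default an α mode at (−65°, −45°) and
a β mode at (−120°, 130°), equal weights, σ = 10° — the two basins real
coil predictions usually show), ensemble weights, and a relative noise
level (default 1%). `make_synthetic_maps()` integrates the mixtures over
the 324 voxels (midpoint rule, 5 sub-points per axis by default);
`make_synthetic_ensemble()` builds one conformer per weight from sampled
torsions and mixes per-conformer observables under the planted weights with
multiplicative Gaussian noise.

The fitted observable stacks the coarse Debye curve
I(q) = Σ_ij sinc(q r_ij) over Cα pairs with PRE intensity ratios
exp(−k/r⁶) from a configurable set of probe sites (the recovery tests use
five, echoing typical spin-label studies). This matters: same-length chains
have smooth, strongly collinear scattering curves — on a 25-conformer set
the SAXS-only design matrix is rank-deficient and decoy mixtures reproduce
the observation within 1% noise, so support recovery from scattering alone
is impossible (consistent with scattering's known insensitivity to compact
sub-states). The distance-steep PRE blocks restore identifiability.

What passing tests therefore show: the pipeline's logic — box extraction,
exhaustive enumeration, reduction, assembly arithmetic, population
inference — is correct on data whose generating process is known.
What they do not show: that real chemical-shift likelihood maps are
well-calibrated, that the coarse Debye predictor approximates solvated
scattering (it has no solvation layer and unit form factors), or that the
single-constant PRE model matches spin-label physics. Those components are
declared stand-ins for external predictors, used for synthetic tests and
qualitative profiles only.

## Problem sizes and numerical tolerances

The test suite runs at desk scale by choice: enumeration bijections on 2–3
residue fragments with ≤4 branch samples per torsion (hundreds to a few
thousand leaves), SOM maps of 8×8–20×20 with 100–500 inputs, recovery
studies with 25 conformers × 20 seeds, and a 12-residue three-fragment
end-to-end pipeline. Key tolerances: trilateration distance residuals
10⁻⁶ Å; torsion↔distance round trip 10⁻⁹ degrees; rigid-motion invariance
of encodings 10⁻⁹; U-matrix vs direct neighbour averages 10⁻¹²; tangency
in trilateration decided at a squared out-of-plane coordinate of
10⁻⁹·(1 + d²), far below the 0.02 Å² scale at which genuinely distinct
mirror candidates appear.

## Known limitations

* Backbone + CB + O only; no sidechains beyond CB, no hydrogens by default,
  ω fixed trans (cis-proline unsupported).
* The enumerator is pure R and exponential by nature; it is meant for
  fragment-scale trees (the clustering between stages is what keeps the
  full pipeline tractable), not for long peptides in one run.
* Chirality-blind encoding (harmless for enumerator output, wrong for mixed
  stereochemistry).
* The PRE and scattering predictors are coarse stand-ins, not replacements
  for dedicated back-calculation software.
* Energy-based filtering, restrained refinement against RDC/PRE, and knot
  detection are outside the package's scope.
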