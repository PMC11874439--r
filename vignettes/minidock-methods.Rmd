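---
title: "MiniDock: models, parameters and design choices"
author: "MiniDock maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MiniDock: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MiniDock)
```

MiniDock is a desk-scale molecular docking stack: Monte Carlo pose
sampling driven by an empirical scoring function, convolutional neural
network (CNN) rescoring on voxelized atom densities, a covalent docking
mode, knowledge distillation of a CNN ensemble into a single fast scorer,
and the standard pose/screening evaluation metrics. This vignette explains
the models it implements, the parameters that matter, what the synthetic
fixtures do and do not show, and the design decisions taken where the
design was genuinely open.

## The empirical scoring function

Pose quality during sampling is judged by a Vina-form empirical score. For
every receptor–ligand heavy-atom pair within an 8 Å center-to-center
cutoff, five terms are evaluated as functions of the *surface distance*
$d = \lVert \mathbf{x}_i - \mathbf{x}_j \rVert - (r_i + r_j)$, with $r$
the built-in van der Waals radii (C 1.9, N 1.8, O 1.7, S 2.0, P 2.1,
halogens 1.8–2.0, metals 1.2 Å):

* `gauss1` $= e^{-(d/0.5)^2}$ and `gauss2` $= e^{-((d-3)/2)^2}$ — smooth
  attraction at contact and at the second shell;
* `repulsion` $= d^2$ for $d<0$, else 0;
* `hydrophobic` — 1 for $d \le 0.5$, 0 for $d \ge 1.5$, linear in
  between, applied only to pairs of hydrophobic carbons;
* `hbond` — 1 for $d \le -0.7$, 0 for $d \ge 0$, linear in between,
  applied only to donor–acceptor pairs.

The weighted sum over pairs is divided by $1 + w_{rot} N_{rot}$, where
$N_{rot}$ counts the ligand's rotatable bonds. The weights are the
published AutoDock Vina coefficients ($w_{g1}=-0.035579$,
$w_{g2}=-0.005156$, $w_{rep}=0.840245$, $w_{hyd}=-0.035069$,
$w_{hb}=-0.587439$, $w_{rot}=0.05846$); they are exposed through
`termWeights()` but there is no re-fit here — the functional form and its
coefficients are inherited, not a contribution of this package.

Atom typing uses a reduced 13-type vocabulary (hydrophobic/other carbon,
donor/acceptor/both for N and O, S, P, halogen, metal, H). It is coarser
than the full smina table but spans exactly the distinctions the five
terms and the CNN channels need. Hydrogens are parsed and used to decide
donor status, then excluded from scoring pairs, RMSDs and grids. Nitrogen
with a bonded hydrogen and fewer than three connections is typed
donor+acceptor, with three donor-only (the amide case); hydrogen-free N
and O are acceptors. This rule set is deliberately simple and documented
rather than exhaustive.

Ligand *internal* energy uses the same five terms over heavy-atom pairs
that lie in different rigid fragments (their distance depends on the
torsions) and are three or more bonds apart. It enters the minimization
objective; the reported pose score remains the inter-molecular part, as
users of Vina-lineage tools expect.

## Degrees of freedom and local minimization

A pose has 6 rigid-body degrees of freedom plus one dihedral per rotatable
bond. Rotatable bonds are acyclic single bonds with a heavy substituent
beyond the axis on both sides; rings and terminal bonds never rotate. The
torsion tree roots at the largest rigid fragment (ties: lowest atom
index), or at a caller-chosen atom in covalent mode. All indices in the
package are 1-based, as is natural in R; user-facing residue numbers stay
as printed in the PDB.

`localMinimize()` is a quasi-Newton (BFGS) descent in the generator basis:
at the current geometry the gradient of the objective with respect to
translation, rotation about the ligand centroid, and each torsion angle is
assembled analytically from the per-atom Cartesian gradient, a BFGS
direction is computed, and the step is applied incrementally (torsions,
then rotation, then translation). An Armijo backtracking line search
accepts only decreasing steps, so the objective is non-increasing by
construction — the property the tests assert. Stops: gradient
infinity-norm below `1e-4`, relative improvement below `1e-8`, or 200
iterations. The piecewise-linear terms get sub-gradient 0 at their kinks;
in practice the line search handles the resulting mild non-smoothness.

## Monte Carlo sampling

`runDocking()` runs `exhaustiveness` independent Metropolis chains
(default 8), each `steps` long (default 200; the tests and examples use
10–30 because the toy complexes are small). One step draws a single move
uniformly among rigid translation (≤ 2 Å), rigid rotation (uniform axis,
full circle) and a single torsion re-draw; the mutated pose is locally
minimized and accepted with probability
$\min(1, e^{-\Delta/T})$ at temperature $T = 1.2$ score units — the
Vina-lineage default; the temperature and step counts are not re-derived
here. Covalent mode draws torsion moves only. Chain $c$ seeds its RNG with
`seed + c`, which makes the whole pipeline reproducible to the byte while
keeping chains independent. Pooled poses are sorted by score, greedily
filtered so survivors are mutually more than `minPoseRmsd` (1 Å) apart in
symmetry-corrected RMSD, and truncated to `numModes` (9).

## Covalent docking

The covalent mode expects the bound covalent form of the ligand. The user
names the warhead atom with a SMARTS pattern and the receptor atom by
chain, residue number and atom name. Every SMARTS match becomes a pairing
and the output is the concatenation over pairings. For each pairing the
package:

1. computes a bond vector at the receptor atom — after discounting one
   bonded hydrogen, the direction is the normalized negative sum of unit
   vectors to the remaining neighbors (isolated atom: +x), and the
   suggested position sits at the sum of the covalent radii along it (the
   user can override the position explicitly);
2. rigidly places the ligand so the warhead atom lands on that position
   with its bonds pointing back along the new bond, then spins it about
   the bond axis to the least-clashing of 12 evenly spaced angles;
3. bonds the warhead to the receptor atom (order configurable, default 1)
   and treats the anchor residue plus ligand as one construct whose
   torsion tree roots at the residue backbone;
4. samples torsions only — no rigid-body moves.

Two details are stricter than a flexible-side-chain reading: the sampled
torsion set keeps the receptor anchor atom itself immobile (only torsions
that move ligand atoms without moving the anchor are drawn), so the
attachment point and the new bond length are invariant across output
poses; and ligand-origin atoms keep their ligand identity flag, so CNN
channel assignment is unchanged by construct building. Optional
`optimizeConstruct` performs a bonded-geometry relaxation that restores
the exact covalent-radius bond length at the junction; a full force-field
relaxation is intentionally out of scope.

The SMARTS matcher is a self-contained subset engine (bracket primitives
for element, connectivity `X`, hydrogen count `H`, ring membership `R`,
charge, negation/conjunction/disjunction; chains, branches, ring closures;
bond symbols `-», `=`, `#`, `~`). Aromatic lowercase atoms are read as
"element in a ring" — no aromaticity perception is attempted. Anything
outside the subset raises a parse error rather than matching incorrectly.

## Grids and CNN scoring

`voxelize()` renders a pose as a multi-channel density grid: each heavy
atom adds $e^{-2d^2/r^2}$ out to its radius and a matching quadratic tail
to $1.5r$ (continuous value and slope), evaluated analytically at voxel
centers, into the channel given by its interaction type and molecule role.
The default grid is 48³ voxels at 0.5 Å with 13 types × 2 roles = 26
channels; the training and rescoring paths use a coarse variant (4
element classes × 2 roles, 8³ voxels at 1.25 Å) that keeps desk-scale
training in seconds — `gridSpec()` controls both.

Two CNN families score grids, both ending in a two-task head (pose
classification logits and an affinity regression):

* **default2018** — a linear stack of five 3×3×3 convolutions with 2×
  max pooling after the first three, widths $w, 2w, 4w, 4w, 4w$;
* **dense** — twelve convolutions in three densely connected blocks
  (growth rate $w$, concatenation within blocks), pooling between blocks.

Training minimizes two-class cross entropy on the pose label (good = RMSD
≤ 2 Å) plus a hinged affinity MSE: squared error on good poses, and
$\max(0, \hat{y} - y)^2$ on bad poses so an inaccurate pose is only
penalized for *over*-predicting affinity. The optimizer is minibatch SGD
with momentum 0.9 and global gradient-norm clipping at 5 — without
clipping the affinity head's large initial error destabilizes the shared
trunk at small batch sizes. Filter counts are desk-scale (4–32); nothing
here claims the released models' capacity, and the affinity head trains
but is never used for ranking.

Ensemble scoring averages member probabilities and affinities
(arithmetic mean, order-invariant) and reports mean pre-softmax logits.
The default ensemble has three members — one teacher-trained dense model,
one distilled dense student and one distilled default2018 student — and
`--cnn fast` selects the single distilled default2018 student.

## Knowledge distillation

`distillStudent()` trains a student on the teachers' own training data
with total loss

$$ L = \lambda \sum_t \mathrm{KL}\big(\sigma(z_t/T) \,\Vert\, \sigma(z_s/T)\big)
     + \mathrm{CE}(z_s, y) + \mathrm{hinge MSE}(\hat{a}_s, a, y), $$

where $z$ are pose logits and $\sigma$ the softmax. Only the pose score is
distilled; affinity stays supervised by ground truth. "KL of the
pre-softmax values" is ambiguous as written (KL is defined on
distributions): the implementation softmaxes the raw logits inside the
loss, and a `soft_ce` mode (soft-target cross entropy, identical gradient)
is available as a configuration switch. Temperature defaults to 1.
Fidelity is reported as mean held-out KL between the student's pose-score
distribution and the ensemble-mean distribution.

## Metrics

* `symmetryRmsd()` — minimum heavy-atom RMSD over automorphisms of the
  element-colored molecular graph, in a common frame (no superposition).
  Bond orders are ignored deliberately, so Kekulé-alternating rings keep
  their rotational symmetry. The automorphism search caps at $10^4$
  mappings and falls back to the identity with a warning.
* `topN()` — percentage of targets with a ≤ 2 Å pose among the first N.
* `rocAuc()` — rank-based (Mann–Whitney), ties counted half.
* `enrichmentFactor()` — active rate in the top `ceil(f·N)` over the
  library rate; ties at the cutoff break by stable input order.
* `normalizedEnrichmentFactor()` — divided by the perfect-ranking EF so
  the value lies in [0, 1] regardless of class balance.

## The synthetic study conditions

`generateToyComplex()` builds a rigid cage of hydrophobic carbons on an
oblate ellipsoid (semi-axes `pocketRadius × (1, 0.88, 0.73)`, default long
axis 5.2 Å, 60 receptor atoms) with one cysteine-like residue embedded in
the wall, its SG pointing into the cavity as a covalent anchor. The
flattened cavity gives the empirical score a single central basin for the
planar/linear ligand templates, so redocking has a well-defined ground
truth: the reference pose is the locally minimized central placement.
`makeGridDataset()` derives pose-labeled grids from these complexes —
good poses jitter the reference (RMSD ≤ 2 Å), bad poses are displaced
2.6–4.5 Å and rotated, and each complex carries a pK drawn from [5, 8].

What these fixtures show: that the sampler recovers a known basin, that
the covalent machinery preserves its invariants, that the CNNs can learn
and be distilled, and that every numeric path is correct against oracles.
What they do not show: pose-prediction or screening accuracy on real
protein–ligand complexes — the good/bad classes are geometrically
separable by construction, real decoys are not, and no claim about real
data transfers from these tests.

Problem sizes used by the test-suite and the acceptance script (chosen so
the full stack runs in minutes on one CPU): 20 redocking targets at
exhaustiveness 3 × 20 steps, 200-example CNN training sets on 8³ coarse
grids, 5 distillation teachers with 56 training and 16 held-out grids,
and 50 complexes for the brute-force scoring comparison.

## Known limitations

* Bond perception for receptors is distance-based; unusual geometries can
  gain or lose bonds. Ligand bonds come from the SDF and are authoritative.
* No protonation, charge assignment, aromaticity perception or conformer
  generation; ligands are used as provided.
* The empirical score's constants are inherited defaults, not re-fitted;
  the CNNs are synthetic-trained and desk-scale.
* The SMARTS engine covers a documented subset; complex queries belong in
  a full cheminformatics toolkit.
* Minimization treats piecewise-linear kinks by sub-gradient; convergence
  to a kink point may stop on the line-search rather than the gradient
  criterion.
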