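---
title: "Pocket voxelization, 3D CNN classification, and CAM interpretation"
author: "pocketvox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pocket voxelization, 3D CNN classification, and CAM interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Proteins with unrelated folds often bind the same class of ligand:
nucleotide- and heme-binding pockets are prominent examples.  Classifying a
binding pocket from structure alone therefore has to work from the local
physicochemical environment of the site, not from global homology.
`pocketvox` treats this as a 3D computer-vision problem: a pocket is turned
into a fixed-size, canonically oriented multi-channel image in which each
voxel carries knowledge-based interaction energies, a compact 3D
convolutional network classifies the image, and a class-activation map
(CAM) projects the network's evidence back onto binding residues.

# From complex to voxel tensor

## Pocket grid and refinement

Given a protein-ligand complex, a spherical grid of **radius 15 Å** with
**1 Å spacing** is centered on the geometric center of the ligand's heavy
atoms.  Three refinement steps remove grid points that do not belong to the
pocket:

1. **Excluded volume** - points within 2 Å of any protein heavy atom are
   removed (`d <= 2` removes; the boundary set has measure zero on real
   coordinates, and the convention is documented in
   `remove_excluded_volume()`).
2. **Envelope clipping** - points sticking out of the protein into bulk
   solvent are removed.  The clipping region is genuinely ambiguous between
   "convex hull of the protein" and "union of atomic envelopes"; both
   readings are implemented.  The default is the convex hull of the
   heavy-atom centers (deterministic and parameter-free, computed by an
   incremental 3D hull with facet half-space tests; boundary points count
   as inside).  `mode = "envelope"` instead keeps points within `r_env`
   (default 4 Å) of any atom.  A degenerate, coplanar atom set makes hull
   mode fall back to envelope mode with a warning.
3. **Largest connected component** - lattice connectivity 6 by default
   (face adjacency at the grid spacing; 26 available).  Size ties break
   toward the component containing the point closest to the grid center,
   then first in component order.

Each step only removes points, and the per-step removal counts are logged
on the grid object.

## Energy channels

Every surviving grid point receives a vector of interaction energies, one
channel per probe atom type.  The 14 SYBYL probes are C.2, C.3, C.ar, N.2,
N.4, N.am, N.ar, N.pl3, O.2, O.3, O.co2, P.3, S.3 and F.  The potential is
a pluggable distance-binned table `u(probe, protein_type, bin)` in the
spirit of distance-scaled ideal-gas reference (DFIRE) statistical
potentials; channel `c` at point `p` is

    E_c(p) = sum over protein atoms a with d(p, a) <= cutoff of
             u(c, sybyl(a), bin(d(p, a)))

with a default cutoff of 14.5 Å (the conventional DFIRE cutoff; the last
bin edge of the table).  Distances are measured point-to-atom-center; no
atomic radii enter the sum.  Real DFIRE parameters are fitted from PDB
statistics and are consumed here as an external table
(`load_potential_table()`); the package ships a deterministic synthetic
table (`toy_potential()`) whose only purpose is to give every
(probe, protein type, bin) triple a distinct nonzero energy so that tests
and the synthetic study are self-contained.  Its magnitudes decay steeply
with the distance bin (1 : 0.2 : 0.05), as real interaction potentials do;
with flat magnitudes the outermost bin, holding the most atoms, would
flood every grid point with the pocket's global composition and no point
would describe its own neighborhood.

Protein atoms are typed by an editable (residue, atom name) table covering
the 20 standard amino acids, with a total element-level fallback
(C→C.3, N→N.am, O→O.2, S→S.3, P→P.3, halogens→F); fallback-typed atoms are
counted in a warning.  Hydrogens and waters are always discarded, and
hetero groups other than the selected ligand take no part in refinement or
energies - metal ions are therefore excluded, a deliberate simplification.

## Canonical orientation and voxelization

Pocket classification by convolution needs a standardized pose.  The frame
is built from the **binding residues** - residues with a heavy atom within
5 Å of a ligand heavy atom (the same distance used for CAM residue
mapping; the definition of "binding" for axis computation is an assumption
documented here, and the cutoff is configurable).  The rotation rows are
the unit eigenvectors of the binding-atom coordinate covariance, ordered by
descending eigenvalue, so the longest/middle/shortest principal axes map to
x/y/z.  Eigenvectors are sign-ambiguous; the convention is that the third
central moment (skewness) of the binding-atom coordinates along x and y is
non-negative, and z completes a right-handed frame (det = +1).  The grid
center (ligand center) maps to the origin.

The canonicalized grid is discretized into **32×32×32 voxels** of 1 ų:
voxel index = `floor(coordinate + 16)` per axis (half-open cells).  After
rotation grid points are off-lattice, so several points can share a voxel;
their channel vectors are **averaged** (the mapping is only 1:1 before
rotation).  The per-point voxel assignment is retained for CAM
back-mapping, and count-weighted sums are conserved exactly.  An
**occupancy baseline** replaces the 14 energy channels with two one-hot
channels (occupied/empty), isolating what shape alone can achieve.

Because the spherical grid lives on a world-aligned 1 Å lattice, the
end-to-end pipeline is *exactly* pose-invariant for rigid motions that map
the lattice to itself (the 24 proper octahedral rotations combined with any
real translation) - the tests assert bit-level equality there, up to the
8 principal-axis sign combinations.  General rotations re-sample the
lattice and are only approximately invariant; this is inherent to any
voxel method with a fixed construction lattice.

# The network

The classifier follows the VoxNet lineage: for a 32³×C input,

    conv(64 filters, kernel 5, stride 1, valid) -> leaky ReLU (slope 0.1)
    conv(64 filters, kernel 3, stride 1, valid) -> leaky ReLU
    dropout(0.2) -> maxpool(2) -> dropout(0.4)
    dense(128) -> leaky ReLU -> dense(K) -> softmax

The kernel pair (5, 3) is the unique conventional choice reproducing the
documented 32 → 26 spatial reduction (32 − 4 − 2 = 26), leaving 64 feature
maps of side 26 after the second convolution.  Dropout rates, the dense
width and the leaky slope are not pinned down by the lineage; the defaults
above are declared assumptions, exposed in `network_config()` and recorded
with every trained model.  An alternative `head = "gap"` (global average
pooling straight into the softmax) is provided because the plain CAM is
exact under that head.

Training minimizes categorical cross-entropy with **Adam** (learning rate
1e-5, decay 0, β₁ 0.9, β₂ 0.999) for 50 epochs at batch size 32 by default
(16-128 behave comparably).  Optional per-channel input normalization is
computed on the training set and stored with the model: `"zscore"` or
`"scale"` (divide by the channel standard deviation only - this preserves
the natural zero of empty voxels, which both keeps "empty space" physically
meaningful and preserves input sparsity).  All convolution arithmetic is
implemented in compiled code as a sum of shifted GEMMs, with a
gather/scatter path over nonzero entries that engages automatically when
the input is sparse, as voxelized pockets are (~4% occupied).

Everything - initialization, shuffling, dropout - draws from a single
seeded RNG stream, so a (seed, data) pair reproduces a run exactly.

# Evaluation

`confusion()`, `classification_metrics()` (ACC, PPV, TNR, TPR, FPR),
`mcc()` and `roc_auc()` implement the standard definitions exactly;
metrics with zero denominators are reported as `NA`, never coerced to 0.
The ROC sweeps distinct score thresholds (ties grouped) and the trapezoidal
AUC equals the Mann-Whitney pair statistic with ties counted ½ - a property
the tests verify against an independent pair-counting oracle and against
pROC.  Multi-class problems are evaluated one-vs-rest using each class's
softmax probability.  `crossvalidate()` uses stratified folds (the class
balance of small datasets is otherwise fragile; stratification is a
documented choice).  `logo_crossvalidate()` holds out one annotated group
per round, e.g. an enzyme-class group, to measure generalization across
rather than within groups.

# Class-activation maps

The deployed network head (maxpool + dense) does not support the plain
GAP-based CAM, so the default is the gradient-weighted generalization: the
feature maps A_k of the second convolution are weighted by the global
average of ∂(class logit)/∂A_k, summed, rectified at zero, and trilinearly
upsampled 26³ → 32³.  Under a GAP + linear head this reduces (up to a
positive constant) to the plain CAM, which is also available as
`method = "cam"`.

The top **1%** of voxels by CAM value are retained (threshold = the
`ceiling(0.01 · 32768)` = 328-th largest value; ties at the threshold are
all kept), intersected with actual pocket grid points, and each selected
point is assigned to the residue of its nearest protein heavy atom if that
distance is ≤ 5 Å (nearest-atom ties break toward the lowest residue
number, then chain).  A residue's **CAM-score** is the sum of its points'
CAM values; unassigned points are counted and their mass reported, so the
aggregation conserves the selected CAM mass exactly.  Whether the "top 1%"
population is voxels or grid points is ambiguous in the lineage; the voxel
reading is used because it yields on the order of 300 points for a typical
pocket.  Scores export as CSV, and selected points as a pseudo-atom PDB
with CAM values in the B-factor column for visualization.

# The synthetic study

Real benchmark sets require thousands of curated PDB complexes and
GPU-scale training; the package instead ships a generator whose outputs
exercise every stage and carry a *known* signal.  `make_complex()` builds a
pseudo-protein shell of 200-300 single-atom residues at radius
(cavity + 0-3 Å) around a 20-atom pseudo-ligand that fills the cavity to
within ~3.5 Å of the lining; cavity radii are drawn from 6-10 Å and
positions are jittered (σ = 0.3 Å).  The class signal is planted in a
spherical cap (half-angle 1.05 rad, ~25% of the lining): cap atoms carry a
class-specific SYBYL type - amide nitrogen (polar), aromatic carbon
(aromatic), or thioether sulfur (sulfur) - while all other lining atoms
share one background mixture of generic carbons (C.3/C.2).  Each cap type
is absent from the background, and the background types appear in no cap,
so the planted cap is the *only* class-specific region: if the background
shared types with a cap (or a class were mostly background-like), that
class would be identifiable by diffuse evidence - e.g. the absence of the
other classes' types anywhere - and the CAM could not be expected to
localize it.  Consequently the **atom-type
composition**, not the pocket shape, separates the classes: the energy
channels must beat the occupancy baseline, and the CAM should point at the
cap.  Everything is deterministic given (seed, class, index).

What the generator does *not* emulate: real backbone connectivity and
side-chain geometry, realistic ligand chemistry, the size distribution of
real pockets, or a physically meaningful potential.  Passing the synthetic
study therefore demonstrates that the pipeline's machinery - carving,
energies, orientation, learning, attribution - works end to end and that
energy channels carry recoverable signal; it says nothing quantitative
about accuracy on real complexes.

## Desk-scale experiment sizes

The studies run by the tests and by `scripts/acceptance.R` use 20 pockets
per class (60 total) and a network with 8 + 8 filters and the **GAP head**,
trained with Adam at learning rate 2e-3, batch 8, 15 epochs and `"scale"`
normalization (~110 optimizer steps, to convergence on this set).  The GAP
head is the right model for this study for a substantive reason: the
planted signal is compositional (which atom types line the pocket), and
after canonical orientation the cap lands in a different direction in every
sample, so a head that pools feature maps spatially generalizes across cap
orientations where the maxpool + dense head tends to memorize locations;
it is also the head under which the plain CAM is exact.  The full-scale
defaults (64-filter maxpool + dense network, learning rate 1e-5, 50
epochs) remain the package defaults; the reduced experiment sizes are the
package's choice of a study that a single CPU reproduces in minutes.

# Numerical choices and edge cases

- Altloc records resolve to the highest occupancy, first record on ties;
  insertion codes are part of residue identity.
- The hull test uses a tolerance of 1e-9 relative to the coordinate scale;
  points on a facet count as inside.
- `build_sphere_grid()` orders points lexicographically (z, y, x) so grid
  provenance is reproducible.
- Voxelization rejects coordinates outside [-16, 16); this cannot occur
  for the default 15 Å radius.
- Eigen-decomposition degeneracy (collinear binding atoms) and skewness
  values of exactly zero are the two ways the canonical frame can be
  ill-defined; the former is an error, the latter keeps the eigenvector
  sign returned by the decomposition (a measure-zero event on real data).
- Softmax is computed with the max-subtraction trick; cross-entropy clamps
  probabilities at 1e-12.

# Limitations

- The package classifies pockets *given* a bound ligand center; it does not
  detect pockets ab initio.
- Shipping real DFIRE parameters is out of scope; users supply their own
  table for physically meaningful energies.
- mmCIF input, bond perception and protonation are out of scope (PDB
  format only, heavy atoms only).
- Exact pose invariance holds for lattice-preserving motions; arbitrary
  rotations incur lattice re-sampling noise.
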