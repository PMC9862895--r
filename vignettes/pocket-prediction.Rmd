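---
title: "Predicting ligand binding sites on protein chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ligand binding sites on protein chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketscout)
```

# The problem

Most of a protein's solvent-accessible surface cannot bind a small
molecule; the few patches that can — binding sites or pockets — are what
docking pipelines, off-target screens and mechanism studies need to find.
pocketscout implements a complete workflow that learns pointwise
*ligandability* (the probability that a ligand can bind at a given surface
point) from structures with bound ligands, and then assembles pointwise
predictions into discrete binding sites.

The pipeline has six stages, each exposed as ordinary functions returning
tibbles or small S3 objects:

1. **Structure cleaning** (`parse_structure()`, `filter_chains()`,
   `filter_ligands()`). Each polymer chain is treated separately. Chains
   with fewer than 28 residues are dropped; a hetero group counts as a
   ligand only if it has at least 7 non-hydrogen atoms and its minimum
   distance to the chain's C$\alpha$ atoms is at most 5 Å. This keeps small
   true binders (insulin-scale chains, drug-like ligands) while discarding
   waters, ions and cryoprotectants (glycerol has 6 heavy atoms). Both
   thresholds are inclusive, reading "at least"/"at most" literally.

2. **Sequence clustering** (`smith_waterman()`, `build_cluster_set()`).
   All chain pairs are locally aligned (BLOSUM62, affine gaps
   11 + L). For aligned sequences $A', B'$ of length $N$, similarity is
   $S = |\{k: a'_k = b'_k\}|/N$ and the covering of $A$ is
   $c = (n_2 - n_1 + 1)/n$ for the spanned region $(n_1, n_2)$. An edge
   joins two chains iff $S > 0.8$ and both coverings exceed $0.9$
   (all strict); clusters are the connected components of this graph, so
   similarity is propagated transitively.

3. **Ligand merging** (`merge_cluster()`). Within a cluster, the chain
   with the most (then largest) bound ligands that superposes well onto at
   least half of its peers becomes the representative. Peers are fitted by
   Kabsch least squares on the C$\alpha$ pairs from aligned non-gap
   columns (gates: similarity and covering above 0.9); a peer is merged
   only if the RMSD
   $\sqrt{\tfrac1n \sum_i d(p_1[i], p_2[i])^2}$ is strictly below 2 Å.
   Merged ligands are transformed with the chain superposition and kept
   unless they clash with a kept ligand or the chain (any heavy-atom pair
   below 1.5 Å — shorter than a covalent bond, hence physically
   impossible) or sit farther than 5 Å from the representative's
   C$\alpha$ atoms. This pools binding-site evidence from redundant
   structures onto one chain and thereby reduces false "non-ligandable"
   labels.

4. **Featurization** (`sas_points()`, `assign_atom_types()`,
   `compute_grid()`, `label_ligandability()`). The surface is a dot
   surface: icosahedrally tessellated spheres of radius
   $r_{vdw} + r_{solvent}$ around every heavy atom, with points inside any
   other expanded sphere removed. Atoms are typed into docking-style
   classes (aliphatic/aromatic carbon, N/O/S acceptors, polar hydrogens,
   metals) and grouped into 8 property channels: hydrophobicity,
   aromaticity, H-bond acceptor, H-bond donor, positive and negative
   ionizability, metal, and excluded volume (every atom). The field of an
   atom at distance $d$ is the occupancy $1 - e^{-(r_{vdw}/d)^{12}}$,
   aggregated per channel by voxelwise maximum on a $19^3$ cube of 1 Å
   voxels centered on the surface point. A point is *ligandable* when some
   ligand atom's occupancy there exceeds $10^{-4}$, which is reached at
   about $10^{1/3} \approx 2.15$ vdW radii — "about twice the atom's
   radius".

5. **CNN scoring** (`build_network()`, `train_cnn()`,
   `predict_points()`). A 3D CNN (four 3×3×3 convolutions with batch
   normalization and ReLU, max pooling after blocks 2 and 4, dropout, one
   hidden dense layer, 2-class softmax) maps each 8×19×19×19 grid to a
   ligandability probability. Batches draw $n_c$ clusters, one chain per
   cluster and $n_p$ points per chain, oversampling ligandable points to a
   50/50 class mix; the learning rate follows a one-cycle schedule
   (max_lr/25 → max_lr over the first 30% of steps, then down to
   max_lr/1000). Data splits for nested cross-validation
   (`make_cv_splits()`) are at cluster granularity — chains of one cluster
   never straddle training/validation/test — with ten pairwise-disjoint
   test sets of 10% of clusters each.

6. **Site grouping and evaluation** (`site_statistics()`,
   `binding_sites()`, `pair_sites()`,
   `chain_classification_metrics()`). Points predicted above an adaptive
   threshold $c$ are clustered into connected components (two points
   connect below 4 Å); a component is accepted as a binding site when its
   point count, mean distance to the geometric center, and the standard
   deviation of that distance all lie within the empirical 10th–90th
   percentile bounds of the true sites' statistics. The threshold moves
   inside an interval $(a, b)$ — shrunk by 20% toward whichever end the
   decision ladder indicates — for at most 21 iterations. Predictions are
   scored by DCC (center–center distance), DVO (intersection-over-union
   of point sets) and per-chain confusion-matrix metrics at thresholds
   $t \in \{0.3, 0.5, 0.7, 0.9\}$.

# Worked example

A self-contained run on synthetic structures (see the README for a larger
one):

```{r example, eval = FALSE}
fx <- make_toy_protein(fixture_spec(seed = 1, n_residues = 45))
entry <- parse_structure(fx$pdb, "toy")[[1]] |> filter_ligands()
feat <- featurize_chain(entry, tessellation_level = 1)
truth <- true_sites_table(feat$points, entry$ligands)
truth[, c("size", "avg_dist", "std_dist")]
```

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_residues` | 28 | inclusive chain-length filter (residues) |
| `min_heavy` | 7 | inclusive ligand heavy-atom filter |
| `max_min_dist` | 5 Å | ligand–C$\alpha$ contact rule |
| `s_bar`, `c_bar` | 0.8, 0.9 | strict similarity / covering bounds for cluster edges |
| `seqid`, `overlap` | 0.9, 0.9 | superposition gates for merging |
| `rmsd_max` | 2 Å | strict RMSD bound for merging |
| `clash_dist` | 1.5 Å | heavy-atom clash distance when adding ligands |
| `solvent_radius` | 1.4 Å | water-probe radius for the dot surface |
| `tessellation_level` | 4 | icosahedron subdivisions; $10\cdot4^L+2$ points/atom |
| `spacing`, `size` | 1 Å, 19 | voxel grid geometry |
| label threshold | $10^{-4}$ | strict occupancy bound defining ligandability |
| `nc`, `np` | 64, 8 | clusters and points per chain per batch ($n_c n_p = 512$) |
| `epochs`, `clusters_per_epoch` | 40, 1024 | full-scale training protocol |
| component cutoff | 4 Å | strict distance for point connectivity |
| $a_0, b_0, c_0$ | 0.3, 1, 0.5 | initial threshold interval |

# Design choices where the design was open

* **Occupancy functional form.** The descriptor literature uses
  $1 - e^{-(r/d)^{12}}$; we adopt it because it reproduces the stated
  property that the $10^{-4}$ label level sits at about twice the atomic
  radius (exactly $10^{1/3} \approx 2.154$ radii by inversion).
* **Gap costs.** The alignment backend is run with BLOSUM62 and affine
  gap costs open 11 / extend 1 — the conventional protein-search defaults;
  the clustering thresholds, not the gap costs, dominate the partition.
  Ties among equally scoring alignments are resolved deterministically by
  the backend.
* **Pooling placement.** The pooling pair sits after conv blocks 2 and 4,
  downsampling 19³ → 9³ → 4³, so the first two convolutions see the full
  resolution around the center voxel.
* **Optimizer.** Adam under the one-cycle schedule is the default: at the
  small step budgets used for tuning and desk-scale runs it converges far
  more reliably than plain momentum SGD, which remains available
  (`optimizer = "sgd"`).
* **Dropout placement** — once, before the first dense layer
  (rate 0.3 by default).
* **Representative acceptance.** A candidate representative must superpose
  (RMSD < 2 Å) onto at least half of the remaining cluster members;
  "sufficiently many" is otherwise unquantified.
* **Percentiles** use linear interpolation between order statistics
  (R type 7). "Fit into the bounds" is inclusive membership in
  $[q_{0.1}, q_{0.9}]$ for all three shape properties.
* **Decision-ladder reading.** In the grouping loop's decision ladder the
  average-distance upper-bound branch admits two readings; the default is
  the symmetric one (a maximum average distance *above* the 90th
  percentile raises the threshold), since the literal alternative
  (below the 90th percentile raises it) makes the lower-bound branch
  unreachable. The flag `avg_upper_literal = TRUE` selects the literal
  reading.
* **Literal loop mechanics.** The first grouping iteration runs under the
  initial condition `"continue"`, and $c$ is reset to $(a+b)/2$ at the end
  of *every* iteration — so $c$ moves from its initial 0.5 to 0.65 after
  one iteration even when the interval is unchanged. Both follow the
  procedure's stated control flow exactly.
* **MCC convention.** A vanishing denominator yields 0. Chains without
  positive labels report sensitivity as missing.
* **Ground-truth sites** are defined per ligand (the points that ligand
  labels), merging sites that share points.
* **Ligand↔chain assignment.** A hetero group contacting several chains is
  attached to the chain whose C$\alpha$ set is nearest; the underlying
  ambiguity is inherent to per-chain processing.

# Numerical notes

* Grid evaluation truncates occupancies below $10^{-8}$ and uses a
  second-order expansion of $1-e^{-t}$ for $t < 0.01$ (relative error
  under $2\times10^{-7}$); the `occupancy()` function itself is exact.
* Batch normalization uses $\epsilon = 10^{-5}$ and momentum 0.1 for the
  running statistics; at inference the affine is folded into the
  convolution weights, which is exactly equivalent in evaluation mode.
* The Kabsch fit enforces a proper rotation (determinant +1) via the sign
  of the SVD determinant product.
* Surface points exactly on a neighboring expanded sphere are kept (the
  inside test has a $10^{-9}$ Å$^2$ slack), and coincident duplicate
  points from coincident atoms are deduplicated.
* Binding-site `std_dist` for a single-point site is 0 by convention.

# What the synthetic generators emulate — and what they do not

`make_toy_protein()` builds compact self-avoiding C$\alpha$ walks with one
side-chain pseudo-atom per residue, carves concave pockets at surface
anchors, and plants a rigid heavy-atom ligand in contact with the chain at
each pocket: small ligands are compact blobs, large ones (≥ 16 heavy
atoms) hug the surface as elongated groove binders, so planted sites span
the sphere-like-to-stretched shape range that makes the percentile gates
of the grouping stage meaningful. The residues lining the ligand footprint
are rewritten as acidic side chains — binding sites in real proteins are
chemically distinctive, often polar or charged — which gives the desk-scale
CNN a chemically learnable cue in addition to geometry.
`make_sequence_family()` derives sequence families by independent point
substitutions, giving expected pairwise identity
$(1-r)^2 + r^2/19$. `make_prediction_field()` plants high-probability
blobs (0.9 inside, 0.05 outside, clipped Gaussian noise) over given point
sets, so the grouping stage can be tested in isolation from the CNN.

These generators reproduce the *structure* of the learning problem —
sparse ligandable labels (a few percent of surface points), chains related
by rigid motions with shared and unique ligands, pockets of varying size
and shape — but not real protein geometry: there are no backbone atoms
beyond C$\alpha$, no rotamers, no real secondary structure, and the
pocket chemistry is deliberately easier to learn than in real structures.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and can recover planted signal end to end; they say nothing about
accuracy on real proteins, which depends on corpus-scale training.

# Problem sizes used in tests

The package's default protocol (40 epochs, 1024 clusters per epoch,
$n_c n_p = 512$) reflects corpus-scale training. The test-suite and
acceptance runs use the package's desk-scale mode: 8 chains of ~45
residues with one pocket each, dot surfaces at tessellation level 1
(~1000 points per chain), a narrow network (conv widths 2-4-4-8), 5
epochs of 64 clusters with $n_c = 2$, $n_p = 16$, and evaluation on a
subset of chains. These sizes were chosen so a complete run takes on the
order of a minute while every stage still operates on non-trivial input.

# Known limitations

* All-pairs alignment is quadratic in the number of chains; no k-mer
  prefilter is implemented (the intended scale is thousands of sequences,
  not millions).
* Ligand atom typing uses distance-based bond perception and
  planarity-checked ring detection; formal charges are recognized only for
  carboxylate/phosphate-like oxygens and quaternary nitrogens.
* Hydrogens are typed only when present in the input; most PDB files omit
  them, and then the H-donor channel is empty.
* mmCIF input, biological-assembly expansion and occupancy-weighted
  coordinates are out of scope.
* The CNN runs on CPU; it is sized for method validation, not for
  large-scale training.
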