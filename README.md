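# pocketscout

Predicting ligand binding sites on protein chains from structure.

Finding where small molecules can bind a protein — and not just the one
annotated site — matters for docking, off-target prediction, and
understanding side effects. pocketscout implements a complete workflow
for this problem:

1. **Clean**: parse PDB structures into per-chain entries; keep chains
   with ≥ 28 residues and ligands with ≥ 7 heavy atoms within 5 Å of a
   Cα atom (waters, ions and cryoprotectants drop out).
2. **Cluster**: all-pairs Smith–Waterman alignment; connect chains with
   similarity S > 0.8 and covering c > 0.9 on both sequences; clusters
   are connected components.
3. **Merge**: superpose similar chains (Kabsch on aligned Cα pairs,
   RMSD < 2 Å) onto a representative and pool their ligands, skipping
   clashes — so one chain carries all binding-site evidence from its
   redundant copies.
4. **Featurize**: solvent-accessible dot surface (icosahedral
   tessellation), 8-channel chemical property grids of shape 19×19×19
   around each surface point, occupancy field `1 − exp(−(r/d)^12)`;
   a point is *ligandable* if a ligand atom's occupancy there exceeds
   1e-4 (reached at ≈ 2.15 vdW radii).
5. **Score**: a 3D convolutional network (4 conv + 2 max-pool + 2 dense
   layers, batch norm, dropout, 2-class softmax) predicts per-point
   ligandability; training uses cluster-aware batches (nc clusters ×
   np points = 512 at full scale), 50/50 oversampling of the sparse
   ligandable class, a one-cycle learning-rate schedule, and nested
   cross-validation split at cluster granularity.
6. **Group & evaluate**: an adaptive-threshold algorithm clusters
   predicted points into binding sites accepted by empirical
   10th–90th percentile shape bounds; results are scored with DCC
   (center–center distance), DVO (point-set intersection over union) and
   per-chain classification metrics (sensitivity, specificity, precision,
   accuracy, balanced accuracy, F1, MCC) at thresholds 0.3/0.5/0.7/0.9.

Everything runs self-contained: synthetic generators produce toy protein
structures with planted pockets, sequence families with controlled
divergence, and prediction fields with planted blobs.

## Worked example

```r
library(pocketscout)

# a toy structure with one pocket and a 12-heavy-atom ligand
fx <- make_toy_protein(fixture_spec(seed = 42, n_residues = 45))
entry <- parse_structure(fx$pdb, "toy42")[[1]] |> filter_ligands()
entry
#> <chain_entry> toy42:A  45 aa, 87 atoms, 1 ligand(s)

feat <- featurize_chain(entry, tessellation_level = 1)
nrow(feat$points); mean(feat$points$ligandable)
#> [1] 1272
#> [1] 0.02358491

truth <- true_sites_table(feat$points, entry$ligands)
truth[, c("site_id", "size", "avg_dist", "std_dist")]
#>   site_id size avg_dist  std_dist
#> 1       1   30 3.149682 0.9347544
```

The 1272 surface points carry a sparse label: 2.4% are ligandable, all
in one site of 30 points whose mean point–center distance is 3.1 Å —
the three shape properties (point count, average center distance, and
its standard deviation) that later gate which predicted clusters count
as binding sites. A planted prediction field exercises the grouping
algorithm without the CNN (the percentile bounds would normally come
from `site_statistics()` over a whole dataset's true sites; here we
spread three jittered copies of the single known site):

```r
yp <- make_prediction_field(feat$points, truth$point_indices,
                            noise_sigma = 0, seed = 1)
stats <- site_statistics(dplyr::bind_rows(
  truth,
  dplyr::mutate(truth, size = size + 8, avg_dist = avg_dist * 1.3,
                std_dist = std_dist * 1.5),
  dplyr::mutate(truth, size = size - 6, avg_dist = avg_dist * 0.8,
                std_dist = std_dist * 0.7)
))
sites <- binding_sites(yp, feat$points, stats)
sites[, c("site_id", "size", "avg_dist", "std_dist")]
#>   site_id size avg_dist  std_dist
#> 1       1   30 3.149682 0.9347544
pair_sites(sites, truth, feat$points)[, c("true_id", "dcc", "dvo")]
#>   true_id dcc dvo
#> 1       1   0   1
```

With noise-free planted predictions the algorithm recovers the site
exactly: DCC 0 and DVO 1. `train_cnn()` / `predict_points()` replace the
planted field with learned predictions; see the vignette for the full
pipeline and the meaning of every parameter.

There is also a thin command-line interface (`exec/pocketscout`) with
subcommands `filter`, `cluster`, `merge`, `featurize`, `sites`,
`evaluate` and `fixtures`.

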