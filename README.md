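# commphylo

Community phylogenetics of dated regional floras: per-grid-cell
divergence-time and phylogenetic-structure statistics on a dated
(Ma-scaled, near-ultrametric) phylogeny, for biogeographers and community
ecologists who score county- or quadrat-level assemblages against a
regional mega-tree.

Given a Newick tree with branch lengths in Ma, a binary grid-cell ×
species presence–absence matrix, and a species→genus map, the package
computes per cell:

- **MDT**, the species-count-weighted mean genus divergence time,
  `MDT = Σ(AGEᵢ·Sᵢ) / ΣSᵢ`, where `AGEᵢ` is the crown age of genus *i*
  (stem age for monotypic genera) and `Sᵢ` its species count in the cell,
  plus the mean ages of the youngest and oldest genus quartiles;
- **PD**, Faith's phylogenetic diversity (root-inclusive branch-length
  sum), and the SR–PD relationship across cells;
- **MPD / MNTD**, mean pairwise and nearest-taxon patristic distances;
- standardized effect sizes against a richness-preserving pool-draw null
  (999 replicates by default): `SES = (obs − mean(null)) / sd(null)`,
  with `NRI = −SES(MPD)` and `NTI = −SES(MNTD)`; |SES| > 1.96 (strict) is
  significant at P < 0.05;
- a per-cell classification from the NRI/NTI sign pair
  (`habitat_filtering` when both are significantly positive,
  `competitive_exclusion` when both significantly negative).

A seeded synthetic-data module (Yule trees with genus structure; random,
filtering, overdispersion and age-gradient landscapes) makes the whole
pipeline testable end to end with no external data.

## Worked example

```r
library(commphylo)

tree <- simulate_yule_tree(200, seed = 1, depth = 100)   # dated 200-tip Yule tree
ls   <- simulate_landscape(tree, scenario_config("filtering", n_cells = 20,
                                                 strength = 1, seed = 2))
run  <- run_analysis(tree, ls$comm, ls$genus_map, n_reps = 999, seed = 1)
print(run)
```

```
Community-phylogenetics run: 20 cells, 66 genera, 999 null reps
  genus ages: mean 21.47 +/- 19.65 Ma, median 16.71 Ma
  SR-PD Pearson r = 0.776 (P = 5.77e-05)
  NRI/NTI sign-pair categories:
    both_positive          2
    nri_neg_nti_pos        1
    habitat_filtering      17
```

```r
head(run$cell_reports[, c("cell","SR","PD","SES_PD","MDT","SES_MDT",
                          "NRI","NTI","classification")], 4)
```

```
      cell SR    PD SES_PD   MDT SES_MDT   NRI   NTI    classification
1 cell_001 25 624.9 -5.844 16.36 -1.2114 9.227 3.648 habitat_filtering
2 cell_002 13 449.2 -3.924 22.18  0.1305 5.044 2.366 habitat_filtering
3 cell_003 13 329.8 -5.848 13.05 -0.9998 7.590 3.763 habitat_filtering
4 cell_004 20 513.6 -5.737 28.84  1.0894 6.802 4.244 habitat_filtering
```

Reading it: the landscape was assembled under environmental filtering, and
the pipeline recovers that — cells hold closely related species, so PD is
far below the random expectation at equal richness (SES-PD ≈ −5), both
NRI and NTI are strongly positive, and 17 of 20 cells are classified as
habitat filtering. `write_cell_reports(run$cell_reports, "cells.csv")`
writes the per-cell table; `write_run_summary(run, "summary.json")` the
aggregate tallies.

For real data, replace the simulated inputs with
`read_newick("tree.nwk")`, `read_community_matrix("matrix.csv")` (first
column cell id, header species names, entries 0/1/empty) and
`read_genus_map("genus_map.csv")` (`species,genus`); `validate_inputs()`
reports species missing from the tree, tree-only tips, cells emptied by
pruning and the tree's deviation from ultrametricity before you commit to
a run.

## The analysis workflow

Numbered drivers under `analysis/` reproduce the package's own study on
synthetic landscapes, writing tables under `results/`:

1. `01_simulate.R` — dated 200-tip tree + four 40-cell landscapes
   (random / filtering / overdispersion / age-gradient), written as
   `tree.nwk`, `matrix.csv`, `genus_map.csv`, `provenance.json`;
2. `02_run_pipeline.R` — the full per-cell analysis on each landscape
   (999 null replicates), per-cell CSVs and summary JSONs;
3. `03_divergence_times.R` — genus crown/stem ages, geological age-bin
   table, and recovery of the imposed MDT gradient;
4. `04_structure_summary.R` — SR–PD coupling and mean SES-PD / NRI / NTI
   per scenario, with the sign-pair classification table.

Run them in order from the repository root:
`Rscript analysis/01_simulate.R` etc.

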