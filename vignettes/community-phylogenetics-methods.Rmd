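---
title: "Methods: divergence times, phylogenetic diversity and community structure on dated trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence times, phylogenetic diversity and community structure on dated trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commphylo)
```

## The problem

Regional floras are usually summarized cell by cell: a province is divided
into grid cells (counties, quadrats), each holding a presence–absence list
of species, and every cell is scored against a dated phylogeny of the
regional species pool. Three families of questions are asked of each cell:

1. **How old is its flora?** — the mean divergence time (MDT) of the genera
   present, and whether the cell is significantly more ancient or more
   recent than a random draw from the regional genus pool (SES-MDT).
2. **How much evolutionary history does it hold?** — Faith's phylogenetic
   diversity (PD) and its standardized effect size at fixed richness
   (SES-PD).
3. **How are its species related to one another?** — mean pairwise distance
   (MPD) and mean nearest-taxon distance (MNTD), standardized into the net
   relatedness index (NRI) and nearest taxon index (NTI), whose sign pair
   classifies the cell as phylogenetically clustered (conventionally read
   as environmental/habitat filtering) or overdispersed (competitive
   exclusion / niche differentiation).

`commphylo` implements this per-cell pipeline end to end, together with a
seeded synthetic-data generator, so every stage can be exercised and
checked without any external dataset.

## Statistics

All times are in Ma (mega-annum); tips of a dated ultrametric tree sit at
age 0 and the root at age = tree depth.

**MDT.** For a cell containing genera $i = 1,\dots,n$ with divergence time
$AGE_i$ and $S_i$ species present,
$$\mathrm{MDT} = \frac{\sum_i AGE_i\, S_i}{\sum_i S_i}.$$
Genus divergence times are crown ages — the node age of the most recent
common ancestor (MRCA) of the genus's tips, which is also defined when a
genus is not monophyletic on the tree. A crown age does not exist for a
monotypic genus, so its age falls back to the stem (the parent node of its
single tip) and the genus is flagged. Alongside MDT, the unweighted mean
ages of the youngest and oldest genus quartiles (the $\lceil n/4 \rceil$
youngest/oldest genera, age ties broken by genus name) are reported; cells
with fewer than 4 genera get the overall mean, flagged.

**PD.** Faith's PD is the sum of branch lengths over the union of edges
connecting the cell's species to the root (root-inclusive convention, the
default of the classic toolchain for this analysis). This makes
single-species PD well defined (its root path) and PD of the full pool
equal to the total branch length.

**MPD / MNTD.** With patristic distances $d(i,j)$ (path length between
tips; $2\times$ MRCA age on an ultrametric tree), MPD is the mean of
$d(i,j)$ over unordered pairs in the cell and MNTD the mean over species of
the distance to their nearest co-occurring relative. Both are
presence–absence (unweighted) forms, matching a binary input matrix. These
metrics are sometimes loosely described as "cumulative sums"; the mean is
what their definitions and their use inside NRI/NTI require, and at fixed
richness the sum/mean distinction cancels in the SES anyway.

**SES and the null model.** Every standardized effect size uses one null
scheme: richness-preserving uniform draws, without replacement, from the
regional pool — species for PD/MPD/MNTD, genera for MDT (with the cell's
observed multiset of $S_i$ values reassigned to the drawn genera in draw
order, preserving the weighting structure). With 999 replicates by default,
$$\mathrm{SES} = \frac{x_{\mathrm{obs}} - \overline{x_{\mathrm{null}}}}
{\mathrm{s.d.}(x_{\mathrm{null}})},\qquad
\mathrm{NRI} = -\mathrm{SES}(\mathrm{MPD}),\quad
\mathrm{NTI} = -\mathrm{SES}(\mathrm{MNTD}),$$
with the sample ($n-1$) standard deviation. Significance is two-sided and
strict: $|\mathrm{SES}| > 1.96$ ($P < 0.05$); a value of exactly 1.96 is
not significant. A rank-based $P = (r+1)/(n_{\mathrm{reps}}+1)$ is reported
alongside but never used for classification. For SES-MDT the null is built
at genus level because genera, not species, carry the ages; for SES-PD,
NRI and NTI it is built at species level. NRI and NTI for one cell reuse
the same sequence of null assemblages, so NRI = NTI holds exactly for
two-species cells (where MPD = MNTD).

## Numerical and design choices

- **Pool-order invariance.** The pool is sorted before drawing, so SES
  values do not depend on the order in which taxa happen to be listed.
- **Reproducibility.** One master seed spawns a deterministic substream per
  (cell, metric) via a string hash, so per-cell results are independent of
  processing order: removing a cell changes only that cell's report, and
  identical seeds give byte-identical output CSVs.
- **Degenerate nulls.** When the null has (numerically) zero variance —
  e.g. a cell equal to the whole pool — the SES is flagged undefined
  (`NA`) rather than ±∞, is never significant, and does not interrupt the
  pipeline. The zero test is relative (s.d. ≤ 1e-9 × max(1, |mean|))
  because floating-point summation order makes a mathematically constant
  statistic vary at the 1e-13 level across draws.
- **Near-ultrametric trees.** Mega-tree-derived dated trees are typically
  ultrametric only to rounding. Tip-depth spread beyond a relative 1e-6
  triggers a warning, not an error; node ages are measured from the
  maximum tip depth so they stay consistent with branch lengths.
- **Classification boundaries.** The NRI/NTI sign pair determines the
  category, with an exact zero counted as positive (the statistics are
  continuous, so ties have probability ~0). The labels `habitat_filtering`
  and `competitive_exclusion` require *both* indices significant in the
  same direction; otherwise the plain sign-pair category is reported.
- **Age bins.** Genus-age summaries use half-open, lower-inclusive bins
  `[0, 23.03), [23.03, 66), [66, 145), [145, ∞)` Ma by default (Neogene /
  Paleogene / Cretaceous / older); an age exactly on an edge belongs to the
  older bin. Edges are user-configurable because epoch phrasings such as
  "less than 23.03 Ma" leave the boundary side ambiguous.
- **Species missing from the tree** are dropped with a warning and recorded
  in the validation report — the routine situation in mega-tree workflows —
  rather than raising an error; SR is counted over tree-matched species
  only, so SR and PD always describe the same assemblage. Genus ages are
  computed on the tree restricted to the analysed species, so tips that
  never occur in the matrix need no genus assignment.

## What the synthetic data emulate

`simulate_yule_tree()` draws a pure-birth (Yule) topology with exponential
waiting times, rescaled to a chosen root age with all tips at 0 Ma, and
partitions the ladderized tip order into contiguous blocks of 1–5 tips per
genus. This mirrors a real flora's mix of small and monotypic genera (a
regional flora of ~5000 species typically spans >1000 genera, ~4–5 species
per genus); blocks are usually clades but occasionally straddle one, which
deliberately exercises the MRCA path for non-monophyletic genera. Yule
rather than birth–death was chosen because the pipeline needs known,
calibrated structure, not macroevolutionary realism.

`simulate_landscape()` assembles each cell at a richness drawn uniformly
from a configured range (defaults: 40 cells, richness 5–25 on a 200-tip
tree — the grid-cell scale of county-level floristic studies, with cells
holding a few percent to ~10% of the pool):

- **random** — uniform sampling; the behaviour of every other scenario at
  `strength = 0`.
- **filtering** — a seed species, then neighbours weighted
  $\exp(-d(i,\mathrm{seed})\cdot\mathrm{strength}\cdot\kappa)$ with
  $\kappa = 5/\text{tree depth}$, giving clade-restricted cells. Tying
  $\kappa$ to tree depth makes `strength` dimensionless and comparable
  across trees.
- **overdispersion** — greedy max-min-distance selection, each step taken
  greedily with probability `strength` (else uniform), spacing cells out.
- **age_gradient** — species weighted through their genus age,
  $\exp(\gamma\, AGE\,\kappa)$, with $\gamma$ sweeping linearly from
  $-\mathrm{strength}$ to $+\mathrm{strength}$ across the cell index. The
  same $\kappa$ normalization is applied here because a raw $\exp(AGE)$
  with ages in Ma overflows for old clades and would make every cell
  degenerate on the oldest genus.

What these landscapes do **not** emulate: spatial autocorrelation between
cells, environmental covariates, abundance structure, sampling error in
the occurrence records, or dating uncertainty in the tree. Passing tests on
them therefore demonstrates that the statistics and null models behave
correctly — calibrated under the null, directionally right under known
regimes — not that any particular empirical flora will show those regimes.

## Problem sizes used in tests and the acceptance script

Exact-agreement checks run on a 4-tip worked fixture and 1,000 random
subsets of a 50-tip tree; Monte-Carlo vs exhaustive-enumeration checks use
a 6-tip tree at 99,999 replicates (tolerance 0.05); null calibration uses
1,000 cells at 199 replicates (mean within ±0.1 of 0, s.d. within ±0.15 of
1, 3–7% of cells flagged); scenario recovery uses 100-cell landscapes on a
200-tip tree at 199 replicates. The analysis scripts under `analysis/` use
the full 999 replicates on 40-cell landscapes. These sizes were chosen so
the whole suite completes in minutes while keeping Monte-Carlo error well
inside each test's tolerance.

## A worked example

```{r example, eval = FALSE}
tree <- simulate_yule_tree(200, seed = 1, depth = 100)
ls <- simulate_landscape(tree, scenario_config("filtering", n_cells = 40,
                                               strength = 1, seed = 2))
run <- run_analysis(tree, ls$comm, ls$genus_map, n_reps = 999, seed = 1)
print(run)
head(run$cell_reports)
write_cell_reports(run$cell_reports, "cells.csv")
```

## Known limitations

- Only the pool-draw null is provided (no independent/trial swap, no
  frequency-weighted schemes); for binary matrices it equals taxa-label
  shuffling in expectation, but null choice can matter for strongly
  structured occupancy.
- Genus ages come from the input tree; no divergence-time estimation is
  performed.
- Whether the reference workflow's SES-MDT nulls preserved the $S_i$
  weights is not documented anywhere we could find; reassigning the
  observed multiset is this package's recorded choice, and the auxiliary
  quartile SES values are reported precisely because the null can be read
  either way.
- The CSV dialect is deliberately rigid (UTF-8, comma, no quoting) to keep
  round trips bit-exact; names containing commas are rejected.
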