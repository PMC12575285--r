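# karstpatch

Patch-scale biodiversity analysis for fragmented karst soils.

In rocky-desertified karst terrain, soil persists as discrete patches set
in exposed limestone. During vegetation recovery on abandoned farmland,
the geometry of those patches and the soil resources they hold structure
the herbaceous communities that reassemble on them. `karstpatch`
implements the patch-scale analysis pipeline for this setting:

- **Patch delineation and geometry.** A plot is surveyed as a regular grid
  of soil-depth points (by default 26 × 26 points at 0.39 m spacing over a
  10 m × 10 m plot; depth 0 = rock). Soil cells are partitioned into
  maximal connected components (4- or 8-adjacency), and each patch gets an
  area *PA* = n·s² (m²), an exposed-edge perimeter *PM* (m), and a
  perimeter–area fractal dimension
  *PFD* = 2·ln(*PM*/4)/ln(*PA*), which is exactly 1 for squares and grows
  with boundary complexity.
- **Soil resources.** Per-patch *availability* (mean) and *heterogeneity*
  (CV = SD/mean) of soil depth, water content, total C, total N and C:N
  from quadrat samples, with the standard variability classes
  weak (≤ 0.15), moderate, strong (≥ 0.36).
- **Taxonomic diversity.** Richness *R*, Shannon–Wiener
  *H′* = −Σ pᵢ log₂ pᵢ, and Pielou evenness *E* = *H′*/ln *S* (the
  mixed-base form used in the field literature, which can exceed 1; a
  consistent-base variant is a flag).
- **Phylogenetic diversity and structure.** Faith's *PD* (branch-length
  sum of the minimal subtree spanning a community, rooted convention),
  mean pairwise distance (MPD) and mean nearest-taxon distance (MNTD) on
  the cophenetic matrix, and the standardized effect sizes
  *NRI* = −(MPD_obs − mean MPD_null)/SD(MPD_null) and the analogous *NTI*
  under a seeded tip-shuffle null (999 permutations by default).
  Both positive → phylogenetic clustering (environmental filtering); both
  negative → overdispersion; mixed → random assembly.
- **Association report.** Per-patch table joining all of the above,
  min/max/mean/SD/CV summary rows, Pearson correlation matrices, and
  OLS fits of diversity against log₁₀ patch area.
- **Synthetic data.** Seeded generators for phylogenies, clumped rock/soil
  grids, quadrat samples and communities under random, filtered
  (clustering) or overdispersed assembly, so the whole pipeline is
  testable without field data.

## Worked example

```r
library(karstpatch)

cfg <- synth_config(seed = 42)        # 26 x 26 grid, 0.39 m cells
sim <- simulate_dataset(cfg)          # tree, grid, patches, samples, comm
sim$patch_map
#> <patch_map> 26 x 26 cells, 5 patch(es)

round(sim$patches[, c("patch_id", "n_cells", "PA_m2", "PM_m", "PFD")], 2)
#>   patch_id n_cells PA_m2   PM_m  PFD
#> 1        1     397 60.38 123.24 1.67
#> 2        2       2  0.30   2.34 0.90
#> 3        3       3  0.46   3.12 0.63
#> 4        4       1  0.15   1.56 1.00
#> 5        5       3  0.46   3.12 0.63

rep <- build_report(sim$grid, sim$samples, sim$comm, sim$tree,
                    n_perm = 999, seed = 42)
round(rep$table[, c("PA_m2", "R", "H", "E", "PD", "NRI", "NTI")], 2)
#>   PA_m2  R    H    E     PD   NRI   NTI
#> 1 60.38 27 4.20 1.28 462.37 -0.75  0.05
#> 2  0.30  7 1.99 1.02 258.04  0.59 -0.42
#> 3  0.46  5 2.19 1.36 236.84 -0.03 -0.19
#> 4  0.15  7 2.10 1.08 180.32  1.93  0.99
#> 5  0.46  6 2.26 1.26 148.04  1.92  1.68
```

One cell is 0.39 m × 0.39 m = 0.15 m², so the single-cell patch 4 has the
minimum area; being square, its PFD is exactly 1. Richness rises with
patch area — the largest patch carries 27 of the 98 pool species and the
highest *H′* and *PD* — and the fitted species–area regression on this run
prints

```r
rep$fits[rep$fits$metric == "R", ]
#> richness ~ log10(PA): slope 8.65, R2 0.93, p 0.00757
```

i.e. about 8.7 extra species per decade of patch area, close to the
generator's configured slope of 8. NRI/NTI are z-scores against the
tip-shuffle null: patches 4 and 5 lean clustered (both indices positive),
patch 3 leans dispersed, none individually significant at |z| ≥ 1.96.

A command-line front end is installed as `exec/karstpatch` with
subcommands `simulate`, `delineate`, `phylostructure` and `report`, e.g.

```sh
Rscript exec/karstpatch simulate --out runs/demo --seed 7
Rscript exec/karstpatch report --grid runs/demo/grid.csv \
    --samples runs/demo/samples.csv --communities runs/demo/communities.csv \
    --tree runs/demo/tree.nwk --seed 7 --out runs/demo/report
```

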