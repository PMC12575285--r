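---
title: "Patch-scale biodiversity analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-scale biodiversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karstpatch)
```

## The setting and the model

Karst rocky desertification leaves soil as an archipelago of patches in
exposed bedrock. At the plot scale the analysis treats each soil patch as
an island whose geometry and soil resources shape the plant community
assembling on it. The pipeline has four stages, each a module with an
explicit contract:

1. **Delineation.** A plot is a raster of soil-depth measurements on a
   regular grid (default 26 × 26 points, 0.39 m apart, so one cell covers
   0.39² ≈ 0.15 m²; depth 0 encodes rock). Patches are maximal connected
   components of soil cells. The default adjacency is 4-connectivity:
   patches drawn on grid cells touch either along an edge or only at a
   corner, and edge contact is the conservative continuity criterion —
   corner-touching regions may merely *appear* connected in plan view
   where a narrow rock sill separates them. 8-connectivity is available
   as a flag for users who prefer the permissive rule.

2. **Geometry.** Per patch: area `PA = n_cells * s^2`; perimeter `PM` as
   the count of cell edges facing rock or the plot boundary times `s`
   (the raster convention — no smoothed outlines, see *Limitations*); and
   the perimeter–area fractal dimension `PFD = 2 ln(PM/4) / ln(PA)`.
   Algebraically every square patch gives exactly 1, and elongated or
   ragged boundaries push PFD up; the formula is singular at `PA = 1` m²
   where `ln PA = 0`, and the package returns `NaN` with a warning there
   rather than a fabricated value.

3. **Resources.** Availability is the per-patch arithmetic mean and
   heterogeneity the per-patch CV = SD/mean of soil depth (Sd), water
   content (SWC), total carbon (TC), total nitrogen (TN) and the
   per-record C:N ratio. Depth statistics use only records with Sd > 0,
   since depth is only measurable where soil exists. CVs are classified
   weak/moderate/strong; the conventional printed limits (≤ 15 %,
   16–35 %, ≥ 36 %) leave the open intervals (0.15, 0.16) and
   (0.35, 0.36) unassigned, which we resolve by closing the classes on
   the printed endpoints: weak ≤ 0.15 < moderate < 0.36 ≤ strong. C:N is
   computed per record and then averaged, not as a ratio of means; for
   the near-constant N typical of these soils the two differ by less
   than sampling noise, and the per-record form keeps C:N a bona fide
   quadrat variable with its own CV.

4. **Diversity and phylogenetic structure.** Richness R, Shannon–Wiener
   `H' = -Σ p_i log2 p_i` (bits), and Pielou evenness `E = H'/ln S`.
   The evenness deliberately mixes bases — H′ in log₂, the denominator in
   ln — because that is the form in use in the field tables this package
   mirrors: uniform communities then score `1/ln 2 ≈ 1.443`, which is the
   only way the published evenness range can exceed 1. Whether the
   original intent was natural logs throughout is undecidable from the
   printed record, so the mixed form is the default and
   `consistent_base = TRUE` gives the textbook E ≤ 1. Faith's PD is the
   branch-length sum of the minimal subtree connecting the community's
   species; the default includes the connection to the root (the classic
   convention, making single-species PD the root-to-tip distance), with
   `rooted = FALSE` spanning only the taxa. MPD and MNTD are
   presence-based (unweighted): the indices average over *species*, not
   individuals, and abundance weighting is out of scope.

### The null model and SES

NRI and NTI are sign-flipped standardized effect sizes,
`-(obs - mean_null)/sd_null`, of MPD and MNTD against a tip-shuffle null:
tip labels are permuted uniformly, which for a fixed community of size k
is equivalent to scoring a uniform random k-subset of tips — that is how
the replicates are drawn. 999 permutations is the default; the seed is a
required argument everywhere randomness enters. Community richness is
held fixed by construction; richness-constrained swap algorithms are not
implemented. Because the null depends only on k, `phylo_structure()`
computes one null per distinct richness value and shares it across
patches — identical output to per-patch nulls at a fraction of the cost.

Numerical choices: the null SD uses the sample (n − 1) estimator by
default (`population_sd` switches it); when the null SD falls below
1e−12 — e.g. a community containing every tip, or an equidistant star
tree — the SES is `NaN` with a warning rather than ±∞. Patches with
fewer than two species propagate `NaN` through E, MPD, MNTD, NRI and
NTI; summaries skip non-finite values and report how many they skipped.

An exhaustive-enumeration oracle (`exhaustive_null`) scores every
k-subset when `choose(n, k) ≤ 1e6` and returns exact moments. One
subtlety worth recording: the oracle's `sd` is the sample SD *over the
enumerated subsets*, while a permutation estimate converges to the SD of
the null distribution itself (the n-denominator form, returned as
`pop_sd`). For 6 subsets those differ by 9 %, far beyond Monte-Carlo
error at 5,000 replicates, so the oracle-equivalence tests compare the
shuffle moments against `pop_sd`.

Interpretation follows the usual sign rule — both indices positive:
clustering, consistent with environmental filtering; both negative:
overdispersion, consistent with competitive exclusion or niche
differentiation; mixed: random assembly — with a companion flag marking
|z| < 1.96 as not individually significant.

## What the synthetic generator emulates

The generator's defaults are the stated world of the sampling design it
stands in for, fixed once and not tuned:

| parameter | default | why |
|---|---|---|
| grid | 26 × 26, 0.39 m cells | the survey protocol (676 depth points per 10 m × 10 m plot) |
| depth | lognormal, mean 24.27 cm, CV 0.53 | reported availability and (strong) heterogeneity magnitudes |
| SWC | lognormal, mean 17.17 %, CV 0.37 | ditto |
| TC | lognormal, mean 1.82 g/kg, CV 0.18 | ditto (moderate) |
| TN | lognormal, mean 0.23 g/kg, CV 0.14 | ditto (weak) |
| species pool | 98 | the census size of the emulated flora |
| richness model | E[R] = 10 + 8·log10(PA) | slope from the recovery criterion; intercept set so R spans ≈ 3–41 over the patch-area spectrum 0.15–67 m² |
| rock fraction / clumping | 0.4 / 2 | fragmented multi-patch plots with half the patches under 10 m² |
| quadrats per patch | 4 | sampling intensity per patch is not standardized in the field design, so it is a free parameter |

Design of the generators:

- **Rock placement** thresholds box-smoothed uniform noise at the
  empirical `rock_fraction` quantile — the simplest mechanism with a
  tunable patch-size spectrum. The quantile threshold makes the realized
  rock fraction exact up to discretization, and smoothing radius
  (`clumping`) > 0 aggregates rock into fewer, larger outcrops.
  Geostatistical simulation was deliberately avoided.
- **Depths and resources** are lognormal, parameterized by arithmetic
  mean and CV — positive and right-skewed, as soil variables are.
  Records are i.i.d. within and between patches, so between-patch
  differences in realized means are pure quadrat-sampling noise; the
  generator does not couple resources to patch size (see *Limitations*).
- **Communities**: richness is Poisson about the log-linear area model,
  clipped to [1, n_taxa] with a warning when the linear model leaves the
  range. Under `filtered` assembly, species are drawn with weights
  `exp(-filter_strength · d / mean(d))`, d the cophenetic distance to a
  random focal tip — a minimal clade-filter model (no generative model is
  prescribed by the field analysis). The distance is normalized by the
  tree's mean pairwise distance so `filter_strength ≈ 1` means "one
  e-fold of weight per average distance" on any branch-length scale.
  `overdispersed` uses greedy maximin spacing. Abundances are
  1 + negative binomial (mu 4, size 0.8), a right-skewed rank-abundance
  shape. The simulated tree is a coalescent rescaled to root depth 100 so
  PD magnitudes resemble dated phylogenies; nothing downstream depends on
  the scale.

A green test on synthetic data establishes that the *pipeline* measures
what the generators put in (slope recovery, assembly-mode ordering, null
centering). It does not establish anything about real karst floras: the
generator has no spatial dispersal, no resource–area coupling, no
abundance structure tied to phylogeny, and no P/K or microbial variables.

## Association stage

Pearson correlations are pairwise-complete with two-sided p-values;
unadjusted p-values are the primary output (matching common field
practice), with a Holm-adjusted matrix added and labelled as an
extension. Diversity–area fits are OLS of the metric on `log10(PA)` —
the log form chosen because richness–area relationships are canonically
log-linear and the generator's richness model is written on that scale.
Random-forest importance, mixed-effects models and variance partitioning
are intentionally *not* reimplemented: they are off-the-shelf analyses a
user can run on the emitted `patch_table.csv` with `randomForest`,
`lme4` and `vegan` directly.

## Known limitations and open points

- The printed minimum patch perimeter in the emulated survey (1.54 m) is
  inconsistent with the exposed-edge rule at 0.39 m cells (4 × 0.39 =
  1.56 m); 26 points across 10 m also admits spacings of ~0.38–0.40 m.
  The package states its convention (raster edges, 0.39 m) and does not
  silently reconcile the 2 cm difference.
- Whether published PD values used the rooted or unrooted convention is
  unverifiable without the deposited tree; both are provided, rooted is
  the default.
- Field CVs may have been computed per patch or per plot; the package
  computes them per patch, as the availability/heterogeneity definitions
  imply.
- Perimeters follow raster cell edges; vectorized (smoothed polygon)
  boundaries are out of scope.
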