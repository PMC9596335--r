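---
title: "Methods: change accounting, the threat-based habitat model, and the synthetic landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: change accounting, the threat-based habitat model, and the synthetic landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habiq)
```

This vignette documents the modeling choices behind `habiq`: what the
pipeline computes, which parameters matter, how the synthetic-landscape
generator works, and where the design was genuinely open and a decision had
to be made. Everything empirical shown here is computed by the code at
build/test time; nothing is transcribed from elsewhere except the published
parameter tables and transfer matrix that ship as CSV fixtures.

## Grid model and formats

All layers live on one regular planar lattice: row-major matrices, origin at
the top-left corner, row index increasing southward, square cells whose side
is given in km (1 km² = 100 hm²). Distances between cells are Euclidean
distances between **cell centers**, in km; nothing finer than the cell size
is modeled, which matches the 1-km resolution of the land-cover products the
workflow targets. The grids are treated as abstract lattices — no map
projection or CRS handling is attempted, and region boundaries enter only as
rasterized masks.

Raster IO uses the ESRI ASCII grid format (header coordinates in metres,
converted to km internally). It is plain text, lossless for integer-coded
and floating-point layers alike, diffable, and needs no binary geospatial
stack; every intermediate surface the pipeline persists can be inspected
with a pager. Categorical grids carry an integer nodata sentinel (default
−9999); continuous grids use NA. Nodata cells are excluded from every
statistic, emit no threat, and receive no model value.

The land-cover classification is the 14-code Chinese remote-sensing
monitoring scheme (arable 1; woodlands 21–24; grassland 3; waters 41, 43,
45, 46; construction 51–53; unused 6), aggregated onto six classes for
change accounting. `class_scheme()` holds the mapping; `reclassify()`
applies it, preserving nodata and cell counts.

## Change accounting

`cross_tabulate()` produces the transfer matrix of a date pair: joint cell
counts scaled to hm². Two conventions matter:

* **Areas are stored in hm²** (the unit of the published matrices); km²
  appears only in presentation columns. This avoids repeated unit drift.
* **Cells nodata at either date are excluded entirely**, rather than being
  counted as change, so row and column marginals are class areas over the
  common valid extent and the grand total is identical for every period
  over the same mask.

`flow_shares()` reports each off-diagonal entry as a percentage of the
destination's inflow (column total minus diagonal) and of the source's
outflow. Destinations with zero inflow get NA shares, not zeros — a diagonal
matrix has no transfers to apportion. Percentages are presented with
half-away-from-zero rounding to two decimals (`round_half_up()`), matching
how such tables are usually printed; base `round()` would round half to
even.

The published five-block transfer matrix ships verbatim as
`inst/extdata/landuse_transfer_matrix.csv`, including its small internal
inconsistencies (grand totals that disagree by 100–200 hm² across blocks —
`area_series()` warns about this — and one `0l` typo transcribed as 0).
Every statistic derived from it is recomputed from the CSV at run time.

## The threat-based habitat model

Degradation of cell $x$ with land-use class $j$ is

$$D_x = \sum_r \frac{\omega_r}{\sum_r \omega_r}\Big[\sum_y r_y\, i_r(d_{xy})\Big]\,\beta_x\, S_{jr}$$

and quality applies a half-saturation transform of the class's intrinsic
suitability $H_j$:

$$Q_x = H_j\left(1 - \frac{D_x^z}{D_x^z + k^z}\right).$$

The shipped parameterization (CSV fixtures `threats.csv`,
`sensitivity.csv`) covers five stressors — arable land (8 km, weight 0.8,
exponential), reservoir (3 km, 0.5, exponential), urban land (6 km, 0.75,
exponential), rural settlements (10 km, 1.0, exponential) and other
construction land (1 km, 0.4, linear) — and per-code suitability and
sensitivity values. Only woodland codes (21–24) and canals (41) have
H > 0; the table as published gives canals full suitability with nonzero
sensitivities while reservoir ponds get 0, and it is used as printed.

Decisions in the implementation:

* **Threat sources by code.** The stressors are named, not coded, in the
  source tables; the unique name correspondence fixes arable → 1,
  reservoir → 43, urban → 51, rural settlements → 52, other construction
  → 53.
* **Binary presence.** Each threat has its own source layer, so the
  per-cell source term $r_y$ is presence/absence, and all threats are
  measured on the same presence scale.
* **Truncation at the maximum effective distance.** The linear kernel
  reaches 0 at $d_{rmax}$ by construction; the exponential kernel is
  truncated to 0 *beyond* $d_{rmax}$ (it still equals
  $e^{-2.99}\approx 0.0503$ at exactly $d_{rmax}$). The 2.99 rate makes the
  kernel decay to ~5% of its peak at the maximum distance.
* **Weight normalization.** Raw weights are normalized to sum to 1, so
  scaling all weights by a common factor leaves D unchanged (tested).
* **Accessibility** $\beta_x$ defaults to 1 everywhere; no accessibility
  layer is part of the shipped parameterization, but any [0,1] surface can
  be supplied.
* **Edges.** Sources outside the raster are assumed absent, so edge cells
  see fewer potential sources. This edge effect is inherent to finite
  rasters and is shared by the brute-force oracle, so it does not affect
  the equivalence tests.
* **Computation.** Each threat's presence grid is correlated with a
  precomputed decay stencil (side $2\lceil d_{rmax}/\text{cell}\rceil+1$,
  center 1) by shift-and-accumulate; the result equals the literal
  quadruple-loop evaluation to ~1e-15 on random landscapes (tested to
  1e-9).

**k and z are not fixed by the workflow's sources**: the model family's
published defaults, z = 2.5 and k = 0.5, are used, with
`k_mode = "half_of_max_D"` available because the model's reference
implementations recommend setting k to half the maximum observed D when
degradation scores are small. Both are plain config parameters, and every
invariant the tests rely on (0 ≤ Q ≤ H, Q strictly decreasing in D,
Q(D=k) = H/2) holds for any k, z > 0.

Degradation is reported on its raw model scale. Published studies are
ambiguous about the scale of degradation summaries (maxima differing by
~45× between tables for the same statistic suggest an unnormalized run);
`rescale01()` offers min–max normalization for cross-study comparison, but
no attempt is made to match any particular printed degradation table.

## Classification and zonal statistics

The quality bands default to the fixed printed thresholds 0.2 / 0.5 / 0.7.
The upper band is read as 0.7–1.0 (its printed upper bound, "0.1", is an
obvious typo: the band must reach the top of quality's range). Binning is
half-open upward-inclusive — [0, 0.2), [0.2, 0.5), [0.5, 0.7), [0.7, 1] — so
a value exactly on a threshold joins the upper band; the overlapping
interval notation used in print forces some convention, and this one keeps
`findInterval()` semantics.

Natural-breaks classification is available as an alternative:
`jenks_breaks()` implements Fisher's exact dynamic program for the optimal
1-D partition (minimal within-class sum of squares). The DP is
$O(kn^2)$, so for samples beyond `sample_max` (default 5000) it runs on a
deterministic systematic subsample of the sorted values; tests compare the
DP against exhaustive enumeration of all partitions for n ≤ 25. The
returned thresholds are the smallest value of each upper class, so the
upward-inclusive binning above reproduces the optimal partition exactly.

Zonal statistics (min, max, mean, sd per mask) use the **population**
standard deviation (÷N) by default, matching common GIS zonal tools, with a
flag for the sample convention. Statistics run over all non-nodata cells of
a mask; restricting to habitat cells (H > 0) is done by intersecting masks.
Empty zones yield NA rows with a warning, never silent zeros.

## Synthetic landscapes

The generator exists so that every pipeline stage can be exercised, at any
size, from a seed — real 1-km land-cover products for the study region are
licensed data and are not required anywhere in the package.

* **Initial maps** threshold a Gaussian random field (smoothed with a
  Gaussian kernel of sd `patch_scale` cells) at the cumulative quantiles of
  the target class proportions. Rank-based thresholding realizes the
  composition to within rounding; `patch_scale = 0` gives spatially
  independent cells (join-count statistics match the random-permutation
  expectation, tested), and clumping grows with `patch_scale`. The default
  composition mirrors the study region: woodland ≈ 69.5%, arable ≈ 21.2%,
  the rest split among grassland, water, construction and unused.
* **Evolution** draws each cell's next class independently from the row of
  a transition model — typically the row-normalized published transfer
  matrix via `matrix_to_probs()`. An optional clustering factor reallocates
  *which* cells convert (preferring cells adjacent to the destination
  class) while keeping the per-class conversion counts, so spatial
  contagion can be emulated without biasing the transition frequencies.
* **Detailed codes** are sampled per aggregate class (uniform by default,
  or per-class `sub_props`), so threat placement and per-code suitability
  lookups are exercised.

What the generator does **not** emulate: the real region's geography,
suitability-driven allocation of change, or temporal autocorrelation beyond
the first-order Markov structure. Passing tests on synthetic landscapes
therefore validate the *accounting and model arithmetic*, not any claim
about the real landscape.

Two statistical conventions in the recovery tests are worth stating.
Empirical transition frequencies are compared to the generating
probabilities within three binomial standard errors **plus a one-count
continuity allowance** ($1/n_i$): several true probabilities are of order
$10^{-4}$, where the discrete count spectrum makes the plain 3σ band
narrower than one observable count. And the directional experiment — mean
quality falling, mean degradation rising, as construction cover moves
through a dip-then-grow 5-date trajectory (1.6–2.7% of the landscape) —
holds everything else fixed: same seed (hence same underlying field) across
dates, woodland compensating the construction change, and one detailed code
per aggregate class, so the comparison isolates the construction effect
instead of drowning a few-cell signal in resampling noise from the
subclass split.

## Problem sizes and numerical choices

The test suite and the acceptance script run, deliberately, at desk scale:
oracle equivalence on 30×30 landscapes (the brute force is quadratic in
cell count), parameter recovery on one 200×200 landscape (40,000 cells put
3σ bands of a fraction of a percent on the common transitions), and
directional experiments on 60×60 grids. These sizes were chosen so the
full suite completes in seconds while every check retains power; the
implementation itself handles larger grids (the kernel correlation is
linear in cells × stencil size).

Tie-breaking and degenerate inputs: field thresholding jitters values by
1e-9 to break rank ties deterministically under the seed; a constant sample
has no valid 2-class partition and `jenks_breaks()` errors; an identically
zero degradation surface under `half_of_max_D` has no meaningful k and
quality collapses to the suitability map; single-cell zones report sd 0.

## Known limitations

* Planar lattices only: no CRS, no reprojection, no vector boundaries.
* ESRI ASCII is the only raster format; anything else should be converted
  on the way in.
* The degradation scale question above means absolute degradation values
  are comparable within a run, not across differently parameterized
  studies.
* The published transfer matrices are used as printed; their internal
  inconsistencies (marginals vs narrative percentages elsewhere) are
  surfaced, not reconciled.
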