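---
title: "Blastomere morphometrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blastomere morphometrics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the geometric and
statistical models, the tunable parameters and why their defaults are what
they are, what the synthetic generator does and does not emulate, and the
design choices made where the problem was genuinely open. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The scientific problem

In cleavage-stage embryos, blastomere position — inside versus outside —
drives the first lineage decision through YAP: cells with substantial
surface exposed to the embryo exterior accumulate YAP in the nucleus, cells
enclosed by neighbours do not. Quantifying that link requires, per cell, a
partition of the limiting membrane into **exposed** (apical), **contact**
(basolateral) and **junctional** domains, a panel of shape and position
descriptors, and compartmental intensity ratios (nuclear/cytoplasmic YAP,
apical/basolateral pERM), followed by unsupervised analyses: a high/low YAP
threshold, hierarchical clustering into inside-like / outside-like /
undefined states, correlation matrices and group tests.

## Volumes and coordinates

Volumes are R arrays with `dim = (nz, ny, nx)`; the first index is the
optical axis. Voxel spacing is given `(z, y, x)` in µm, voxel indices are
0-based in the physical convention: voxel `(i, j, k)` (1-based in R) has its
centre at `((i-1)·sz, (j-1)·sy, (k-1)·sx)`. All thresholds and areas are in
µm. TIFF stacks store page *k* as z-slice *k*; a sidecar JSON records axis
order, spacing and the integer scale, and a minimal raw-encoded NRRD
reader/writer is provided for interoperability.

## Surface extraction

Each cell's binary mask is smoothed with a separable Gaussian
(`smooth_sigma`, default **0.8 voxels**) and triangulated at the 0.5
iso-level by marching tetrahedra (six tetrahedra per grid cube sharing the
main diagonal, so faces are crack-free across cubes). Raw voxel-face area
overestimates smooth surfaces — by roughly 1.5× for a sphere — which is why
the mesh route exists and the voxel-face route is kept only as a test
oracle. The smoothing width was calibrated once against analytic phantoms:
digital spheres of radius 6–20 voxels reproduce 4πR² within ±2.3%, and a
split cube (the worst case: sharp edges that smoothing rounds off) is
within ~4–5% at edge length 40. Larger σ rounds edges too aggressively;
smaller σ lets the staircase bias through. Cells under 8 voxels are flagged
and skipped.

## Domain classification

A mesh face of cell *i* is **contact** when the estimated gap between it and
the nearest surface of a different cell is at most δ (`domain_params`,
default **δ = 1 µm** — one z-step at typical 1 µm confocal sampling; the
proximity rule's numeric value is not published for the original in-house
implementation, so it is an exposed knob). The gap is the exact Euclidean
distance transform of the other cells' voxels (Felzenszwalb's separable
algorithm, anisotropy-aware), sampled trilinearly at the face centroid,
minus half a voxel for the centre-to-surface offset, clamped at zero.
Remaining faces are **exposed**. With band half-width *w* (default
**1 µm**), any face within *w* of a face of the opposite class is
relabelled **junctional**, so the band girdles the exposed/contact rim.
Because the gap function is 1-Lipschitz in position, only faces with gaps in
`[δ−w, δ+w]` can be relabelled; the implementation restricts the search to
that rim, which is an exact optimisation, not an approximation. The three
domains partition one set of faces, so their areas sum to the total area
exactly, by construction.

Per-cell EDTs run on the cell's bounding box plus a margin covering
`δ + w + half-voxel`: distances within the compared range are exact there,
larger ones are only ever compared against smaller thresholds.

## Descriptors

* volume `V` = voxel count × voxel volume; total area `A` = mesh triangle
  sum; sphericity `Ψ = π^(1/3)(6V)^(2/3)/A`.
* Ellipsoid semi-axes from the second central moments of voxel centres with
  solid-uniform scaling (`axis = sqrt(5λ)`), sorted `a ≥ b ≥ c`;
  **prolateness** `(a−b)/a` (rugby-ball-like), **oblateness** `(b−c)/b`
  (flying-saucer-like). These definitions are this package's own — the
  source toolchain does not define its oblate/prolate measures publicly —
  and they recover 0.5 on digital 2:1:1 and 2:2:1 ellipsoids by design.
  Rank-deficient moment matrices (flat or linear cells) set a `degenerate`
  flag; descriptors are still emitted where computable.
* Position: domain areas, their proportions of total area (all three use
  the total area as denominator — whether the original analysis included
  the band in the contact denominator is unstated), and the A/J ratio
  `exposed/junctional`, reported absent when the band is empty (e.g. an
  isolated cell, or `w = 0`).
* Records: one row per non-dividing cell; dividing cells (annotation flag)
  are excluded and counted in a message, since their geometry and
  disassembled nuclear envelope make the descriptors meaningless.

## Intensity ratios

N/C YAP is the mean intensity over nucleus voxels divided by the mean over
cytoplasm voxels (cell minus nucleus, membrane shells included — no erosion
rule is published). A/B pERM divides the mean over the apical shell (cell
voxels within `t = 1 µm` of exposed boundary voxels) by the mean over the
basolateral shell (within *t* of contact boundary voxels). Means, not sums,
keep the ratios scale-free across cell sizes; both ratios are invariant
under multiplying a channel by any positive constant. Empty compartments
(lost nucleus, fully internal cell) yield `NA` plus a QC flag rather than a
number. No background subtraction is applied — synthetic data are
background-free; for real data a constant offset should be removed upstream.

## Threshold and clustering

`yap_threshold()` standardises the values, runs 1-D k-means with k = 2
(10 restarts under a fixed seed, best inertia kept, ties broken toward the
lower centroid) and reports the cut on the original scale as the midpoint
between the maximum of the low cluster and the minimum of the high cluster;
a cell is "high" strictly above the cut. Standardising before clustering
and reporting the cut on the raw scale resolves the ambiguity of where the
standardisation belongs; the classification is invariant under affine
rescaling either way.

`hier_cluster()` z-scores the chosen variables (default `nc_yap`,
`prop_exposed`), builds Euclidean distances, and applies Ward linkage
(`ward.D2`). The cluster count comes from an adaptive tree cut: among
k ∈ 2..6 whose clusters all reach a minimum size (`max(3, 5%)`), choose the
k with the largest relative drop in merge height; if no candidate
qualifies, fall back to k = 3, the cluster count the embryo data are known
to form. (The reference dynamic-tree-cut implementation's defaults are
ecosystem-specific, so the cut is reimplemented as this deterministic
heuristic.) Cluster names derive from centroids on the original scale:
lowest N/C YAP *and* lowest exposure → inside-like; highest N/C YAP among
the rest → outside-like; the remainder (highest exposure, intermediate YAP)
→ undefined. If no cluster is lowest in both variables the ordering is
ambiguous and names stay unset with a warning — the naming never guesses.
A mean silhouette below 0.15 also leaves names unset, flagging
structureless input.

Statistics: Spearman correlations with tie-corrected asymptotic p-values
(constant columns report `NA`); the Shapiro–Wilk gate at α = 0.05 per group
selects ANOVA + Tukey HSD when every group is compatible with normality and
Kruskal–Wallis + Dunn otherwise. Dunn's rank test is implemented in-package
(tie-corrected z statistics) because no installed package provides it;
p-values are reported raw and Holm-adjusted — the original analysis does
not state an adjustment, so both are kept. Fisher's exact test serves 2×2
composition tables.

## The synthetic generator

The generator exists so that every downstream stage can be validated
against known truth. Cells are the envelope-clipped Voronoi regions of
`n_cells` Lloyd-relaxed seed points on the voxel grid (10 iterations,
deterministic from the seed) — voxel-native, reproducible, and a reasonable
cartoon of packed blastomeres without a physics engine. Equal-weight seeds
are used throughout: no per-stage distribution of blastomere volumes is
published, so cells are approximately equal-sized, and this is a documented
simplification. `compaction` γ opens gaps of half-width
`0.15·r_cell·(1−γ)` along Voronoi boundaries (γ = 1, the default, is a
fully packed partition). Each cell receives a spherical nucleus
(`nucleus_radius_fraction`, default 0.4 of the cell's equivalent radius)
clipped to the cell, so nuclei are always strictly inside their cells.

**Envelopes.** Total embryo volume equals a sphere of `envelope_radius`
(default **20 µm**, a compact idealised cleavage embryo) for every envelope,
so confinement redistributes volume rather than changing it. The cylinder
uses `channel_radius` = **12.5 µm** (25 µm diameter microchannels) with its
length set by volume conservation; the slab is `slab_fraction` (default
**0.8**) of the sphere diameter thick — mild planar compression under a
hydrogel sheet, consistent with planar confinement leaving surface
accessibility largely intact — with its lateral disc set by volume
conservation. The single envelope-radius parameter of a naive design is
deliberately split into these three fields, because the sphere radius plays
a different role (total volume) than the cylinder radius (channel bore).

**Intensity model.** Cytoplasm level 100 (arbitrary units; ratios are
scale-free), nucleus level `100 · coupling(p)`, where *p* is the cell's
*true* exposed proportion computed by the voxel-face oracle on the
generated labels, and the coupling is non-decreasing (default affine
`r(p) = 1 + 1.5·p`, placing a fully internal cell at 1.0 and the high/low
boundary near p ≈ 0.4, the regime observed in real embryos). The pERM
channel carries `100·(1 + polarity·k)` on the 1 µm exposed-membrane shell
(k = 4; `perm_polarity = 0` emulates pharmacological loss of apical pERM).
Noise is per-voxel, multiplicative, mean-one log-normal
(`exp(σZ − σ²/2)`, default σ = 0.05) — intensities stay non-negative and
compartment means stay unbiased.

**What it does not emulate:** hydrogel mechanics and surface-tension-driven
compaction dynamics, cell division, apical actin rings, per-stage volume
asymmetries, imaging PSF and background. Passing tests therefore
demonstrate correctness of the measurement and analysis pipeline on
geometry of known truth — not segmentation accuracy or biological fidelity
of real confocal data.

## The voxel-face oracle and its bias

`voxel_face_domains()` classifies every boundary voxel face (6-connectivity)
by marching along its outward normal up to δ: meeting a different cell
within the gap marks contact, otherwise exposed. It is exact counting on
the voxel grid and independent of the mesh pipeline, which makes it the
ground-truth generator and the brute-force cross-check. Its areas, however,
carry an orientation bias: axis-aligned flat interfaces are measured
exactly while curved or oblique surfaces are overestimated by up to ~1.5×.
On densely packed Voronoi embryos — flat oblique interfaces against curved
exposed caps — the oracle's *proportions* can therefore deviate from the
mesh-based ones by up to ~20%, and peripheral cells with near-identical
exposure make cross-method rank comparisons ill-posed. The
oracle-equivalence checks consequently run on ball-chain phantoms whose
exposure levels are separated by construction and whose domains are all
spherical, where the biases cancel and ranking is meaningful (agreement is
then within a few percent).

## The in-silico confinement study

The confinement analysis compares spherical controls against
cylinder-confined and slab-confined cohorts at the **32-cell stage**, ten
embryos per arm. The stage is a geometric consequence of the generator: a
confined Voronoi cell spanning the channel bore is a disc of height
`h = L/n` whose exposed proportion is ≈ `h/(h+r)`, which falls below the
spherical control's median only once `h < r/3` — at the default embryo
volume, from ~32 cells — and channel cultures in the modelled experiments
do reach that stage. Two caveats are documented deliberately: the capped
cylinder leaves its two end cells large exposed caps, which distorts the
*mean* exposed proportion (the median is the robust summary and is the one
used); and because the Voronoi partition has no adhesion energetics, the
mesh-measured exposed-proportion shift is small — the generator's
oracle-level ground truth (and hence the N/C YAP shift it drives) shows the
confinement effect more strongly than the unbiased mesh measurement does.
The slab arm serves as the negative control: mild planar compression
leaves the exposure distribution close to the spherical control's.

## Numerical and degenerate-input conventions

* All randomness flows from a single integer seed per generated object;
  cohorts derive embryo seeds as `seed + 97·index`. Identical configs give
  bit-identical volumes.
* k-means ties break toward the lowest centroid; Ward trees are cut
  deterministically; record order does not affect cluster names (they
  derive from centroids).
* Infeasible packings (envelope too small for `n_cells` at the given
  spacing) fail loudly, naming the constraint, rather than emitting
  degenerate cells.
* Volumes round-trip as 16-bit integers; intensities are rounded to the
  nearest integer on write (sub-integer noise is below any quantity of
  interest at base level 100).
* Problem sizes in the tests and acceptance script (embryo radius 20 µm at
  1 µm spacing, 45³-voxel spheres, cohorts of 4–10 embryos, 10 seeds per
  confinement arm, 100 threshold replicates) were chosen as the smallest
  sizes at which the geometric quantities stabilise, keeping the whole
  validation suite runnable in minutes.

## Known limitations

* The proximity parameters δ and w are conventions, not published values;
  both are exposed and all domain areas vary smoothly (and monotonically)
  with them.
* Contact-partner identity is recorded per face but unused by the analyses,
  matching the published scope; it is kept for extensibility.
* The generator's cells are convex polyhedra; real blastomeres bulge and
  dome, so A/J ratios here exercise the measurement, not the biology's
  dynamic range.
* Real printed effect sizes (correlation coefficients, cluster composition
  percentages, the 1.6 threshold) belong to a confocal dataset that is not
  redistributable; the package validates properties — directions,
  conservation laws, oracle agreements, calibrated regimes — rather than
  reproducing those numbers.
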