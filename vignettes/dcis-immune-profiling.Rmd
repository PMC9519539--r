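---
title: "Methods: quantifying the DCIS immune microenvironment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the DCIS immune microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, parameter choices and numerical
conventions behind `dcisime`, in the spirit of a methods section: what is
computed, under which assumptions, and where design decisions were
genuinely open.

## 1. Inputs and units

A slide is a set of cell centroids in micrometres (origin top-left, y
increasing downward, the image convention) with 0/1 marker flags, plus a
tissue segmentation into four compartments: DCIS epithelium, periductal
stroma, intraluminal debris and background. Cells are points — the
metrics are centroid-based counts, so cell shapes are never needed. All
areas are reported in mm²; all distances in µm. Debris and background
cells are excluded from every metric: the analysis concerns the DCIS
epithelium and its periductal stroma only.

Two assays coexist per patient: the 6-marker mIF panel (panCK, CD3, CD8,
CD20, FOXP3, CD68) and a separate CD8/Ki67 double stain, mirroring
workflows where Ki67 is not part of the multiplex panel. Ki67 flags on
mIF rows are rejected unless explicitly enabled.

## 2. Gating model

Gating is a pure function of the marker vector and the assay tag.
Precedence resolves contradictory flags deterministically:
`panCK > CD3 lineage > CD20 > CD68 > other`; within the CD3 lineage,
`FOXP3+ → Treg`, else `CD8+ → cytotoxic`, else `helper`. CD4 is not in
the panel, so helper T cells are operationally CD3+CD8−FOXP3−. CD68+CD3+
conflicts resolve to the T lineage (T-cell markers are the more specific
stain). On the double stain, only CD8/Ki67 are visible: CD8+Ki67+ is an
activated cytotoxic T cell, CD8+Ki67− cytotoxic, anything else `other`.

**The triple-positive question.** The lymphocyte definition used in this
field is a four-term sum (helper + cytotoxic + CD8− Treg + B cells) that
omits CD3+CD8+FOXP3+ cells, while the Treg definition (CD3+FOXP3+)
includes them. Whether the original analyses counted such cells as
lymphocytes is not documented. The package defaults to the
*strict-literal* mode — the printed formula, under which a
triple-positive cell is a Treg but not a lymphocyte — and offers an
*inclusive* mode that adds the combination to the lymphocyte sum. Both
are tested; the default follows what is printed rather than what might
have been intended. With the generator's default Treg-CD8 fraction of 0
the two modes coincide.

## 3. Spatial summaries

*Densities* are `count / area_mm2` per subset and compartment. Subsets
whose defining markers failed on a slide (FOXP3 is the common case) are
emitted as missing, never zero — a zero is a biological claim, a missing
value is not.

*Ratios* cover all 28 unordered pairs of the 8 subsets in a canonical
order. `0/0` is undefined (NA); `x/0` is `+Inf`, kept in the table but
dropped by the complete-case rule of every rank test downstream.

*Proximity index*: immune cells whose nearest DCIS cell lies within
`radius_um`, divided by the DCIS cell count. Choices made explicit:

* distance is centroid-to-centroid; the 25 µm default approximates a
  DCIS cell diameter, so "within one cell diameter" is the intent;
* the boundary is closed (`<=`), configurable, because the printed
  definition does not state it; the hand-checked fixture (immune cells
  at 10, 25, 26 µm of a single DCIS cell → index 2.0) freezes the rule;
* each immune cell counts at most once however many DCIS cells surround
  it — the numerator counts immune cells, not pairs;
* only mIF cells participate (the double stain has no panCK reference),
  and a slide without DCIS cells is an error, not an index of 0.

The neighbourhood search buckets DCIS cells on a grid of cell size `r`
and scans the 3×3 neighbourhood; equivalence with the O(n²) brute force
is asserted over random fixtures rather than assumed.

## 4. TLS detection

Published TLS counts in this setting come from pathologists; any
algorithmic detector is a stand-in. The package's detector is the
simplest one with a ground-truth guarantee on its own generator:

1. cluster B cells by connected components at `eps_um` (single-link
   chaining) and keep components of at least `min_follicle` cells;
2. count CD3+ T cells within `t_zone_um` of the follicle convex hull
   (distance 0 inside); require `min_t_zone` of them.

Defaults `eps_um = 30`, `min_follicle = 20`, `t_zone_um = 50`,
`min_t_zone = 30` were chosen once, a priori, to satisfy two conditions
at the generator's stated world: every seeded follicle (60 B cells in a
40 µm blob with an 80-cell T ring) is called, and homogeneous Poisson
background at realistic B-cell density (~120/mm²) is never called — at
that density the expected B-neighbour count within 30 µm is ≈0.34, far
below the chaining percolation regime, so 20-cell components do not
arise. The acceptance suite verifies sensitivity 1.0 with zero false
positives over 100 seeds and that removing the T ring removes every
call.

GC-TLS detection clusters double-stain cells positive for CD8 or Ki67,
takes the convex hull, shrinks it about its centroid to `gc_core_frac`
(default 0.5) of the hull area, and calls a germinal centre when the
Ki67+ fraction in the core reaches `gc_threshold` (default 0.3; 0
returns every candidate aggregate, a tested superset property).
Detection is invariant under translation and rotation, and raising
either size threshold can only remove calls (monotonicity, tested).

## 5. Statistics

*Permutation tests.* The Mann-Whitney effect is `|U − n_a n_b / 2|`
(symmetric, hence two-sided); ranks are averaged over ties. Exact
enumeration is auto-selected when `choose(n, n_a) ≤ 50,000`; otherwise
Monte-Carlo with `n_perm = 10,000` by default and the add-one estimator
`(1 + #extreme)/(1 + n_perm)`, which cannot return 0 and keeps the test
valid. Kruskal-Wallis uses the tie-corrected H and the same permutation
scheme; with fewer than two distinct values p = 1 by convention (with a
warning). Per-test seeds derive from a base seed and the feature index,
so results are independent of iteration order.

*FDR.* BH q-values are computed by the step-up definition, applied
within feature families (stromal densities; intraepithelial densities;
each compartment's 28 ratios; proximity indices; TLS densities) for the
case-control contrast. Clinicopathological association tests (grade via
Kruskal-Wallis; ER, PR, HER2, COX-2, fibrosis, comedonecrosis, Ki67
category via Mann-Whitney) are deliberately left uncorrected and flagged
as such — they validate expected patterns rather than discover.

*ICC.* McGraw-Wong estimators from the two-way ANOVA decomposition, all
four combinations of form (absolute/consistency) and unit
(single/mean-of-k), with F-based 95% CIs (Satterthwaite df for the
absolute form). Complete-case row removal; shift invariance and the
Spearman-Brown inequality (mean-of-k ≥ single) are tested properties.
The rater simulator draws `y_ij = mu + s_i + r_j + e_ij`; its `true_icc`
is defined as the population ICC(A,k) with k = n_raters, because
mean-rating absolute agreement is the estimand of record for TLS
scoring; recovery within 0.05 at true ICC ∈ {0.72, 0.89, 0.97} — the
agreement levels reported for Ki67, zone-TLS and GC-TLS scoring — is an
acceptance criterion.

*Clustering.* `log(1 + x)` transform, Euclidean distance, complete
linkage. Merge heights are checked against a naive agglomerator;
the dendrogram is exported as Newick (parsed back with `ape` in tests).

## 6. The synthetic world

The generator is a stated world, not a tuning dial:

* **Geometry.** Ducts are disks (regular 96-gons; the polygon, not the
  circle, is the ground truth for areas, membership and sampling, making
  Poisson calibration exact). Periductal stroma is an annulus of
  configurable width. Placement rejects configurations where stroma
  annuli would overlap and keeps ducts wholly inside the slide — a mild
  strengthening of "ducts don't overlap" that buys exact analytic areas
  without polygon union machinery. A bounded rejection loop errors with
  the attempt count if the requested ducts cannot be placed.
* **Intensities.** Homogeneous Poisson per compartment. Default stromal
  intensities (B 120, helper 140, cytotoxic 80, Treg 30 cells/mm²) sum
  to 370 lymphocytes/mm², the median stromal lymphocyte density scale
  for DCIS; macrophages 80/mm²; intraepithelial intensities are an order
  of magnitude lower, matching the sparse intraepithelial infiltrate.
  Epithelial cellularity defaults to 4,000 cells/mm², a typical DCIS
  epithelial packing. An optional exponential decay of stromal intensity
  with distance to the nearest duct boundary creates proximity-index
  structure when needed.
* **Cohorts.** Per-patient lognormal multipliers (SD 1.0 on the log
  scale, consistent with the ~4× interquartile ratio reported for
  stromal lymphocyte density) scale all immune intensities; the
  case-control design defaults to 77/64; `case_effect` multiplies
  stromal intensities for cases and defaults to 1 — the null, matching
  the negative primary finding this pipeline is built to probe.
  Metadata frequencies follow the pooled margins of that design (grade
  12/64/24%, ER+ 80%, HER2+ 28%, fibrosis 30%, comedonecrosis 79%,
  Ki67≥14% 13%). Child seeds are `(seed + 1000003·i) mod 2147483647`,
  so slides reproduce under reordering.
* **What it does not emulate.** Real duct morphology and branching,
  segmentation error, staining artefacts, spatial clustering of immune
  cells beyond the seeded TLS (no per-duct heterogeneity model), and
  marker intensity distributions (flags are binary by construction). A
  green test therefore establishes correctness of the *computation*
  under a known point-process model — not robustness to segmentation or
  staining pathology.

## 7. Numerical conventions and degenerate inputs

* Boundary points in compartment assignment follow the precedence
  `epithelium > debris > stroma > background` (a point exactly on the
  epithelium/stroma interface is epithelial); a point inside a hole
  boundary belongs to the enclosing region. Point-in-polygon is even-odd
  crossing with an explicit boundary-distance check (tolerance 1e-9 µm),
  validated against a winding-number oracle.
* Zero compartment area with a non-zero count is an error (inconsistent
  geometry); zero area with zero count drops the row with a warning.
* File-supplied compartment labels win over geometry (upstream
  segmentation is trusted) unless reassignment is forced.
* CSV is UTF-8, comma-separated, '.' decimal, header mandatory. Configs
  and spec files are JSON rather than YAML — functionally equivalent
  here and avoids a dependency outside the guaranteed stack; geometry is
  GeoJSON with a `compartment` property per polygon feature.
* Determinism contract: identical spec + seed reproduces slides
  byte-for-byte, and identical config + seed reproduces every pipeline
  table byte-for-byte (tested via md5).

## 8. Known limitations

* The TLS thresholds are calibrated to the generator's follicle model,
  not to pathologist consensus; on real slides they are a starting point
  and the manual-counts path (rater matrices + ICC) remains the
  reference workflow.
* The proximity index approximates "within one cell diameter" by a
  centroid distance; membrane-to-membrane intent would need cell
  boundaries the data model deliberately omits.
* Exact permutation enumeration is limited to 50,000 splits; beyond
  that, Monte-Carlo error of order `1/sqrt(n_perm)` applies to nominal
  p-values and hence to borderline FDR calls.
* The generator's null is exchangeable by construction; it cannot probe
  confounding structures (e.g. grade-immune correlations) unless the
  user wires them into `case_effect`/metadata jointly.
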