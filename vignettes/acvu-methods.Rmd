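---
title: "Methods: reporter quantification, fate classification, and screen hit calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reporter quantification, fate classification, and screen hit calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acvu)
```

## Scope

`acvu` analyses two-channel confocal z-stacks of the *C. elegans* somatic
gonad primordium at the stage when four cells — α₁, α₂ and their lineage
sisters β₁, β₂ — compete for the anchor-cell (AC) fate. A GFP-tagged fate
reporter is bright in the AC and degraded in ventral uterine precursor
(VU) cells; an mCherry-histone marker labels the nuclei for segmentation.
This vignette documents the models, parameters and numerical conventions
behind each stage, the design decisions taken where the underlying
protocol left the choice open, and what the synthetic validation does and
does not establish about real images.

## Synthetic image model

The generator (`sample_condition()`, `make_animal_image()`) emulates the
statistical structure the analysis assumes, not optics.

**Geometry.** Four nuclei of radius 4 voxels sit in a planar quartet
(sisters 10 voxels apart, the two sister pairs 18 voxels apart) at the
centre of a 44 × 32 × 20 voxel grid, each centre jittered uniformly by
±1.5 voxels per axis. Voxels are treated as isotropic at the acquisition
z-spacing of 260 nm, making a nucleus ≈ 2 µm across — a realistic somatic
gonad nucleus. The larva is an axis-aligned ellipsoid enclosing the nuclei
with a margin, unioned with every rendered nucleus support so the mask
provably covers all signal; the corners of the frame remain outside the
larva, which the background-correction and visibility machinery requires.

**Fluorophores.** Each nucleus is an isotropic 3D Gaussian blob with
σ = radius/2, truncated at 3σ and renormalized so the noise-free rendered
intensity sums exactly to the nucleus's true total. True totals are
log-normal per fate class:

| parameter | default | units | rationale |
|---|---|---|---|
| AC-level GFP | lognormal(log 30 000, 0.25) | AU | bright, stable reporter; 10× the VU level |
| VU-level GFP | lognormal(log 3 000, 0.25) | AU | residual reporter after degradation |
| mCherry marker | lognormal(log 500 000, 0.15) | AU | segmentation marker far above noise (peak SNR ≈ 50) |
| background | 0.5 | AU/voxel | faint autofluorescence, inside the larva only |

Cells with AC fate — and VU-fated cells "stabilized" by an RNAi
perturbation, drawn per cell with the condition's penetrance — receive
AC-level draws; all other VU-fated cells receive VU-level draws. Fate
structure per condition: the wild-type-like conditions give exactly one α
cell the AC fate; the Notch-null-like condition (`condition_lin12_null()`)
gives both α cells AC fate and each β cell AC fate with probability 0.1,
which is also the default `f` of the top-fraction β-cell correction.

**Camera model.** Expected intensity → Poisson shot noise → constant
offset (150 AU) → additive Gaussian read noise (SD 80 AU) → clamp at zero.
The offset keeps near-zero expectations from being clipped into a biased
half-normal; the read-noise SD is set so that, with the k = 5 visibility
rule below, an unstabilized VU-level nucleus falls below the visibility
cut while an AC-level nucleus is far above it — the qualitative structure
the screen design presumes (ACs always visibly bright, VUs not). All
randomness flows from one explicit seed through a deterministic splitter;
no global RNG state leaks between stages.

**What is deliberately not modelled** — diffraction and PSF anisotropy,
spectral bleed-through, photobleaching, stage drift, textured
autofluorescence, and within-nucleus marker heterogeneity. Passing the
validation suite therefore shows the *pipeline logic* is correct under the
assumed noise structure; it does not certify performance on real
microscope data, where segmentation difficulty is dominated by exactly the
effects excluded here. The segmentation-QC exclusion rules exist for that
reality and are exercised synthetically only at their boundaries (merged,
fragmented, dim-marker cases).

## Segmentation

`segment_nuclei()` is an automated stand-in for interactively drawn marker
boundaries: Gaussian smoothing (σ = 1 voxel) of the mCherry channel, a
global Otsu threshold, 26-connectivity 3D connected components (components
under 10 voxels discarded as specks), and a marker-based split —
local-maximum seeds at least one expected radius apart, voxels assigned to
the nearest seed — attempted for components larger than 1.8× the median
component volume, and for every component whenever fewer components than
expected nuclei are found (two sister pairs merging symmetrically leaves
the median volume uninformative). A component with a single intensity
maximum never splits, so the attempt is safe for well-separated nuclei.

Each component is then refined to a **relative-intensity boundary**: the
voxels above 30% of that nucleus's background-subtracted smoothed peak.
This makes boundary area depend on nucleus geometry rather than marker
brightness, so a dim and a bright nucleus of equal size get equal-sized
boundaries — important because the no-background-correction measurement
(method B below) otherwise inherits a brightness-dependent area term.

QC flags mirror the three exclusion reasons used when scoring real images:
`merged-nuclei` (nuclei too close to separate), `fragmented` (one nucleus
split into multiple objects), `dim-marker` (marker too weak to segment; a
weak-contrast guard also catches stacks that are pure noise). Animals
carrying any of these flags are excluded before screen counting. On
synthetic data the ground-truth overlap test (centres closer than one
radius) is authoritative for the merged case.

## Measurement methods

**Method A — `measure_sumproj_bgcorr()`.** GFP integrated inside the
boundary footprint on the sum z-projection restricted to the nucleus's
slices, minus GFP integrated over the same footprint placed wholly outside
the larva on the same slices (first raster-order placement; placement and
subtraction both use identical voxel counts, so constant camera terms
cancel exactly). The projection is per-nucleus, not whole-stack. Whether
the original background region was matched per-slice or on the projection
is not determinable from the protocol; we subtract on the projection over
the same slices and flag this as an interpretation. Negative corrected
values are retained and flagged, never clamped — clamping would bias
population means.

**Method B — `measure_top5()`.** The 5 z-slices with the highest per-slice
integrated mCherry are selected (ties resolved toward lower z, for
determinism); GFP inside the boundary is summed over exactly those slices;
no background correction. Nuclei spanning fewer than 5 slices use all
slices and are flagged `short_span` rather than dropped, since dropping
them would bias screens against small or edge nuclei. Because slice
selection is separable, the top-5-by-slice rule attains the brute-force
best 5-subset of slices; the test suite verifies this by enumeration.

## Naming, AC inference, thresholds

Within an animal, the α cell with the higher GFP value is α₁ (the
presumptive AC), its lineage sister β₁; α ties are broken toward the lower
centroid x and flagged for audit. When lineage identity is unavailable,
each β is paired to an α by the one-to-one assignment minimizing total
centroid distance. Animals with missing or excluded cells get all roles
set to unknown.

The AC-like threshold is the negative-control AC mean minus one sample SD
(n − 1 denominator — control samples are small); a cell is AC-like iff
strictly above the threshold. The per-role AC-like table excludes α₁, the
presumptive AC. The β-cell fate-transformation correction removes the
⌈f·n⌉ largest β values (ties toward the larger value, then input order)
before population comparisons; `f` defaults to 0.1, matching the observed
β-to-AC transformation proportion it corrects for, and is exposed as a
parameter.

The by-eye "visible GFP" call is formalized as `gfp_value > m + k·s`,
where m and s are the median and SD of background sums over regions tiled
outside the larva with exactly the same voxel support as the measurement
(so the camera offset cancels voxel-for-voxel), and k = 5 mimics a
confident visual call. When the outside-larva margin is too narrow to tile
disjointly, overlapping placements are used; if no placement fits, the
animal is excluded rather than guessed at.

## Screen logic

Per animal, the GFP-positive cells among the four (excluded animals
dropped) are counted. A round is scored only if its controls behave: at
least 50% of negative-control animals with exactly one positive cell, and
strictly more than 50% of positive-control animals with more than one.
A clone is a **strict** hit if its mean count is ≥ 2 and a **lenient** hit
if at least one animal has all 4 cells positive and at least half the
animals have more than 1. Clones are scoreable with at least 20 counted
animals; the generator simulates extra animals so that the target number
pass QC, mirroring a protocol that scores a fixed number of individuals.
Triplicate confirmation — whose original wording does not say whether all
three replicates had to pass — defaults to a majority rule (≥ 2 of 3
replicates meeting strict or lenient), which tolerates one bad replicate;
`rule = "all"` is available.

## Statistics

- **Mann–Whitney U**, two-sided. Exact mode uses the null distribution of
  U (the tie-free closed form, or full enumeration of labelings under
  ties, feasible to n = 16); the two-sided p doubles the smaller tail,
  capped at 1 — the standard convention, chosen where the protocol is
  silent. Asymptotic mode is the normal approximation with tie correction
  and a continuity correction; without the continuity correction the
  worst-case disagreement with the exact p at n = 6 + 6 is 0.069, with it
  0.015.
- **Kruskal–Wallis**: tie-corrected H with the χ² reference (k − 1 df),
  plus an exact full-enumeration permutation mode for total n ≤ 12.
- **Dunn's post hoc** comparisons versus a control: z statistics on pooled
  mean ranks with tie-corrected variance, Bonferroni-adjusted over the
  vs-control family by default (the correction attached to Dunn's test is
  not otherwise specified; the adjustment is a parameter).
- **Fisher's exact test** on 2×2 tables: two-sided by the probability
  method (sum of hypergeometric probabilities of tables no more probable
  than observed), the most common convention.
- **Mean ± 95% CI**: t-based, appropriate for the small per-group n of
  these experiments; a bootstrap alternative is provided for skewed
  samples.

Rank-based p-values are invariant under monotone data transformations, and
the exact implementations are checked against independent enumeration
oracles in the test suite.

## Validation design and problem sizes

The package validates itself at these scales, chosen as the smallest that
exercise each claim meaningfully: measurement recovery on 50 animals (200
cells) with both methods; planted-hit recovery on 20 independent screens
of 10 clones (2 planted at penetrance 0.9) with 20 scored animals per
clone; the classifier on a 50-animal negative-control population; the
exact Mann–Whitney size on 10 000 null draws at n = 6 + 6; the hit-rule
truth table on all 625 count vectors; Fisher agreement on all 2×2 tables
with margins ≤ 20.

The recovery experiment uses `condition_recovery()`, in which every cell
draws its true total from one wide log-normal (meanlog log 20 000, sdlog
1.0) spanning the pipeline's dynamic range — a calibration-series design.
Measured against the narrow per-role screen condition instead, a rank
correlation would mostly measure photon and read noise within a
biologically narrow band, which is not what a recovery validation is for.

Note on the exact test's size: at n = 6 + 6 the attainable two-sided level
just below 0.05 is 2·P(U ≤ 5) ≈ 0.041, so the empirical rejection rate over
10 000 simulations concentrates near 0.041, not 0.05 — the familiar
conservatism of exact rank tests at small n.

## Numerical conventions and degenerate inputs

Deterministic tie-breaks throughout: lower z for slice selection, lower
centroid x for α ties, first-seed assignment for equidistant watershed
voxels, larger-value-then-input-order for the top-fraction exclusion.
Zero-variance inputs are legal: a constant control sample gives
σ = 0 and threshold = mean; a constant sample gives a degenerate CI; a
fully tied comparison gives p = 1. An empty mCherry channel yields zero
segments plus the dim-marker flag, not an error. Stacks round-trip through
16-bit unsigned TIFF bit-exactly for integer intensities, with clipping
above 65 535 warned about; sidecar coordinates are 0-based (x, y, z), while
R internals are 1-based.

## Known limitations

Segmentation is tuned for blob-like, well-separated nuclei at the
simulated SNR; heavily overlapping nuclei are flagged and excluded rather
than resolved. The visibility surrogate is a formalization of a by-eye
call, not a reproduction of it — k = 5 is a design constant, not a fitted
value. Absolute intensity scales are arbitrary units; only relative
structure (ratios, ranks, thresholds derived from controls) is
meaningful. The image model omits optical effects entirely (see above), so
conclusions about real-data performance require real annotated images.
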