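# acvu

Quantitative analysis of anchor-cell fate reporter fluorescence in the
*C. elegans* somatic gonad primordium, and penetrance-based hit calling for
RNAi screens built on it.

## The problem

Early in gonadogenesis four cells — two α cells and their lineage sisters,
the β cells — have the potential to become the single anchor cell (AC). The
β cells normally adopt the ventral uterine precursor (VU) fate; the two α
cells resolve AC versus VU through LIN-12/Notch signaling. A GFP-tagged
transcription factor required for AC fate stays bright in the AC and is
degraded in presumptive VUs, so per-nucleus GFP level is a readout of fate
and of reporter stability. Experiments built on that readout need:

- per-nucleus GFP quantification from two-channel (GFP + mCherry-histone)
  confocal z-stacks, with the mCherry channel as segmentation marker;
- naming of the quartet (α₁ = α cell with the higher GFP in an animal, its
  sister β₁, and likewise α₂/β₂) and inference of the AC;
- a threshold classifier for "AC-like" GFP levels;
- screen logic that converts per-animal counts of GFP-positive cells into
  clone-level hit calls behind control quality gates.

`acvu` implements all of these, plus a synthetic image generator with known
ground truth so every stage can be validated end-to-end, and the
nonparametric statistics the analyses use.

## The core rules

With per-cell integrated intensities \(v\) (AU):

- **Measurement A** (`measure_sumproj_bgcorr`): GFP integrated over the
  nucleus boundary on a sum z-projection of the nucleus's slices, minus
  the GFP integrated over a same-shaped region outside the larva on the
  same slices.
- **Measurement B** (`measure_top5`): GFP summed inside the boundary over
  the 5 z-slices with the highest per-slice integrated mCherry; no
  background correction.
- **AC-like threshold** (`fit_ac_threshold`): \(t = \mu_{AC} - \sigma_{AC}\),
  the mean of negative-control AC values minus one sample SD; a cell is
  AC-like iff \(v > t\).
- **Visibility surrogate** (`call_gfp_positive`): a cell is GFP-positive iff
  \(v > m + k s\), with \(m, s\) the median and SD of same-shaped
  outside-larva background region sums and \(k = 5\).
- **Strict hit**: mean GFP-positive cells per animal ≥ 2.
  **Lenient hit**: some animal has all 4 cells positive *and* at least half
  the animals have > 1.
  **Gates**: a round is scored only if ≥ 50% of negative-control animals
  have exactly one positive cell and > 50% of positive-control animals have
  more than one.
- **β-cell correction** (`exclude_top_fraction`): drop the
  \(\lceil f n \rceil\) highest β-cell values (default \(f = 0.1\)) before
  comparing VU-fated populations in backgrounds where some β cells become
  ACs.

Statistics: exact and tie-corrected asymptotic Mann–Whitney U,
Kruskal–Wallis (with full-enumeration exact mode at small n), Dunn's
post hoc comparisons versus a control, Fisher's exact test, and t-based
confidence intervals on means.

## Worked example

Simulate one screening round (a lacZ negative control, a lin-12 positive
control, three experimental clones of which one stabilizes the reporter in
90% of VU-fated cells), run the screen, and fit the AC-like threshold:

```r
library(acvu)

design  <- screen_design(n_clones = 3, n_planted = 1,
                         planted_penetrance = 0.9, n_animals = 20)
dataset <- make_screen_dataset(design, seed = 61)
report  <- run_screen(dataset)
report
#> <screen_report> 5 clones; 1 hits; 1 of 1 rounds valid
#>   planted-hit recovery: sensitivity 1.00, 0 false positive(s)

cells   <- name_cells(dataset$cells)
ctrl_ac <- cells$gfp_value[cells$clone_id == "lacZ" &
                           cells$role == "alpha1" & !cells$excluded]
model   <- fit_ac_threshold(ctrl_ac)
model
#> <ac_threshold> mu_ac = 4.193e+04, sigma_ac = 3255, threshold = 3.867e+04 (n = 20)

ac_like_table(cells[cells$clone_id %in% c("lacZ", "clone_01") &
                    cells$role == "alpha2", ], model)
#> # A tibble: 2 x 5
#>   condition role       n n_ac_like pct_ac_like
#>   <chr>     <chr>  <int>     <int>       <dbl>
#> 1 clone_01  alpha2    20        14          70
#> 2 lacZ      alpha2    20         0           0

x <- cells$gfp_value[cells$clone_id == "clone_01" &
                     cells$role == "alpha2" & !cells$excluded]
y <- cells$gfp_value[cells$clone_id == "lacZ" &
                     cells$role == "alpha2" & !cells$excluded]
mann_whitney_u(x, y)
#> # A tibble: 1 x 5
#>   method               statistic      p_value n_per_group adjusted
#>   <chr>                    <dbl>        <dbl> <list>      <lgl>
#> 1 mann_whitney_u_exact       382 0.0000000232 <int [2]>   FALSE
```

The planted clone is the only hit (mean 3.7 GFP-positive cells per animal
against 1.1 in the control), 70% of its α₂ cells sit above the AC-like
threshold versus none in the control, and the α₂ fluorescence shift is
highly significant by the exact Mann–Whitney test. `autoplot(report)` and
`plot_ac_like(cells, model)` draw the standard displays;
`tidy()`/`glance()` return the tabular results. `run_pipeline()` chains
synthesis, quantification, classification, screening and statistics into a
seeded, logged run directory.

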