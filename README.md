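# phrenoscope

Quantification of left/right asymmetry in diaphragm innervation and phrenic
motoneuron assays.

The left and right phrenic nerves innervate the diaphragm asymmetrically:
the left nerve enters close to the motor endplate band and splits almost
flat ("T"-like), the right enters further away, splits more acutely
("V"-like) and defasciculates into roughly twice as many secondary
branches. phrenoscope is for developmental neurobiologists who need to turn
traced nerve skeletons, binary masks and paired left/right assay tables
into the standard asymmetry measures and statistics:

- **Nerve morphometry** — defasciculation distance *d* (perpendicular
  distance from the nerve entry point to the endplate tangent, a
  total-least-squares principal-axis fit of the α-bungarotoxin mask),
  secondary-branch count (fascicles crossing a line parallel to the
  tangent at 0.8 *d* from the entry, within the primary span), primary
  split angle, and endplate-band thickness (mean perpendicular extent of
  30 equal-length bins along the band axis). `quantify_hemidiaphragm()`
  returns all four; `lr_ratio_summary()` forms per-embryo R/L ratios with
  mean ± SEM.
- **Explant outgrowth** — concentric rings at 25 px spacing around an
  explant border (`build_rings()`), total labelled area, maximal growth
  distance, and the proximo-distal defasciculation index
  Σw(proximal) / Σw(distal) with widths measured as arc-length runs along
  iso-distance contours.
- **Transcript lateralization** — paired L/R samples of *n* embryos; a
  probe is right-enriched iff all per-embryo log2(R/L) > 0, their mean
  exceeds log2(1.5) = 0.5849, and ≥ 2 embryos individually exceed the fold
  (`detect_lateralized()`, after the present-call and intensity-floor gate
  of `filter_expressed()`).
- **Assay quantifiers** — RNAscope supra-threshold surface ratios with a
  cross-applied Otsu threshold, in situ zymography positive-cell
  fractions, and western-blot left+right sum normalization.
- **Exact tests** — Mann-Whitney U and Wilcoxon signed rank with exact
  small-sample p-values by complete enumeration, as used for L-vs-R
  comparisons.
- **Synthetic data** — generators for every input type with known ground
  truth, including presets carrying the measured wild-type group means
  (E13.5–E15.5, left/right).

## Worked example

```r
library(phrenoscope)

left  <- make_nerve_pattern(preset_pattern_params("E15.5-left"))
right <- make_nerve_pattern(preset_pattern_params("E15.5-right"))
rbind(quantify_hemidiaphragm(left$pattern,  left$band),
      quantify_hemidiaphragm(right$pattern, right$band))
#>    side defasciculation_distance secondary_branch_count split_angle
#> 1  left                     77.5                      6         166
#> 2 right                    188.5                     11         132
#>   endplate_thickness
#> 1                254
#> 2                528
```

The synthetic E15.5 presets are generated at the measured group means
(77.16/188.51 µm, 6/11 branches, 166°/132°, 254.9/529.3 µm), and the
morphometry recovers them to within rasterization error: distances to
0.4%, counts exactly, angles exactly, thicknesses to 0.4%. The thickness
ratio reproduces the ~2.1-fold medio-lateral scattering of receptor
clusters on the right:

```r
lr_ratio_summary(data.frame(left = 254.9, right = 529.3))
#> <ratio_summary> R/L = 2.077  (n = 1, per_pair)
```

Comparing left and right measurements from different embryos uses the
exact rank-sum test:

```r
mann_whitney(c(77.2, 80.1, 75.3, 79.4, 76.8, 78.2),
             c(188.5, 190.2, 185.7, 187.3, 191.0, 186.4))
#> <phreno_test> U = 0, p = 0.0021645 (exact, two.sided)
```

U = 0 means no left value exceeds any right value; the exact two-sided
p is 2/choose(12, 6) = 0.0022, the smallest attainable at n = 6 + 6.
Lateralized transcripts from a paired 3-embryo design:

```r
ds <- make_expression_dataset(n_probes = 5000, n_left_enriched = 15,
                              n_right_enriched = 25, seed = 7)
detect_lateralized(ds$matrix)
#> <lateralized_gene_set> 15 left-enriched, 25 right-enriched (fold > 1.5, >= 2 embryos)
```

A thin CLI wraps the same functions
(`exec/phrenoscope quantify|ratios|outgrowth|lateralize|test`).

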