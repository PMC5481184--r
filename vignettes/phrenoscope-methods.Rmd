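---
title: "Quantifying left/right asymmetry of diaphragm innervation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying left/right asymmetry of diaphragm innervation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phrenoscope)
```

## Background

The mammalian diaphragm is innervated by the left and right phrenic nerves,
which split into dorsal and ventral primary branches on reaching the lateral
muscles. The two sides are not mirror images: the left nerve enters close to
the motor endplate band and splits almost flat (a "T"-like pattern), while
the right nerve enters further away and splits more acutely (a "V"-like
pattern), defasciculating into roughly twice as many secondary branches. The
endplate band itself — the stripe of acetylcholine-receptor clusters
labelled by alpha-bungarotoxin — is correspondingly more scattered
medio-laterally on the right. These asymmetries arise before synapse
formation, are controlled by Nodal-pathway signaling, and are accompanied by
intrinsic left/right differences in the motoneurons themselves: lateralized
transcripts measurable in paired laser-captured samples, differential
Slit/Robo receptor processing on western blots, and higher right-sided MMP2
gelatinase activity in cultured motoneurons.

phrenoscope implements the full measurement chain behind these observations:
geometric morphometry of traced nerve patterns, concentric-ring scoring of
explant outgrowth, a paired lateralization filter for expression data, the
assay-level quantifiers, and the exact nonparametric tests used to compare
left and right. A synthetic-data module generates every input type with
known ground truth, so the whole chain is testable without microscopes or
arrays.

## Nerve morphometry

A hemidiaphragm is described by two objects: a `nerve_pattern` (a rooted
tree of 2D points in micrometres; the root is the nerve entry point, edges
carry a branch order of 1–3) and an `endplate_band` (a binary mask of the
alpha-bungarotoxin-positive region). Four measures are taken.

**Endplate tangent.** Manual workflows trace a straight line "tangentially"
along the band. We replace the hand trace with a total-least-squares fit:
the line through the centroid of the foreground pixels along their major
principal axis (`fit_endplate_axis()`). A meaningful tangent requires an
elongated band; masks whose principal-axis ratio is at or below 1.2 raise a
`DegenerateShape` error rather than returning an arbitrary direction.

**Defasciculation distance** is the perpendicular distance from the entry
point to that tangent (`defasciculation_distance()`), in micrometres. It is
invariant under rigid motion of pattern and band together, and mirror
reflection preserves it exactly.

**Secondary branch count.** A counting line is drawn parallel to the
tangent, at a configurable fraction of the defasciculation distance from
the entry point (`branch_crossings()`). Published descriptions of this
procedure place the line either at 80% of the distance from the entry or at
one quarter of the distance from the endplate; we take the fraction from
the entry point with a default of 0.8, and expose it as a parameter since
the two conventions differ slightly. Fascicles of the requested orders
(secondary and tertiary by default) whose polylines straddle the line are
counted, restricted to the span between the extremes of the two primary
branches; a fascicle is one maximal run of connected same-order edges and
is counted once however often it wiggles across the line. An optional gap
tolerance (default 0 µm) merges crossings closer than a stated distance,
mimicking fascicles that are indistinguishable at the imaging resolution.
For raster input, `branch_crossings_raster()` counts connected foreground
components of the order-filtered mask within a one-pixel band at the same
line.

**Split angle** (`split_angle()`) is the angle between the two primary
branch directions leaving the entry, each direction averaged over the first
three edges of its chain so that local tracing jitter does not dominate.

**Endplate thickness** (`endplate_thickness()`) reproduces the
outline-and-rectangles procedure: the band is divided into 30 equal-length
bins along its fitted axis, the width of each bin is the foreground extent
perpendicular to the axis (plus one pixel for the pixel footprint), and the
mean width is reported in micrometres. Width is extent, not area divided by
length, which matches the rectangle construction and is robust to holes in
the staining.

`quantify_hemidiaphragm()` bundles the four measures into one record;
`lr_ratio_summary()` forms per-embryo right/left ratios with mean ± SEM.
The mean of per-embryo ratios is the default aggregation; a
ratio-of-group-means variant is available (`aggregate = "ratio_of_means"`)
because summary figures in the literature are sometimes quoted that way —
for a single pair the two coincide.

## Explant outgrowth

Axon outgrowth from ventral spinal-cord explants is scored in concentric
rings, following the NeuriteJ convention of radial ROIs spaced 25 pixels
apart. `build_rings()` partitions the image outside the explant border by
Euclidean distance to the explant (distance transform); ring *k* holds the
pixels between (k−1) and k spacings from the border, clipped at the image
edge. `outgrowth_area()` sums the labelled surface over rings (which, by
construction, equals the whole-image foreground outside the border — a
conservation property the tests assert) and reports the outer offset of
the farthest occupied ring as the maximal growth distance.

The **proximo-distal defasciculation index** compares total fascicle width
on a proximal ring (the second ring) with that on a distal ring, the first
ring whose outer offset exceeds 30% of the maximal growth distance. Width
is measured along the ring's mid-offset iso-distance contour. Counting raw
band pixels is biased by the pixel lattice — a 20-pixel-wide fascicle
running diagonally leaves only ~15 pixels on a one-pixel band — so the
contour is instead sampled at uniform angular steps around the explant
centroid (a radial march to the first point at the mid offset, assuming a
star-shaped explant, which holds for real explant blobs), and each run of
labelled samples accumulates true arc length. Fascicles that split while
conserving total width leave the index near 1; distal widening — including
width-preserving branch addition — lowers it, and distal thinning raises
it. Note the index only probes the region between the proximal contour and
30% of the maximal growth distance: events planted beyond that window are
invisible to it by design, which the synthetic generator's `split_at`
parameter makes explicit.

## Transcript lateralization

Expression input is a probes × samples matrix of normalized intensities
with present/absent calls and an (embryo, side) design in which every
embryo contributes exactly one left and one right sample. Upstream
normalization and call generation are consumed, never computed.

`filter_expressed()` keeps a probe if it is called present in at least one
sample of *every* embryo and its maximal intensity reaches the
low-expression floor (default 200). The two gates commute, so their order
is immaterial. `detect_lateralized()` then calls a probe right-enriched
when its per-embryo log2(R/L) ratios all share a positive sign, their
*mean* exceeds log2(fold) (the mean is taken on the log2 scale, not as the
log of the mean ratio), and at least `min_embryos` (default 2) embryos
individually exceed the fold change in the consistent direction;
left-enrichment is the mirror rule. With the default 1.5-fold threshold
the log2 cutoff is 0.5849. All inequalities are strict — a probe sitting
exactly at the threshold is not called — and the comparisons carry an
absolute guard of 1e-9 on the log2 scale so that floating-point rounding
of a ratio constructed exactly at the boundary can never flip the
decision. Intensities are floored at 1 before ratios so zeros cannot
produce infinities; a per-embryo ratio of exactly zero breaks the
same-sign requirement and the probe is not called. Arrays carry up to two
probes per gene; the filter operates at probe level, with an optional
collapse to the highest-intensity probe per gene.

`category_proportions()` tallies annotation categories (e.g. Gene Ontology
cellular-component terms) per side, with unannotated probes pooled
explicitly, and `qpcr_relative()` implements reference-gene normalization
(relative expression `2^-(Ct_target − Ct_reference)`, right/left ratio per
embryo).

## Assay quantifiers

**RNAscope surface ratios** (`rnascope_lr_ratio()`): punctate in situ
signal is quantified as the supra-threshold surface fraction of the sum
projection within a region of interest, with the threshold computed on one
side and *cross-applied* to the other so the two sides are measured on a
common scale. The thresholding method is Otsu's between-class-variance
maximization, computed on the ROI-restricted pixel sample (a fixed-value
override is available). When the intensity histogram has an empty gap
between modes the Otsu criterion is exactly flat across the gap; the
threshold is placed mid-plateau, which is deterministic and matches
whole-image implementations. A zero supra-threshold surface on either side
yields an infinite log2 ratio flagged by `zero_surface = TRUE` with a
warning — never a silent number.

**Zymography fractions** (`zymography_fraction()`): the percentage of
marker-positive cells (Islet1/2+ motoneurons) with gelatinase activity per
side, and the right/left fold. Marker-negative cells never enter the
denominator.

**Blot normalization** (`normalize_blot_pairs()`): to compare left/right
band intensities across western blots, every replicate is rescaled so its
left + right sum equals the grand mean of the raw sums. Any common target
would do — the choice only fixes the display scale, since per-replicate
right/left ratios are scale-invariant; the grand mean keeps the values in
the units of the raw measurements.

## Statistics

Left/right comparisons in this field use small samples, so
`mann_whitney()` and `wilcoxon_signed_rank()` compute exact p-values:
the rank-sum null distribution is obtained by a subset-sum count over all
`choose(n1+n2, n1)` group assignments (up to 20 tie-free observations),
and the signed-rank null by the generating function of all `2^n` sign
assignments (up to 20 nonzero differences). Beyond those sizes, or with
ties in the rank-sum case, a normal approximation with midranks, tie
correction and a 0.5 continuity correction is used, and the `method` field
records which path was taken. Conventions: two-sided exact p is twice the
smaller tail, capped at 1; zero differences are dropped before ranking
(the Pratt variant, which ranks them first, is available via
`zeros = "pratt"`). Exact p-values are multiples of one over the number of
arrangements, and the tests' type-I error at any level is at most that
level. One caveat for reuse: paired left/right designs belong to the
signed-rank test, but published legends sometimes label such comparisons
Mann-Whitney; both tests are exposed and the choice is the analyst's.

`mean_sem()` returns the mean with the SEM (sample SD over √n); with a
single value the SEM is undefined and returned as `NA` rather than 0.

## Synthetic data

Every generator is deterministic per seed (the seed is recorded in the
returned `truth` object, which round-trips through JSON) and emulates the
study design rather than the optics — no photorealistic noise, staining
artefacts, tracing errors, or curved endplate bands.

- `make_nerve_pattern()` builds a hemidiaphragm from `pattern_params()`:
  a straight endplate band, an entry point at the stated perpendicular
  distance from the band's axis, two primary branches at the stated split
  angle, and evenly spaced secondary branches running from the primaries
  into the band, with optional Gaussian positional jitter. Presets
  `"E13.5/E14.5/E15.5-left/right"` carry the measured wild-type group
  means as parameters (e.g. 77.16 vs 188.51 µm and 6 vs 11 secondaries at
  E15.5, split angles 166° vs 132°, endplate thickness 254.9 vs 529.3 µm;
  the thickness values are only available at E15.5 and are reused for the
  earlier stages). The band is 2000 µm long by default: the tangent fit
  needs the band to be much longer than it is thick, and a length in the
  low millimetres matches an embryonic hemidiaphragm. Secondary
  attachment points are kept below 64% of the defasciculation distance so
  the default counting line at 80% always separates attachments from
  branch tips. `rasterize_pattern()` draws the same geometry as per-order
  masks (3-pixel strokes at 1 µm/pixel by default) so graph and raster
  quantifications can be compared on identical ground truth.
- `make_explant_image()` grows radial fascicles of constant pixel width
  from a circular border; a chosen fraction bifurcate at `split_at` of the
  maximal extent, either conserving total width (`"conserve"`, two
  half-width daughters) or preserving per-branch width (`"preserve"`,
  which doubles local total width).
- `make_expression_dataset()` emulates the paired design: 3 embryos × two
  sides, log-normal baselines around 1000, planted left/right-enriched
  probes multiplied by the fold on one side, i.i.d. log2-normal noise, and
  present calls below a call floor of 100. Planted probes get baselines of
  at least 500 so the expressed-transcript gate never hides planted truth
  — the generator is for testing the filter, not the gate.
- `make_cell_assay()` and `make_blot_replicates()` draw per-cell Bernoulli
  assay tables (defaults calibrated to the measured 23.4% / 37.9% active
  fractions at 792/797 cells) and per-blot left/right pairs centred on a
  chosen right/left ratio (default five replicates at 1.22).

What passing tests on these inputs do show: the estimators recover known
geometry and planted effects at the study's effect sizes, the filter's
decision boundary behaves as specified, and the exact tests hold their
size. What they do not show: robustness to segmentation errors, uneven
staining, curved or fragmented endplate bands, non-star-shaped explants,
or array normalization artefacts — those enter upstream of this package's
inputs.

## Numerical choices and problem sizes

- Raster conventions: masks are matrices indexed `[row, col]`, 0-based
  pixel coordinates with centres at integers, 1 µm/pixel unless stated.
- The principal-axis ratio cut-off for a valid tangent is 1.2; the
  counting-line band is one pixel; raster crossings split at gaps wider
  than 1.5 px along the line (8-connectivity).
- The test suite validates the exact tests against full-enumeration
  oracles at n ≤ 8 (200 instances), raster crossings against a
  connected-component oracle on 100 random patterns, and the
  lateralization filter against a per-probe loop oracle on 50 random
  100-probe matrices; the type-I error check runs 10,000 null simulations
  at n = 9 per group. These sizes make the full suite run in well under a
  minute while keeping Monte-Carlo error small relative to the asserted
  tolerances.

## Limitations

The package quantifies; it does not segment or trace. Nerve patterns come
from tracing (or the synthetic generator), masks from upstream
thresholding, expression matrices from array processing software. The
explant width measure assumes a star-shaped explant; strongly concave
borders would need a different contour parameterization. The muscle-domain
asymmetry score used alongside these measures in the literature is not
implemented, as its published description underdetermines the computation.
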