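---
title: "Quantifying adhesin-mediated kin discrimination: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adhesin-mediated kin discrimination: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floquant)
```

`floquant` quantifies three read-outs of Flo11A-mediated cell–cell adhesion
in yeast: aggregate-size distributions from plate images (QCAM), genotype
segregation in competing biofilm colonies from two-channel fluorescence
images, and maximum adhesion forces from single-cell force spectroscopy
(SCFS) force–distance curves. This vignette explains each procedure, the
parameters that matter, the synthetic-data generators used for validation,
and the numerical conventions chosen where the underlying experimental
protocols leave the algorithmic details open.

## Image substrate and conventions

All image pipelines operate on an `intensity_grid`: a numeric matrix of
intensities normalised to [0, 1] by the source bit depth's maximum, plus a
physical calibration in mm per pixel. Fixing the intensity domain makes a
global threshold mean the same thing for 8-bit and 16-bit acquisitions. The
calibration has **no default** — cameras differ, and silently assuming one
would corrupt every mm² value downstream — so `read_image()` requires it.
Pixels are addressed R-natively as `pixels[row, col]`, 1-based, origin at
the top-left.

Two generic operators deserve comment:

* **Otsu's threshold** (`otsu_threshold()`) maximises the between-class
  variance of a 256-bin histogram (256 matches 8-bit acquisition depth). The
  histogram spans the *observed* intensity range rather than a fixed [0, 1],
  which makes the threshold exactly equivariant under affine intensity
  rescaling — and therefore makes colony detection invariant to global
  exposure changes. Among tied maxima the middle boundary is taken, so a
  symmetric two-level image thresholds at its midpoint and the result is
  deterministic.
* **Watershed dissection** (`watershed_split()`) splits touching convex
  objects by flooding the Euclidean distance transform of the mask. Basins
  whose distance-map peak rises less than `tolerance` (default 1 px) above
  the separating saddle are merged. The tolerance formulation (rather than a
  minimum seed distance) is robust to the plateau maxima that perfect discs
  produce: an isolated round object always stays one label, while two
  overlapping discs of radius 20 px with centres 30 px apart split into two
  labels whose areas each land within 10% of a single disc.

Connected components use 8-connectivity for objects and the complementary
4-connectivity logic for background (hole filling), the standard duality
that avoids topological paradoxes.

## QCAM: aggregate size distributions

The pipeline (`run_qcam()`) follows the acquisition design: aggregates are
darker than the agar on a plate scan, so subtracting the scene from an
averaged cell-free background image simultaneously flattens the illumination
and inverts the contrast (`clamp(background − scene, 0, 1)`), leaving bright
clumps on a near-zero field. Segmentation then applies:

1. one **global threshold**, deliberately manual and shared by all images of
   an experiment (automatic per-image thresholds would confound the
   between-strain comparison that is the point of the assay);
2. **watershed dissection** of touching clumps — applied uniformly to every
   mask, since "obviously clumped" is not an algorithmic criterion; the
   tolerance is set so isolated round objects never split;
3. a **minimum object area** (default 5 px) replacing manual dust removal
   with an objective, reproducible rule.

Objects are converted to mm² (`area_px × pixel_size_mm²`) and binned into
four half-open size classes I (< b₁), II ([b₁, b₂)), III ([b₂, b₃)),
IV (≥ b₃). The default bounds (0.001, 0.01, 0.1) mm² are logarithmic decades
placing aggregates approaching 1 mm² in class IV; they are a declared
convention (`size_class_config()`) and fully configurable. The read-out per
image is the total area per class normalised to 1 cm² of field; replicates
are summarised by mean and sample SD per class. Two invariants pin the
arithmetic down: class totals sum exactly to `pixel_size² ×` (labelled
pixels), and raising the threshold can never increase total labelled area.

## Biofilm segregation: iterative Otsu and the edge ring

Competing strains tagged RFP/GFP are imaged through separate filters. The
colony footprint must be found without favouring either genotype, so both
channels are fused by pixelwise mean first. A single Otsu pass on the fused
image keeps only the brightest region and misses dimmer colony peripheries;
`detect_colony()` therefore *expands* the bright region iteratively:
recompute Otsu's threshold on the pixels still outside the mask, and accrete
newly-above-threshold pixels 8-connected to the mask.

The expansion loop needs a stopping rule, which the source protocols leave
unstated. Relying on a relative added-area cutoff alone is unstable: once
only featureless background remains, Otsu splits the noise histogram near
its middle and roughly half of the rim-adjacent background accretes each
iteration — a creeping noise halo. The package therefore also requires the
outside histogram to remain genuinely bimodal, measured by Otsu's own
separability `η = σ²_between/σ²_total` at the optimum. Pure Gaussian noise
yields η ≈ 0.64; a real dim-periphery/background mixture yields η near 1.
The default guard `min_separability = 0.8` sits between the two regimes.
Growth also stops when an iteration adds less than `stop_fraction`
(default 0.005) of the current area or after `max_iter` (default 10)
iterations; the final mask keeps the largest component with holes filled.
On a two-step phantom (bright core, dim annulus, dark background,
proportions chosen so the first Otsu pass provably keeps only the core) the
iterative expansion recovers the full colony exactly while a single pass
reaches IoU ≈ 0.38.

Channel normalisation subtracts each channel's median intensity *outside*
the colony (medium autofluorescence) and divides by its 99th percentile
*inside* (fluorophore gain). Median and high-percentile are used instead of
means and maxima for robustness to stray bright pixels; the exact statistics
are a declared convention. Genotype fractions are **pixel counts**, not
intensity sums: a pixel is RFP territory iff normalised RFP strictly
exceeds normalised GFP, ties counting against RFP (an intensity-weighted
variant would re-import the gain asymmetry the normalisation just removed).
The headline fraction is measured on the ring of colony pixels 50 px inside
the edge — the newest, still-growing cohort where founder effects of range
expansion are sharpest — implemented as the pixels whose distance to the
edge contour lies in [depth − 0.5, depth + 0.5), i.e. a one-pixel contour.
The dominance ratio is `max(f, 1−f)/min(f, 1−f)` from the edge fraction,
reported at a cap (default 1000) when the inferior fraction is 0, and banded
into five categories at (1.5, 4, 20, 100) — bounds that are again a declared,
configurable convention since only the banded presentation, not the numeric
cuts, is standard.

## SCFS: baseline correction and F_max

A force–distance curve records cantilever force against probe–target
separation for an approach and a retract segment (µm, nN). The retract
segment crosses zero as the contact force relaxes, dives into an adhesion
well as the cell–cell bonds load, and returns to the free-cantilever
baseline through discrete unbinding steps. `F_max` is the depth of that well
below the baseline, reported as a positive magnitude.

The baseline is estimated by a least-squares line on the final
`tail_fraction` of the retract segment — the fully separated regime, the
only part of the curve guaranteed free of interaction — and subtracted from
both segments, removing constant offsets and linear drift; `F_max` is then
`max(0, −min F_retract)`. The default tail is **40%** of the segment. The
choice is driven by extrapolation variance: the fitted line is evaluated
back at the adhesion well several µm away, so the slope error is amplified
by that lever arm. With Gaussian force noise σ the well-position baseline
error is ≈ σ·Δs/(sd(s_tail)·√n_tail); for a 20% tail this roughly doubles
the per-curve F_max noise, while a 40% tail keeps it well below σ/2. The
well vertex of the synthetic generator sits exactly on the sampling grid,
so noise-free recovery is exact to machine precision — a sharp regression
guard for the whole chain. F_max is invariant under constant force offsets
by construction (the intercept absorbs them).

Curves travel in a vendor-neutral delimited format (`# key: value` headers,
then `separation_um, force_nN, segment`); JPK or other vendor exports need a
one-off conversion, which is deliberately left outside the package. Group
summaries use the sample SD (n−1) and warn below 15 measurements per group,
the conventional minimum for reported averages; each curve counts as one
measurement, and any pooling across repeated probe–target pairs is the
caller's manifest decision. `adhesion_kinetics()` summarises F_max per
contact time (0.5–20 s is the meaningful range; beyond that probe cells tear
off the cantilever, which is an acquisition limit, not an analysis one).

## Statistical layer

Group comparisons use Welch's unequal-variance *t*-test (group spreads
visibly differ between variants, and assuming pooled variance would be the
stronger, unneeded assumption) and the Wilcoxon rank-sum test. Both are
two-sided throughout, and no multiple-testing correction is applied — the
assays report per-comparison stars. The Wilcoxon p is exact by enumeration
of all `choose(n1+n2, n1)` midrank assignments for pooled sizes ≤ 12 (924
combinations at worst; ties enter through midranks, which the standard
exact implementation refuses to handle), and a tie-corrected normal
approximation with continuity correction beyond. Spearman's rank correlation
— used to relate per-variant mean F_max to total aggregate area, the
cross-assay consistency check — enumerates all n! permutations for n ≤ 7 and
uses the t approximation above. Exactness cutoffs are set where enumeration
is cheap (≤ ~5000 evaluations) and approximations are still shaky. The star
mapping is boundary-inclusive exactly as conventionally printed: p = 0.05
earns \*, p = 0.001 earns \*\*\*.

Under 10,000 null replicates of n = 15 per group (standard normal), both
tests' empirical type-I error at α = 0.05 falls within [0.04, 0.06]
(`scripts/acceptance.R` recomputes this).

## What the synthetic data do and do not emulate

The generators are pure functions of their arguments including the seed
(bit-reproducible, global RNG untouched), and their defaults are the
validation conditions used throughout the tests:

* `gen_aggregate_scene()` — dark objects (discs/ellipses hitting target
  areas) on a bright, smoothly inhomogeneous background (tilt + broad bump,
  amplitude 0.1), object contrast 0.3, Gaussian pixel noise SD 0.01,
  optional deliberately touching pairs to exercise watershed. Truth records
  realised per-object pixel areas.
* `gen_biofilm_pair()` — colony of radius 150 px with a well-mixed core
  (40 px, per-pixel random genotype, the founding 1:1 inoculum) surrounded
  by radial sectors whose arc lengths realise the requested edge
  monopolization; channels rendered as gain × indicator + autofluorescence +
  noise with asymmetric gains (0.6/0.45) and autofluorescence (0.08/0.06),
  noise SD 0.02.
* `gen_force_curve()` — 1 nN contact force, 5 µm/s nominal speed, 400
  samples over 10 µm, adhesion well snapped to the grid, 1–3 discrete
  rupture steps, optional linear drift and Gaussian force noise.

They emulate the *geometry and contrast structure* the pipelines must
handle, not the physics: no optical point-spread function, no colony-growth
simulation (sectors are ideal wedges), no cantilever mechanics or worm-like
chain unbinding, additive clipped Gaussian noise only. Passing the recovery
tests therefore demonstrates that the pipelines measure what they claim on
images with known answers — not that a particular threshold or bound is
right for any given microscope; the global QCAM threshold in particular
remains a per-experiment manual choice by design.

Validation problem sizes are chosen to give the properties room to fail
while staying light: 600² px scenes with 40 objects (ten per size class) for
QCAM recovery within 2%; six colonies spanning edge monopolization 0.5–1.0
recovered within ±0.03; 200 noisy curves (σ = 0.1 nN, drift 0.2 nN/µm) with
every per-curve F_max error below 0.5 nN; 10,000 null replicates for test
calibration.

## Degenerate inputs and edge cases

Constant images have no Otsu threshold (error, by contract); all-true or
all-false masks have no boundary distance (error); colony masks must leave
at least 1% background to estimate autofluorescence; an edge ring deeper
than the colony inradius is an error rather than an empty silent result; a
channel with no signal above autofluorescence is a degenerate-channel error.
Equal-mean zero-variance samples yield t statistic 0 with p 1 rather than an
error, matching how such degenerate comparisons are reported in practice.
Single-image QCAM runs and single-member groups report SD 0 with a warning.

## Known limitations

* The edge ring is a 1-px contour; protocols that mean a wider band at
  "50 px from the edge" should sample several depths.
* Watershed over-splits strongly elongated objects only if their distance
  ridge undulates by more than the tolerance; raise `tolerance` for such
  morphologies.
* The F_max extractor reports the global retract minimum; individual
  unbinding events (rupture-step statistics) are out of scope.
* `detect_colony()` assumes one colony per image (largest component wins).
* Real plate images may need flat-field handling beyond a single averaged
  background image; only that correction is implemented.
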