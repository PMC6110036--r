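---
title: "Methods: vessel morphometry, densitometry and TOPSIS efficacy ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vessel morphometry, densitometry and TOPSIS efficacy ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmorph)
```

# Scope and model

`vesselmorph` implements the quantitative core of a balloon-injury
intimal-hyperplasia study: per-slice vessel morphometry, IOD-based
protein-expression quantification, group statistics, and a
multi-criteria efficacy ranking. Everything upstream of measured
contours and IODs — surgery, staining, image acquisition, segmentation,
band detection — is out of scope; the pipeline starts from geometry and
densities.

## Morphometry

A vessel cross-section is represented by three nested simple polygons:
the inner boundaries of the external elastic lamina (EEL) and internal
elastic lamina (IEL), and the lumen boundary, with vertices in
continuous µm coordinates (no pixel grid). Areas are absolute shoelace
areas, invariant to orientation, cyclic vertex rotation and rigid
motion. From the area triple the six indices are

$$MA = A_{EEL} - A_{IEL}, \qquad IA = A_{IEL} - A_{lumen},$$
$$MT = r(A_{EEL}) - r(A_{IEL}), \qquad r(A) = \sqrt{A/\pi},$$
$$HRIA = \frac{IA}{IA + MA}, \qquad HRIT = \frac{IT}{IT + MT}.$$

**The IT ambiguity.** The source formula for intimal thickness is
printed with the *outer* elastic membrane as first operand,
$IT = r(A_{EEL}) - r(A_{lumen})$, which includes the media; measured
anatomically the intima spans IEL to lumen. Both are implemented:
`mode = "printed"` (default, faithful to the printed convention) and
`mode = "anatomical"`. A consequence of printed mode worth knowing: an
uninjured vessel has $IT = MT$, so $HRIT = 0.5$, not 0, while $HRIA = 0$
still identifies the uninjured state; anatomical mode gives $HRIT = 0$.
We also read the printed formulas' "area/π" operands as equivalent-circle
radii $\sqrt{A/\pi}$ — the only reading with length units, and the
standard morphometric convention.

**Degenerate inputs.** Nesting $A_{EEL} \ge A_{IEL} \ge A_{lumen} \ge 0$
is validated with a $10^{-9}$ relative tolerance and violations name the
offending slice. Zero denominators (an uninjured vessel with
$IA + MA > 0$ but $IA = 0$, or a fully collapsed annulus) return ratio 0
rather than an error, so normal groups flow through the pipeline.

**Aggregation.** The 8 slices cut from one vessel are repeated
measurements, not independent replicates: the animal value is the mean
over its slices, and the group value is mean ± sample SD (n − 1
denominator) over animals, n = animals. Whether the original analysts
did this or pooled slices is not stated anywhere; slice-level pooling
would understate between-animal variance, so animal-level averaging is
the defensible choice and is applied consistently to morphometry and
IHC.

## Densitometry

IHC expression for a slice is the mean IOD of its (default 3) fields;
the animal value is the mean of slice means. Western-blot relative
expression is target-band IOD divided by the beta-actin band IOD of the
same lane, which cancels common exposure scaling. Positivity
thresholding inside a field is upstream wet-lab work and is not
modelled. No hypothesis testing happens in this module.

## Group statistics

One-way fixed-effects ANOVA (direct sums of squares; equivalent to
`oneway.test(var.equal = TRUE)` and verified against it in the tests)
provides the omnibus test and the pooled variance. Post-hoc comparisons
against designated reference groups (normal, model, positive control)
default to Fisher's LSD on the pooled MSE with df = N − k; the original
analysis names no post-hoc method, so the method is pluggable
(`"welch"` as the non-pooled alternative) and we do not claim to
reproduce the original choice. P values map to the two-tier convention
(`p<0.05`, `p<0.01`) and **no multiplicity correction** is applied
across indices or proteins — matching the reporting convention being
emulated, and stated here explicitly so nobody mistakes the output for
familywise-corrected inference. Perfect separation (zero within-group
variance) is flagged and reported as $F \to \infty$, $p = 0$; an
all-constant data set is flagged as degenerate with $F$ undefined.

## Efficacy ranking (single-factor fuzzy comprehensive evaluation)

The judgement set is the injured groups (the normal group is excluded by
default — it is not a treatment); the evaluation factor set defaults to
{HRIA (%), HRIT (%)}. Both are **cost** criteria: less residual
hyperplasia means better efficacy. This direction is forced by the
published worked example, where the model group (worst hyperplasia) has
closeness 0 and the best treatment has closeness 1.

TOPSIS procedure: normalize the group × criteria matrix, apply
criterion weights, take the per-criterion best (ideal) and worst
(anti-ideal) values, measure Euclidean distances $D^+$, $D^-$ of each
group to them, and compute the closeness grade

$$C = \frac{D^-}{D^+ + D^-} \in [0, 1],$$

dense-ranked in descending order (tied C share a rank; the next distinct
C takes the next integer — the published table's 7/7/8 pattern).

Design choices where the source is silent:

* **Normalization**: unstated in the source; classic vector
  normalization (column ÷ Euclidean norm) is the default, with
  direction-aware min–max and pass-through selectable. The acceptance
  surface deliberately relies only on the scheme-independent identity
  $C = D^-/(D^+ + D^-)$ applied to the *published* distance pairs, plus
  rank order — the unpublished group means cannot be recovered, so raw
  $D$ values are never asserted.
* **Weights**: equal (0.5, 0.5); none are named in the source.
* **Ties**: ranks are computed on unrounded C; exact ties (identical
  criterion rows) produce exact floating-point ties. C is additionally
  reported rounded to 3 decimals for table comparison.
* **Degenerate matrix**: a single-point matrix gives $D^+ = D^- = 0$;
  C is defined as 1 with a warning rather than NaN.

# The synthetic cohort: what it emulates and what it does not

The generator emulates the study design — ten groups (normal, model,
two single herbs, five herb ratios, atorvastatin; dose labels are
metadata only), 8 animals per group, 8 slices per vessel, 3 IHC fields
per slice — as a *stated world* with known truth, so downstream modules
can be tested for parameter recovery.

Geometry: each section is three star-shaped polygons (default 128
vertices; a regular 128-gon's area differs from its circle by < 0.05%,
far below every tolerance used). The lumen centre is offset by
`eccentricity × intimal thickness`, producing the concentric/eccentric
stenosis phenotypes seen on injured vessels. Noise is multiplicative
lognormal with mean 1 throughout — positivity is guaranteed and the cv
parameterization is exact.

Noise layering: the group `cv` (default 0.1, a typical between-animal
biological cv for this kind of morphometry) applies at the animal level;
slices within an animal vary at `cv/2`; vertex-level jitter runs at
`cv/5`. Full-strength vertex noise would break ring nesting on nearly
every section with a thin intima (independent ±10% radial spikes on a
30 µm annulus), so the bulk of the variance is carried where it matters
statistically — between animals — and nesting is still enforced by
truncating offending vertex radii at a 0.5 µm floor (the section records
whether the floor fired). When the sampled intimal thickness is exactly
0, the lumen boundary *is* the IEL ring: an uninjured vessel has no
separate lumen contour, and drawing one independently would bias the
normal group's IA away from 0 through the nesting cap.

Default effect sizes: media thickness 80 µm everywhere (medial indices
do not separate groups, as in the emulated study); lumen radius 350 µm
(normal), 250 µm (model stenosis), 300 µm under treatment; intimal
thickness 0 (normal), 130 µm (model) and strictly ordered over the
eight treated groups from 21 µm (ratio 1:1) to 88 µm (ratio 2:1).

**Why this grid.** The design targets are (a) model HRIA ≈ 0.5 and best
treatment ≈ 0.2 (the qualitative pattern of the emulated study's bar
charts — simulation defaults, not claims about unpublished data), and
(b) recoverability of the configured order by the end-to-end ranking in
≥ 95% of seeds at cv 0.1, n = 8. The per-animal SD of HRIA has two
comparable contributions — the intima term
$f'(t)\,\sigma_t \approx 0.02$–0.025 and the media term
$\approx 0.02$ (a first analysis that neglected the media term produced
too-narrow spacing and only ~87% recovery; the grid was recalibrated
once from the corrected variance budget, not by searching seeds). With
$\sigma_{HRIA} \approx 0.03$ per animal, the group-mean difference SE at
n = 8 is ≈ 0.015, so adjacent groups need ≈ 0.04 in mean HRIA for
≳ 2.5 SE separation: the default grid spaces mean HRIA almost evenly
over 0.18–0.55 (0.55 and 0.18 still being "≈ 0.5" and "≈ 0.2" for
target (a)). The fixed-seed acceptance test recovers the full order in
95/100 seeds.

Densitometry defaults emulate a proliferation marker (`pcna`, ~2× in
the model group) and a contractile marker (`sma_actin`, ~0.5× in the
model group), interpolated toward normal in proportion to each group's
residual intimal effect, with beta-actin reference IODs around 10⁴.

**What a green test does not establish.** The generator produces smooth
star-shaped rings with lognormal noise; real sections have irregular,
non-star-shaped laminae, tissue folds, oblique cuts, and segmentation
error that is neither multiplicative nor independent. Group effects
here are exactly proportional between HRIA and HRIT, which makes the
two criteria nearly collinear — real criteria can disagree, and the
ranking's behaviour under conflicting criteria is exercised only by the
randomized property tests, not by the cohort. Passing the recovery test
shows the pipeline's statistics are consistent with its own stated
world, not that the biological conclusions of any study are correct.

# Reproducibility and numerics

All randomness flows from one root seed: the cohort consumes it
directly and densitometry uses a fixed offset substream (+1000), so
stages can be regenerated independently. Pipeline runs are
byte-identical for a fixed config and seed (the run log records package
and R versions and the seed; no timestamps enter artifacts).
Self-intersection validation of polygons is O(n²) per contour and is
skipped (by default) for generator output, which is simple by
construction — radial polygons cannot self-intersect.

# Known limitations

* Slices are averaged per animal; a mixed model treating slice as a
  nested level is out of scope by design.
* The LSD default reproduces a two-tier star convention but the original
  post-hoc method is unknowable from the source.
* Printed-mode HRIT has a floor of 0.5 for uninjured vessels (see
  above); cross-study comparisons of HRIT should state the mode.
* The bundled worked example fixes the published distance pairs; the
  group means that generated them were never published, so the chain
  from raw means to those exact distances cannot be reproduced, only the
  closeness/ranking identity on top of them.
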