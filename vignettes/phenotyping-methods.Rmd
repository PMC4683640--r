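---
title: "Methods: computational phenotyping of male reproductive traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: computational phenotyping of male reproductive traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the choices made where the
design was genuinely open. The package covers three layers of a
strain-panel survey of male reproduction: quantitative testis histology
from section images, sperm-track kinematics with motility-pattern
classification, and the strain-level statistics that turn animal
measurements into comparable strain phenotypes. Because the original
animals and images are not redistributable, every layer is paired with a
synthetic generator that produces inputs with known ground truth; all
quantitative claims in the tests are made against that ground truth.

## Testis histology

### Detection model

A transverse testis section shows many roughly circular seminiferous
tubule cross sections (and possibly a rete testis region) in stained
tissue. Centers are detected by a pixel classifier:

* **Features.** At each pixel, the concatenation of per-channel intensity
  histograms over a square window centered there (window 21 px,
  8 bins/channel by default, so 24 features), each channel normalized to
  sum 1. Windows shrink at image borders. Color histograms carry no
  geometry, which is exactly why they work here: a window centered in a
  tubule lumen is dominated by pale lumen pixels, a window in the
  epithelium ring by stain, a window in interstitium by its own hue.
  The default window was chosen so that a window at the center of a
  *small* tubule (radius about 20 px at the default scale) still sits
  mostly inside the lumen; with substantially larger windows, small-tubule
  centers become indistinguishable from epithelium and recall drops.
* **Classifier.** A probability random forest (200 trees) over three
  classes: background, tubule-center core, rete-center core. Training
  uses at most 0.1% of the pixels of the annotated training sections.
  Positives are pixels within 0.3 x the object's radius of an annotated
  center ("center core"); the positive budget is stratified per object so
  small tubules contribute as many training pixels as large ones.
  Negatives are sampled uniformly from everything else. All sampling and
  forest construction are seeded.
* **Localization.** The per-pixel core probability map is
  Gaussian-smoothed (sigma 6 px by default), thresholded at 0.5, and each
  connected supra-threshold component is reduced to one candidate at its
  probability-weighted centroid; greedy non-maximum suppression then
  enforces a minimum separation between detections. The centroid-per-
  component step matters because a wide lumen (or the rete's duct region)
  produces a probability *plateau* on which several local maxima can
  survive plain suppression, each offset from the true center; the
  centroid of the component is both unique and well centered. The
  suppression distance defaults to 1.2 x the expected tubule radius in
  the pipeline: large enough that one lumen cannot yield two detections,
  and safely below the smallest possible separation of two genuine
  neighbouring centers (the sum of their radii plus the interstitial
  gap).

Detection quality is scored by greedy one-to-one matching of detections
to ground-truth centers within half the true radius of each object;
recall is matched/truth, and the type-1 error is unmatched detections as
a percentage of the truth count per image. The per-truth denominator is a
choice (the source bound "per image" does not state one) and is the
stricter reading at realistic detection counts.

### Radii and section metrics

The radius of each cross section is estimated as half the distance to the
nearest neighbouring center — the survey's rule. Note its geometry: the
rule is exact when neighbouring tubules touch, and overestimates radii in
proportion to the interstitial slack. On synthetic sections with a
12 um minimum gap and random packing the estimate runs some 20-25% above
the true radii; on tightly packed real tissue the bias is smaller. All
downstream metrics take whatever radii they are given:

* number of tubule cross sections (rete excluded from all metrics);
* mean tubule radius (um);
* seminiferous epithelium length = mean radius x 2 x pi x tubule count;
* abnormality counts: tubules with vacuoles, with "many" vacuoles
  (>= 3 by default — the survey never quantified "many", so the
  threshold is a configurable parameter, not biology), with germ cell
  loss, with abnormal germ cells, with sloughing.

Manual review is file-driven rather than interactive: a correction set
(additions, deletions, relabels) is applied to the detected records, and
radii are recomputed afterwards because deletions and additions change
nearest neighbours. Re-applying an already-applied correction set is a
no-op; adding a duplicate of an automatically detected center is an
error.

## CASA kinematics and motility classification

### Parameters

A track is 90 head positions at 60 Hz (1.5 s). With duration
`T = (n-1)/fps`:

* `VCL` — raw polyline length / T (um/s);
* `VSL` — |last - first| / T;
* `VAP` — length of the *average path* / T, where the average path is a
  centered moving average (5 frames by default) whose window shrinks
  symmetrically at the ends, preserving the endpoints — the instrument's
  own smoother is proprietary, so a transparent one is used;
* `ALH` — 2 x the mean perpendicular deviation of the raw track from the
  average path (the "2 x mean" convention; vendors differ between
  2 x mean and 2 x max, and the alternative is a parameter);
* `BCF` — sign changes of that signed deviation / T;
* `STR = VSL/VAP`, `LIN = VSL/VCL`, stored as fractions in [0, 1], zero
  when the denominator is zero.

These definitions guarantee `VSL <= VCL` (triangle inequality),
`VAP <= VCL` (averaging shortens paths) and `STR <= 1` (the average path
preserves endpoints), which the tests assert over randomized tracks, along
with invariance under rigid motions. Under-sampling is real: at 60 Hz an
8 Hz beat is cut at ~7 samples/cycle and VCL reads a few percent short of
the continuous path; the dense-grid oracle test quantifies this at
beat parameters where the discretization error is within 5%.

A track is **motile** if `VCL >= 25 um/s` or its net displacement is
`>= 4 um`; both gates are deliberately permissive because in this
protocol slow sperm count as motile, and "static" is reserved for tracks
that barely move at all.

### The SVM cascade

Motile tracks are classified into five patterns — progressive,
intermediate, hyperactivated, slow, weakly motile — by a cascade of
binary SVMs (RBF kernel, features standardized by the training mean/sd):
first vigorous (progressive + intermediate + hyperactivated) vs
nonvigorous, then hyperactivated vs the rest of vigorous, then
progressive vs intermediate, and slow vs weakly motile on the nonvigorous
side. The published classifier of this design ships fixed decision
boundaries for one mouse stock; those constants are not public, so the
model here is *trained* on labelled tracks (synthetic by default) rather
than hard-coded. Static tracks must be gated out before classification;
the cascade never assigns "static".

Time-course profiles report, per nominal incubation minute (10, 30, 60,
90, 120), the percentage of motile sperm in each class (summing to 100),
the percent motile over all tracks, and percent vigorous = progressive +
intermediate + hyperactivated.

## Strain-level statistics

* **Modified z-score** per strain and trait:
  `z = 0.6745 (strain median - population median) / MAD`, with the MAD
  taken raw (no 1.4826 consistency factor — the 0.6745 multiplier plays
  that role), falling back to
  `z = 0.98 (strain median - population median) / mean absolute
  deviation` when the MAD is zero. The population median pools all
  animals of all strains, including the strain being scored. Classes are
  strict: `z > 3` very high, `1 < z <= 3` high, symmetric on the negative
  side; boundary values are *not* outliers. A strain with zero spread off
  the population median gets a signed infinite score with a warning.
* **Broad-sense heritability** `h2 = VA / (VA + VE)`. The survey states
  the ratio but not the estimator, so two are provided: the default takes
  VA as the sample variance of strain means and VE as the unweighted mean
  of within-strain variances (which leaves VE/n of sampling noise inside
  VA — about 0.01 at 25 animals/strain); the alternative is the one-way
  ANOVA method-of-moments, `VA = (MSB - MSW)/n0` clipped at zero. On
  balanced data with >= 25 animals/strain they agree within 0.02. With 8
  strains the sampling spread of any estimator is large (the variance of
  a variance over 8 draws), so single-table estimates scatter around the
  truth with an sd near 0.1; recovery claims are therefore made on
  replicate means.
* **Correlations** are pairwise-complete Pearson: each trait pair uses
  the rows where both are present; cells with fewer than 3 complete pairs
  are reported missing.
* **ANOVA**: one-way for a single grouping factor, and the two-way model
  `trait ~ strain + age + strain:age` with age *continuous in days*
  (the survey never defines age bins) and sequential type-I sums of
  squares in that order. Missing trait values are dropped per trait.
  No multiple-testing correction is applied anywhere, matching the
  survey's analysis.

## Synthetic generators: what they emulate, and what they do not

* **Sections** (`gen_histology`): an elliptical tissue region packed with
  non-overlapping circles by rejection-sampled dart throwing (largest
  first; failure after a bounded number of attempts signals an infeasible
  config). Each tubule is an annulus — stained epithelium ring around a
  pale lumen — on pale-pink interstitium; vacuolated tubules carry small
  white ellipses in the ring; germ-cell-loss tubules have a thinned ring
  (lumen at 0.8 x radius instead of 0.45 x); one rete region is rendered
  as a pale duct area with stained strands. Radii are lognormal
  (moment-matched mean 80 um, sd 12 um at 2.5 um/px), 40 tubules per
  section, minimum gap 12 um, vacuole probability 0.2 with a decaying
  count law on 1..10, germ-cell-loss probability 0.08; independent
  Gaussian pixel noise (sd 0.02) is added last. The palette and geometry
  are sufficient for color-histogram features to be informative, which is
  the property the detector relies on in real stained tissue; the
  generator does *not* attempt photorealism, spermatogenic staging,
  tile-stitching artifacts, or stain variation between slides — so
  passing detection bounds here demonstrates the pipeline's mechanics,
  not robustness to staining drift.
* **Tracks** (`gen_tracks`): constant-speed drift along a slowly
  wandering heading, plus a sinusoidal lateral beat perpendicular to it,
  plus Gaussian positional jitter; the five classes differ only in
  parameter ranges (speed, beat amplitude/frequency, heading-change rate,
  jitter). Defaults were set once so the classes are separable by
  (VCL, LIN, ALH) by construction — progressive fast and straight,
  hyperactivated dominated by a 10-16 um beat with little progress,
  weakly motile under 5 um of net displacement in 1.5 s — and so the
  fastest tracks reach the >300 um/s curvilinear velocities seen in the
  fastest wild-derived strains. Real sperm change pattern within a track
  and interact with walls; these tracks do not.
* **Phenotype tables** (`gen_phenotypes`):
  `y = grand_mean + strain_effect + age_slope x age + noise` with strain
  effects drawn at variance `va`, residuals at `ve`, ages uniform on
  70-461 days (the survey's observed range), and optional missingness.
  8 strains x 25 animals by default, mirroring the survey's scale
  (>20 males per founder strain).

Every generator consumes one integer seed and is a pure function of its
config; identical configs give bit-identical output, and all randomness
is restored to the caller's RNG state afterwards.

## Problem sizes and numerical choices

The detection benchmark uses 12 default-scale sections (~40 tubules plus
one rete each), trains on 6 with at most 0.1% of their pixels, and
evaluates on the 6 held-out sections; this finishes in a couple of
minutes on one CPU and is the scale at which the recall/type-1 bounds are
asserted. Heritability recovery uses 200 replicate tables per true h2 on
the {0.1, 0.3, 0.5, 0.7, 0.9} grid at 8 strains x 25 animals. Kinematic
invariants are asserted over 1000 random tracks.

CSV files are written with doubles at 17 significant digits and read back
with a correctly rounded parser, so write/read cycles are bit-exact.
Images travel as 8-bit PNG (1/255 quantization — well below the pixel
noise), annotations and corrections as JSON with 0-based (row, col) pixel
coordinates and radii in micrometres.

## Known limitations

* The nearest-neighbour radius rule inherits the packing bias described
  above; epithelium length scales with it.
* The published survey's per-strain trait values cannot be recomputed
  without its animal-level supplementary tables, which have no public
  programmatic accession; `reproduce_study_table()` runs the full
  statistics layer on such a table when the user supplies one.
* The detector is trained and validated on the synthetic stain model;
  applying it to real slides requires retraining on a small annotated
  subset of those slides (which is the intended workflow — the training
  budget is <0.1% of pixels precisely so that annotation stays cheap).
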