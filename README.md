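# spermatoscope

Computational phenotyping of male reproduction for inbred strain panels:
quantitative testis histology from stained section images, CASA sperm-track
kinematics with five-class motility classification, and the strain-level
statistics that make traits comparable across a panel. It is aimed at
groups running strain surveys (e.g. across the founder strains of a
multiparental panel) who need the image analysis, track analysis and
statistics of such a survey in one tested, reproducible pipeline — plus
synthetic generators with known ground truth so every stage can be
validated without animals.

## What it computes

**Histology.** Seminiferous-tubule cross-section centers are detected by a
random forest over local color-histogram features (trained on less than
0.1% of the pixels of a few annotated sections), localized from the
smoothed probability map, and optionally corrected from a review file.
Radii follow the nearest-neighbour rule
*r*<sub>i</sub> = ½ min<sub>j≠i</sub> d(c<sub>i</sub>, c<sub>j</sub>), and
section metrics include the seminiferous epithelium length

> epithelium length = mean tubule radius × 2π × number of tubule cross sections

together with counts of tubules with vacuoles, many vacuoles, germ cell
loss, abnormal germ cells and sloughing.

**CASA.** Each 90-frame, 60 Hz head track is summarized by VAP, VSL, VCL
(µm/s), ALH (µm), BCF (Hz), STR = VSL/VAP and LIN = VSL/VCL; a permissive
gate (VCL ≥ 25 µm/s or net displacement ≥ 4 µm) separates motile from
static, and a cascade of RBF SVMs classifies motile tracks as progressive,
intermediate, hyperactivated, slow or weakly motile, with capacitation
time-course profiles (percent vigorous = progressive + intermediate +
hyperactivated).

**Strain statistics.** Per-strain modified z-scores
z = 0.6745 (strain median − population median)/MAD, with the
0.98/mean-absolute-deviation fallback when the MAD is zero, classified at
strict ±1/±3 thresholds; broad-sense heritability h² = V<sub>A</sub>/(V<sub>A</sub> + V<sub>E</sub>)
under two variance-component estimators; pairwise-complete Pearson
correlations; one-way ANOVA and the two-way model
trait ~ strain + age + strain:age with age continuous in days.

See `vignettes/phenotyping-methods.Rmd` for the full model descriptions,
parameter defaults and design rationale.

## Worked example

```r
library(spermatoscope)

# 1. render a synthetic testis section and detect tubule centers
section <- gen_histology(histology_sim_config(seed = 1L))
train <- lapply(2:4, function(i) gen_histology(histology_sim_config(seed = i)))
clf <- train_center_classifier(train, lapply(train, `[[`, "truth"),
                               training_fraction = 0.001, seed = 1L)
centers <- localize_centers(predict_center_map(section, clf),
                            min_distance_px = 1.2 * 80 / section$um_per_px)
quality <- evaluate_detection(section$truth, centers,
                              0.5 * section$truth$radius_um / section$um_per_px)
records <- make_tubule_records(centers, section$um_per_px)
metrics <- compute_metrics(records)

# 2. CASA kinematics + five-class motility classification
kin <- kinematics_table(gen_tracks(track_sim_config(n_per_class = 60L, seed = 2L)))
kin$motile <- is_motile(kin)
model <- train_motility_svm(kin[kin$motile, ], seed = 1L)
held <- kinematics_table(gen_tracks(track_sim_config(n_per_class = 60L, seed = 3L)))
held$motile <- is_motile(held)
acc <- mean(classify_tracks(model, held[held$motile, ]) == held$class[held$motile])

# 3. strain statistics on a simulated 8-strain phenotype table
pheno <- gen_phenotypes(pheno_sim_config(va = 0.7, ve = 0.3, seed = 4L))
heritability(pheno, "trait")
strain_summaries(pheno, "trait")
```

This prints (numbers from the code as run):

```
recall 95.1%, false positives 0.0%
39 tubules, mean radius 95.7 um, epithelium length 23439 um
motility SVM held-out accuracy: 100.0%
     va    ve    h2
1 0.577 0.310 0.650
  strain median     z z_class
1 S02    -0.499 -1.06 low
2 S05     1.34   2.15 high
3 S07    -1.08  -2.57 low
```

Reading the output: the detector recovered 39 of the section's 41 true
centers (95.1% recall) with no spurious detections; the mean
nearest-neighbour radius estimate (95.7 µm) runs above the generator's
true 80 µm mean because the rule attributes interstitial slack to the
tubules (see the vignette); the h² estimate 0.65 sits within the sampling
spread expected around the true 0.70 for an 8-strain panel; and three
simulated strains are flagged as modified-z outliers for the trait.

The `analysis/` directory holds the same workflow as numbered drivers —
`01_simulate.R`, `02_histology.R`, `03_casa.R`, `04_strain_stats.R` —
each writing its tables under `results/`. `run_pipeline()` ties the
stages together behind one config with a checksum manifest.

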