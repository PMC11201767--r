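---
title: "Depth-stratified quantification of DNA damage and senescence markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-stratified quantification of DNA damage and senescence markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexlam)
```

## The analysis

cortexlam quantifies how two immunofluorescence markers distribute across
the depth of the cortical gray matter: 53BP1, which accumulates at DNA
double-strand breaks and marks damaged nuclei, and p16^INK4a^, a
cyclin-dependent-kinase inhibitor used as a cellular-senescence marker.
The unit of analysis is the *radial zone*: a cortical column bounded by the
pia and the white matter is divided into six equal depth bands (Zone 1 at
the pia, Zone 6 at the white matter), a surrogate for the histological
layers I–VI.

The pipeline has four stages:

1. **Detection** (`detect_nuclei`, `expand_pseudoplasm`, `measure_cells`,
   `classify_positive`): nuclei are segmented in the DAPI channel by
   Gaussian smoothing, a global threshold, hole filling and a
   distance-transform watershed; each nucleus is then expanded by 5 µm
   following its shape into a non-overlapping perinuclear annulus
   ("pseudoplasm") used to sample cytoplasmic staining. A cell is
   marker-positive when its nuclear mean intensity strictly exceeds the
   channel threshold.
2. **Zonation** (`build_columns`, `zone_points`, `build_zones`,
   `assign_zone`): column lines connect points at equal arclength
   fractions along the pia and white-matter boundaries; each line carries
   its endpoints plus five equidistant interior points, and connecting
   matched points across adjacent lines yields six quadrilateral zones per
   column. Cells are assigned to zones by their centroid, with
   boundary ties going to the pia-ward zone.
3. **Statistics** (`zone_summary`, `fit_linear`, `fit_quadratic`,
   `compare_models`, `two_way_anova`, `size_ranked_profile`,
   `coupling_regression`, `subset_intensity_profiles`,
   `culture_fractions`): the central model is the quadratic depth profile
   of the 53BP1-positive fraction,
   $f(z) = a + b\,z + c\,z^2$ over the zone index $z = 1,\dots,6$, fitted
   by ordinary least squares to one observation per case × zone. The
   quadratic is compared with the linear profile by adjusted $r^2$ and a
   partial F-test; for an inverted-U profile the vertex $-b/(2c)$ locates
   the depth of maximal damage.
4. **Synthesis** (`generator_config`, `sample_cells`,
   `assign_intensities`, `render_image`, `simulate_culture`): a generative
   model of the same statistical structure, used as ground truth for every
   stage.

## The generative model and its defaults

No deposited data accompany the study this package models, so the
generator's defaults *are* the study conditions, chosen once to reproduce
the published summary statistics:

* **Damage profiles.** AD: $p(z) = 0.0201 + 0.0955\,z - 0.010612\,z^2$
  (clipped to [0, 1]), peaking between Zones 4 and 5 with mean 19.3%
  across zones; UC: flat 5.5%. These encode a roughly 3.5-fold AD/UC
  difference with an inverted-U AD profile.
* **Cases.** 4 AD and 3 UC cases. A per-case random effect (sd 0.15 on
  the logit of the positive probability) spreads cases around the profile;
  the drawn effects are centered within each cohort so that between-case
  spread does not move the cohort-mean fraction, which is what the
  between-case variability is meant to model.
* **Cells per case.** Default 2000 — a desk-scale compromise: per-zone
  binomial noise and the between-case effect are then comparable, which
  keeps the zero-slope test on flat (UC) cohorts close to its nominal
  level while quadratic fits on AD cohorts still localize the vertex
  inside (4, 5) in ~96% of cohorts.
* **Nuclear sizes.** A neuron/glia log-normal mixture: 40% neurons with
  mean area 79 µm², 60% glia with mean 28 µm², both with log-sd 0.25 —
  neurons clearly larger, with overlap.
* **53BP1 intensity.** Log-normal, log-mean log(20) for negative and
  log(100) for positive cells (log-sd 0.3), plus a shallow size term
  κ = 0.1 a.u./µm² about the mixture mean area. Intensity units are
  arbitrary throughout; only ratios, correlations and test statistics are
  meaningful.
* **p16 coupling.** Among damage-positive cells, nuclear p16 =
  10 + 1 × i53BP1 + slope·zone + ε with sd(ε) equal to
  `coupling_noise_ratio` times the sd of 53BP1 intensity among positives.
  With a unit coupling slope the population $r^2$ of p16 on 53BP1 is
  $1/(1+\text{ratio}^2)$: the AD default ratio 0.62 targets $r^2 = 0.72$,
  the UC default 1.60 targets $r^2 = 0.28$. The depth term (3 a.u./zone in
  AD, 0 in UC) reproduces the robustly significant AD depth trend of
  nuclear p16; it dilutes the AD coupling $r^2$ only to ≈ 0.71.
  Damage-negative cells get baseline 15 plus the same depth slope and
  Gaussian noise (sd 5); the perinuclear compartment gets baseline 12 and
  a weak depth slope 0.5, identical across conditions.
* **Placement.** Nuclei are placed by hard-core rejection sampling with an
  8 µm minimum spacing (50× oversampling before a packing error);
  `min_spacing = 0` switches to independent uniform placement, the fast
  path used by repetition-heavy statistical simulations where geometry is
  irrelevant.
* **Culture.** γ-H2AX-positive probabilities 5% (control), 18% (1 µM
  etoposide — a placeholder between the published endpoints) and 38%
  (10 µM); p27-positive probability 15% in every condition, with p27
  intensity drawn independently of γ-H2AX, encoding the observed absence
  of a senescence response 24 h after damage induction.

## Rendering and detection

Rendered images are deliberately simple: each nucleus is an isotropic
Gaussian blob with σ equal to half the equivalent nuclear radius,
amplitude proportional to the channel intensity (constant in DAPI), over a
constant background of 10 counts with Poisson shot noise; the default
synthetic pixel size is 0.5 µm/px (configurable — whole-slide scanners
typically deliver 0.325 µm/px). There is no optical PSF, no autofluorescence
gradient, no out-of-focus light, no stain bleed-through, and cytoplasmic
p16 is not rendered (perinuclear statistics run on the ground-truth
tables). Detection performance on these images — precision and recall
≥ 0.95, Spearman ≥ 0.9 between measured and generating intensities —
therefore validates the *bookkeeping* of the pipeline (segmentation,
partition, measurement, thresholds, zonation, statistics), not robustness
to the artifacts of real tissue.

## Numerical choices

* Positivity is a strict inequality (a value exactly at the threshold is
  negative).
* The automatic intensity threshold is the kernel-density valley between
  the two most prominent modes, with an iterated two-class inter-mean
  split as fallback for weakly bimodal data.
* Annulus partition: each background pixel within the expansion distance
  joins its nearest nucleus by Euclidean distance between pixel centres;
  exact ties go to the lower label id. Computed exactly via per-label
  cropped distance transforms.
* Coordinates are pixel-centre based, origin top-left, x rightward,
  y downward, physical = index × pixel size. Intensity means are computed
  on raw (unsmoothed) pixels.
* Zone bands are half-open, [(k−1)/6, k/6), with depth 0 in Zone 1;
  centroids exactly on a shared zone boundary go to the pia-ward zone.
* The two-way condition × zone ANOVA uses Type II sums of squares (the
  4-vs-3-case design is unbalanced) on one observation per case × zone,
  and degenerate (constant) responses report missing F.
* t-tests are pooled-variance by default (`welch = TRUE` available); raw
  p-values are reported without multiple-testing correction.
* Size-ranked binning sorts ascending by nuclear area with ties broken by
  cell id, uses bins of exactly 100 cells and drops the remainder.
* Coupling regressions sample exactly 100 damage-positive cells per case
  without replacement, seeded; cases with fewer eligible cells contribute
  all of them (with a warning), and a case with none is an error.

## Problem sizes used by the test-suite simulations

Cohort-level checks use the default 2000 cells/case (8000 AD / 6000 UC
cells per cohort); fraction-ceiling checks use ≥ 20,000 cells; the
coupling closed form is checked at 50,000+ positives; calibration rates
use 200–2000 replicates (vertex location 200, flatness 500, ANOVA null
2000); detection checks use rendered fields of 60–200 nuclei. These sizes
were chosen so each property's Monte-Carlo error is small relative to its
tolerance band.

## Known limitations

* The generator keeps total cell density equal across conditions; the
  slight AD density trend seen in real tissue is not modelled.
* UC damage-positive cells have no p16 depth trend in the default model,
  so the weak-but-significant UC slope reported for real tissue is not
  reproduced — only the AD trend is.
* The slope t-test on case × zone fractions is mildly conservative under
  the between-case random effect (measured rejection ≈ 3% at α = 0.05
  under the flat UC model), because case offsets inflate the OLS residual
  variance; a mixed model would restore exact calibration but is outside
  the analysis this package mirrors.
* No 3-D tissue, no z-stacks, no machine-learned segmentation, no
  brightfield deconvolution, and no modelling of amyloid, tau, or the
  γ-H2AX tissue channel.

## A worked example

```{r example, eval = FALSE}
geom <- make_geometry(width = 1000, depth = 2400, curvature_amplitude = 0,
                      pixel_size = 0.5)
cfg <- pipeline_config(
  generator = list(generator_config("AD"), generator_config("UC")),
  geometry = geom, culture = culture_config(),
  truth_bypass = TRUE, output_dir = "run1", seed = 1)
man <- run_pipeline(cfg)
res <- attr(man, "results")
res$fits$AD$comparison   # quadratic vs linear depth profile
res$coupling$AD          # p16-53BP1 coupling regression
res$anova                # condition x zone ANOVA
```

The same analyses run on real QuPath exports via `read_detections()` plus
zone polygons from `read_zones_geojson()`, with the generator playing no
role.
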