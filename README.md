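# cortexlam

Depth-stratified quantification of DNA-damage and senescence markers in
cortical tissue.

## What it does, and for whom

In immunostained sections of human prefrontal cortex, nuclear 53BP1 marks
cells with DNA double-strand breaks and p16^INK4a^ marks cellular
senescence. A question with anatomical teeth is not just *how many* cells
carry damage, but *where* across the cortical depth they sit. cortexlam is
an R package for researchers doing this kind of laminar image analysis:
it takes per-cell detection tables (its own detector on fluorescence
images, or QuPath exports) plus pia/white-matter boundary annotations, and
produces per-zone statistics of marker-positive cells across six radial
zones between the pia (Zone 1) and the white matter (Zone 6).

The statistical core is the quadratic depth profile of the damaged-cell
fraction over the zone index z = 1..6,

    f(z) = a + b z + c z^2,

fitted by OLS to one observation per case × zone, with adjusted
r² = 1 − (1 − r²)(n − 1)/(n − 3), a partial F-test against the linear
profile, and the vertex −b/(2c) locating the depth of maximal damage.
Around it: per-zone fractions and densities, a Type II condition × zone
ANOVA for the unbalanced case design, size-ranked intensity binning (100
cells/bin), per-cell p16-on-53BP1 coupling regression (100 cells/case,
sampled without replacement), p16 profiles of the 53BP1-positive and
-negative subsets in the nuclear and perinuclear ("pseudoplasm")
compartments, and positive-fraction analysis of an etoposide
dose-response culture experiment.

Because no public dataset accompanies the study design this package
mirrors, it ships a synthetic-cortex generator whose defaults encode the
published summary structure (flat ≈5.5% damage in controls; an AD profile
peaking between Zones 4 and 5 with mean ≈19.3%; strong p16–53BP1 coupling
in AD, weak in controls; a neuron/glia nuclear-size mixture; an etoposide
culture reaching ≈38% γ-H2AX-positive at 10 µM). Every pipeline stage is
validated against this ground truth.

## A worked example

```r
library(cortexlam)

geom <- make_geometry(width = 1000, depth = 2400,
                      curvature_amplitude = 0, pixel_size = 0.5)
cells <- simulate_tissue(geom, generator_config("AD"), seed = 1)
zs <- zone_summary(cells, areas_mm2 = rep(0.4, 6))

lin  <- fit_linear(zs$zone, zs$fraction)
quad <- fit_quadratic(zs$zone, zs$fraction)
compare_models(lin, quad)
```

```
Model comparison: quadratic preferred (adj r^2 0.3883 vs 0.6343)
  partial F(1, 21) = 15.8, p = 0.0006895 for the quadratic term
```

```r
quad
```

```
Quadratic depth-profile fit (n = 24)
  coefficients: a = 0.0168898, b = 0.0961708, c = -0.0108339
  r^2 = 0.6661, adjusted r^2 = 0.6343
  vertex at z = 4.438
```

The fitted parabola recovers the generating profile (a, b, c) =
(0.0201, 0.0955, −0.010612) within noise, prefers the quadratic over the
linear model decisively, and places the vertex — the depth of maximal
DNA damage — between Zone 4 and Zone 5. The per-cell coupling of
senescence to damage:

```r
coupling_regression(cells, per_case_n = 100, seed = 1)
```

```
Marker-coupling regression (n = 400, seed 1)
  p16 = 23.11 + 0.9694 x 53BP1, r^2 = 0.6897
```

An r² near 0.72 is the strong-coupling (AD) regime; the control
configuration (`generator_config("UC")`) targets r² ≈ 0.28.

The full pipeline — simulate, render multi-channel TIFFs, detect nuclei,
expand pseudoplasm annuli, zonate, quantify, analyze, report — runs from
one configuration object via `run_pipeline(pipeline_config(...))`; see the
vignette (`vignettes/depth-profiles.Rmd`) for the model, parameter and
design documentation, and `inst/cli/cortexlam` for a minimal command-line
wrapper.

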