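# capimorph

3D morphometry of the cardiac capillary network in cleared-tissue
two-photon image stacks.

Hypertensive heart disease remodels the coronary microcirculation, and the
capillary bed — the vessels that actually feed the cardiomyocytes — can only
be judged fairly in 3D: section-plane artifacts have made 2D capillary
counts notoriously contradictory. `capimorph` implements the full
quantification chain for multi-channel stacks of optically cleared
ventricular tissue (lumen-filled vessels, cell membranes, second-harmonic
collagen), plus a synthetic phantom generator with exact ground truth so
that every estimator is validated even though raw volumes of such studies
are rarely deposited. It is aimed at cardiovascular imaging groups who
have stacks of their own, and at methodologists who want a tested open
implementation of this analysis style.

## What it computes

Per stack:

* **Mean lumen diameter** — the vessel mask (global Otsu threshold) is
  thinned to a topology-preserving 3D skeleton and decomposed into
  branch-free segments with length `L`, mean radius `r` (distance
  transform) and volume `∑ π r_i² Δs_i`. Segments are binned by length into
  `[0,5), [5,10), …, [25,30)` µm; the stack diameter is the mean over
  non-empty bins of the per-bin Mode of segment diameters (0.1 µm
  discretization).
* **Capillary density** — total vessel surface over stack volume,
  `ρ_s = A(∂V_vessel) / V_stack` (µm⁻¹), with the surface area measured on
  a marching-tetrahedra isosurface triangulation of the mask.
* **Angular dispersion / myocardial disarray** — per 60 µm block the
  structure tensor `J = ∑ ∇I ∇Iᵀ` yields the tissue axis (eigenvector of
  the smallest eigenvalue); per 120 µm super-block,
  `Disarray = 1 − ‖mean versor‖` with axial sign alignment, and the global
  value is the mean over super-blocks. Applied to the vessel channel this
  is the capillary angular dispersion, to the cell channel the myocardial
  disarray.
* **Collagen %** — isodata-thresholded second-harmonic channel, foreground
  voxels over all voxels.

Per study: two-way ANOVA (strain × age, Type II SS), Fisher LSD post hoc
comparisons, Student *t*, Pearson correlations between vascular and tissue
metrics, and min–max-normalized summary tables.

## Worked example

Generate a synthetic stack with known ground truth and analyse it:

```r
library(capimorph)

ph <- generate_phantom(phantom_spec(seed = 7))   # 128 um cube, 50 tubes of 6 um
rec <- analyze_stack(ph$vessel, ph$cell, ph$collagen,
                     metadata = list(strain = "WKY"))
rec[, c("mean_diameter_um", "density_um_inv", "angular_dispersion",
        "disarray_cell", "collagen_pct", "n_segments")]
#>   mean_diameter_um density_um_inv angular_dispersion disarray_cell collagen_pct n_segments
#> 1         5.916667     0.04921504        0.001451111   0.007543441     8.582115        283
```

The true tube diameter is 6 µm (estimate −1.4%), the analytic surface
density of the generated tubes is 0.0554 µm⁻¹ (the estimate is lower
because overlapping tubes share surface), and at concentration κ = 20 both
orientation statistics are correctly near zero; the generated collagen
fraction was 8%.

A whole synthetic study — two strains × four ages × three regions, with a
2× capillary-count ratio and age-increasing dispersion in one strain —
runs end to end with:

```r
design <- phantom_study_design(seed = 100)
res <- run_study(list(seed = 100, out_dir = "study_out",
                      design = list(type = "phantom", stacks = design)))
two_way_anova(res$records, "density_um_inv")
```

Real stacks enter the same pipeline through a `type: "files"` design (one
multi-page TIFF per channel plus the acquisition pitches), or through the
thin CLI at `inst/cli/capimorph.R` (`generate`, `rescale`, `segment`,
`disarray`, `collagen`, `run` subcommands).

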