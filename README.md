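# pethet: phantom-based selection of reliable PET texture heterogeneity parameters

Texture ("radiomics") indices of FDG-PET tumour images are widely proposed
as quantitative heterogeneity biomarkers, but many of them are confounded by
lesion volume, acquisition protocol and reconstruction settings.  `pethet`
implements a phantom-based quality-assurance strategy for deciding which of
27 commonly used heterogeneity parameters are reliable enough for clinical
use.  It is aimed at medical physicists and imaging researchers who want to
stress-test texture indices under fully controlled conditions.

The package simulates three classes of phantom experiments and feeds them
into a three-criterion selection pipeline:

1. **Volume independence** — a homogeneous 20 cm cylinder (5 kBq/ml F-18)
   imaged with routine protocols on three emulated scanners; every parameter
   is computed on concentric spherical VOIs from 0.5 to 1000 ml and its
   curve is classified in log-log space as converging (A), positive slope
   (B), random-like (C) or negative slope (D).
2. **Reproducibility** — a custom seven-syringe "Revolver" insert (8.66 mm
   bores, 3 ml each; 80/40/20 kBq/ml over a 5 kBq/ml background) in a
   NEMA-IQ-like body, imaged in triplicate for each of 6 reconstruction
   settings x 4 acquisition times; the replicate coefficient of variation
   `CV = SD/mean` must stay below 10% in almost all cells.
3. **Sensitivity** — a dual-isotope Revolver series (C-11 and F-18
   syringes) sampled over 80 minutes: physical decay sweeps the pattern from
   heterogeneous through homogeneous and back, and a parameter must respond
   by a sizeable relative change.

## The quantities computed

Voxels inside a VOI are resampled to a fixed number of grey levels
(64 by default):

    V(x) = floor( L * (I(x) - min I) / (max I - min I) + 1 ),  clipped to L

Three texture matrices are built strictly inside the VOI — the grey-level
co-occurrence matrix (averaged over all 26 3-D neighbour directions), the
volumetric run-length matrix (13 directions, counts aggregated) and the
size-zone matrix (26-connected zones) — and 26 standard indices are derived
from them (Homogeneity, Correlation, Entropy, Contrast, Intensity
Variability, and the run/zone emphasis and non-uniformity families).  The
27th parameter is the first-order Coefficient of Variation, computed on the
raw intensities.  `heterogeneity_parameters()` lists the short names.

## Worked example

Simulate one Revolver scan, segment the insert at 2.5 x background, and
compute all 27 parameters:

```r
library(pethet)

phantom <- build_revolver_phantom()                     # 7 syringes in a NEMA-like body
setting <- acquisition_setting(acq_time_s = 120, seed = 7, label = "A")
img     <- simulate_pet_image(phantom, setting)         # resample, blur, noise, post-filter
voi     <- threshold_segment(img, mode = "relative", threshold = 2.5,
                             box = list(lower = c(-25, -25, -35),
                                        upper = c(25, 25, 35)))
voi
#> <voi_mask> 647 voxels, 41.41 ml
ft <- compute_all_features(img, voi)
round(ft[, c("volume_ml", "CoV", "ENT", "HOM", "COR", "CON")], 3)
#>   volume_ml   CoV   ENT   HOM   COR    CON
#> 1    41.408 0.489 9.998 0.211 0.538 178.27
```

The segmented insert (hot syringes plus their partial-volume halo) measures
~41 ml; its Coefficient of Variation of 0.49 reflects the deliberately
heterogeneous 80/40/20 kBq/ml fill, and Correlation ~0.54 the smooth
structure introduced by the ~8 mm effective resolution.

The full study — all three experiments plus the conjunctive selection —
is one call:

```r
res <- run_full_study(study_config(seed = 1))
glance(res)      # counts per criterion
tidy(res)        # per-parameter verdicts
autoplot(res$curves)                      # volume-dependence curves
plot_reproducibility(res$repro)           # CV grid, settings x times
plot_sensitivity_profiles(res$profiles)   # dual-isotope time courses
```

On the default configuration this evaluates 27 parameters; the replicate CV
of Entropy, Homogeneity and Correlation stays below 2% over the whole
settings grid, and the dual-isotope Coefficient-of-Variation profile shows
the expected two maxima with an interior minimum at the empirically located
equilibrium frame.  See the methods vignette
(`vignettes/phantom-selection.Rmd`) for the model, all tunable parameters,
and a frank discussion of which published findings the simulation does and
does not reproduce.

A thin command-line wrapper is provided in
`inst/scripts/pethet-cli.R` (subcommands `simulate`, `segment`, `features`,
`run-all`), and `inst/extdata/study-config.yaml` is the checked-in default
configuration; NIfTI-1 is used for images and masks, CSV for feature
tables, YAML for configuration and JSON for the selection report.

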