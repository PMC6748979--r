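# vesselmink

Morphometry of 3D capillary networks with Minkowski functionals.

Capillary beds imaged by confocal fluorescence microscopy arrive as noisy
z-stacks, while the quantities that matter physiologically are properties
of the *network*: how much vessel there is, how much wall surface, how
tortuous the tubes are, and how many loops (collaterals) provide alternate
flow paths and pressure equalization.  `vesselmink` implements a two-stage
analysis:

1. **Segmentation** — an adaptive structure filter turns a z-stack into a
   binary tubular model: Frangi-type Hessian vesselness
   `V = (1 − e^{−R_A²/2α²}) e^{−R_B²/2β²} (1 − e^{−S²/2γ²})` computed at
   multiple calibres, combined voxel-wise as the maximum of
   `log(ε + V_σ)` across scales, used to detect tubular support;
   thresholding and connected-component cleaning then delineate the
   vessels at their imaged calibre.
2. **Morphometry** — the four 3D Minkowski functionals (volume `V`,
   surface area `S`, mean breadth `B = M/2π` with `M` the integral of mean
   curvature, and the Euler number `χ = components − tunnels + cavities`)
   are evaluated on dilated copies of the vessel set over a range of radii
   driven by an exact Euclidean distance transform.  Ten summaries of each
   of the four *dilation signatures* (variance, SD, mean, median, max,
   maxScale, min, minScale, dmax, dmaxScale) give a fixed 40-feature
   vector per sample.  Cohort statistics — z-scoring, PCA with biplot
   loadings, age-group ANOVA with Bonferroni correction, and bootstrap
   stepwise regression with selection-frequency reporting — rank which
   features of microvascular architecture track age.

Because the Euler number is exactly additive and integer-valued on the
digital lattice, loop counts are measured, not estimated: the package
carries an exact cubical-complex Euler characteristic (foreground-26 /
background-6 convention), verified against an independent cell-counting
path and connected-component Betti numbers.  A phantom generator produces
tubular networks with *known* component and loop counts, plus a
confocal-style renderer (anisotropic PSF, background gradients, Gaussian
noise, speckle), so every stage is validated against ground truth.

## A worked example

```r
library(vesselmink)

ph   <- standard_phantom(seed = 1, snr = 5)   # known truth + rendered stack
mask <- segment_stack(ph$noisy)               # adaptive structure filter
dice(mask, ph$truth)
#> [1] 0.934

minkowski_3d(mask)
#> <mf_vector> [voxel units]
#>   volume        7048
#>   surface area  4256 (face count 5984)
#>   mean breadth  93.33
#>   Euler number  2

sig <- mf_signature(mask, radii = 0:10)       # dilation signatures
feats <- extract_features(sig)                # the 40-feature summary
round(feats[c("surf_area_dmax", "euler3D_mean", "mean_breadth_var")], 3)
#> surf_area_dmax   euler3D_mean mean_breadth_var
#>       1675.364          2.000           55.482
```

The Dice overlap of 0.934 says the filter recovered the vessel set at
signal-to-noise 5 to within a fraction of a voxel at the walls;
`surf_area_dmax` is the steepest growth of wall surface under inflation,
the feature family that carries most age signal in this framework.

At cohort level, a table with a planted two-feature age model shows how the
bootstrap stepwise layer reports stability:

```r
tab <- synthetic_feature_cohort(n = 52, seed = 3)
bootstrap_stepwise(tab, n_boot = 300, n_repeats = 6, seed = 11)
#> <stepwise_report> 52 samples, 6 x 300 bootstrap stepwise regressions
#>   model size 25/50/75th percentiles: 7/10/16
#>   conservative models (2-4 features): 67 of 1800; r2 = 0.971 +/- 0.001 (mean +/- SE), median F = 455.7
#>   top 4 selection frequencies (% of conservative fits, mean +/- SD over repeats):
#>     surf_area_dmax         100.0 +/- 0.00   p_med <2e-16
#>     euler3D_mean           100.0 +/- 0.00   p_med <2e-16
#>     mean_breadth_median     24.0 +/- 16.91  p_med 0.0041
#>     surf_area_var           22.9 +/- 17.73  p_med 0.001
```

Both planted features are selected in 100% of the conservative (2–4
feature) models in every repeat; everything else trails far behind.

A thin command-line front end wraps the same functions
(`inst/cli/vesselmink.R`): `phantom`, `segment`, `thickness`, `minkowski`,
`signature`, `features`, `run-sample`, and `run-cohort` subcommands; see
the header comment of that script for usage.

The methods vignette (`vignettes/minkowski-morphometry.Rmd`) documents the
model, the digital-topology conventions, the additivity caveat for masks
that touch without overlapping, the segmentation design, parameter
defaults, and known limitations.

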