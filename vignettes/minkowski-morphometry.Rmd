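---
title: "Minkowski-functional morphometry of 3D capillary networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minkowski-functional morphometry of 3D capillary networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(vesselmink)
```

## The analysis in one paragraph

Confocal z-stacks of fluorescently labelled capillary beds are noisy clouds
of intensity, not models of vessels.  `vesselmink` converts such stacks into
binary tubular networks with an adaptive multi-scale Hessian structure
filter, then quantifies each network with the four 3D Minkowski functionals
— volume $V$, surface area $S$, mean breadth $B$, and Euler number $\chi$ —
evaluated on a family of dilated copies of the vessel set (the *dilation
signature*).  Ten summary statistics of each of the four signature curves
give a fixed 40-feature vector per sample; a cohort of such vectors feeds
z-scoring, principal components, age-group ANOVA with Bonferroni
correction, and a bootstrap stepwise regression whose feature-selection
frequencies rank which aspects of microvascular architecture track age.
The mean breadth is proportional to the integral of mean curvature and acts
as a tortuosity / resistance-to-flow proxy; the Euler number counts
connected components minus tunnels plus cavities, so capillary loops
(collaterals) drive it down.

## The four functionals on a voxel lattice

A binary volume is realized as a union of closed unit cubes, which makes
the foreground 26-connected and the background 6-connected — the standard
Jordan-separating pair; the complementary (6, 26) convention is available
behind the `connectivity` field.  All four functionals are linear in the
histogram of $2\times2\times2$ voxel configurations of the one-layer-padded
volume (`config_counts()`):

* **Volume** — the foreground voxel count; exact.
* **Euler number** — the alternating cell count $V - E + F - C$ of the
  cubical complex, folded into a 256-entry lookup table by attributing
  every cell to the window centred on its minimal lattice vertex; exact
  integer.  The test suite checks it against an independent path that
  counts vertices, edges, faces and cubes globally, and against Betti
  numbers ($b_0 - b_1 + b_2$) obtained from connected-component labelling.
* **Surface area** — a Cauchy–Crofton estimate over the 13 lattice
  directions of the $2\times2\times2$ cell, with spherical direction
  weights 0.045778 / 0.036981 / 0.035196 (axis / face diagonal / space
  diagonal).  It converges for smooth bodies (a digitized radius-24 ball is
  reproduced to about 0.6%); the exact digital face count, which is
  unbiased for the digital boundary but overestimates smooth area by up to
  50%, is reported alongside as a diagnostic.
* **Mean breadth** — Crofton over the three axis directions: the mean over
  axes of the summed 2D Euler characteristics of all slices, normalized so
  a ball's mean breadth equals its diameter ($B = M / 2\pi$ with $M$ the
  integral of mean curvature, also reported raw).  Three directions
  reproduce balls to the digitization limit (≈ 2% at radius 24, the odd
  +1 slice count) but underestimate strongly anisotropic bodies (a cube
  reads $a$ instead of $3a/2$); a 13-direction extension would remove this
  bias and is left as future work.  For tortuosity comparisons between
  tube networks of similar orientation statistics, the bias cancels in
  rank order.

### Additivity and its digital limits

The functionals are *valuations*: $F(A \cup B) + F(A \cap B) = F(A) +
F(B)$.  On the voxel lattice this identity holds **exactly** whenever the
two sets touch only where they overlap — the situation of overlapping
sampling windows cut from one specimen, which is what makes means over
fields of view well defined.  It does *not* hold for arbitrary voxel-set
pairs: two adjacent voxels $A = \{x\}$, $B = \{y\}$ have closed-cube
realizations that intersect in a shared face, which the voxel-set
intersection $A \cap B = \emptyset$ cannot represent, leaving a residual
$\chi$-defect of $-1$.  `mf_additivity_check()` exposes the residual;
the test suite verifies exact zero over 500 random window-split pairs and
documents the adjacent-voxel defect.  Consequence for practice: combine
samples by splitting a common volume with overlapping windows, never by
abutting disjoint masks.

## Stage one: the adaptive structure filter

At each scale $\sigma$ (physical units; divided per axis by the voxel
spacing so 1 µm optical sections are not smeared against 0.44 µm pixels)
the stack is Gaussian-smoothed and the $\sigma^2$-normalized Hessian
eigenvalues $|\lambda_1| \le |\lambda_2| \le |\lambda_3|$ feed the Frangi
bright-tube vesselness

$$ V_\sigma = \left(1 - e^{-R_A^2/2\alpha^2}\right)
   e^{-R_B^2/2\beta^2} \left(1 - e^{-S^2/2\gamma^2}\right), $$

zero wherever $\lambda_2 > 0$ or $\lambda_3 > 0$, with $R_A =
|\lambda_2|/|\lambda_3|$ (plate rejection), $R_B =
|\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$ (blob rejection) and $S$ the
Frobenius norm (structure).  Defaults $\alpha = \beta = 0.5$ and $\gamma =
\max S / 2$ are the classical choices.  The *adaptive* filter takes, at
each voxel, the maximum of $\log(10^{-6} + V_\sigma)$ across five
log-spaced scales spanning 0.5–2× the mean vessel radius, which is itself
bootstrapped from a provisional single-scale segmentation followed by
local thickness — so the probed calibres track the data.

**Detection versus delineation.**  Thresholding the multi-scale tube score
directly recovers the *ridge* of each vessel, not its calibre: the score
decays over roughly one $\sigma$ from the axis, so the resulting masks are
systematically thin and overlap scores against ground truth saturate far
below what the data support.  The default filter therefore uses the tube
score for *detection* only — its isodata threshold marks tubular support,
expanded by the largest probed calibre — and returns as the score field the
conditioned intensity inside that support (percentile-clipped to the
(0.5, 99.9) range, rescaled, and denoised with a 1-voxel Gaussian when the
raw-minus-smoothed median absolute deviation exceeds 0.02, so a clean stack
passes through untouched).  Thresholding then *delineates* vessels at their
imaged calibre while non-tubular structure — speckle, autofluorescence
gradients — stays suppressed.  The literal max-log-vesselness score is
available via `combine = "vesselness"`.

**Binarisation.**  The default threshold is *core-referenced*: a first-pass
isodata mask is eroded by 2 voxels, the median score of the remaining core
is taken as the vessel level, and the cut is placed at 0.6 of it.  The
classical half-maximum criterion (0.5) overestimates tube width when the
axial PSF is comparable to the vessel radius, and global histogram cuts
(Otsu, isodata) land at the background/vessel valley and produce fat
masks; the 0.6 fraction was calibrated once on rendered cylinders of known
radius (volume consistency gives 0.53–0.68 over radii 2–4 voxels) and is
frozen.  Otsu, isodata and fixed thresholds remain available.  Cleaning
removes 26-connected components below `min_cluster_voxels` (default 64).

On the package's standard validation phantom (two components, three loops,
radius 3 voxels, PSF (1, 1, 2), signal-to-noise 5) the full chain recovers
the ground truth at Dice ≈ 0.93, and exactly (Dice 1.0) for an
undegraded rendering; both numbers are recomputed by
`scripts/acceptance.R` and the test suite.

## Stage two: signatures and features

The exact Euclidean distance transform (Felzenszwalb–Huttenlocher,
anisotropy-aware) is computed once; the dilation by radius $r$ is its
sublevel set, so `r = 0` reproduces the input bit-exactly and the family is
nested.  `mf_signature()` evaluates the four functionals at integer radii
`0..R`, with `R = ceil(3 × mean vessel radius)` (capped at 25) by default —
wide enough that neighbouring vessels merge and the loop structure
saturates.  Each curve is summarized by ten statistics: population variance
and SD, mean, median, max and its abscissa, min and its abscissa, and the
maximum forward difference $\Delta y / \Delta r$ with its left abscissa
(ties toward the smallest abscissa).  The 40 names follow the
`prefix_feature` scheme (`surf_area_dmax`, `euler3D_minScale`, …); note
that `vol_maxScale` and `vol_minScale` are degenerate by monotonicity
whenever all samples share one radius grid — per-sample automatic grids
avoid this, and `zscore()` refuses constant columns rather than silently
producing NaNs.  Multiple fields of view per sample are averaged feature-wise
(`average_features()`), which additivity makes meaningful.

## The statistics layer

Features are z-scored with the sample SD ($n-1$).  `pca_features()`
decomposes the covariance of the z-scored table (equivalently the
correlation matrix), fixes signs so each component's largest-magnitude
loading is positive, and reports orthonormal loadings for biplots.  Ages
are binned into the six standard groups (5–44, 45–54, 55–69, 70–74, 75–79,
80–84), and `anova_pairwise()` runs one-way F tests per feature per group
pair with Bonferroni correction over the whole family tested in the call.

`stepwise_ols()` is the classical forward–backward selection on partial-F
p-values (enter 0.05, remove 0.1), capped at twice the feature count with
cycle detection.  Two behavioural facts matter for interpretation and are
verified by simulation in the tests:

* with 40 candidates, each forward step under the null still clears
  p = 0.05 with probability ≈ 0.85 for *some* candidate, so single runs
  over-select; sparsity comes from the bootstrap layer, not single fits;
* the marginal null selection rate per feature approaches the nominal 0.05
  only when $n$ is large relative to the pool (measured 0.050 at $n = 200$
  but ≈ 0.062 at $n = 52$, where the post-selection residual variance is
  deflated).

`bootstrap_stepwise()` resamples subjects with replacement (`n_boot` per
repeat, `n_repeats` independent repeats, counter-split seeds), restricts by
default to samples aged ≥ 40 (the near-linear regime), tallies selection
frequencies over the *conservative* models that selected 2–4 features, and
reports them as mean ± SD across repeats together with model-size
percentiles, $r^2$ (mean ± SE), the median F and per-feature median
p-values — the stability-selection summary of which architecture features
carry the age signal.

## The phantom generator: what it does and does not emulate

`make_network()` builds tubular networks whose topology is *known by
construction*: disjoint tortuous backbone tubes (sinusoidal lateral
wiggle), one per component, with half-sine bridge arcs welded on — each arc
follows the backbone's lateral wiggle and lifts away axially by
$2r + 3$ voxels, so it touches the backbone in exactly two contiguous weld
regions and contributes exactly one independent cycle.  Intended-disjoint
structures keep ≥ $2r_{max} + 3$ voxels of clearance, making the ground
truth independent of the connectivity convention; the generator verifies
the measured Betti numbers before returning and refuses infeasible
packings.  `render_zstack()` degrades a network with an anisotropic
Gaussian PSF, constant-plus-gradient background (autofluorescence rises
with specimen age in practice, hence the gradient), additive Gaussian
noise, and impulse speckle; everything is driven by one integer seed
through counter-based splitting.

The standard validation conditions are: grid 96 × 64 × 32, two components,
three loops, radius 3 voxels, tortuosity 2, PSF (1, 1, 2) voxels,
signal-to-noise 5, speckle rate 5 × 10⁻⁴, background 0.05.  The paper-scale
cohort statistics run at feature level (`synthetic_feature_cohort()` plants
a linear two-feature age model at n = 52; `synthetic_factor_cohort()` gives
the correlated factor structure PCA needs), with bootstrap sizes reduced to
300 × 6 and the null calibration at 200 runs — sizes chosen so the whole
validation executes in minutes on one CPU while keeping every comparison
statistically meaningful.

What the phantoms do **not** emulate: curved vessel branching and
bifurcation angles, calibre tapering, depth-dependent attenuation,
stitching seams between fields of view, and real PSF side-lobes.  Passing
phantom tests therefore demonstrates correctness of the measurement chain
and recoverability under the modelled degradations, not performance on any
particular microscope's data.

## Numerical choices and degenerate inputs

* Distances: exact EDT with a large finite sentinel in place of IEEE
  infinities (infinite parabola intercepts break the lower-envelope
  recursion); empty foreground yields an all-infinite field with a warning.
* Local thickness: inscribed-sphere radius is the EDT to the nearest
  background voxel centre; the assigned diameter is $2\,\mathrm{EDT} - 1$,
  measured to the digital surface, so an isolated voxel has thickness 1.
  Anisotropic grids are nearest-neighbour resampled to the finest spacing
  first (inscribed spheres are ill-defined otherwise); the staircase this
  introduces carries an error of order the coarse spacing.  The volume
  border is not treated as background, so tubes crossing the field of view
  keep their calibre at the open ends.
* Otsu's criterion plateaus across an empty inter-class gap; the midpoint
  of the maximizing interval is returned.
* All-equal score fields are an error directing the user to a fixed
  threshold; an all-zero nonzero-score set likewise.
* Ties in curve features break toward the smallest abscissa; variance is
  the population variance.
* `sym_eigen3()` (closed-form symmetric 3 × 3 eigenvalues) guards the
  isotropic case $p \to 0$ explicitly.

## A worked example

```{r example, eval = FALSE}
ph <- standard_phantom(seed = 1, snr = 5)
mask <- segment_stack(ph$noisy)
dice(mask, ph$truth)                     # ~0.93
minkowski_3d(mask)                       # volume, surface, breadth, chi
sig <- mf_signature(mask)
plot(sig)
feats <- extract_features(sig)
feats[c("surf_area_dmax", "euler3D_mean")]

tab <- synthetic_feature_cohort(n = 52, seed = 3)
bootstrap_stepwise(tab, n_boot = 300, n_repeats = 6, seed = 11)
```

## Known limitations

* The 3-direction mean breadth is biased low for strongly anisotropic
  structures (see above).
* Minus-sampling edge correction is not implemented: structure clipped at
  the stack border counts as boundary, which slightly inflates surface
  area and can sever loops at the field edge.
* The core-referenced binarisation factor (0.6) was calibrated for PSFs
  with axial sigma comparable to the vessel radius; markedly different
  optics warrant recalibration against rendered cylinders.
* Segmentation of vessels thinner than ~2 voxels in any direction is
  unreliable — at that scale the Hessian is sampling-noise dominated.
* Stepwise selection frequencies are stability rankings, not causal or
  even unbiased effect estimates; the reported per-feature p-values are
  medians over selected models and inherit selection bias.
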