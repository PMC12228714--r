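---
title: "Mapping wound pH and nitric oxide from fluorescent images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping wound pH and nitric oxide from fluorescent images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundfluor)
```

`woundfluor` analyses fluorescent images of healing skin wounds captured
with simple single-filter microscopes: a pH map read through the red
channel (SNARF dye) and a nitric-oxide map read through the green channel
(DAF-FM dye). This vignette explains the models the package implements,
the choices behind their defaults, and what the synthetic phantoms do and
do not establish.

## The pH calibration model

A single-wavelength SNARF readout is linear in pH over the biologically
relevant window of early acute wound healing. The calibration is a
straight line between buffer pH and the mean red-channel fluorescent
intensity (FI, 0–255) of a dyed sample:

$$\mathrm{FI} = a \cdot \mathrm{pH} + b$$

`fit_calibration()` estimates $(a, b)$ by ordinary least squares
(`stats::lm`) and reports fit quality as the squared Pearson correlation
of the calibration points. The packaged default, available from
`default_calibration()`, is $a = 28.8$ FI units per pH unit and
$b = -120.05$ FI units with $R^2 = 0.957$; both constants live in
`inst/extdata/defaults.yaml` and are overridable by refitting.

Two assumptions matter in practice. First, linearity holds over pH 5–9
only; the dye response flattens outside it, so `estimate_ph()` returns
out-of-range estimates but attaches a warning. Second, a single-wavelength
intensity readout — unlike the ratiometric two-wavelength method — is
sensitive to dye concentration and illumination; the package assumes these
are controlled experimentally (fixed dye dilution, dark room, fixed LED
drive) and offers no photobleaching or illumination-field correction.

## Wound segmentation

Segmentation follows a fixed sequence, exposed piecewise
(`apply_brightness_threshold()`, `build_feature_table()`,
`kmeans_cluster()`, `relabel_and_stats()`) and as one call
(`segment_wound()`):

1. **Brightness threshold.** A pixel is retained when its mean R,G,B value
   is at least `threshold` (default 10/255). The cut-off only has to
   separate the unlit background from dyed tissue, so any small value
   works; it is configurable because exposure varies between set-ups.
2. **Features.** Each retained pixel contributes its channel intensities
   plus its 0-based `(x, y)` position (x = column, y = row, origin
   top-left). pH maps use all of `R, G, B, x, y`; NO maps use `G, x, y`
   only, which empirically separates capillary structure better. Every
   column is min–max scaled to [0, 1] by default: without scaling,
   positions measured in hundreds of pixels dominate 8-bit intensities and
   the clustering degenerates to a spatial tiling.
3. **k-means.** Lloyd's algorithm with k-means++ seeding, `n_init = 10`
   restarts keeping the lowest-inertia solution, at most 300 sweeps,
   assignment ties broken toward the lowest centre index, and every draw
   governed by a single seed — two runs with the same seed are identical.
   The implementation records the objective after every assignment step,
   which the test suite uses to assert monotone descent, and is checked
   against `stats::kmeans` and against exhaustive minimum-inertia
   enumeration on small instances. A centre that loses all members is
   re-seeded at the worst-fitted point, unless the fit is already exact
   (duplicated rows), in which case fewer than `k` effective clusters are
   returned.
4. **Canonical labels.** Sub-threshold pixels carry label 0. The clustered
   pixels are renumbered $1 \dots k-1$ by ascending mean intensity of the
   ordering channel (red for pH, green for NO), so "cluster 4" means the
   brightest — and, through the calibration, highest-pH — region in every
   wound on every day. Day-to-day correspondence is by this canonical
   ordering alone; no labels are tracked across images.

With the default `k = 5` the background takes one label and the wound is
split four ways. Two readings of that arrangement are defensible, and both
are implemented: by default sub-threshold pixels never enter k-means and
the retained pixels get $k - 1 = 4$ centroids (`background = "exclude"`);
alternatively all pixels are clustered with $k$ centroids and the cluster
dominated by sub-threshold pixels is mapped to 0
(`background = "cluster"`). The default was chosen because it honours the
idea that thresholding *eliminates* the background rather than leaving it
to chance, and it guarantees exactly four wound clusters.

`inertia_curve()` supports choosing `k` by elbow inspection; the package
deliberately ships no automatic selection rule.

## pH dynamics and the variance test

`build_ph_series()` tabulates per-cluster mean pH and pixel counts per
wound and day; `compute_delta_ph()` takes, for each wound and cluster, the
absolute change in mean pH between consecutive days
($|\Delta \mathrm{pH}|$), skipping gapped day pairs with a warning because
the acquisition protocol images daily. `summarize_delta()` reports the
per-cluster mean, standard deviation and variance with the $n-1$
denominator.

The headline spatial question — does the wound centre's pH fluctuate more
than the periphery's? — is answered by a one-sample chi-squared variance
test:

$$\chi^2 = \frac{(n-1)\, s^2}{\sigma_0^2}, \qquad p = P\!\left(\chi^2_{n-1} > \chi^2\right)$$

where $s^2$ is the sample variance of the centre cluster's
$|\Delta \mathrm{pH}|$ values and $\sigma_0^2$ a reference built from the
three peripheral clusters. How to combine three peripheral variances into
one reference is genuinely open; the package defaults to their plain mean
(`reference = "mean"`) and also offers the df-weighted pooled variance
(`reference = "pooled"`) — with equal per-cluster counts, as in a complete
daily series, the two coincide. In a 3-wound, 4-day study each cluster has
$n = 9$ transitions, so the test runs on 8 degrees of freedom.

Worth knowing when planning a study of this size: the one-sided test at
$\alpha = 0.05$ with $n = 9$ has analytic power
$P(\chi^2_8 > \chi^2_{8,0.95} / \rho)$ at true variance ratio $\rho$ —
about 0.63 at $\rho = 2.5$, and 0.8 is reached only near $\rho \approx 4$.
The Monte-Carlo test in the suite verifies the implementation against
exactly this curve.

## NO features and the healing regressions

Three features summarize a green-channel NO image, each normalized to
[0, 1]:

* `full_fi` — mean green intensity over the wound crop, divided by 255;
* `cluster_fi` — mean green intensity (÷255) of the highest-NO cluster of
  a `G, x, y` segmentation;
* `cluster_area` — that cluster's share of the retained wound pixels.

Outcomes are normalized likewise: healing day ÷ 6 (so day 3 is 0.5 and day
6 is 1.0) and percent re-epithelialization ÷ 100. Each feature drives its
own multi-output ridge regression of both outcomes
(`fit_multioutput_ridge()`), fitted in closed form with the intercept
unpenalized:

$$\hat\beta = (X_c^\top X_c + \alpha I)^{-1} X_c^\top Y_c$$

with centred feature and outcomes. The default penalty is $\alpha = 0$,
which makes the fit exactly OLS; the ridge form is kept because the two
outcomes are strongly correlated and a user may want $\alpha > 0$ on small
noisy cohorts. The packaged default coefficients relating each feature to
each outcome (e.g. normalized day $= 0.85 \cdot$ `full_fi` $+ 0.57$) are
stored in `defaults.yaml`; fluorescent-intensity slopes are positive and
the area slope negative — as healing progresses the high-NO region shrinks
while staying bright.

Model error is the per-outcome mean squared error, in-sample and under
leave-one-out cross-validation (`loo_cv()`): with $n$ samples there are
exactly $n$ folds, one held-out sample each, in sample order. Errors are
reported on the normalized scale and de-normalized (day residuals × 6,
re-epi residuals × 100), so the day MSE is in days² and the re-epi MSE in
percentage points². A fold whose training design is singular is dropped
with a warning.

## The synthetic phantoms

The phantom generators replace an unreleased in vivo image set. They are
first-class, tested code, and their defaults define the package's
simulated study conditions.

**pH phantom** (`generate_ph_phantom()`): a circular wound (radius 40 px
in a 96 × 96 frame) on a dark background (8/255), with a concentric pH
field — highest at the centre, decreasing outward — rendered into the red
channel through the active calibration line. Rendering adds optional
Gaussian noise *before* clamping and rounding to 8 bits, mimicking sensor
quantization; inverting the calibration on a noise-free rendering
therefore recovers the true field to within the quantization bound
$0.5/28.8 \approx 0.017$ pH units. Green and blue carry a low-amplitude
(15/255) radial ramp standing in for the out-of-band signal that leaks
through the emission filter and traces the wound topology; the ramp rides
on a 40 % rim offset so the wound boundary is a sharp step that a
sharpness metric can see, while min–max scaling makes the offset invisible
to the clustering features. The generator emits an 11-frame focus stack
(stage positions 0–1000) with Gaussian blur growing by 0.7 px of sigma per
frame away from the designated focus frame; `select_focused()` picks the
sharp frame by the variance of a 3 × 3 Laplacian of the green channel,
with `first` and fixed-`index` strategies available because real
acquisition software may already know the focal frame.

Three radial profiles are available. `linear` (default) and `quadratic`
interpolate centre→edge pH continuously. `stepped` quantizes the wound
into `n_rings` concentric *equal-area* bands with *equally spaced* pH
levels; this is the phantom whose ground-truth ring labels a `k = 5`
segmentation can recover exactly. The two design choices are deliberate:
equal-area rings balance the positional variance that tempts k-means into
splitting large outer annuli angularly, and equally spaced pH levels keep
the between-band colour separation uniform after min–max scaling. Under
those defaults the ring partition is the global minimum of the k-means
objective and recovery is exact (adjusted Rand index 1.0, verified across
seeds); perturbing either choice — unequal colour steps, or a continuous
gradient — flips the optimum to an angular split. The centre pH default
(8.5) and edge default (6.5) span the range reported for acute wounds.

**NO phantom** (`generate_no_phantom()`): green channel at a diffuse level
(60/255) inside the wound and background (8/255) outside, with bright
(200/255) capillary-like strokes drawn as persistent-direction random
walks of unit steps and gentle curvature, clipped to the wound. No
quantitative description of real capillary geometry was available, so the
walk model is an explicit stand-in; its purpose is only to create a
bright, spatially sparse structure whose area and intensity the
highest-NO-cluster extractor must recover, which it does to within a
couple of boundary pixels on noise-free renders.

**Feature cohorts** (`generate_feature_cohort()`): one feature drawn
uniformly, both normalized outcomes generated linearly with Gaussian noise
and clipped to [0, 1], de-normalized columns recovered through the inverse
rules. The default feature range is computed from the coefficients as the
widest sub-interval of [0, 1] on which both noise-free outcomes stay in
[0, 1], so noise-free cohorts satisfy their generating relations exactly
and coefficient-recovery tests are exact to numerical precision. The
default cohort size is 8, matching the study design the regression
defaults describe.

### What passing tests do and do not show

The phantoms establish that the pipeline is *correct*: calibration
round-trips, exact coefficient recovery, exact ring recovery, determinism,
conservative cross-validation. They do not establish *robustness to real
tissue*: real wounds have irregular boundaries, inhomogeneous dye
delivery, specular highlights and motion blur, none of which are
modelled. One limitation found while validating the package is worth
stating plainly: min–max feature scaling is sensitive to noise — additive
channel noise inflates the per-column ranges, shrinks the effective colour
separation, and can flip the k-means optimum from concentric rings to an
angular tiling even at moderate noise (σ ≈ 1 grey level on the texture
channels). Recovery guarantees therefore hold for noise-free renders only,
and on real data the cluster geometry should be inspected visually (e.g.
`autoplot()` on a `cluster_map`) rather than assumed.

## Numerical choices and degenerate inputs

* 16-bit TIFF input is converted to 8 bits by integer division by 257,
  mapping full scale to full scale exactly (65535 → 255).
* Polygon ROIs rasterize by the even-odd rule at 0-based pixel centres;
  the implementation is property-tested against an independent
  point-in-polygon oracle.
* Min–max scaling maps a constant feature column to 0.
* k-means assignment ties break toward the lowest centre index; restart
  count, iteration cap and seed are explicit arguments everywhere.
* The variance test refuses $n < 2$ or $\sigma_0^2 \le 0$; per-cluster
  variance summaries refuse singleton clusters.
* Ridge fitting with $\alpha = 0$ on a constant feature raises a
  singular-design error rather than returning a pseudo-inverse fit.
* Reported tables round nothing; rounding (pH to 2 decimals, p to 3) is
  left to presentation code.
* Test problem sizes: phantoms are 96 × 96 (32–48 px for plumbing tests),
  Monte-Carlo suites use 100 seeded cohorts or 1000 test replicates —
  sizes at which every property is exercised in seconds.

## Limitations

Beyond the scaling sensitivity above: the package does not model optics
(PSF, vignetting), does not correct photobleaching or dye concentration,
ships no automatic `k` selection, performs no multiple-testing correction
(a single variance test is reported, as in the underlying study design),
and treats wound-stage classification from brightfield images as out of
scope — its outputs can be carried as sample metadata but are never
computed here.
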