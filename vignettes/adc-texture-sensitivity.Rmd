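---
title: "How imaging and pre-processing choices move Haralick features of ADC maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How imaging and pre-processing choices move Haralick features of ADC maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adctexture)
```

## The problem

Gray-level co-occurrence matrix (GLCM) texture features are computed from
images that have already passed through a long chain of choices:
acquisition resolution and signal-to-noise ratio, the b-values used to fit
the apparent diffusion coefficient (ADC) map, the rule that maps continuous
ADC values to a small number of gray levels, and the number of gray levels
itself. None of these choices is standardized, and most of them change the
feature values. `adctexture` quantifies those changes on synthetic phantoms
where the ground truth is known and every stage is controlled.

## The model

### Signal and ADC

Water diffusion attenuates the diffusion-weighted signal
mono-exponentially,

$$S(b) = S_0\,e^{-b\,\mathrm{ADC}\cdot 10^{-6}} + \varepsilon,\qquad
\varepsilon \sim \mathcal N(0, \sigma^2),$$

with ADC expressed in $10^{-6}\,\mathrm{mm^2/s}$ so that clinical values
span roughly 0–3000 (free fluid such as CSF or urine sits near 3000, solid
tissue near 600–1500, signal voids at 0). Noise is Gaussian on the
magnitude signal; this is accurate at the signal-to-noise ratios simulated
here and keeps the noise model exact, at the price of occasionally negative
simulated signals (handled at the fitting stage, below). The ADC map is
recovered voxel-wise by ordinary least squares of $\ln S$ on $b$;
$\mathrm{ADC} = -\hat\beta_1 \times 10^6$. With two b-values this is the
textbook two-point formula. Because the decay truly is mono-exponential in
the simulation, *every* b-value subset estimates the same slope on clean
data — which is exactly why the b-value factor produces no significant
feature shifts (see below), and why observing such shifts in real data
would indicate non-mono-exponential behavior (perfusion, kurtosis) rather
than fitting artifacts.

### Texture pipeline

Within an ROI, ADC values are quantized to gray levels $1..N$ over limits
chosen by one of three schemes — AutoROI (ROI min/max), AutoSlice
(per-slice min/max), Manual (fixed limits, out-of-range values clipped into
the boundary bins). Labels use uniform half-open bins with the top edge
closed, $\ell(v) = 1 + \lfloor N(v - lo)/(hi - lo)\rfloor$, $v = hi \mapsto
N$. Per slice, a symmetric GLCM counts every ordered pair of 8-adjacent
voxels that both lie inside the ROI (distance 1; including background
neighbors would leak non-tumor intensities into tumor texture, so the
both-inside rule is used). Slice matrices are summed and normalized to
$p(i,j)$ with $\sum_{i,j} p(i,j) = 1$; the 19 Haralick features are
functionals of $p$.

Two definitional choices deserve a note. The natural logarithm is used in
every entropy (the base only rescales globally). The correlation feature is
computed as $(\sum_{ij} ij\,p(i,j) - \mu_x\mu_y)/(\sigma_x\sigma_y)$ — the
form that is bounded in $[-1, 1]$ and equals 1 for a diagonal GLCM. Cluster
prominence uses the third power and cluster shade the fourth power of
$(i + j - 2\mu)$ by default; because much of the literature swaps these
exponents, `compute_features(cluster_convention = "conventional")` provides
the swapped assignment. Degenerate GLCMs make correlation
($\sigma_x\sigma_y = 0$) and the first information measure of correlation
($\max(HX, HY) = 0$) undefined; they are reported as `NA`, propagated as
missing values, and dropped pairwise from KS samples — never silently
replaced by a number.

### The one-at-a-time design

The reference workflow is: native resolution (factor 1.0), native noise
(factor 1.0), the protocol's reference b-subset (200–1000 s/mm² in steps
of 200 for the glioma protocol; 0 and 800 for the prostate protocol),
$N = 32$ gray levels, AutoROI. One parameter at a time is replaced by each
of its alternative settings; every unordered pair of settings of a
parameter is compared per feature with a two-sample Kolmogorov–Smirnov
test over the ROI cohort. With 19 features the glioma design implies
$19 \times (3 + 3 + 6 + 10 + 3) = 475$ tests and the prostate design
$19 \times (3 + 3 + 10 + 3) = 361$, i.e. 836 jointly; each test is run at
$\alpha = 0.01$ with Bonferroni correction for the applicable total (the
joint 836 when both designs are analyzed together, the design's own count
otherwise — the denominator is recorded in every output). A parameter is
deemed to affect a feature if *any* of its setting pairs is significant;
the per-(parameter, feature) summary is the minimum pairwise p-value,
which is also the natural heatmap statistic. Asymptotic KS p-values are
used; they are adequate for cohorts of a few dozen ROIs per setting and
are a documented limitation for much smaller batches.

## The phantom generator

Each phantom is an ellipsoidal ROI on a $48 \times 48 \times 3$ grid whose
ADC texture is a Gaussian random field: seeded white noise smoothed
in-plane with a Gaussian kernel, standardized, and mapped affinely to a
target mean and standard deviation. Per-phantom parameters are drawn from
fixed ranges chosen to mimic an inter-patient tumor cohort on the ADC
scale: base mean $\sim U(900, 1300)$, texture amplitude
$\sim U(200, 400)$ (both $\times 10^{-6}\,\mathrm{mm^2/s}$), correlation
length $\sim U(1, 3)$ voxels, in-plane radii $\sim U(8, 12)$ voxels. The
unattenuated amplitude is $S_0 = 1000$, giving an SNR of about 59 at
$b = 0$ under the glioma protocol's $\sigma = 17$ — high enough that the
Gaussian noise assumption is sound. By default each phantom also carries a
fluid-like slab (ADC $\approx 3000$) immediately beyond the ROI's edge, so
that delineation experiments can capture fluid voxels the way a tumor
bordering a ventricle or the bladder would. Batch seeding derives one seed
per phantom from the master seed, so enlarging a batch never perturbs
existing phantoms.

What the generator does **not** emulate: partial-volume mixing at tissue
boundaries, perfusion (bi-exponential decay), Rician noise at low SNR, EPI
distortion, bias fields, or anatomically realistic tumor shapes. Passing
tests therefore demonstrate the *mechanics* of the workflow's sensitivity
— which knobs move which features, and why — not the clinical effect sizes
of any patient cohort. True tumor ADC textures are unknown; the texture
parameters are knobs, not calibrated values.

## Numerical choices and degenerate inputs

* Non-positive signals are clamped to $10^{-3}$ of the voxel's maximum
  signal before the log-fit; voxels with no positive signal at all get
  ADC 0 and are tallied (`n_failed`). Clamping keeps every voxel defined
  without biasing the noise model at generation time.
* Resampling uses block averaging for integer factors (it emulates
  acquiring at coarser resolution, including the accompanying noise
  averaging) and bilinear interpolation at coarse-pixel centers otherwise.
  Whether a scanner-side resolution change corresponds to k-space
  truncation or image-space interpolation is acquisition-dependent; the
  method here is a documented, fixed choice. Masks are always resampled
  nearest-neighbor so they stay binary.
* A constant ROI (or constant AutoSlice slice) quantizes to all-ones with
  a warning; its GLCM is a point mass, and the undefined features are `NA`.
* Slices whose ROI cross-section has no valid neighbor pair contribute a
  zero GLCM and a tally, not an error, so multi-slice ROIs with thin tips
  still process.
* Manual-limit selection for a cohort uses the lower quartile of per-ROI
  minima and the upper quartile of per-ROI maxima, with quartiles by
  linear interpolation between order statistics (R's default type 7) for
  reproducibility.
* KS p-values come from the asymptotic two-sample distribution
  (`stats::ks.test`, `exact = FALSE`); pairs with fewer than two finite
  values on either side yield a missing p-value, never a silent 1.

## What the cohort experiments show

With 72 phantoms under the glioma design (the cohort size used throughout;
the full run takes seconds):

* **b-values**: zero significant pairs — the mono-exponential mechanism
  above.
* **Gray levels**: nearly every feature shifts by orders of magnitude,
  because features depend on the indices $(i,j)$ and on $p(i,j)$, both of
  which rescale with $N$. Correlation, which normalizes by the marginal
  moments, is the exception.
* **Quantization method**: most features shift; Manual limits spanning
  0–3000 compress a typical ROI's histogram into the middle bins relative
  to AutoROI.
* **Resolution and noise**: smoothing (block averaging) suppresses
  neighbor differences, noise inflates them; roughly half to most features
  react.
* **Delineation**: expanding the ROI by one voxel into an adjacent fluid
  slab stretches the AutoROI intensity range dramatically, while fixed
  Manual limits (500–1500, a parenchyma-and-tumor window) absorb it; the
  majority of features change less under Manual.

These are the package's reproducible, qualitative statements; the exact
p-values depend on the phantom cohort and are not estimates of any
patient-data quantity.

## Limitations

Feature sensitivity is measured distribution-wise across a cohort, not
voxel-wise; a parameter that shifts all ROIs identically *and* strongly is
flagged, but a parameter that merely reorders ROIs without moving the
distribution would not be. The Bonferroni correction is deliberately
conservative, matching the design's emphasis on confident claims of
sensitivity. All conclusions are conditional on the phantom model stated
above.
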