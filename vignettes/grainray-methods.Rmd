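---
title: "grainray: methods, phantom design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{grainray: methods, phantom design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainray)
```

## The measurement model

A transmission radiograph records, at each detector pixel, the photon count
$I$ surviving the beam's passage through whatever material lies along it.
For thin biological samples this follows the Beer–Lambert law,
$I = I_0 \exp(-\int \mu \, ds)$, so the attenuation line integral is
recovered as $I_\mathrm{corr} = -\ln(I/I_0)$. Because the sample holder
leaves well over half of the detector uncovered, $I_0$ is estimated as the
mode of the integer grey-value histogram; ties are broken towards the
brighter value, since in transmission imaging the background is the
brightest dominant region. Zero counts are floored to one count before the
log (they occur only in saturated-dark pixels inside grains); counts above
$I_0$ — pure noise — keep their small negative attenuation rather than
being clipped, so the background noise statistics survive into the
grey-value SD feature f4.

A paddy grain is, to good approximation for this purpose, a dense starchy
kernel inside a thin, weakly attenuating husk. A chaffy (unfilled) grain is
the husk alone, which is why it is dramatically fainter; chalky kernel
tissue differs from vitreous tissue in its packing, which perturbs both the
local attenuation and its spatial homogeneity.

## Segmentation

The "dual watershed" is implemented as two marker-driven watershed passes:

1. **Foreground/background.** Sure-background and sure-grain markers are
   flooded along the gradient magnitude, so the boundary settles on the
   grain edge. Markers come from a robust model of the background noise:
   the median/MAD of the attenuation map estimate the background spread
   $\sigma$ (the background dominates the image by design), pixels above
   $8\sigma$ are surely grain matter, pixels below $4\sigma$ surely
   background. A global Otsu threshold was considered and rejected: with
   mixed scenes it drops faint husk-only grains (their attenuation is an
   order of magnitude below filled grains), and with sparsely loaded
   holders (a few grains on the full detector) any global two-class split
   lands inside the background noise. Otsu's method remains exported
   (`otsu_threshold()`) as a utility.
2. **Instance splitting.** Within each foreground component, markers are
   the superlevel set of the Euclidean distance transform at 60% of the
   component's maximum. For a convex blob the EDT is concave, so this set
   is connected and yields exactly one marker; for a touching pair each
   grain contributes its own peak. Flooding the negated EDT then assigns
   every foreground pixel to one grain. Tie-breaks in the priority flood
   are FIFO, making label images bit-reproducible.

Cleanup is a binary opening (erosion–dilation) with a disk structuring
element of radius 1.5 px — the full 3×3 neighbourhood — applied to each
segment's own mask so neighbouring segments cannot merge, followed by
dropping segments below `min_area_px` (default 50 px; the smallest
plausible grain at 49.5 µm pixels is orders of magnitude larger).
Everything uses 8-connectivity, 0-based row-major coordinates and
half-open bounding boxes; segments are relabelled in lexicographic bbox
order so CSV outputs are reproducible.

## Features

All grey-value features (f2, f3, f4, f6) are computed on the *normalized*
attenuation image: the virtual weight f3 is defined as a sum of normalized
grey values, and computing f2/f4 on the same image keeps the descriptors
coherent (whether the original analysis used raw or normalized grey values
for f2/f4 is not documented; the normalized choice is the default and the
functions accept any attenuation matrix, so a raw-image variant is a
one-line change). f4 is the *population* standard deviation — it is a
descriptor of the segment, not an estimator of anything beyond it.

The minimum covering circle (f7) is computed on pixel centers via Welzl's
incremental algorithm applied to the convex hull, with a deterministic
pseudo-random insertion order; a single-pixel segment has radius 0 by
convention. A consequence of using pixel centers is that f8 = f5/f7 can
marginally exceed 1 for small rasterized disks (the equal-area radius
"sees" the half-pixel rim that the covering circle of centers does not); a
rasterization tolerance of 0.02 is admitted throughout and values are not
clipped in stored tables.

## Embedding and trait models

Features are z-scored per column (population SD; zero-variance columns get
$\sigma = 1$ so they scale to zeros rather than dividing by zero) and
embedded with a three-component PCA — three components are what all three
trait models operate on. The PCA uses the population covariance for
consistency with the scaler; loadings are sign-fixed (largest-magnitude
loading positive) so serialized models reload to identical projections.
The per-trait feature subsets are fixed to the published ones rather than
re-derived by correlation screening — reproducibility over automation:
all of f1–f8 for chaffiness, (f2, f3, f4, f6) for chalkiness,
(f1, f3, f4, f5, f7) for HRR.

**Chaffiness.** The non-chaffy grains form one cluster in PC space,
summarized by its sample mean and covariance; a grain is chaffy when its
Mahalanobis distance exceeds θ = 17 (normalized PCA units), using a strict
`>` so a grain exactly at the threshold stays non-chaffy. The threshold is
a fixed operating point of the published method, not refitted. Distances
use the Cholesky factor; near-singular covariances are ridged with a
warning.

**Chalkiness and virtual de-husking.** The chalky/non-chalky separator is
a linear soft-margin SVM (dual coordinate descent, C = 1 recorded in the
model JSON; no SVM library dependency) fitted on *kernel* (de-husked)
ground-truth data in PC space. Whole grains are classified after a
feature-space translation: with $\mu_\mathrm{GT}$ the kernel ground-truth
mean and $\mu_\mathrm{grain}$ the whole-grain mean over (f2, f3, f4, f6),

$$x_\mathrm{kernel} = x_\mathrm{grain} + (\mu_\mathrm{GT} - \mu_\mathrm{grain}).$$

The sign is chosen so the operation performs its stated purpose: the
shifted population mean coincides *exactly* with the kernel ground-truth
mean (removing a husk must move features towards kernels, i.e. downwards
for weight-like features). The source description of this shift is
ambiguous about both the sign and whether it acts on features or on PC
coordinates; since scaling and projection are affine, both readings are
translations, and the feature-space shift before scaling/PCA is
implemented. The shift is global, not per-cultivar. A decision value of
exactly 0 counts as non-chalky. CRK% is simply
$100 \cdot n_\mathrm{chalky} / n_\mathrm{total}$.

**HRR.** Head-rice recovery cannot be measured per grain (milling needs
~20 g), so grains inherit the class of their milling subset, discretized
into five classes (100/80/60/40/20% HRR). One linear SVM per class
(one-vs-rest) with Platt sigmoid calibration — fitted by minimizing the
cross-entropy against Platt's smoothed targets, which stays finite on
separable data — gives each grain five membership probabilities. The
predicted class is the argmax; its probability is the reported
reliability; exact ties resolve to the lowest class value (a conservative
recovery estimate). The sample-level HRR% is the arithmetic mean of the
per-grain class values — the simplest unbiased aggregation; the original
study does not state how its per-grain classes became sample values.

## The phantom

Each grain is two coaxial ellipsoids: the outer surface bounds the husk,
the inner (outer semi-axes each reduced by the husk thickness) holds the
kernel. A parallel beam is assumed — the through-thickness of an ellipsoid
with semi-axes $(a, b, c)$ at in-plane offset $(x, y)$ is
$2c\sqrt{1 - x^2/a^2 - y^2/b^2}$ — because the cone-beam magnification is
essentially constant over the thin holder and the analysis operates in
pixel units; acquisition geometry (voltage, current, exposure, distances)
is carried as metadata only. Counts are
$\mathrm{clip}(\mathrm{round}(I_0 e^{-\sum \mu t} + \varepsilon), 0,
2^{14}-1)$ with additive Gaussian noise $\varepsilon$ (default SD 0.5% of
$I_0$) on a 14-bit detector of 1300 × 2304 pixels at 49.5 µm — the study
scanner's active area — and $I_0 = 12000$ counts.

Defaults emulate life-size slender paddy grains: in-plane semi-axes
$a \sim \mathcal{N}(42, 3)$ px (≈ 8.3 mm length), $b \sim \mathcal{N}(12,
0.9)$ px, depth semi-axis $c = 0.95\,b$, husk 1.8 px thick,
$\mu_\mathrm{husk} = 0.025$, $\mu_\mathrm{kernel} = 0.10$ per pixel
length. Grains sit on a fixed grid with pitch 2.2× the maximal grain axis
per direction (the holder guarantees non-touching grains; a dedicated
`touching_pair_scene()` fixture exercises the instance watershed).
Trait labels are apportioned exactly (largest remainder) and positions
shuffled under the scene seed; identical seeds give field-identical scenes
and bit-identical renders.

* **Chaffy** grains are empty husk shells (kernel absent) — physically
  faithful and the reason real chaffy grains are near-transparent.
* **Chalk** is modelled as *lower* attenuation (`chalk_factor = 0.85`)
  in a randomly placed sub-ellipse covering `chalk_fraction` of the kernel
  footprint. The radiographic contrast sign of chalky tissue is not
  documented anywhere we know of; the sign and magnitude are free
  simulator parameters, stated here as an assumption. A grain is chalky in
  truth tables iff `chalk_fraction > 0.20`, mirroring the > 20%
  opaque-area rule, with strict inequality at the boundary. Non-chalky
  grains may carry small (≤ 15%) inclusions so the negative class is not
  artificially clean.
* **HRR classes** map monotonically to generative parameters — class value
  $v \in \{100, \dots, 20\}$ gives size scale $0.86 + 0.0014v$, kernel
  density scale $0.90 + 0.0010v$ and a multiplicative kernel mottle with
  SD $0.0025(100 - v)$ — because poorer-milling grains are smaller, less
  dense and more heterogeneous. HRR experiments additionally use
  `hrr_subset_geometry()`: a 20 g milling subset comes from one cultivar
  and one harvest, so its within-subset geometric and density CV (2%) is
  far smaller than the across-cultivar default (≈ 7%). This map is the
  package's own construction; the original study states only that HRR is a
  complex multi-feature trait.

**What a green test establishes — and what it does not.** The phantom has
exact ground truth, ellipsoidal geometry, uniform tissues, Gaussian noise
and no scatter, beam hardening, detector blur or cultivar-specific shape
statistics. Green trait-recovery tests therefore establish that the
pipeline is *internally correct and well-conditioned* — segmentation
recovers known grains, the embedding and classifiers recover known,
adequately separated class structure. They do not establish the field
accuracies of the original study (its scans were never deposited), and the
published R²/RMSE values are used only to motivate tolerance choices.

## Numerical choices and conventions

* Histograms for $I_0$ run over native integer grey levels (one bin per
  level); float inputs are rounded first.
* The noise-free normalization round-trip is exact up to count
  quantization: the attenuation error at a pixel with $I$ counts is
  bounded by $2/I$ ($2/I_0$ on background). The bound is checked per
  pixel at its own scale.
* The minimum-enclosing-circle containment tolerance is $10^{-9}$;
  circumcircles of near-collinear triples fall back to the widest diameter
  circle.
* SVM: dual coordinate descent with fixed sweep order (no shuffling),
  projected-gradient stopping at $10^{-9}$, bias via feature augmentation
  (regularized). Duplicated separable training sets reproduce the same
  hyperplane.
* PCA rank deficiency below three components raises a warning and pads
  explained-variance ratios with zeros.
* All stochastic stages take explicit integer seeds; package internals
  save and restore the caller's RNG state.
* On-disk rasters are ASCII PGM (16-bit capable, plain text) plus 8-bit
  PNG previews; floating-point images are TSV; models and reports JSON;
  configs YAML. TIFF is not supported in this build (no TIFF codec among
  the supported dependencies).

## Known limitations

* The virtual de-husking shift is global; grain types whose husk/kernel
  partition deviates from the training population (e.g. short-bold types
  in the original study) will be biased.
* One-vs-rest linear separators cannot isolate *middle* HRR classes that
  lie between their neighbours in PC space; per-grain confusion is mostly
  adjacent-class, which largely cancels in the sample mean but caps
  per-grain accuracy.
* Watershed splitting handles touching pairs with distinct distance
  peaks, not heavily overlapping grains or in-panicle imagery.
* The chalk contrast sign is an assumption (see above); if real chalky
  tissue attenuates *more*, the phantom and the sign conventions of the
  hyperplane orientation still apply, but retraining on correctly signed
  data is required.
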