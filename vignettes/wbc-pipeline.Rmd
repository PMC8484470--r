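---
title: "Segmenting and classifying white blood cells with wbcseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and classifying white blood cells with wbcseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbcseg)
```

## The problem

Differential counting of the five peripheral-blood leukocyte types
(lymphocyte, monocyte, neutrophil, eosinophil, basophil) from stained
smear images is a routine haematology task. `wbcseg` implements a
training-free, interpretable pipeline for single-cell crops: segment the
nucleus from colour-space arithmetic, approximate the cytoplasm by the
convex hull of the nucleus, describe the cell by 51 shape and colour
features, and classify with a class-weighted SVM. Everything runs at
native image resolution; no resizing, no learned segmentation model.

## Nucleus segmentation

Giemsa-type stains render the chromatin-rich nucleus a dark purple and
leave cytoplasm and erythrocytes pink to salmon. The segmenter exploits
this with pure colour arithmetic:

1. **Colour balancing.** Each channel is rescaled so its mean equals the
   mean of the luma grayscale (`new = old * mean(gray)/mean(old)`,
   rounded and clipped to [0, 255]). This cancels global stain and
   illumination casts. We use BT.601 luma weights (0.299, 0.587, 0.114);
   the procedure is idempotent up to rounding.
2. **Soft map.** From the balanced crop we take the K and M planes of a
   naive CMYK decomposition (`K = 1 - max(R,G,B)`,
   `M = (1 - G - K)/(1 - K)`, with `M = 0` on pure black) and the
   saturation plane S of HSL. Red cells and cytoplasm are brighter in K
   than in M, the nucleus is the opposite; background and red cells have
   small `min(M, S)`. The map `min(M, S) - (K - M)` is therefore high on
   the nucleus and near zero elsewhere. Both subtractions are clipped at
   0: negative values carry no nucleus evidence, and clipping keeps the
   map a nonnegative evidence image on [0, 1].
3. **Otsu threshold.** The map is quantized to 256 uniform bins and the
   threshold maximizing between-class variance is chosen; ties go to the
   lowest qualifying threshold and foreground is *strictly above* the
   threshold. A constant map has no separating threshold and yields an
   empty mask with a warning.
4. **Clean-up.** Interior holes are filled, components below 1% of the
   image area are dropped, and the component whose centroid is nearest
   the image centre is kept — the target cell of a single-cell crop. A
   `keepAll` switch retains all surviving components instead, which can
   help when the lobes of a neutrophil nucleus disconnect.

All planes live on a common [0, 1] scale, which is what makes mixing
CMYK and HLS components arithmetically meaningful. LAB conversions use
the D65 white point with sRGB companding and 8-bit-style rescaling;
YCbCr uses BT.601 full range. These constants are fixed in code so
results are reproducible bit for bit.

## The cytoplasm proxy (ROC)

Cytoplasm boundaries are genuinely hard to segment, so the pipeline
never tries. Instead the convex hull of the nucleus is rasterized (a
pixel belongs to the hull if its centre is inside or on the hull polygon
of the nucleus pixel centres) and the **representative of the cytoplasm
(ROC)** is the hull minus the nucleus. The hull spans all nucleus
pixels, not single components, so for a lobed nucleus the ROC captures
the inter-lobe cytoplasm. The more convex the nucleus, the smaller the
ROC — itself a class signal.

## Features

Three shape descriptors of the nucleus,

* solidity = area(nucleus) / area(hull),
* convexity = perimeter(hull) / perimeter(nucleus),
* circularity = perimeter(nucleus)^2 / (4 * pi * area(nucleus)),

plus four colour ratios — mean(nucleus)/mean(hull), sd(nucleus)/sd(hull),
mean(ROC)/mean(hull), sd(ROC)/sd(hull) — on each of 12 colour planes
(R, G, B; H, S, V; L*, a*, b*; Y, Cr, Cb), for 3 + 48 = 51 features in a
fixed, fingerprinted order.

Measurement conventions that matter:

* **Perimeter** is the length of the closed polygon traced through the
  boundary pixel centres (Moore contour). A 10 x 10 square thus has
  perimeter 36, and digitization biases the perimeter of smooth shapes
  upward by roughly 5%, so the circularity of a rasterized circle is
  about 1.10 rather than 1.0. The estimator is deterministic and
  oracle-checkable, which we value over unbiasedness; tests allow
  solidity and convexity 3% and circularity 12% around analytic values.
* **Statistics are population statistics** (divide by n): regions are
  full pixel sets, not samples.
* **Guards, not NaNs.** A hull statistic below 1e-6 zeroes the ratio and
  an empty ROC zeroes all 24 ROC entries, keeping vectors finite for the
  SVM. A perfectly convex nucleus genuinely has no ROC signal.
* Features are computed on the **original** crop; colour balancing is
  internal to segmentation.
* Nuclei below 16 px are rejected as artefacts.

## Classification

Features are min-max normalized with statistics learned on the training
set only (constant features map to 0; test values are clamped into
[0, 1]). The SVM is C-classification with one-vs-one multi-class
decomposition, class weight 1 for every class except neutrophils. The
neutrophil upweighting reflects that neutrophil morphology (multi-lobed,
variable) is both the hardest and, in normal blood, the most abundant
class. Defaults are the grid-search winner on real smear data:
polynomial kernel of degree 3, C = 6, neutrophil weight 10.

`gridSearchWBC()` reproduces the selection protocol: stratified 5-fold
cross-validation over the 108-point grid {linear, rbf, poly3} x
{1, 2, 5, 10, 15, 20} x {1, 2, 4, 6, 8, 10}, reporting mean and standard
deviation of fold accuracies per configuration. Normalization is refit
inside every training fold, so no statistics leak from validation folds.
Unstated auxiliaries are fixed to mainstream defaults and documented:
gamma = 1/(51 * var(normalized features)), coef0 = 0, argmax ties broken
by smaller C, then smaller weight, then kernel order linear < rbf <
poly3, and a seeded fold assignment.

## Augmentation

Training sets are balanced with geometric transforms only: horizontal
and vertical flips, rotation uniform in [-90, 90] degrees, rescale
uniform in [0.8, 1.2], and compositions. The canvas never changes:
rotation is about the crop centre and rescaling is followed by centre
crop or padding, with the border-median colour as fill. Interpolation is
bilinear. Photometric augmentation is deliberately out of scope.

## The synthetic generator

`makeCrop()` renders parametric Giemsa-like crops with exact ground
truth: a pale background, salmon erythrocyte disks placed away from the
cell, a pale low-chroma cytoplasm ellipse, and a class-typical nucleus
— a near-convex ellipse for lymphocytes, a kidney-shaped (indented)
ellipse for monocytes, 3–4 bridged lobes along an arc for neutrophils,
two bridged lobes for eosinophils, and for basophils a granulated whole
cell, whose ground truth is the whole cell because granules obscure the
nucleus. Mild per-channel gain jitter (0.95–1.05) and uniform pixel
noise (default ±2 levels) are added; the truth mask equals the
rasterized geometry exactly.

Palette centres follow the stain's colour logic: the nucleus is a dark,
G-poor purple (high M), and the cytoplasm is deliberately low-chroma so
that `min(M, S)` suppresses it — the premise the soft map rests on. The
kidney/lobed shapes are not cosmetic: with a perfectly convex nucleus
the hull equals the nucleus, the ROC is empty and all 48 ratio features
collapse to the same point for every mononuclear class, so realistic
nuclear irregularity is what gives the colour ratios any class signal.

What passing tests on this generator do **not** show: robustness to
touching or overlapping cells, stain variability beyond a global cast,
focus blur, or camera response — real-data performance must be
established on real, expert-annotated crops (the package reads standard
8-bit PNG/JPEG/TIFF crops and {0, 255} mask PNGs for exactly that
purpose).

`makeFeatureDataset()` complements the renderer with 51-dimensional
Gaussian class clusters at a controllable separation (inter-mean
distance as a multiple of the within-class standard deviation, class
means on orthonormal directions), for classifier tests that need exact
separability statements.

## Numerical choices and degenerate inputs

* Images below 8 x 8, non-8-bit values and non-integer channels are
  rejected at the door.
* Blank or constant crops give a degenerate soft map: empty mask plus
  warning, and feature extraction fails with a clear error.
* Collinear "nuclei" are their own convex hull (the hull polygon is
  degenerate).
* Otsu, the hull rasterization, and fold assignment are exactly
  deterministic; every stochastic step (generator, augmentation, fold
  shuffling) is seeded.

## Problem sizes

The test suite and the acceptance script run on 96 x 96 crops, 100-crop
segmentation datasets (20 per class), 120-crop classification datasets
with a stratified 70/30 split, and 50-sample feature sets for the grid
search — sizes chosen so the whole suite completes in well under a
minute on one core while every claim (DSC, accuracy, oracle
equivalences) is still measured, not assumed.

## Known limitations

* Single-cell crops only; no whole-slide or multi-cell scenes and no
  touching-cell splitting.
* The ROC is a proxy, not a cytoplasm segmentation; true cytoplasm
  boundaries are out of scope by design.
* The contour-polygon perimeter overestimates smooth boundaries by a
  few percent; circularity values are comparable within this package
  but not directly against analytic values.
* Basophils are evaluated against whole-cell ground truth; the
  segmenter itself has no basophil special-casing.
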