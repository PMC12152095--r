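---
title: "Detecting hidden aphid colonies in VNIR hyperspectral imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hidden aphid colonies in VNIR hyperspectral imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aphidSID)
```

## The problem

Black bean aphids colonize the underside of faba bean leaves. The
colonies are invisible from above, yet they alter the leaf's
visible/near-infrared reflectance: part of the NIR light transmitted
through the lamina interacts with the aphid bodies and returns to the
sensor, depressing the apparent reflectance of infested tissue across
the red edge and NIR plateau. `aphidSID` turns that physical signal into
three products: a pixel-level **infestation map**, a leaf-level
**healthy/infested call**, and an estimated **aphid count** with a
Low / Medium / High severity band.

## Spectral Information Divergence

Every pixel spectrum $x = (x_1,\dots,x_L)^\top$ is treated as a discrete
probability distribution over its bands,

$$p_l = \frac{x_l}{\sum_{k=1}^{L} x_k},$$

and two spectra are compared by the symmetric relative entropy

$$\mathrm{SID}(x,y) = D(p\|q) + D(q\|p), \qquad
  D(p\|q) = \sum_l p_l \log\frac{p_l}{q_l}.$$

SID is non-negative, symmetric, zero exactly when the normalized spectra
coincide, and invariant to positive scaling of either spectrum — so it
responds to spectral *shape*, not illumination level. Three numerical
choices matter and are fixed package-wide:

- **Natural logarithm.** Any fixed base only rescales SID, so scores and
  thresholds are reported in nats.
- **Flooring.** Calibrated reflectance can dip below zero; probabilities
  are undefined there. Entries are clipped to a floor of $10^{-12}$
  before normalization, which keeps every divergence finite without
  measurably perturbing well-behaved spectra.
- **Threshold direction.** The reference is built from *infested*
  material, so **low** SID means "similar to aphid" and pixels at or
  below the threshold are marked infested. Otsu's method on the finite
  scores is the default; a fixed threshold is available for constant or
  heavily skewed maps, and the chosen value is always recorded on the
  output mask.

The SID map is computed inside a wavelength window, by default
**710–825 nm**: the red-edge region where the aphid-body signal is
strongest relative to healthy-tissue variation. Windows resolve to the
nearest band on each side, inclusive, with half-way ties rounded toward
the window interior; on the default 224-band 380–1000 nm grid the
710–825 nm window spans 42 bands.

## From cube to reference spectrum

1. **Calibration.** $R = (\mathrm{raw} - \mathrm{dark}) /
   (\mathrm{white} - \mathrm{dark})$ element-wise; single-line white and
   dark frames broadcast along the scan axis of a push-broom
   acquisition. Negative values are preserved (they carry information
   about calibration noise) and only floored inside SID.
2. **Segmentation.** A linear-kernel SVM trained on a few hundred
   labeled plant and background pixels; the plant/substrate contrast
   makes this near-separable. The mask is then eroded with a 5×5
   all-ones structuring element under **zero padding** — pixels outside
   the image count as background, so the mask also shrinks at image
   borders. Zero padding is deliberate: the erosion exists to remove
   spectrally mixed edge pixels, and border pixels are exactly as
   suspect as interior edges.
3. **Endmembers.** N-FINDR inflates a simplex in the PCA projection of
   the masked pixels to $K-1$ dimensions ($K = 6$ by default):
   starting from a seeded random vertex set, every vertex is tested
   against every candidate pixel and any replacement that strictly
   increases the simplex volume $|\det[\,\mathbf{1};\,V\,]|/(K-1)!$ is
   accepted, until a sweep changes nothing. Because single runs are
   initialization-sensitive, 10 seeded restarts are run and the
   largest-volume simplex kept. Returned endmembers are always actual
   pixels of the cube (the pure-pixel assumption).
4. **Reference.** On infested imagery only a minority of the $K$
   endmembers carry the aphid signature; the others are healthy-tissue
   variants, and averaging all of them drags the reference toward
   healthy tissue. `aphidEndmembers()` therefore scores each endmember
   by its in-window SID against the plant-mean spectrum and keeps those
   with above-average divergence; the reference is the band-wise mean of
   that subset. `buildReference()` still defaults to averaging all
   endmembers, with the subset as an explicit argument.

Abundances come from fully constrained least squares (non-negative,
sum-to-one), solved by eliminating the equality constraint via its
Lagrange system and clamping negative abundances with an active-set
iteration; the per-pixel residual norm is returned for diagnostics.

## Detection and quantification

Leaf-level detection uses mean-leaf spectra, SNV pre-treated, with
wavelengths selected by a 200-tree bagged random forest: out-of-bag
permutation importance, max-normalized, with bands above 0.5 retained.
Four classifiers are available (LDA; RBF-SVM; KNN; a feedforward neural
network). The evaluation protocol is a stratified 60/40 train/test split
(per-class floor rounding: 336 balanced spectra give 200 train / 136
test) with stratified 10-fold cross-validation repeated over re-drawn
fold partitions on the training portion; per-class accuracies are
class-conditional recalls, and AUC/F1/precision take the infested class
as positive.

Choices the protocol leaves open were fixed as follows:

- **RBF-SVM hyperparameters**: inner 3-fold grid search over
  $C \in \{0.1, 1, 10, 100\}$ and $\gamma \in \{0.1, 1, 10\}/p$
  ($p$ = feature count; features are standardized inside the SVM, making
  $1/p$ the natural scale). The search runs once on the training
  portion and the winning pair is held fixed across CV folds.
- **KNN**: $k = 5$, Euclidean distance; the odd $k$ avoids vote ties in
  a two-class problem.
- **ANN**: a single hidden layer of 32 logistic units with softmax
  output, weight decay $10^{-3}$, seeded initialization. A compact
  single-hidden-layer network is sufficient at these feature counts
  (22–224 bands) and keeps training deterministic and fast; "three
  layers" is read as input–hidden–output.
- **Per-class accuracy** columns (A = healthy, B = infested) are
  class-conditional recalls — the only decoding under which a per-class
  "accuracy" is well defined.

Aphid counts are regressed from infested-area spectra by PLS1 (NIPALS),
with X and y mean-centered inside the fit and pre-treatments (raw, SNV,
log(1/R), Savitzky–Golay first/second derivative) applied beforehand on
a shared split. The latent-variable count is chosen at the minimum
10-fold RMSECV with a one-standard-error tie-break toward fewer
components (capped at 50). RMSE uses $1/n$, making hand-oracle tests
exact; $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$. Severity bands are
Low $< 20$, Medium $20$–$50$, High $> 50$ aphids per leaf; the boundary
counts 20 and 50 belong to Medium, consistent with 50 aphids/leaf being
the economic-threshold *reference* rather than already above it.

Other fixed numerical conventions: SNV uses the sample ($n-1$) standard
deviation (the dominant chemometric convention); log(1/R) is base 10
(absorbance convention) with floor $10^{-4}$; derivatives are
Savitzky–Golay (window 7, polynomial order 2) rather than raw finite
differences, which would be hostile to 224 noisy bands, and edge bands
use the polynomial fit within the edge window so polynomial spectra are
differentiated exactly everywhere.

## The synthetic scene generator

No instrument data ship with the package; the generator provides the
study conditions every test runs under. A scene is a filled-ellipse leaf
of a smooth *healthy* archetype on a dark substrate, with an elliptical
patch whose pixels are convex mixtures
$(1-a)\,\mathrm{healthy} + a\,\mathrm{aphid}$; $a$ grows linearly with
the aphid count (slope 0.01, saturating at 1). Archetypes are parametric
curves — a logistic red edge at 715 nm rising to a 0.58 NIR plateau,
Gaussian pigment features in the visible, and an aphid signature that
subtracts a depression centred near 770 nm plus a sustained NIR offset,
scaled by a depth parameter (default 0.6). The depression is deepest
inside 710–825 nm, so the class contrast peaks where the real signal
does. Noise is per-pixel lognormal multiplicative gain (sd 0.05 — the
scatter SNV exists to remove) plus i.i.d. additive Gaussian noise
(sd 0.005 reflectance units).

Labeled campaigns draw counts uniformly from 5–100, spanning all three
severity bands; the floor of five reflects the founding colony of five
adult aphids placed under each infested leaf, below which counts do not
occur in the emulated design. The default campaign size is 168 samples
per class (336 total). Mean-leaf spectra are synthesized directly from
the archetypes (patch fraction 0.25) rather than by averaging full
scenes — distributionally equivalent and orders of magnitude faster.

What the generator does *not* emulate: radiative-transfer leaf optics,
within-class biological variation of healthy tissue, multi-leaf
canopies, specular effects, sensor striping, or temporal colony growth.
Tests passing on these scenes therefore demonstrate the correctness of
the algorithms under controlled conditions — not field-level
performance, which depends on exactly the variation the generator
omits.

## Problem sizes and reproducibility

The test-suite and acceptance computations use 64×64-pixel scenes with
224 bands, 336-spectrum campaigns, 10-fold CV repeated 10 times, toy
N-FINDR instances of 20–60 pixels checked against exhaustive
maximum-volume search, and 1000 random spectrum pairs for the SID
oracle — sizes chosen so a full run completes in about a minute on one
core while still exercising every code path at realistic
dimensionality. Every stochastic step takes an explicit seed; the
pipeline fans a single master seed out to per-stage seeds by fixed
offsets, so stages are independently reproducible and repeated runs are
byte-identical apart from log timestamps.

## Known limitations

- The pure-pixel assumption of N-FINDR fails if no pixel is close to a
  pure aphid signature; abundance maps then underestimate infestation.
- Otsu thresholding assumes a roughly bimodal SID score distribution;
  sparse or diffuse colonies may need the fixed-threshold path.
- The PLS count model is linear in the (pre-treated) spectra; counts
  beyond the saturation of the count-to-abundance mapping (≥ 100 under
  defaults) are not identifiable.
- LDA on full spectra operates with more bands than samples; it relies
  on the generalized inverse behaviour of the underlying discriminant
  fit and is included for protocol completeness rather than recommended
  use.
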