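---
title: "Methods: automated glaucoma screening from fundus photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated glaucoma screening from fundus photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The screening problem

Glaucoma damages the optic nerve head long before a patient notices field
loss, and the damage is visible in an ordinary colour fundus photograph as
an enlarged optic cup (OC) relative to the optic disc (OD) and as thinning
of the neuro-retinal rim (NRR). `fundoscreen` implements a complete
screening chain over such photographs:

1. **OD localization** by morphological enhancement and sliding-window
   confidence over intensity and vessel feature maps;
2. **simultaneous OD/OC segmentation** on a square region of interest
   (ROI) with an encoder-decoder network carrying a *concatenating path*
   and trained with a *fusion loss*;
3. **ellipse post-processing** of the raw masks;
4. **25 clinical features** (CDR family and ISNT family) from the fitted
   geometry;
5. **risk classification** with SMOTE oversampling and gradient-boosted
   decision trees, evaluated by 10-fold cross-validation.

Every stage is exercised on a seeded synthetic fundus generator, so the
whole pipeline is testable without downloading any dataset.

# Optic-disc localization

The gray-level image (luminance weights 0.299/0.587/0.114) is enhanced as

$$F' = F + G_T - G_B,$$

where $G_T$ and $G_B$ are the white top-hat and black bottom-hat
transforms with a disc structuring element. The element must be *larger
than the disc* for the top-hat term to lift the disc above the background
(a vessel-scale element would leave the disc untouched and only darken
vessels); the default radius is a fifth of the image side, which exceeds
the largest disc the generator draws. Pixels in the top 6.5% of the
enhanced dynamic range (value $\ge 0.935 \cdot \max F'$) form the
disc-candidate map. We read the published "pixels bigger than 6.5% of the
maximum" rule as the top 6.5% *of the dynamic range*: the literal reading
(anything above $0.065\max$) would select nearly the whole fundus and
contradict the stated intent of isolating the brightest area.

Vessels are extracted from the CLAHE-equalised green channel — the channel
where vessel/background contrast is strongest — as the bottom-hat minus
top-hat response $F_{vessel} = G_B - G_T$ with a 15 px element, thresholded
by Otsu's rule on the nonzero response and median-filtered (3×3). The
binary map is clipped to an eroded, hole-filled field-of-view mask: the
dark rim of the camera aperture itself responds strongly to the bottom-hat
and would otherwise dominate the map. This guard is standard practice in
retinal vessel analysis.

A square window then scans three maps — the binary candidate map, the
vessel map, and their pixelwise mean (the fusion map). Each window's raw
score is the in-window sum; scores are min-max normalised to $[0,1]$ per
map (a map whose scores are all equal normalises to zero), and the final
score $s$ is the mean of the three. The window with maximal $s$ is the
disc; ties break to the smallest row, then column.

**Window side.** On a binary candidate map, every window that fully
contains (or is fully contained in) the candidate blob receives the same
raw score, and the deterministic tie-break can land up to half the
size-mismatch away from the true centre. The worst-case offset is
minimised by a window near the *middle* of the expected disc-diameter
range rather than its maximum; the default is 0.28 of the image side
(72 px at 256², against 64–96 px discs). With that choice the localization
error stays below a quarter disc diameter on 100/100 seeded samples; with
a window at the maximum diameter it fails on about one sample in eight.

The ROI is a square of side $1.5\times$ the maximum OD diameter — a
dataset statistic carried in the pipeline configuration, not estimated per
image — shifted (never shrunk) to stay inside the frame.

# Segmentation network

The network is a U-shaped encoder-decoder built from (convolution 3×3,
batch normalisation, ReLU) ×2 blocks with 2×2 max pooling. Two additions
define the architecture:

* **Concatenating path.** At every encoder level below the first, the raw
  input image, average-pooled to that level's resolution, is concatenated
  with the pooled features. Each deep level therefore sees a multi-scale
  view of the input, at the cost of `in_channels × 9 × width` extra
  weights per level (verified by parameter counting in the tests).
* **Multi-label head.** The final 1×1 convolution emits two *independent*
  sigmoid channels (disc, cup) — a pixel may belong to both, which matches
  the anatomy (the cup lies inside the disc) and sidesteps the class
  imbalance of softmax labelling.

The decoder mirrors the encoder with nearest-neighbour upsampling followed
by a 3×3 convolution (the up-convolution), skip concatenation from the
matched encoder level, and two conv-BN-ReLU blocks.

## Fusion loss

Training minimises

$$L = \lambda_1 (L_{CE}^{disc} + L_{dice}^{disc})
    + \lambda_2 (L_{CE}^{cup} + L_{dice}^{cup}),
  \qquad \lambda_1 = \lambda_2 = 0.5,$$

with per-channel terms

$$L_{CE} = -\tfrac1N \sum_i \left[ w\, q^i \log p^i + (1 - q^i)
  \log (1 - p^i) \right], \qquad
  L_{dice} = -\frac{2 \sum_i p^i q^i}{\sum_i (p^i)^2 + \sum_i (q^i)^2
  + \varepsilon}.$$

Two readings deserve a note. The Dice term is implemented as the standard
soft Dice with the sums *inside* the ratio; a per-pixel ratio that is then
summed degenerates to counting positive pixels and cannot serve as a Dice
coefficient loss. The cross-entropy uses the two-term binary form; the
one-term form (positive pixels only) would ignore false positives
entirely. The positive-class weight $w$ of the weighted cross-entropy is
exposed and defaults to 1. Probabilities are clipped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-7}$, which also
guards the Dice denominator; at a perfect prediction the loss attains its
lower bound $-(\lambda_1 + \lambda_2) = -1$.

The layer primitives (im2col convolution, pooling, upsampling, batch
normalisation) are implemented in C++ (RcppArmadillo) with the training
loop, Adam optimiser and augmentation in R. Analytic gradients are checked
against numerical differentiation through the whole network in the test
suite. Augmentation applies seeded flips, rotation, colour jitter and a
small affine transform, with nearest-neighbour resampling for masks.

## Desk-scale training conditions

The reference training protocol (Adam, learning rate $10^{-4}$, 256×256
inputs, 500 epochs, a 450/50/150 split) targets GPU-scale runs on a real
annotated dataset. The package's own experiments, including the test suite
and `scripts/acceptance.R`, use a desk-scale configuration chosen once: 40
training / 10 validation ROIs at 128×128, encoder widths (16, 32, 64),
batch size 8, learning rate $10^{-3}$, 30 epochs. On the synthetic data
this reaches a validation disc overlap around 0.98 and cup overlap around
0.85 in a few minutes on one CPU core; those scores say the implementation
learns the task the generator poses, *not* that it reproduces published
scores on real datasets, which are out of scope here. Early stopping is
available (`early_stop_patience`) but off by default, honouring the
fixed-epoch protocol.

# Ellipse post-processing

The raw binary masks are reduced to their largest connected component,
hole-filled, and opened with a 3 px disc. Hole-filling must precede the
opening: salt-and-pepper corruption punches interior holes, and an erosion
applied first would eat the blob from every hole simultaneously. Contour
pixels are then taken from a Canny detector (Sobel gradients, non-maximum
suppression, two-threshold hysteresis with automatically scaled
thresholds) and fitted with the numerically stable direct least-squares
conic fit constrained to ellipses. The fitted disc and cup are re-rendered
as filled ellipses and the cup is clipped by the disc, enforcing the
anatomical containment that raw network output cannot guarantee. On
rendered ellipses the fit round-trips centre and axes within 1 px and
rotation within 0.05 rad (rotation is compared modulo $\pi$ and is only
meaningful away from circularity, so the round-trip draws use aspect
ratios of 0.6–0.9).

# Clinical features

From the fitted ellipses: vertical CDR (vertical cup extent over vertical
disc extent), horizontal CDR, the two diameters, ellipse areas
($\pi a b$), their ratio, and both eccentricities. From the masks: the rim
(disc minus cup) is split into four 90° sectors about the cup centroid,
with boundaries at ±45° from the image axes; superior is image-up and the
nasal/temporal pair follows eye laterality (right eye: temporal =
image-left). Per sector we record area, area-to-disc ratio, and mean
radial thickness — the average over rays from the cup centre of the
outermost disc radius minus the outermost cup radius, 180 rays over the
circle. The ISNT rule holds when inferior ≥ superior ≥ nasal ≥ temporal
mean thickness (ties allowed); its margin is the smallest consecutive
difference, negative when violated. Together with the rim area and
rim-to-disc ratio this yields the canonical 25-feature vector; the roster
is versioned in `clinical_feature_names()`. Radial (rather than
boundary-normal) thickness was chosen for simplicity and because the two
coincide on the near-circular geometry the features are consumed on.

# Classifier

Feature selection runs in three stages with defaults chosen where the
published description names the analyses but no cutoffs: a variance filter
on min-max-scaled features (cutoff 0.005), a greedy correlation filter
(|r| > 0.95, dropping the member with the weaker point-biserial label
correlation), and a 10-tree random-forest Gini ranking from which the top
8 features are kept. SMOTE (k = 5 neighbours) balances the classes by
interpolating between minority nearest neighbours; gradient-boosted trees
(100 rounds, depth 3, learning rate 0.1 — likewise unstated in the source
description) fit the balanced table. Cross-validation is stratified
10-fold with selection and SMOTE fitted *inside* each training fold; the
test suite verifies the protocol by showing that label permutation drives
the held-out AUC to chance. Ranking is computed on the original
(unresampled) training data, not after SMOTE, so importances are not
biased by interpolated points.

# What the synthetic generator does and does not emulate

Each sample is a reddish-orange background behind a circular aperture with
multiplicative vignetting and per-sample brightness jitter, a bright
elliptical disc containing a brighter elliptical cup, tapering dark
Bézier-curve vessels converging into the disc (starting just outside the
cup), Gaussian pixel noise, and 8-bit quantisation so PNG round-trips are
exact. Class structure: vertical CDR is drawn from U(0.25, 0.45) for
healthy eyes and U(0.60, 0.85) for glaucoma — clinically plausible ranges
kept disjoint so synthetic ground truth is unambiguous. The cup is offset
superiorly and temporally: a small offset leaves healthy rims obeying the
ISNT ordering with a clear margin, while the larger superior offset of
glaucomatous samples (rim loss) breaks it. The vertical cup/disc semi-axis
ratio equals the drawn CDR exactly, so the mask-level CDR matches the
label's range to within a pixel of quantisation.

The generator deliberately does **not** model fundus texture,
peripapillary atrophy, exudates or haemorrhages, camera distortion, or
inter-image colour variation beyond brightness jitter. Consequently a
passing test suite shows the *algorithms* are implemented correctly and
interact correctly — it does not certify clinical performance on real
photographs, and the published real-data scores are intentionally not
reproduction targets.

# Numerical choices and degenerate inputs

* Degenerate min-max normalisation (all window scores equal) maps to 0.
* Two empty masks have overlap score 1 (perfect agreement).
* Pixels exactly at a binarisation or decision threshold are set
  (≥ rule), documented at each site.
* The balanced accuracy of a mask and the plain accuracy of a classifier
  are deliberately separate functions (`balanced_accuracy`,
  `classification_metrics()$accuracy`) because the two quantities share a
  name in common usage; specificity is the standard true-negative rate.
* Published-style tables round accuracies half-up to 4 decimals
  (`round_half_up`), not half-to-even.
* Coordinates are 1-based (row, column) as native in R; crops are closed
  intervals. Ellipse rotation is normalised to $[0, \pi)$.
* All randomness flows through seeded entry points; the internal helper
  saves and restores the caller's RNG state.

# Known limitations

* The encoder widths of the published architecture figure are not stated;
  (32, 64, 128, 256) is the configurable default, and the desk-scale runs
  use (16, 32, 64).
* The localization stage assumes a single bright disc; images with large
  bright artefacts would need the window score to be robustified.
* SMOTE distances are unscaled Euclidean over the selected features;
  features with large ranges dominate neighbourhoods. The selected-8
  features on synthetic data have comparable scales, so this was left
  simple.
* The fundus-vs-non-fundus input guard is a two-rule heuristic (warm-hue
  fraction, dark aperture corners); it is a stand-in for an unspecified
  component and is tested only against obvious non-fundus inputs.
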