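---
title: "Methods: nuclei segmentation by semantic masks and seeded watershed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nuclei segmentation by semantic masks and seeded watershed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Cytological smears stained with hematoxylin and eosin (H&E) contain cell
nuclei that frequently touch and overlap.  Morphometry-based diagnosis
needs each nucleus as a separate object, but a binary nuclei mask — no
matter how it was obtained — fuses overlapping nuclei into single
connected components.  `nucseg` implements a complete chain that (i)
converts the RGB image into a hematoxylin concentration image, (ii)
produces a binary nuclei mask, (iii) detects which mask components are
clumps of several nuclei, and (iv) splits those clumps with a seeded
(marker-controlled) watershed.

## Stain separation

Light transmission through the stained sample follows the Beer–Lambert
law.  We use the base-10 convention throughout:

$$ OD_c = -\log_{10}\!\frac{\max(I_c, 1)}{I_0}, \qquad OD = W\,H, $$

where $I_c$ is the measured 8-bit intensity in channel $c$, $I_0 = 255$
is the incident (white) intensity, $W$ is the $3\times 3$ stain color
matrix and $H$ holds the per-pixel stain concentrations.  The default
$W$ contains the classic ImageJ H&E absorption vectors — hematoxylin
$(0.650, 0.704, 0.286)$, eosin $(0.072, 0.990, 0.105)$, both
column-normalized, and a residual channel equal to their normalized
cross product.  Concentrations are recovered by the pseudo-inverse,
`deconvolve()`.  Note that some presentations write the forward model
with $e^{-WH}$; the package uses $10^{-WH}$ consistently in both the
deconvolution and the synthetic renderer so that the two are exact
inverses of each other — with a mixed convention every recovered
concentration would be scaled by $\ln 10$.

Zero intensities are clamped to 1 before the logarithm, so optical
density is finite everywhere (at most $\log_{10} 255 \approx 2.4$).

Hematoxylin images are standardized feature-wise before classification:
each position of the $43\times 43$ patch frame is one feature, with mean
and population standard deviation (floored at $10^{-6}$) estimated from
a sample of training patches.  The phrase "position in the image" is
ambiguous between patch frame and whole image; the patch frame is used,
because the statistics are fitted on patches drawn from many image
locations, which makes whole-image positions ill-defined.

## Semantic nuclei masks

The reference mask generator is a small convolutional pixel classifier:
for every pixel, the $43\times43$ standardized hematoxylin patch centered
there is classified into nucleus, nucleus border, cytoplasm or
background; the pixel takes the class of highest probability (exact ties
break by that fixed class order).  The architecture is
conv–conv–pool–conv–conv–pool–dense–dense with ReLU activations,
$2\times2$ max pooling, Xavier initialization, dropout on the hidden
dense layer, and plain SGD with weight decay on softmax cross-entropy.
The reference description does not print kernel sizes or filter counts;
the declared defaults are $3\times3$ kernels with $(32, 32, 64, 64)$
filters and a 512-unit dense layer.  They are defaults, not inferences.

The binary nuclei mask keeps *nucleus* pixels only.  Excluding the
predicted one-pixel border ring is what lets the semantic mask separate
touching nuclei — this is deliberate and configurable
(`mask_from_semantic(..., include_border = TRUE)` restores the fused
behavior).  Two thresholding baselines are provided for comparison:
global Otsu (`mask_otsu`) and adaptive local-mean thresholding
(`mask_adaptive`); the reference description leaves the adaptive window
and offset unstated, so the package declares its own defaults (window
75 px, offset $-0.05$ concentration units, i.e. threshold = local mean
$+ 0.05$).

Desk-scale training: the published training run used $\sim$18M patches
and 20 epochs at learning rate $10^{-4}$ on a GPU.  At the package's
test scale ($\sim$20k synthetic patches, minutes of CPU) that learning
rate cannot move Xavier-initialized weights far enough; tests therefore
use a tiny filter bank $(8, 8, 16, 16)$, a 64-unit dense layer, learning
rate $0.05$ with a per-epoch decay of $0.6$ and at most 6 epochs.  The
`lr_decay` knob exists for exactly this purpose and defaults to 1
(constant rate, the reference behavior).

## Morphometric gating

Mask components are labeled (8-connectivity) and measured:

* area — pixel count;
* perimeter — Crofton 4-direction estimator from $2\times2$ pixel
  configuration counts.  Plain pixel-edge counting overestimates
  perimeter by up to 40% and would depress every roundness value;
  the Crofton estimator is within about 1% of $2\pi r$ on digital
  discs.  The independent test oracle is a Moore contour walk with
  Vossepoel–Smeulders step weights ($0.948$ axial, $1.340$ diagonal);
* roundness — $4\pi A / P^2$.  The printed formula $4A/P^2$ caps at
  $1/\pi \approx 0.318$ for a circle, which contradicts the printed
  empirical roundness range 0.31–0.99; the $4\pi$ normalization is the
  standard definition and reproduces that range, so it is the one
  implemented.

A component is a *single* nucleus iff area $\in [309, 7801]$ px and
roundness $\in [0.31, 0.99]$ (bounds from the reference distribution of
4447 annotated nuclei).  Components below the minimum area are *debris*
and are discarded — an object smaller than the smallest nucleus cannot
contain one.  Everything else is a *clump* and goes to the separator.
With the Crofton estimator a perfectly circular digital disc lands at
roundness $\approx 0.98$–1.0, i.e. right at or above the upper gate;
real (and synthetic) nuclei are elliptical and fall safely inside.

## Seed detection by conditional erosion

Each clump is eroded in two phases with the published structuring
elements: a $7\times7$ octagon $M_c$ (23 px) while the component's area
is at least $T_1 = 350$ px, then the $3\times3$ cross $M_f$ (5 px) while
it is at least $T_2 = 50$ px.  Components are re-identified
(8-connectivity) after every pass, so a component that splits is
afterwards processed per piece.  A component that would vanish under the
next erosion is frozen at its last non-empty state; this implements the
stated "prevent objects from disappearing" and guarantees at least one
seed per input component.  The coarse phase is applied iteratively
before each area check (the single-pass reading differs only for very
large clumps).  Erosion treats outside-of-image as background.

## Seeded watershed

The topographic prototype is the exact Euclidean distance transform of
the clump mask.  Seeds are imposed by grayscale morphological
reconstruction: the marker equals the distance map on seed pixels and 0
elsewhere, and its reconstruction under the map (iterated elementary
4-connected geodesic dilation to stability) flattens every regional
maximum that contains no seed down to its connecting saddle.  The seeds
are binary but the map is real-valued; valuing the marker by the
distance map at seed pixels preserves seed peak heights and is the
standard maxima-imposition reading of the ambiguous notation.

Flooding runs on the negated reconstructed map with a priority queue
(Meyer), FIFO tie-breaking on equal priority, 4-connected to match the
geodesic element.  Watershed-line pixels join the first-arriving basin,
so the basins partition the mask and the region count equals the seed
component count.  Each clump is processed on its bounding box with a
one-pixel background margin.

Fragments produced by the watershed are gated again: singles are
accepted (provenance `"watershed"`), sub-minimum fragments are dropped,
and clumps that still fail the gate are rejected outright — no recovery
is attempted, matching the reference procedure.

## Evaluation protocol

Reference and predicted objects are compared as pixel sets with the
Hausdorff distance (full object sets, not contours: bounded and stable
for blob-shaped objects) and the Jaccard distance
$1 - |A\cap B|/|A\cup B|$.  Pairs farther apart than 30 px (Hausdorff)
or 0.5 (Jaccard) cannot match.  Matching is greedy, globally smallest
distance first, one-to-one; on small instances an exhaustive optimal
assignment oracle verifies that this choice is immaterial for the
counts.  Unmatched references are FN, unmatched predictions FP, and the
reported rates are $TP/|\mathrm{ref}|$ and $FP/|\mathrm{pred}|$.  The
reference description never defines the rate denominators; these are
declared conventions, with $|\mathrm{pred}|$ chosen for FP so that a
method emitting many spurious objects is penalized.  Candidate pruning
by bounding boxes is exact under both thresholds.

# The synthetic world

`generate_scene()` renders elliptical, hematoxylin-dominant nuclei with
eosin-dominant cytoplasm halos on a clean background through the forward
Beer–Lambert model, with a 1 px Gaussian optical blur of the
concentration maps and additive Gaussian sensor noise (sd 2 on the 8-bit
scale).  Ground truth is exact: per-nucleus silhouettes, a z-order label
mask, and a semantic map whose border class is the one-pixel
visible-contour ring (including the separation line between overlapping
nuclei, as a human annotator would draw it).

Choices worth stating explicitly:

* **Nucleus size.** Minor semi-axis 34–38 px, aspect ratio 1.3–1.6,
  giving areas of about 4700–7300 px — the upper part of the reference
  gate.  This is not cosmetic: the morphometric gate detects clumps
  mainly through the area maximum (a merged pair of mid-sized nuclei
  has roundness $\approx$ 0.7–0.9, well inside the roundness gate), so a
  faithful test of the separator needs nuclei large enough that a pair
  exceeds 7801 px.  The aspect-ratio floor of 1.3 keeps single-nucleus
  roundness below the 0.99 gate ($\approx 0.975$ at ratio 1.3).
* **Overlap geometry.** An overlap fraction of 0.3 means 30% of nuclei
  are placed as partners of a previously isolated host at a center
  distance of 1.3–1.5 mean equivalent radii, forming two-nucleus clumps
  (60% of nuclei end up inside a clump).  `generate_clump()` (the seed
  recovery fixture) uses discs of radius 12–30 px, radius ratios at most
  4:3 and center distances of 1.55–1.75 mean radii.  Deeper overlaps are
  geometrically unseparable by conditional erosion: the neck's inscribed
  radius (the lens half-height) then approaches the smaller disc's
  radius, so the blob erodes to a single residue before it can split —
  this is precisely the failure mode the pipeline answers by rejecting
  unseparated clumps.
* **Concentrations.** Nucleus H/E $= 1.0/0.2$ (with $\pm10\%$
  per-nucleus jitter), cytoplasm $0.15/0.7$, background $0.02$ —
  hematoxylin-dominant nuclei on eosin-dominant cytoplasm.
* **Nuclear rim.** The one-pixel visible contour of each nucleus is
  rendered at `rim_factor` (default 1.6) times the nuclear hematoxylin,
  emulating peripheral chromatin condensation.  Without it the boundary
  between two overlapping same-stain nuclei is optically invisible, the
  border class is unlearnable there, and no pixel classifier — however
  good — could separate touching nuclei.  The semantic task presumes
  class regions with distinct intensity distributions; the rim is what
  realizes that premise for the border class.
* **Border thickness.** The reference border ring is the visible
  contour plus one inward dilation ($\approx$3 px).  A one-pixel ring is
  an unrealistic annotation (human strokes are wider) and cannot survive
  single-pixel classifier errors: one leaked pixel re-bridges the
  component under 8-connected labeling.
* **Border augmentation.** The corpus builder can multiply
  border-class training patches with the package's own `augment()`
  (randomized scale 0.8–1.2, rotation, flips — the reference
  augmentation recipe); the acceptance run uses factor 4.  In
  measurements this lifted border recall along internal (nucleus to
  nucleus) boundaries from about 75% to 98%, which is what makes the
  predicted mask actually cut clumps.

What a green synthetic test does and does not establish: it shows the
chain — deconvolution, gating, conditional erosion, reconstruction,
flooding, matching — is implemented correctly and behaves as designed on
scenes whose morphometry matches the stated reference distribution.  It
does not certify clinical accuracy: real smears have texture, stain
heterogeneity, debris, out-of-focus regions and chains of more than two
overlapping nuclei, none of which the generator emulates.  The published
per-image accuracy tables require the undeposited clinical corpus and
are out of numeric scope.

# Numerical choices

* Distance transform: exact Euclidean (Felzenszwalb–Huttenlocher),
  verified against an $O(N^2)$ scan.
* Reconstruction: hybrid raster/anti-raster sweep with a FIFO queue
  (Vincent), verified to equal the literal fixpoint of elementary
  geodesic dilations.
* Component labeling in raster-scan order; all connectivities are 8 for
  blobs/seeds and 4 for geodesic/flooding operations.
* Argmax ties in classification break by the fixed class order
  (nucleus < nucleus_border < cytoplasm < background).
* All randomness flows from explicit seeds (`with_seed` internally, one
  `seed` per config object); generation, training and flooding are
  deterministic given the seed.
* Degenerate inputs: blank images produce empty results without error;
  constant images give an empty Otsu mask with a warning; empty seed
  masks and rank-deficient stain matrices are errors.

# Known limitations

* The sliding-window classifier predicts each pixel independently
  (stride 1); a fully convolutional network would be orders of magnitude
  faster but is deliberately out of scope.
* Clumps where one nucleus is mostly engulfed by another are rejected,
  not recovered.
* The Crofton perimeter makes digital circles reach roundness
  $\approx 1.0 > 0.99$; perfectly circular objects would be gated as
  clumps and, having one seed, rejected.  With elliptical nuclei (the
  realistic case and the generator's default) this does not occur.
* File I/O is plain ASCII PNM/CSV/JSON only; binary TIFF/PNG support
  would need an image I/O dependency not available in the target
  environment.
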