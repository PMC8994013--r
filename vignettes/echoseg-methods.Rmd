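---
title: "Methods: reference-guided echo segmentation and cardiac quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-guided echo segmentation and cardiac quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`echoseg`, the assumptions behind them, the parameters a user may want to
change, and the design decisions that were genuinely open — together with
why each was resolved the way it was.

## The segmentation model

`echoseg` performs *semi-supervised video object segmentation*: the user
delineates the chamber in the first frame of a cardiac cycle, and the
network propagates that delineation through the remaining frames. Two
ideas are combined:

1. **Reference guidance.** Two encoder streams with shared weights (a
   Siamese encoder) process two-channel inputs of shape 128×256×2 (height
   × width × {image, mask}). The *reference stream* sees the annotated
   first frame once per sequence; the *main stream* sees the current
   frame plus the previous frame's predicted mask. The reference stream
   anchors the appearance of the object, which is what makes the
   propagation robust to drift when the chamber contracts.
2. **Anchor-based detection with a mask head.** Each stream feeds a
   feature pyramid (levels P3–P7, strides 8–128, all at a fixed channel
   width); the two pyramids are fused level-wise by concatenation + 1×1
   convolution. A classification subnet (4×(3×3 conv + ReLU), then a
   conv with A filters and a sigmoid) scores A = 9 anchors per location;
   a structurally identical regression subnet with 4A output filters
   predicts box offsets. The best box after decoding, clipping, score
   thresholding and NMS is cropped from the fused pyramid by RoIAlign
   and segmented by a small fully convolutional mask subnet
   (4×(3×3 conv), 2× upsample, two convs, sigmoid).

The per-frame output mask is thresholded at 0.5, pasted back into the
frame, and becomes the guidance channel of the next frame, closing the
recurrent loop. If no detection survives filtering, the guidance mask is
carried forward unchanged and the frame is flagged (`fallback_used`);
this keeps inference total.

### Losses

* Classification: focal loss FL(p_t) = −α_t (1−p_t)^γ log(p_t) with
  p_t = p for positive anchors and 1−p for background; α_t = 0.25,
  γ = 2 by default. Ignored anchors (assignment band [0.4, 0.5)) do not
  contribute. The sum is normalised by the number of positive anchors
  (at least one); normalising rather than averaging over all anchors
  keeps the positive gradient magnitude independent of the anchor count.
* Regression: smooth-L1 per offset component, F(x) = 0.5x²/σ for
  |x| < σ, |x| − 0.5σ otherwise, σ = 3, averaged over the positive
  anchors' components; zero when there are no positives.
* Mask: average binary cross-entropy between the mask-subnet output and
  the ground-truth mask cropped to the ground-truth box (the box that
  feeds the mask head during training; at inference the detected box is
  used).

The total loss is a weighted sum (defaults 1, 1, 1). Predicted
probabilities are clipped to [1e−7, 1−1e−7] before any logarithm.

### Anchors and filtering

Aspect ratios {0.5, 1, 2} × scale multipliers {2^0, 2^(1/3), 2^(2/3)}
give 9 anchors per location with base areas 32²–512² on P3–P7. These are
the canonical single-stage-detector defaults; the architecture fixes only
"three ratios and three scales", so the standard values are used and
exposed in `anchor_config()`. Assignment bands: best-IoU ≥ 0.5 positive,
< 0.4 background, otherwise ignored. Offsets are normalised by
(0.1, 0.1, 0.2, 0.2). Detection filtering collects the top 1000
candidates per level, applies the 0.5 score threshold, and runs greedy
NMS at IoU 0.5 with ties broken towards the lower box index. Boxes are
clipped to the image *after* regression, matching the layer order
(Regress-Boxes → ClipBoxes → Filter-detections).

### Training

Plain stochastic gradient descent, end to end. Sequences are sampled
uniformly; the first frame feeds the reference stream and all remaining
frames form the main-stream batch. By default training uses *teacher
forcing*: the guidance channel of frame t is the ground-truth mask of
frame t−1 rather than the model's own prediction. This makes iterations
independent of the current weights (stable, cacheable) at the cost of a
small train/inference mismatch; `train_config(teacher_forcing = FALSE)`
switches to self-guidance, recomputing the propagated masks each
iteration. The default learning rate is 1e−5; the desk-scale experiments
below use 3e−3, chosen by a short pilot sweep (40 iterations at
{3e−2, 1e−2, 3e−3}) on phantom data — the width-reduced network needs a
far larger step than the full-scale model the 1e−5 default belongs to.

Weight initialisation is He-normal; the final classification bias is set
to −log((1−π)/π) with prior π = 0.01 so the untrained classifier scores
anchors near 0.01 and the focal loss is not swamped by background terms
in the first iterations. `transfer_backbone()` copies the encoder
(stem + residual stages) from a trained model while leaving all other
layers at their random initial weights — the intended route for training
an RV model from an LV model when RV data are scarce.

### Presets

Two configurations are provided. `"full"` mirrors the five-stage
bottleneck-residual encoder with a 256-channel pyramid at 128×256 inputs.
`"reduced"` divides all widths by 8, uses one bottleneck per stage and
64×128 inputs; it exists so that training experiments run in minutes on
one CPU. The tests and the acceptance script use the reduced preset with
five 8-frame training phantoms and 200 SGD iterations — sizes chosen so
that a full experiment (training, held-out propagation, quantification)
completes in a few minutes while still demonstrating loss reduction and
≥ 0.85 held-out Dice.

The network engine itself (convolutions via im2col and BLAS, reverse-mode
autodiff on a tape, SGD) is part of the package; its analytic gradients
are pinned against central finite differences in the test suite, which is
the independent oracle for everything the engine computes.

## Clinical quantification

The LV pipeline per frame: area S = foreground pixels × spacing² (cm²);
long-axis length L (cm) from three landmarks; volume by the single-plane
area-length model V = 8S²/(3πL) (cm³ = mL) — the "modified Simpson"
single-plane rule, which assumes rotational symmetry of the chamber about
its long axis. ED/ES are the argmax/argmin of the volume curve (ties to
the earliest frame; a constant curve warns and returns frame 1), and
EF = 100·(EDV−ESV)/EDV. Biplane volumes are out of scope by design: they
would require a second view.

RV: only the area is tracked. FAC = 100·(EDA−ESA)/EDA at ED/ES indices
that *must* be supplied by the user — the RV has no reliable volumetric
phase cue, so automatic RV phase detection is deliberately refused rather
than silently guessed.

### Landmark strategy

The three LV landmarks (two mitral-valve joints, apex) are taken from the
convex hull of the segmented region. How exactly is an open design point
(the underlying method is only sketched in the literature this package
follows), and two strategies were evaluated:

* *Basal-edge pick*: mitral chord = the hull edge closest to the basal
  image side, apex = the hull vertex farthest from it. Simple, but the
  chosen edge can change from frame to frame, moving the chord midpoint
  laterally by ±2–3 px and injecting ~1% frame-to-frame noise into L.
* *Principal axis* (the implemented default): the long axis is the first
  principal component of the foreground pixel coordinates, oriented
  towards the basal side (with the basal-edge normal as fallback when the
  region is not elongated apex-to-base); the mitral chord is the hull
  edge the axis exits through basally, and apex/chord-midpoint are the
  axis/boundary intersections, refined to sub-pixel precision by a
  parabolic-cap model of the projected pixel-count profile.

The refinement matters because V ∝ S²/L: a 1-px jitter in L on a
~150-px-long chamber is a ~0.7% volume jitter, comparable to the true
frame-to-frame volume change near end-systole, where the volume curve is
flat — without it, ED/ES detection on ground-truth masks misidentifies
the ES frame by ±1 in a noticeable fraction of sequences. Masks are
quantified at their native resolution (network outputs are upsampled
back with nearest-neighbour first), so `spacing` always refers to
acquisition pixels.

Frames with empty masks are flagged and their measures linearly
interpolated from neighbouring frames for the volume curve — treating
them as V = 0 would fabricate an end-systole.

## The phantom

`generate_phantom_sequence()` renders one cardiac cycle of an elliptical
chamber: a dark blood pool, a bright myocardial ring of fixed thickness,
mid-gray background, and multiplicative uniform speckle
(frame × (1 + strength·U(−1,1)), clipped to [0,1]). The long axis runs
along image rows (apex down, base up). Semi-axes follow cosine limbs from
the end-diastolic size to end-systole and back; the per-frame mask is the
filled cavity ellipse, and the analytic truth (per-frame semi-axes,
area-length volumes, ED/ES indices, EF) is stored alongside.

Three generator choices exist specifically so that the stored truth is
*recoverable* from rasterised masks:

* end-systole is snapped to an integer frame, so the volume trough sits
  on a frame rather than between two frames (in which case the true
  argmin would be decided by an arbitrarily small margin);
* the relaxation limb is parameterised to reach ED again 5% *past* the
  last frame, so the final frames stay clearly below the ED volume and
  frame 1 is the unique ED;
* default geometry (320×384 px, ED semi-axes ≈ 80–110 × 45–62 px,
  contractions 0.18–0.3 and 0.25–0.35, 18–26 frames per cycle) keeps the
  analytic frame-to-frame volume change near the extremes several times
  larger than the residual rasterisation noise. Under these study
  conditions, quantification of ground-truth masks recovered the exact
  ED/ES frames in 150/150 random specs with a maximum EF error of 0.27
  points (bound: 2 points).

Defaults correspond to a normal ventricle: EF ≈ 58%, EDV ≈ 81 mL, LV
length ≈ 8 cm at 0.04 cm/px.

What the phantom does *not* emulate: real speckle statistics (Rayleigh),
papillary muscles and trabeculation, valve motion, shadowing and edge
dropout, probe geometry, multi-chamber scenes, or inter-observer
annotation variability. Tests passing on phantoms therefore validate the
machinery (formulas, geometry, training dynamics, propagation logic) —
they are not evidence about clinical-image accuracy.

## Evaluation statistics

Overlap: DSC, JSC, precision, recall, with the convention that two empty
masks score 1 (ground-truth-vs-ground-truth evaluation must be perfect).
Paired agreement: RMSE; MAE; R² defined as 1 − SS_res/SS_tot (not the
squared Pearson correlation — the two differ under bias); two-item
Cronbach's α with sample variances, undefined when var(x+y) = 0; Pearson
r, undefined for constant inputs; Bland–Altman bias and limits of
agreement mean ± 1.96 sd with their width (the "width of the confidence
interval" in the Bland–Altman sense).

## Numerical choices and degenerate inputs

* Probability clipping 1e−7 guards every log; encode/decode of box
  deltas round-trips to < 1e−6.
* Min–max normalisation of a constant frame is undefined; the frame
  becomes all zeros with a warning.
* Mask binarisation maps values *at* the threshold to 1; images resize
  bilinearly, masks with nearest-neighbour so they stay binary.
* Zero-area boxes have IoU 0 against everything; encoding against a
  zero-extent anchor is an error; RoIAlign refuses degenerate boxes.
* Feature-map sizes use ceiling division throughout, so the anchor count
  formula Σ_l ceil(H/s_l)·ceil(W/s_l)·9 holds for any input shape.
* NMS ties (equal scores) are broken towards the lower box index;
  ED/ES volume-curve ties towards the earlier frame.
* "Both masks empty" scores 1 in overlap metrics; undefined statistics
  (R², α, r) are reported as `NA`, never silently dropped.

## Known limitations

* The reduced-preset experiments demonstrate the mechanism at desk
  scale; clinical-grade accuracy requires the full preset, large
  annotated datasets and accelerator-scale training, none of which this
  package attempts on its own.
* The mask head paste-back uses a 28×28 probability grid resized into
  the detected box, which limits boundary detail at high resolutions.
* Sequence I/O reads PNG/TIFF frame stacks (with an optional JSON
  manifest); DICOM and vendor formats are out of scope.
* The phantom's analytic FAC refers to the cavity-area ratio of the
  ellipse family; for real RV geometry FAC depends on the traced view.
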