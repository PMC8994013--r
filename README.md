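# echoseg

Semi-automated segmentation of cardiac chambers in echocardiography image
sequences, and the clinical measurements derived from the segmentations.

Quantifying left-ventricle (LV) and right-ventricle (RV) function from
four-chamber-view echo loops — lengths, areas, volumes, ejection fraction
(EF), fractional area change (FAC) — normally requires an expert to trace
the chamber in every frame. `echoseg` automates the tracing: the user
annotates only the **first frame** of a cycle, and a two-stream
("reference-guided") neural network propagates that annotation through the
rest of the sequence. Post-processing then turns the per-frame masks into
the clinical parameters.

The package is aimed at researchers in cardiac image analysis who want a
fully inspectable, dependency-light implementation of this pipeline —
every layer of the network, every loss and every measurement formula is
plain R — together with a synthetic "beating ventricle" phantom generator
whose ground truth is known analytically, so each stage can be validated
without access to clinical data.

## The model

**Segmentation network.** A Siamese (weight-shared) five-stage residual
encoder processes two two-channel inputs: the *main stream* receives the
current frame stacked with the previous frame's predicted mask, the
*reference stream* receives the annotated first frame stacked with its
annotation. Each stream feeds a feature pyramid (P3–P7); the streams are
fused per level by channel concatenation and 1×1 reduction. On the fused
pyramid:

- a **classification subnet** scores object presence for A = 9 anchor
  boxes per location, trained with the focal loss
  FL(p_t) = −α_t (1 − p_t)^γ log(p_t);
- a **regression subnet** predicts anchor-to-box offsets, trained with the
  smooth-L1 loss (quadratic below σ, linear above);
- after box decoding, clipping, score thresholding (0.5) and greedy NMS
  (IoU 0.5), the best detection is cropped by sub-pixel **RoIAlign** and a
  **mask subnet** (trained with average binary cross-entropy) produces the
  chamber mask, which is thresholded, pasted back, and fed forward as the
  next frame's guidance mask.

Anchors are assigned to ground truth by IoU: ≥ 0.5 positive, < 0.4
background, in between ignored. Training is plain SGD, end to end.

**Quantification.** For the LV, each mask yields the area S (pixel count ×
spacing²), the long-axis length L (apex to mitral-chord midpoint, both
found on the mask's convex hull), and the single-plane area-length
("modified Simpson") volume

    V = 8 S² / (3 π L).

End-diastole/end-systole are the volume-curve argmax/argmin, and
EF = 100·(EDV − ESV)/EDV. For the RV only the area is tracked;
FAC = 100·(EDA − ESA)/EDA at expert-chosen ED/ES frames (the RV volume
curve carries no reliable phase cue, so phase selection is deliberately
left to the user).

**Evaluation.** Dice/Jaccard/precision/recall for masks; RMSE, MAE, R²,
Cronbach's α, Pearson correlation and Bland–Altman limits of agreement for
paired parameter series.

## Worked example

```r
library(echoseg)

## a synthetic beating ventricle with analytically known truth
ps <- generate_phantom_sequence(phantom_spec(seed = 1))
ps
#> phantom_sequence: 26 frames 320x384, ED frame 1, ES frame 11, EF 58.5%

## clinical quantification on the ground-truth masks
lv <- quantify_lv_sequence(ps$masks, ps$pixel_spacing)
lv
#> LV report over 26 frames:
#>   ED frame 1 (EDV 80.9 mL) | ES frame 11 (ESV 33.7 mL) | EF 58.3%
#>   length 6.40-8.00 cm | area 15.94-27.61 cm^2

rv <- quantify_rv_sequence(ps$masks, ps$pixel_spacing,
                           ed_index = ps$true_ed_index,
                           es_index = ps$true_es_index)
rv
#> RV report over 26 frames: EDA 27.61 cm^2 (frame 1) | ESA 15.94 cm^2 (frame 11) | FAC 42.3%
```

The reported EF (58.3%) recovers the phantom's analytic truth (58.5%) to
within a fifth of an EF point; the ED/ES frames match exactly. A
segmentation model is trained and applied with:

```r
dataset <- lapply(1:5, function(i)
  generate_phantom_sequence(phantom_spec(n_frames = 8, seed = i)))
model <- build_echo_net(network_config("reduced"))
fit <- train_echo_net(model, dataset,
                      train_config(learning_rate = 3e-3, iterations = 200))
masks <- segment_sequence(fit$model, ps, ps$masks[[1]])  # first-frame annotation
seg_scores(masks$masks[[5]], ps$masks[[5]])
```

Command-line entry points for the whole workflow (phantom generation,
training, segmentation, quantification, evaluation) are in
`inst/cli/echoseg`; see `?run_command`.

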