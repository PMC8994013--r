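## Shared fixtures: the canonical random phantom sampler (the study
## conditions of the synthetic experiments) and a small training set.

rand_phantom_spec <- function(seed) {
  set.seed(seed)
  phantom_spec(
    n_frames = sample(18:26, 1L),
    semi_axis_long_ed = runif(1, 80, 110),
    semi_axis_short_ed = runif(1, 45, 62),
    contraction_long = runif(1, 0.18, 0.3),
    contraction_short = runif(1, 0.25, 0.35),
    es_frame_fraction = runif(1, 0.35, 0.5),
    speckle_strength = runif(1, 0, 0.4),
    seed = seed)
}

## five short annotated cycles used by the training experiments
phantom_train_set <- function(n_frames = 8L) {
  lapply(1:5, function(i) generate_phantom_sequence(phantom_spec(
    n_frames = n_frames, seed = i,
    semi_axis_long_ed = c(85, 95, 100, 105, 92)[i],
    semi_axis_short_ed = c(48, 55, 58, 50, 53)[i],
    contraction_long = c(0.2, 0.22, 0.18, 0.25, 0.21)[i],
    contraction_short = c(0.3, 0.28, 0.26, 0.32, 0.27)[i])))
}

phantom_holdout <- function(n_frames = 8L) {
  generate_phantom_sequence(phantom_spec(
    n_frames = n_frames, seed = 99,
    semi_axis_long_ed = 98, semi_axis_short_ed = 52))
}

mean_dsc <- function(pred_masks, gt_masks) {
  mean(vapply(seq_along(pred_masks), function(i)
    seg_scores(pred_masks[[i]], gt_masks[[i]])$dsc, numeric(1L)))
}
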