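# Small in-code fixtures shared across test files. Image side length 64 keeps
# the conv backbone cheap (grid 2x2); scientific-scale settings live in
# test-acceptance.R only.

tiny_cfg <- function(n_samples = 8, n_vox = 40, n_roi = 6, img_size = 64,
                     seed = 3, alignment_strength = 0.8, noise_sd = 0.1, ...) {
  synthetic_config(n_samples = n_samples, n_vox = n_vox, n_roi = n_roi,
                   img_size = img_size, seed = seed,
                   alignment_strength = alignment_strength,
                   noise_sd = noise_sd, ...)
}

tiny_model <- function(n_vox = 40, n_roi = 6, d = 16, img_size = 64,
                       seed = 2, w = 8, s = 4, h = 2) {
  nf_model(n_vox = n_vox, n_roi = n_roi, d = d, img_size = img_size,
           tf = timeformer_config(w = w, s = s, h = h, d = d),
           backbone = backbone_spec(d = d), seed = seed)
}

# Zero out the residual branches of a transformer block so it becomes the
# identity map.
identity_block <- function(params) {
  params$Wo[] <- 0; params$bo[] <- 0
  params$W2[] <- 0; params$b2[] <- 0
  params
}

random_grid_with_labels <- function(coords, labels, signal = NULL) {
  structure(list(coords = coords, roi_labels = as.integer(labels),
                 signal = signal, n_vox = nrow(coords),
                 n_roi = length(unique(labels))),
            class = "nf_voxel_grid")
}
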