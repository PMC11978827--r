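# neurofusion

Cross-modal contrastive alignment of fMRI voxel signals and natural images,
in R, at desk scale.

## The problem

Visual neuroscience increasingly treats the brain's response to an image as
a *second view* of that image: if an encoder can place fMRI voxel responses
and the images that evoked them close together in one feature space, the
shared space supports image-from-brain retrieval, voxel-response prediction
(encoding models), and brain-guided pretraining of vision backbones. This
package is a self-contained reference implementation of such a method for
researchers who want to study the *objective and architecture* — not to
reproduce GPU-scale benchmark numbers, which require external datasets
(large 7T recordings, COCO/ADE20K) and pretrained backbones that are out of
scope here.

## The method

For image `i` with global visual feature `p_i` and fMRI global feature
`q_i` (unit-normalized), the symmetric contrastive loss with temperature σ:

    L_con = -(1/N) Σ_i log[ exp(p_i·q_i/σ) / Σ_j exp(p_i·q_j/σ) ]
            -(1/N) Σ_i log[ exp(q_i·p_i/σ) / Σ_j exp(q_i·p_j/σ) ]

and, with per-ROI image features `p̄_ik` and brain-ROI features `q̄_ik`
(N_r ROIs), the ROI-level guided loss:

    L_bfg = -(1/N_r) Σ_i Σ_k log[ exp(p̄_ik·q̄_ik) / Σ_g exp(p̄_ik·q̄_ig) ]

trained jointly as `L = λ_con·L_con + λ_bfg·L_bfg`.

The fMRI branch embeds each voxel's 3D coordinate linearly, tokenizes the
serialized voxel signal with a strided 1D convolution (kernel 32, stride 16)
fused additively with receptive-field-pooled coordinate embeddings, and
encodes the token sequence with a sliced-window transformer (window w = 64,
stride s = 32, h = 2 layers; windowed attention costs `n_windows·w²`
query-key pairs instead of `L²`). The visual branch is a small
self-contained conv backbone with one global and N_r per-ROI projection
heads. A synthetic paired-data generator with a known, tunable latent
coupling (`alignment_strength`) makes the whole pipeline testable without
any download; see `vignettes/cross-modal-alignment.Rmd` for the model,
assumptions, and design decisions.

## Worked example

```r
library(neurofusion)

cfg <- synthetic_config(n_samples = 96, n_vox = 60, n_roi = 6,
                        img_size = 224, alignment_strength = 0.9,
                        noise_sd = 0.1, seed = 42)
pairs <- generate_pairs(cfg)

model <- nf_model(n_vox = 60, n_roi = 6, d = 32, img_size = 224, seed = 42)
trained <- train(pairs, model,
                 train_config(lr = 0.01, epochs = 20, batch_size = 32,
                              seed = 42))
report <- evaluate(trained)
```

Output of this exact script (~1 min on one CPU):

```
held-out top-1 retrieval: 0.579 (chance 0.053)
held-out top-5 retrieval: 1.000
mean voxel-wise PCC:      0.493
contrastive loss: 8.866 (epoch 1) -> 0.127 (epoch 20)
```

Reading: with a strong planted coupling (0.9) and weak noise (0.1), the
trained heads retrieve the matching fMRI response for 58% of held-out
images (chance 5.3%), every true match ranks in the top 5, and the encoding
head predicts held-out voxel responses at mean Pearson r ≈ 0.49. Setting
`alignment_strength = 0` drops retrieval to chance — the recovery test that
the acceptance suite runs over five seeds.

## Command line

```sh
Rscript inst/cli/neurofusion simulate --config cfg.yaml --out data/
Rscript inst/cli/neurofusion train    --config cfg.yaml --data data/ --out run/
Rscript inst/cli/neurofusion evaluate --run run/ --report report.json
Rscript inst/cli/neurofusion embed    --config cfg.yaml --out features.h5
```

An empty `cfg.yaml` gives all defaults (window 64/stride 32/2 layers, six
ROIs, kernel 32/stride 16, 224×224 images, lr 1e-4). Datasets are written
as NIfTI volumes + integer NIfTI ROI masks, PNG images, and HDF5 latent
sidecars; every run archives its effective config, seed, input hash and
per-epoch losses.

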