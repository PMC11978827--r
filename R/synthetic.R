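#' Configuration for the synthetic paired-data generator
#'
#' The generator emulates the structure of a natural-scenes fMRI experiment at
#' desk scale: a shared voxel grid partitioned into spatially contiguous ROIs,
#' per-stimulus voxel response vectors, procedurally rendered stimulus images,
#' and a known latent coupling between image content and ROI responses.
#'
#' Each sample draws one latent code per ROI. The code is rendered into the
#' image as a coloured geometric glyph placed in that ROI's fixed image sector
#' (mimicking category-selective visual regions), and drives the ROI's voxel
#' responses through a fixed random loading matrix:
#' `response = alignment_strength * (loading %*% code) + noise_sd * eps`.
#'
#' @param n_samples number of paired samples.
#' @param n_vox number of voxels (>= `n_roi`).
#' @param n_roi number of regions of interest; default 6.
#' @param img_size image side length in pixels; default 224.
#' @param d_latent latent code dimension per ROI; default 4 (3 colour channels
#'   plus glyph radius, so the rendered image fully determines the code).
#' @param alignment_strength cross-modal coupling in `[0, 1]`; 0 decouples
#'   images from responses entirely.
#' @param noise_sd standard deviation of additive Gaussian response noise.
#' @param t_steps optional number of repeated time steps per stimulus
#'   (default 1, i.e. per-stimulus beta responses). When > 1 an AR(1) noise
#'   process is superimposed per step.
#' @param ar_coef AR(1) coefficient used when `t_steps > 1`.
#' @param seed integer RNG seed; equal seeds give bit-identical datasets.
#' @return an object of class `nf_synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 64, n_vox = 60, n_roi = 6,
                             img_size = 224, d_latent = 4,
                             alignment_strength = 0.8, noise_sd = 0.1,
                             t_steps = 1, ar_coef = 0.5, seed = 1) {
  cfg <- list(
    n_samples = n_samples, n_vox = n_vox, n_roi = n_roi, img_size = img_size,
    d_latent = d_latent, alignment_strength = alignment_strength,
    noise_sd = noise_sd, t_steps = t_steps, ar_coef = ar_coef, seed = seed
  )
  class(cfg) <- "nf_synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  chk_count <- function(x, nm, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x != round(x))
      nf_config_error("invalid synthetic config field '%s': %s", nm, format(x))
  }
  chk_count(cfg$n_samples, "n_samples")
  chk_count(cfg$n_vox, "n_vox")
  chk_count(cfg$n_roi, "n_roi")
  chk_count(cfg$img_size, "img_size", min = 4)
  chk_count(cfg$d_latent, "d_latent")
  chk_count(cfg$t_steps, "t_steps")
  chk_count(cfg$seed, "seed", min = -Inf)
  if (cfg$n_vox < cfg$n_roi)
    nf_config_error("invalid synthetic config field 'n_vox': must be >= n_roi (%d < %d)",
                    cfg$n_vox, cfg$n_roi)
  a <- cfg$alignment_strength
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a < 0 || a > 1)
    nf_config_error("invalid synthetic config field 'alignment_strength': must be in [0, 1]")
  if (!is.numeric(cfg$noise_sd) || length(cfg$noise_sd) != 1 ||
      !is.finite(cfg$noise_sd) || cfg$noise_sd < 0)
    nf_config_error("invalid synthetic config field 'noise_sd': must be >= 0")
  invisible(cfg)
}

#' Construct a voxel grid with spatially contiguous ROIs
#'
#' Voxel coordinates are drawn without replacement from an integer 3D lattice
#' just large enough to hold them, then partitioned into `n_roi` spatially
#' contiguous blobs by k-means clustering of the coordinates. Voxels are
#' serialized in ascending `(z, y, x)` lexicographic order; this order is the
#' package-wide voxel serialization used by the 1D tokenizer and all I/O.
#'
#' @param n_vox number of voxels (>= `n_roi`).
#' @param n_roi number of ROIs.
#' @param seed integer RNG seed.
#' @param signal optional `T x n_vox` signal matrix to attach.
#' @return an object of class `nf_voxel_grid` with fields `coords`
#'   (`n_vox x 3` integer matrix, 0-based lattice units), `roi_labels`
#'   (0-based integers in `[0, n_roi)`), `signal`, `n_vox`, `n_roi`.
#' @export
make_voxel_grid <- function(n_vox, n_roi, seed = 1, signal = NULL) {
  if (!is.numeric(n_vox) || !is.numeric(n_roi) || n_vox < n_roi || n_roi < 1)
    nf_config_error("make_voxel_grid: need n_vox >= n_roi >= 1 (got %s, %s)",
                    format(n_vox), format(n_roi))
  n_vox <- as.integer(n_vox); n_roi <- as.integer(n_roi)
  side <- max(2L, as.integer(ceiling((2 * n_vox)^(1 / 3))))
  lattice <- as.matrix(expand.grid(x = 0:(side - 1), y = 0:(side - 1),
                                   z = 0:(side - 1)))
  coords <- with_seed(seed, {
    idx <- sample.int(nrow(lattice), n_vox)
    coords <- lattice[idx, , drop = FALSE]
    # package-wide serialization: ascending (z, y, x)
    coords[order(coords[, 3], coords[, 2], coords[, 1]), , drop = FALSE]
  })
  labels <- with_seed(derive_seed(seed, "roi"), {
    if (n_roi == n_vox) {
      seq_len(n_vox)
    } else if (n_roi == 1L) {
      rep(1L, n_vox)
    } else {
      km <- stats::kmeans(coords, centers = n_roi, nstart = 5, iter.max = 50)
      km$cluster
    }
  })
  # relabel by first occurrence so labels are deterministic in voxel order
  u <- unique(labels)
  remap <- integer(max(labels))
  remap[u] <- seq_along(u) - 1L
  roi_labels <- remap[labels]
  grid <- structure(
    list(coords = coords, roi_labels = as.integer(roi_labels),
         signal = signal, n_vox = n_vox, n_roi = n_roi),
    class = "nf_voxel_grid"
  )
  validate_voxel_grid(grid)
  grid
}

validate_voxel_grid <- function(grid) {
  if (anyDuplicated(grid$coords))
    nf_input_error("voxel grid has duplicate coordinates")
  if (length(grid$roi_labels) != nrow(grid$coords))
    nf_shape_error("roi_labels length (%d) != coordinate rows (%d)",
                   length(grid$roi_labels), nrow(grid$coords))
  tab <- tabulate(grid$roi_labels + 1L, nbins = grid$n_roi)
  if (any(tab == 0))
    nf_degenerate_error("ROI %d contains no voxels", which(tab == 0)[1] - 1L)
  if (!is.null(grid$signal)) {
    if (ncol(grid$signal) != grid$n_vox)
      nf_shape_error("signal columns (%d) != n_vox (%d)",
                     ncol(grid$signal), grid$n_vox)
    check_finite(grid$signal, "voxel signal")
  }
  invisible(grid)
}

# Fixed image sector (row/col pixel ranges, 1-based inclusive) for each ROI.
roi_sectors <- function(img_size, n_roi) {
  nrow_s <- max(1L, floor(sqrt(n_roi)))
  ncol_s <- as.integer(ceiling(n_roi / nrow_s))
  lapply(seq_len(n_roi) - 1L, function(r) {
    ri <- r %/% ncol_s; ci <- r %% ncol_s
    list(
      rows = (floor(img_size * ri / nrow_s) + 1L):floor(img_size * (ri + 1) / nrow_s),
      cols = (floor(img_size * ci / ncol_s) + 1L):floor(img_size * (ci + 1) / ncol_s)
    )
  })
}

# Render one ROI's glyph into an image array in place. Glyph family is fixed
# per ROI (discs for even ROIs, squares for odd); the latent code sets the
# RGB colour (3 components through a logistic squash) and the radius.
render_glyph <- function(img, sector, roi, code) {
  d <- length(code)
  col_idx <- (0:2 %% d) + 1L
  colr <- stats::plogis(code[col_idx])
  size <- stats::plogis(code[(3L %% d) + 1L])
  rows <- sector$rows; cols <- sector$cols
  h <- length(rows); w <- length(cols)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rad <- (0.2 + 0.3 * size) * min(h, w) / 2
  dy <- seq_len(h) - cy; dx <- seq_len(w) - cx
  mask <- if (roi %% 2L == 0L) {
    outer(dy^2, dx^2, `+`) <= rad^2
  } else {
    outer(abs(dy), abs(dx), pmax) <= rad
  }
  for (ch in 1:3) {
    sub <- img[rows, cols, ch]
    sub[mask] <- colr[ch]
    img[rows, cols, ch] <- sub
  }
  img
}

#' Generate paired (image, fMRI response) samples with known latent coupling
#'
#' Draws per-sample, per-ROI latent codes; renders each image procedurally from
#' the codes (one glyph per ROI in a fixed image sector); and produces each
#' voxel's response as `alignment_strength` times its ROI's latent code
#' projected through a fixed random unit-norm voxel loading, plus
#' `noise_sd`-scaled Gaussian noise. Voxel loadings are fixed per grid so the
#' coupling is learnable across samples. Ground-truth latents are returned for
#' recovery tests.
#'
#' @param cfg an [synthetic_config()] object.
#' @return an object of class `nf_pair_set` with fields `images`
#'   (`n x S x S x 3` in `[0, 1]`), `grid` ([make_voxel_grid()]), `responses`
#'   (`n x n_vox`), `latents` (`n x n_roi x d_latent`), `loadings`
#'   (list of per-ROI loading matrices), and `config`. When `t_steps > 1` an
#'   additional `responses_t` array (`n x t_steps x n_vox`) carries the
#'   repeated-measure AR(1) variant.
#' @export
generate_pairs <- function(cfg) {
  if (!inherits(cfg, "nf_synthetic_config")) cfg <- do.call(synthetic_config, cfg)
  validate_synthetic_config(cfg)
  grid <- make_voxel_grid(cfg$n_vox, cfg$n_roi, seed = cfg$seed)
  n <- cfg$n_samples; S <- cfg$img_size
  nr <- cfg$n_roi; dl <- cfg$d_latent

  loadings <- with_seed(derive_seed(cfg$seed, "loadings"), {
    lapply(seq_len(nr) - 1L, function(r) {
      nv <- sum(grid$roi_labels == r)
      L <- matrix(stats::rnorm(nv * dl), nv, dl)
      L / sqrt(rowSums(L^2)) # unit-norm rows: signal variance = alignment^2
    })
  })

  out <- with_seed(derive_seed(cfg$seed, "pairs"), {
    latents <- array(stats::rnorm(n * nr * dl), c(n, nr, dl))
    sectors <- roi_sectors(S, nr)
    images <- array(0.5, c(n, S, S, 3))
    img <- array(0.5, c(S, S, 3))
    for (i in seq_len(n)) {
      im <- img
      for (r in seq_len(nr)) {
        im <- render_glyph(im, sectors[[r]], r - 1L, latents[i, r, ])
      }
      images[i, , , ] <- im
    }
    responses <- matrix(0, n, cfg$n_vox)
    for (r in seq_len(nr)) {
      idx <- which(grid$roi_labels == r - 1L)
      responses[, idx] <- cfg$alignment_strength *
        (matrix(latents[, r, ], n, dl) %*% t(loadings[[r]]))
    }
    responses <- responses + cfg$noise_sd * matrix(stats::rnorm(n * cfg$n_vox),
                                                   n, cfg$n_vox)
    res <- list(images = images, responses = responses, latents = latents)
    if (cfg$t_steps > 1) {
      Tn <- cfg$t_steps
      rt <- array(0, c(n, Tn, cfg$n_vox))
      innov_sd <- cfg$noise_sd * sqrt(1 - cfg$ar_coef^2)
      for (tt in seq_len(Tn)) {
        eps <- matrix(stats::rnorm(n * cfg$n_vox, sd = innov_sd), n, cfg$n_vox)
        prev <- if (tt == 1) matrix(stats::rnorm(n * cfg$n_vox, sd = cfg$noise_sd),
                                    n, cfg$n_vox) else ar_state
        ar_state <- cfg$ar_coef * prev + eps
        rt[, tt, ] <- (responses - 0) + ar_state # base signal + AR(1) noise
      }
      res$responses_t <- rt
    }
    res
  })

  structure(
    list(images = out$images, grid = grid, responses = out$responses,
         latents = out$latents, loadings = loadings,
         responses_t = out$responses_t, config = cfg),
    class = "nf_pair_set"
  )
}

#' Variance in voxel responses explained by the ground-truth latents
#'
#' Regresses every voxel's response across samples on the flattened latent
#' codes and returns the mean coefficient of determination over voxels — the
#' generator's signal-to-noise summary, nondecreasing in `alignment_strength`
#' at fixed `noise_sd`.
#'
#' @param pairs an [generate_pairs()] result.
#' @return mean R^2 over voxels (scalar in `[0, 1]`).
#' @export
variance_explained <- function(pairs) {
  n <- dim(pairs$latents)[1]
  X <- cbind(1, matrix(pairs$latents, n))
  Y <- pairs$responses
  fit <- stats::lm.fit(X, Y)
  res <- as.matrix(fit$residuals)
  tot <- sweep(Y, 2, colMeans(Y))
  ss_res <- colSums(res^2)
  ss_tot <- colSums(tot^2)
  keep <- ss_tot > 0
  if (!any(keep)) return(0)
  mean(1 - ss_res[keep] / ss_tot[keep])
}
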