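# Dataset input/output: NIfTI volumes + integer ROI masks for the fMRI side,
# PNG images for stimuli, HDF5 sidecars for latents and exported features.
# Voxels are serialized in ascending (z, y, x) order everywhere; 0-based
# voxel indices and half-open ranges are the package-wide convention.

#' Read a 4D fMRI volume and ROI mask into a voxel grid
#'
#' Voxels with ROI label > 0 are extracted in ascending `(z, y, x)` order;
#' coordinates are the 0-based voxel indices; background (label 0) is
#' excluded. Mask labels `1..K` map to 0-based ROI labels `0..K-1`.
#'
#' @param volume_path 4D (or 3D) NIfTI signal volume.
#' @param roi_mask_path 3D integer NIfTI ROI mask with the same spatial shape.
#' @return an `nf_voxel_grid` with the `T x n_vox` signal attached.
#' @export
read_fmri <- function(volume_path, roi_mask_path) {
  vol <- read_nifti(volume_path)
  mask <- read_nifti(roi_mask_path)
  vd <- dim(vol); md <- dim(mask)
  if (length(vd) == 3) { dim(vol) <- c(vd, 1); vd <- dim(vol) }
  if (length(vd) != 4)
    nf_input_error("signal volume must be 3D or 4D, got %dD", length(vd))
  if (length(md) != 3 || !all(vd[1:3] == md))
    nf_input_error("volume spatial shape [%s] does not match mask shape [%s]",
                   paste(vd[1:3], collapse = ","),
                   paste(md, collapse = ","))
  if (any(mask != round(mask)) || any(mask < 0))
    nf_input_error("ROI mask must contain nonnegative integer labels")
  sel <- which(mask > 0, arr.ind = TRUE)
  if (nrow(sel) == 0) nf_input_error("no ROI voxels: mask has no nonzero labels")
  coords <- sel - 1L # 0-based (x, y, z) indices
  ord <- order(coords[, 3], coords[, 2], coords[, 1]) # ascending (z, y, x)
  coords <- coords[ord, , drop = FALSE]
  labs_raw <- mask[sel][ord]
  u <- sort(unique(labs_raw))
  labels <- match(labs_raw, u) - 1L
  n_vox <- nrow(coords)
  Tn <- vd[4]
  signal <- matrix(0, Tn, n_vox)
  flat <- (coords[, 1] + 1L) + vd[1] * (coords[, 2] + (vd[2] * coords[, 3]))
  volm <- matrix(vol, prod(vd[1:3]), Tn)
  signal[] <- t(volm[flat, , drop = FALSE])
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  grid <- structure(
    list(coords = coords, roi_labels = labels, signal = signal,
         n_vox = n_vox, n_roi = length(u)),
    class = "nf_voxel_grid"
  )
  validate_voxel_grid(grid)
  grid
}

#' Write a synthetic pair set to disk
#'
#' Responses become a 4D NIfTI volume (x, y, z, sample), ROI labels a 3D
#' integer NIfTI mask (label + 1, background 0), images PNG files, and
#' latents plus voxel loadings an HDF5 sidecar; the generator config is
#' archived as YAML.
#'
#' @param pairs an [generate_pairs()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pairs <- function(pairs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  grid <- pairs$grid
  dims <- apply(grid$coords, 2, max) + 1L
  n <- nrow(pairs$responses)
  vol <- array(0, c(dims, n))
  maskv <- array(0L, dims)
  volm <- matrix(vol, prod(dims), n)
  flat <- (grid$coords[, 1] + 1L) +
    dims[1] * (grid$coords[, 2] + dims[2] * grid$coords[, 3])
  volm[flat, ] <- t(pairs$responses)
  vol <- array(volm, c(dims, n))
  maskv[flat] <- grid$roi_labels + 1L
  write_nifti(vol, file.path(dir, "responses.nii.gz"), "float64")
  write_nifti(maskv, file.path(dir, "roi_mask.nii.gz"), "int32")
  for (i in seq_len(n)) {
    png::writePNG(pairs$images[i, , , ],
                  file.path(dir, "images", sprintf("img_%04d.png", i)))
  }
  h5 <- file.path(dir, "latents.h5")
  if (file.exists(h5)) file.remove(h5)
  rhdf5::h5createFile(h5)
  rhdf5::h5write(pairs$latents, h5, "latents")
  for (r in seq_along(pairs$loadings)) {
    rhdf5::h5write(pairs$loadings[[r]], h5, sprintf("loadings_roi%d", r - 1L))
  }
  rhdf5::h5closeAll()
  yaml::write_yaml(unclass(pairs$config)[setdiff(names(pairs$config), NULL)],
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Load a pair set written by [write_pairs()]
#'
#' @param dir dataset directory.
#' @return an `nf_pair_set` (images quantized to PNG 8-bit depth; grid,
#'   responses and latents exact).
#' @export
load_pairs <- function(dir) {
  cfgl <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- do.call(synthetic_config, cfgl)
  grid <- read_fmri(file.path(dir, "responses.nii.gz"),
                    file.path(dir, "roi_mask.nii.gz"))
  responses <- grid$signal # samples along the 4th volume dimension
  n <- nrow(responses)
  files <- file.path(dir, "images", sprintf("img_%04d.png", seq_len(n)))
  img1 <- png::readPNG(files[1])
  images <- array(0, c(n, dim(img1)))
  images[1, , , ] <- img1
  for (i in seq_len(n)[-1]) images[i, , , ] <- png::readPNG(files[i])
  h5 <- file.path(dir, "latents.h5")
  latents <- rhdf5::h5read(h5, "latents")
  loadings <- lapply(seq_len(cfg$n_roi) - 1L, function(r) {
    rhdf5::h5read(h5, sprintf("loadings_roi%d", r))
  })
  rhdf5::h5closeAll()
  structure(list(images = images, grid = grid, responses = responses,
                 latents = latents, loadings = loadings, config = cfg),
            class = "nf_pair_set")
}

#' Read an image file as an RGB array resized for the encoder
#'
#' Reads PNG or JPEG, converts grayscale/RGBA to RGB, and bilinearly resizes
#' to `size x size`.
#'
#' @param path image file.
#' @param size target side length (default 224).
#' @return `size x size x 3` array in `[0, 1]`.
#' @export
read_image <- function(path, size = 224) {
  if (!file.exists(path)) nf_io_error("image '%s' not found", path)
  img <- if (grepl("\\.(jpe?g)$", path, ignore.case = TRUE)) {
    jpeg::readJPEG(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3]
  resize_bilinear(img, size)
}

# Bilinear resize of an H x W x C array to size x size.
resize_bilinear <- function(img, size) {
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  if (H == size && W == size) return(img)
  map <- function(n_out, n_in) {
    x <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    x <- pmin(pmax(x, 0), n_in - 1)
    lo <- floor(x)
    list(lo = lo + 1, hi = pmin(lo + 1, n_in - 1) + 1, f = x - lo)
  }
  ry <- map(size, H); rx <- map(size, W)
  out <- array(0, c(size, size, C))
  fx <- matrix(rx$f, size, size, byrow = TRUE)
  fy <- matrix(ry$f, size, size)
  for (ch in seq_len(C)) {
    M <- img[, , ch]
    top <- M[ry$lo, rx$lo] * (1 - fx) + M[ry$lo, rx$hi] * fx
    bot <- M[ry$hi, rx$lo] * (1 - fx) + M[ry$hi, rx$hi] * fx
    out[, , ch] <- top * (1 - fy) + bot * fy
  }
  out
}

#' Write named feature arrays to an HDF5 file
#'
#' @param path output `.h5` path (overwritten).
#' @param ... named numeric arrays.
#' @return `path`, invisibly.
#' @export
write_features_h5 <- function(path, ...) {
  feats <- list(...)
  if (is.null(names(feats)) || any(names(feats) == ""))
    nf_config_error("all feature arrays must be named")
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  for (nm in names(feats)) rhdf5::h5write(feats[[nm]], path, nm)
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a feature array from an HDF5 file
#'
#' @param path `.h5` file.
#' @param name dataset name.
#' @return the stored array.
#' @export
read_features_h5 <- function(path, name) {
  out <- rhdf5::h5read(path, name)
  rhdf5::h5closeAll()
  out
}
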