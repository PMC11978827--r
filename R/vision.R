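# Visual branch: a small self-contained convolutional backbone (tiny_conv)
# produces a spatial feature grid; a fully connected head projects the grid
# mean into the shared space (global feature p) and one fully connected head
# per brain ROI projects the flattened grid into the shared space (local
# features p_bar). No external weights are required.

#' Backbone specification for the visual encoder
#'
#' @param name `"tiny_conv"` (self-contained, default) or `"external"`
#'   (caller supplies a function mapping an image to a feature grid).
#' @param d output (shared-space) dimension.
#' @param seed RNG seed for weight initialisation.
#' @param grid_channels channels of the final feature grid (tiny_conv only).
#' @param external_fn for `name = "external"`: `function(image)` returning an
#'   `g x g x C` feature grid.
#' @return object of class `nf_backbone_spec`.
#' @export
backbone_spec <- function(name = c("tiny_conv", "external"), d = 32, seed = 1,
                          grid_channels = 32, external_fn = NULL) {
  name <- match.arg(name)
  if (name == "external" && !is.function(external_fn))
    nf_config_error("external backbone needs an external_fn")
  structure(list(name = name, d = as.integer(d), seed = as.integer(seed),
                 grid_channels = as.integer(grid_channels),
                 external_fn = external_fn),
            class = "nf_backbone_spec")
}

# tiny_conv architecture: 4 stages of (3x3 conv, pad 1, ReLU) + mean-pool,
# pool factors 4, 2, 2, 2 — a 224 x 224 input yields a 7 x 7 grid.
tiny_conv_arch <- function(grid_channels = 32) {
  list(channels = c(3L, 8L, 16L, 32L, as.integer(grid_channels)),
       pools = c(4L, 2L, 2L, 2L))
}

#' Initialise visual-encoder parameters (backbone + projection heads)
#'
#' @param spec an [backbone_spec()].
#' @param n_roi number of per-ROI local heads.
#' @param img_size image side length; must be divisible by 32 (the product of
#'   the pool factors).
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return parameter list of class `nf_vision_params`.
#' @export
vision_params <- function(spec, n_roi = 6, img_size = 224, seed = spec$seed) {
  if (img_size %% 32 != 0)
    nf_shape_error("img_size (%d) must be divisible by 32", img_size)
  arch <- tiny_conv_arch(spec$grid_channels)
  side <- img_size %/% 32L
  C <- arch$channels[length(arch$channels)]
  flat_dim <- side * side * C
  with_seed(derive_seed(seed, "vision"), {
    conv <- lapply(seq_along(arch$pools), function(l) {
      list(W = init_mat(9L * arch$channels[l], arch$channels[l + 1]),
           b = numeric(arch$channels[l + 1]))
    })
    heads <- list(
      W_g = init_mat(flat_dim, spec$d), b_g = numeric(spec$d),
      W_l = lapply(seq_len(n_roi), function(k) init_mat(flat_dim, spec$d)),
      b_l = lapply(seq_len(n_roi), function(k) numeric(spec$d))
    )
    structure(list(spec = spec, arch = arch, conv = conv, heads = heads,
                   n_roi = as.integer(n_roi), img_size = as.integer(img_size),
                   grid_side = side, flat_dim = flat_dim),
              class = "nf_vision_params")
  })
}

# 3x3 same-padding convolution + ReLU via im2col and one matrix multiply.
conv2d_relu <- function(x, W, b) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; C <- dim(x)[3]
  P <- array(0, c(H + 2, Wd + 2, C))
  P[2:(H + 1), 2:(Wd + 1), ] <- x
  cols <- matrix(0, H * Wd, 9 * C)
  blk <- 1L
  for (dj in 0:2) {
    for (di in 0:2) {
      cols[, ((blk - 1) * C + 1):(blk * C)] <-
        matrix(P[di + (1:H), dj + (1:Wd), , drop = FALSE], H * Wd, C)
      blk <- blk + 1L
    }
  }
  out <- sweep(cols %*% W, 2, b, "+")
  out[out < 0] <- 0
  array(out, c(H, Wd, ncol(W)))
}

# Non-overlapping p x p mean pooling.
mean_pool <- function(x, p) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; C <- dim(x)[3]
  a <- colMeans(array(x, c(p, H %/% p, Wd, C)), dims = 1)    # pool rows
  a <- aperm(a, c(2, 1, 3))                                  # (W, H/p, C)
  a <- colMeans(array(a, c(p, Wd %/% p, H %/% p, C)), dims = 1)
  aperm(a, c(2, 1, 3))                                       # (H/p, W/p, C)
}

# Backbone forward: image (H x W x 3, values in [0, 1]) -> feature grid.
tiny_conv_forward <- function(img, params) {
  x <- img - 0.5 # centre inputs
  for (l in seq_along(params$conv)) {
    x <- conv2d_relu(x, params$conv[[l]]$W, params$conv[[l]]$b)
    x <- mean_pool(x, params$arch$pools[l])
  }
  x
}

check_image_batch <- function(images, img_size) {
  dm <- dim(images)
  if (length(dm) == 3) {
    images <- array(images, c(1, dm))
    dm <- dim(images)
  }
  if (length(dm) != 4 || dm[4] != 3)
    nf_shape_error("images must be n x H x W x 3, got dims [%s]",
                   paste(dm, collapse = ", "))
  if (dm[2] != img_size || dm[3] != img_size)
    nf_shape_error("image size %dx%d does not match encoder size %d",
                   dm[2], dm[3], img_size)
  images
}

#' Pre-projection backbone features for a batch of images
#'
#' Returns the grid-mean vector and the flattened grid per image — the inputs
#' of the global and local projection heads. Used to cache the frozen-backbone
#' features once before training.
#'
#' @param images `n x S x S x 3` array (or single `S x S x 3` image).
#' @param params an [vision_params()] list.
#' @return list with `gvec` (`n x C`) and `flat` (`n x flat_dim`).
#' @export
tiny_conv_features <- function(images, params) {
  images <- check_image_batch(images, params$img_size)
  n <- dim(images)[1]
  C <- params$arch$channels[length(params$arch$channels)]
  gvec <- matrix(0, n, C)
  flat <- matrix(0, n, params$flat_dim)
  for (i in seq_len(n)) {
    g <- if (params$spec$name == "external") {
      params$spec$external_fn(images[i, , , ])
    } else {
      tiny_conv_forward(images[i, , , ], params)
    }
    gvec[i, ] <- colMeans(matrix(g, prod(dim(g)[1:2]), dim(g)[3]))
    flat[i, ] <- as.vector(g)
  }
  list(gvec = gvec, flat = flat)
}

#' Encode images into global and per-ROI local visual features
#'
#' The global and local projections both read the flattened backbone grid:
#' a mean-pooled summary would be blind to where content appears in the
#' image, while the brain responses the features must align with are driven
#' by spatially localized (category-selective) content.
#'
#' @param images `n x S x S x 3` array (or single image) with values in
#'   `[0, 1]`, `S` matching the encoder's `img_size` (224 by default).
#' @param params an [vision_params()] list.
#' @param features optional precomputed [tiny_conv_features()] to reuse.
#' @return object of class `nf_visual_feature`: `global` (`n x d`), `local`
#'   (`n x n_roi x d`).
#' @export
encode_image <- function(images, params, features = NULL) {
  if (is.null(features)) features <- tiny_conv_features(images, params)
  n <- nrow(features$gvec)
  d <- params$spec$d
  h <- params$heads
  global <- sweep(features$flat %*% h$W_g, 2, h$b_g, "+")
  local <- array(0, c(n, params$n_roi, d))
  for (k in seq_len(params$n_roi)) {
    local[, k, ] <- sweep(features$flat %*% h$W_l[[k]], 2, h$b_l[[k]], "+")
  }
  structure(list(global = global, local = local), class = "nf_visual_feature")
}

#' Pixel receptive field of one tiny_conv grid cell
#'
#' Computed by index arithmetic back through the conv (kernel 3, pad 1,
#' stride 1) and mean-pool stages; ranges are clamped to the image.
#'
#' @param i,j 0-based grid-cell row/column.
#' @param img_size image side length.
#' @return list with 0-based half-open pixel ranges `rows` and `cols`.
#' @export
tiny_conv_receptive_field <- function(i, j, img_size = 224) {
  arch <- tiny_conv_arch()
  rng <- function(a, b) {
    for (p in rev(arch$pools)) {
      a <- a * p; b <- b * p  # undo pooling
      a <- a - 1; b <- b + 1  # undo 3x3 same-padding conv
    }
    c(max(0, a), min(img_size, b))
  }
  list(rows = rng(i, i + 1), cols = rng(j, j + 1))
}

# ---- weight archive ---------------------------------------------------------

flatten_tensors <- function(x, prefix = "") {
  out <- list()
  nms <- names(x)
  if (is.null(nms)) nms <- as.character(seq_along(x))
  nms[nms == ""] <- as.character(which(nms == ""))
  for (i in seq_along(x)) {
    v <- x[[i]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nms[i]) else nms[i]
    if (is.numeric(v)) {
      # 17 significant digits round-trip IEEE doubles bit-exactly
      out[[key]] <- list(dim = if (is.matrix(v)) dim(v) else length(v),
                         data = sprintf("%.17g", as.numeric(v)))
    } else if (is.list(v)) {
      out <- c(out, flatten_tensors(v, key))
    }
  }
  out
}

#' Export visual-encoder weights as a self-describing archive
#'
#' The archive is a plain-text file: a checksum line followed by a JSON body
#' carrying the architecture description and all weight tensors at full
#' precision. [load_backbone()] verifies the checksum and reproduces every
#' tensor bit-exactly.
#'
#' @param params an [vision_params()] list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_backbone <- function(params, path) {
  arch_string <- sprintf("tiny_conv(d=%d, n_roi=%d, img_size=%d, grid_channels=%d)",
                         params$spec$d, params$n_roi, params$img_size,
                         params$spec$grid_channels)
  body <- list(
    arch = arch_string,
    d = params$spec$d, n_roi = params$n_roi, img_size = params$img_size,
    grid_channels = params$spec$grid_channels, seed = params$spec$seed,
    tensors = flatten_tensors(list(conv = params$conv, heads = params$heads))
  )
  json <- as.character(jsonlite::toJSON(body, digits = NA, auto_unbox = TRUE))
  sum <- digest::digest(json, algo = "sha256", serialize = FALSE)
  ok <- tryCatch({
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c(paste0("neurofusion-weights-v1 sha256:", sum), json), con)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) nf_io_error("cannot write weight archive to '%s'", path)
  invisible(path)
}

#' Load a visual-encoder weight archive
#'
#' @param path archive written by [export_backbone()].
#' @return list with `params` (an [vision_params()] object, tensors
#'   bit-identical to the exported ones) and `arch` (architecture string).
#' @export
load_backbone <- function(path) {
  if (!file.exists(path)) nf_io_error("weight archive '%s' not found", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2 || !startsWith(lines[1], "neurofusion-weights-v1 sha256:"))
    nf_io_error("'%s' is not a neurofusion weight archive", path)
  expected <- sub("^neurofusion-weights-v1 sha256:", "", lines[1])
  json <- paste(lines[-1], collapse = "\n")
  actual <- digest::digest(json, algo = "sha256", serialize = FALSE)
  if (!identical(expected, actual))
    nf_io_error("weight archive checksum failure: expected %s, got %s",
                expected, actual)
  body <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  spec <- backbone_spec("tiny_conv", d = body$d, seed = body$seed,
                        grid_channels = body$grid_channels)
  params <- vision_params(spec, n_roi = body$n_roi, img_size = body$img_size)
  restore <- function(key) {
    t <- body$tensors[[key]]
    v <- as.numeric(t$data)
    if (length(t$dim) == 2) matrix(v, t$dim[1], t$dim[2]) else v
  }
  for (l in seq_along(params$conv)) {
    params$conv[[l]]$W <- restore(sprintf("conv.%d.W", l))
    params$conv[[l]]$b <- restore(sprintf("conv.%d.b", l))
  }
  params$heads$W_g <- restore("heads.W_g")
  params$heads$b_g <- restore("heads.b_g")
  for (k in seq_len(params$n_roi)) {
    params$heads$W_l[[k]] <- restore(sprintf("heads.W_l.%d", k))
    params$heads$b_l[[k]] <- restore(sprintf("heads.b_l.%d", k))
  }
  list(params = params, arch = body$arch)
}
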