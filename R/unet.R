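#' Architecture of the half-width density-regression U-Net
#'
#' An encoder/decoder U-Net with four 2x2 max-pooling levels whose
#' convolutional filter counts are half those of the original segmentation
#' architecture (`base_filters = 32` against the original 64, doubling at
#' every level), all 3x3 convolutions padded so feature maps never shrink,
#' and a rectified-linear final activation instead of a sigmoid so the head
#' regresses a nonnegative, linear-range count density rather than a
#' segmentation probability. The decoder uses nearest-neighbour upsampling
#' followed by a 3x3 convolution, keeping the filter-halving and skip
#' concatenation of the original design. Input side lengths must be
#' divisible by `2^depth = 16`.
#'
#' @param base_filters Filters in the first encoder level (doubles per
#'   level).
#' @param depth Number of max-pooling levels (default 4).
#' @param in_channels Input channels (grayscale: 1).
#' @return An object of class `unet_spec`.
#' @export
unet_spec <- function(base_filters = 32L, depth = 4L, in_channels = 1L) {
  stop_if_not(is_count(base_filters) && base_filters >= 1,
              "base_filters must be a positive integer")
  stop_if_not(is_count(depth) && depth >= 1, "depth must be >= 1")
  structure(list(base_filters = as.integer(base_filters),
                 depth = as.integer(depth),
                 in_channels = as.integer(in_channels),
                 upsampling = "nearest+conv3x3",
                 final_activation = "relu"),
            class = "unet_spec")
}

#' Normalize a grayscale image to the network's input range
#'
#' Subtracts the image mean and divides by twice the pixel standard
#' deviation, so intensities within two standard deviations of the mean land
#' in `[-1, 1]`; remaining outlier pixels are clipped to -1 or 1. The result
#' is invariant to any positive affine rescaling of the input (gain/offset
#' changes from acquisition or staining). A constant image maps to all
#' zeros.
#'
#' @param image Numeric matrix.
#' @return Matrix of the same shape with values in `[-1, 1]`.
#' @export
normalize_image <- function(image) {
  stop_if_not(length(image) > 0, "image must be nonempty")
  s <- sd(image)
  if (!is.finite(s) || s == 0) {
    return(matrix(0, nrow(image), ncol(image)))
  }
  clamp((image - mean(image)) / (2 * s), -1, 1)
}

#' Reflect-pad an image without duplicating the edge pixel
#'
#' Extends each side by `pad_px` pixels of mirrored content (the reflection
#' axis lies on the border pixel, which is not repeated), so a
#' fully convolutional network sees plausible context instead of a hard
#' zero edge; 192x192 becomes 224x224 at the default padding. The returned
#' mask marks the original (non-mirrored) region, which is the only region
#' the training loss is evaluated on.
#'
#' @param image Numeric matrix.
#' @param pad_px Padding width per side; must be smaller than both image
#'   sides.
#' @return List with `image` (padded matrix), `mask` (logical matrix of the
#'   padded shape, `TRUE` on original pixels), and `pad_px`.
#' @export
mirror_pad <- function(image, pad_px = 16L) {
  H <- nrow(image); W <- ncol(image)
  stop_if_not(is_count(pad_px) && pad_px >= 0, "pad_px must be >= 0")
  stop_if_not(pad_px < min(H, W), "pad_px must be smaller than both sides")
  ridx <- reflect_indices(H, pad_px)
  cidx <- reflect_indices(W, pad_px)
  mask <- matrix(FALSE, H + 2 * pad_px, W + 2 * pad_px)
  if (pad_px == 0) mask[] <- TRUE else {
    mask[(pad_px + 1):(pad_px + H), (pad_px + 1):(pad_px + W)] <- TRUE
  }
  list(image = image[ridx, cidx, drop = FALSE], mask = mask,
       pad_px = as.integer(pad_px))
}

# index vector realizing reflection without edge duplication
reflect_indices <- function(n, pad) {
  if (pad == 0) return(seq_len(n))
  c(seq(pad + 1, 2), seq_len(n), seq(n - 1, n - pad))
}

#' Initialize a half-width U-Net density regressor
#'
#' Allocates He-initialized weights for every convolution in the
#' architecture described by [unet_spec()]. The returned model maps a
#' normalized grayscale image (sides divisible by 16) to a same-shaped
#' nonnegative density prediction.
#'
#' @param spec A [unet_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `unet_model` with elements `spec`, `params`,
#'   `m` (density scaling factor, set during training; 1 when untrained) and
#'   `pad_px` (mirror padding used at inference).
#' @export
build_unet <- function(spec = unet_spec(), seed = 1L) {
  stop_if_not(inherits(spec, "unet_spec"), "spec must be a unet_spec")
  filters <- spec$base_filters * 2^(seq_len(spec$depth + 1) - 1)
  params <- list()
  with_seed(seed, {
    he_conv <- function(c_in, c_out) {
      list(W = matrix(rnorm(9 * c_in * c_out, 0, sqrt(2 / (9 * c_in))),
                      9 * c_in, c_out),
           b = numeric(c_out))
    }
    c_prev <- spec$in_channels
    for (l in seq_len(spec$depth)) {
      params[[paste0("enc", l, "_a")]] <- he_conv(c_prev, filters[l])
      params[[paste0("enc", l, "_b")]] <- he_conv(filters[l], filters[l])
      c_prev <- filters[l]
    }
    params[["bot_a"]] <- he_conv(c_prev, filters[spec$depth + 1])
    params[["bot_b"]] <- he_conv(filters[spec$depth + 1],
                                 filters[spec$depth + 1])
    c_prev <- filters[spec$depth + 1]
    for (l in rev(seq_len(spec$depth))) {
      params[[paste0("up", l)]] <- he_conv(c_prev, filters[l])
      params[[paste0("dec", l, "_a")]] <- he_conv(2 * filters[l], filters[l])
      params[[paste0("dec", l, "_b")]] <- he_conv(filters[l], filters[l])
      c_prev <- filters[l]
    }
    # the head bias starts slightly positive so the rectified output begins
    # in its active regime; a head initialized at (or driven to) an
    # everywhere-negative pre-activation would predict zero density with no
    # gradient to recover
    params[["final"]] <- list(
      W = matrix(rnorm(filters[1], 0, sqrt(2 / filters[1])), filters[1], 1),
      b = 0.5)
  })
  structure(list(spec = spec, params = params, m = 1, pad_px = 16L),
            class = "unet_model")
}

#' Number of trainable parameters of a model
#'
#' @param model A `unet_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf(
    "unet_model: base %d filters, depth %d, %d parameters, m = %g\n",
    x$spec$base_filters, x$spec$depth, count_params(x), x$m))
  invisible(x)
}

# Forward pass. `x` is an H x W matrix with H, W divisible by 2^depth.
# Returns list(out = H x W matrix, cache = environment for backprop when
# want_cache is TRUE).
nn_forward <- function(model, x, want_cache = FALSE) {
  spec <- model$spec
  p <- model$params
  H <- nrow(x); W <- ncol(x)
  div <- 2^spec$depth
  stop_if_not(H %% div == 0 && W %% div == 0,
              sprintf("input sides must be divisible by %d", div))
  cache <- if (want_cache) new.env(parent = emptyenv()) else NULL
  conv <- function(name, input) {
    out <- conv3x3_forward(input, p[[name]]$W, p[[name]]$b, TRUE)
    if (want_cache) {
      # stored by reference: no data is copied
      assign(name, list(x = input, out = out), envir = cache)
    }
    out
  }
  cur <- array(x, c(H, W, 1L))
  skips <- vector("list", spec$depth)
  for (l in seq_len(spec$depth)) {
    cur <- conv(paste0("enc", l, "_a"), cur)
    cur <- conv(paste0("enc", l, "_b"), cur)
    skips[[l]] <- cur
    mp <- maxpool2_forward(cur)
    if (want_cache) {
      assign(paste0("pool", l),
             list(arg = mp$arg, H = dim(cur)[1], W = dim(cur)[2]),
             envir = cache)
    }
    cur <- mp$out
  }
  cur <- conv("bot_a", cur)
  cur <- conv("bot_b", cur)
  for (l in rev(seq_len(spec$depth))) {
    cur <- upsample2_forward(cur)
    cur <- conv(paste0("up", l), cur)
    nc <- dim(cur)[3]
    cat_in <- array(0, c(dim(cur)[1], dim(cur)[2], 2L * nc))
    cat_in[, , seq_len(nc)] <- cur
    cat_in[, , nc + seq_len(nc)] <- skips[[l]]
    cur <- conv(paste0("dec", l, "_a"), cat_in)
    cur <- conv(paste0("dec", l, "_b"), cur)
  }
  # 1x1 rectified-linear head
  Xmat <- matrix(cur, H * W, dim(cur)[3])
  pre <- as.numeric(Xmat %*% p$final$W) + p$final$b
  msk <- pre > 0
  out <- matrix(pre * msk, H, W)
  if (want_cache) {
    assign("final", list(X = Xmat, mask = msk, H = H, W = W), envir = cache)
  }
  list(out = out, cache = cache)
}

# Backward pass from d(loss)/d(output). Returns gradients named like params.
nn_backward <- function(model, cache, grad_out) {
  spec <- model$spec
  p <- model$params
  grads <- list()
  conv_bw <- function(name, g) {
    cc <- get(name, envir = cache)
    r <- conv3x3_backward(cc$x, p[[name]]$W, cc$out, g, TRUE)
    grads[[name]] <<- list(W = r$grad_w, b = as.numeric(r$grad_b))
    r$grad_x
  }
  cc <- get("final", envir = cache)
  gv <- as.numeric(grad_out) * cc$mask
  grads$final <- list(W = crossprod(cc$X, gv), b = sum(gv))
  g <- array(gv %o% as.numeric(p$final$W), c(cc$H, cc$W, nrow(p$final$W)))
  skip_grads <- vector("list", spec$depth)
  for (l in seq_len(spec$depth)) {
    g <- conv_bw(paste0("dec", l, "_b"), g)
    g <- conv_bw(paste0("dec", l, "_a"), g)
    nc <- dim(g)[3] / 2
    skip_grads[[l]] <- g[, , nc + seq_len(nc), drop = FALSE]
    g <- conv_bw(paste0("up", l), g[, , seq_len(nc), drop = FALSE])
    g <- upsample2_backward(g)
  }
  g <- conv_bw("bot_b", g)
  g <- conv_bw("bot_a", g)
  for (l in rev(seq_len(spec$depth))) {
    pc <- get(paste0("pool", l), envir = cache)
    g <- maxpool2_backward(g, pc$arg, pc$H, pc$W)
    g <- g + skip_grads[[l]]
    g <- conv_bw(paste0("enc", l, "_b"), g)
    g <- conv_bw(paste0("enc", l, "_a"), g)
  }
  grads
}
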