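#' Tiling configuration for whole-nerve inference
#'
#' Whole optic-nerve mosaics are far larger than the network's training
#' frames, so they are processed as a grid of tiles. Each tile is padded
#' with `context_px` of true pixels from its neighbours where available
#' (mirror padding stands in at the mosaic boundary), predicted, and the
#' resulting density map cropped back to the tile core before stitching, so
#' tile-edge cropping artifacts never reach the stitched map.
#'
#' @param tile_px Core tile side length; divisible by 16.
#' @param context_px Neighbour context per side; must itself be divisible by
#'   16 (context is only attached where true pixels exist, so any
#'   combination of sides must leave the tile's dimensions divisible by 16).
#' @return An object of class `tiling_scheme`.
#' @export
tiling_scheme <- function(tile_px = 192L, context_px = 16L) {
  stop_if_not(is_count(tile_px) && tile_px %% 16 == 0,
              "tile_px must be a positive multiple of 16")
  stop_if_not(is_count(context_px) && context_px >= 0 &&
                context_px %% 16 == 0,
              "context_px must be a nonnegative multiple of 16 (it is only attached where true pixels exist, so each side must independently keep the input divisible by 16)")
  structure(list(tile_px = as.integer(tile_px),
                 context_px = as.integer(context_px)),
            class = "tiling_scheme")
}

#' Predict a count-density map for one image
#'
#' Normalizes the image (optional, for callers that have already normalized
#' a larger mosaic), mirror-pads it by the model's training padding, runs
#' the network, crops the prediction back to the original extent, and
#' divides by the density scaling factor `m` so the map is on the true
#' count-per-pixel scale. All values are nonnegative by construction of the
#' rectified-linear head.
#'
#' @param model A `unet_model` (trained via [train_unet()]).
#' @param image Numeric matrix with side lengths divisible by 16.
#' @param normalize Apply [normalize_image()] first (default `TRUE`).
#' @return A density map matrix of the image's shape.
#' @export
predict_density <- function(model, image, normalize = TRUE) {
  stop_if_not(inherits(model, "unet_model"), "model must be a unet_model")
  if (normalize) image <- normalize_image(image)
  padded <- mirror_pad(image, model$pad_px)
  out <- nn_forward(model, padded$image)$out
  p <- model$pad_px
  H <- nrow(image); W <- ncol(image)
  core <- out[(p + 1):(p + H), (p + 1):(p + W), drop = FALSE]
  core / model$m
}

#' Count axons in one image
#'
#' The automated count: the integral of the predicted count-density map.
#'
#' @inheritParams predict_density
#' @return A nonnegative number.
#' @export
count_axons <- function(model, image, normalize = TRUE) {
  integrate_density(predict_density(model, image, normalize = normalize))
}

# core tile start positions covering 1..n: full tiles, plus a right/bottom-
# aligned overlapping tile whose core is clipped to the remainder
tile_grid <- function(n, tile) {
  n_full <- n %/% tile
  starts <- if (n_full > 0) (seq_len(n_full) - 1) * tile + 1 else integer(0)
  cores <- lapply(starts, function(s) c(s, s + tile - 1))
  if (n %% tile != 0) {
    cores[[length(cores) + 1]] <- c(n_full * tile + 1, n)
  }
  cores
}

#' Split a mosaic into context-padded tiles
#'
#' Partitions the image into `tile_px` core tiles (the final row/column of
#' an image whose sides are not multiples of `tile_px` is covered by
#' right/bottom-aligned overlapping tiles whose cores are clipped to the
#' remainder, so every pixel belongs to exactly one core). Each tile region
#' is extended by `context_px` per side with true neighbouring pixels where
#' they exist; no context is attached along the mosaic boundary, where the
#' prediction step's own edge mirroring provides the padding instead.
#'
#' @param image Numeric matrix at least `tile_px` in each dimension.
#' @param scheme A [tiling_scheme()].
#' @return List of tiles, each with `tile` (padded input matrix), `core`
#'   (`r0, r1, c0, c1` in mosaic coordinates) and `inner` (location of the
#'   core inside `tile`).
#' @export
tile_image <- function(image, scheme = tiling_scheme()) {
  H <- nrow(image); W <- ncol(image)
  tp <- scheme$tile_px; cx <- scheme$context_px
  stop_if_not(H >= tp && W >= tp,
              "image smaller than one tile; use predict_density directly")
  rg <- tile_grid(H, tp)
  cg <- tile_grid(W, tp)
  tiles <- list()
  for (rc in rg) {
    for (cc in cg) {
      # the network input region is the full (right/bottom-aligned) tile
      tr <- c(min(rc[1], H - tp + 1), min(rc[1], H - tp + 1) + tp - 1)
      tc <- c(min(cc[1], W - tp + 1), min(cc[1], W - tp + 1) + tp - 1)
      # attach context only where true pixels exist: tiles at the mosaic
      # boundary keep their bare edge (the prediction step mirrors it)
      ar <- c(if (tr[1] - cx >= 1) tr[1] - cx else tr[1],
              if (tr[2] + cx <= H) tr[2] + cx else tr[2])
      ac <- c(if (tc[1] - cx >= 1) tc[1] - cx else tc[1],
              if (tc[2] + cx <= W) tc[2] + cx else tc[2])
      sub <- image[ar[1]:ar[2], ac[1]:ac[2], drop = FALSE]
      inner <- c(rc[1] - ar[1] + 1, rc[2] - ar[1] + 1,
                 cc[1] - ac[1] + 1, cc[2] - ac[1] + 1)
      tiles[[length(tiles) + 1]] <- list(
        tile = sub,
        core = c(rc[1], rc[2], cc[1], cc[2]),
        inner = inner)
    }
  }
  tiles
}

#' Count axons over a whole-nerve mosaic by tiled inference
#'
#' Normalizes the mosaic once (so all tiles share one intensity scale),
#' splits it into context-padded tiles, predicts each tile's density map,
#' crops each prediction back to its core, and stitches the cores — every
#' mosaic pixel's density is predicted exactly once. The total count is the
#' integral of the stitched map. Images smaller than one tile are resized
#' to the nearest multiple-of-16 dimensions and predicted in a single pass.
#'
#' @param model A trained `unet_model`.
#' @param image Grayscale mosaic matrix.
#' @param scheme A [tiling_scheme()].
#' @return List with `count` and `density` (stitched map of the mosaic's
#'   shape).
#' @export
count_full_nerve <- function(model, image, scheme = tiling_scheme()) {
  H <- nrow(image); W <- ncol(image)
  if (H < scheme$tile_px || W < scheme$tile_px) {
    small <- resize_with_points(image)$image
    dens <- predict_density(model, small)
    return(list(count = integrate_density(dens), density = dens))
  }
  norm <- normalize_image(image)
  tiles <- tile_image(norm, scheme)
  stitched <- matrix(NA_real_, H, W)
  for (i in seq_along(tiles)) {
    t <- tiles[[i]]
    pred <- tryCatch(
      predict_density(model, t$tile, normalize = FALSE),
      error = function(e) {
        stop(sprintf("tile %d (rows %d-%d, cols %d-%d): %s", i,
                     t$core[1], t$core[2], t$core[3], t$core[4],
                     conditionMessage(e)), call. = FALSE)
      })
    stitched[t$core[1]:t$core[2], t$core[3]:t$core[4]] <-
      pred[t$inner[1]:t$inner[2], t$inner[3]:t$inner[4]]
  }
  list(count = integrate_density(stitched), density = stitched)
}
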