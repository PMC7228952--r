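#' Point annotations from one counter
#'
#' @param counter_id Identifier of the counter.
#' @param points Integer matrix with columns `row`, `col` (1-based pixel
#'   coordinates); at most one point per pixel.
#' @param image_shape Integer `(H, W)` of the annotated image.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(counter_id, points, image_shape) {
  if (length(points) == 0) {
    points <- matrix(integer(0), 0, 2)
  }
  points <- as.matrix(points)
  storage.mode(points) <- "integer"
  colnames(points) <- c("row", "col")
  stop_if_not(length(image_shape) == 2 && all(image_shape >= 1),
              "image_shape must be (H, W)")
  if (nrow(points) > 0) {
    stop_if_not(all(points[, 1] >= 1 & points[, 1] <= image_shape[1] &
                      points[, 2] >= 1 & points[, 2] <= image_shape[2]),
                "all points must lie inside the image")
    stop_if_not(!anyDuplicated(points),
                "at most one point per pixel per counter")
  }
  structure(list(counter_id = counter_id, points = points,
                 image_shape = as.integer(image_shape)),
            class = "annotation_set")
}

#' Average multi-counter point annotations into a count-density matrix
#'
#' Builds the ground-truth axon count density matrix `D`: the entry at pixel
#' `(i, j)` is the fraction of counters who annotated that pixel, i.e.
#' `D(i,j) = (1/K) * sum_k c_k(i,j)` where `c_k(i,j)` is 1 when counter `k`
#' marked pixel `(i, j)`. Its total therefore equals the mean of the
#' counters' per-image counts.
#'
#' @param annotations List of [annotation_set()]s sharing `image_shape`.
#' @param shape Optional `(H, W)`; defaults to the annotations' shape.
#' @return An `H x W` numeric matrix with attribute `n_counters`; entries are
#'   multiples of `1/K`.
#' @export
rasterize_annotations <- function(annotations, shape = NULL) {
  stop_if_not(length(annotations) >= 1, "need at least one counter (K >= 1)")
  shapes <- lapply(annotations, `[[`, "image_shape")
  if (is.null(shape)) shape <- shapes[[1]]
  for (s in shapes) {
    stop_if_not(all(s == shape), "all annotation sets must share the shape")
  }
  K <- length(annotations)
  D <- matrix(0, shape[1], shape[2])
  for (a in annotations) {
    if (nrow(a$points) > 0) {
      idx <- a$points[, 1] + shape[1] * (a$points[, 2] - 1L)
      D[idx] <- D[idx] + 1 / K
    }
  }
  attr(D, "n_counters") <- K
  D
}

#' Truncated, unit-normalized isotropic Gaussian kernel
#'
#' The separable 2-D kernel used to distribute annotated point masses over
#' each axon's extent. After truncation to `kernel_size` taps the 1-D profile
#' is renormalized to unit sum, so a point annotation lying at least
#' `(kernel_size-1)/2` pixels from every border contributes exactly 1 to the
#' blurred map's integral.
#'
#' @param sigma Gaussian standard deviation in pixels.
#' @param kernel_size Odd number of taps per side.
#' @return A `kernel_size x kernel_size` matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma = 8, kernel_size = 33) {
  stop_if_not(sigma > 0, "sigma must be positive")
  stop_if_not(is_count(kernel_size) && kernel_size %% 2 == 1,
              "kernel_size must be an odd integer")
  half <- (kernel_size - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  g <- g / sum(g)
  outer(g, g)
}

#' Blur an annotation matrix into a count-density map
#'
#' Convolves the annotation matrix with the truncated unit-sum Gaussian
#' kernel using implicit zero padding and crops the result to the image:
#' density mass carried past the image border is discarded, so an axon
#' annotated near the edge contributes fractionally — partial objects should
#' not count as whole ones. Implemented by stamping the kernel at each
#' nonzero annotation entry, which is exactly equivalent to the zero-padded
#' convolution for the point-mass matrices produced by
#' [rasterize_annotations()].
#'
#' @param D Annotation (or any sparse nonnegative) matrix.
#' @param sigma,kernel_size Kernel parameters, see [gaussian_kernel()].
#' @return An `H x W` double matrix (the count-density map `D_dist`).
#' @export
blur_density <- function(D, sigma = 8, kernel_size = 33) {
  kern <- gaussian_kernel(sigma, kernel_size)
  half <- (kernel_size - 1) / 2
  H <- nrow(D); W <- ncol(D)
  out <- matrix(0, H, W)
  nz <- which(D != 0, arr.ind = TRUE)
  for (n in seq_len(nrow(nz))) {
    i <- nz[n, 1]; j <- nz[n, 2]
    i0 <- max(1, i - half); i1 <- min(H, i + half)
    j0 <- max(1, j - half); j1 <- min(W, j + half)
    out[i0:i1, j0:j1] <- out[i0:i1, j0:j1] +
      D[i, j] * kern[(i0:i1) - i + half + 1, (j0:j1) - j + half + 1]
  }
  out
}

#' Integrate a density map to a count
#'
#' The sum of all entries of a count-density map: for ground-truth maps this
#' is the mean manual count less any boundary leakage; for predictions it is
#' the automated count.
#'
#' @param D A density map matrix.
#' @return A single number.
#' @export
integrate_density <- function(D) sum(D)

#' Resize an image to the nearest multiple-of-16 dimensions, with its points
#'
#' The density-regression network halves the spatial dimensions four times,
#' so inputs must have side lengths divisible by 16. Images are resized with
#' bilinear interpolation to the multiple of 16 closest to each original
#' side (ties round up; 187 px becomes 192 px), and point annotations are
#' rescaled by the same factors and rounded to the nearest pixel. Density
#' maps must be built *after* rescaling the points — interpolating a density
#' map would not conserve its integral, whereas rescaled points conserve the
#' count exactly.
#'
#' @param image `H x W` numeric matrix.
#' @param points Optional integer matrix of `row`, `col` points (1-based), or
#'   a list of [annotation_set()]s.
#' @param target_multiple Side lengths are snapped to multiples of this
#'   (default 16).
#' @return A list with `image` (resized matrix), `points` (rescaled, same
#'   form as the input), and `scale` (row, col scale factors).
#' @export
resize_with_points <- function(image, points = NULL, target_multiple = 16) {
  H <- nrow(image); W <- ncol(image)
  stop_if_not(H >= target_multiple && W >= target_multiple,
              "image must be at least target_multiple in each dimension")
  H2 <- nearest_multiple(H, target_multiple)
  W2 <- nearest_multiple(W, target_multiple)
  scale <- c(H2 / H, W2 / W)
  out <- if (H2 == H && W2 == W) {
    image
  } else {
    EBImage::imageData(EBImage::resize(EBImage::as.Image(image),
                                       w = H2, h = W2, filter = "bilinear"))
  }
  rescale_pts <- function(p, shape) {
    if (nrow(p) == 0) return(p)
    q <- round((p - 0.5) * matrix(scale, nrow(p), 2, byrow = TRUE) + 0.5)
    q[, 1] <- clamp(q[, 1], 1, shape[1])
    q[, 2] <- clamp(q[, 2], 1, shape[2])
    storage.mode(q) <- "integer"
    colnames(q) <- c("row", "col")
    q
  }
  new_points <- NULL
  if (!is.null(points)) {
    if (is.list(points) && !is.matrix(points)) {
      new_points <- lapply(points, function(a) {
        annotation_set(a$counter_id,
                       unique(rescale_pts(a$points, c(H2, W2))),
                       c(H2, W2))
      })
    } else {
      new_points <- rescale_pts(points, c(H2, W2))
    }
  }
  list(image = out, points = new_points, scale = scale)
}
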