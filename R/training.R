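#' Training hyperparameters for the density regressor
#'
#' Defaults follow the reference training recipe: 25 epochs of Adam at
#' learning rate 1e-4 with batch size 1, targets scaled by the density
#' scaling factor `m = 1000` (predictions are divided by `m` at inference),
#' 16-pixel edge mirroring with the loss restricted to non-mirrored pixels,
#' a 10-bin uniform count resampling of the training set, and dihedral plus
#' multiplicative-noise augmentation.
#'
#' @param epochs Training epochs (one pass over the resampled multiset).
#' @param batch_size Images per optimizer step (the recipe uses 1).
#' @param learning_rate Adam step size.
#' @param m Density scaling factor applied to targets during training.
#' @param pad_px Mirror padding width.
#' @param resample_bins Bins for uniform count resampling; 0 disables it.
#' @param augment Apply augmentation during training.
#' @param warmup_steps Steps over which the learning rate ramps linearly
#'   from 0 to `learning_rate`. Adam moves every weight by roughly the
#'   learning rate regardless of gradient magnitude, so the first full-size
#'   steps from a fresh initialization can drive the rectifier head
#'   negative everywhere — a dead network that predicts zero density with
#'   no gradient to recover. A short warmup removes that failure mode.
#' @param seed Seed for shuffling and augmentation draws.
#' @return An object of class `training_config`.
#' @export
training_config <- function(epochs = 25L, batch_size = 1L,
                            learning_rate = 1e-4, m = 1000,
                            pad_px = 16L, resample_bins = 10L,
                            augment = TRUE, warmup_steps = 30L,
                            seed = 1L) {
  stop_if_not(is_count(epochs) && epochs >= 1, "epochs must be >= 1")
  stop_if_not(m > 0, "m must be positive")
  stop_if_not(learning_rate > 0, "learning_rate must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, m = m,
                 pad_px = as.integer(pad_px),
                 resample_bins = as.integer(resample_bins),
                 augment = isTRUE(augment),
                 warmup_steps = as.integer(warmup_steps),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Masked mean-squared-error density loss
#'
#' Mean over the masked pixels of the squared difference between the
#' predicted density and the `m`-scaled target density. During training the
#' mask excludes mirrored border pixels, so edge artifacts introduced by
#' padding never contribute to the loss.
#'
#' @param prediction,target Numeric matrices of one shape (`target` on the
#'   unscaled count-density scale).
#' @param mask Logical matrix of the same shape (`TRUE` = include), or
#'   `NULL` for all pixels.
#' @param m Density scaling factor.
#' @return A single number.
#' @export
density_loss <- function(prediction, target, mask = NULL, m = 1000) {
  stop_if_not(all(dim(prediction) == dim(target)),
              "prediction and target shapes must match")
  d <- prediction - m * target
  if (is.null(mask)) return(mean(d^2))
  stop_if_not(all(dim(mask) == dim(prediction)),
              "mask shape must match prediction")
  mean(d[mask]^2)
}

# one of the 8 symmetries of the square, k in 0..7:
# k %% 4 = number of 90-degree rotations, k >= 4 adds a transpose flip
dihedral_apply <- function(mat, k) {
  if (k >= 4) mat <- t(mat)
  for (i in seq_len(k %% 4)) mat <- t(mat[nrow(mat):1, , drop = FALSE])
  mat
}

#' Augment an image/target pair
#'
#' Applies one of the eight dihedral symmetries of the square (identity,
#' rotations by multiples of 90 degrees, mirrorings) identically to the
#' image and its density target, then multiplies the image — and the image
#' only — elementwise by independent uniform values in `[0.85, 1.15]`.
#' Geometric operations permute pixels, so the target's integral (the count)
#' is preserved exactly.
#'
#' @param image,target Square numeric matrices of one shape.
#' @param seed Optional seed; by default draws from the current RNG stream.
#' @return List with `image` and `target`.
#' @export
augment_pair <- function(image, target, seed = NULL) {
  stop_if_not(nrow(image) == ncol(image), "augmentation expects square images")
  stop_if_not(all(dim(image) == dim(target)), "shapes must match")
  with_seed(seed, {
    k <- sample(0:7, 1)
    image <- dihedral_apply(image, k)
    target <- dihedral_apply(target, k)
    noise <- matrix(runif(length(image), 0.85, 1.15), nrow(image))
    list(image = image * noise, target = target)
  })
}

#' Replicate training images toward a uniform count histogram
#'
#' Datasets contain few images with extreme (very low or very high) axon
#' counts, which biases a trained counter toward the dataset mean. A
#' histogram of per-image counts with `n_bins` equal-width bins is built and
#' every image in an under-filled bin is replicated `round(max_bin /
#' bin_size)` times, so each nonempty bin ends up approximately as full as
#' the fullest one. All originals are retained; empty bins are skipped.
#'
#' @param examples List of training examples.
#' @param counts Numeric per-example counts; defaults to `$count` of each
#'   example.
#' @param n_bins Number of histogram bins.
#' @return The expanded list of examples (a multiset superset of the input).
#' @export
resample_uniform <- function(examples, counts = NULL, n_bins = 10) {
  stop_if_not(length(examples) >= 1, "training set must be nonempty")
  if (is.null(counts)) {
    counts <- vapply(examples, function(e) e$count, numeric(1))
  }
  stop_if_not(length(counts) == length(examples),
              "one count per example required")
  if (n_bins < 2 || diff(range(counts)) == 0) return(examples)
  breaks <- seq(min(counts), max(counts), length.out = n_bins + 1)
  bin <- findInterval(counts, breaks, rightmost.closed = TRUE)
  sizes <- tabulate(bin, nbins = n_bins)
  max_size <- max(sizes)
  factor <- ifelse(sizes > 0, pmax(1, round(max_size / pmax(sizes, 1))), 0)
  idx <- unlist(lapply(seq_along(examples),
                       function(i) rep(i, factor[bin[i]])))
  examples[idx]
}

#' Build network-ready training examples from annotated images
#'
#' For each record, resizes the image to multiple-of-16 dimensions with
#' [resize_with_points()], rasterizes the rescaled annotations (Gaussian
#' count density is always built at the resized resolution so the count is
#' conserved exactly), and blurs them into the density target.
#'
#' @param records List of dataset records (as produced by
#'   [generate_dataset()]), each with `image` and `annotations`.
#' @param sigma,kernel_size Blur parameters, see [blur_density()].
#' @return List of examples with `image` (matrix), `target` (density map),
#'   `count` (mean manual count), and `id`.
#' @export
build_training_examples <- function(records, sigma = 8, kernel_size = 33) {
  lapply(records, function(r) {
    rs <- resize_with_points(r$image$pixels, r$annotations)
    D <- rasterize_annotations(rs$points)
    list(image = rs$image,
         target = blur_density(D, sigma = sigma, kernel_size = kernel_size),
         count = mean_manual_count(rs$points),
         id = r$id)
  })
}

# Adam update of a flat list of parameter tensors; state carried in `opt`.
adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  for (name in names(params)) {
    for (slot in c("W", "b")) {
      g <- grads[[name]][[slot]]
      key <- paste0(name, ".", slot)
      if (is.null(opt$m[[key]])) {
        opt$m[[key]] <- g * 0
        opt$v[[key]] <- g * 0
      }
      opt$m[[key]] <- beta1 * opt$m[[key]] + (1 - beta1) * g
      opt$v[[key]] <- beta2 * opt$v[[key]] + (1 - beta2) * g^2
      mhat <- opt$m[[key]] / corr1
      vhat <- opt$v[[key]] / corr2
      params[[name]][[slot]] <- params[[name]][[slot]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, opt = opt)
}

# forward + masked loss for one example; returns loss and, optionally, the
# parameter gradients
train_step <- function(model, example, config, augment = FALSE,
                       want_grads = TRUE) {
  img <- normalize_image(example$image)
  target <- example$target
  if (augment) {
    aug <- augment_pair(img, target)
    img <- aug$image
    target <- aug$target
  }
  padded <- mirror_pad(img, config$pad_px)
  fw <- nn_forward(model, padded$image, want_cache = want_grads)
  core <- padded$mask
  diff <- fw$out[core] - config$m * target
  loss <- mean(diff^2)
  if (!want_grads) return(list(loss = loss))
  grad_out <- matrix(0, nrow(padded$image), ncol(padded$image))
  grad_out[core] <- 2 * diff / length(diff)
  list(loss = loss, grads = nn_backward(model, fw$cache, grad_out))
}

#' Train the density regressor
#'
#' Runs the full training recipe: optional uniform count resampling of the
#' training examples, then `epochs` passes of batch-size-1 Adam over the
#' shuffled (resampled) multiset, each step normalizing the image,
#' optionally augmenting it, mirror-padding image and target context, and
#' minimizing the masked mean-squared density error against the `m`-scaled
#' target. Per-epoch mean training loss and validation loss (no
#' augmentation, same masking) are logged so train/validation curves can be
#' compared for overfitting. Training aborts with a diagnostic if the loss
#' becomes non-finite. With a fixed `config$seed` and single-threaded
#' execution, the loss trajectory is reproducible on one platform.
#'
#' @param model A `unet_model` from [build_unet()].
#' @param examples Training examples from [build_training_examples()].
#' @param config A [training_config()].
#' @param val_examples Optional validation examples.
#' @param verbose Print per-epoch losses.
#' @return List with `model` (trained; `m` recorded for inference) and
#'   `history` (data frame: epoch, train_loss, val_loss).
#' @export
train_unet <- function(model, examples, config = training_config(),
                       val_examples = NULL, verbose = FALSE) {
  stop_if_not(length(examples) >= 1, "training set must be nonempty")
  stop_if_not(inherits(config, "training_config"),
              "config must be a training_config")
  if (config$resample_bins >= 2) {
    examples <- resample_uniform(examples, n_bins = config$resample_bins)
  }
  opt <- list(t = 0, m = list(), v = list())
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  model$m <- config$m
  model$pad_px <- config$pad_px
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      order_idx <- sample.int(length(examples))
      losses <- numeric(length(examples))
      for (i in seq_along(order_idx)) {
        st <- train_step(model, examples[[order_idx[i]]], config,
                         augment = config$augment)
        if (!is.finite(st$loss)) {
          stop(sprintf(
            "non-finite loss at epoch %d, step %d (example %s)",
            epoch, i, examples[[order_idx[i]]]$id), call. = FALSE)
        }
        losses[i] <- st$loss
        lr_t <- config$learning_rate
        ws <- config$warmup_steps
        if (!is.null(ws) && ws > 0 && opt$t < ws) {
          lr_t <- lr_t * (opt$t + 1) / ws
        }
        upd <- adam_step(model$params, st$grads, opt, lr_t)
        model$params <- upd$params
        opt <- upd$opt
      }
      val_loss <- NA_real_
      if (!is.null(val_examples) && length(val_examples) > 0) {
        val_loss <- mean(vapply(val_examples, function(e) {
          train_step(model, e, config, augment = FALSE,
                     want_grads = FALSE)$loss
        }, numeric(1)))
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = mean(losses),
                                  val_loss = val_loss))
      if (verbose) {
        message(sprintf("epoch %d: train %.4g, val %.4g", epoch,
                        mean(losses), val_loss))
      }
    }
  })
  list(model = model, history = history)
}
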