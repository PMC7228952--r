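test_that("the density loss is the masked mean squared error against m-scaled targets", {
  target <- matrix(runif(64, 0, 0.01), 8, 8)
  m <- 1000
  expect_equal(density_loss(m * target, target, m = m), 0)
  expect_equal(density_loss(m * target + 1, target, m = m), 1)
  expect_error(density_loss(matrix(0, 4, 4), matrix(0, 8, 8)), "match")
})

test_that("pixels outside the mask never influence the loss", {
  set.seed(3)
  img <- matrix(runif(96 * 96), 96, 96)
  p <- mirror_pad(img, 16)
  target <- matrix(runif(128 * 128, 0, 0.01), 128, 128)
  pred <- matrix(runif(128 * 128), 128, 128)
  base <- density_loss(pred, target, mask = p$mask)
  corrupted <- pred
  corrupted[!p$mask] <- corrupted[!p$mask] + 100
  expect_equal(density_loss(corrupted, target, mask = p$mask), base)
})

test_that("augmentation preserves the target integral and bounds the noise", {
  set.seed(4)
  img <- matrix(runif(64 * 64), 64, 64)
  target <- blur_density({
    D <- matrix(0, 64, 64); D[cbind(sample(64, 5), sample(64, 5))] <- 1; D
  })
  for (s in 1:8) {
    aug <- augment_pair(img, target, seed = s)
    expect_equal(integrate_density(aug$target), integrate_density(target),
                 tolerance = 1e-12)
    expect_equal(dim(aug$image), dim(img))
  }
  # find a seed whose dihedral draw is the identity, then check the
  # multiplicative noise envelope on its own
  id_seed <- Find(function(s) {
    axodense:::with_seed(s, sample(0:7, 1)) == 0
  }, 1:100)
  aug <- augment_pair(img, target, seed = id_seed)
  ratio <- aug$image / img
  expect_true(all(ratio >= 0.85 - 1e-12 & ratio <= 1.15 + 1e-12))
  expect_identical(aug$target, target)
})

test_that("dihedral transforms are the 8 square symmetries", {
  m <- matrix(1:12, 3, 4)[1:3, 1:3]
  seen <- unique(lapply(0:7, function(k) axodense:::dihedral_apply(m, k)))
  expect_length(seen, 8)
  expect_identical(axodense:::dihedral_apply(m, 0), m)
  # four applications of the rotation return to start
  r4 <- Reduce(function(x, .) axodense:::dihedral_apply(x, 1), 1:4, m)
  expect_identical(r4, m)
})

test_that("count resampling flattens the histogram without dropping images", {
  mk <- function(counts) lapply(seq_along(counts), function(i) {
    list(id = i, count = counts[i])
  })
  # bins {10, 5} -> the small bin doubles
  ex <- mk(c(rep(1, 10), rep(9, 5)))
  out <- resample_uniform(ex, n_bins = 2)
  counts <- vapply(out, `[[`, numeric(1), "count")
  expect_equal(sum(counts == 1), 10)
  expect_equal(sum(counts == 9), 10)
  # already uniform -> unchanged
  ex2 <- mk(c(rep(1, 5), rep(9, 5)))
  expect_length(resample_uniform(ex2, n_bins = 2), 10)
  # constant counts (single bin, others empty) -> unchanged, no div by zero
  ex3 <- mk(rep(4, 6))
  expect_length(resample_uniform(ex3, n_bins = 10), 6)
  # multiset superset: every original id still present at least once
  ids <- vapply(out, `[[`, numeric(1), "id")
  expect_true(all(seq_len(15) %in% ids))
})

test_that("a short training run reduces the loss and logs finite histories", {
  cfg <- synthetic_nerve_config(image_size_px = 64, axon_density = 8,
                                radius_range_px = c(2, 3), myelin_width_px = 1,
                                seed = 2)
  recs <- lapply(1:3, function(i) {
    c2 <- cfg; c2$seed <- i
    img <- generate_axon_image(c2)
    list(id = paste0("img", i), image = img,
         annotations = simulate_counters(img, 2, miss_rate = 0,
                                         spurious_rate = 0, jitter_px = 0,
                                         seed = i))
  })
  ex <- build_training_examples(recs)
  model <- build_unet(unet_spec(base_filters = 2), seed = 1)
  res <- train_unet(model, ex,
                    training_config(epochs = 3, augment = FALSE,
                                    resample_bins = 0, learning_rate = 1e-3,
                                    seed = 1),
                    val_examples = ex)
  expect_equal(nrow(res$history), 3)
  expect_true(all(is.finite(res$history$train_loss)))
  expect_true(all(is.finite(res$history$val_loss)))
  expect_lt(min(res$history$train_loss), res$history$train_loss[1] + 1e-12)
  expect_equal(res$model$m, 1000)
  # reproducible loss trajectory under the same seed
  res2 <- train_unet(model, ex,
                     training_config(epochs = 3, augment = FALSE,
                                     resample_bins = 0, learning_rate = 1e-3,
                                     seed = 1),
                     val_examples = ex)
  expect_equal(res$history, res2$history)
})
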