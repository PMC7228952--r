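# Shared, memoized heavy fixtures: the scaled-down reference training run
# (10 synthetic nerves, 60 training images at 96 px, width-8 model, 10
# epochs) and its dataset. Built once per test session and reused by the
# tiling and recovery tests.

.run_cache <- new.env(parent = emptyenv())

scaled_config <- function() {
  synthetic_nerve_config(image_size_px = 96, axon_density = 20,
                         radius_range_px = c(2, 3.5), myelin_width_px = 1.5,
                         damage_level = 0.3)
}

scaled_dataset <- function() {
  if (is.null(.run_cache$dataset)) {
    .run_cache$dataset <- generate_dataset(
      n_nerves = 10, images_per_nerve = 10, config = scaled_config(),
      density_range = c(2, 40), damage_range = c(0, 0.6), seed = 11)
  }
  .run_cache$dataset
}

scaled_training_run <- function() {
  if (is.null(.run_cache$run)) {
    ds <- scaled_dataset()
    # at half resolution the blur scales with the axons: sigma 4, 17 taps
    tr <- build_training_examples(dataset_subset(ds, "train"),
                                  sigma = 4, kernel_size = 17)
    va <- build_training_examples(dataset_subset(ds, "val"),
                                  sigma = 4, kernel_size = 17)
    model <- build_unet(unet_spec(base_filters = 8), seed = 7)
    res <- train_unet(model, tr,
                      training_config(epochs = 10, learning_rate = 2e-4,
                                      seed = 5),
                      val_examples = va)
    .run_cache$run <- list(model = res$model, history = res$history)
  }
  .run_cache$run
}
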