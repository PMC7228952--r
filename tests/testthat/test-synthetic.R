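small_config <- function(...) {
  defaults <- list(image_size_px = 96, axon_density = 20,
                   radius_range_px = c(2, 3.5), myelin_width_px = 1.5)
  do.call(synthetic_nerve_config, utils::modifyList(defaults, list(...)))
}

test_that("generation is deterministic for a fixed seed", {
  a <- generate_axon_image(small_config(seed = 42))
  b <- generate_axon_image(small_config(seed = 42))
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$true_points, b$true_points)
  c <- generate_axon_image(small_config(seed = 43))
  expect_false(identical(a$pixels, c$pixels))
})

test_that("zero density yields an empty ground truth and config is validated", {
  img <- generate_axon_image(small_config(axon_density = 0, seed = 1))
  expect_equal(nrow(img$true_points), 0)
  expect_error(synthetic_nerve_config(image_size_px = 48), "64")
  expect_error(synthetic_nerve_config(damage_level = 1.5), "damage")
  expect_error(synthetic_nerve_config(radius_range_px = c(3, 2)), "radius")
})

test_that("pixels stay in range and points satisfy the counting region", {
  for (s in 1:5) {
    img <- generate_axon_image(small_config(seed = s, damage_level = 0.5))
    expect_true(all(img$pixels >= 0 & img$pixels <= 1))
    if (nrow(img$true_points) > 0) {
      expect_true(all(img$true_points[, 1] >= 1 &
                        img$true_points[, 1] <= 96))
      expect_true(all(img$true_points[, 2] >= 1 &
                        img$true_points[, 2] <= 96))
    }
  }
})

test_that("border rule counts top/left crossers >50% inside, never right/bottom", {
  # centre on the right border: touches it, excluded
  expect_false(axodense:::axon_is_counted(50, 96, 4, 96, 96))
  expect_false(axodense:::axon_is_counted(96, 50, 4, 96, 96))
  # >50% inside across the left border: counted
  expect_true(axodense:::axon_is_counted(50, 2, 4, 96, 96))
  # centre exactly on the left border: exactly half inside, not counted
  expect_false(axodense:::axon_is_counted(50, 0, 4, 96, 96))
  # <50% inside across the top border: excluded
  expect_false(axodense:::axon_is_counted(-1.5, 50, 4, 96, 96))
  # fully interior: counted
  expect_true(axodense:::axon_is_counted(50, 50, 4, 96, 96))
})

test_that("mean generated count matches the requested density", {
  counts <- vapply(1:80, function(s) {
    nrow(generate_axon_image(small_config(seed = s))$true_points)
  }, numeric(1))
  se <- sqrt(20 / 80)  # Poisson placement: var = mean = 20
  expect_lt(abs(mean(counts) - 20), 3 * se)
})

test_that("noise-free counters reproduce the ground truth exactly", {
  img <- generate_axon_image(small_config(seed = 7))
  ann <- simulate_counters(img, 4, miss_rate = 0, spurious_rate = 0,
                           jitter_px = 0, seed = 1)
  expect_length(ann, 4)
  for (a in ann) {
    expect_equal(a$points[order(a$points[, 1], a$points[, 2]), ],
                 img$true_points[order(img$true_points[, 1],
                                       img$true_points[, 2]), ])
  }
})

test_that("counter counts follow binomial thinning of the true points", {
  img <- generate_axon_image(small_config(axon_density = 50, seed = 3))
  n_true <- nrow(img$true_points)
  counts <- unlist(lapply(1:50, function(s) {
    ann <- simulate_counters(img, 4, miss_rate = 0.1, spurious_rate = 0,
                             jitter_px = 0, counter_sd = 0, seed = s)
    vapply(ann, function(a) nrow(a$points), numeric(1))
  }))
  expected <- 0.9 * n_true
  se <- sqrt(n_true * 0.1 * 0.9 / length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("datasets partition whole nerves across subsets", {
  ds <- generate_dataset(10, 2, split = c(0.6, 0.2, 0.2),
                         config = small_config(), n_counters = 2, seed = 5)
  by_subset <- split(ds$manifest$nerve_id, ds$manifest$subset)
  expect_equal(lengths(lapply(by_subset, unique)),
               c(test = 2, train = 6, val = 2))
  # no nerve in two subsets
  ids <- lapply(by_subset, unique)
  expect_length(Reduce(intersect, ids), 0)
  # conservation of images
  expect_equal(nrow(ds$manifest), 20)
  # dataset-level determinism
  ds2 <- generate_dataset(10, 2, split = c(0.6, 0.2, 0.2),
                          config = small_config(), n_counters = 2, seed = 5)
  expect_identical(ds$images[[3]]$image$pixels, ds2$images[[3]]$image$pixels)
})

test_that("degenerate splits are honoured and bad splits rejected", {
  ds <- generate_dataset(5, 1, split = c(1, 0, 0), config = small_config(),
                         n_counters = 2, seed = 2)
  expect_true(all(ds$manifest$subset == "train"))
  expect_error(generate_dataset(5, 1, split = c(0.6, 0.3, 0.3),
                                config = small_config()), "summing to 1")
})
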