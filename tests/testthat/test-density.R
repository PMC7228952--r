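test_that("rasterization averages counters per pixel", {
  # one counter, one point
  a <- annotation_set("c1", cbind(5, 5), c(20, 20))
  D <- rasterize_annotations(list(a))
  expect_equal(D[5, 5], 1)
  expect_equal(sum(D), 1)
  # 3 of 4 counters mark one pixel
  anns <- lapply(1:4, function(k) {
    pts <- if (k <= 3) cbind(10, 10) else matrix(integer(0), 0, 2)
    annotation_set(paste0("c", k), pts, c(20, 20))
  })
  D <- rasterize_annotations(anns)
  expect_equal(D[10, 10], 0.75)
  # sum equals the mean per-counter count
  a1 <- annotation_set("A", rbind(c(1, 1), c(2, 2)), c(20, 20))
  a2 <- annotation_set("B", cbind(2, 2), c(20, 20))
  expect_equal(sum(rasterize_annotations(list(a1, a2))), 1.5)
})

test_that("annotation matrices are quantized to multiples of 1/K", {
  set.seed(1)
  for (K in c(2, 4)) {
    anns <- lapply(seq_len(K), function(k) {
      pts <- cbind(sample(30, 10), sample(30, 10))
      annotation_set(paste0("c", k), unique(pts), c(30, 30))
    })
    D <- rasterize_annotations(anns)
    expect_true(all(abs(D * K - round(D * K)) < 1e-12))
  }
})

test_that("annotation sets validate their points", {
  expect_error(annotation_set("c", cbind(0, 5), c(10, 10)), "inside")
  expect_error(annotation_set("c", cbind(11, 5), c(10, 10)), "inside")
  expect_error(annotation_set("c", rbind(c(2, 2), c(2, 2)), c(10, 10)),
               "one point per pixel")
  expect_error(rasterize_annotations(list()), "K >= 1")
  expect_error(
    rasterize_annotations(list(annotation_set("a", cbind(1, 1), c(10, 10)),
                               annotation_set("b", cbind(1, 1), c(12, 12)))),
    "share")
})

test_that("an interior point blurs to unit mass, a corner point loses mass", {
  D <- matrix(0, 192, 192)
  D[96, 96] <- 1
  expect_equal(integrate_density(blur_density(D)), 1, tolerance = 1e-12)
  # corner point: independent separable oracle — squared one-sided 1-D mass
  g <- exp(-((-16:16)^2) / (2 * 8^2))
  g <- g / sum(g)
  oracle <- sum(g[17:33])^2
  Dc <- matrix(0, 192, 192)
  Dc[1, 1] <- 1
  got <- integrate_density(blur_density(Dc))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_lt(got, 0.5)
  expect_gt(got, 0.25)
})

test_that("blur of an empty matrix is zero and the kernel must be odd", {
  expect_equal(blur_density(matrix(0, 64, 64)), matrix(0, 64, 64))
  expect_error(blur_density(matrix(0, 64, 64), kernel_size = 32), "odd")
})

test_that("blur is linear and translation-equivariant for interior points", {
  D1 <- matrix(0, 96, 96); D1[40, 40] <- 1
  D2 <- matrix(0, 96, 96); D2[52, 61] <- 0.75
  expect_equal(blur_density(D1 + D2), blur_density(D1) + blur_density(D2),
               tolerance = 1e-12)
  # shifting an interior point shifts the map
  b1 <- blur_density(D1)
  D3 <- matrix(0, 96, 96); D3[43, 45] <- 1
  b3 <- blur_density(D3)
  expect_equal(b3[(1 + 3):96, (1 + 5):96], b1[1:(96 - 3), 1:(96 - 5)],
               tolerance = 1e-14)
})

test_that("density integrals behave linearly", {
  expect_equal(integrate_density(matrix(0, 10, 10)), 0)
  a <- annotation_set("c", cbind(sample(60:130, 7), sample(60:130, 7)),
                      c(192, 192))
  M <- blur_density(rasterize_annotations(list(a)))
  expect_equal(integrate_density(M), 7, tolerance = 1e-9)
  expect_equal(integrate_density(2 * M), 2 * integrate_density(M))
})

test_that("conservation holds for points at least 16 px from every border", {
  set.seed(42)
  for (i in 1:10) {
    K <- sample(c(2, 4), 1)
    anns <- lapply(seq_len(K), function(k) {
      n <- sample(5:20, 1)
      pts <- unique(cbind(sample(17:(96 - 16), n, replace = TRUE),
                          sample(17:(96 - 16), n, replace = TRUE)))
      annotation_set(paste0("c", k), pts, c(96, 96))
    })
    D <- rasterize_annotations(anns)
    mc <- mean(vapply(anns, function(a) nrow(a$points), numeric(1)))
    expect_equal(integrate_density(blur_density(D)), mc, tolerance = 1e-9)
  }
})

test_that("images resize to the nearest multiple of 16, ties rounding up", {
  img <- matrix(runif(187 * 187), 187, 187)
  rs <- resize_with_points(img)
  expect_equal(dim(rs$image), c(192, 192))
  # identity when already a multiple of 16
  img192 <- matrix(runif(192 * 192), 192, 192)
  expect_identical(resize_with_points(img192)$image, img192)
  # 200 is a tie (192 vs 208): round up; 184 is closest to 192
  img2 <- matrix(runif(200 * 184), 200, 184)
  expect_equal(dim(resize_with_points(img2)$image), c(208, 192))
})

test_that("points are rescaled with the image and counts conserved", {
  a <- annotation_set("c", cbind(c(50, 90, 150), c(60, 100, 170)),
                      c(187, 187))
  rs <- resize_with_points(matrix(0.5, 187, 187), list(a))
  expect_equal(rs$points[[1]]$image_shape, c(192L, 192L))
  expect_equal(nrow(rs$points[[1]]$points), 3)
  # rescaled coordinates are within one pixel of the exact scaling
  exact <- (cbind(c(50, 90, 150), c(60, 100, 170)) - 0.5) * (192 / 187) + 0.5
  expect_true(all(abs(rs$points[[1]]$points - exact) <= 0.5 + 1e-9))
})
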