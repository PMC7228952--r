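#' Configuration for the synthetic optic-nerve image generator
#'
#' Describes one synthetic optic-nerve sub-image: geometry, expected axon
#' density, damage severity, and grayscale statistics. "Normal"-appearing
#' axons are rendered as annuli (light axoplasmic core inside a dark myelin
#' ring); `damage_level` controls shape irregularity, myelin discontinuity
#' and the fraction of "abnormal" distractor axons (collapsed dark core,
#' broken ring) which are drawn but never listed as ground truth, mimicking
#' the counting rule used for real nerves where only "normal"-appearing axons
#' are annotated.
#'
#' @param image_size_px Side length in pixels (square images). Must be at
#'   least 64 so the 33-pixel density blur kernel fits meaningfully.
#' @param px_per_um Image resolution, pixels per micrometre.
#' @param axon_density Expected number of countable axons per image (Poisson
#'   mean, after the border counting rule).
#' @param damage_level Severity in `[0, 1]`: 0 renders clean circular annuli,
#'   1 renders strongly irregular, discontinuous myelin plus abnormal
#'   distractors at half the normal density.
#' @param radius_range_px Numeric length-2, min and max inner (core) radius
#'   in pixels.
#' @param myelin_width_px Width of the dark myelin ring in pixels.
#' @param background_mean,background_noise_sd Gray level statistics of the
#'   neuropil background on the `[0, 1]` intensity scale.
#' @param contrast_scale Global multiplier on axon contrast, emulating
#'   staining intensity variation.
#' @param seed Integer seed; identical configurations generate bit-identical
#'   images.
#' @return An object of class `synthetic_nerve_config`.
#' @seealso [generate_axon_image()], [generate_dataset()]
#' @export
synthetic_nerve_config <- function(image_size_px = 187,
                                   px_per_um = 15.7,
                                   axon_density = 40,
                                   damage_level = 0,
                                   radius_range_px = c(3, 5),
                                   myelin_width_px = 2,
                                   background_mean = 0.55,
                                   background_noise_sd = 0.04,
                                   contrast_scale = 1,
                                   seed = 1L) {
  stop_if_not(is_count(image_size_px) && image_size_px >= 64,
              "image_size_px must be an integer >= 64")
  stop_if_not(px_per_um > 0, "px_per_um must be positive")
  stop_if_not(axon_density >= 0, "axon_density must be nonnegative")
  stop_if_not(damage_level >= 0 && damage_level <= 1,
              "damage_level must lie in [0, 1]")
  stop_if_not(length(radius_range_px) == 2 &&
                radius_range_px[1] < radius_range_px[2] &&
                radius_range_px[1] > 0,
              "radius_range_px must be (min, max) with 0 < min < max")
  stop_if_not(myelin_width_px > 0, "myelin_width_px must be positive")
  stop_if_not(contrast_scale > 0, "contrast_scale must be positive")
  structure(list(image_size_px = as.integer(image_size_px),
                 px_per_um = px_per_um,
                 axon_density = axon_density,
                 damage_level = damage_level,
                 radius_range_px = radius_range_px,
                 myelin_width_px = myelin_width_px,
                 background_mean = background_mean,
                 background_noise_sd = background_noise_sd,
                 contrast_scale = contrast_scale,
                 seed = as.integer(seed)),
            class = "synthetic_nerve_config")
}

# Border counting rule on the continuous image domain [0, H] x [0, W]
# (rows increase downward; top = row 0, left = col 0). An axon disk is
# counted iff it lies fully inside, or it crosses the top and/or left border
# with strictly more than half of its area inside. Disks touching the right
# or bottom border are never counted, so adjacent tiles never double-count.
axon_is_counted <- function(row, col, r, H, W) {
  if (row - r >= 0 && col - r >= 0 && row + r <= H && col + r <= W) {
    return(TRUE)
  }
  if (row + r > H || col + r > W) return(FALSE)
  disk_inside_fraction(row, col, r, H, W) > 0.5 + 1e-9
}

# Area fraction of the disk inside [0, H] x [0, W], by deterministic
# subpixel grid quadrature (exact enough for the >50% decision away from the
# knife edge; a disk centred exactly on a border evaluates to ~0.5 and is
# therefore not counted).
disk_inside_fraction <- function(row, col, r, H, W) {
  g <- seq(-r, r, length.out = 61)
  dy <- outer(g, rep(1, 61))
  dx <- outer(rep(1, 61), g)
  in_disk <- dy * dy + dx * dx <= r * r
  y <- row + dy[in_disk]
  x <- col + dx[in_disk]
  # strict on the top/left boundary so a disk centred exactly on a border
  # resolves to "half inside" from below and is not counted
  mean(y > 0 & y <= H & x > 0 & x <= W)
}

smoothstep <- function(t) {
  t <- clamp(t, 0, 1)
  t * t * (3 - 2 * t)
}

# Stamp one axon into the pixel matrix. `type` is "normal" or "abnormal".
# Continuous centre (row, col); pixel (i, j) has centre (i - 0.5, j - 0.5).
render_axon <- function(px, row, col, r_in, r_out, type, damage, contrast) {
  H <- nrow(px); W <- ncol(px)
  i0 <- max(1L, floor(row - r_out - 1)); i1 <- min(H, ceiling(row + r_out + 2))
  j0 <- max(1L, floor(col - r_out - 1)); j1 <- min(W, ceiling(col + r_out + 2))
  if (i0 > i1 || j0 > j1) return(px)
  dy <- (i0:i1) - 0.5 - row
  dx <- (j0:j1) - 0.5 - col
  d <- sqrt(outer(dy^2, dx^2, `+`))
  theta <- atan2(outer(dy, rep(1, length(dx))), outer(rep(1, length(dy)), dx))
  # radial wobble: damaged axons lose circularity
  k <- sample(2:5, 1)
  phi <- runif(1, 0, 2 * pi)
  wobble <- 1 + 0.25 * damage * sin(k * theta + phi)
  rin_eff <- r_in * wobble
  rout_eff <- r_out * wobble
  e <- 0.8  # edge softness, px
  core <- smoothstep((rin_eff - d) / e)
  ring <- smoothstep((d - rin_eff) / e) * smoothstep((rout_eff - d) / e)
  amp <- contrast * runif(1, 0.75, 1.25)
  if (type == "normal") {
    # myelin discontinuity appears with probability ~ damage
    if (damage > 0 && runif(1) < damage) {
      g0 <- runif(1, -pi, pi)
      gw <- runif(1, 0.3, 0.5 + damage)
      ring <- ring * (1 - in_arc(theta, g0, gw))
    }
    patch <- amp * (0.25 * core - 0.35 * ring)
  } else {
    # collapsed dark core, heavily broken ring — drawn, never annotated
    g0 <- runif(1, -pi, pi)
    gw <- runif(1, 1, 2.5)
    ring <- ring * (1 - in_arc(theta, g0, gw))
    patch <- amp * (-0.2 * core - 0.2 * ring)
  }
  px[i0:i1, j0:j1] <- px[i0:i1, j0:j1] + patch
  px
}

in_arc <- function(theta, start, width) {
  a <- (theta - start) %% (2 * pi)
  (a < width) * 1
}

#' Generate one synthetic optic-nerve sub-image with known axon locations
#'
#' Draws a Poisson number of countable "normal" axons (light core, dark
#' myelin annulus) placed so that each satisfies the border counting rule:
#' axons fully inside the frame are counted, axons crossing the top or left
#' border are counted when more than half of their area lies inside, and
#' axons touching the right or bottom border are never counted. Additional
#' border-excluded axons and, at `damage_level > 0`, "abnormal" distractor
#' axons are rendered but never listed in the ground truth.
#'
#' @param config A [synthetic_nerve_config()].
#' @param nerve_id Identifier of the synthetic nerve (animal) this image
#'   belongs to; subsets are partitioned at nerve level.
#' @return An object of class `synthetic_image`: a list with `pixels` (an
#'   `H x W` matrix of gray values in `[0, 1]`), `true_points` (integer
#'   matrix with columns `row`, `col`, 1-based pixel coordinates of counted
#'   axon centres), `nerve_id`, and the generating `config`.
#' @examples
#' img <- generate_axon_image(synthetic_nerve_config(axon_density = 20))
#' nrow(img$true_points)
#' @export
generate_axon_image <- function(config, nerve_id = "nerve_1") {
  stop_if_not(inherits(config, "synthetic_nerve_config"),
              "config must be a synthetic_nerve_config")
  with_seed(config$seed, {
    H <- W <- config$image_size_px
    dmg <- config$damage_level
    px <- matrix(rnorm(H * W, config$background_mean,
                       config$background_noise_sd), H, W)
    # gentle illumination/staining gradient
    th <- runif(1, 0, 2 * pi)
    px <- px + 0.03 * outer((seq_len(H) / H - 0.5) * sin(th),
                            rep(1, W)) +
      0.03 * outer(rep(1, H), (seq_len(W) / W - 0.5) * cos(th))

    rbar <- mean(config$radius_range_px) + config$myelin_width_px
    placed <- matrix(numeric(0), 0, 3)  # row, col, r_out of accepted axons
    draw_radius <- function() {
      r_in <- runif(1, config$radius_range_px[1], config$radius_range_px[2])
      c(r_in, r_in + config$myelin_width_px)
    }
    overlaps <- function(row, col, r_out) {
      if (nrow(placed) == 0) return(FALSE)
      dd <- sqrt((placed[, 1] - row)^2 + (placed[, 2] - col)^2)
      any(dd < 0.8 * (placed[, 3] + r_out))
    }

    true_points <- matrix(integer(0), 0, 2,
                          dimnames = list(NULL, c("row", "col")))
    n_counted <- rpois(1, config$axon_density)
    for (a in seq_len(n_counted)) {
      rr <- draw_radius()
      for (try in 1:300) {
        row <- runif(1, -rr[2], H + rr[2])
        col <- runif(1, -rr[2], W + rr[2])
        if (axon_is_counted(row, col, rr[2], H, W) &&
            !overlaps(row, col, rr[2])) break
      }
      placed <- rbind(placed, c(row, col, rr[2]))
      px <- render_axon(px, row, col, rr[1], rr[2], "normal", dmg,
                        config$contrast_scale)
      pt <- clamp(ceiling(c(row, col)), 1, c(H, W))
      true_points <- rbind(true_points, as.integer(pt))
    }

    # axons visible at the right/bottom borders (or <=50% inside at top/left):
    # rendered for realism, excluded by the counting rule
    n_border <- rpois(1, config$axon_density * 2.5 * rbar * (H + W) / (H * W))
    for (a in seq_len(n_border)) {
      rr <- draw_radius()
      for (try in 1:300) {
        row <- runif(1, -rr[2], H + rr[2])
        col <- runif(1, -rr[2], W + rr[2])
        visible <- disk_inside_fraction(row, col, rr[2], H, W) > 0
        if (visible && !axon_is_counted(row, col, rr[2], H, W) &&
            !overlaps(row, col, rr[2])) break
      }
      placed <- rbind(placed, c(row, col, rr[2]))
      px <- render_axon(px, row, col, rr[1], rr[2], "normal", dmg,
                        config$contrast_scale)
    }

    # abnormal distractors in damaged nerves, never annotated
    n_abn <- rpois(1, config$axon_density * 0.5 * dmg)
    for (a in seq_len(n_abn)) {
      rr <- draw_radius()
      for (try in 1:300) {
        row <- runif(1, 0, H)
        col <- runif(1, 0, W)
        if (!overlaps(row, col, rr[2])) break
      }
      placed <- rbind(placed, c(row, col, rr[2]))
      px <- render_axon(px, row, col, rr[1], rr[2], "abnormal", max(dmg, 0.5),
                        config$contrast_scale)
    }

    colnames(true_points) <- c("row", "col")
    structure(list(pixels = clamp(px, 0, 1),
                   true_points = true_points,
                   nerve_id = nerve_id,
                   config = config),
              class = "synthetic_image")
  })
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat(sprintf("synthetic optic-nerve image %dx%d px, %d counted axons (%s)\n",
              nrow(x$pixels), ncol(x$pixels), nrow(x$true_points),
              x$nerve_id))
  invisible(x)
}

#' Simulate independent manual counters annotating one image
#'
#' Each simulated counter independently misses some true axons, adds some
#' spurious annotations, and displaces retained points by a small jitter —
#' the error structure of trained human counters marking one point per axon.
#' Counter strictness varies: counter `k`'s miss probability is drawn as
#' `N(miss_rate, counter_sd)` truncated to `[0, 0.95]`, so some counters are
#' systematically more conservative than others on a given image. The default
#' `counter_sd = 2 * miss_rate` calibrates the simulated panel so that, at
#' the default generator settings, the median per-image coefficient of
#' variation of four counters' counts is close to the 0.12 observed between
#' trained human counters on rat optic nerve sub-images; with
#' `miss_rate = 0` all noise sources vanish and every counter reproduces the
#' ground truth exactly.
#'
#' @param image A `synthetic_image`.
#' @param n_counters Number of independent counters (the reference datasets
#'   used 4, or 2 counting by consensus).
#' @param miss_rate Mean probability that a counter overlooks a true axon.
#' @param spurious_rate Expected spurious annotations per true axon.
#' @param jitter_px Standard deviation (pixels) of the annotation placement
#'   error.
#' @param counter_sd Between-counter SD of the miss probability; defaults to
#'   `2 * miss_rate`.
#' @param seed Optional integer seed.
#' @return A list of `annotation_set` objects, one per counter, each with
#'   `counter_id`, `points` (integer matrix, columns `row`, `col`, 1-based),
#'   and `image_shape`.
#' @export
simulate_counters <- function(image, n_counters, miss_rate = 0.08,
                              spurious_rate = 0.05, jitter_px = 1,
                              counter_sd = 2 * miss_rate, seed = NULL) {
  stop_if_not(inherits(image, "synthetic_image"), "image must be synthetic")
  stop_if_not(is_count(n_counters) && n_counters >= 1,
              "n_counters must be a positive integer")
  stop_if_not(miss_rate >= 0 && miss_rate < 1, "miss_rate must be in [0, 1)")
  stop_if_not(spurious_rate >= 0, "spurious_rate must be nonnegative")
  stop_if_not(jitter_px >= 0, "jitter_px must be nonnegative")
  H <- nrow(image$pixels); W <- ncol(image$pixels)
  pts <- image$true_points
  with_seed(seed, {
    lapply(seq_len(n_counters), function(k) {
      p_miss <- clamp(rnorm(1, miss_rate, counter_sd), 0, 0.95)
      keep <- if (nrow(pts) > 0) runif(nrow(pts)) >= p_miss else logical(0)
      kept <- pts[keep, , drop = FALSE]
      if (jitter_px > 0 && nrow(kept) > 0) {
        kept <- round(kept + matrix(rnorm(2 * nrow(kept), 0, jitter_px),
                                    ncol = 2))
        kept[, 1] <- clamp(kept[, 1], 1, H)
        kept[, 2] <- clamp(kept[, 2], 1, W)
      }
      n_sp <- if (spurious_rate > 0) rpois(1, spurious_rate * nrow(pts)) else 0
      if (n_sp > 0) {
        sp <- cbind(sample.int(H, n_sp, replace = TRUE),
                    sample.int(W, n_sp, replace = TRUE))
        kept <- rbind(kept, sp)
      }
      kept <- unique(kept)  # at most one point per pixel per counter
      storage.mode(kept) <- "integer"
      colnames(kept) <- c("row", "col")
      annotation_set(paste0("counter_", k), kept, c(H, W))
    })
  })
}

#' Generate a nerve-partitioned synthetic dataset
#'
#' Builds `n_nerves * images_per_nerve` annotated synthetic sub-images and
#' assigns whole nerves — never individual images — to the training,
#' validation, and testing subsets, so that no synthetic animal contributes
#' images to more than one subset. Each nerve receives its own health state:
#' an expected axon density drawn uniformly from `density_range` and a damage
#' level drawn from `damage_range`, giving the across-image count spread a
#' counting tool must handle.
#'
#' @param n_nerves Number of synthetic nerves (>= 5).
#' @param images_per_nerve Sub-images sampled per nerve.
#' @param split Length-3 fractions (train, validation, test) summing to 1.
#'   Nerves are apportioned by largest-remainder rounding.
#' @param config Template [synthetic_nerve_config()]; per-image seeds,
#'   densities and damage levels are drawn from it.
#' @param n_counters Simulated manual counters per image.
#' @param density_range Length-2 range of per-nerve expected axon density;
#'   default `c(0.25, 1.75) * config$axon_density`.
#' @param damage_range Length-2 range of per-nerve damage level; default
#'   `c(config$damage_level, config$damage_level)`.
#' @param miss_rate,spurious_rate,jitter_px Passed to [simulate_counters()].
#' @param seed Integer seed for the whole dataset.
#' @return An object of class `axon_dataset`: `images` (list of records with
#'   `id`, `image`, `annotations`, `nerve_id`, `subset`) and a `manifest`
#'   data frame.
#' @export
generate_dataset <- function(n_nerves, images_per_nerve,
                             split = c(0.6, 0.2, 0.2),
                             config = synthetic_nerve_config(),
                             n_counters = 4,
                             density_range = NULL,
                             damage_range = NULL,
                             miss_rate = 0.08, spurious_rate = 0.05,
                             jitter_px = 1,
                             seed = 1L) {
  stop_if_not(is_count(n_nerves) && n_nerves >= 5, "n_nerves must be >= 5")
  stop_if_not(is_count(images_per_nerve) && images_per_nerve >= 1,
              "images_per_nerve must be a positive integer")
  stop_if_not(length(split) == 3 && all(split >= 0) &&
                abs(sum(split) - 1) < 1e-8,
              "split must be three nonnegative fractions summing to 1")
  if (is.null(density_range)) {
    density_range <- c(0.25, 1.75) * config$axon_density
  }
  if (is.null(damage_range)) {
    damage_range <- rep(config$damage_level, 2)
  }
  subsets <- c("train", "val", "test")
  with_seed(seed, {
    # largest-remainder apportionment of nerves to subsets
    raw <- split * n_nerves
    n_sub <- floor(raw)
    rem <- n_nerves - sum(n_sub)
    if (rem > 0) {
      order_frac <- order(raw - n_sub, decreasing = TRUE)
      n_sub[order_frac[seq_len(rem)]] <- n_sub[order_frac[seq_len(rem)]] + 1
    }
    nerve_subset <- rep(subsets, times = n_sub)[sample.int(n_nerves)]
    records <- list()
    for (nv in seq_len(n_nerves)) {
      nerve_id <- sprintf("nerve_%02d", nv)
      dens <- runif(1, density_range[1], density_range[2])
      dmg <- runif(1, damage_range[1], damage_range[2])
      for (im in seq_len(images_per_nerve)) {
        cfg <- config
        # sub-images sample different regions of the cross section, whose
        # local axon density varies around the nerve's overall health level
        cfg$axon_density <- dens * runif(1, 0.5, 1.5)
        cfg$damage_level <- dmg
        cfg$seed <- sample.int(.Machine$integer.max, 1)
        img <- generate_axon_image(cfg, nerve_id = nerve_id)
        ann <- simulate_counters(img, n_counters, miss_rate = miss_rate,
                                 spurious_rate = spurious_rate,
                                 jitter_px = jitter_px,
                                 seed = sample.int(.Machine$integer.max, 1))
        records[[length(records) + 1]] <- list(
          id = sprintf("%s_img_%03d", nerve_id, im),
          image = img,
          annotations = ann,
          nerve_id = nerve_id,
          subset = nerve_subset[nv])
      }
    }
    manifest <- data.frame(
      image_id = vapply(records, `[[`, "", "id"),
      nerve_id = vapply(records, `[[`, "", "nerve_id"),
      subset = vapply(records, `[[`, "", "subset"),
      stringsAsFactors = FALSE)
    structure(list(images = records, manifest = manifest),
              class = "axon_dataset")
  })
}

#' @export
print.axon_dataset <- function(x, ...) {
  tab <- table(x$manifest$subset)
  cat(sprintf("axon_dataset: %d images, %d nerves (%s)\n",
              nrow(x$manifest), length(unique(x$manifest$nerve_id)),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Extract the records of one dataset subset
#'
#' @param dataset An `axon_dataset`.
#' @param subset One of `"train"`, `"val"`, `"test"`.
#' @return List of image records.
#' @export
dataset_subset <- function(dataset, subset = c("train", "val", "test")) {
  subset <- match.arg(subset)
  Filter(function(r) r$subset == subset, dataset$images)
}

#' Mean manual count across an image's counters
#'
#' @param annotations List of `annotation_set`s for one image.
#' @return The mean of the per-counter point counts.
#' @export
mean_manual_count <- function(annotations) {
  mean(vapply(annotations, function(a) nrow(a$points), numeric(1)))
}
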