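# TIFF and CSV interchange. Annotation CSVs use the header counter_id,x,y
# with 0-based pixel coordinates, x = column and y = row; in-memory points
# are 1-based (row, col) matrices, the natural R indexing.

#' Write a grayscale image as single-channel TIFF
#'
#' @param image Matrix with values in `[0, 1]`.
#' @param path Output file.
#' @param bits 8 or 16 bits per sample.
#' @export
write_image_tiff <- function(image, path, bits = 8) {
  stop_if_not(bits %in% c(8, 16), "bits must be 8 or 16")
  tiff::writeTIFF(clamp(image, 0, 1), path, bits.per.sample = bits)
  invisible(path)
}

#' Read a grayscale TIFF as a matrix
#'
#' Multi-channel images are averaged to one channel.
#'
#' @param path TIFF file.
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
read_image_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- apply(x, c(1, 2), mean)
  x
}

#' Write a density map as 32-bit floating-point TIFF
#'
#' @param density Numeric matrix (count per pixel; values may exceed 1 on
#'   the `m`-scaled training scale, they are written unclamped).
#' @param path Output file.
#' @export
write_density_tiff <- function(density, path) {
  tiff::writeTIFF(density, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' Write per-counter annotations to CSV
#'
#' One row per point with header `counter_id,x,y`; coordinates are 0-based,
#' `x` the column and `y` the row.
#'
#' @param annotations List of [annotation_set()]s.
#' @param path Output file.
#' @export
write_annotations_csv <- function(annotations, path) {
  rows <- do.call(rbind, lapply(annotations, function(a) {
    if (nrow(a$points) == 0) return(NULL)
    data.frame(counter_id = a$counter_id,
               x = a$points[, "col"] - 1L,
               y = a$points[, "row"] - 1L)
  }))
  if (is.null(rows)) {
    rows <- data.frame(counter_id = character(0), x = integer(0),
                       y = integer(0))
  }
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read per-counter annotations from CSV
#'
#' Reads the `counter_id,x,y` interchange format. `origin = "zero"` is the
#' package's own convention; use `origin = "one"` for 1-based exports (e.g.
#' Fiji Cell Counter point lists), which are shifted by -1 on import.
#'
#' @param path CSV file.
#' @param image_shape Integer `(H, W)` the points belong to.
#' @param origin `"zero"` (default) or `"one"`.
#' @return List of `annotation_set`s, one per counter in the file.
#' @export
read_annotations_csv <- function(path, image_shape,
                                 origin = c("zero", "one")) {
  origin <- match.arg(origin)
  df <- read.csv(path, stringsAsFactors = FALSE)
  stop_if_not(all(c("counter_id", "x", "y") %in% names(df)),
              "CSV must have columns counter_id, x, y")
  off <- if (origin == "zero") 1L else 0L
  lapply(split(df, df$counter_id), function(d) {
    annotation_set(d$counter_id[1],
                   cbind(row = d$y + off, col = d$x + off),
                   image_shape)
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes each image as TIFF under `images/`, its annotations as CSV under
#' `annotations/`, and a `manifest.csv` mapping image file to nerve and
#' subset.
#'
#' @param dataset An `axon_dataset`.
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "annotations"), recursive = TRUE,
             showWarnings = FALSE)
  for (r in dataset$images) {
    write_image_tiff(r$image$pixels,
                     file.path(dir, "images", paste0(r$id, ".tif")))
    write_annotations_csv(r$annotations,
                          file.path(dir, "annotations",
                                    paste0(r$id, ".csv")))
  }
  manifest <- dataset$manifest
  manifest$image_file <- file.path("images", paste0(manifest$image_id,
                                                    ".tif"))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
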