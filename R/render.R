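# Rasterisation of stimulus specifications.

#' Render one stimulus
#'
#' Draws the patches of a manifest row onto a white canvas. Rendering is a
#' pure function of the row's seed and the dataset metadata: the same row
#' always yields the identical raster.
#'
#' @param row A single manifest row (one-row tibble).
#' @param meta Dataset metadata; defaults to the metadata attached to a
#'   manifest, so usually only `row` is needed when slicing a manifest.
#' @param size Optional output side length; when given, the canvas raster is
#'   resampled (nearest neighbour) to `size` x `size`.
#' @return A numeric array `H x W x 3` with values in `[0, 1]`.
#' @examples
#' m <- generate_dataset("exp4", "a", n_train = 5, n_test_per_condition = 5, seed = 1)
#' img <- render_stimulus(m[1, ], size = 64)
#' dim(img)
#' @export
render_stimulus <- function(row, meta = attr(row, "sb_meta"), size = NULL) {
  if (is.null(meta)) stop("no dataset metadata: pass `meta` or slice a manifest with dplyr")
  config <- meta$config
  geom <- stimulus_geometry(row, meta)
  canvas <- as.integer(round(config$canvas))
  pal <- rbind(meta$palette$colours, meta$palette$background) / 255
  img <- array(1, dim = c(canvas, canvas, 3))
  p <- geom$patches
  half <- p$size / 2
  r1 <- pmax(1L, as.integer(round(p$y - half)))
  r2 <- pmin(canvas, pmax(r1, as.integer(round(p$y + half)) - 1L))
  c1 <- pmax(1L, as.integer(round(p$x - half)))
  c2 <- pmin(canvas, pmax(c1, as.integer(round(p$x + half)) - 1L))
  for (i in seq_len(nrow(p))) {
    col <- pal[p$colour[i], ]
    img[r1[i]:r2[i], c1[i]:c2[i], 1] <- col[1]
    img[r1[i]:r2[i], c1[i]:c2[i], 2] <- col[2]
    img[r1[i]:r2[i], c1[i]:c2[i], 3] <- col[3]
  }
  if (!is.null(size) && size != canvas) img <- resample_nearest(img, size)
  img
}

# Nearest-neighbour resampling to a square target.
resample_nearest <- function(img, size) {
  n <- dim(img)[1]
  idx <- pmin(n, pmax(1L, as.integer(ceiling((seq_len(size) - 0.5) * n / size))))
  img[idx, idx, , drop = FALSE]
}

#' Render a whole manifest
#'
#' @param manifest A manifest tibble (or subset of one, with metadata passed
#'   explicitly).
#' @param size Output side length (default the config's `target`).
#' @param meta Dataset metadata.
#' @return A numeric array `size x size x 3 x nrow(manifest)`.
#' @export
render_dataset <- function(manifest, size = NULL, meta = manifest_meta(manifest)) {
  if (is.null(size)) size <- meta$config$target
  n <- nrow(manifest)
  out <- array(0, dim = c(size, size, 3, n))
  for (i in seq_len(n)) out[, , , i] <- render_stimulus(manifest[i, ], meta, size = size)
  out
}

#' Write manifest images as PNG files
#'
#' Renders every row at the configured canvas size and writes 8-bit RGB PNG
#' files `img_00001.png`, ... under `dir`, returning the manifest with the
#' `image` column filled in.
#'
#' @param manifest A manifest tibble.
#' @param dir Output directory (created if needed).
#' @param size Optional output side length (default: canvas size).
#' @return The manifest with `image` paths, invisibly.
#' @export
write_images <- function(manifest, dir, size = NULL) {
  meta <- manifest_meta(manifest)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("img_%05d.png", seq_len(nrow(manifest))))
  for (i in seq_len(nrow(manifest)))
    png::writePNG(render_stimulus(manifest[i, ], meta, size = size), paths[i])
  manifest$image <- paths
  attr(manifest, "sb_meta") <- meta
  invisible(manifest)
}
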