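# Per-image geometry: patch counts, positions, sizes and colours, sampled
# deterministically from the row seed. The renderer and the patch-count
# accessors both derive from this single source of truth.

parse_diag <- function(diag_json) {
  jsonlite::fromJSON(diag_json, simplifyVector = TRUE)
}

# Geometry for one manifest row. Returns a list with `patches` (tibble:
# x, y (canvas px, y downwards), size, colour) and `n_patches`.
stimulus_geometry <- function(row, meta) {
  info <- experiment_info(row$experiment)
  config <- meta$config
  diag <- parse_diag(row$diag_json)
  with_seed(mix_seed(row$seed, 22), {
    has_diag_patch <- info$feature == "patch" && !is.null(diag$loc)
    n_short <- sample(SEG_SHORT_MIN:SEG_SHORT_MAX, 4, replace = TRUE)
    # the free-standing diagnostic patch counts towards the 30-55 budget
    long_max <- if (has_diag_patch) SEG_LONG_MAX - 1L else SEG_LONG_MAX
    n_long <- sample(SEG_LONG_MIN:long_max, 1)
    counts <- c(n_long, n_short) # segment 1 is the long one in templates

    pitch <- config$pitch
    size_nom <- if (info$feature == "size") config$size_levels[diag$level]
                else config$patch_size

    centres <- segment_patch_centres(row, meta, counts, pitch)

    n_fig <- nrow(centres)
    jit <- config$jitter
    x <- centres[, 1] + stats::runif(n_fig, -jit, jit) * pitch
    y <- centres[, 2] + stats::runif(n_fig, -jit, jit) * pitch
    sizes <- size_nom * stats::runif(n_fig, 1 - jit, 1 + jit)

    colours <- switch(info$feature,
      patch = sample_int(nondiag_colours(), n_fig, replace = TRUE),
      size = sample_int(nondiag_colours(), n_fig, replace = TRUE),
      segment = rep(diag$seg_colours, counts),
      colour = rep(diag$colour, n_fig))

    patches <- tibble::tibble(x = x, y = y, size = sizes, colour = as.integer(colours))
    if (has_diag_patch) {
      loc <- diag_locations(config)[diag$loc, ]
      dsize <- config$patch_size * stats::runif(1, 1 - jit, 1 + jit)
      patches <- dplyr::bind_rows(patches, tibble::tibble(
        x = loc[["x"]], y = loc[["y"]], size = dsize, colour = as.integer(diag$colour)))
    }
    list(patches = patches, n_patches = nrow(patches),
         segment_counts = counts)
  })
}

# Unjittered patch centres for the five segments: either the category's
# template (rotated by a random quarter-turn and translated to a random
# admissible canvas position) or, for images without a coherent shape, five
# independently scattered segments.
segment_patch_centres <- function(row, meta, counts, pitch) {
  config <- meta$config
  m <- config$margin
  canvas <- config$canvas
  if (!is.na(row$shape_id)) {
    tpl <- meta$templates[[row$shape_id]]
    seg <- tpl$segments
    # long first to match `counts`
    seg <- seg[order(seg$role != "long"), ]
    cells <- do.call(rbind, lapply(seq_len(5), function(i)
      segment_cells(seg$anchor_x[i], seg$anchor_y[i], seg$orientation[i], counts[i])))
    ang <- sample_int(config$orientations)
    xy <- cbind(cells[, 1] * cos(ang) - cells[, 2] * sin(ang),
                cells[, 1] * sin(ang) + cells[, 2] * cos(ang))
    xy[, 1] <- xy[, 1] - min(xy[, 1])
    xy[, 2] <- xy[, 2] - min(xy[, 2])
    pts <- xy * pitch
    ext <- c(max(pts[, 1]), max(pts[, 2]))
    lo <- m
    hi <- canvas - m - ext
    if (any(hi < lo))
      stop("figure exceeds canvas: extent ", paste(round(ext), collapse = "x"),
           " does not fit within margins")
    off <- c(stats::runif(1, lo, hi[1]), stats::runif(1, lo, hi[2]))
    cbind(pts[, 1] + off[1], pts[, 2] + off[2])
  } else {
    # scrambled: place each segment at a random admissible location
    do.call(rbind, lapply(seq_len(5), function(i) {
      len <- counts[i]
      ori <- sample_int(c("h", "v"))
      span <- (len - 1) * pitch
      if (canvas - 2 * m - span < 0)
        stop("segment exceeds canvas: reduce pitch or margin")
      x0 <- stats::runif(1, m, canvas - m - (if (ori == "h") span else 0))
      y0 <- stats::runif(1, m, canvas - m - (if (ori == "v") span else 0))
      d <- (seq_len(len) - 1) * pitch
      if (ori == "h") cbind(x0 + d, y0) else cbind(x0, y0 + d)
    }))
  }
}

#' Patch counts of manifest rows
#'
#' Total number of coloured patches each image realises (segments plus, for
#' the patch experiments, the free-standing diagnostic patch), computed from
#' the symbolic geometry without rendering.
#'
#' @param manifest A manifest tibble.
#' @return An integer vector, one count per row.
#' @export
patch_counts <- function(manifest) {
  meta <- manifest_meta(manifest)
  vapply(seq_len(nrow(manifest)), function(i)
    stimulus_geometry(manifest[i, ], meta)$n_patches, integer(1))
}
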