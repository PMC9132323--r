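# Shape templates: the five category-defining spatial configurations of
# segments. A template places 5 segments (4 short + 1 long) on a coarse cell
# grid; patches are later laid along each segment at one cell per patch.
# Shapes are built connected (every segment starts next to a cell that is
# always occupied, whatever patch counts are drawn) and are pairwise
# non-congruent under quarter-turn rotations.

SEG_SHORT_MIN <- 5L
SEG_SHORT_MAX <- 10L
SEG_LONG_MIN <- 10L
SEG_LONG_MAX <- 15L

segment_cells <- function(ax, ay, orientation, len) {
  if (orientation == "h") cbind(ax + 0:(len - 1), ay) else cbind(ax, ay + 0:(len - 1))
}

# Canonical serialisation of a cell set under the 4 quarter-turn rotations.
canonical_cells <- function(cells) {
  keys <- vapply(0:3, function(r) {
    xy <- cells
    for (i in seq_len(r)) xy <- cbind(xy[, 2], -xy[, 1])
    xy[, 1] <- xy[, 1] - min(xy[, 1])
    xy[, 2] <- xy[, 2] - min(xy[, 2])
    paste(xy[order(xy[, 1], xy[, 2]), ], collapse = ",")
  }, character(1))
  min(keys)
}

#' Generate the five category shape templates
#'
#' Draws five pairwise non-congruent connected arrangements of four short and
#' one long segment on a cell grid. Each category keeps one template for the
#' whole dataset; the spatial configuration of its segments *is* the
#' category's shape feature.
#'
#' @param seed Integer seed; the same seed always returns identical templates.
#' @param n_categories Number of categories (default 5).
#' @param grid Side length of the cell grid the segments are placed on.
#' @return A list of `n_categories` templates. Each template is a list with
#'   `category_id` and `segments`, a tibble with columns `segment`, `role`
#'   (`"long"` or `"short"`), `anchor_x`, `anchor_y` and `orientation`
#'   (`"h"` or `"v"`).
#' @examples
#' tpl <- make_templates(seed = 0)
#' tpl[[1]]$segments
#' @export
make_templates <- function(seed, n_categories = 5, grid = 20L) {
  with_seed(mix_seed(seed, 7001), {
    templates <- list()
    keys <- character(0)
    guard <- 0L
    while (length(templates) < n_categories) {
      guard <- guard + 1L
      if (guard > 10000L) stop("template generation failed to converge")
      tpl <- propose_template(grid)
      if (is.null(tpl)) next
      key <- canonical_cells(template_cells(tpl, max_len = TRUE))
      if (key %in% keys) next
      tpl$category_id <- length(templates) + 1L
      templates[[length(templates) + 1L]] <- tpl
      keys <- c(keys, key)
    }
    templates
  })
}

# All cells a template can occupy (max_len = TRUE) or always occupies.
template_cells <- function(tpl, max_len = TRUE) {
  seg <- tpl$segments
  lens <- ifelse(seg$role == "long",
                 if (max_len) SEG_LONG_MAX else SEG_LONG_MIN,
                 if (max_len) SEG_SHORT_MAX else SEG_SHORT_MIN)
  do.call(rbind, lapply(seq_len(nrow(seg)), function(i)
    segment_cells(seg$anchor_x[i], seg$anchor_y[i], seg$orientation[i], lens[i])))
}

propose_template <- function(grid) {
  ori <- sample_int(c("h", "v"))
  span <- SEG_LONG_MAX
  ax <- if (ori == "h") sample.int(grid - span + 1L, 1L) else sample.int(grid, 1L)
  ay <- if (ori == "v") sample.int(grid - span + 1L, 1L) else sample.int(grid, 1L)
  seg <- tibble::tibble(segment = 1L, role = "long", anchor_x = ax, anchor_y = ay,
                        orientation = ori)
  occupied <- segment_cells(ax, ay, ori, SEG_LONG_MAX)
  guaranteed <- segment_cells(ax, ay, ori, SEG_LONG_MIN)
  for (s in 2:5) {
    placed <- FALSE
    for (try in 1:50) {
      base <- guaranteed[sample.int(nrow(guaranteed), 1L), ]
      step <- sample_int(list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))[[1]]
      ax <- unname(base[1] + step[1]); ay <- unname(base[2] + step[2])
      ori <- sample_int(c("h", "v"))
      cells <- segment_cells(ax, ay, ori, SEG_SHORT_MAX)
      inb <- all(cells >= 1L) && all(cells <= grid)
      clash <- any(paste(cells[, 1], cells[, 2]) %in% paste(occupied[, 1], occupied[, 2]))
      if (inb && !clash) {
        seg <- dplyr::bind_rows(seg, tibble::tibble(
          segment = s, role = "short", anchor_x = ax, anchor_y = ay, orientation = ori))
        occupied <- rbind(occupied, cells)
        guaranteed <- rbind(guaranteed, segment_cells(ax, ay, ori, SEG_SHORT_MIN))
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  list(category_id = NA_integer_, segments = seg)
}

templates_to_df <- function(templates) {
  dplyr::bind_rows(lapply(templates, function(t)
    dplyr::mutate(t$segments, category_id = t$category_id, .before = 1)))
}

templates_from_df <- function(df) {
  lapply(unname(split(df, df$category_id)), function(d)
    list(category_id = d$category_id[1],
         segments = tibble::as_tibble(d[, c("segment", "role", "anchor_x",
                                            "anchor_y", "orientation")])))
}
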