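# Dataset generation: symbolic stimulus specifications for training and the
# four test conditions, assembled into a manifest tibble.

#' Rendering configuration
#'
#' Geometry of the rendered stimuli. All lengths are in pixels on the canvas;
#' everything scales linearly with `canvas` so the same dataset can be
#' rendered at any resolution.
#'
#' @param canvas Canvas side length (default 600).
#' @param target Resampling target for classifier input (default 224).
#' @param pitch Nominal centre-to-centre spacing of patches in a segment.
#' @param patch_size Nominal patch side length (non-size experiments).
#' @param margin Exclusion border: figures are translated so that their
#'   bounding box stays at least this far from the canvas edge, keeping the
#'   absolute diagnostic patch locations (placed in the border zone) free.
#' @param jitter Relative jitter applied to patch positions (fraction of
#'   `pitch`) and patch sizes (fraction of the nominal size).
#' @param size_levels Nominal patch side per diagnostic size level; level 6 is
#'   the super-diagnostic level used only by Shape-condition test images of
#'   the size experiment. Consecutive levels are separated by more than the
#'   1.3/0.7 jitter ratio so the jittered supports never overlap.
#' @param orientations Global figure orientations in radians; the default is
#'   the four quarter-turns, which keep segments axis-aligned.
#' @return A list of class `sb_render_config`.
#' @export
render_config <- function(canvas = 600, target = 224, pitch = 24 * canvas / 600,
                          patch_size = 16 * canvas / 600, margin = 64 * canvas / 600,
                          jitter = 0.3,
                          size_levels = c(2, 3.8, 7.1, 13.2, 24.5, 45.5) * canvas / 600,
                          orientations = c(0, pi / 2, pi, 3 * pi / 2)) {
  structure(list(canvas = canvas, target = target, pitch = pitch,
                 patch_size = patch_size, margin = margin, jitter = jitter,
                 size_levels = size_levels, orientations = orientations),
            class = "sb_render_config")
}

# Absolute canvas positions of the five diagnostic patch locations (exp1).
diag_locations <- function(config) {
  fx <- c(0.05, 0.95, 0.05, 0.95, 0.50)
  fy <- c(0.05, 0.05, 0.95, 0.95, 0.95)
  cbind(x = fx * config$canvas, y = fy * config$canvas)
}

# Diagnostic feature values carried by one image, as a JSON string.
# `category` is the category whose non-shape feature the image carries
# (NA for Shape-condition images, which carry a non-diagnostic value).
sample_diag_json <- function(feature, category, seed) {
  with_seed(mix_seed(seed, 11), {
    switch(feature,
      patch = if (is.na(category)) '{"loc":null,"colour":null}'
              else sprintf('{"loc":%d,"colour":%d}', category, category),
      segment = {
        if (is.na(category)) {
          sprintf('{"seg_colours":[%s],"diag_segment":null}',
                  paste(sample_int(nondiag_colours(), 5), collapse = ","))
        } else {
          idx <- sample.int(5L, 1L)
          cols <- integer(5)
          cols[idx] <- category
          cols[-idx] <- sample_int(nondiag_colours(), 4)
          sprintf('{"seg_colours":[%s],"diag_segment":%d}',
                  paste(cols, collapse = ","), idx)
        }
      },
      size = sprintf('{"level":%d}', if (is.na(category)) 6L else category),
      colour = sprintf('{"colour":%d}',
                       if (is.na(category)) sample_int(nondiag_colours())
                       else as.integer(category)),
      stop("unknown feature type: ", feature))
  })
}

spec_row <- function(experiment, variant, condition, label, shape_id,
                     nonshape_category, seed, feature) {
  diag_cat <- if (condition == "shape") NA_integer_ else nonshape_category
  tibble::tibble(
    image = NA_character_,
    experiment = experiment, variant = variant, condition = condition,
    label = as.integer(label), shape_id = as.integer(shape_id),
    nonshape_category = as.integer(nonshape_category),
    diag_json = sample_diag_json(feature, diag_cat, seed),
    seed = as.integer(seed))
}

#' Sample one training stimulus specification
#'
#' Training images always carry the label's non-shape feature; the shape of
#' the label is present with probability `shape_prob` (1 for variant `a`,
#' 0.8 for variant `b`, 0 for `noshape`), and images without a shape show the
#' same segments scattered at random canvas locations.
#'
#' @param experiment,variant Experiment id and variant.
#' @param label Category label in 1..5.
#' @param shape_prob Probability that the image carries the label's shape.
#' @param seed Integer seed for this row.
#' @return A one-row spec tibble.
#' @export
sample_training_spec <- function(experiment, variant, label, shape_prob = shape_prob_for(variant),
                                 seed = 0L) {
  info <- experiment_info(experiment)
  stopifnot(variant %in% info$variants)
  if (!is.numeric(label) || length(label) != 1 || !label %in% 1:5)
    stop("label must be a single integer in 1..5")
  if (shape_prob < 0 || shape_prob > 1) stop("shape_prob must be in [0, 1]")
  has_shape <- variant != "noshape" &&
    with_seed(mix_seed(seed, 31), stats::runif(1) < shape_prob)
  spec_row(experiment, variant, "train", label,
           shape_id = if (has_shape) label else NA_integer_,
           nonshape_category = label, seed = seed, feature = info$feature)
}

#' Sample one test stimulus specification
#'
#' Both: shape and non-shape feature of the label. Conflict: shape of the
#' label, non-shape feature of the fixed derangement partner
#' `(label mod 5) + 1`; the scored label is the shape category. Shape: shape
#' of the label with a non-diagnostic non-shape channel. Non-shape: no
#' coherent shape, non-shape feature of the label.
#'
#' @inheritParams sample_training_spec
#' @param condition One of `"both"`, `"conflict"`, `"shape"`, `"nonshape"`.
#' @return A one-row spec tibble.
#' @export
sample_test_spec <- function(experiment, condition, label, seed = 0L) {
  info <- experiment_info(experiment)
  condition <- match.arg(condition, TEST_CONDITIONS)
  if (!condition %in% info$conditions)
    stop("condition '", condition, "' is not defined for ", experiment)
  if (!is.numeric(label) || length(label) != 1 || !label %in% 1:5)
    stop("label must be a single integer in 1..5")
  variant <- if (info$has_shape) "a" else "noshape"
  switch(condition,
    both = spec_row(experiment, variant, condition, label, label, label,
                    seed, info$feature),
    conflict = spec_row(experiment, variant, condition, label, label,
                        conflict_partner(label), seed, info$feature),
    shape = spec_row(experiment, variant, condition, label, label,
                     NA_integer_, seed, info$feature),
    nonshape = spec_row(experiment, variant, condition, label, NA_integer_,
                        label, seed, info$feature))
}

#' Generate a stimulus dataset
#'
#' Builds the full symbolic manifest for one experiment/variant: `n_train`
#' training rows (balanced over the five categories, with the realised
#' shape-bearing fraction stratified to equal the variant's predictiveness
#' exactly within each category) and `n_test_per_condition` rows for each
#' admissible test condition. Rendering is a separate step
#' ([render_stimulus()], [render_dataset()]); the manifest itself is purely
#' symbolic, which keeps ideal-observer runs fast.
#'
#' @inheritParams sample_training_spec
#' @param n_train Number of training rows (divisible by 5; default 2000).
#' @param n_test_per_condition Test rows per condition (divisible by 5;
#'   default 500).
#' @param seed Dataset seed. Every row derives an independent substream from
#'   it, so identical arguments give byte-identical manifests and any subset
#'   re-renders identically.
#' @param config Render configuration (stored in the manifest metadata).
#' @return A tibble with columns `image`, `experiment`, `variant`,
#'   `condition`, `label`, `shape_id`, `nonshape_category`, `diag_json`,
#'   `seed`, carrying dataset metadata (palette, templates, seed, config) in
#'   attribute `sb_meta`.
#' @examples
#' m <- generate_dataset("exp3", "a", n_train = 50, n_test_per_condition = 10, seed = 1)
#' dplyr::count(m, condition)
#' @export
generate_dataset <- function(experiment, variant, n_train = 2000,
                             n_test_per_condition = 500, seed = 1,
                             config = render_config()) {
  info <- experiment_info(experiment)
  variant <- match.arg(variant, info$variants)
  if (n_train %% 5 != 0 || n_test_per_condition %% 5 != 0)
    stop("n_train and n_test_per_condition must be divisible by 5")
  shape_prob <- shape_prob_for(variant)
  per_class <- n_train / 5

  # training split: exact stratification of the shape-bearing fraction
  n_shape <- round(shape_prob * per_class)
  lab <- rep(1:5, each = per_class)
  has_shape <- rep(c(rep(TRUE, n_shape), rep(FALSE, per_class - n_shape)), 5)
  seeds <- mapply(function(l, i) mix_seed(seed, 1L, l, i), lab,
                  rep(seq_len(per_class), 5))
  train <- tibble::tibble(
    image = NA_character_, experiment = experiment, variant = variant,
    condition = "train", label = as.integer(lab),
    shape_id = ifelse(has_shape, lab, NA_integer_),
    nonshape_category = as.integer(lab),
    diag_json = vapply(seq_along(lab), function(i)
      sample_diag_json(info$feature, lab[i], seeds[i]), character(1)),
    seed = as.integer(seeds))
  # deterministic shuffle so sequential prefixes are label-mixed
  train <- train[with_seed(mix_seed(seed, 99), sample.int(nrow(train))), ]

  tests <- purrr::map_dfr(info$conditions, function(cond) {
    salt <- 1L + match(cond, TEST_CONDITIONS)
    n_per <- n_test_per_condition / 5
    lab <- rep(1:5, each = n_per)
    seeds <- mapply(function(l, i) mix_seed(seed, salt, l, i), lab,
                    rep(seq_len(n_per), 5))
    shape_id <- switch(cond, nonshape = rep(NA_integer_, length(lab)), lab)
    nonshape <- switch(cond,
      both = lab, nonshape = lab,
      conflict = conflict_partner(lab),
      shape = rep(NA_integer_, length(lab)))
    diag_cat <- if (cond == "shape") rep(NA_integer_, length(lab)) else nonshape
    tibble::tibble(
      image = NA_character_, experiment = experiment,
      variant = variant, condition = cond,
      label = as.integer(lab), shape_id = as.integer(shape_id),
      nonshape_category = as.integer(nonshape),
      diag_json = vapply(seq_along(lab), function(i)
        sample_diag_json(info$feature, diag_cat[i], seeds[i]), character(1)),
      seed = as.integer(seeds))
  })

  manifest <- dplyr::bind_rows(train, tests)
  attr(manifest, "sb_meta") <- list(
    experiment = experiment, variant = variant, seed = as.integer(seed),
    n_train = as.integer(n_train),
    n_test_per_condition = as.integer(n_test_per_condition),
    palette = sb_palette(),
    templates = if (info$has_shape) make_templates(seed) else make_templates(seed),
    config = config,
    version = "1")
  manifest
}

manifest_meta <- function(manifest) {
  meta <- attr(manifest, "sb_meta")
  if (is.null(meta)) stop("manifest has no sb_meta attribute; use generate_dataset() or read_manifest()")
  meta
}

#' Write / read a dataset manifest
#'
#' The rows go to CSV (columns exactly: image, experiment, variant,
#' condition, label, shape_id, nonshape_category, diag_json, seed); dataset
#' metadata (palette, templates, seeds, render configuration) goes to a JSON
#' sidecar at `<path>.meta.json`. The round trip is lossless.
#'
#' @param manifest A manifest tibble from [generate_dataset()].
#' @param path CSV file path.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   returns the manifest tibble with metadata reattached.
#' @export
write_manifest <- function(manifest, path) {
  cols <- c("image", "experiment", "variant", "condition", "label",
            "shape_id", "nonshape_category", "diag_json", "seed")
  readr::write_csv(manifest[, cols], path, na = "")
  meta <- attr(manifest, "sb_meta")
  if (!is.null(meta)) {
    ser <- meta
    ser$templates <- templates_to_df(meta$templates)
    ser$config <- unclass(meta$config)
    ser$palette <- list(colours = meta$palette$colours,
                        background = meta$palette$background)
    jsonlite::write_json(ser, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    image = readr::col_character(), experiment = readr::col_character(),
    variant = readr::col_character(), condition = readr::col_character(),
    label = readr::col_character(), shape_id = readr::col_character(),
    nonshape_category = readr::col_character(),
    diag_json = readr::col_character(), seed = readr::col_character()),
    na = character(), progress = FALSE)
  parse_int_col <- function(x, name, allow_na = FALSE, domain = NULL) {
    out <- suppressWarnings(as.integer(x))
    bad <- (is.na(out) & !(allow_na & x == "")) |
      (!is.null(domain) & !is.na(out) & !out %in% domain)
    if (any(bad))
      stop("malformed ", name, " in manifest row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    out
  }
  if (nrow(df) > 0) {
    df$label <- parse_int_col(df$label, "label", domain = 1:5)
    df$shape_id <- parse_int_col(df$shape_id, "shape_id", allow_na = TRUE, domain = 1:5)
    df$nonshape_category <- parse_int_col(df$nonshape_category, "nonshape_category",
                                          allow_na = TRUE, domain = 1:5)
    df$seed <- parse_int_col(df$seed, "seed")
    df$image[df$image == ""] <- NA_character_
  } else {
    for (col in c("label", "shape_id", "nonshape_category", "seed"))
      df[[col]] <- integer(0)
    df$image <- character(0)
  }
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    meta$templates <- templates_from_df(meta$templates)
    meta$config <- do.call(render_config, as.list(meta$config)[
      setdiff(names(meta$config), character(0))])
    meta$palette <- list(colours = matrix(as.integer(meta$palette$colours), ncol = 3),
                         background = as.integer(meta$palette$background))
    attr(df, "sb_meta") <- meta
  }
  df
}
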