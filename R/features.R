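# Symbolic feature schemas and extraction.
#
# The ideal observer is defined on symbolic feature vectors, not pixels, so
# extraction reads the ground-truth spec of each image. Channels are
# categorical; the segment-colour counts of the segment experiments form one
# joint multinomial block (five segment-colour draws), exposed as 20 count
# columns that always sum to 5.

SHAPE_SCRAMBLED <- 6L   # shape channel value for images with no coherent shape
LOC_BACKGROUND <- 21L   # location channel value when a diagnostic location is empty

#' Feature schema of an experiment
#'
#' Channel layout of the per-trial feature vector:
#' * patch experiments: `shape` (6 values: categories 1--5 + scrambled) and
#'   five location channels `loc1`..`loc5` (21 values: colours 1--20 +
#'   background), reporting the colour sitting at each absolute diagnostic
#'   location;
#' * segment experiments: `shape` plus 20 count channels `cnt_c01`..`cnt_c20`
#'   (values 0--5), the number of segments of each colour; the counts form
#'   one multinomial block of 5 draws;
#' * size experiments: `shape` plus `size` (6 levels; level 6 is the
#'   super-diagnostic Shape-condition level);
#' * colour experiments: `shape` plus `colour` (20 values).
#'
#' @param experiment Experiment id.
#' @return A tibble of class `sb_schema` with columns `channel`, `block`,
#'   `kind` (`"categorical"` or `"count"`) and `K` (cardinality of the
#'   channel domain, or of the block's colour domain for count channels),
#'   plus attributes `experiment` and `blocks` (per-block cardinality and
#'   draws).
#' @examples
#' nrow(feature_schema("exp2")) # 21 channels
#' @export
feature_schema <- function(experiment) {
  info <- experiment_info(experiment)
  shape <- tibble::tibble(channel = "shape", block = "shape",
                          kind = "categorical", K = 6L)
  rest <- switch(info$feature,
    patch = tibble::tibble(channel = paste0("loc", 1:5),
                           block = paste0("loc", 1:5),
                           kind = "categorical", K = 21L),
    segment = tibble::tibble(channel = sprintf("cnt_c%02d", 1:20),
                             block = "segment_colour", kind = "count", K = 20L),
    size = tibble::tibble(channel = "size", block = "size",
                          kind = "categorical", K = 6L),
    colour = tibble::tibble(channel = "colour", block = "colour",
                            kind = "categorical", K = 20L))
  schema <- dplyr::bind_rows(shape, rest)
  blocks <- dplyr::distinct(schema, .data$block, .data$kind, .data$K)
  blocks$draws <- ifelse(blocks$kind == "count", 5L, 1L)
  attr(schema, "experiment") <- experiment
  attr(schema, "blocks") <- blocks
  class(schema) <- c("sb_schema", class(schema))
  schema
}

schema_blocks <- function(schema) attr(schema, "blocks")
schema_experiment <- function(schema) attr(schema, "experiment")

#' Extract symbolic feature vectors
#'
#' Pure function of the specs: turns manifest rows into a wide feature table
#' (one column per channel) under the experiment's schema. The shape channel
#' is the shape category, or the scrambled value 6 for images with no
#' coherent shape; empty diagnostic locations report the background value 21.
#'
#' @param manifest A manifest tibble (any mix of conditions).
#' @param schema Schema; defaults to the manifest's experiment.
#' @return A tibble with `nrow(manifest)` rows and one integer column per
#'   channel, in schema order.
#' @examples
#' m <- generate_dataset("exp2", "a", n_train = 10, n_test_per_condition = 5, seed = 1)
#' f <- extract_features(m)
#' all(rowSums(f[, -1]) == 5)
#' @export
extract_features <- function(manifest, schema = NULL) {
  if (nrow(manifest) == 0) stop("empty manifest")
  experiment <- manifest$experiment[1]
  if (!all(manifest$experiment == experiment))
    stop("manifest mixes experiments; extract one at a time")
  if (is.null(schema)) schema <- feature_schema(experiment)
  if (!identical(schema_experiment(schema), experiment))
    stop("schema is for ", schema_experiment(schema), ", manifest is ", experiment)
  info <- experiment_info(experiment)
  diags <- lapply(manifest$diag_json, parse_diag)
  n <- nrow(manifest)

  shape <- ifelse(is.na(manifest$shape_id), SHAPE_SCRAMBLED, manifest$shape_id)
  out <- tibble::tibble(shape = as.integer(shape))

  if (info$feature == "patch") {
    locs <- matrix(LOC_BACKGROUND, n, 5)
    for (i in seq_len(n)) {
      d <- diags[[i]]
      if (!is.null(d$loc)) locs[i, d$loc] <- d$colour
    }
    colnames(locs) <- paste0("loc", 1:5)
    out <- dplyr::bind_cols(out, tibble::as_tibble(locs))
  } else if (info$feature == "segment") {
    cnt <- t(vapply(diags, function(d) tabulate(d$seg_colours, n_colours()),
                    integer(n_colours())))
    colnames(cnt) <- sprintf("cnt_c%02d", 1:20)
    out <- dplyr::bind_cols(out, tibble::as_tibble(cnt))
  } else if (info$feature == "size") {
    out$size <- vapply(diags, function(d) as.integer(d$level), integer(1))
  } else {
    out$colour <- vapply(diags, function(d) as.integer(d$colour), integer(1))
  }
  storage.mode(out$shape) <- "integer"
  out[, schema$channel]
}
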