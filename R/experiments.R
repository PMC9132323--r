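# Experiment registry: which non-shape feature each experiment uses and which
# variants / test conditions are meaningful for it.

EXPERIMENTS <- c("exp1", "exp2", "exp3", "exp4",
                 "exp5_patch", "exp5_segment", "exp5_size", "exp5_colour")
VARIANTS <- c("a", "b", "noshape")
TEST_CONDITIONS <- c("both", "conflict", "shape", "nonshape")

#' Experiment metadata
#'
#' @param experiment One of `"exp1"`, `"exp2"`, `"exp3"`, `"exp4"`,
#'   `"exp5_patch"`, `"exp5_segment"`, `"exp5_size"`, `"exp5_colour"`.
#' @return A list with the non-shape `feature` type (`"patch"`, `"segment"`,
#'   `"size"` or `"colour"`), whether the experiment has shape-bearing
#'   variants (`has_shape`), the admissible `variants` and test `conditions`.
#' @examples
#' experiment_info("exp3")$feature
#' @export
experiment_info <- function(experiment) {
  experiment <- match.arg(experiment, EXPERIMENTS)
  no_shape <- startsWith(experiment, "exp5")
  feature <- switch(experiment,
    exp1 = "patch", exp2 = "segment", exp3 = "size", exp4 = "colour",
    sub("exp5_", "", experiment))
  list(
    experiment = experiment,
    feature = feature,
    has_shape = !no_shape,
    variants = if (no_shape) "noshape" else c("a", "b"),
    conditions = if (no_shape) "nonshape" else TEST_CONDITIONS
  )
}

shape_prob_for <- function(variant) {
  switch(variant, a = 1, b = 0.8, noshape = 0,
         stop("unknown variant: ", variant))
}

# Fixed derangement used to pick the non-shape category of Conflict trials.
conflict_partner <- function(label) (label %% n_categories()) + 1L
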