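# Scoring rules, condition-pattern classification, learner-group splitting
# and report serialisation, shared by the ideal observer and the CNN harness.

#' Scored category of test trials
#'
#' Accuracy in the Both, Conflict and Shape conditions is scored against the
#' category predicted by the shape feature; accuracy in the Non-shape
#' condition is scored against the category predicted by the non-shape
#' feature.
#'
#' @param manifest Manifest rows; all must be test conditions.
#' @return Integer vector of scored class labels.
#' @examples
#' m <- generate_dataset("exp2", "a", n_train = 5, n_test_per_condition = 5, seed = 1)
#' conf <- dplyr::filter(m, condition == "conflict")
#' all(scored_label(conf) == conf$shape_id)
#' @export
scored_label <- function(manifest) {
  if (any(!manifest$condition %in% TEST_CONDITIONS))
    stop("scored_label is defined for test conditions only")
  ifelse(manifest$condition == "nonshape",
         manifest$nonshape_category, manifest$shape_id)
}

#' Classify a four-condition performance pattern
#'
#' Maps per-condition accuracy to qualitative levels (high / medium / low)
#' and names the reliance pattern: high-high-high-low across
#' Both/Conflict/Shape/Non-shape indicates shape reliance,
#' high-low-low-high indicates non-shape reliance, high everywhere (with
#' Conflict at least medium) indicates use of both features, all-low means
#' the task was not learned, anything else is mixed.
#'
#' @param report A tibble with columns `condition` and a metric column
#'   (`accuracy` by default); must contain all four test conditions (row
#'   order is irrelevant).
#' @param chance Chance level (default 0.2).
#' @param high_threshold,low_threshold Level cut-offs: metric >= high is
#'   "high", metric <= low is "low", otherwise "medium".
#' @param metric Name of the metric column.
#' @return A one-row tibble: levels per condition plus `pattern`.
#' @export
classify_pattern <- function(report, chance = 0.2, high_threshold = 0.5,
                             low_threshold = 0.3, metric = "accuracy") {
  missing <- setdiff(TEST_CONDITIONS, report$condition)
  if (length(missing) > 0)
    stop("missing condition(s): ", paste(missing, collapse = ", "))
  val <- vapply(TEST_CONDITIONS, function(cond)
    report[[metric]][match(cond, report$condition)], numeric(1))
  lev <- ifelse(val >= high_threshold, "high",
                ifelse(val <= low_threshold, "low", "medium"))
  names(lev) <- TEST_CONDITIONS
  pattern <- if (all(lev == "low")) "unlearned"
    else if (identical(unname(lev), c("high", "high", "high", "low"))) "shape-reliant"
    else if (identical(unname(lev), c("high", "low", "low", "high"))) "nonshape-reliant"
    else if (lev[["both"]] == "high" && lev[["shape"]] == "high" &&
             lev[["nonshape"]] == "high" && lev[["conflict"]] != "low") "both-features"
    else "mixed"
  tibble::tibble(both = lev[["both"]], conflict = lev[["conflict"]],
                 shape = lev[["shape"]], nonshape = lev[["nonshape"]],
                 pattern = pattern)
}

#' Split learners into shape- and non-shape-reliant groups
#'
#' A learner counts as relying on the non-shape feature if its Non-shape
#' performance exceeds its Shape performance; ties go to the shape group.
#' The split partitions the input: every learner lands in exactly one group.
#'
#' @param reports A tibble of per-learner condition reports with columns
#'   `learner`, `condition` and the metric column.
#' @param metric Name of the metric column (default `"accuracy"`).
#' @return A list with `shape` and `nonshape` tibbles (subsets of
#'   `reports`), plus `summary`: per-group mean metric by condition.
#' @export
split_groups <- function(reports, metric = "accuracy") {
  if (nrow(reports) == 0) stop("empty input")
  wide <- reports |>
    dplyr::filter(.data$condition %in% c("shape", "nonshape")) |>
    dplyr::select("learner", "condition", dplyr::all_of(metric)) |>
    tidyr::pivot_wider(names_from = "condition", values_from = dplyr::all_of(metric))
  if (!all(c("shape", "nonshape") %in% names(wide)))
    stop("reports must contain shape and nonshape conditions")
  nonshape_ids <- wide$learner[wide$nonshape > wide$shape]
  grp <- list(
    shape = reports[!reports$learner %in% nonshape_ids, ],
    nonshape = reports[reports$learner %in% nonshape_ids, ])
  summary <- dplyr::bind_rows(
    dplyr::mutate(grp$shape, group = "shape"),
    dplyr::mutate(grp$nonshape, group = "nonshape")) |>
    dplyr::group_by(.data$group, .data$condition) |>
    dplyr::summarise(n_learners = dplyr::n_distinct(.data$learner),
                     mean_metric = mean(.data[[metric]]), .groups = "drop")
  c(grp, list(summary = summary))
}

#' Write a tidy evaluation report
#'
#' Serialises condition reports (and, optionally, learning curves) as tidy
#' CSV files plus a JSON summary. Reading the CSVs back gives the same
#' values.
#'
#' @param reports Condition-report tibble (long format).
#' @param dir Output directory (created if needed).
#' @param curves Optional learning-curve tibble.
#' @return Invisibly, the paths written.
#' @export
make_report <- function(reports, dir, curves = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "conditions.csv")
  readr::write_csv(reports, paths)
  if (!is.null(curves)) {
    p <- file.path(dir, "curves.csv")
    readr::write_csv(curves, p)
    paths <- c(paths, p)
  }
  summary <- reports |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean), .groups = "drop")
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, p))
}

# Normal-approximation 95% confidence half-width.
ci95 <- function(x) {
  if (length(x) < 2) return(NA_real_)
  1.96 * stats::sd(x) / sqrt(length(x))
}
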