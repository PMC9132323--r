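# Sequential Dirichlet-multinomial ideal observer.
#
# Class-conditionals are Dirichlet-multinomial posterior predictives with a
# flat prior (alpha = 1, Laplace smoothing), factorised over the schema's
# blocks. Updating adds the observed feature-value counts to the per-class
# count tables; the multinomial parameters are integrated out analytically
# and never stored. The posterior over the five categories is
#   p(Y = c | x, D)  proportional to  p(Y = c) * prod_f p(x_f | Y = c, D)
# with per-draw predictive (N_k + alpha_k) / (sum_v N_v + alpha_v). The
# segment-colour counts form one multinomial block of five draws, whose joint
# predictive multiplies per-draw terms with within-image count increments;
# absent colours contribute nothing (no spurious absence signal).

#' Create an untrained ideal observer
#'
#' @param schema A feature schema from [feature_schema()], or an experiment id.
#' @param alpha Dirichlet hyper-parameter, a single positive number applied
#'   to every feature value (default 1: flat prior / Laplace smoothing).
#' @param class_prior Prior over the five categories (default uniform).
#' @return An object of class `ideal_observer`: per-class, per-block count
#'   tables, all zero.
#' @examples
#' io <- ideal_observer("exp3")
#' observer_posterior(io, tibble::tibble(shape = 1L, size = 2L))
#' @export
ideal_observer <- function(schema, alpha = 1, class_prior = rep(1 / 5, 5)) {
  if (is.character(schema)) schema <- feature_schema(schema)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stop("alpha must be a single positive number")
  if (length(class_prior) != 5 || any(class_prior < 0) ||
      abs(sum(class_prior) - 1) > 1e-8)
    stop("class_prior must be 5 non-negative probabilities summing to 1")
  blocks <- schema_blocks(schema)
  counts <- lapply(seq_len(nrow(blocks)), function(i)
    matrix(0, nrow = blocks$K[i], ncol = 5))
  names(counts) <- blocks$block
  structure(list(schema = schema, alpha = alpha, class_prior = class_prior,
                 counts = counts, n_per_class = rep(0L, 5)),
            class = "ideal_observer")
}

# Columns of `features` belonging to one block, as an integer matrix.
block_values <- function(io, features, block) {
  schema <- io$schema
  cols <- schema$channel[schema$block == block]
  as.matrix(features[, cols, drop = FALSE])
}

#' Update an ideal observer with labelled trials
#'
#' Adds the feature-value counts of each trial to the count table of its
#' class. Batch order is irrelevant: any permutation of the same trials
#' yields an identical model.
#'
#' @param io An `ideal_observer`.
#' @param features Feature table from [extract_features()] (rows are trials).
#' @param labels Integer class labels in 1..5, one per row.
#' @return The updated `ideal_observer`.
#' @export
update_observer <- function(io, features, labels) {
  stopifnot(inherits(io, "ideal_observer"))
  labels <- as.integer(labels)
  if (length(labels) != nrow(features)) stop("labels must match feature rows")
  if (any(is.na(labels)) || any(labels < 1 | labels > 5))
    stop("labels must be integers in 1..5")
  blocks <- schema_blocks(io$schema)
  for (i in seq_len(nrow(blocks))) {
    b <- blocks$block[i]
    K <- blocks$K[i]
    vals <- block_values(io, features, b)
    if (blocks$kind[i] == "categorical") {
      if (any(vals < 1 | vals > K)) stop("value outside channel domain in block ", b)
      inc <- table(factor(vals[, 1], levels = 1:K), factor(labels, levels = 1:5))
    } else {
      if (any(vals < 0)) stop("negative count in block ", b)
      onehot <- matrix(0, length(labels), 5)
      onehot[cbind(seq_along(labels), labels)] <- 1
      inc <- t(vals) %*% onehot
    }
    io$counts[[b]] <- io$counts[[b]] + unclass(inc)
  }
  io$n_per_class <- io$n_per_class +
    as.integer(table(factor(labels, levels = 1:5)))
  io
}

#' Posterior-predictive class-conditional of one channel value
#'
#' The probability that channel `channel` takes value `value` (for count
#' channels: that the colour appears `value` times among the five segments)
#' under class `class`, given the training counts. For fixed channel and
#' class the probabilities sum to 1 over the channel's domain.
#'
#' @param io An `ideal_observer`.
#' @param channel Channel name from the schema.
#' @param value Channel value (categorical: 1..K; count channels: 0..5).
#' @param class Class label in 1..5.
#' @return A single probability.
#' @export
class_conditional <- function(io, channel, value, class) {
  schema <- io$schema
  if (!channel %in% schema$channel) stop("unknown channel: ", channel)
  row <- schema[schema$channel == channel, ]
  blocks <- schema_blocks(io$schema)
  blk <- blocks[blocks$block == row$block, ]
  N <- io$counts[[row$block]]
  a <- io$alpha
  if (row$kind == "categorical") {
    if (!value %in% seq_len(blk$K)) stop("value outside channel domain")
    (N[value, class] + a) / (sum(N[, class]) + blk$K * a)
  } else {
    # marginal beta-binomial predictive for this colour's count in 5 draws
    m <- blk$draws
    if (!value %in% 0:m) stop("value outside channel domain")
    k <- match(channel, schema$channel[schema$block == row$block])
    A <- sum(N[, class]) + blk$K * a
    Nk <- N[k, class] + a
    exp(lchoose(m, value) +
          lgamma(Nk + value) - lgamma(Nk) +
          lgamma(A - Nk + m - value) - lgamma(A - Nk) +
          lgamma(A) - lgamma(A + m))
  }
}

# n x 5 matrix of log p(x | c, D) + log prior, unnormalised.
observer_loglik <- function(io, features) {
  blocks <- schema_blocks(io$schema)
  n <- nrow(features)
  ll <- matrix(rep(log(io$class_prior), each = n), n, 5)
  a <- io$alpha
  for (i in seq_len(nrow(blocks))) {
    b <- blocks$block[i]
    K <- blocks$K[i]
    N <- io$counts[[b]]
    vals <- block_values(io, features, b)
    if (blocks$kind[i] == "categorical") {
      v <- vals[, 1]
      if (any(v < 1 | v > K)) stop("value outside channel domain in block ", b)
      for (c in 1:5) {
        denom <- sum(N[, c]) + K * a
        ll[, c] <- ll[, c] + log(N[v, c] + a) - log(denom)
      }
    } else {
      m <- blocks$draws[i]
      if (any(rowSums(vals) != m))
        stop("count block ", b, " must sum to ", m, " in every row")
      coeff <- lgamma(m + 1) - rowSums(lgamma(vals + 1))
      for (c in 1:5) {
        A <- sum(N[, c]) + K * a
        Na <- N[, c] + a
        term <- sweep(lgamma(sweep(vals, 2, Na, "+")), 2, lgamma(Na), "-")
        ll[, c] <- ll[, c] + coeff + rowSums(term) + lgamma(A) - lgamma(A + m)
      }
    }
  }
  ll
}

#' Posterior over categories for test trials
#'
#' @param io A (possibly trained) `ideal_observer`.
#' @param features Feature table (rows are test trials).
#' @return A tibble with columns `p1`..`p5`; each row is a normalised
#'   posterior (computed in log space, so long channel products do not
#'   underflow).
#' @export
observer_posterior <- function(io, features) {
  ll <- observer_loglik(io, features)
  mx <- apply(ll, 1, max)
  p <- exp(ll - mx)
  p <- p / rowSums(p)
  colnames(p) <- paste0("p", 1:5)
  tibble::as_tibble(p)
}

#' Predicted class for test trials
#'
#' Argmax of the posterior; exact ties break toward the lowest class index.
#'
#' @inheritParams observer_posterior
#' @return An integer vector of class labels.
#' @export
observer_predict <- function(io, features) {
  ll <- observer_loglik(io, features)
  max.col(ll, ties.method = "first")
}

#' Evaluate an observer on one test condition
#'
#' Scores every trial against the condition's scoring rule (shape category
#' for Both/Conflict/Shape, non-shape category for Non-shape) and reports
#' the mean posterior mass on the scored class and the argmax accuracy.
#'
#' @param io A trained `ideal_observer`.
#' @param manifest Manifest rows of a single test condition.
#' @param features Optional pre-extracted features for `manifest`.
#' @return A one-row tibble: `condition`, `n`, `mean_posterior`, `accuracy`.
#' @export
evaluate_condition <- function(io, manifest, features = NULL) {
  if (nrow(manifest) == 0) stop("empty test set")
  cond <- unique(manifest$condition)
  if (length(cond) != 1) stop("mixed conditions: ", paste(cond, collapse = ", "))
  if (!cond %in% TEST_CONDITIONS) stop("not a test condition: ", cond)
  if (is.null(features)) features <- extract_features(manifest, io$schema)
  scored <- scored_label(manifest)
  post <- as.matrix(observer_posterior(io, features))
  pred <- observer_predict(io, features)
  tibble::tibble(condition = cond, n = nrow(manifest),
                 mean_posterior = mean(post[cbind(seq_along(scored), scored)]),
                 accuracy = mean(pred == scored))
}

#' Ideal-observer learning curve
#'
#' Trains the observer sequentially on the first `N` training trials for each
#' checkpoint `N` (reusing counts between checkpoints, never refitting from
#' scratch) and evaluates every test condition at each checkpoint.
#'
#' @param experiment,variant Dataset to generate.
#' @param checkpoints Increasing trial counts at which to evaluate.
#' @param seed Dataset seed.
#' @param n_train,n_test_per_condition Dataset sizes.
#' @return A tibble with columns `checkpoint`, `condition`, `n`,
#'   `mean_posterior`, `accuracy`.
#' @export
learning_curve <- function(experiment, variant, checkpoints, seed = 1,
                           n_train = 2000, n_test_per_condition = 500) {
  checkpoints <- sort(unique(as.integer(checkpoints)))
  if (any(checkpoints < 0) || any(checkpoints > n_train))
    stop("checkpoints must lie in [0, n_train]")
  manifest <- generate_dataset(experiment, variant, n_train = n_train,
                               n_test_per_condition = n_test_per_condition,
                               seed = seed)
  info <- experiment_info(experiment)
  schema <- feature_schema(experiment)
  train <- manifest[manifest$condition == "train", ]
  train_f <- extract_features(train, schema)
  tests <- lapply(info$conditions, function(cond) {
    rows <- manifest[manifest$condition == cond, ]
    list(rows = rows, features = extract_features(rows, schema))
  })
  names(tests) <- info$conditions

  io <- ideal_observer(schema)
  done <- 0L
  purrr::map_dfr(checkpoints, function(ck) {
    if (ck > done) {
      idx <- (done + 1L):ck
      io <<- update_observer(io, train_f[idx, ], train$label[idx])
      done <<- ck
    }
    purrr::map_dfr(tests, function(t)
      dplyr::mutate(evaluate_condition(io, t$rows, t$features),
                    checkpoint = ck, .before = 1))
  })
}

#' @export
print.ideal_observer <- function(x, ...) {
  cat("Dirichlet-multinomial ideal observer (", schema_experiment(x$schema),
      ")\n", sep = "")
  cat("  trials seen:", sum(x$n_per_class),
      "(per class:", paste(x$n_per_class, collapse = ", "), ")\n")
  cat("  alpha:", x$alpha, " blocks:",
      paste(names(x$counts), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy an ideal observer's count tables
#'
#' @param x An `ideal_observer`.
#' @param ... Unused.
#' @return A long tibble: `block`, `value`, `class`, `count`,
#'   `predictive` (the per-draw posterior-predictive probability).
#' @export
tidy.ideal_observer <- function(x, ...) {
  a <- x$alpha
  purrr::map_dfr(names(x$counts), function(b) {
    N <- x$counts[[b]]
    K <- nrow(N)
    purrr::map_dfr(1:5, function(c) tibble::tibble(
      block = b, value = seq_len(K), class = c, count = N[, c],
      predictive = (N[, c] + a) / (sum(N[, c]) + K * a)))
  })
}

#' @rdname tidy.ideal_observer
#' @return `glance()`: a one-row tibble with `experiment`, `n_train`,
#'   `n_blocks`, `n_channels`, `alpha`.
#' @export
glance.ideal_observer <- function(x, ...) {
  tibble::tibble(experiment = schema_experiment(x$schema),
                 n_train = sum(x$n_per_class),
                 n_blocks = length(x$counts),
                 n_channels = nrow(x$schema), alpha = x$alpha)
}
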