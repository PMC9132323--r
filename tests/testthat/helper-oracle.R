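# Brute-force Bayes oracle, independent of the package's count-table path.
#
# Recomputes every class-conditional directly from the raw trial log each
# time it is called: no sequential updating, no cached counts. Categorical
# channels use the Dirichlet-categorical predictive; count blocks use the
# exact Dirichlet-multinomial joint predictive evaluated draw by draw.

oracle_posterior <- function(trials, labels, test_row, blocks, alpha = 1,
                             prior = rep(1 / 5, 5)) {
  ll <- log(prior)
  for (c in 1:5) {
    rows <- trials[labels == c, , drop = FALSE]
    for (b in seq_len(nrow(blocks))) {
      cols <- unlist(blocks$cols[b])
      K <- blocks$K[b]
      if (blocks$kind[b] == "categorical") {
        v <- test_row[[cols]]
        Nk <- sum(rows[[cols]] == v)
        ll[c] <- ll[c] + log(Nk + alpha) - log(nrow(rows) + K * alpha)
      } else {
        # expand the test counts into an explicit draw sequence and apply the
        # per-draw predictive with within-image increments
        counts_train <- colSums(rows[, cols, drop = FALSE])
        n_test <- as.numeric(test_row[, cols])
        draws <- rep(seq_len(K), n_test)
        seen <- numeric(K)
        A <- sum(counts_train) + K * alpha
        for (j in seq_along(draws)) {
          k <- draws[j]
          ll[c] <- ll[c] + log(counts_train[k] + alpha + seen[k]) -
            log(A + (j - 1))
          seen[k] <- seen[k] + 1
        }
        # draw-sequence orderings are exchangeable up to the multinomial
        # coefficient, which the package includes; add it here too
        ll[c] <- ll[c] + lgamma(sum(n_test) + 1) - sum(lgamma(n_test + 1))
      }
    }
  }
  p <- exp(ll - max(ll))
  p / sum(p)
}

# Random small trial logs over arbitrary schemas for property tests.
random_small_problem <- function(seed, n_trials = 30) {
  withr::local_seed(seed)
  blocks <- tibble::tibble(
    cols = list("ch1", "ch2", c("c1", "c2", "c3")),
    kind = c("categorical", "categorical", "count"),
    K = c(3L, 4L, 3L))
  draws <- 2L
  trials <- tibble::tibble(
    ch1 = sample.int(3, n_trials, replace = TRUE),
    ch2 = sample.int(4, n_trials, replace = TRUE))
  cnt <- t(stats::rmultinom(n_trials, draws, prob = c(0.5, 0.3, 0.2)))
  colnames(cnt) <- c("c1", "c2", "c3")
  trials <- dplyr::bind_cols(trials, tibble::as_tibble(cnt))
  labels <- sample.int(5, n_trials, replace = TRUE)
  list(trials = trials, labels = labels, blocks = blocks, draws = draws)
}

# Build an ideal_observer over the same ad-hoc schema as random_small_problem.
observer_for_problem <- function(prob) {
  schema <- tibble::tibble(
    channel = c("ch1", "ch2", "c1", "c2", "c3"),
    block = c("ch1", "ch2", "cnt", "cnt", "cnt"),
    kind = c("categorical", "categorical", "count", "count", "count"),
    K = c(3L, 4L, 3L, 3L, 3L))
  blocks <- dplyr::distinct(schema, block, kind, K)
  blocks$draws <- ifelse(blocks$kind == "count", prob$draws, 1L)
  attr(schema, "experiment") <- "adhoc"
  attr(schema, "blocks") <- blocks
  class(schema) <- c("sb_schema", class(schema))
  ideal_observer(schema)
}

# Small manifest defaults used across tests.
small_dataset <- function(experiment, variant, seed = 1, n_train = 100,
                          n_test = 20) {
  generate_dataset(experiment, variant, n_train = n_train,
                   n_test_per_condition = n_test, seed = seed)
}
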