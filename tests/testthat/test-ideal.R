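# Dirichlet-multinomial ideal observer.

test_that("an untrained observer is uniform and a dominating prior dominates", {
  io <- ideal_observer("exp3")
  f <- tibble::tibble(shape = 2L, size = 3L)
  expect_equal(as.numeric(observer_posterior(io, f)), rep(0.2, 5), tolerance = 1e-12)
  io1 <- ideal_observer("exp3", class_prior = c(1, 0, 0, 0, 0))
  expect_equal(as.numeric(observer_posterior(io1, f)), c(1, 0, 0, 0, 0))
  expect_identical(ideal_observer("exp3"), ideal_observer("exp3"))
  expect_error(ideal_observer("exp3", alpha = 0), "positive")
})

test_that("one update moves the class-conditional to (N+1)/(N+K)", {
  io <- ideal_observer("exp3")
  io <- update_observer(io, tibble::tibble(shape = 4L, size = 2L), 4L)
  expect_equal(class_conditional(io, "size", 2, 4), 2 / 7) # K = 6
  expect_equal(class_conditional(io, "size", 3, 4), 1 / 7)
  # other classes untouched
  expect_equal(class_conditional(io, "size", 2, 1), 1 / 6)
  # channel conditionals sum to one
  expect_equal(sum(vapply(1:6, function(k)
    class_conditional(io, "size", k, 4), numeric(1))), 1)
})

test_that("count-channel conditionals are beta-binomial and sum to one", {
  m <- small_dataset("exp2", "a", n_train = 50, n_test = 5)
  tr <- m[m$condition == "train", ]
  io <- update_observer(ideal_observer("exp2"), extract_features(tr), tr$label)
  p <- vapply(0:5, function(v)
    class_conditional(io, "cnt_c01", v, 1), numeric(1))
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # seeing category 1's diagnostic colour is far likelier under category 1
  expect_gt(class_conditional(io, "cnt_c01", 1, 1),
            3 * class_conditional(io, "cnt_c01", 1, 2))
})

test_that("updates are exchangeable: permuted replay gives an identical model", {
  m <- small_dataset("exp2", "b", n_train = 50, n_test = 5)
  tr <- m[m$condition == "train", ]
  f <- extract_features(tr)
  io1 <- update_observer(ideal_observer("exp2"), f, tr$label)
  perm <- rev(seq_len(nrow(f)))
  io2 <- update_observer(ideal_observer("exp2"), f[perm, ], tr$label[perm])
  expect_equal(io1$counts, io2$counts)
  expect_equal(io1$n_per_class, io2$n_per_class)
  # incremental vs batch
  io3 <- ideal_observer("exp2")
  for (i in seq_len(nrow(f))) io3 <- update_observer(io3, f[i, ], tr$label[i])
  expect_equal(io1$counts, io3$counts)
})

test_that("posteriors match the brute-force oracle on small random problems", {
  for (seed in 1:8) {
    prob <- random_small_problem(seed)
    io <- observer_for_problem(prob)
    io <- update_observer(io, prob$trials, prob$labels)
    test_rows <- random_small_problem(seed + 100, n_trials = 5)$trials
    post <- as.matrix(observer_posterior(io, test_rows))
    for (i in seq_len(nrow(test_rows))) {
      oracle <- oracle_posterior(prob$trials, prob$labels, test_rows[i, ],
                                 prob$blocks)
      expect_equal(as.numeric(post[i, ]), oracle, tolerance = 1e-10)
    }
  }
})

test_that("posteriors normalise and long channel products do not underflow", {
  m <- small_dataset("exp1", "a", n_train = 100, n_test = 20)
  tr <- m[m$condition == "train", ]
  io <- update_observer(ideal_observer("exp1"), extract_features(tr), tr$label)
  post <- as.matrix(observer_posterior(io, extract_features(m)))
  expect_true(all(abs(rowSums(post) - 1) < 1e-12))
  expect_true(all(post >= 0))
})

test_that("predict is the posterior argmax with ties to the lowest index", {
  io <- ideal_observer("exp4")
  f <- tibble::tibble(shape = 1L, colour = 7L)
  expect_equal(observer_predict(io, f), 1L) # five-way tie
  m <- small_dataset("exp4", "a", n_train = 50, n_test = 10)
  tr <- m[m$condition == "train", ]
  io <- update_observer(io, extract_features(tr), tr$label)
  ftest <- extract_features(m)
  post <- as.matrix(observer_posterior(io, ftest))
  expect_equal(observer_predict(io, ftest), max.col(post, ties.method = "first"))
})

test_that("relabelling categories by a permutation permutes posteriors", {
  prob <- random_small_problem(21)
  perm <- c(3L, 5L, 1L, 2L, 4L)
  io <- observer_for_problem(prob)
  ioa <- update_observer(io, prob$trials, prob$labels)
  iob <- update_observer(io, prob$trials, perm[prob$labels])
  test_rows <- prob$trials[1:5, ]
  pa <- as.matrix(observer_posterior(ioa, test_rows))
  pb <- as.matrix(observer_posterior(iob, test_rows))
  expect_equal(pb[, perm], pa, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("the trained model recovers every category's diagnostic value", {
  sets <- list(c("exp1", "a"), c("exp1", "b"), c("exp2", "a"), c("exp2", "b"),
               c("exp3", "a"), c("exp3", "b"), c("exp4", "a"), c("exp4", "b"),
               c("exp5_patch", "noshape"), c("exp5_segment", "noshape"),
               c("exp5_size", "noshape"), c("exp5_colour", "noshape"))
  for (s in sets) {
    m <- small_dataset(s[1], s[2], n_train = 200, n_test = 5, seed = 9)
    tr <- m[m$condition == "train", ]
    io <- update_observer(ideal_observer(s[1]), extract_features(tr), tr$label)
    feature <- experiment_info(s[1])$feature
    for (c in 1:5) {
      modal <- switch(feature,
        patch = which.max(io$counts[[paste0("loc", c)]][, c]),
        segment = which.max(io$counts$segment_colour[, c]),
        size = which.max(io$counts$size[, c]),
        colour = which.max(io$counts$colour[, c]))
      expect_equal(unname(modal), c)
    }
  }
})

test_that("Both-condition posterior concentrates monotonically with training", {
  checkpoints <- c(0, 25, 50, 100, 200, 400)
  curves <- sapply(1:5, function(seed) {
    lc <- learning_curve("exp3", "a", checkpoints, seed = seed,
                         n_train = 400, n_test_per_condition = 50)
    lc$mean_posterior[lc$condition == "both"]
  })
  avg <- rowMeans(curves)
  expect_true(all(diff(avg) > -0.005))
  expect_equal(avg[1], 0.2)
})

test_that("evaluate_condition enforces a single non-empty test condition", {
  m <- small_dataset("exp3", "a", n_train = 25, n_test = 10)
  io <- ideal_observer("exp3")
  expect_error(evaluate_condition(io, m[0, ]), "empty")
  expect_error(evaluate_condition(io, m), "mixed")
  expect_error(evaluate_condition(io, m[m$condition == "train", ]), "test")
  r <- evaluate_condition(io, m[m$condition == "both", ])
  expect_equal(r$mean_posterior, 0.2)
})

test_that("the learning curve ends where full training ends", {
  m <- generate_dataset("exp3", "b", n_train = 200, n_test_per_condition = 50,
                        seed = 5)
  lc <- learning_curve("exp3", "b", c(0, 100, 200), seed = 5,
                       n_train = 200, n_test_per_condition = 50)
  tr <- m[m$condition == "train", ]
  io <- update_observer(ideal_observer("exp3"), extract_features(tr), tr$label)
  for (cond in c("both", "conflict", "shape", "nonshape")) {
    full <- evaluate_condition(io, m[m$condition == cond, ])
    at_end <- lc[lc$checkpoint == 200 & lc$condition == cond, ]
    expect_equal(at_end$mean_posterior, full$mean_posterior)
    expect_equal(at_end$accuracy, full$accuracy)
  }
  expect_error(learning_curve("exp3", "a", c(0, 300), n_train = 200,
                              n_test_per_condition = 50), "checkpoints")
})

test_that("tidy and glance summarise the model", {
  m <- small_dataset("exp3", "a", n_train = 25, n_test = 5)
  tr <- m[m$condition == "train", ]
  io <- update_observer(ideal_observer("exp3"), extract_features(tr), tr$label)
  td <- tidy(io)
  expect_true(all(c("block", "value", "class", "count", "predictive") %in% names(td)))
  sums <- td |> dplyr::group_by(block, class) |>
    dplyr::summarise(s = sum(predictive), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  g <- glance(io)
  expect_equal(g$n_train, 25)
  expect_equal(g$experiment, "exp3")
})
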