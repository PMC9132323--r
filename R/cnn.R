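# Training and evaluating image classifiers on rendered stimulus datasets.

#' Classifier training configuration
#'
#' The desk-scale default is a compact convolutional network trained from
#' scratch on 64 x 64 renders; that preset reproduces the qualitative
#' four-condition patterns of much larger fine-tuned architectures at a
#' fraction of the cost. A user-supplied weights file (saved parameter list)
#' can initialise the network instead, and `freeze_backbone` restricts
#' learning to the final linear layer.
#'
#' @param architecture `"compact"` (two conv blocks + linear readout).
#' @param input_size Input side length in pixels; must be a multiple of 8
#'   (default 64).
#' @param weights_init `"scratch"` or a path to an RDS file with a saved
#'   parameter list (as produced by `fit$layers`).
#' @param freeze_backbone If `TRUE`, only the final linear layer is trained.
#' @param lr Adam learning rate. Default 1e-3 for scratch training; the
#'   fine-tuning protocol of large pretrained networks uses 1e-5.
#' @param batch_size Mini-batch size (default 32).
#' @param plateau_factor Factor by which the learning rate is divided when
#'   the training loss plateaus (default 10).
#' @param plateau_patience Epochs without improvement before decaying.
#' @param convergence_tol,convergence_patience Training stops once the epoch
#'   loss improves by less than `convergence_tol` for `convergence_patience`
#'   consecutive epochs.
#' @param max_epochs Hard epoch cap.
#' @param n_seeds Number of random seeds an experiment run averages over.
#' @return A list of class `sb_train_config`.
#' @export
train_config <- function(architecture = "compact", input_size = 64,
                         weights_init = "scratch", freeze_backbone = FALSE,
                         lr = 1e-3, batch_size = 32, plateau_factor = 10,
                         plateau_patience = 3, convergence_tol = 1e-4,
                         convergence_patience = 5, max_epochs = 60,
                         n_seeds = 10) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (plateau_factor <= 1) stop("plateau_factor must be > 1")
  if (input_size %% 8 != 0) stop("input_size must be a multiple of 8")
  structure(as.list(environment()), class = "sb_train_config")
}

#' Build a classifier
#'
#' Instantiates the configured architecture with `n_classes` outputs. With
#' `weights_init = "scratch"` parameters are He-initialised from `seed`;
#' with a weights file the saved parameters are loaded and (typically
#' together with `freeze_backbone = TRUE`) only the replaced final layer is
#' learned.
#'
#' @param config A [train_config()].
#' @param n_classes Number of output classes (default 5).
#' @param seed Initialisation seed.
#' @return A list of class `sb_cnn` with `layers`, `config`, `n_classes`.
#' @export
build_classifier <- function(config, n_classes = 5, seed = 1) {
  if (!identical(config$architecture, "compact"))
    stop("unknown architecture: ", config$architecture)
  S <- config$input_size
  spec <- list(
    list(type = "conv", k = 2, stride = 2, pad = 0, n_in = 3, n_out = 16),
    list(type = "relu"),
    list(type = "maxpool"),
    list(type = "maxpool"),
    list(type = "conv", k = 3, stride = 1, pad = 1, n_in = 16, n_out = 32),
    list(type = "relu"),
    list(type = "flatten"),
    list(type = "linear"))
  sizes <- c(S, S / 2, S / 2, S / 4, S / 8, S / 8, S / 8)
  layers <- with_seed(mix_seed(seed, 4242), {
    H <- S
    lapply(seq_along(spec), function(i) {
      l <- spec[[i]]
      if (l$type == "conv") {
        fan_in <- l$k^2 * l$n_in
        l$W <- array(stats::rnorm(l$k^2 * l$n_in * l$n_out, 0, sqrt(2 / fan_in)),
                     c(l$k, l$k, l$n_in, l$n_out))
        l$b <- numeric(l$n_out)
        l$plan <- conv_plan(sizes[i], sizes[i], l$n_in, l$k, l$stride, l$pad)
      } else if (l$type == "linear") {
        D <- (S / 8)^2 * 32
        l$W <- matrix(stats::rnorm(D * n_classes, 0, sqrt(2 / D)), D, n_classes)
        l$b <- numeric(n_classes)
      }
      l
    })
  })
  if (!identical(config$weights_init, "scratch")) {
    if (!file.exists(config$weights_init))
      stop("weights file not found: ", config$weights_init)
    saved <- readRDS(config$weights_init)
    for (i in seq_along(layers)) {
      if (is.null(layers[[i]]$W) || i == length(layers)) next # final layer replaced
      if (!identical(dim(saved[[i]]$W), dim(layers[[i]]$W)))
        stop("saved weights do not match the architecture at layer ", i)
      layers[[i]]$W <- saved[[i]]$W
      layers[[i]]$b <- saved[[i]]$b
    }
  }
  structure(list(layers = layers, config = config, n_classes = n_classes,
                 seed = seed), class = "sb_cnn")
}

# Indices of layers whose parameters are updated.
trainable_layers <- function(model) {
  param <- which(vapply(model$layers, function(l) !is.null(l$W), logical(1)))
  if (model$config$freeze_backbone) utils::tail(param, 1) else param
}

#' Count trainable parameters
#' @param model An `sb_cnn`.
#' @return Number of scalar parameters that training may change.
#' @export
n_trainable_params <- function(model) {
  sum(vapply(trainable_layers(model), function(i)
    length(model$layers[[i]]$W) + length(model$layers[[i]]$b), numeric(1)))
}

predict_logits <- function(model, images, batch = 256) {
  N <- dim(images)[4]
  out <- matrix(0, model$n_classes, N)
  for (s in seq(1, N, by = batch)) {
    idx <- s:min(N, s + batch - 1)
    out[, idx] <- net_forward(model$layers, images[, , , idx, drop = FALSE])$logits
  }
  out
}

#' Predicted classes for images
#' @param model An `sb_cnn` (trained or not).
#' @param images `[S, S, 3, N]` array.
#' @return Integer class labels (ties to the lowest index).
#' @export
cnn_predict <- function(model, images) {
  max.col(t(predict_logits(model, images)), ties.method = "first")
}

#' Train a classifier
#'
#' Minimises softmax cross-entropy with Adam, decaying the learning rate by
#' `plateau_factor` when the epoch loss stops improving, and stopping once
#' the loss has improved by less than `convergence_tol` for
#' `convergence_patience` consecutive epochs (or at `max_epochs`). With
#' `freeze_backbone` only the final layer is updated. Reproducible given
#' `seed`; aborts with a diagnostic if the loss turns non-finite.
#'
#' @param model An `sb_cnn` from [build_classifier()].
#' @param images `[S, S, 3, N]` training images (see [render_dataset()]).
#' @param labels Integer labels in 1..n_classes.
#' @param seed Seed for shuffling (defaults to the model's build seed).
#' @return An object of class `sb_cnn_fit`: the trained model plus a
#'   per-epoch `history` tibble (`epoch`, `loss`, `accuracy`, `lr`),
#'   `converged`, and `train_accuracy` (full-pass accuracy at convergence).
#' @export
train_cnn <- function(model, images, labels, seed = model$seed) {
  cfg <- model$config
  labels <- as.integer(labels)
  N <- dim(images)[4]
  stopifnot(length(labels) == N)
  upd <- trainable_layers(model)
  states <- lapply(model$layers, function(l) {
    if (is.null(l$W)) return(NULL)
    list(m = list(W = array(0, dim = dim(l$W) %||% length(l$W)), b = numeric(length(l$b))),
         v = list(W = array(0, dim = dim(l$W) %||% length(l$W)), b = numeric(length(l$b))))
  })
  lr <- cfg$lr
  history <- list()
  best <- Inf; stall_decay <- 0L; stall_conv <- 0L; tstep <- 0L
  converged <- FALSE
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(mix_seed(seed, 515, epoch), sample.int(N))
    losses <- numeric(0); correct <- 0L
    for (s in seq(1, N, by = cfg$batch_size)) {
      idx <- ord[s:min(N, s + cfg$batch_size - 1)]
      xb <- images[, , , idx, drop = FALSE]
      yb <- labels[idx]
      fw <- net_forward(model$layers, xb)
      ce <- softmax_ce(fw$logits, yb)
      if (!is.finite(ce$loss))
        stop("non-finite loss at epoch ", epoch, "; lr=", lr)
      losses <- c(losses, ce$loss)
      correct <- correct + sum(max.col(t(fw$logits), ties.method = "first") == yb)
      grads <- net_backward(model$layers, fw$caches, ce$dlogits)
      tstep <- tstep + 1L
      for (i in upd) {
        st <- adam_step(model$layers[[i]], grads[[i]], states[[i]], lr, t = tstep)
        model$layers[[i]] <- st$layer
        states[[i]] <- st$state
      }
    }
    epoch_loss <- mean(losses)
    history[[epoch]] <- tibble::tibble(epoch = epoch, loss = epoch_loss,
                                       accuracy = correct / N, lr = lr)
    improved <- best - epoch_loss
    if (epoch_loss < best) best <- epoch_loss
    if (improved < cfg$convergence_tol) {
      stall_conv <- stall_conv + 1L
      stall_decay <- stall_decay + 1L
    } else {
      stall_conv <- 0L; stall_decay <- 0L
    }
    if (stall_conv >= cfg$convergence_patience) { converged <- TRUE; break }
    if (stall_decay >= cfg$plateau_patience) {
      lr <- lr / cfg$plateau_factor
      stall_decay <- 0L
    }
  }
  preds <- cnn_predict(model, images)
  structure(list(layers = model$layers, config = cfg, n_classes = model$n_classes,
                 seed = model$seed, history = dplyr::bind_rows(history),
                 converged = converged, train_accuracy = mean(preds == labels)),
            class = c("sb_cnn_fit", "sb_cnn"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a trained classifier on the four test conditions
#'
#' @param fit A trained `sb_cnn_fit` (or any `sb_cnn`).
#' @param manifest Test-condition manifest rows.
#' @param images Rendered images for `manifest` (same row order).
#' @return A tibble with one row per condition: `condition`, `n`,
#'   `accuracy`, scored with [scored_label()].
#' @export
evaluate_cnn <- function(fit, manifest, images) {
  if (nrow(manifest) != dim(images)[4]) stop("manifest and images disagree")
  conds <- intersect(TEST_CONDITIONS, unique(manifest$condition))
  if (length(conds) == 0) stop("no test conditions in manifest")
  pred <- cnn_predict(fit, images)
  scored <- scored_label(manifest)
  purrr::map_dfr(conds, function(cond) {
    i <- manifest$condition == cond
    tibble::tibble(condition = cond, n = sum(i),
                   accuracy = mean(pred[i] == scored[i]))
  })
}

#' Run the full classifier protocol on one dataset
#'
#' Generates the dataset, renders it at the configured input size, then for
#' each seed builds, trains and evaluates a classifier, reporting
#' per-condition accuracy per seed and the across-seed mean with a
#' normal-approximation 95% confidence half-width.
#'
#' @param experiment,variant Dataset to run.
#' @param config A [train_config()].
#' @param seeds Seeds to average over (default `1:config$n_seeds`).
#' @param n_train,n_test_per_condition Dataset sizes.
#' @param dataset_seed Seed for stimulus generation.
#' @return A list of class `sb_cnn_eval`: `per_seed` (condition accuracies
#'   and training accuracy per seed), `summary` (mean and `ci95` per
#'   condition), and `history` (per-epoch curves per seed).
#' @export
cnn_experiment <- function(experiment, variant, config = train_config(),
                           seeds = seq_len(config$n_seeds),
                           n_train = 2000, n_test_per_condition = 500,
                           dataset_seed = 1) {
  manifest <- generate_dataset(experiment, variant, n_train = n_train,
                               n_test_per_condition = n_test_per_condition,
                               seed = dataset_seed)
  train_rows <- manifest$condition == "train"
  train_m <- manifest[train_rows, ]
  test_m <- manifest[!train_rows, ]
  meta <- manifest_meta(manifest)
  train_x <- render_dataset(train_m, size = config$input_size, meta = meta)
  test_x <- render_dataset(test_m, size = config$input_size, meta = meta)
  runs <- purrr::map(seeds, function(sd) {
    model <- build_classifier(config, n_classes = 5, seed = sd)
    fit <- train_cnn(model, train_x, train_m$label, seed = sd)
    list(eval = dplyr::mutate(evaluate_cnn(fit, test_m, test_x), seed = sd,
                              train_accuracy = fit$train_accuracy),
         history = dplyr::mutate(fit$history, seed = sd))
  })
  per_seed <- purrr::map_dfr(runs, "eval")
  summary <- per_seed |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_seeds = dplyr::n(), mean_accuracy = mean(.data$accuracy),
                     ci95 = ci95(.data$accuracy), .groups = "drop")
  structure(list(experiment = experiment, variant = variant,
                 per_seed = per_seed, summary = summary,
                 history = purrr::map_dfr(runs, "history")),
            class = "sb_cnn_eval")
}

#' @export
print.sb_cnn_eval <- function(x, ...) {
  cat("CNN evaluation:", x$experiment, "variant", x$variant, "\n")
  print(x$summary)
  invisible(x)
}

#' Tidy CNN training history
#' @param x An `sb_cnn_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @export
tidy.sb_cnn_fit <- function(x, ...) x$history

#' @rdname tidy.sb_cnn_fit
#' @return `glance()`: one row with `epochs`, `converged`, `train_accuracy`,
#'   `final_loss`, `final_lr`.
#' @export
glance.sb_cnn_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h), converged = x$converged,
                 train_accuracy = x$train_accuracy,
                 final_loss = h$loss[nrow(h)], final_lr = h$lr[nrow(h)])
}
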