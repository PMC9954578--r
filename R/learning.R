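#' Fixed random feedback pathways
#'
#' Error credit assignment in the hidden layers can use three pathways:
#' \describe{
#'   \item{BP}{exact backpropagation through the transposed forward weights —
#'     no random matrices are needed;}
#'   \item{FA}{feedback alignment — the forward weights in the backward pass
#'     are replaced by fixed random matrices `B_l`, one per connection, with
#'     the same shapes as the forward weights;}
#'   \item{BA}{broadcast alignment (direct feedback alignment) — the output
#'     error is broadcast straight to layer l through a single fixed random
#'     matrix `Bp_l` of shape `H_L x H_l`.}
#' }
#' All feedback matrices are drawn i.i.d. N(0,1) once and never updated
#' during training.
#'
#' @param mode One of `"BP"`, `"FA"`, `"BA"` (case-insensitive).
#' @param layer_sizes Integer vector `H_0, ..., H_L`.
#' @param seed Optional integer seed for the random draw.
#' @return An object of class `feedback_config` with fields `mode`,
#'   `fa_matrices` (`B_l`, indexed like the forward weights; only for FA) and
#'   `ba_matrices` (`Bp_l` for hidden layers l = 1..L-1; only for BA).
#' @export
feedback_config <- function(mode = c("BP", "FA", "BA"), layer_sizes,
                            seed = NULL) {
  mode <- toupper(mode)
  mode <- match.arg(mode, c("BP", "FA", "BA"))
  layer_sizes <- as.integer(layer_sizes)
  L <- length(layer_sizes) - 1L
  fa <- ba <- NULL
  if (mode == "FA") {
    fa <- with_optional_seed(seed, {
      lapply(seq_len(L), function(l) {
        matrix(stats::rnorm(layer_sizes[l + 1L] * layer_sizes[l]),
               nrow = layer_sizes[l + 1L], ncol = layer_sizes[l])
      })
    })
  } else if (mode == "BA") {
    HL <- layer_sizes[L + 1L]
    ba <- with_optional_seed(seed, {
      lapply(seq_len(L - 1L), function(l) {
        matrix(stats::rnorm(HL * layer_sizes[l + 1L]),
               nrow = HL, ncol = layer_sizes[l + 1L])
      })
    })
  }
  structure(list(mode = mode, fa_matrices = fa, ba_matrices = ba),
            class = "feedback_config")
}

#' @export
print.feedback_config <- function(x, ...) {
  cat(sprintf("<feedback_config> mode %s\n", x$mode))
  invisible(x)
}

#' Training configuration
#'
#' @param learning_rate Positive step size eta. Default 0.00008, the
#'   full-scale image-classification setting; small networks want larger
#'   values (the synthetic task uses 1e-3).
#' @param batch_size Mini-batch size (>= 1). Default 64.
#' @param epochs Number of passes over the training set. Default 150.
#' @param kernel A [kernel_spec] used for all STIP computations.
#' @param interval_end,dt Simulation interval and step in ms.
#' @param target_spikes Spikes per target train (default: one per step).
#' @param frozen_encoding If `TRUE`, inputs are Poisson-encoded once and
#'   reused every epoch; default `FALSE` re-draws the encoding at every
#'   presentation.
#' @param early_stop_acc Optional accuracy level (fraction in \[0,1\]) at
#'   which training stops early; measured on the test split when one is
#'   given, on the training pass otherwise.
#' @param guard Abort threshold on `max(abs(W))`; non-finite weights always
#'   abort. Default `1e8`.
#' @param divergence `"error"` to raise an error naming the epoch and layer,
#'   `"stop"` to truncate training with a warning and return the record so
#'   far.
#' @param seed Integer seed controlling encoding draws and batch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.00008, batch_size = 64,
                         epochs = 150, kernel = kernel_spec("gaussian", 40),
                         interval_end = 10, dt = 1, target_spikes = NULL,
                         frozen_encoding = FALSE, early_stop_acc = NULL,
                         guard = 1e8, divergence = c("error", "stop"),
                         seed = 1L) {
  if (learning_rate <= 0) stop("`learning_rate` must be positive", call. = FALSE)
  if (batch_size < 1) stop("`batch_size` must be >= 1", call. = FALSE)
  if (epochs < 0) stop("`epochs` must be >= 0", call. = FALSE)
  stopifnot(inherits(kernel, "kernel_spec"))
  divergence <- match.arg(divergence)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), kernel = kernel,
                 interval_end = interval_end, dt = dt,
                 target_spikes = target_spikes,
                 frozen_encoding = isTRUE(frozen_encoding),
                 early_stop_acc = early_stop_acc, guard = guard,
                 divergence = divergence, seed = as.integer(seed)),
            class = "train_config")
}

# Shared error factor of all three rules: the STIP-matrix difference
# F(actual, prev) - F(desired, prev).
stip_error_term <- function(actual, desired, prev_layer, spec) {
  stip_matrix(actual, prev_layer, spec) - stip_matrix(desired, prev_layer, spec)
}

# Transposed pathway product t(M_L %*% ... %*% M_{l+1}), accumulated
# right-to-left.
path_transpose <- function(mats, l) {
  L <- length(mats)
  P <- t(mats[[L]])
  if (L - 1L >= l + 1L) {
    for (j in seq(L - 1L, l + 1L)) P <- t(mats[[j]]) %*% P
  }
  P
}

#' Output-layer weight update
#'
#' The update for the weights between the last hidden layer and the output
#' layer, shared by all three feedback modes:
#' `dW_L = -eta * (F(actual, hidden) - F(desired, hidden))`, where F is the
#' STIP matrix between layers.
#'
#' @param actual,desired Output-layer [spike_train_set]s (actual firing and
#'   target).
#' @param last_hidden [spike_train_set] of the last hidden layer.
#' @param spec A [kernel_spec].
#' @param eta Learning rate.
#' @return An `H_L x H_{L-1}` update matrix (to be added to `W_L`).
#' @export
output_delta <- function(actual, desired, last_hidden, spec, eta) {
  if (actual$layer_size != desired$layer_size) {
    stop("`actual` and `desired` must have the same size", call. = FALSE)
  }
  -eta * stip_error_term(actual, desired, last_hidden, spec)
}

#' Hidden-layer update under exact backpropagation
#'
#' The update for `W_l` (1 <= l <= L-1) propagates the output error through
#' the transposed product of the downstream forward weights:
#' `dW_l = -eta * t(W_L ... W_{l+1}) %*% (F(actual, prev) - F(desired, prev))`.
#'
#' @param l Hidden-layer index (1-based; 1 is the first hidden layer).
#' @param actual,desired Output-layer [spike_train_set]s.
#' @param prev_layer [spike_train_set] of layer l-1 (the presynaptic layer;
#'   layer 0 is the input).
#' @param weights List of all forward weight matrices `W_1..W_L`.
#' @param spec A [kernel_spec].
#' @param eta Learning rate.
#' @return An `H_l x H_{l-1}` update matrix.
#' @export
bp_hidden_delta <- function(l, actual, desired, prev_layer, weights, spec, eta) {
  L <- length(weights)
  if (l < 1 || l > L - 1) stop("`l` must be a hidden-layer index", call. = FALSE)
  -eta * path_transpose(weights, l) %*%
    stip_error_term(actual, desired, prev_layer, spec)
}

#' Hidden-layer update under feedback alignment
#'
#' As [bp_hidden_delta()], but the backward pathway uses the fixed random
#' feedback matrices `B_l` instead of the forward weights:
#' `dW_l = -eta * t(B_L ... B_{l+1}) %*% (F(actual, prev) - F(desired, prev))`.
#' Setting every `B_l = W_l` reproduces the backpropagation update exactly.
#'
#' @inheritParams bp_hidden_delta
#' @param feedback A [feedback_config] with `mode = "FA"`.
#' @return An `H_l x H_{l-1}` update matrix.
#' @export
fa_hidden_delta <- function(l, actual, desired, prev_layer, feedback, spec, eta) {
  stopifnot(inherits(feedback, "feedback_config"))
  if (feedback$mode != "FA") stop("feedback mode must be FA", call. = FALSE)
  L <- length(feedback$fa_matrices)
  if (l < 1 || l > L - 1) stop("`l` must be a hidden-layer index", call. = FALSE)
  -eta * path_transpose(feedback$fa_matrices, l) %*%
    stip_error_term(actual, desired, prev_layer, spec)
}

#' Hidden-layer update under broadcast alignment
#'
#' The output error is broadcast directly to layer l through the single fixed
#' random matrix `Bp_l` (shape `H_L x H_l`):
#' `dW_l = -eta * t(Bp_l) %*% (F(actual, prev) - F(desired, prev))`.
#' The update is local: it involves no other layer's weights, only the output
#' error and the presynaptic spikes — a three-factor plasticity rule.
#'
#' @inheritParams fa_hidden_delta
#' @param feedback A [feedback_config] with `mode = "BA"`.
#' @return An `H_l x H_{l-1}` update matrix.
#' @export
ba_hidden_delta <- function(l, actual, desired, prev_layer, feedback, spec, eta) {
  stopifnot(inherits(feedback, "feedback_config"))
  if (feedback$mode != "BA") stop("feedback mode must be BA", call. = FALSE)
  if (l < 1 || l > length(feedback$ba_matrices)) {
    stop("`l` must be a hidden-layer index", call. = FALSE)
  }
  -eta * t(feedback$ba_matrices[[l]]) %*%
    stip_error_term(actual, desired, prev_layer, spec)
}

#' Train a spiking network with STIP-based updates
#'
#' Mini-batch training loop. Per batch: each sample's intensity vector is
#' Poisson-encoded (a fresh draw per presentation unless
#' `cfg$frozen_encoding`), the LIF network is simulated, and the per-layer
#' weight updates are computed from the same pre-update weights under the
#' configured feedback mode ([output_delta()] for the output layer in all
#' modes). Updates are averaged over the batch and applied synchronously.
#' Per epoch the mean training RKHS error, the training accuracy and (when a
#' test split is given) the test accuracy are recorded.
#'
#' @param dataset A list with elements `train` and optionally `test`, each a
#'   list with `x` (samples x input_dim intensity matrix, values in \[0,1\])
#'   and `y` (integer labels, 0-based) — the format produced by
#'   [make_task()].
#' @param net A [network_config] (e.g. from [init_weights()]).
#' @param feedback A [feedback_config].
#' @param cfg A [train_config].
#' @return A list with `net` (trained [network_config]) and `record`, a
#'   data.frame with columns `epoch`, `train_loss`, `train_acc`, `test_acc`
#'   (NA when no test split), one row per completed epoch; the attribute
#'   `"diverged"` carries the epoch/layer when training was truncated.
#' @examples
#' task <- make_task(synthetic_task_spec(seed = 1))
#' net <- init_weights(c(20, 30, 30, 3), seed = 1)
#' fb <- feedback_config("BA", c(20, 30, 30, 3), seed = 2)
#' cfg <- train_config(learning_rate = 1e-3, epochs = 2, seed = 3)
#' fit <- train_snn(task, net, fb, cfg)
#' @export
train_snn <- function(dataset, net, feedback, cfg) {
  stopifnot(inherits(net, "network_config"),
            inherits(feedback, "feedback_config"),
            inherits(cfg, "train_config"))
  train <- dataset$train
  if (is.null(train) || !nrow(train$x)) stop("empty training set", call. = FALSE)
  if (!is.null(dataset$test) && !nrow(dataset$test$x)) dataset$test <- NULL
  sizes <- net$layer_sizes
  L <- length(net$weights)
  n_classes <- sizes[L + 1L]
  eta <- cfg$learning_rate
  K <- grid_gram(cfg$kernel, cfg$interval_end, cfg$dt)
  n_steps <- nrow(K)
  tmpl <- label_templates(n_classes, cfg$interval_end, cfg$dt, cfg$target_spikes)
  tmpl_steps <- lapply(tmpl, set_to_steps, dt = cfg$dt)
  weights <- net$weights
  net$lif$dt <- cfg$dt

  set.seed(cfg$seed)
  frozen_train <- frozen_test <- NULL
  if (cfg$frozen_encoding) {
    frozen_train <- poisson_encode_batch(train$x, cfg$interval_end, cfg$dt)
    if (!is.null(dataset$test)) {
      frozen_test <- poisson_encode_batch(dataset$test$x, cfg$interval_end, cfg$dt)
    }
  }

  rec <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    train_acc = numeric(0), test_acc = numeric(0))
  diverged <- NULL
  n_train <- nrow(train$x)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n_train)
    loss_sum <- 0
    correct <- 0L
    for (start in seq(1, n_train, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n_train)]
      B <- length(idx)
      arr0 <- if (cfg$frozen_encoding) frozen_train[, , idx, drop = FALSE]
              else poisson_encode_batch(train$x[idx, , drop = FALSE],
                                        cfg$interval_end, cfg$dt)
      cur <- network_config(sizes, weights, net$lif)
      fwd <- lif_forward_batch(arr0, cur)$spikes
      delta <- lapply(weights, function(w) matrix(0, nrow(w), ncol(w)))
      paths <- backward_paths(weights, feedback, L)
      for (b in seq_len(B)) {
        A <- matrix(fwd[[L]][, , b], nrow = n_classes)
        D <- tmpl_steps[[train$y[idx[b]] + 1L]]
        RK <- (A - D) %*% K   # n_classes x n_steps
        loss_sum <- loss_sum + rkhs_error_steps(A, D, K)
        dist <- vapply(tmpl_steps, function(Tc) rkhs_error_steps(A, Tc, K),
                       numeric(1))
        if (which.min(dist) - 1L == train$y[idx[b]]) correct <- correct + 1L
        for (l in seq_len(L)) {
          prev <- if (l == 1L) matrix(arr0[, , b], ncol = n_steps)
                  else matrix(fwd[[l - 1L]][, , b], ncol = n_steps)
          err <- RK %*% t(prev) # F(actual, prev) - F(desired, prev)
          delta[[l]] <- delta[[l]] +
            if (l == L) -eta * err else -eta * paths[[l]] %*% err
        }
      }
      for (l in seq_len(L)) weights[[l]] <- weights[[l]] + delta[[l]] / B
      bad <- which(vapply(weights, function(w) {
        any(!is.finite(w)) || max(abs(w)) > cfg$guard
      }, logical(1)))
      if (length(bad)) {
        msg <- sprintf("weights diverged at epoch %d, layer %d", epoch, bad[1L])
        if (cfg$divergence == "error") stop(msg, call. = FALSE)
        warning(paste0(msg, "; training truncated"), call. = FALSE)
        diverged <- list(epoch = epoch, layer = bad[1L])
        break
      }
    }
    if (!is.null(diverged)) break
    trained <- network_config(sizes, weights, net$lif)
    test_acc <- NA_real_
    if (!is.null(dataset$test)) {
      arr_t <- if (cfg$frozen_encoding) frozen_test
               else poisson_encode_batch(dataset$test$x, cfg$interval_end, cfg$dt)
      test_acc <- accuracy_on_steps(arr_t, dataset$test$y, trained, tmpl_steps, K)
    }
    rec <- rbind(rec, data.frame(epoch = epoch, train_loss = loss_sum / n_train,
                                 train_acc = correct / n_train,
                                 test_acc = test_acc))
    stop_metric <- if (is.na(test_acc)) correct / n_train else test_acc
    if (!is.null(cfg$early_stop_acc) && stop_metric >= cfg$early_stop_acc) break
  }
  out_net <- network_config(sizes, weights, net$lif)
  attr(rec, "diverged") <- diverged
  list(net = out_net, record = rec)
}

# Pathway factors for the hidden layers 1..L-1 under the configured mode.
backward_paths <- function(weights, feedback, L) {
  if (L < 2L) return(list())
  mats <- switch(feedback$mode,
    BP = weights,
    FA = feedback$fa_matrices,
    BA = NULL)
  lapply(seq_len(L - 1L), function(l) {
    if (feedback$mode == "BA") t(feedback$ba_matrices[[l]])
    else path_transpose(mats, l)
  })
}

# Classification accuracy for an encoded batch (internal fast path).
accuracy_on_steps <- function(arr0, y, net, tmpl_steps, K) {
  fwd <- lif_forward_batch(arr0, net)$spikes
  outL <- fwd[[length(fwd)]]
  n_classes <- dim(outL)[1]
  B <- dim(outL)[3]
  correct <- 0L
  for (b in seq_len(B)) {
    A <- matrix(outL[, , b], nrow = n_classes)
    dist <- vapply(tmpl_steps, function(Tc) rkhs_error_steps(A, Tc, K),
                   numeric(1))
    if (which.min(dist) - 1L == y[b]) correct <- correct + 1L
  }
  correct / B
}

#' Classification accuracy of a trained network
#'
#' Encodes the samples, simulates the network and decodes the output trains
#' with [classify_spikes()] against the label templates.
#'
#' @param split A list with `x` (intensity matrix) and `y` (0-based labels).
#' @param net A [network_config].
#' @param kernel A [kernel_spec].
#' @param interval_end,dt Simulation interval and step in ms.
#' @param target_spikes Spikes per target train (default one per step).
#' @param seed Optional seed for the encoding draw.
#' @return Fraction of correctly classified samples.
#' @export
evaluate_accuracy <- function(split, net, kernel = kernel_spec("gaussian", 40),
                              interval_end = 10, dt = 1, target_spikes = NULL,
                              seed = NULL) {
  n_classes <- net$layer_sizes[length(net$layer_sizes)]
  K <- grid_gram(kernel, interval_end, dt)
  tmpl <- label_templates(n_classes, interval_end, dt, target_spikes)
  tmpl_steps <- lapply(tmpl, set_to_steps, dt = dt)
  net$lif$dt <- dt
  arr0 <- with_optional_seed(seed,
    poisson_encode_batch(split$x, interval_end, dt))
  accuracy_on_steps(arr0, split$y, net, tmpl_steps, K)
}
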