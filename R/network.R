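#' Leaky integrate-and-fire neuron parameters
#'
#' Single-state LIF dynamics on a fixed step grid: between steps the membrane
#' potential decays as `V <- V * exp(-dt / tau)`; incoming spikes add their
#' synaptic weights instantaneously (delta synapses); when V reaches
#' `threshold` the neuron emits a spike at that step's time and V is hard-reset
#' to `reset`. There is no refractory period and no bias current.
#'
#' @param tau Membrane time constant in ms (> 0). Default 5.
#' @param threshold Firing threshold (dimensionless potential). Default 5.
#' @param reset Reset (and resting/initial) potential; must be below
#'   `threshold`. Default 0.
#' @param dt Simulation step in ms (> 0). Default 1.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(tau = 5, threshold = 5, reset = 0, dt = 1) {
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (threshold <= reset) stop("`threshold` must exceed `reset`", call. = FALSE)
  structure(list(tau = tau, threshold = threshold, reset = reset, dt = dt),
            class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat(sprintf("<lif_params> tau %g ms, threshold %g, reset %g, dt %g ms\n",
              x$tau, x$threshold, x$reset, x$dt))
  invisible(x)
}

#' Assemble a feedforward network configuration
#'
#' Layers are numbered from the input (layer 0) to the output (layer L);
#' `weights[[l]]` is the `H_l x H_{l-1}` synaptic matrix feeding layer l.
#'
#' @param layer_sizes Integer vector `H_0, ..., H_L` (at least one hidden
#'   layer, so length >= 3).
#' @param weights List of L numeric matrices with shapes consistent with
#'   `layer_sizes`.
#' @param lif A [lif_params] object.
#' @return An object of class `network_config`.
#' @export
network_config <- function(layer_sizes, weights, lif = lif_params()) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 3L) {
    stop("need at least one hidden layer (length(layer_sizes) >= 3)",
         call. = FALSE)
  }
  if (length(weights) != length(layer_sizes) - 1L) {
    stop("need one weight matrix per connection", call. = FALSE)
  }
  for (l in seq_along(weights)) {
    dm <- dim(weights[[l]])
    if (is.null(dm) || dm[1] != layer_sizes[l + 1L] || dm[2] != layer_sizes[l]) {
      stop(sprintf("weights[[%d]] must be %d x %d", l,
                   layer_sizes[l + 1L], layer_sizes[l]), call. = FALSE)
    }
  }
  structure(list(layer_sizes = layer_sizes, weights = weights, lif = lif),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> layers %s\n",
              paste(x$layer_sizes, collapse = "-")))
  print(x$lif)
  invisible(x)
}

#' Randomly initialize network weights
#'
#' Draws every synaptic weight i.i.d. from N(0, `scale`^2); the default
#' `scale = 1` is standard-normal initialization.
#'
#' @inheritParams network_config
#' @param seed Optional integer seed for a reproducible draw (the caller's
#'   RNG stream is left untouched when given).
#' @param scale Standard deviation of the weight distribution.
#' @return A [network_config].
#' @examples
#' net <- init_weights(c(20, 30, 30, 3), seed = 1)
#' @export
init_weights <- function(layer_sizes, seed = NULL, scale = 1,
                         lif = lif_params()) {
  layer_sizes <- as.integer(layer_sizes)
  weights <- with_optional_seed(seed, {
    lapply(seq_len(length(layer_sizes) - 1L), function(l) {
      matrix(stats::rnorm(layer_sizes[l + 1L] * layer_sizes[l], sd = scale),
             nrow = layer_sizes[l + 1L], ncol = layer_sizes[l])
    })
  })
  network_config(layer_sizes, weights, lif)
}

#' Simulate the LIF network on input spike trains
#'
#' Clock-driven simulation: at every step each neuron first decays its
#' membrane potential, then adds the weighted spikes arriving from the
#' presynaptic layer at this step, then fires (and hard-resets) if the
#' potential reached threshold. Spikes propagate to the next layer within the
#' same step. Input spikes must lie on the step grid `0, dt, ..., T - dt`.
#'
#' @param inputs A [spike_train_set] with `H_0` trains.
#' @param net A [network_config].
#' @param record_potential If `TRUE`, also return the per-step membrane
#'   potentials of every layer (after decay+input, before reset), as matrices
#'   `H_l x n_steps`.
#' @return A list of [spike_train_set]s, one per layer 1..L (hidden layers
#'   first, output layer last). With `record_potential = TRUE`, a list with
#'   fields `spikes` and `potentials`.
#' @examples
#' net <- init_weights(c(3, 4, 2), seed = 1)
#' inp <- poisson_encode(c(1, 0.5, 0), 10, 1, seed = 2)
#' lif_forward(inp, net)
#' @export
lif_forward <- function(inputs, net, record_potential = FALSE) {
  stopifnot(inherits(inputs, "spike_train_set"),
            inherits(net, "network_config"))
  if (inputs$layer_size != net$layer_sizes[1L]) {
    stop("input size does not match the network's input layer", call. = FALSE)
  }
  dt <- net$lif$dt
  s0 <- set_to_steps(inputs, dt) # errors on off-grid times
  arr0 <- array(s0, dim = c(dim(s0), 1L))
  res <- lif_forward_batch(arr0, net, record_potential = record_potential)
  spikes <- lapply(res$spikes, function(a) {
    steps_to_set(matrix(a, nrow = dim(a)[1]), inputs$interval_end, dt)
  })
  if (record_potential) {
    pots <- lapply(res$potentials, function(a) matrix(a, nrow = dim(a)[1]))
    list(spikes = spikes, potentials = pots)
  } else {
    spikes
  }
}

# Batched clock-driven simulation on binary arrays.
# arr0: H_0 x n_steps x B input spike array. Returns per-layer spike arrays
# (and optionally potentials) with the same step/batch layout.
lif_forward_batch <- function(arr0, net, record_potential = FALSE) {
  lif <- net$lif
  decay <- exp(-lif$dt / lif$tau)
  n <- dim(arr0)[2]
  B <- dim(arr0)[3]
  L <- length(net$weights)
  spikes <- vector("list", L)
  pots <- if (record_potential) vector("list", L) else NULL
  prev <- arr0
  for (l in seq_len(L)) {
    W <- net$weights[[l]]
    H <- nrow(W)
    V <- matrix(lif$reset, nrow = H, ncol = B)
    out <- array(0, dim = c(H, n, B))
    if (record_potential) pv <- array(0, dim = c(H, n, B))
    for (k in seq_len(n)) {
      V <- V * decay + W %*% matrix(prev[, k, ], nrow = dim(prev)[1], ncol = B)
      if (record_potential) pv[, k, ] <- V
      fired <- V >= lif$threshold
      if (any(fired)) {
        out[, k, ][fired] <- 1
        V[fired] <- lif$reset
      }
    }
    spikes[[l]] <- out
    if (record_potential) pots[[l]] <- pv
    prev <- out
  }
  list(spikes = spikes, potentials = pots)
}
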