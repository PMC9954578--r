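# Independent oracles shared across the test files. Everything here is
# deliberately written the slow, obvious way (explicit loops, closed forms,
# numerical quadrature) and never calls the package's vectorized paths.

# Closed-form kernel expressions, restated independently of kernel_eval().
ref_kernel <- function(family, param) {
  switch(family,
    gaussian  = function(x, y) exp(-(x - y)^2 / (2 * param^2)),
    laplacian = function(x, y) exp(-abs(x - y) / param),
    inverse_multiquadratic = function(x, y) 1 / sqrt((x - y)^2 + param^2),
    alpha     = function(x, y) (abs(x - y) / param) * exp(-abs(x - y) / param))
}

# Explicit nested double loop over spike pairs.
stip_loop <- function(a, b, kfun) {
  s <- 0
  for (tm in a$times) for (tn in b$times) s <- s + kfun(tm, tn)
  s
}

rand_train <- function(n_max = 10, interval_end = 10) {
  n <- sample.int(n_max + 1L, 1L) - 1L
  spike_train(sort(runif(n, 0, interval_end)), interval_end)
}

rand_set <- function(n_neurons, n_max = 10, interval_end = 10) {
  spike_train_set(replicate(n_neurons, rand_train(n_max, interval_end),
                            simplify = FALSE))
}

# --- quadrature machinery for the gaussian kernel ---------------------------
# The smoothing filter phi reproducing kappa(d) = exp(-d^2 / (2 sigma^2)) as
# phi * phi over the real line is the Gaussian with sd sigma/sqrt(2) and
# amplitude (s * sqrt(pi))^(-1/2).

quad_grid <- function(interval_end, sigma, step_frac = 40) {
  s <- sigma / sqrt(2)
  seq(-8 * s, interval_end + 8 * s, by = s / step_frac)
}

# Matrix of smoothed signals: one row per train, evaluated on the grid.
smoothed_signals <- function(set, sigma, tg) {
  s <- sigma / sqrt(2)
  amp <- (s * sqrt(pi))^(-1 / 2)
  out <- matrix(0, nrow = set$layer_size, ncol = length(tg))
  for (i in seq_len(set$layer_size)) {
    for (tt in set$trains[[i]]$times) {
      out[i, ] <- out[i, ] + amp * exp(-(tg - tt)^2 / (2 * s^2))
    }
  }
  out
}

trapz_ref <- function(tg, y) pracma::trapz(tg, y)

# Quadrature evaluation of the squared-distance error integral.
quad_rkhs_error <- function(actual, desired, sigma) {
  tg <- quad_grid(actual$interval_end, sigma)
  ha <- smoothed_signals(actual, sigma, tg)
  hd <- smoothed_signals(desired, sigma, tg)
  trapz_ref(tg, colSums((ha - hd)^2)) / 2
}

# Quadrature evaluation of the linear-surrogate network error
# E(W) = 1/2 integral || (W_L ... W_1) h_0(t) - h_d(t) ||^2 dt.
surrogate_error <- function(weights, input, desired, sigma) {
  tg <- quad_grid(input$interval_end, sigma)
  h0 <- smoothed_signals(input, sigma, tg)
  hd <- smoothed_signals(desired, sigma, tg)
  M <- Reduce(`%*%`, rev(weights))
  trapz_ref(tg, colSums((M %*% h0 - hd)^2)) / 2
}

# Central finite differences of f over the entries of matrix M.
fd_grad <- function(f, M, h = 1e-4) {
  g <- M
  for (i in seq_along(M)) {
    Mp <- M; Mp[i] <- M[i] + h
    Mm <- M; Mm[i] <- M[i] - h
    g[i] <- (f(Mp) - f(Mm)) / (2 * h)
  }
  g
}

# --- linear-consistent random network fixtures ------------------------------
# Forward matrices with 0/1 entries make every downstream train the literal
# merge of its selected presynaptic trains, so the linear spike-train
# relation h_l = W_l h_{l-1} holds exactly for genuine spike trains. Spike
# times are drawn globally distinct so merges never collide.

merge_trains <- function(trains, interval_end) {
  spike_train(sort(unlist(lapply(trains, `[[`, "times"))), interval_end)
}

propagate_merge <- function(input, weights) {
  layers <- list()
  prev <- input
  for (l in seq_along(weights)) {
    W <- weights[[l]]
    trains <- lapply(seq_len(nrow(W)), function(i) {
      merge_trains(prev$trains[W[i, ] > 0], input$interval_end)
    })
    prev <- spike_train_set(trains, interval_end = input$interval_end)
    layers[[l]] <- prev
  }
  layers
}

# Random instance with sizes (3, 4, 2): distinct input times, 0/1 forward
# matrices, arbitrary desired trains.
rand_linear_instance <- function(interval_end = 10, max_spikes = 3) {
  sizes <- c(3, 4, 2)
  pool <- sample(seq(0.05, interval_end - 0.05, by = 0.05))
  counts <- sample.int(max_spikes + 1L, sizes[1], replace = TRUE) - 1L
  taken <- 0
  trains <- lapply(counts, function(n) {
    tt <- sort(pool[taken + seq_len(n)])
    taken <<- taken + n
    spike_train(tt, interval_end)
  })
  input <- spike_train_set(trains, interval_end = interval_end)
  # reject draws whose end-to-end selection count exceeds 1: those would merge
  # the same input train into one output twice (a duplicate spike time)
  repeat {
    weights <- list(
      matrix(rbinom(sizes[2] * sizes[1], 1, 0.5), sizes[2], sizes[1]),
      matrix(rbinom(sizes[3] * sizes[2], 1, 0.5), sizes[3], sizes[2]))
    if (max(weights[[2]] %*% weights[[1]]) <= 1) break
  }
  layers <- propagate_merge(input, weights)
  desired <- rand_set(sizes[3], n_max = max_spikes, interval_end = interval_end)
  list(input = input, weights = weights, hidden = layers[[1]],
       output = layers[[2]], desired = desired)
}

relative_max_err <- function(got, want) {
  max(abs(got - want)) / max(max(abs(want)), 1e-12)
}
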