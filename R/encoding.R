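#' Poisson-encode an intensity vector into spike trains
#'
#' Clock-driven Poisson rate coding: for each component of `values` and each
#' simulation step, an independent Bernoulli draw with success probability
#' equal to the component's intensity decides whether a spike is placed at
#' that step's time. Intensity 0 yields a silent train, intensity 1 a spike
#' at every step (one spike per step is the maximum rate).
#'
#' @param values Numeric vector of intensities in \[0, 1\] (one per input
#'   neuron).
#' @param interval_end Simulation interval T in ms.
#' @param dt Step size in ms; must divide `interval_end` exactly.
#' @param seed Optional integer; when given, the draw is made deterministic
#'   without disturbing the caller's RNG stream. When `NULL`, the current RNG
#'   stream is used (and advanced).
#' @return A [spike_train_set] with `length(values)` trains whose spikes lie
#'   on the step grid `0, dt, ..., T - dt`.
#' @examples
#' poisson_encode(c(0, 0.5, 1), interval_end = 10, dt = 1, seed = 1)
#' @export
poisson_encode <- function(values, interval_end = 10, dt = 1, seed = NULL) {
  values <- as.numeric(values)
  if (anyNA(values) || any(values < 0 | values > 1)) {
    stop("intensities must lie in [0, 1]", call. = FALSE)
  }
  n <- as.integer(round(interval_end / dt))
  grid_times(interval_end, dt) # validates divisibility
  mat <- with_optional_seed(seed, {
    matrix(stats::runif(length(values) * n) < rep(values, times = n),
           nrow = length(values), ncol = n)
  })
  steps_to_set(mat * 1, interval_end, dt)
}

# Batched encoder used by the trainer: x is a samples x dim intensity matrix;
# returns a dim x n_steps x n_samples binary array.
poisson_encode_batch <- function(x, interval_end, dt) {
  n <- as.integer(round(interval_end / dt))
  d <- ncol(x)
  b <- nrow(x)
  p <- aperm(array(t(x), dim = c(d, b, n)), c(1, 3, 2)) # d x n x b
  array(stats::runif(d * n * b) < p, dim = c(d, n, b)) * 1
}

#' Encode a class label as target spike trains
#'
#' One-hot temporal extension of a label: the target neuron fires evenly
#' across the simulation interval while every other output neuron stays
#' silent. "Evenly" defaults to one spike per simulation step; a smaller
#' `n_spikes` places that many spikes at evenly spaced grid steps.
#'
#' @param label Integer class index in `0:(n_classes - 1)`.
#' @param n_classes Number of classes (output neurons).
#' @param interval_end,dt Simulation interval and step in ms.
#' @param n_spikes Number of spikes for the target neuron; default one per
#'   step.
#' @return A [spike_train_set] with `n_classes` trains.
#' @examples
#' encode_label(3, n_classes = 10)
#' @export
encode_label <- function(label, n_classes, interval_end = 10, dt = 1,
                         n_spikes = NULL) {
  label <- as.integer(label)
  if (length(label) != 1L || is.na(label) || label < 0 || label >= n_classes) {
    stop("`label` must satisfy 0 <= label < n_classes", call. = FALSE)
  }
  tg <- grid_times(interval_end, dt)
  if (is.null(n_spikes)) n_spikes <- length(tg)
  if (n_spikes < 1 || n_spikes > length(tg)) {
    stop("`n_spikes` must be between 1 and the number of steps", call. = FALSE)
  }
  idx <- unique(round(seq(1, length(tg), length.out = n_spikes)))
  trains <- replicate(n_classes, spike_train(numeric(0), interval_end),
                      simplify = FALSE)
  trains[[label + 1L]] <- spike_train(tg[idx], interval_end)
  spike_train_set(trains, interval_end = interval_end)
}

#' Target templates for every class
#'
#' @param n_classes Number of classes.
#' @inheritParams encode_label
#' @return A list of `n_classes` [spike_train_set] templates,
#'   `templates[[c + 1]]` being the target for class `c`.
#' @export
label_templates <- function(n_classes, interval_end = 10, dt = 1,
                            n_spikes = NULL) {
  lapply(seq_len(n_classes) - 1L, encode_label, n_classes = n_classes,
         interval_end = interval_end, dt = dt, n_spikes = n_spikes)
}

#' Classify output spike trains against class templates
#'
#' Softmax-like decoding: the RKHS error between the output trains and each
#' class's target template is computed, the class with the smallest distance
#' wins (ties go to the lowest class index), and `softmax(-distance)` is
#' reported as a score vector.
#'
#' @param output A [spike_train_set] from the network's output layer.
#' @param templates List of per-class target [spike_train_set]s, e.g. from
#'   [label_templates()].
#' @param spec A [kernel_spec].
#' @return A list with `class` (0-based predicted label), `distances`
#'   (per-class RKHS errors) and `scores` (softmax of the negated distances,
#'   summing to 1).
#' @export
classify_spikes <- function(output, templates, spec) {
  d <- vapply(templates, function(tp) rkhs_error(output, tp, spec), numeric(1))
  list(class = which.min(d) - 1L, distances = d, scores = softmax(-d))
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
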