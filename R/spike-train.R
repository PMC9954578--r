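#' Construct a spike train
#'
#' A spike train is the ordered set of firing times of one neuron over a
#' simulation interval \[0, T\]. It is the universal information carrier in
#' this package: inputs, hidden activity, outputs and classification targets
#' are all spike trains. The empty train (a silent neuron) is valid.
#'
#' @param times Numeric vector of spike times in milliseconds, strictly
#'   increasing, all within \[0, `interval_end`\]. May be empty.
#' @param interval_end Duration T of the simulation interval in milliseconds.
#' @return An object of class `spike_train`.
#' @examples
#' spike_train(c(1, 4, 8.5), interval_end = 10)
#' spike_train(numeric(0), interval_end = 10) # a silent neuron
#' @export
spike_train <- function(times, interval_end) {
  times <- as.numeric(times)
  interval_end <- as.numeric(interval_end)
  if (length(interval_end) != 1L || !is.finite(interval_end) || interval_end <= 0) {
    stop("`interval_end` must be a single positive number (ms)", call. = FALSE)
  }
  if (anyNA(times) || any(!is.finite(times))) {
    stop("spike times must be finite", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  if (length(times) && (times[1L] < 0 || times[length(times)] > interval_end)) {
    stop("spike times must lie in [0, interval_end]", call. = FALSE)
  }
  structure(list(times = times, interval_end = interval_end),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<spike_train> %d spike%s over [0, %g] ms\n",
              n, if (n == 1L) "" else "s", x$interval_end))
  if (n) cat(" ", paste(signif(x$times, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a set of spike trains for one layer
#'
#' Bundles one spike train per neuron of a network layer. All trains must
#' share the same simulation interval.
#'
#' @param trains List of [spike_train] objects (or numeric vectors of spike
#'   times, which are promoted using `interval_end`).
#' @param interval_end Simulation interval end in ms; required when any
#'   element of `trains` is a bare numeric vector, otherwise inferred.
#' @return An object of class `spike_train_set` with fields `trains`,
#'   `layer_size` and `interval_end`.
#' @examples
#' spike_train_set(list(c(1, 2), numeric(0), 5), interval_end = 10)
#' @export
spike_train_set <- function(trains, interval_end = NULL) {
  if (!is.list(trains)) stop("`trains` must be a list", call. = FALSE)
  trains <- lapply(trains, function(tr) {
    if (inherits(tr, "spike_train")) return(tr)
    if (is.null(interval_end)) {
      stop("`interval_end` is required when trains are bare numeric vectors",
           call. = FALSE)
    }
    spike_train(tr, interval_end)
  })
  ends <- vapply(trains, function(tr) tr$interval_end, numeric(1))
  if (length(ends) == 0L) {
    if (is.null(interval_end)) {
      stop("an empty set needs an explicit `interval_end`", call. = FALSE)
    }
    end <- as.numeric(interval_end)
  } else {
    end <- ends[1L]
    if (any(abs(ends - end) > 1e-9)) {
      stop("all trains in a set must share the same interval_end", call. = FALSE)
    }
    if (!is.null(interval_end) && abs(end - interval_end) > 1e-9) {
      stop("`interval_end` disagrees with the trains' interval", call. = FALSE)
    }
  }
  structure(list(trains = trains, layer_size = length(trains),
                 interval_end = end),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  counts <- vapply(x$trains, function(tr) length(tr$times), integer(1))
  cat(sprintf("<spike_train_set> %d neurons over [0, %g] ms, %d spikes total\n",
              x$layer_size, x$interval_end, sum(counts)))
  invisible(x)
}

#' Total spike count of a train set
#'
#' @param x A [spike_train_set].
#' @return Integer vector of per-neuron spike counts.
#' @export
spike_counts <- function(x) {
  stopifnot(inherits(x, "spike_train_set"))
  vapply(x$trains, function(tr) length(tr$times), integer(1))
}

# ---- grid helpers (internal) -------------------------------------------------
# The clock-driven simulator and the encoders place every spike on the grid
# t_k = (k-1)*dt, k = 1..n_steps, with n_steps*dt = interval_end.

grid_times <- function(interval_end, dt) {
  n <- interval_end / dt
  if (abs(n - round(n)) > 1e-9) {
    stop("`dt` must divide `interval_end` into an integer number of steps",
         call. = FALSE)
  }
  n <- as.integer(round(n))
  (seq_len(n) - 1L) * dt
}

# Map a spike train to 0/1 indicators on the step grid; errors on off-grid times.
train_to_steps <- function(tr, interval_end, dt) {
  n <- as.integer(round(interval_end / dt))
  v <- numeric(n)
  if (length(tr$times)) {
    idx <- tr$times / dt + 1
    if (any(abs(idx - round(idx)) > 1e-6) || any(round(idx) > n)) {
      stop("spike times are not aligned to the dt grid", call. = FALSE)
    }
    v[as.integer(round(idx))] <- 1
  }
  v
}

# layer_size x n_steps 0/1 matrix for a whole set
set_to_steps <- function(set, dt) {
  n <- as.integer(round(set$interval_end / dt))
  out <- matrix(0, nrow = set$layer_size, ncol = n)
  for (i in seq_len(set$layer_size)) {
    out[i, ] <- train_to_steps(set$trains[[i]], set$interval_end, dt)
  }
  out
}

# Inverse of set_to_steps for a binary spike matrix (rows = neurons)
steps_to_set <- function(mat, interval_end, dt) {
  tg <- grid_times(interval_end, dt)
  trains <- lapply(seq_len(nrow(mat)), function(i) {
    spike_train(tg[mat[i, ] > 0], interval_end)
  })
  spike_train_set(trains, interval_end = interval_end)
}

check_same_interval <- function(a, b) {
  if (abs(a$interval_end - b$interval_end) > 1e-9) {
    stop("spike trains live on different simulation intervals", call. = FALSE)
  }
  invisible(TRUE)
}
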