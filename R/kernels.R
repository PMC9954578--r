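#' Specify a spike-time kernel
#'
#' Spike trains are compared through a shift-invariant kernel on spike times.
#' Four families are supported (d = |x - y|, all times in ms):
#' \describe{
#'   \item{gaussian}{`exp(-d^2 / (2 sigma^2))`, default width 40 ms}
#'   \item{laplacian}{`exp(-d / sigma)`, default width 80 ms}
#'   \item{inverse_multiquadratic}{`1 / sqrt(d^2 + c^2)` (or `1/(d^2+c^2)`
#'     with `imq_form = "squared"`), default c = 30 ms}
#'   \item{alpha}{`(d / sigma) * exp(-d / sigma)`, default width 5 ms.
#'     Note `k(x, x) = 0`: the alpha family is not positive definite, so
#'     Gram matrices need not be PSD and the RKHS error can be negative.}
#' }
#'
#' @param family One of `"gaussian"`, `"laplacian"`,
#'   `"inverse_multiquadratic"` (alias `"invmq"`), `"alpha"`.
#' @param parameter Positive kernel width/shape parameter in ms (sigma for
#'   gaussian/laplacian/alpha, c for inverse multiquadratic). Defaults per
#'   family as listed above.
#' @param imq_form For the inverse multiquadratic family only: `"root"`
#'   (standard, `1/sqrt(d^2+c^2)`) or `"squared"` (`1/(d^2+c^2)`).
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("gaussian", 40)
#' kernel_spec("invmq", 30, imq_form = "squared")
#' @export
kernel_spec <- function(family = c("gaussian", "laplacian",
                                   "inverse_multiquadratic", "invmq", "alpha"),
                        parameter = NULL,
                        imq_form = c("root", "squared")) {
  family <- match.arg(family)
  if (family == "invmq") family <- "inverse_multiquadratic"
  imq_form <- match.arg(imq_form)
  if (is.null(parameter)) {
    parameter <- switch(family,
      gaussian = 40, laplacian = 80,
      inverse_multiquadratic = 30, alpha = 5)
  }
  parameter <- as.numeric(parameter)
  if (length(parameter) != 1L || !is.finite(parameter) || parameter <= 0) {
    stop("kernel `parameter` must be a single positive number", call. = FALSE)
  }
  structure(list(family = family, parameter = parameter, imq_form = imq_form),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  extra <- if (x$family == "inverse_multiquadratic") {
    sprintf(" (%s form)", x$imq_form)
  } else ""
  cat(sprintf("<kernel_spec> %s, parameter %g ms%s\n", x$family, x$parameter, extra))
  invisible(x)
}

#' Evaluate a spike-time kernel
#'
#' Computes k(|tm - tn|) for the chosen family. Vectorized over `tm`/`tn`
#' with the usual recycling rules; symmetric in its two arguments.
#'
#' @param tm,tn Spike times in ms.
#' @param spec A [kernel_spec].
#' @return Numeric vector of kernel values (finite, non-negative).
#' @examples
#' kernel_eval(2, 5, kernel_spec("gaussian", 40))
#' @export
kernel_eval <- function(tm, tn, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  d <- abs(tm - tn)
  p <- spec$parameter
  switch(spec$family,
    gaussian  = exp(-d^2 / (2 * p^2)),
    laplacian = exp(-d / p),
    inverse_multiquadratic =
      if (spec$imq_form == "root") 1 / sqrt(d^2 + p^2) else 1 / (d^2 + p^2),
    alpha     = (d / p) * exp(-d / p),
    stop("unknown kernel family", call. = FALSE))
}

#' Spike-train inner product (STIP)
#'
#' The inner product of two spike trains in the RKHS induced by the chosen
#' spike-time kernel: the double sum of `kernel_eval` over all pairs of spike
#' times, one from each train. Any term involving an empty train is an empty
#' sum, so the STIP with a silent neuron is 0.
#'
#' @param a,b [spike_train] objects on the same interval.
#' @param spec A [kernel_spec].
#' @return A single number; symmetric in `a` and `b`.
#' @examples
#' k <- kernel_spec("gaussian", 40)
#' stip_pair(spike_train(c(1, 2), 10), spike_train(c(1, 2), 10), k)
#' @export
stip_pair <- function(a, b, spec) {
  stopifnot(inherits(a, "spike_train"), inherits(b, "spike_train"))
  check_same_interval(a, b)
  if (!length(a$times) || !length(b$times)) return(0)
  sum(kernel_eval(rep(a$times, times = length(b$times)),
                  rep(b$times, each = length(a$times)),
                  spec))
}

#' STIP (Gram) matrix between two layers of spike trains
#'
#' Entry (i, j) is `stip_pair(p$trains[[i]], q$trains[[j]], spec)`. With
#' `p = q` this is the Gram matrix of the layer's trains, positive
#' semidefinite for the positive-definite kernel families.
#'
#' @param p,q [spike_train_set] objects on the same interval.
#' @param spec A [kernel_spec].
#' @return A `p$layer_size` by `q$layer_size` numeric matrix.
#' @export
stip_matrix <- function(p, q, spec) {
  stopifnot(inherits(p, "spike_train_set"), inherits(q, "spike_train_set"))
  check_same_interval(p, q)
  # Pool q's spike times once; each row is then one vectorized kernel sweep
  # followed by a per-train accumulation. Equivalent to the per-pair double sum.
  tb <- unlist(lapply(q$trains, `[[`, "times"))
  nb <- vapply(q$trains, function(tr) length(tr$times), integer(1))
  ib <- rep.int(seq_len(q$layer_size), nb)
  out <- matrix(0, nrow = p$layer_size, ncol = q$layer_size)
  if (!length(tb)) return(out)
  for (i in seq_len(p$layer_size)) {
    ti <- p$trains[[i]]$times
    if (!length(ti)) next
    kv <- colSums(outer(ti, tb, function(x, y) kernel_eval(x, y, spec)))
    acc <- rowsum(kv, group = ib, reorder = TRUE)
    out[i, as.integer(rownames(acc))] <- acc[, 1L]
  }
  out
}

#' RKHS error between actual and desired output trains
#'
#' The network error is half the squared RKHS distance between the actual and
#' desired output spike trains, summed over output neurons. It expands in
#' closed form into STIP terms:
#' `E = 1/2 * sum_i [ <a_i,a_i> - 2<a_i,d_i> + <d_i,d_i> ]`.
#' For positive-definite kernels E >= 0 with equality iff the trains induce
#' identical smoothed signals; for the alpha family no such guarantee exists.
#'
#' @param actual,desired [spike_train_set] objects of equal size on the same
#'   interval.
#' @param spec A [kernel_spec].
#' @return A single number; exactly 0 when `actual` and `desired` are
#'   identical.
#' @export
rkhs_error <- function(actual, desired, spec) {
  stopifnot(inherits(actual, "spike_train_set"),
            inherits(desired, "spike_train_set"))
  if (actual$layer_size != desired$layer_size) {
    stop("`actual` and `desired` must have the same number of neurons",
         call. = FALSE)
  }
  check_same_interval(actual, desired)
  e <- 0
  for (i in seq_len(actual$layer_size)) {
    a <- actual$trains[[i]]
    d <- desired$trains[[i]]
    e <- e + stip_pair(a, a, spec) - 2 * stip_pair(a, d, spec) +
      stip_pair(d, d, spec)
  }
  e / 2
}

# ---- grid-based fast path (internal) ----------------------------------------
# For spike trains that live on the simulation step grid, a train is a 0/1
# indicator vector over steps and every STIP reduces to S_p %*% K %*% t(S_q)
# with K the step-time kernel Gram matrix, precomputed once per run.

grid_gram <- function(spec, interval_end, dt) {
  tg <- grid_times(interval_end, dt)
  outer(tg, tg, function(x, y) kernel_eval(x, y, spec))
}

# STIP matrix between two binary spike matrices (rows = neurons, cols = steps)
stip_matrix_steps <- function(sp, sq, K) {
  sp %*% K %*% t(sq)
}

rkhs_error_steps <- function(sa, sd, K) {
  aK <- sa %*% K
  dK <- sd %*% K
  (sum(aK * sa) - 2 * sum(aK * sd) + sum(dK * sd)) / 2
}
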