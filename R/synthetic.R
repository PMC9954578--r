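#' Specify a synthetic classification task
#'
#' Self-contained stand-in for an image-classification pipeline: each class
#' has a fixed random binary intensity prototype (a subset of components at
#' `on_intensity`, the rest at `off_intensity`), and each sample is its class
#' prototype with independent component flips at rate `flip_noise`. Samples
#' are then Poisson-encoded into spike trains exactly like image pixels.
#'
#' Defaults are chosen so that one full training run of a 20-30-30-3 network
#' finishes in seconds: 3 classes, 20 inputs, 300 training and 90 test
#' samples, on/off intensities 0.9/0.05, 2% flip noise.
#'
#' @param n_classes Number of classes.
#' @param input_dim Number of input components.
#' @param prototype_on_fraction Fraction of components active in each class
#'   prototype.
#' @param on_intensity,off_intensity Intensities of active/inactive
#'   components, in \[0,1\].
#' @param flip_noise Probability that a component's intensity is swapped
#'   (on <-> off) in a sample.
#' @param n_train,n_test Split sizes (balanced across classes; must be
#'   divisible by `n_classes`).
#' @param seed Integer seed.
#' @return An object of class `synthetic_task_spec`.
#' @export
synthetic_task_spec <- function(n_classes = 3, input_dim = 20,
                                prototype_on_fraction = 0.5,
                                on_intensity = 0.9, off_intensity = 0.05,
                                flip_noise = 0.02, n_train = 300, n_test = 90,
                                seed = 1L) {
  probs <- c(prototype_on_fraction, on_intensity, off_intensity, flip_noise)
  if (any(probs < 0 | probs > 1)) {
    stop("fractions, intensities and noise must lie in [0, 1]", call. = FALSE)
  }
  if (n_train %% n_classes || n_test %% n_classes) {
    stop("`n_train` and `n_test` must be divisible by `n_classes`",
         call. = FALSE)
  }
  structure(list(n_classes = as.integer(n_classes),
                 input_dim = as.integer(input_dim),
                 prototype_on_fraction = prototype_on_fraction,
                 on_intensity = on_intensity, off_intensity = off_intensity,
                 flip_noise = flip_noise, n_train = as.integer(n_train),
                 n_test = as.integer(n_test), seed = as.integer(seed)),
            class = "synthetic_task_spec")
}

#' Generate a synthetic classification task
#'
#' Draws class prototypes (re-drawing with a message if any pair is closer
#' than 25% of `input_dim` in Hamming distance), then balanced train/test
#' splits of noisy prototype copies. Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_task_spec].
#' @return A list with `train` and `test` (each a list with intensity matrix
#'   `x`, rows in sample order, and 0-based label vector `y`), `prototypes`
#'   (class x component intensity matrix) and `spec`.
#' @examples
#' task <- make_task(synthetic_task_spec(seed = 7))
#' dim(task$train$x)
#' @export
make_task <- function(spec) {
  stopifnot(inherits(spec, "synthetic_task_spec"))
  with_optional_seed(spec$seed, {
    n_on <- max(1L, round(spec$prototype_on_fraction * spec$input_dim))
    min_dist <- ceiling(0.25 * spec$input_dim)
    for (attempt in seq_len(100L)) {
      proto_mask <- t(replicate(spec$n_classes, {
        m <- logical(spec$input_dim)
        m[sample.int(spec$input_dim, n_on)] <- TRUE
        m
      }))
      dists <- utils::combn(spec$n_classes, 2, function(ij) {
        sum(xor(proto_mask[ij[1], ], proto_mask[ij[2], ]))
      })
      if (all(dists >= min_dist)) break
      if (attempt == 100L) {
        stop("could not draw well-separated prototypes; relax the spec",
             call. = FALSE)
      }
      message("prototype draw too close (Hamming < ", min_dist, "); re-drawing")
    }
    prototypes <- ifelse(proto_mask, spec$on_intensity, spec$off_intensity)
    draw_split <- function(n) {
      per_class <- n / spec$n_classes
      y <- rep(seq_len(spec$n_classes) - 1L, each = per_class)
      x <- matrix(0, nrow = n, ncol = spec$input_dim)
      for (s in seq_len(n)) {
        mask <- proto_mask[y[s] + 1L, ]
        flip <- stats::runif(spec$input_dim) < spec$flip_noise
        mask <- xor(mask, flip)
        x[s, ] <- ifelse(mask, spec$on_intensity, spec$off_intensity)
      }
      ord <- sample.int(n)
      list(x = x[ord, , drop = FALSE], y = y[ord])
    }
    list(train = draw_split(spec$n_train), test = draw_split(spec$n_test),
         prototypes = prototypes, spec = spec)
  })
}

#' Shuffle the labels of a task split
#'
#' Control experiment: permuting the training labels destroys the
#' input-label association, so a sound trainer should stay at chance on the
#' (untouched) test split.
#'
#' @param task A task from [make_task()].
#' @param seed Integer seed for the permutation.
#' @return The task with `train$y` randomly permuted.
#' @export
shuffle_labels <- function(task, seed = 1L) {
  task$train$y <- with_optional_seed(seed, sample(task$train$y))
  task
}

#' Write / read a task as plain tabular files
#'
#' The intensities go to `<stem>_train.tsv` / `<stem>_test.tsv` with the
#' label in the first column, so CLI runs and tests can share inputs.
#'
#' @param task A task from [make_task()].
#' @param stem Path stem for the output files.
#' @return `write_task` returns the two file paths invisibly; `read_task`
#'   returns a task-shaped list with `train` and `test`.
#' @export
write_task <- function(task, stem) {
  paths <- c(train = paste0(stem, "_train.tsv"), test = paste0(stem, "_test.tsv"))
  for (nm in names(paths)) {
    split <- task[[nm]]
    df <- data.frame(label = split$y, split$x, check.names = FALSE)
    colnames(df) <- c("label", paste0("x", seq_len(ncol(split$x))))
    utils::write.table(df, paths[[nm]], sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(paths)
}

#' @rdname write_task
#' @export
read_task <- function(stem) {
  read_split <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t")
    list(x = as.matrix(df[, -1, drop = FALSE]), y = as.integer(df$label))
  }
  list(train = read_split(paste0(stem, "_train.tsv")),
       test = read_split(paste0(stem, "_test.tsv")))
}

#' Hand-checkable worked example
#'
#' A fixed tiny instance (layer sizes 3-4-2, at most three spikes per train,
#' every spike time listed) together with golden reference values computed by
#' independent oracles: the STIP matrices by an explicit double loop over
#' spike pairs, and the backpropagation update additionally cross-checked
#' against central finite differences of the quadrature-evaluated linear
#' surrogate error. The forward matrices are 0/1 selection/merge matrices so
#' the hidden and output trains are literally the merges of the selected
#' input trains and the linear spike-train relation holds exactly.
#'
#' @return A list with the inputs (`input`, `hidden`, `output`, `desired`
#'   spike-train sets; `weights`; `fa_matrices`; `ba_matrix`; `kernel`;
#'   `eta`) and the golden values (`stip_output_hidden`,
#'   `stip_desired_hidden`, `stip_output_input`, `stip_desired_input`,
#'   `delta_w2`, `delta_w1_bp`, `delta_w1_fa`, `delta_w1_ba`).
#' @export
worked_example_fixture <- function() {
  golden_path <- system.file("extdata", "worked_example.json",
                             package = "stipnet", mustWork = TRUE)
  golden <- jsonlite::fromJSON(golden_path)
  iv <- 10
  input <- spike_train_set(list(c(1, 4), 2.5, c(6, 8.5, 9)), interval_end = iv)
  w1 <- rbind(c(1, 0, 0), c(0, 1, 1), c(1, 0, 1), c(0, 0, 0))
  w2 <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  hidden <- spike_train_set(list(c(1, 4), c(2.5, 6, 8.5, 9),
                                 c(1, 4, 6, 8.5, 9), numeric(0)),
                            interval_end = iv)
  output <- spike_train_set(list(c(1, 2.5, 4, 6, 8.5, 9),
                                 c(1, 4, 6, 8.5, 9)), interval_end = iv)
  desired <- spike_train_set(list(c(2, 5, 8), c(3, 7)), interval_end = iv)
  fa2 <- rbind(c(0.5, -1.2, 0.3, 2.0), c(-0.7, 0.4, 1.5, -0.2))
  ba1 <- rbind(c(1.1, -0.3, 0.8, -1.4), c(0.2, 0.9, -0.6, 0.5))
  list(input = input, hidden = hidden, output = output, desired = desired,
       weights = list(w1, w2),
       fa_matrices = list(matrix(0, 4, 3), fa2), ba_matrix = ba1,
       kernel = kernel_spec("gaussian", 40), eta = 0.1,
       golden = lapply(golden, function(g) {
         if (is.matrix(g)) g else as.matrix(g)
       }))
}
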