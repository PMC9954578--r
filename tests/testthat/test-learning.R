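test_that("the worked example reproduces its oracle-derived golden values", {
  fx <- worked_example_fixture()
  g <- fx$golden
  expect_equal(stip_matrix(fx$output, fx$hidden, fx$kernel),
               g$stip_output_hidden, tolerance = 1e-12)
  expect_equal(stip_matrix(fx$desired, fx$hidden, fx$kernel),
               g$stip_desired_hidden, tolerance = 1e-12)
  expect_equal(output_delta(fx$output, fx$desired, fx$hidden, fx$kernel, fx$eta),
               g$delta_w2, tolerance = 1e-12)
  expect_equal(bp_hidden_delta(1, fx$output, fx$desired, fx$input, fx$weights,
                               fx$kernel, fx$eta),
               g$delta_w1_bp, tolerance = 1e-12)
  fb_fa <- structure(list(mode = "FA", fa_matrices = fx$fa_matrices,
                          ba_matrices = NULL), class = "feedback_config")
  expect_equal(fa_hidden_delta(1, fx$output, fx$desired, fx$input, fb_fa,
                               fx$kernel, fx$eta),
               g$delta_w1_fa, tolerance = 1e-12)
  fb_ba <- structure(list(mode = "BA", fa_matrices = NULL,
                          ba_matrices = list(fx$ba_matrix)),
                     class = "feedback_config")
  expect_equal(ba_hidden_delta(1, fx$output, fx$desired, fx$input, fb_ba,
                               fx$kernel, fx$eta),
               g$delta_w1_ba, tolerance = 1e-12)
  # the hidden/output trains of the fixture really are the forward merges
  layers <- propagate_merge(fx$input, fx$weights)
  expect_equal(layers[[1]], fx$hidden)
  expect_equal(layers[[2]], fx$output)
})

test_that("all three rules sit at an exact fixed point when actual = desired", {
  set.seed(41)
  g <- kernel_spec("laplacian", 80)
  sizes <- c(3, 4, 4, 2)
  out <- rand_set(2)
  hid <- rand_set(4)
  prev <- rand_set(3)
  weights <- init_weights(sizes, seed = 1)$weights
  fa <- feedback_config("FA", sizes, seed = 2)
  ba <- feedback_config("BA", sizes, seed = 3)
  expect_identical(output_delta(out, out, hid, g, 0.5), matrix(0, 2, 4))
  for (l in 1:2) {
    pl <- if (l == 1) prev else hid
    expect_identical(bp_hidden_delta(l, out, out, pl, weights, g, 0.5),
                     matrix(0, sizes[l + 1], sizes[l]))
    expect_identical(fa_hidden_delta(l, out, out, pl, fa, g, 0.5),
                     matrix(0, sizes[l + 1], sizes[l]))
    expect_identical(ba_hidden_delta(l, out, out, pl, ba, g, 0.5),
                     matrix(0, sizes[l + 1], sizes[l]))
  }
})

test_that("feedback alignment with B = W reproduces backpropagation exactly", {
  set.seed(43)
  g <- kernel_spec("gaussian", 40)
  sizes <- c(3, 5, 4, 2)
  weights <- init_weights(sizes, seed = 4)$weights
  fb <- structure(list(mode = "FA", fa_matrices = weights, ba_matrices = NULL),
                  class = "feedback_config")
  out <- rand_set(2); des <- rand_set(2)
  for (l in 1:2) {
    pl <- rand_set(sizes[l])
    expect_identical(fa_hidden_delta(l, out, des, pl, fb, g, 0.3),
                     bp_hidden_delta(l, out, des, pl, weights, g, 0.3))
  }
})

test_that("broadcast-alignment updates are local to their layer", {
  set.seed(47)
  g <- kernel_spec("gaussian", 40)
  sizes <- c(3, 4, 4, 2)
  ba <- feedback_config("BA", sizes, seed = 5)
  out <- rand_set(2); des <- rand_set(2); prev <- rand_set(3)
  d1 <- ba_hidden_delta(1, out, des, prev, ba, g, 0.2)
  # the BA rule consumes no forward weights at all, so perturbing W_{l+1}
  # cannot enter; check shape and invariance under a fresh evaluation
  expect_equal(dim(d1), c(4L, 3L))
  expect_identical(d1, ba_hidden_delta(1, out, des, prev, ba, g, 0.2))
})

test_that("updates scale linearly in the learning rate", {
  set.seed(53)
  g <- kernel_spec("alpha", 5)
  out <- rand_set(2); des <- rand_set(2); hid <- rand_set(4)
  d1 <- output_delta(out, des, hid, g, 0.1)
  d3 <- output_delta(out, des, hid, g, 0.3)
  expect_equal(d3, 3 * d1, tolerance = 1e-12)
})

test_that("BP updates match the quadrature finite-difference gradient", {
  set.seed(59)
  sigma <- 40
  spec <- kernel_spec("gaussian", sigma)
  eta <- 1
  for (rep in 1:5) {
    inst <- rand_linear_instance()
    if (sum(spike_counts(inst$output)) == 0) next
    fd2 <- fd_grad(function(M) {
      surrogate_error(list(inst$weights[[1]], M), inst$input, inst$desired, sigma)
    }, inst$weights[[2]])
    got2 <- output_delta(inst$output, inst$desired, inst$hidden, spec, eta)
    expect_lt(relative_max_err(got2, -eta * fd2), 1e-4)
    fd1 <- fd_grad(function(M) {
      surrogate_error(list(M, inst$weights[[2]]), inst$input, inst$desired, sigma)
    }, inst$weights[[1]])
    got1 <- bp_hidden_delta(1, inst$output, inst$desired, inst$input,
                            inst$weights, spec, eta)
    expect_lt(relative_max_err(got1, -eta * fd1), 1e-4)
  }
})

test_that("feedback matrices are immutable across training", {
  task <- make_task(synthetic_task_spec(n_train = 30, n_test = 15, seed = 2))
  sizes <- c(20, 10, 10, 3)
  fb <- feedback_config("FA", sizes, seed = 6)
  before <- serialize(fb, NULL)
  net <- init_weights(sizes, seed = 7)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 10, epochs = 3,
                      seed = 8)
  invisible(train_snn(task, net, fb, cfg))
  expect_identical(serialize(fb, NULL), before)
})

test_that("the training loop respects zero epochs and degenerate fixtures", {
  task <- make_task(synthetic_task_spec(n_train = 30, n_test = 15, seed = 3))
  sizes <- c(20, 10, 10, 3)
  net <- init_weights(sizes, seed = 9)
  fb <- feedback_config("BA", sizes, seed = 10)
  cfg <- train_config(learning_rate = 1e-3, epochs = 0, seed = 11)
  fit <- train_snn(task, net, fb, cfg)
  expect_identical(fit$net$weights, net$weights)
  expect_equal(nrow(fit$record), 0)
})

test_that("training is reproducible given the seeds", {
  task <- make_task(synthetic_task_spec(n_train = 30, n_test = 15, seed = 4))
  sizes <- c(20, 10, 10, 3)
  run <- function() {
    net <- init_weights(sizes, seed = 12)
    fb <- feedback_config("FA", sizes, seed = 13)
    cfg <- train_config(learning_rate = 1e-3, batch_size = 10, epochs = 3,
                        seed = 14)
    train_snn(task, net, fb, cfg)
  }
  a <- run(); b <- run()
  expect_identical(a$net$weights, b$net$weights)
  expect_identical(a$record, b$record)
})

test_that("divergence aborts with a diagnostic naming epoch and layer", {
  task <- make_task(synthetic_task_spec(n_train = 30, n_test = 15, seed = 5))
  sizes <- c(20, 10, 10, 3)
  net <- init_weights(sizes, seed = 15)
  fb <- feedback_config("BP", sizes, seed = 16)
  cfg <- train_config(learning_rate = 1e6, batch_size = 10, epochs = 5,
                      guard = 1e4, seed = 17)
  expect_error(train_snn(task, net, fb, cfg), "epoch \\d+, layer \\d+")
  cfg2 <- train_config(learning_rate = 1e6, batch_size = 10, epochs = 5,
                       guard = 1e4, divergence = "stop", seed = 17)
  fit <- suppressWarnings(train_snn(task, net, fb, cfg2))
  expect_false(is.null(attr(fit$record, "diverged")))
})
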