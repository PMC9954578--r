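test_that("kernel families match their closed-form expressions", {
  g <- kernel_spec("gaussian", 40)
  expect_identical(kernel_eval(7, 7, g), 1)
  expect_equal(kernel_eval(2, 5, g), exp(-9 / 3200))
  expect_equal(kernel_eval(0, 8, kernel_spec("laplacian", 80)), exp(-0.1))
  expect_identical(kernel_eval(3, 3, kernel_spec("alpha", 5)), 0)
  expect_equal(kernel_eval(4, 1, kernel_spec("invmq", 30)), 1 / sqrt(9 + 900))
  expect_equal(kernel_eval(4, 1, kernel_spec("invmq", 30, imq_form = "squared")),
               1 / 909)
  # symmetry and vectorization
  expect_equal(kernel_eval(c(1, 2), c(9, 3), g), kernel_eval(c(9, 3), c(1, 2), g))
})

test_that("kernel_spec validates its inputs and supplies family defaults", {
  expect_error(kernel_spec("gaussian", -1), "positive")
  expect_error(kernel_spec("gaussian", 0), "positive")
  expect_error(kernel_spec("nonsense"), "arg")
  expect_equal(kernel_spec("gaussian")$parameter, 40)
  expect_equal(kernel_spec("laplacian")$parameter, 80)
  expect_equal(kernel_spec("invmq")$parameter, 30)
  expect_equal(kernel_spec("alpha")$parameter, 5)
})

test_that("spike_train enforces its invariants", {
  expect_error(spike_train(c(2, 1), 10), "increasing")
  expect_error(spike_train(c(1, 1), 10), "increasing")
  expect_error(spike_train(c(-1, 2), 10), "0, interval_end")
  expect_error(spike_train(c(2, 11), 10), "0, interval_end")
  expect_silent(spike_train(numeric(0), 10))
  expect_silent(spike_train(c(0, 10), 10))
})

test_that("stip_pair matches hand-derived values and is symmetric", {
  g <- kernel_spec("gaussian", 40)
  empty <- spike_train(numeric(0), 10)
  expect_identical(stip_pair(empty, spike_train(c(1, 5, 9), 10), g), 0)
  expect_equal(stip_pair(spike_train(2, 10), spike_train(5, 10), g),
               exp(-9 / 3200))
  expect_equal(stip_pair(spike_train(c(1, 2), 10), spike_train(c(1, 2), 10), g),
               2 + 2 * exp(-1 / 3200))
  a <- spike_train(c(0.3, 4.4, 7.1), 10)
  b <- spike_train(c(2.2, 9.9), 10)
  expect_identical(stip_pair(a, b, g), stip_pair(b, a, g))
  expect_error(stip_pair(a, spike_train(1, 20), g), "interval")
})

test_that("stip_pair is additive under train concatenation", {
  set.seed(42)
  g <- kernel_spec("laplacian", 80)
  for (rep in 1:20) {
    ta <- sort(runif(4, 0, 5))
    tap <- sort(runif(3, 5.01, 10))
    b <- rand_train()
    a <- spike_train(ta, 10)
    ap <- spike_train(tap, 10)
    both <- spike_train(c(ta, tap), 10)
    expect_equal(stip_pair(both, b, g),
                 stip_pair(a, b, g) + stip_pair(ap, b, g), tolerance = 1e-12)
  }
})

test_that("stip_matrix has the layer-pair shape and transpose symmetry", {
  set.seed(7)
  g <- kernel_spec("gaussian", 40)
  p <- rand_set(3)
  q <- rand_set(5)
  M <- stip_matrix(p, q, g)
  expect_equal(dim(M), c(3L, 5L))
  expect_equal(M, t(stip_matrix(q, p, g)), tolerance = 1e-14)
  for (i in 1:3) for (j in 1:5) {
    expect_equal(M[i, j], stip_pair(p$trains[[i]], q$trains[[j]], g),
                 tolerance = 1e-12)
  }
  silent <- spike_train_set(replicate(4, spike_train(numeric(0), 10),
                                      simplify = FALSE))
  expect_equal(stip_matrix(silent, silent, g), matrix(0, 4, 4))
})

test_that("self Gram matrices are PSD for the positive-definite families", {
  set.seed(11)
  for (family in c("gaussian", "laplacian", "inverse_multiquadratic")) {
    spec <- kernel_spec(family)
    for (rep in 1:5) {
      p <- rand_set(8)
      ev <- eigen(stip_matrix(p, p, spec), symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gte(min(ev), -1e-9)
    }
  }
})

test_that("rkhs_error expands the squared RKHS distance correctly", {
  g <- kernel_spec("gaussian", 40)
  a <- rand_set(3)
  expect_identical(rkhs_error(a, a, g), 0)
  one_empty <- spike_train_set(list(numeric(0)), interval_end = 10)
  one_spike <- spike_train_set(list(5), interval_end = 10)
  expect_equal(rkhs_error(one_empty, one_spike, g), 0.5)
  expect_error(rkhs_error(rand_set(2), rand_set(3), g), "same number")
})

test_that("gaussian rkhs_error matches the quadrature of the smoothed signals", {
  set.seed(19)
  for (sigma in c(2, 5)) {
    spec <- kernel_spec("gaussian", sigma)
    for (rep in 1:5) {
      a <- rand_set(3, n_max = 5)
      d <- rand_set(3, n_max = 5)
      want <- quad_rkhs_error(a, d, sigma)
      expect_equal(rkhs_error(a, d, spec), want, tolerance = 1e-3)
    }
  }
})

test_that("the grid fast path agrees with the general STIP functions", {
  set.seed(23)
  g <- kernel_spec("laplacian", 80)
  K <- stipnet:::grid_gram(g, 10, 1)
  for (rep in 1:5) {
    mat_a <- matrix(rbinom(30, 1, 0.4), nrow = 3)
    mat_b <- matrix(rbinom(40, 1, 0.4), nrow = 4)
    sa <- stipnet:::steps_to_set(mat_a, 10, 1)
    sb <- stipnet:::steps_to_set(mat_b, 10, 1)
    expect_equal(stipnet:::stip_matrix_steps(mat_a, mat_b, K),
                 stip_matrix(sa, sb, g), tolerance = 1e-12)
    expect_equal(stipnet:::rkhs_error_steps(mat_a, mat_a[c(2, 1, 3), ], K),
                 rkhs_error(sa, stipnet:::steps_to_set(mat_a[c(2, 1, 3), ], 10, 1), g),
                 tolerance = 1e-12)
  }
})
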