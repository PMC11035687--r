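test_that("parameter and state constructors enforce their invariants", {
  p <- ccnn_params()
  expect_equal(p$alpha_f, 0.1)
  expect_equal(p$alpha_e, 1)
  expect_equal(p$alpha_l, 0.1)
  expect_equal(p$beta, 0.5)
  expect_error(ccnn_params(alpha_f = 0), "strictly positive")
  expect_error(ccnn_params(alpha_e = -1), "strictly positive")

  expect_error(coupling_kernels(4), "must be 3 or 5")
  expect_error(coupling_kernels(m = matrix(0, 2, 2), w = matrix(0, 2, 2)),
               "odd")
  expect_error(coupling_kernels(m = matrix(0, 3, 3), w = matrix(0, 5, 5)),
               "identical shape")

  s <- zero_state(6, 7)
  expect_true(all(s$f == 0) && all(s$l == 0) && all(s$u == 0) &&
                all(s$e == 0) && all(s$y == 0))
  expect_error(lattice_state(matrix(0, 2, 2), matrix(0, 2, 2),
                             matrix(0, 2, 2), matrix(0, 2, 3),
                             matrix(0, 2, 2)), "share one shape")

  expect_error(stimulus(matrix(2, 3, 3)), "0, 1")
  expect_equal(max(stimulus(matrix(255, 3, 3), normalize = TRUE)), 1)
})

test_that("one CCNN step matches the hand-evaluated recursions", {
  p <- ccnn_params()
  k0 <- coupling_kernels(m = matrix(0, 3, 3), w = matrix(0, 3, 3))
  # zero state, zero stimulus: Y = sigmoid(0 - 0) = 1/2 everywhere
  s <- ccnn_step(zero_state(8, 8), matrix(0, 8, 8), p, k0)
  expect_equal(unique(as.vector(s$y)), 0.5)
  # zero state, unit stimulus: F=1, L=0, U=1, Y=sigmoid(1)
  s <- ccnn_step(zero_state(8, 8), matrix(1, 8, 8), p, k0)
  expect_equal(unique(as.vector(s$f)), 1)
  expect_equal(unique(as.vector(s$l)), 0)
  expect_equal(unique(as.vector(s$u)), 1)
  expect_equal(unique(as.vector(s$y)), 1 / (1 + exp(-1)), tolerance = 1e-12)
})

test_that("one PCNN step fires on strict threshold crossing only", {
  p <- ccnn_params()
  k0 <- coupling_kernels(m = matrix(0, 3, 3), w = matrix(0, 3, 3))
  # U = 0, E = 0: strict inequality, no firing
  s <- pcnn_step(zero_state(8, 8), matrix(0, 8, 8), p, k0)
  expect_equal(unique(as.vector(s$y)), 0)
  # U = 1 > 0: everything fires
  s <- pcnn_step(zero_state(8, 8), matrix(1, 8, 8), p, k0)
  expect_equal(unique(as.vector(s$y)), 1)
})

test_that("vectorized steps match the per-neuron loop oracle", {
  set.seed(101)
  for (rep in 1:25) {
    ks <- sample(c(3L, 5L), 1)
    kern <- coupling_kernels(m = matrix(rnorm(ks^2, 0, 0.3), ks, ks),
                             w = matrix(rnorm(ks^2, 0, 0.3), ks, ks))
    p <- ccnn_params(alpha_f = runif(1, 0.05, 1), alpha_l = runif(1, 0.05, 1),
                     alpha_e = runif(1, 0.5, 2), beta = runif(1, 0, 1),
                     v_f = runif(1, 0.5, 2), v_l = runif(1, 0.5, 2),
                     v_e = runif(1, 0.5, 2))
    st <- random_state(8, 8)
    stim <- matrix(runif(64), 8, 8)
    expect_lt(max_state_diff(ccnn_step(st, stim, p, kern),
                             oracle_step(st, stim, p, kern)), 1e-10)
    expect_lt(max_state_diff(pcnn_step(st, stim, p, kern),
                             oracle_step(st, stim, p, kern, hard = TRUE)), 1e-10)
  }
})

test_that("CCNN output stays strictly inside (0,1); PCNN output is binary", {
  set.seed(5)
  kern <- coupling_kernels(3, seed = 2)
  p <- ccnn_params()
  st <- random_state(8, 8)
  # push towards saturation but keep |U - E| below the double-precision
  # saturation point of the sigmoid (~36), where (0,1) is representable
  st$f <- st$f * 10
  s <- ccnn_step(st, matrix(runif(64), 8, 8), p, kern)
  expect_true(all(s$y > 0 & s$y < 1))
  s2 <- pcnn_step(st, matrix(runif(64), 8, 8), p, kern)
  expect_true(all(s2$y %in% c(0, 1)))
})

test_that("identical inputs give bit-identical next states", {
  set.seed(6)
  kern <- coupling_kernels(3, seed = 2)
  st <- random_state(8, 8)
  stim <- matrix(runif(64), 8, 8)
  a <- ccnn_step(st, stim, ccnn_params(), kern)
  b <- ccnn_step(st, stim, ccnn_params(), kern)
  expect_identical(a, b)
})

test_that("step errors on malformed input", {
  kern <- coupling_kernels(3, seed = 1)
  expect_error(ccnn_step(zero_state(8, 8), matrix(0, 6, 6), ccnn_params(), kern),
               "shapes differ")
  bad <- zero_state(8, 8); bad$f[1, 1] <- NaN
  expect_error(ccnn_step(bad, matrix(0, 8, 8), ccnn_params(), kern),
               "non-finite")
})

test_that("with zero coupling, F follows the geometric closed form", {
  p <- ccnn_params()
  k0 <- coupling_kernels(m = matrix(0, 3, 3), w = matrix(0, 3, 3))
  s_val <- 0.8
  stim <- matrix(s_val, 8, 8)
  r <- exp(-p$alpha_f)
  st <- zero_state(8, 8)
  for (n in 1:100) {
    st <- ccnn_step(st, stim, p, k0)
    expect_lt(max(abs(st$f - s_val * (1 - r^n) / (1 - r))), 1e-8)
  }
  # the n -> Inf limit: S / (1 - e^{-alpha_f})
  expect_equal(st$f[1, 1], s_val / (1 - exp(-0.1)), tolerance = 1e-3)
})

test_that("run_lattice iterates and records the trajectory", {
  p <- ccnn_params()
  kern <- coupling_kernels(3, seed = 4)
  stim <- matrix(runif(64), 8, 8)
  one <- run_lattice(zero_state(8, 8), list(stim), p, kern)
  expect_equal(one$final, ccnn_step(zero_state(8, 8), stim, p, kern))
  r <- run_lattice(zero_state(8, 8), rep(list(stim), 7), p, kern, record = TRUE)
  expect_length(r$trajectory, 7)
  expect_identical(r$trajectory[[7]], r$final)
  expect_error(run_lattice(zero_state(8, 8), list(), p, kern), "non-empty")
})

test_that("a stimulus perturbation propagates no faster than the light cone", {
  p <- ccnn_params()
  kern <- coupling_kernels(3, seed = 8)
  h <- 15L
  base <- matrix(0.3, h, h)
  pert <- base; pert[8, 8] <- 0.9
  sa <- sb <- zero_state(h, h)
  m <- (kern$size - 1L) %/% 2L
  for (k in 0:4) {
    sa <- ccnn_step(sa, base, p, kern)
    sb <- ccnn_step(sb, pert, p, kern)
    diff <- abs(sa$y - sb$y) > 0
    rows <- which(diff, arr.ind = TRUE)
    if (nrow(rows) > 0) {
      cheb <- pmax(abs(rows[, 1] - 8L), abs(rows[, 2] - 8L))
      expect_lte(max(cheb), k * m)
    }
  }
})

test_that("the alternative threshold timing updates E before Y", {
  p <- ccnn_params()
  kern <- coupling_kernels(3, seed = 3)
  st <- random_state(8, 8)
  stim <- matrix(runif(64), 8, 8)
  pre <- ccnn_step(st, stim, p, kern, e_update = "after_y")
  post <- ccnn_step(st, stim, p, kern, e_update = "before_y")
  # E itself is the same either way; Y differs by which E enters the sigmoid
  expect_identical(pre$e, post$e)
  expect_equal(post$y, 1 / (1 + exp(-(post$u - post$e))), tolerance = 1e-12)
  expect_equal(pre$y, 1 / (1 + exp(-(pre$u - st$e))), tolerance = 1e-12)
})
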