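make_quick_net <- function() {
  net <- satiation_network(rf_size = 3, seed = 2)
  set.seed(21)
  net$readout_w <- matrix(rnorm(7840, 0, 0.05), 784, 10)
  net$trained <- TRUE
  net
}

test_that("protocol construction validates its fields", {
  expect_error(prime_target_protocol(1L, 3L, prime_repeats = 10, t_max = 10),
               "smaller than")
  expect_error(prime_target_protocol(1L, c(1L, 3L)), "allow_prime_target")
  pr <- prime_target_protocol(1L, c(1L, 3L), allow_prime_target = TRUE)
  expect_equal(pr$target_classes, c(1L, 3L))
})

test_that("same-stimulus runs record consistent curves and traces", {
  net <- make_quick_net()
  ds <- tiny_glyphs()
  res <- run_same_stimulus(net, ds, t_max = 8)
  expect_equal(nrow(res$curve), 8)
  expect_equal(dim(res$traces$preds), c(nrow(ds$images), 8))
  expect_equal(dim(res$traces$mean_y), c(nrow(ds$images), 8))
  expect_equal(dim(res$traces$semantics), c(nrow(ds$images), 10, 8))
  expect_true(all(res$traces$mean_y > 0 & res$traces$mean_y < 1))
  expect_equal(res$curve$accuracy, colMeans(res$traces$correct))
  res2 <- run_same_stimulus(net, ds, t_max = 8)
  expect_identical(res$traces, res2$traces)
  expect_warning(run_same_stimulus(satiation_network(seed = 1), ds, t_max = 2),
                 "not been trained")
})

test_that("a zero-repeat prime protocol degenerates to the same-stimulus run", {
  net <- make_quick_net()
  ds <- tiny_glyphs()
  # one image per target class so that pair sampling is the identity
  one_per <- labeled_image_set(
    ds$images[c(which(ds$labels == 3)[1], which(ds$labels == 1)[1]), ],
    c(3L, 1L), class_names = ds$class_names, source = ds$source)
  pr <- prime_target_protocol(1L, 3L, prime_repeats = 0L, t_max = 12L,
                              n_pairs = 4L, seed = 3L)
  res <- run_prime_target(net, one_per, pr)
  base <- run_same_stimulus(net, subset_classes(one_per, 3L), t_max = 12)
  expect_equal(res$curves$accuracy, base$curve$accuracy)
})

test_that("the prime/target switch carries the full lattice state over", {
  net <- make_quick_net()
  ds <- tiny_glyphs()
  a <- get_image(ds, which(ds$labels == 1)[1])
  b <- get_image(ds, which(ds$labels == 3)[1])
  p <- net$params; k <- net$kernels
  primed <- run_lattice(zero_state(), c(rep(list(a), 5), rep(list(b), 3)),
                        p, k, record = TRUE)
  prime_only <- run_lattice(zero_state(), rep(list(a), 5), p, k)
  expect_identical(primed$trajectory[[5]], prime_only$final)
})

test_that("prime/target runs report per-class post-switch accuracy curves", {
  net <- make_quick_net()
  ds <- tiny_glyphs()
  pr <- prime_target_protocol(1L, c(3L, 7L), prime_repeats = 4L, t_max = 20L,
                              n_pairs = 6L, seed = 5L)
  res <- run_prime_target(net, ds, pr)
  expect_equal(sort(unique(res$curves$target_class)), c(3L, 7L))
  expect_equal(nrow(res$curves), 2 * 16)
  expect_true(all(res$curves$accuracy >= 0 & res$curves$accuracy <= 1))
  expect_equal(res$curves$model_time, res$curves$post_switch_time + 4L)
  expect_equal(nrow(res$summary), 2)
  # deterministic under the protocol seed
  res2 <- run_prime_target(net, ds, pr)
  expect_identical(res$curves, res2$curves)
})

test_that("the prime's residual correlation fades to the never-primed level", {
  net <- make_quick_net()
  ds <- tiny_glyphs()
  a <- get_image(ds, which(ds$labels == 1)[1])
  b <- get_image(ds, which(ds$labels == 3)[1])
  p <- net$params; k <- net$kernels
  primed <- run_lattice(zero_state(), c(rep(list(a), 10), rep(list(b), 60)),
                        p, k, record = TRUE)
  plain <- run_lattice(zero_state(), rep(list(b), 60), p, k, record = TRUE)
  resid <- function(kk) {
    cor(as.vector(primed$trajectory[[10 + kk]]$y), as.vector(a)) -
      cor(as.vector(plain$trajectory[[kk]]$y), as.vector(a))
  }
  expect_lt(abs(resid(60)), 0.01)
  expect_lt(abs(resid(60)), abs(resid(5)))
})

test_that("D-value curves are non-negative differences of class averages", {
  net <- make_quick_net()
  ds <- tiny_glyphs()
  res <- run_same_stimulus(net, ds, t_max = 6, keep_semantics = FALSE)
  bc <- traces_by_class(res$traces)
  dv <- n400_proxy(bc, list(c(3, 7), c(9, 7)))
  expect_equal(sort(unique(dv$pair)), c("3-7", "9-7"))
  expect_true(all(dv$d_value >= 0))
  # identical trace sets on both sides of a pair: identically zero
  dup <- list("3" = bc[["3"]], "7" = bc[["3"]])
  expect_equal(n400_proxy(dup, list(c(3, 7)))$d_value, rep(0, 6))
  # signed mode is the raw difference
  sg <- n400_proxy(bc, list(c(3, 7)), signed = TRUE)
  expect_equal(abs(sg$d_value), dv$d_value[dv$pair == "3-7"])
  expect_error(n400_proxy(list("3" = bc[["3"]]), list(c(3, 7))), "missing")
  expect_error(n400_proxy(list("3" = bc[["3"]][0, , drop = FALSE],
                               "7" = bc[["7"]]), list(c(3, 7))), "empty")
})
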