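test_that("forward pass yields one semantic vector per model time", {
  net <- satiation_network(rf_size = 3, seed = 1)
  img <- get_image(tiny_glyphs(), 1)
  # zero readout: softmax of zeros is uniform over the 10 classes
  fw <- forward_pass(net, img, t = 1)
  expect_equal(as.vector(fw$probs), rep(0.1, 10), tolerance = 1e-12)
  fw <- forward_pass(net, img, t = 6, record = TRUE)
  expect_equal(nrow(fw$scores), 6)
  expect_length(fw$trajectory, 6)
  expect_equal(rowSums(fw$probs), rep(1, 6), tolerance = 1e-9)
  expect_error(forward_pass(net, img, t = 0), ">= 1")
})

test_that("forward pass composes across state carry-over", {
  net <- satiation_network(rf_size = 3, seed = 2)
  net$readout_w <- matrix(rnorm(784 * 10, 0, 0.05), 784, 10)
  img <- get_image(tiny_glyphs(), 3)
  full <- forward_pass(net, img, t = 4)
  half1 <- forward_pass(net, img, t = 2)
  half2 <- forward_pass(net, img, t = 2, init_state = half1$final_state)
  expect_equal(half2$scores[2, ], full$scores[4, ], tolerance = 1e-12)
  expect_equal(half2$final_state, full$final_state, tolerance = 1e-12)
})

test_that("analytic BPTT gradients match finite differences", {
  set.seed(7)
  net <- satiation_network(rf_size = 3, n_classes = 3, input_dim = c(8, 8),
                           seed = 3)
  net$readout_w <- matrix(rnorm(64 * 3, 0, 0.1), 64, 3)
  net$readout_b <- rnorm(3, 0, 0.1)
  stim <- matrix(runif(4 * 64), 4, 64)
  labels <- c(0L, 1L, 2L, 0L)
  g <- ccnnsat:::ccnn_loss_grads(net, stim, labels, 2L)
  lossfn <- function(n2) ccnnsat:::ccnn_loss_grads(n2, stim, labels, 2L)$loss
  h <- 1e-6
  rel_err <- function(analytic, bump) {
    n1 <- bump(net, h); n2 <- bump(net, -h)
    fd <- (lossfn(n1) - lossfn(n2)) / (2 * h)
    abs(fd - analytic) / max(abs(fd), 1e-8)
  }
  for (nm in c("m", "w")) {
    for (i in seq_len(9)) {
      expect_lt(rel_err(g[[paste0("g_", nm)]][i], function(n, d) {
        n$kernels[[nm]][i] <- n$kernels[[nm]][i] + d; n
      }), 1e-4)
    }
  }
  for (i in sample(64 * 3, 15)) {
    expect_lt(rel_err(g$g_wout[i], function(n, d) {
      n$readout_w[i] <- n$readout_w[i] + d; n
    }), 1e-4)
  }
  for (i in 1:3) {
    expect_lt(rel_err(g$g_b[i], function(n, d) {
      n$readout_b[i] <- n$readout_b[i] + d; n
    }), 1e-4)
  }
})

test_that("training on a 2-class glyph problem reaches high accuracy", {
  ds <- subset_classes(generate_glyphs(glyph_spec_default(), 100, seed = 5),
                       c(1L, 3L), relabel = TRUE)
  net <- satiation_network(rf_size = 3, n_classes = 2, seed = 1)
  fit <- train_network(net, ds, training_config(n_repeat = 4, batch_size = 50,
                                                max_epochs = 5, seed = 1))
  expect_true(all(is.finite(fit$history$loss)))
  expect_true(all(diff(fit$history$loss) < 0))  # loss decreases every epoch here
  run <- ccnnsat:::model_run_batch(fit$net, ds$images, 4L,
                                   keep_semantics = FALSE)
  expect_gt(mean(run$preds[, 4] == ds$labels), 0.9)
  expect_true(fit$net$trained)
})

test_that("zero learning rate leaves the network untouched", {
  ds <- tiny_glyphs()
  net <- satiation_network(rf_size = 3, seed = 4)
  net$readout_w <- matrix(rnorm(7840, 0, 0.01), 784, 10)
  fit <- train_network(net, ds, training_config(batch_size = 25,
                                                learning_rate = 0,
                                                max_epochs = 2, seed = 1))
  expect_equal(fit$net$kernels$m, net$kernels$m)
  expect_equal(fit$net$kernels$w, net$kernels$w)
  expect_equal(fit$net$readout_w, net$readout_w)
  expect_equal(fit$net$readout_b, net$readout_b)
})

test_that("identical seeds reproduce identical loss histories", {
  ds <- tiny_glyphs(8L)
  cfg <- training_config(batch_size = 20, max_epochs = 3, seed = 11)
  f1 <- train_network(satiation_network(seed = 5), ds, cfg)
  f2 <- train_network(satiation_network(seed = 5), ds, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net$kernels, f2$net$kernels)
})

test_that("evaluate_over_time scores every model time with first-index ties", {
  ds <- tiny_glyphs()
  net <- satiation_network(rf_size = 3, seed = 1)
  curve <- evaluate_over_time(net, ds, t_max = 5)
  expect_equal(curve$model_time, 1:5)
  expect_true(all(curve$accuracy >= 0 & curve$accuracy <= 1))
  expect_equal(unique(curve$n_images), nrow(ds$images))
  # zero readout: all class scores tie; ties resolve to the lowest index (0)
  only0 <- subset_classes(ds, 0L)
  expect_equal(evaluate_over_time(net, only0, t_max = 3)$accuracy, rep(1, 3))
  # a readout rigged for one class pins the curve at 1
  rig <- net; rig$readout_b <- c(rep(0, 7), 10, 0, 0)
  only7 <- subset_classes(ds, 7L)
  expect_equal(evaluate_over_time(rig, only7, t_max = 4)$accuracy, rep(1, 4))
  expect_error(evaluate_over_time(net, labeled_image_set(
    matrix(numeric(0), 0, 784), integer(0)), 5), "empty")
})

test_that("checkpoints round-trip the full network", {
  ds <- tiny_glyphs()
  net <- satiation_network(rf_size = 5, seed = 2)
  net$readout_w <- matrix(rnorm(7840, 0, 0.1), 784, 10)
  net$trained <- TRUE
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(net, path)
  back <- load_checkpoint(path)
  img <- get_image(ds, 2)
  expect_equal(forward_pass(back, img, 3)$scores,
               forward_pass(net, img, 3)$scores, tolerance = 1e-12)
  expect_true(back$trained)
  expect_equal(back$kernels$size, 5L)
})
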