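# Training: the coupling kernels M, W and the dense readout are learned
# jointly by backpropagation through time over the unrolled CCNN recursion.
# The loss is the cross-entropy between the softmaxed readout at model time
# n_repeat and the labels — only the n_repeat-th model time is supervised;
# testing then probes every model time (see evaluate_over_time()). Gradients
# are propagated through all five recursions analytically (the CCNN is fully
# differentiable); they are checked against finite differences in the test
# suite.

#' Training configuration
#'
#' Defaults follow the reference protocol: supervision at model time 4,
#' batches of 200, Adam with learning rate 0.001, at most 100 epochs.
#'
#' @param n_repeat Model time at which the loss is applied (the network is
#'   trained only on the state after `n_repeat` repetitions of the stimulus).
#' @param batch_size Images per gradient step.
#' @param learning_rate Adam step size.
#' @param max_epochs Cap on passes over the training split.
#' @param seed RNG seed controlling the train/validation split and batch
#'   shuffling.
#' @param val_fraction Fraction of the data held out for validation
#'   accuracy logging (split 90/10 by default).
#' @return An object of class `training_config`.
#' @export
training_config <- function(n_repeat = 4L, batch_size = 200L,
                            learning_rate = 0.001, max_epochs = 100L,
                            seed = 1L, val_fraction = 0.1) {
  stopifnot(n_repeat >= 1, batch_size >= 1, learning_rate >= 0,
            max_epochs >= 1, val_fraction >= 0, val_fraction < 1)
  structure(list(n_repeat = as.integer(n_repeat),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed),
                 val_fraction = val_fraction),
            class = "training_config")
}

# Forward through n_rep lattice steps + readout, then analytic BPTT.
# stim: B x P; labels in 0..(n_classes-1). Returns loss, accuracy at the
# supervised step, and gradients for kernels m, w, readout weights and bias.
ccnn_loss_grads <- function(net, stim, labels, n_rep, plan = net_plan(net)) {
  p <- net$params
  df <- exp(-p$alpha_f); dl <- exp(-p$alpha_l); de <- exp(-p$alpha_e)
  b <- nrow(stim)
  st <- zero_batch_state(b, plan$p)
  fs <- ls_ <- ys <- es_prev <- vector("list", n_rep)
  for (n in seq_len(n_rep)) {
    es_prev[[n]] <- st$e
    st <- step_batch(st, stim, p, net$kernels, plan, e_update = net$e_update)
    fs[[n]] <- st$f; ls_[[n]] <- st$l; ys[[n]] <- st$y
  }
  z <- readout_scores(net, st$y)
  probs <- softmax_rows(z)
  idx <- cbind(seq_len(b), labels + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-300)))
  acc <- mean(max.col(z, ties.method = "first") - 1L == labels)

  onehot <- matrix(0, b, net$n_classes)
  onehot[idx] <- 1
  gz <- (probs - onehot) / b
  g_wout <- crossprod(st$y, gz)
  g_b <- colSums(gz)

  gy <- gz %*% t(net$readout_w)
  zero <- matrix(0, b, plan$p)
  gf_next <- gl_next <- ge_next <- zero
  g_m <- matrix(0, net$kernels$size, net$kernels$size)
  g_w <- matrix(0, net$kernels$size, net$kernels$size)
  for (n in rev(seq_len(n_rep))) {
    y_n <- ys[[n]]
    gu <- gy * y_n * (1 - y_n)
    ge_prev <- -gu                      # Y(n) = sigmoid(U(n) - E(n-1))
    gf <- gf_next + gu * (1 + p$beta * ls_[[n]])
    gl <- gl_next + gu * p$beta * fs[[n]]
    y_prev <- if (n > 1L) ys[[n - 1L]] else zero
    gy_prev <- zero
    if (n > 1L) {
      yp_pad <- pad_batch(y_prev, plan)
      g_m <- g_m + p$v_f * conv_kernel_grad(gf, plan, yp_pad)
      g_w <- g_w + p$v_l * conv_kernel_grad(gl, plan, yp_pad)
      gy_prev <- p$v_f * conv_input_grad(gf, net$kernels$m, plan) +
        p$v_l * conv_input_grad(gl, net$kernels$w, plan) +
        p$v_e * ge_next                 # E(n) = de E(n-1) + v_e Y(n-1)
    }
    ge_prev <- ge_prev + de * ge_next
    gy <- gy_prev
    gf_next <- df * gf
    gl_next <- dl * gl
    ge_next <- ge_prev
  }
  list(loss = loss, accuracy = acc,
       g_m = g_m, g_w = g_w, g_wout = g_wout, g_b = g_b)
}

adam_init <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, s), v = array(0, s)))
}

adam_update <- function(param, grad, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train the satiation network
#'
#' Fits the coupling kernels M, W and the dense readout by full
#' backpropagation through time over the `n_repeat` unrolled lattice steps,
#' minimizing the cross-entropy of the readout at model time `n_repeat`
#' with Adam. A seeded validation split is held out for accuracy logging.
#'
#' @param net A [satiation_network()]; its current kernels are the
#'   initialization.
#' @param dataset A [labeled_image_set()] of training images.
#' @param cfg A [training_config()].
#' @param verbose Print one line per epoch.
#' @return A list with `net` (the trained network) and `history`, a data
#'   frame with per-epoch columns `epoch`, `loss` (mean batch loss),
#'   `train_accuracy` (at model time `n_repeat`) and `val_accuracy`.
#' @export
train_network <- function(net, dataset, cfg = training_config(),
                          verbose = FALSE) {
  if (!inherits(dataset, "labeled_image_set")) {
    stop("`dataset` must be a labeled_image_set", call. = FALSE)
  }
  if (!identical(net$e_update, "after_y")) {
    stop("training is implemented for the default `after_y` update ordering",
         call. = FALSE)
  }
  plan <- net_plan(net)
  n <- nrow(dataset$images)
  set.seed(cfg$seed)
  perm <- sample.int(n)
  n_val <- floor(cfg$val_fraction * n)
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  tr_idx <- perm[setdiff(seq_len(n), seq_len(n_val))]

  kern <- net$kernels
  wout <- net$readout_w; bias <- net$readout_b
  ks <- c(kern$size, kern$size)
  opt <- adam_init(list(m = ks, w = ks, wout = dim(wout), b = length(bias)))
  step_t <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        train_accuracy = numeric(0), val_accuracy = numeric(0))

  for (epoch in seq_len(cfg$max_epochs)) {
    order_ep <- sample(tr_idx)
    batches <- split(order_ep, ceiling(seq_along(order_ep) / cfg$batch_size))
    ep_loss <- ep_acc <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      ids <- batches[[bi]]
      net$kernels <- kern; net$readout_w <- wout; net$readout_b <- bias
      g <- ccnn_loss_grads(net, dataset$images[ids, , drop = FALSE],
                           dataset$labels[ids], cfg$n_repeat, plan)
      if (!is.finite(g$loss)) {
        dump <- tempfile("ccnnsat-diverged-", fileext = ".rds")
        saveRDS(list(epoch = epoch, batch = bi, kernels = kern,
                     readout_w = wout, readout_b = bias), dump)
        stop(sprintf("non-finite loss at epoch %d batch %d; state dumped to %s",
                     epoch, bi, dump), call. = FALSE)
      }
      step_t <- step_t + 1L
      up <- adam_update(kern$m, g$g_m, opt$m, cfg$learning_rate, step_t)
      kern$m <- up$param; opt$m <- up$state
      up <- adam_update(kern$w, g$g_w, opt$w, cfg$learning_rate, step_t)
      kern$w <- up$param; opt$w <- up$state
      up <- adam_update(wout, g$g_wout, opt$wout, cfg$learning_rate, step_t)
      wout <- up$param; opt$wout <- up$state
      up <- adam_update(bias, g$g_b, opt$b, cfg$learning_rate, step_t)
      bias <- as.vector(up$param); opt$b <- up$state
      ep_loss[bi] <- g$loss; ep_acc[bi] <- g$accuracy
    }
    net$kernels <- kern; net$readout_w <- wout; net$readout_b <- bias
    val_acc <- NA_real_
    if (length(val_idx) > 0) {
      run <- model_run_batch(net, dataset$images[val_idx, , drop = FALSE],
                             cfg$n_repeat, keep_semantics = FALSE)
      val_acc <- mean(run$preds[, cfg$n_repeat] == dataset$labels[val_idx])
    }
    history[epoch, ] <- list(epoch, mean(ep_loss), mean(ep_acc), val_acc)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  train acc %.3f  val acc %.3f",
                      epoch, mean(ep_loss), mean(ep_acc), val_acc))
    }
  }
  net$trained <- TRUE
  net$train_config <- cfg
  list(net = net, history = history)
}
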