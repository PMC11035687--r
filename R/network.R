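# The two-stage model: a CCNN lattice the size of the input image (the
# model's "primary visual cortex") followed by a dense 10-way readout on the
# flattened lattice output (the model's "IT area"). The readout consumes the
# lattice output in row-major flatten order (see flatten_image()); its
# pre-softmax 10-d score vector is the "semantic vector" used by the
# distance analyses, with softmax probabilities alongside.

#' Construct the CCNN + dense-readout satiation network
#'
#' Builds the full model: a coupled lattice matching the input image size
#' (784 neurons for 28x28 input) whose feeding/linking kernels are
#' learnable, and a dense readout mapping the flattened lattice output to
#' one score per class.
#'
#' @param rf_size Receptive-field size of the lattice kernels (3 or 5).
#' @param n_classes Number of output classes (10 for the digit and fashion
#'   benchmarks).
#' @param input_dim Integer vector `c(height, width)` of the input images.
#' @param params A [ccnn_params()] object.
#' @param seed Integer seed for the kernel initialization (small positive
#'   uniform values) — the readout starts at zero.
#' @param e_update Dynamic-activity update ordering, see [ccnn_step()].
#' @return An object of class `satiation_network`.
#' @export
#' @examples
#' net <- satiation_network(rf_size = 3, seed = 1)
#' net
satiation_network <- function(rf_size = 3, n_classes = 10L,
                              input_dim = c(28L, 28L),
                              params = ccnn_params(), seed = 1L,
                              e_update = c("after_y", "before_y")) {
  e_update <- match.arg(e_update)
  p <- prod(input_dim)
  structure(
    list(
      params = params,
      kernels = coupling_kernels(rf_size, seed = seed),
      readout_w = matrix(0, p, n_classes),
      readout_b = numeric(n_classes),
      n_classes = as.integer(n_classes),
      input_dim = as.integer(input_dim),
      e_update = e_update,
      trained = FALSE,
      seed = as.integer(seed)
    ),
    class = "satiation_network"
  )
}

#' @export
print.satiation_network <- function(x, ...) {
  cat(sprintf("Satiation network: %dx%d lattice (rf %dx%d) -> %d classes [%s]\n",
              x$input_dim[1], x$input_dim[2], x$kernels$size, x$kernels$size,
              x$n_classes, if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}

net_plan <- function(net) {
  conv_plan(net$input_dim[1], net$input_dim[2], net$kernels$size)
}

zero_batch_state <- function(b, p) {
  z <- matrix(0, b, p)
  list(f = z, l = z, e = z, y = z)
}

readout_scores <- function(net, y) {
  sweep(y %*% net$readout_w, 2L, net$readout_b, "+")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

#' Run the network forward over model time
#'
#' Starts the lattice from the all-zero state (or a supplied state), applies
#' the constant stimulus for `t` model times, and at every step flattens the
#' lattice output and applies the dense readout, yielding one semantic
#' vector (10 class scores and their softmax) per model time.
#'
#' @param net A [satiation_network()].
#' @param image Stimulus matrix in \[0, 1\] with the network's input shape.
#' @param t Number of model times (>= 1).
#' @param record If `TRUE`, also return the per-step lattice trajectory.
#' @param init_state Optional `lattice_state` to resume from instead of the
#'   zero state, enabling stimulus switches with state carry-over.
#' @return A list with `scores` (t x n_classes pre-softmax semantic vectors),
#'   `probs` (their row-wise softmax), `final_state` (a `lattice_state`),
#'   and `trajectory` when recorded.
#' @export
forward_pass <- function(net, image, t, record = FALSE, init_state = NULL) {
  if (!is.numeric(t) || length(t) != 1L || t < 1) {
    stop("`t` must be a count >= 1", call. = FALSE)
  }
  t <- as.integer(t)
  h <- net$input_dim[1]; w <- net$input_dim[2]
  if (!identical(dim(image), c(h, w))) stop("image shape does not match network", call. = FALSE)
  plan <- net_plan(net)
  if (is.null(init_state)) {
    st <- zero_batch_state(1L, plan$p)
  } else {
    st <- list(f = matrix(flatten_image(init_state$f), 1),
               l = matrix(flatten_image(init_state$l), 1),
               e = matrix(flatten_image(init_state$e), 1),
               y = matrix(flatten_image(init_state$y), 1))
  }
  s <- matrix(flatten_image(image), 1)
  scores <- matrix(NA_real_, t, net$n_classes)
  traj <- if (record) vector("list", t) else NULL
  for (n in seq_len(t)) {
    st <- step_batch(st, s, net$params, net$kernels, plan,
                     e_update = net$e_update)
    scores[n, ] <- readout_scores(net, st$y)
    if (record) {
      traj[[n]] <- lattice_state(unflatten_image(st$f[1, ], h, w),
                                 unflatten_image(st$l[1, ], h, w),
                                 unflatten_image(st$u[1, ], h, w),
                                 unflatten_image(st$e[1, ], h, w),
                                 unflatten_image(st$y[1, ], h, w))
    }
  }
  out <- list(scores = scores, probs = softmax_rows(scores),
              final_state = lattice_state(unflatten_image(st$f[1, ], h, w),
                                          unflatten_image(st$l[1, ], h, w),
                                          unflatten_image(st$u[1, ], h, w),
                                          unflatten_image(st$e[1, ], h, w),
                                          unflatten_image(st$y[1, ], h, w)))
  if (record) out$trajectory <- traj
  out
}

# Batched engine shared by evaluation and the experiment protocols.
# `stim` is B x P; if `stim2`/`switch_after` are given the external input
# switches from `stim` to `stim2` after `switch_after` steps WITHOUT
# resetting the lattice state. Records per-step predictions, mean lattice
# output, and (optionally) the full semantic vectors.
model_run_batch <- function(net, stim, t_max, stim2 = NULL, switch_after = 0L,
                            keep_semantics = TRUE, init = NULL) {
  plan <- net_plan(net)
  b <- nrow(stim)
  st <- if (is.null(init)) zero_batch_state(b, plan$p) else init
  preds <- matrix(NA_integer_, b, t_max)
  mean_y <- matrix(NA_real_, b, t_max)
  semantics <- if (keep_semantics) array(NA_real_, c(b, net$n_classes, t_max)) else NULL
  for (n in seq_len(t_max)) {
    s <- if (!is.null(stim2) && n > switch_after) stim2 else stim
    st <- step_batch(st, s, net$params, net$kernels, plan,
                     e_update = net$e_update)
    z <- readout_scores(net, st$y)
    preds[, n] <- max.col(z, ties.method = "first") - 1L
    mean_y[, n] <- rowMeans(st$y)
    if (keep_semantics) semantics[, , n] <- z
  }
  list(preds = preds, mean_y = mean_y, semantics = semantics, state = st)
}

#' Accuracy as a function of model time
#'
#' Runs every image of a dataset through the network for `t_max` model
#' times; the accuracy at model time t is the fraction of images whose
#' highest-scoring class at step t equals the label (ties broken towards the
#' lowest class index).
#'
#' @param net A trained [satiation_network()].
#' @param dataset A [labeled_image_set()].
#' @param t_max Number of model times to evaluate (the reference protocol
#'   uses 100).
#' @return A data frame with columns `model_time`, `accuracy`, `n_images`.
#' @export
evaluate_over_time <- function(net, dataset, t_max = 100L) {
  if (!inherits(dataset, "labeled_image_set")) {
    stop("`dataset` must be a labeled_image_set", call. = FALSE)
  }
  if (nrow(dataset$images) == 0L) stop("empty dataset", call. = FALSE)
  if (t_max < 1) stop("`t_max` must be >= 1", call. = FALSE)
  run <- model_run_batch(net, dataset$images, as.integer(t_max),
                         keep_semantics = FALSE)
  acc <- colMeans(run$preds == matrix(dataset$labels, nrow(run$preds),
                                      ncol(run$preds)))
  data.frame(model_time = seq_len(t_max), accuracy = acc,
             n_images = nrow(dataset$images))
}
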