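# The three satiation protocols: repeated same stimulus, prime/target
# switching with state carry-over, and the N400-style population statistic
# on mean lattice output.

#' Prime/target protocol description
#'
#' In the similar-stimulus protocol a prime stimulus (input-1) is presented
#' for `prime_repeats` model times, then the external input switches to a
#' target stimulus (input-2) WITHOUT resetting the lattice state, and the
#' target is classified at every subsequent model time.
#'
#' @param prime_class Class index of the prime (input-1).
#' @param target_classes Integer vector of target classes (input-2).
#' @param prime_repeats Number of prime presentations (the reference
#'   protocol uses 5 or 10); must be < `t_max`. 0 degenerates to the
#'   same-stimulus protocol on the targets.
#' @param t_max Total model times.
#' @param n_pairs Sampled (prime image, target image) pairs per target class.
#' @param seed Seed for pair sampling.
#' @param allow_prime_target If `FALSE` (default) the prime class may not
#'   appear among the targets.
#' @param early_window Number of post-switch model times entering the scalar
#'   early-accuracy summary.
#' @return An object of class `prime_target_protocol`.
#' @export
prime_target_protocol <- function(prime_class, target_classes,
                                  prime_repeats = 5L, t_max = 100L,
                                  n_pairs = 500L, seed = 1L,
                                  allow_prime_target = FALSE,
                                  early_window = 20L) {
  if (prime_repeats >= t_max) {
    stop("`prime_repeats` must be smaller than `t_max`", call. = FALSE)
  }
  if (!allow_prime_target && prime_class %in% target_classes) {
    stop("prime class among targets; set `allow_prime_target = TRUE` if intended",
         call. = FALSE)
  }
  structure(list(prime_class = as.integer(prime_class),
                 target_classes = as.integer(target_classes),
                 prime_repeats = as.integer(prime_repeats),
                 t_max = as.integer(t_max), n_pairs = as.integer(n_pairs),
                 seed = as.integer(seed), early_window = as.integer(early_window)),
            class = "prime_target_protocol")
}

warn_if_untrained <- function(net) {
  if (!isTRUE(net$trained)) {
    warning("network has not been trained; results reflect the initialization",
            call. = FALSE)
  }
}

#' Same-repeated-stimulus satiation experiment
#'
#' Presents every image of the dataset unchanged for `t_max` model times and
#' records, per image and model time, the predicted class, its correctness,
#' the mean lattice output (the population-activity proxy), and the semantic
#' vector. The accuracy curve is the satiation readout: it rises to a peak
#' near the supervised model time and then declines.
#'
#' @param net A trained [satiation_network()] (a warning is issued if
#'   untrained).
#' @param dataset A [labeled_image_set()].
#' @param t_max Number of model times (reference protocol: 100).
#' @param keep_semantics Record the full per-time semantic vectors (needed
#'   by [semantic_distances()]).
#' @return A list with `curve` (as [evaluate_over_time()]) and `traces`,
#'   itself a list with matrices `preds`, `correct`, `mean_y` (all B x
#'   t_max), array `semantics` (B x K x t_max) when kept, and `labels`.
#' @export
run_same_stimulus <- function(net, dataset, t_max = 100L,
                              keep_semantics = TRUE) {
  if (!inherits(dataset, "labeled_image_set")) {
    stop("`dataset` must be a labeled_image_set", call. = FALSE)
  }
  warn_if_untrained(net)
  run <- model_run_batch(net, dataset$images, as.integer(t_max),
                         keep_semantics = keep_semantics)
  correct <- run$preds == matrix(dataset$labels, nrow(run$preds), t_max)
  curve <- data.frame(model_time = seq_len(t_max),
                      accuracy = colMeans(correct),
                      n_images = nrow(dataset$images))
  list(curve = curve,
       traces = list(preds = run$preds, correct = correct,
                     mean_y = run$mean_y, semantics = run$semantics,
                     labels = dataset$labels, t_max = as.integer(t_max)))
}

#' Prime/target (similar-stimulus) satiation experiment
#'
#' For each target class, samples `n_pairs` (prime image, target image)
#' pairs, evolves the lattice `prime_repeats` steps under the prime, then
#' switches the external input to the target with full state carry-over,
#' and scores the target's true class at every post-switch model time.
#' The more similar the target class is to the prime, the harder the
#' post-switch classification.
#'
#' @param net A trained [satiation_network()].
#' @param dataset A [labeled_image_set()] supplying prime and target images.
#' @param protocol A [prime_target_protocol()].
#' @return A list with `curves` (data frame: `target_class`,
#'   `post_switch_time`, `model_time`, `accuracy`), `summary` (data frame:
#'   `target_class`, `early_accuracy` — mean over the first `early_window`
#'   post-switch steps), `mean_y` (list per target class of B x t_max mean
#'   outputs) and the protocol.
#' @export
run_prime_target <- function(net, dataset, protocol) {
  if (!inherits(protocol, "prime_target_protocol")) {
    stop("`protocol` must be a prime_target_protocol", call. = FALSE)
  }
  warn_if_untrained(net)
  set.seed(protocol$seed)
  prime_ids <- which(dataset$labels == protocol$prime_class)
  if (length(prime_ids) == 0L) stop("no images of the prime class", call. = FALSE)
  post_steps <- protocol$t_max - protocol$prime_repeats
  curves <- list(); summary_rows <- list(); mean_y <- list()
  for (tc in protocol$target_classes) {
    tgt_ids <- which(dataset$labels == tc)
    if (length(tgt_ids) == 0L) {
      stop(sprintf("no images of target class %d", tc), call. = FALSE)
    }
    pi_ <- sample(prime_ids, protocol$n_pairs, replace = TRUE)
    ti_ <- sample(tgt_ids, protocol$n_pairs, replace = TRUE)
    run <- model_run_batch(net,
                           dataset$images[pi_, , drop = FALSE],
                           protocol$t_max,
                           stim2 = dataset$images[ti_, , drop = FALSE],
                           switch_after = protocol$prime_repeats,
                           keep_semantics = FALSE)
    post <- seq(protocol$prime_repeats + 1L, protocol$t_max)
    acc <- colMeans(run$preds[, post, drop = FALSE] == tc)
    curves[[length(curves) + 1L]] <- data.frame(
      target_class = tc, post_switch_time = seq_len(post_steps),
      model_time = post, accuracy = acc)
    ew <- min(protocol$early_window, post_steps)
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      target_class = tc, early_accuracy = mean(acc[seq_len(ew)]))
    mean_y[[as.character(tc)]] <- run$mean_y
  }
  list(curves = do.call(rbind, curves),
       summary = do.call(rbind, summary_rows),
       mean_y = mean_y, protocol = protocol)
}

#' Group mean-output traces of a same-stimulus run by stimulus class
#'
#' @param traces The `traces` element returned by [run_same_stimulus()].
#' @return A named list (class index as name) of B_c x t_max matrices of
#'   mean lattice outputs.
#' @export
traces_by_class <- function(traces) {
  split.data.frame(traces$mean_y, traces$labels)
}

#' N400-style D-value curves from class-averaged lattice output
#'
#' For each class, the mean lattice output is averaged over that class's
#' traces at every model time; the D-value of a class pair is the
#' (by default absolute) difference of these per-time class averages — the
#' model-side analogue of the N400 amplitude difference between unrelated
#' and related stimuli. Dissimilar pairs give larger early D-values, and
#' the curves decline as satiation sets in.
#'
#' @param by_class Named list of B x T matrices of mean outputs per class
#'   (see [traces_by_class()]).
#' @param class_pairs List of length-2 vectors of class indices, e.g.
#'   `list(c(3, 7), c(9, 7))`.
#' @param signed If `TRUE`, return the signed difference (first minus
#'   second) instead of the absolute one.
#' @return A data frame with columns `pair`, `model_time`, `d_value`.
#' @export
n400_proxy <- function(by_class, class_pairs, signed = FALSE) {
  avg <- lapply(by_class, function(m) {
    if (is.null(m) || nrow(m) == 0L) stop("empty class group", call. = FALSE)
    colMeans(m)
  })
  rows <- lapply(class_pairs, function(pr) {
    a <- as.character(pr[1]); b <- as.character(pr[2])
    if (is.null(avg[[a]]) || is.null(avg[[b]])) {
      stop(sprintf("missing traces for pair (%s, %s)", a, b), call. = FALSE)
    }
    d <- avg[[a]] - avg[[b]]
    if (!signed) d <- abs(d)
    data.frame(pair = paste0(a, "-", b), model_time = seq_along(d),
               d_value = d)
  })
  do.call(rbind, rows)
}
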