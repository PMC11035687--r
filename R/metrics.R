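# Quantitative comparisons: structural similarity between image categories
# and inter-/intra-class Euclidean distances of the 10-d semantic vectors.

# (n - 2m) x n valid-mode filter matrix applying the 1-D kernel g
filter_matrix <- function(n, g) {
  m <- (length(g) - 1L) %/% 2L
  out <- matrix(0, n - 2L * m, n)
  for (i in seq_len(n - 2L * m)) out[i, i:(i + 2L * m)] <- g
  out
}

#' Structural similarity index (SSIM) of two images
#'
#' The standard Gaussian-weighted SSIM: local means, variances and
#' covariance are computed under a normalized truncated Gaussian window and
#' combined as
#' `((2*mu_a*mu_b + C1) * (2*cov_ab + C2)) / ((mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2))`,
#' with `C1 = (k1 * L)^2`, `C2 = (k2 * L)^2` for data range L; the index is
#' the mean of this map over all fully-supported window positions. Values
#' lie in \[-1, 1\], with 1 for identical images.
#'
#' @param image_a,image_b Numeric matrices of one shape.
#' @param window Odd window side length (default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @param k1,k2 Stabilization constants.
#' @param data_range Dynamic range L of the data (1 for \[0, 1\] images).
#' @return A scalar similarity in \[-1, 1\].
#' @export
#' @examples
#' a <- matrix(runif(784), 28, 28)
#' ssim(a, a)
ssim <- function(image_a, image_b, window = 11L, sigma = 1.5,
                 k1 = 0.01, k2 = 0.03, data_range = 1.0) {
  if (!identical(dim(image_a), dim(image_b))) {
    stop("images must share one shape", call. = FALSE)
  }
  if (data_range <= 0) stop("`data_range` must be > 0", call. = FALSE)
  if (window %% 2L != 1L) stop("`window` must be odd", call. = FALSE)
  if (window > min(dim(image_a))) {
    stop("`window` larger than the image", call. = FALSE)
  }
  m <- (window - 1L) %/% 2L
  g <- exp(-(seq(-m, m))^2 / (2 * sigma^2))
  g <- g / sum(g)
  a_rows <- filter_matrix(nrow(image_a), g)
  a_cols <- filter_matrix(ncol(image_a), g)
  filt <- function(x) a_rows %*% x %*% t(a_cols)
  mu_a <- filt(image_a); mu_b <- filt(image_b)
  var_a <- filt(image_a * image_a) - mu_a^2
  var_b <- filt(image_b * image_b) - mu_b^2
  cov_ab <- filt(image_a * image_b) - mu_a * mu_b
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  map <- ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
  mean(map)
}

#' SSIM matrix between all class-mean images of a dataset
#'
#' Computes the pixel-wise mean image of every class and the SSIM between
#' every pair of class means: a symmetric matrix with unit diagonal, rows
#' and columns labeled with the class names. A fixed-seed single-exemplar
#' mode is available as an alternative to class means.
#'
#' @param dataset A [labeled_image_set()] covering all of its classes.
#' @param mode `"mean"` (pixel-wise class-mean images, the default) or
#'   `"exemplar"` (one seeded random exemplar per class).
#' @param seed Seed for exemplar sampling.
#' @param ... Passed to [ssim()].
#' @return A symmetric `n_classes` x `n_classes` numeric matrix.
#' @export
class_similarity_matrix <- function(dataset, mode = c("mean", "exemplar"),
                                    seed = 1L, ...) {
  mode <- match.arg(mode)
  k <- length(dataset$class_names)
  present <- sort(unique(dataset$labels))
  if (!identical(present, 0:(k - 1L))) {
    stop(sprintf("dataset is missing classes: %s",
                 paste(setdiff(0:(k - 1L), present), collapse = ", ")),
         call. = FALSE)
  }
  reps <- vector("list", k)
  if (mode == "mean") {
    for (c in seq_len(k)) reps[[c]] <- class_mean_image(dataset, c - 1L)
  } else {
    set.seed(seed)
    for (c in seq_len(k)) {
      ids <- which(dataset$labels == c - 1L)
      reps[[c]] <- get_image(dataset, sample(ids, 1L))
    }
  }
  s <- diag(1, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      s[i, j] <- s[j, i] <- ssim(reps[[i]], reps[[j]], ...)
    }
  }
  dimnames(s) <- list(dataset$class_names, dataset$class_names)
  s
}

#' Inter- and intra-class semantic distances per model time
#'
#' For the 10-d semantic vectors recorded at each model time, computes the
#' class centroids and reports: `inter_class`, the mean Euclidean distance
#' between centroids over all unordered class pairs, and `intra_class`, the
#' mean distance from each sample's vector to its class centroid, averaged
#' over classes. Classes with fewer than 2 samples are excluded with a
#' warning.
#'
#' @param semantics A B x K x T array of semantic vectors (B samples, K
#'   classes/scores, T model times), e.g. `traces$semantics` from
#'   [run_same_stimulus()].
#' @param labels Integer class labels of the B samples.
#' @param intra `"centroid"` (mean sample-to-centroid distance, default) or
#'   `"pairwise"` (mean pairwise distance within class).
#' @param pairwise_inter If `TRUE`, attach the per-pair centroid distance
#'   matrices as attribute `"pair_distances"` (a list over model times).
#' @return A data frame with columns `model_time`, `inter_class`,
#'   `intra_class`.
#' @export
semantic_distances <- function(semantics, labels,
                               intra = c("centroid", "pairwise"),
                               pairwise_inter = FALSE) {
  intra <- match.arg(intra)
  stopifnot(length(dim(semantics)) == 3L, dim(semantics)[1] == length(labels))
  tmax <- dim(semantics)[3]
  counts <- table(labels)
  keep <- as.integer(names(counts)[counts >= 2L])
  if (length(keep) < length(counts)) {
    warning(sprintf("excluding classes with < 2 samples: %s",
                    paste(setdiff(as.integer(names(counts)), keep),
                          collapse = ", ")))
  }
  if (length(keep) < 1L) stop("no class has >= 2 samples", call. = FALSE)
  inter <- intra_d <- numeric(tmax)
  pair_list <- if (pairwise_inter) vector("list", tmax) else NULL
  for (t in seq_len(tmax)) {
    v <- semantics[, , t, drop = TRUE]
    if (is.null(dim(v))) v <- matrix(v, ncol = dim(semantics)[2])
    cents <- t(vapply(keep, function(cl)
      colMeans(v[labels == cl, , drop = FALSE]), numeric(ncol(v))))
    dd <- as.matrix(stats::dist(cents))
    inter[t] <- if (length(keep) > 1L) mean(dd[upper.tri(dd)]) else 0
    if (pairwise_inter) {
      dimnames(dd) <- list(keep, keep)
      pair_list[[t]] <- dd
    }
    per_class <- vapply(seq_along(keep), function(i) {
      rows <- v[labels == keep[i], , drop = FALSE]
      if (intra == "centroid") {
        mean(sqrt(rowSums(sweep(rows, 2L, cents[i, ])^2)))
      } else {
        mean(stats::dist(rows))
      }
    }, numeric(1))
    intra_d[t] <- mean(per_class)
  }
  out <- data.frame(model_time = seq_len(tmax), inter_class = inter,
                    intra_class = intra_d)
  if (pairwise_inter) attr(out, "pair_distances") <- pair_list
  out
}

#' Project semantic vectors to two dimensions
#'
#' Thin hook delegating to an off-the-shelf embedding routine for plotting;
#' the default is the first two principal components (`stats::prcomp`). Any
#' function taking a matrix and returning an n x 2 matrix can be plugged in
#' (the seed is set before it is called, so stochastic embeddings are
#' reproducible).
#'
#' @param vectors An n x d numeric matrix (n >= 10).
#' @param seed RNG seed set before the method runs.
#' @param method Embedding function; `NULL` uses the PCA default.
#' @return An n x 2 matrix of coordinates.
#' @export
embed_2d <- function(vectors, seed = 1L, method = NULL) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 10L) stop("need at least 10 vectors", call. = FALSE)
  set.seed(seed)
  if (is.null(method)) {
    method <- function(x) {
      p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 2L)
      s <- p$x
      if (ncol(s) < 2L) s <- cbind(s, 0)
      s[, 1:2, drop = FALSE]
    }
  }
  out <- method(vectors)
  stopifnot(nrow(out) == nrow(vectors), ncol(out) == 2L)
  unname(as.matrix(out))
}
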