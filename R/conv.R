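# Zero-padded, stride-1 cross-correlation over a flattened lattice.
#
# Images live in B x P matrices, one row per lattice, pixel index
# p = (row - 1) * W + col (row-major flatten; see flatten_image()). A conv
# "plan" precomputes, for each kernel offset, the column indices into the
# zero-padded layout, so a convolution is k^2 scaled column-gathers — fast
# enough in plain R for 28x28 lattices at training batch sizes.

.conv_plan_cache <- new.env(parent = emptyenv())

conv_plan <- function(h, w, ksize) {
  key <- paste(h, w, ksize, sep = "x")
  if (!is.null(.conv_plan_cache[[key]])) return(.conv_plan_cache[[key]])
  m <- (ksize - 1L) %/% 2L
  wp <- w + 2L * m
  rows <- rep(seq_len(h), each = w)
  cols <- rep(seq_len(w), times = h)
  # column in the padded layout holding original pixel (r, c)
  pad_at <- function(r, c) (r + m - 1L) * wp + (c + m)
  pad_idx <- pad_at(rows, cols)
  # offsets enumerated in column-major order of the k x k kernel matrix:
  # kernel[a, b] couples output (r, c) to input (r + a - 1 - m, c + b - 1 - m)
  offs <- vector("list", ksize * ksize)
  i <- 1L
  for (b in seq_len(ksize)) {
    dc <- b - 1L - m
    for (a in seq_len(ksize)) {
      dr <- a - 1L - m
      offs[[i]] <- pad_at(rows + dr, cols + dc)
      i <- i + 1L
    }
  }
  plan <- list(h = h, w = w, ksize = ksize, margin = m,
               p = h * w, p_padded = (h + 2L * m) * wp,
               pad_idx = pad_idx, offsets = offs)
  .conv_plan_cache[[key]] <- plan
  plan
}

pad_batch <- function(x, plan) {
  xp <- matrix(0, nrow(x), plan$p_padded)
  xp[, plan$pad_idx] <- x
  xp
}

# cross-correlation: out[, p] = sum_k kernel_vec[k] * x[, p + off_k]
conv_batch <- function(x, kernel, plan, x_padded = NULL) {
  kv <- as.vector(kernel)
  if (length(kv) != plan$ksize^2) stop("kernel size does not match plan")
  if (is.null(x_padded)) x_padded <- pad_batch(x, plan)
  acc <- matrix(0, nrow(x_padded), plan$p)
  for (k in seq_along(kv)) {
    if (kv[k] != 0) acc <- acc + kv[k] * x_padded[, plan$offsets[[k]]]
  }
  acc
}

# gradient of sum(g * conv(x, kernel)) w.r.t. the kernel entries
conv_kernel_grad <- function(g, plan, x_padded) {
  kv <- numeric(plan$ksize^2)
  for (k in seq_along(kv)) {
    kv[k] <- sum(g * x_padded[, plan$offsets[[k]]])
  }
  matrix(kv, plan$ksize, plan$ksize)
}

# gradient of sum(g * conv(x, kernel)) w.r.t. x: correlation with the
# 180-degree-rotated kernel (column-major vector reversal flips both axes)
conv_input_grad <- function(g, kernel, plan) {
  conv_batch(g, rev(as.vector(kernel)), plan)
}

#' Flatten a lattice matrix to the row-major vector order used by the readout
#'
#' The dense readout consumes the 28x28 lattice output as a 784-vector in
#' row-major order: pixel (r, c) maps to index `(r - 1) * ncol + c`. All
#' batched internal computations use this order.
#'
#' @param img A numeric matrix.
#' @return A numeric vector of length `nrow(img) * ncol(img)`.
#' @export
flatten_image <- function(img) as.vector(t(img))

#' Inverse of [flatten_image()]
#'
#' @param v A numeric vector of length `nrow * ncol`.
#' @param nrow,ncol Target matrix shape.
#' @return A numeric matrix.
#' @export
unflatten_image <- function(v, nrow = 28, ncol = 28) {
  matrix(v, nrow, ncol, byrow = TRUE)
}
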