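# Literal per-neuron double-loop implementation of the lattice recursions,
# kept deliberately naive and independent of the vectorized path.
oracle_step <- function(state, stim, params, kernels, hard = FALSE) {
  h <- nrow(stim); w <- ncol(stim)
  ks <- kernels$size; m <- (ks - 1L) %/% 2L
  f <- l <- u <- e <- y <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      conv_m <- 0; conv_w <- 0
      for (a in seq_len(ks)) {
        for (b in seq_len(ks)) {
          ki <- i + a - 1L - m
          kj <- j + b - 1L - m
          if (ki >= 1 && ki <= h && kj >= 1 && kj <= w) {
            conv_m <- conv_m + kernels$m[a, b] * state$y[ki, kj]
            conv_w <- conv_w + kernels$w[a, b] * state$y[ki, kj]
          }
        }
      }
      f[i, j] <- exp(-params$alpha_f) * state$f[i, j] +
        params$v_f * conv_m + stim[i, j]
      l[i, j] <- exp(-params$alpha_l) * state$l[i, j] + params$v_l * conv_w
      u[i, j] <- f[i, j] * (1 + params$beta * l[i, j])
      y[i, j] <- if (hard) {
        as.numeric(u[i, j] > state$e[i, j])
      } else {
        1 / (1 + exp(-(u[i, j] - state$e[i, j])))
      }
      e[i, j] <- exp(-params$alpha_e) * state$e[i, j] +
        params$v_e * state$y[i, j]
    }
  }
  lattice_state(f, l, u, e, y)
}

random_state <- function(h, w) {
  lattice_state(matrix(rnorm(h * w), h, w), matrix(rnorm(h * w), h, w),
                matrix(rnorm(h * w), h, w), matrix(rnorm(h * w), h, w),
                matrix(runif(h * w), h, w))
}

max_state_diff <- function(a, b) {
  max(abs(a$f - b$f), abs(a$l - b$l), abs(a$u - b$u),
      abs(a$e - b$e), abs(a$y - b$y))
}
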