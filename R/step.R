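# Lattice update rules.
#
# One model time advances the five coupled recursions in the order
# F, L, U, Y, E:
#   F(n) = exp(-alpha_f) F(n-1) + V_F (M * Y(n-1)) + S
#   L(n) = exp(-alpha_l) L(n-1) + V_L (W * Y(n-1))
#   U(n) = F(n) (1 + beta L(n))
#   Y(n) = sigmoid(U(n) - E(n-1))          (CCNN)  |  1[U(n) > E(n-1)]  (PCNN)
#   E(n) = exp(-alpha_e) E(n-1) + V_E Y(n-1)
# where * is zero-padded cross-correlation with the shared receptive-field
# kernel. The printed recursions define Y(n) through E(n) while E(n) itself
# is driven by Y(n-1); the default breaks that circularity by thresholding
# against the pre-update activity E(n-1) (`e_update = "after_y"`). The
# alternative ordering, updating E first and using E(n) inside Y(n), is
# available as `e_update = "before_y"`.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Batched single step on B x P matrices. `st` is list(f, l, e, y); returns
# list(f, l, u, e, y). Shared by the public step functions, the experiment
# engine and the trainer.
step_batch <- function(st, s, params, kernels, plan,
                       hard = FALSE, e_update = c("after_y", "before_y"),
                       y_padded = NULL) {
  e_update <- match.arg(e_update)
  if (is.null(y_padded)) y_padded <- pad_batch(st$y, plan)
  f <- exp(-params$alpha_f) * st$f +
    params$v_f * conv_batch(NULL, kernels$m, plan, x_padded = y_padded) + s
  l <- exp(-params$alpha_l) * st$l +
    params$v_l * conv_batch(NULL, kernels$w, plan, x_padded = y_padded)
  u <- f * (1 + params$beta * l)
  e_new <- exp(-params$alpha_e) * st$e + params$v_e * st$y
  e_thr <- if (e_update == "before_y") e_new else st$e
  y <- if (hard) (u > e_thr) + 0 else sigmoid(u - e_thr)
  list(f = f, l = l, u = u, e = e_new, y = y)
}

check_step_args <- function(state, stim, kernels) {
  if (!inherits(state, "lattice_state")) stop("`state` must be a lattice_state", call. = FALSE)
  if (!is.matrix(stim)) stop("`stimulus` must be a matrix", call. = FALSE)
  if (!identical(dim(state$f), dim(stim))) {
    stop("state and stimulus shapes differ", call. = FALSE)
  }
  for (nm in c("f", "l", "u", "e", "y")) {
    if (any(!is.finite(state[[nm]]))) {
      stop(sprintf("non-finite values in state matrix `%s`", nm), call. = FALSE)
    }
  }
  if (!inherits(kernels, "coupling_kernels")) {
    stop("`kernels` must be a coupling_kernels object", call. = FALSE)
  }
}

step_one <- function(state, stim, params, kernels, hard, e_update) {
  check_step_args(state, stim, kernels)
  h <- nrow(stim); w <- ncol(stim)
  plan <- conv_plan(h, w, kernels$size)
  st <- list(f = matrix(flatten_image(state$f), 1),
             l = matrix(flatten_image(state$l), 1),
             e = matrix(flatten_image(state$e), 1),
             y = matrix(flatten_image(state$y), 1))
  nx <- step_batch(st, matrix(flatten_image(stim), 1), params, kernels, plan,
                   hard = hard, e_update = e_update)
  lattice_state(unflatten_image(nx$f[1, ], h, w),
                unflatten_image(nx$l[1, ], h, w),
                unflatten_image(nx$u[1, ], h, w),
                unflatten_image(nx$e[1, ], h, w),
                unflatten_image(nx$y[1, ], h, w))
}

#' Advance the CCNN lattice by one model time
#'
#' Computes the next state of the continuous coupled lattice under an
#' external feeding stimulus, in the order F, L, U, Y, E. The continuous
#' output is `Y(n) = sigmoid(U(n) - E(n-1))`, so every entry of `y` lies
#' strictly in (0, 1).
#'
#' @param state Current [lattice_state()] (use [zero_state()] at model time 0:
#'   all neurons start static).
#' @param stim External feeding input matrix with values in \[0, 1\] and the
#'   same shape as the state (see [stimulus()]).
#' @param params A [ccnn_params()] object.
#' @param kernels A [coupling_kernels()] object.
#' @param e_update Ordering of the dynamic-activity update relative to the
#'   output: `"after_y"` (default) thresholds Y against the pre-update
#'   activity E(n-1); `"before_y"` updates E first and uses E(n).
#' @return The next `lattice_state`.
#' @export
#' @examples
#' s <- ccnn_step(zero_state(8, 8), matrix(1, 8, 8),
#'                ccnn_params(), coupling_kernels(3, seed = 1))
#' range(s$y)
ccnn_step <- function(state, stim, params = ccnn_params(),
                      kernels = coupling_kernels(3, seed = 0L),
                      e_update = c("after_y", "before_y")) {
  step_one(state, stim, params, kernels, hard = FALSE,
           e_update = match.arg(e_update))
}

#' Advance the PCNN lattice by one model time
#'
#' Identical to [ccnn_step()] except that the output is the hard pulse
#' `Y(n) = 1` when `U(n) > E(n-1)` and 0 otherwise (strict inequality: a
#' neuron exactly at threshold does not fire).
#'
#' @inheritParams ccnn_step
#' @return The next `lattice_state`, with binary `y`.
#' @export
pcnn_step <- function(state, stim, params = ccnn_params(),
                      kernels = coupling_kernels(3, seed = 0L),
                      e_update = c("after_y", "before_y")) {
  step_one(state, stim, params, kernels, hard = TRUE,
           e_update = match.arg(e_update))
}

#' Iterate the lattice over a stimulus sequence
#'
#' Runs the coupled lattice for `length(stimuli)` model times, feeding
#' `stimuli[[n]]` at step n. Model time counts discrete updates and stands
#' in for stimulus presentation duration.
#'
#' @param initial Starting [lattice_state()].
#' @param stimuli A non-empty list of stimulus matrices (or a single matrix,
#'   taken as a one-step sequence). All must share the state's shape.
#' @param params A [ccnn_params()] object.
#' @param kernels A [coupling_kernels()] object.
#' @param rule `"ccnn"` (continuous output) or `"pcnn"` (binary pulses).
#' @param record If `TRUE`, keep the full per-step trajectory.
#' @inheritParams ccnn_step
#' @return A list with `final` (the last `lattice_state`) and, when
#'   `record = TRUE`, `trajectory`: a list of `lattice_state`s of length
#'   `length(stimuli)`.
#' @export
run_lattice <- function(initial, stimuli, params = ccnn_params(),
                        kernels = coupling_kernels(3, seed = 0L),
                        rule = c("ccnn", "pcnn"), record = FALSE,
                        e_update = c("after_y", "before_y")) {
  rule <- match.arg(rule)
  e_update <- match.arg(e_update)
  if (is.matrix(stimuli)) stimuli <- list(stimuli)
  if (length(stimuli) == 0L) stop("`stimuli` must be non-empty", call. = FALSE)
  state <- initial
  traj <- if (record) vector("list", length(stimuli)) else NULL
  for (n in seq_along(stimuli)) {
    state <- step_one(state, stimuli[[n]], params, kernels,
                      hard = (rule == "pcnn"), e_update = e_update)
    if (record) traj[[n]] <- state
  }
  out <- list(final = state)
  if (record) out$trajectory <- traj
  out
}
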