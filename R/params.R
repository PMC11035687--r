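#' CCNN / PCNN neuron parameters
#'
#' Bundles the exponential decay factors, weighting factors and linking
#' strength that govern the coupled-lattice update rules. The defaults are
#' the reference configuration used throughout the package's experiments:
#' `alpha_f = 0.1`, `alpha_l = 0.1`, `alpha_e = 1`, `beta = 0.5`, and unit
#' weighting factors.
#'
#' @param alpha_f Exponential decay factor of the feeding input (dimensionless,
#'   > 0); the feeding accumulator is multiplied by `exp(-alpha_f)` each step.
#' @param alpha_l Exponential decay factor of the linking input (> 0).
#' @param alpha_e Exponential decay factor of the dynamic activity
#'   (adaptive threshold, > 0).
#' @param beta Linking strength coupling the linking input into the
#'   modulation product `U = F * (1 + beta * L)`.
#' @param v_f,v_l,v_e Weighting factors of the feeding, linking and
#'   dynamic-activity contributions. Not fixed by the reference
#'   configuration; unit weighting is the conventional baseline and is the
#'   default (see the package vignette).
#'
#' @return An object of class `ccnn_params`.
#' @seealso [coupling_kernels()], [ccnn_step()], [pcnn_step()]
#' @export
#' @examples
#' p <- ccnn_params()
#' p$beta
ccnn_params <- function(alpha_f = 0.1, alpha_l = 0.1, alpha_e = 1,
                        beta = 0.5, v_f = 1, v_l = 1, v_e = 1) {
  for (nm in c("alpha_f", "alpha_l", "alpha_e")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single strictly positive number", nm),
           call. = FALSE)
    }
  }
  for (nm in c("beta", "v_f", "v_l", "v_e")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
  }
  structure(
    list(alpha_f = alpha_f, alpha_l = alpha_l, alpha_e = alpha_e,
         beta = beta, v_f = v_f, v_l = v_l, v_e = v_e),
    class = "ccnn_params"
  )
}

#' @export
print.ccnn_params <- function(x, ...) {
  cat("CCNN parameters\n")
  cat(sprintf("  decay:    alpha_f=%g alpha_l=%g alpha_e=%g\n",
              x$alpha_f, x$alpha_l, x$alpha_e))
  cat(sprintf("  linking:  beta=%g\n", x$beta))
  cat(sprintf("  weights:  v_f=%g v_l=%g v_e=%g\n", x$v_f, x$v_l, x$v_e))
  invisible(x)
}

#' Feeding and linking receptive-field kernels
#'
#' The two learnable square kernels through which each lattice neuron
#' receives the outputs of its neighbours: `m` feeds into the feeding input
#' F and `w` into the linking input L. Both are applied as zero-padded,
#' stride-1 cross-correlation ("convolution without bias") and are shared
#' across all lattice positions, which is what makes them learnable as
#' convolution kernels.
#'
#' @param size Odd kernel side length; the supported receptive fields are
#'   3 and 5. Ignored when both `m` and `w` are given.
#' @param m,w Optional numeric square matrices of identical odd size. When
#'   omitted, kernels are initialized with small positive uniform values in
#'   (0, `init_scale`], mirroring excitatory coupling.
#' @param init_scale Upper bound of the uniform initialization.
#' @param seed Optional integer seed for the random initialization.
#'
#' @return An object of class `coupling_kernels` with elements `m`, `w` and
#'   `size`.
#' @export
#' @examples
#' k <- coupling_kernels(3, seed = 1)
#' dim(k$m)
coupling_kernels <- function(size = 3, m = NULL, w = NULL,
                             init_scale = 0.1, seed = NULL) {
  if (is.null(m) != is.null(w)) {
    stop("supply both `m` and `w`, or neither", call. = FALSE)
  }
  if (is.null(m)) {
    if (!size %in% c(3, 5)) {
      stop("`size` must be 3 or 5", call. = FALSE)
    }
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    m <- matrix(stats::runif(size^2, 0, init_scale), size, size)
    w <- matrix(stats::runif(size^2, 0, init_scale), size, size)
  } else {
    m <- as.matrix(m); w <- as.matrix(w)
    if (!identical(dim(m), dim(w)) || nrow(m) != ncol(m)) {
      stop("`m` and `w` must be square matrices of identical shape",
           call. = FALSE)
    }
    if (nrow(m) %% 2L == 0L) {
      stop("kernel side length must be odd", call. = FALSE)
    }
    size <- nrow(m)
  }
  structure(list(m = m, w = w, size = as.integer(size)),
            class = "coupling_kernels")
}

#' @export
print.coupling_kernels <- function(x, ...) {
  cat(sprintf("Coupling kernels (%dx%d receptive field)\n", x$size, x$size))
  cat("  m (feeding):  range", signif(range(x$m), 4), "\n")
  cat("  w (linking):  range", signif(range(x$w), 4), "\n")
  invisible(x)
}

#' Lattice state of the coupled network
#'
#' The five per-neuron matrices of the lattice at one model time: feeding
#' input `f`, linking `l`, modulation product `u`, dynamic activity (adaptive
#' threshold) `e`, and output `y`. For the CCNN, `y` is a continuous value in
#' (0, 1); for the PCNN it is binary.
#'
#' @param f,l,u,e,y Numeric matrices of one common shape.
#' @return An object of class `lattice_state`.
#' @seealso [zero_state()]
#' @export
lattice_state <- function(f, l, u, e, y) {
  mats <- list(f = f, l = l, u = u, e = e, y = y)
  d <- dim(f)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!is.matrix(m) || !is.numeric(m)) {
      stop(sprintf("`%s` must be a numeric matrix", nm), call. = FALSE)
    }
    if (!identical(dim(m), d)) {
      stop("all five state matrices must share one shape", call. = FALSE)
    }
  }
  structure(mats, class = "lattice_state")
}

#' All-neurons-static initial state
#'
#' Every neuron starts static: all five matrices F, L, U, E, Y are zero.
#'
#' @param nrow,ncol Lattice dimensions (default the 28x28 = 784-neuron
#'   lattice matching the input images).
#' @return A `lattice_state` of zeros.
#' @export
#' @examples
#' s <- zero_state(28, 28)
#' all(s$y == 0)
zero_state <- function(nrow = 28, ncol = 28) {
  z <- matrix(0, nrow, ncol)
  lattice_state(z, z, z, z, z)
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("Lattice state %dx%d; mean Y = %.4f\n",
              nrow(x$f), ncol(x$f), mean(x$y)))
  invisible(x)
}

#' External feeding stimulus
#'
#' Validates (and optionally rescales) an image into the external feeding
#' input S of the lattice. Values must lie in [0, 1] after normalization.
#'
#' @param x Numeric matrix of pixel intensities.
#' @param normalize If `TRUE`, divide by 255 first (8-bit input).
#' @return An object of class `stimulus` (a numeric matrix).
#' @export
stimulus <- function(x, normalize = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("stimulus must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("stimulus contains non-finite values", call. = FALSE)
  if (normalize) x <- x / 255
  if (min(x) < 0 || max(x) > 1) {
    stop("stimulus intensities must lie in [0, 1] (use normalize = TRUE for 8-bit input)",
         call. = FALSE)
  }
  structure(x, class = c("stimulus", "matrix"))
}
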