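# Synthetic stroke-glyph generator.
#
# Renders 28x28 grayscale glyphs from stroke specifications (line segments
# and elliptical arcs in the unit square, y pointing down), with per-sample
# affine jitter and pixel noise, emulating the structure of handwritten-digit
# data: bright anti-aliased strokes on a dark background, 10 classes, and a
# controllable pairwise structural similarity between classes driven by how
# many strokes two classes share. The frozen default specification ships in
# inst/extdata/glyphs10.yaml; its class geometries mirror the similarity
# relations of the digits (class 7 shares the near-vertical stroke of class
# 1, class 9 shares it partially, class 3 not at all).

#' Glyph specification
#'
#' @param classes List of classes; each is a list with `name` and `strokes`,
#'   where a stroke is `list(type = "line", x1, y1, x2, y2)` or
#'   `list(type = "arc", cx, cy, rx, ry, from, to)` (angles in degrees,
#'   y-down coordinates).
#' @param image_size Output image side length in pixels.
#' @param thickness Stroke half-width in unit-square units.
#' @param aa Anti-aliasing roll-off width.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param jitter_sd Scale of the per-sample affine perturbation (rotation in
#'   radians, relative scale, and translation share this SD).
#' @param seed Base RNG seed; rendering is deterministic given the seed.
#' @return An object of class `glyph_spec`.
#' @export
glyph_spec <- function(classes, image_size = 28L, thickness = 0.04,
                       aa = 0.02, noise_sd = 0.05, jitter_sd = 0.05,
                       seed = 42L) {
  if (length(classes) == 0L) stop("at least one class required", call. = FALSE)
  for (cl in classes) {
    if (is.null(cl$strokes) || length(cl$strokes) == 0L) {
      stop("every class needs at least one stroke", call. = FALSE)
    }
  }
  structure(list(classes = classes, image_size = as.integer(image_size),
                 thickness = thickness, aa = aa, noise_sd = noise_sd,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "glyph_spec")
}

#' Read a glyph specification from YAML
#'
#' @param path Path to a YAML file with the fields of [glyph_spec()].
#' @return A `glyph_spec`.
#' @export
read_glyph_spec <- function(path) {
  y <- yaml::read_yaml(path)
  glyph_spec(classes = y$classes, image_size = y$image_size %||% 28L,
             thickness = y$thickness %||% 0.04, aa = y$aa %||% 0.02,
             noise_sd = y$noise_sd %||% 0.05,
             jitter_sd = y$jitter_sd %||% 0.05, seed = y$seed %||% 42L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The frozen 10-class default glyph specification
#'
#' Ten digit-like stroke glyphs whose class-mean structural similarities
#' reproduce the orderings the satiation protocols rely on (see the package
#' vignette).
#'
#' @return A `glyph_spec`.
#' @export
glyph_spec_default <- function() {
  read_glyph_spec(system.file("extdata", "glyphs10.yaml",
                              package = "ccnnsat", mustWork = TRUE))
}

# polyline points (2 x k matrix) of one stroke, before jitter
stroke_points <- function(st) {
  if (st$type == "line") {
    rbind(c(st$x1, st$x2), c(st$y1, st$y2))
  } else if (st$type == "arc") {
    span <- abs(st$to - st$from)
    k <- max(8L, ceiling(span / 9))
    ang <- seq(st$from, st$to, length.out = k + 1L) * pi / 180
    rbind(st$cx + st$rx * cos(ang), st$cy + st$ry * sin(ang))
  } else {
    stop(sprintf("unknown stroke type '%s'", st$type), call. = FALSE)
  }
}

# min distance from each of the points (2 x P) to the polyline (2 x K)
dist_to_polyline <- function(px, py, poly) {
  d2 <- rep(Inf, length(px))
  for (i in seq_len(ncol(poly) - 1L)) {
    ax <- poly[1, i]; ay <- poly[2, i]
    bx <- poly[1, i + 1L]; by <- poly[2, i + 1L]
    vx <- bx - ax; vy <- by - ay
    vv <- vx * vx + vy * vy
    t <- if (vv == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / vv))
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

render_glyph <- function(strokes, spec, rot = 0, scale = 1, shift = c(0, 0)) {
  n <- spec$image_size
  cc <- (seq_len(n) - 0.5) / n
  px <- rep(cc, times = n)          # row-major flatten: x varies fastest
  py <- rep(cc, each = n)
  cs <- cos(rot); sn <- sin(rot)
  img <- numeric(n * n)
  for (st in strokes) {
    pts <- stroke_points(st)
    # affine about the glyph centre
    qx <- (pts[1, ] - 0.5) * scale; qy <- (pts[2, ] - 0.5) * scale
    tx <- 0.5 + cs * qx - sn * qy + shift[1]
    ty <- 0.5 + sn * qx + cs * qy + shift[2]
    d <- dist_to_polyline(px, py, rbind(tx, ty))
    img <- pmax(img, pmin(1, pmax(0, (spec$thickness + spec$aa - d) / spec$aa)))
  }
  img
}

#' Generate a balanced synthetic glyph dataset
#'
#' Renders `n_per_class` jittered, noisy samples of every class of the
#' specification. Generation is deterministic given the seed (same seed,
#' byte-identical output).
#'
#' @param spec A [glyph_spec()].
#' @param n_per_class Samples per class.
#' @param seed Seed override (defaults to `spec$seed`).
#' @return A [labeled_image_set()] with source `"synthetic:<seed>"`.
#' @export
#' @examples
#' ds <- generate_glyphs(glyph_spec_default(), n_per_class = 5)
#' table(ds$labels)
generate_glyphs <- function(spec, n_per_class, seed = spec$seed) {
  if (n_per_class < 1) stop("`n_per_class` must be >= 1", call. = FALSE)
  k <- length(spec$classes)
  n <- spec$image_size
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  images <- matrix(0, k * n_per_class, n * n)
  labels <- integer(k * n_per_class)
  row <- 1L
  for (ci in seq_len(k)) {
    strokes <- spec$classes[[ci]]$strokes
    for (s in seq_len(n_per_class)) {
      rot <- stats::rnorm(1, 0, spec$jitter_sd)
      scale <- 1 + stats::rnorm(1, 0, spec$jitter_sd)
      shift <- stats::rnorm(2, 0, spec$jitter_sd)
      img <- render_glyph(strokes, spec, rot, scale, shift)
      if (spec$noise_sd > 0) {
        img <- pmin(1, pmax(0, img + stats::rnorm(n * n, 0, spec$noise_sd)))
      }
      images[row, ] <- img
      labels[row] <- ci - 1L
      row <- row + 1L
    }
  }
  labeled_image_set(images, labels,
                    class_names = vapply(spec$classes, function(cl)
                      as.character(cl$name), character(1)),
                    source = paste0("synthetic:", seed), dim = c(n, n))
}

#' The frozen synthetic benchmark splits
#'
#' The package's default download-free benchmark: the 10-class glyph
#' specification with 1000 training and 200 test images per class, train and
#' test drawn with distinct seeds.
#'
#' @param n_train,n_test Images per class in each split.
#' @param seed Base seed; the test split uses `seed + 1`.
#' @param spec The glyph specification (default [glyph_spec_default()]).
#' @return A list with elements `train` and `test`.
#' @export
synthetic_benchmark <- function(n_train = 1000L, n_test = 200L, seed = 42L,
                                spec = glyph_spec_default()) {
  list(train = generate_glyphs(spec, n_train, seed = seed),
       test = generate_glyphs(spec, n_test, seed = seed + 1L))
}
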