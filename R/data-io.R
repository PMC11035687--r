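# Labeled image sets and IDX (ubyte) input/output.
#
# Images are stored as an N x P matrix of intensities in [0, 1], one row per
# image in row-major pixel order (the order IDX files store pixels in, and
# the order the dense readout consumes).

#' Labeled set of grayscale images
#'
#' @param images An N x P numeric matrix (P = height * width, row-major
#'   pixel order) or an N x H x W array, intensities in \[0, 1\].
#' @param labels Integer class indices in 0..(n_classes - 1).
#' @param class_names Character vector of class names (default "0".."9").
#' @param source Provenance tag, e.g. `"mnist"`, `"fashion"`,
#'   `"synthetic:42"`.
#' @param dim Image dimensions `c(height, width)`.
#' @return An object of class `labeled_image_set`.
#' @export
labeled_image_set <- function(images, labels, class_names = as.character(0:9),
                              source = "unknown", dim = c(28L, 28L)) {
  if (is.array(images) && length(base::dim(images)) == 3L) {
    d <- base::dim(images)
    dim <- d[2:3]
    images <- t(apply(images, 1L, function(m) as.vector(t(matrix(m, d[2], d[3])))))
  }
  images <- as.matrix(images)
  labels <- as.integer(labels)
  if (nrow(images) != length(labels)) {
    stop("images and labels differ in length", call. = FALSE)
  }
  if (nrow(images) > 0 && (min(images) < 0 || max(images) > 1)) {
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  }
  if (length(labels) > 0 &&
      (min(labels) < 0 || max(labels) >= length(class_names))) {
    stop("labels out of range for the given class names", call. = FALSE)
  }
  structure(list(images = images, labels = labels,
                 class_names = as.character(class_names),
                 source = source, dim = as.integer(dim)),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat(sprintf("Labeled image set: %d images (%dx%d), %d classes [%s]\n",
              nrow(x$images), x$dim[1], x$dim[2], length(x$class_names),
              x$source))
  invisible(x)
}

#' Extract one image as a matrix
#'
#' @param set A [labeled_image_set()].
#' @param i Image index.
#' @return An H x W numeric matrix.
#' @export
get_image <- function(set, i) {
  unflatten_image(set$images[i, ], set$dim[1], set$dim[2])
}

#' Keep only the given classes
#'
#' @param set A [labeled_image_set()].
#' @param classes Integer class indices to keep.
#' @param relabel If `TRUE`, relabel the kept classes 0..(k-1).
#' @return A `labeled_image_set`.
#' @export
subset_classes <- function(set, classes, relabel = FALSE) {
  keep <- set$labels %in% classes
  labels <- set$labels[keep]
  names <- set$class_names
  if (relabel) {
    labels <- match(labels, sort(unique(classes))) - 1L
    names <- set$class_names[sort(unique(classes)) + 1L]
  }
  labeled_image_set(set$images[keep, , drop = FALSE], labels,
                    class_names = names, source = set$source, dim = set$dim)
}

#' Pixel-wise mean image of one class
#'
#' @param set A [labeled_image_set()].
#' @param class Integer class index.
#' @return An H x W matrix in \[0, 1\].
#' @export
class_mean_image <- function(set, class) {
  rows <- set$labels == class
  if (!any(rows)) stop(sprintf("no images of class %d", class), call. = FALSE)
  unflatten_image(colMeans(set$images[rows, , drop = FALSE]),
                  set$dim[1], set$dim[2])
}

IDX_MAGIC_IMAGES <- 2051L  # 0x00000803
IDX_MAGIC_LABELS <- 2049L  # 0x00000801

read_be_int <- function(con, what) {
  v <- readBin(con, integer(), n = 1L, size = 4L, endian = "big")
  if (length(v) != 1L) stop(sprintf("truncated IDX header: missing %s", what),
                            call. = FALSE)
  v
}

#' Read an IDX image/label file pair
#'
#' Reads the big-endian ubyte IDX container in which MNIST-style datasets
#' are distributed. Gzip-compressed files are accepted transparently.
#' Intensities are scaled to \[0, 1\] by dividing by 255.
#'
#' @param images_path Path to the images file (magic 0x00000803).
#' @param labels_path Path to the labels file (magic 0x00000801).
#' @param class_names,source Passed to [labeled_image_set()].
#' @return A [labeled_image_set()].
#' @export
read_idx <- function(images_path, labels_path,
                     class_names = as.character(0:9), source = "idx") {
  con <- gzfile(images_path, "rb"); on.exit(close(con), add = TRUE)
  magic <- read_be_int(con, "images magic")
  if (magic != IDX_MAGIC_IMAGES) {
    stop(sprintf("bad magic 0x%08x in images file (expected 0x%08x)",
                 magic, IDX_MAGIC_IMAGES), call. = FALSE)
  }
  n <- read_be_int(con, "image count")
  h <- read_be_int(con, "image rows")
  w <- read_be_int(con, "image cols")
  raw_px <- readBin(con, integer(), n = n * h * w, size = 1L, signed = FALSE)
  if (length(raw_px) != n * h * w) {
    stop("truncated IDX image payload", call. = FALSE)
  }
  lcon <- gzfile(labels_path, "rb"); on.exit(close(lcon), add = TRUE)
  lmagic <- read_be_int(lcon, "labels magic")
  if (lmagic != IDX_MAGIC_LABELS) {
    stop(sprintf("bad magic 0x%08x in labels file (expected 0x%08x)",
                 lmagic, IDX_MAGIC_LABELS), call. = FALSE)
  }
  nl <- read_be_int(lcon, "label count")
  if (nl != n) {
    stop(sprintf("image count %d and label count %d disagree", n, nl),
         call. = FALSE)
  }
  labels <- readBin(lcon, integer(), n = nl, size = 1L, signed = FALSE)
  if (length(labels) != nl) stop("truncated IDX label payload", call. = FALSE)
  images <- matrix(raw_px / 255, nrow = n, ncol = h * w, byrow = TRUE)
  labeled_image_set(images, labels, class_names = class_names,
                    source = source, dim = c(h, w))
}

#' Write a labeled image set as an IDX file pair
#'
#' Emits standard big-endian ubyte IDX files; intensities are quantized to
#' 8 bits (`round(x * 255)`), so a read-back agrees with the input to within
#' 1/255 per pixel. Paths ending in `.gz` are gzip-compressed.
#'
#' @param set A [labeled_image_set()].
#' @param images_path,labels_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_idx <- function(set, images_path, labels_path) {
  open_out <- function(path) {
    if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  }
  n <- nrow(set$images); h <- set$dim[1]; w <- set$dim[2]
  con <- open_out(images_path)
  writeBin(c(IDX_MAGIC_IMAGES, n, h, w), con, size = 4L, endian = "big")
  if (n > 0) {
    px <- as.integer(round(t(set$images) * 255))
    writeBin(as.raw(px), con)
  }
  close(con)
  lcon <- open_out(labels_path)
  writeBin(c(IDX_MAGIC_LABELS, n), lcon, size = 4L, endian = "big")
  if (n > 0) writeBin(as.raw(set$labels), lcon)
  close(lcon)
  invisible(c(images_path, labels_path))
}
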