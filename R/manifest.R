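# Run manifests and model checkpoints (versioned JSON containers).

#' Content fingerprint of a labeled image set
#'
#' MD5 over a canonical serialization of the images and labels; used to
#' record dataset provenance in run manifests.
#'
#' @param set A [labeled_image_set()].
#' @return A hex digest string.
#' @export
dataset_fingerprint <- function(set) {
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp), add = TRUE)
  con <- file(tmp, "wb")
  writeBin(as.vector(set$images), con)
  writeBin(as.integer(set$labels), con)
  close(con)
  unname(tools::md5sum(tmp))
}

#' Write a run manifest
#'
#' Every experiment output directory carries one manifest: a JSON snapshot
#' of the configuration, seeds, dataset fingerprint, package version,
#' timestamp and output file index — sufficient to rerun the job.
#'
#' @param out_dir Output directory (created if needed).
#' @param config Named list of configuration values.
#' @param seed Integer seed(s) of the run.
#' @param dataset Optional [labeled_image_set()] to fingerprint.
#' @param outputs Character vector of output files produced by the run.
#' @return Invisibly, the manifest path.
#' @export
write_run_manifest <- function(out_dir, config = list(), seed = NA_integer_,
                               dataset = NULL, outputs = character()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    schema_version = 1L,
    package = "ccnnsat",
    package_version = as.character(utils::packageVersion("ccnnsat")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    dataset_fingerprint = if (is.null(dataset)) NULL else dataset_fingerprint(dataset),
    dataset_source = if (is.null(dataset)) NULL else dataset$source,
    outputs = as.list(outputs)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Save a network checkpoint
#'
#' Single-file JSON container (schema version 1) holding the lattice
#' parameters, both coupling kernels, the dense readout, the update
#' ordering, and the training configuration and seed when present.
#'
#' @param net A [satiation_network()].
#' @param path Output path (conventionally `.json`).
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(net, path) {
  ck <- list(
    schema_version = 1L,
    package_version = as.character(utils::packageVersion("ccnnsat")),
    params = unclass(net$params),
    rf_size = net$kernels$size,
    kernel_m = as.vector(net$kernels$m),
    kernel_w = as.vector(net$kernels$w),
    readout_w = as.vector(net$readout_w),
    readout_b = as.vector(net$readout_b),
    n_classes = net$n_classes,
    input_dim = net$input_dim,
    e_update = net$e_update,
    trained = isTRUE(net$trained),
    seed = net$seed,
    train_config = if (is.null(net$train_config)) NULL else unclass(net$train_config)
  )
  jsonlite::write_json(ck, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return A [satiation_network()].
#' @export
load_checkpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(ck$schema_version) || ck$schema_version != 1L) {
    stop("unsupported checkpoint schema", call. = FALSE)
  }
  net <- satiation_network(rf_size = ck$rf_size, n_classes = ck$n_classes,
                           input_dim = ck$input_dim,
                           params = do.call(ccnn_params, as.list(ck$params)),
                           seed = ck$seed, e_update = ck$e_update)
  net$kernels <- coupling_kernels(
    m = matrix(ck$kernel_m, ck$rf_size, ck$rf_size),
    w = matrix(ck$kernel_w, ck$rf_size, ck$rf_size))
  net$readout_w <- matrix(ck$readout_w, prod(ck$input_dim), ck$n_classes)
  net$readout_b <- as.numeric(ck$readout_b)
  net$trained <- isTRUE(ck$trained)
  if (!is.null(ck$train_config)) {
    net$train_config <- do.call(training_config, as.list(ck$train_config))
  }
  net
}
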