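# Visualization of intermediate lattice states and a generic parameter
# sweep utility.

scale_panel <- function(m) {
  rng <- range(m)
  if (rng[1] == rng[2]) {
    # degenerate all-constant panel: mid-gray by convention
    list(img = matrix(0.5, nrow(m), ncol(m)), min = rng[1], max = rng[2])
  } else {
    list(img = (m - rng[1]) / (rng[2] - rng[1]), min = rng[1], max = rng[2])
  }
}

#' Render intermediate lattice states as grayscale panels
#'
#' Writes one 8-bit grayscale PNG per requested (state variable, model time)
#' combination, each linearly min-max scaled per panel (an all-constant
#' panel renders mid-gray); the scaling bounds are recorded in a JSON
#' sidecar next to the panels.
#'
#' @param trajectory A list of [lattice_state()]s (e.g. from
#'   [run_lattice()] with `record = TRUE`, or [forward_pass()]).
#' @param which Subset of `c("F", "L", "U", "E", "Y")` to render.
#' @param times Model-time indices into the trajectory.
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, a data frame with columns `variable`, `model_time`,
#'   `file`, `min`, `max`.
#' @export
render_state_montage <- function(trajectory, which = c("F", "L", "U", "E", "Y"),
                                 times, out_dir = ".", prefix = "state") {
  which <- match.arg(which, several.ok = TRUE)
  if (any(times < 1L | times > length(trajectory))) {
    stop("`times` outside the trajectory", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (t in times) {
    st <- trajectory[[t]]
    for (v in which) {
      m <- st[[tolower(v)]]
      sc <- scale_panel(m)
      f <- file.path(out_dir, sprintf("%s_%s_t%03d.png", prefix, v, t))
      png::writePNG(sc$img, f)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, model_time = t, file = f, min = sc$min, max = sc$max)
    }
  }
  index <- do.call(rbind, rows)
  jsonlite::write_json(index, file.path(out_dir, paste0(prefix, "_scales.json")),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(index)
}

#' Export a recorded trajectory to a directory container
#'
#' Writes each state matrix of each recorded model time as a CSV file plus
#' a JSON manifest describing the layout — a plain-text trajectory
#' container usable for downstream analysis.
#'
#' @param trajectory A list of [lattice_state()]s.
#' @param out_dir Output directory.
#' @param which Subset of state variables to export.
#' @return Invisibly, the manifest path.
#' @export
export_trajectory <- function(trajectory, out_dir,
                              which = c("F", "L", "U", "E", "Y")) {
  which <- match.arg(which, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (t in seq_along(trajectory)) {
    for (v in which) {
      f <- file.path(out_dir, sprintf("%s_t%03d.csv", v, t))
      utils::write.table(trajectory[[t]][[tolower(v)]], f, sep = ",",
                         row.names = FALSE, col.names = FALSE)
      files[[length(files) + 1L]] <- list(variable = v, model_time = t,
                                          file = basename(f))
    }
  }
  manifest <- file.path(out_dir, "trajectory.json")
  jsonlite::write_json(list(n_times = length(trajectory), variables = which,
                            files = files),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Sweep lattice parameters over a grid
#'
#' Runs an evaluation callback at every point of a parameter grid with an
#' isolated, per-point seed, collecting the results in a long-format table.
#' Callback failures are recorded per point and do not stop the sweep.
#'
#' @param grid A data frame of parameter combinations (e.g. from
#'   [expand.grid()]); column names should match [ccnn_params()] fields or
#'   whatever the callback expects.
#' @param eval_fn Function taking a named list of one grid row's parameters
#'   and returning a named numeric vector (or list) of metrics.
#' @param seed Base seed; point i runs under `seed + i`.
#' @return A data frame: the grid columns, `seed`, `error` (NA or the
#'   failure message) and one column per metric.
#' @export
parameter_sweep <- function(grid, eval_fn, seed = 1L) {
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L) stop("empty grid", call. = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    set.seed(seed + i)
    res <- tryCatch(eval_fn(as.list(grid[i, , drop = FALSE])),
                    error = function(e) e)
    row <- cbind(grid[i, , drop = FALSE],
                 data.frame(seed = seed + i, error = NA_character_))
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
    } else {
      for (nm in names(res)) row[[nm]] <- as.numeric(res[[nm]])
    }
    out[[i]] <- row
  }
  rows <- out[[1]]
  for (i in seq_along(out)[-1]) {
    miss1 <- setdiff(names(out[[i]]), names(rows))
    for (nm in miss1) rows[[nm]] <- NA_real_
    miss2 <- setdiff(names(rows), names(out[[i]]))
    for (nm in miss2) out[[i]][[nm]] <- NA_real_
    rows <- rbind(rows, out[[i]][names(rows)])
  }
  rownames(rows) <- NULL
  rows
}
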