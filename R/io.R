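# External interfaces: BIDS-style event TSVs, JSON configs, NIfTI volumes.

#' Write and read BIDS-style event tables
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type`,
#' `modulator` (plus any extra columns present); onsets in seconds, 0-based.
#'
#' @param events Event tibble, e.g. from [event_table()].
#' @param path File path (`.tsv`).
#' @return `write_events()` returns `path` invisibly; `read_events()` the
#'   tibble.
#' @export
write_events <- function(events, path) {
  assert_columns(events, c("onset", "duration", "trial_type", "modulator"),
                 "`events`")
  readr::write_tsv(events, path, na = "n/a")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  readr::read_tsv(path, na = c("n/a", "NA"), show_col_types = FALSE)
}

#' Serialize and restore a pipeline configuration as JSON
#'
#' Configurations round-trip losslessly, so a run is reproducible from its
#' config file alone.
#'
#' @param config A `pipeline_config`.
#' @param path File path (`.json`).
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  raw <- unclass(config)
  raw$roi_models <- as.list(raw$roi_models) # keep names through JSON
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[setdiff(names(raw), character())])
}

#' Write a per-voxel map to a NIfTI volume
#'
#' Places the values of one column of a tidy voxel table into the 3D grid
#' (background voxels are `NA`) and writes a NIfTI-1 file. Requires the
#' RNifti package.
#'
#' @param tbl Tibble with a `voxel` column and the value column.
#' @param grid The `voxel_grid` defining the geometry.
#' @param column Name of the value column to write.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(tbl, grid, column, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("write_map_nifti() requires the RNifti package", call. = FALSE)
  }
  assert_columns(tbl, c("voxel", column), "`tbl`")
  dim3 <- attr(grid, "dim3")
  vol <- array(NA_real_, dim = dim3)
  vol[tbl$voxel] <- tbl[[column]]
  vs <- attr(grid, "voxel_size") %||% 1
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(vs, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a simulated BOLD run as a 4D NIfTI volume
#'
#' @param bold A `bold_run`.
#' @param grid The `voxel_grid` whose voxels the columns of `bold$data`
#'   correspond to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(bold, grid, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("write_bold_nifti() requires the RNifti package", call. = FALSE)
  }
  stopifnot(inherits(bold, "bold_run"))
  dim3 <- attr(grid, "dim3")
  vol <- array(NA_real_, dim = c(dim3, bold$n_volumes))
  step <- prod(dim3)
  for (t in seq_len(bold$n_volumes)) {
    frame <- array(NA_real_, dim3)
    frame[grid$voxel] <- bold$data[t, ]
    vol[(t - 1L) * step + seq_len(step)] <- frame
  }
  vs <- attr(grid, "voxel_size") %||% 1
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(rep(vs, 3), bold$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI volume into a time x voxel matrix
#'
#' @param path NIfTI file path.
#' @param grid Optional `voxel_grid`; when given, only the grid's voxels are
#'   extracted (in `voxel` order).
#' @return A `bold_run` (with `tr` taken from the header's 4th pixdim).
#' @export
read_bold_nifti <- function(path, grid = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("read_bold_nifti() requires the RNifti package", call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stopifnot(length(d) == 4L)
  mat <- matrix(img, nrow = prod(d[1:3]), ncol = d[4])
  if (!is.null(grid)) mat <- mat[grid$voxel, , drop = FALSE]
  tr <- RNifti::pixdim(img)[4]
  structure(
    list(data = t(mat), tr = tr, n_volumes = d[4],
         frame_times = (seq_len(d[4]) - 1L) * tr, noise = NULL,
         seed = NULL, microtime = NULL),
    class = "bold_run"
  )
}
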