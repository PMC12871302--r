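#' Read and write tidy analysis tables
#'
#' Thin readr wrappers with column checks for the package's tidy CSV
#' interchange formats: track points (`axon_id`, `track_id`, `t_s`,
#' `x_um`, a pre-traced manual-tracing workflow), spike times
#' (`electrode_id`, `t_s`) and Ct tables (`sample_id`, `genotype`,
#' `replicate_id`, `gene`, `ct`).
#'
#' @param path file path.
#' @name tidy_io
NULL

#' @rdname tidy_io
#' @export
read_tracks_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("axon_id", "track_id", "t_s", "x_um")
  if (!all(need %in% names(x))) {
    abort_bad_arg(sprintf("track CSV needs columns %s", paste(need, collapse = ", ")))
  }
  x
}

#' @rdname tidy_io
#' @param x table to write.
#' @export
write_tracks_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname tidy_io
#' @export
read_spikes_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("electrode_id", "t_s") %in% names(x))) {
    abort_bad_arg("spike CSV needs columns electrode_id, t_s")
  }
  x
}

#' @rdname tidy_io
#' @export
read_ct_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sample_id", "genotype", "gene", "ct")
  if (!all(need %in% names(x))) {
    abort_bad_arg(sprintf("Ct CSV needs columns %s", paste(need, collapse = ", ")))
  }
  x
}

#' Write / read a kymograph as TIFF with a JSON calibration sidecar
#'
#' The intensity grid is stored as a 32-bit float TIFF; `px_um` and
#' `dt_s` go to `<path>.json`.
#'
#' @param kymo a [kymograph()].
#' @param path TIFF path (sidecar written at `paste0(path, ".json")`).
#' @return `write_kymograph()` returns the path; `read_kymograph()` a
#'   [kymograph()].
#' @export
write_kymograph <- function(kymo, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort_bad_arg("writing TIFF kymographs needs the tiff package")
  }
  v <- kymo$values
  scale <- max(abs(v), 1)
  tiff::writeTIFF(v / scale, path, bits.per.sample = 32)
  jsonlite::write_json(list(px_um = kymo$px_um, dt_s = kymo$dt_s, scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort_bad_arg("reading TIFF kymographs needs the tiff package")
  }
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- tiff::readTIFF(path) * (meta$scale %||% 1)
  kymograph(v, meta$px_um, meta$dt_s)
}
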