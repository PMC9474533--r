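#' Read / write capnograph traces
#'
#' Traces are stored as two-column delimited text (`time_s`, `co2_mmHg`).
#'
#' @param path file path.
#' @return `read_capno` returns a `capno_trace` object.
#' @export
read_capno <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (ncol(df) < 2) stop_cvr("capno-io", "expected two columns (time_s, co2_mmHg)")
  capno_trace(t = df[[1]], co2 = df[[2]])
}

#' @rdname read_capno
#' @param trace a `capno_trace`.
#' @export
write_capno <- function(trace, path) {
  write.table(data.frame(time_s = trace$t, co2_mmHg = trace$co2),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a capnograph trace object
#'
#' @param t sample times, s, strictly increasing.
#' @param co2 CO2 partial pressure, mmHg, non-negative.
#' @return a `capno_trace` (list with fields `t`, `co2`).
#' @export
capno_trace <- function(t, co2) {
  if (length(t) != length(co2) || length(t) < 2)
    stop_cvr("capno", "trace needs >= 2 (t, co2) samples of equal length")
  if (any(diff(t) <= 0)) stop_cvr("capno", "times must be strictly increasing")
  if (any(co2 < 0)) stop_cvr("capno", "co2 must be non-negative")
  structure(list(t = as.numeric(t), co2 = as.numeric(co2)),
            class = "capno_trace")
}

#' Read / write a 3D or 4D volume as NIfTI
#'
#' Thin wrappers over RNifti keeping the rest of the package array-based.
#'
#' @param path NIfTI file path.
#' @param data numeric array.
#' @param voxel_mm voxel dimensions in mm.
#' @param tr_s repetition time for 4D data, s.
#' @return `read_volume` returns a plain array with a `voxel_mm` attribute.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "voxel_mm") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(arr))))]
  arr
}

#' @rdname read_volume
#' @export
write_volume <- function(data, path, voxel_mm = c(3, 3, 3), tr_s = NULL) {
  pd <- if (length(dim(data)) == 4 && !is.null(tr_s)) c(voxel_mm, tr_s) else voxel_mm
  img <- RNifti::asNifti(unclass(data), pixdim = pd)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a cohort table
#'
#' Tab-delimited with one row per subject-session. Columns: `subject`,
#' `group` (HC or MS), `session`, `cvr_gm`, `cvr_wm`, `cvr_lesion`,
#' `gd_count`, `vol_gm`, `vol_wm`.
#'
#' @param path file path.
#' @param table a cohort data.frame.
#' @return `read_cohort_table` returns a data.frame.
#' @export
read_cohort_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_cohort_table
#' @export
write_cohort_table <- function(table, path) {
  write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
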