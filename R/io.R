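# Serialization. Cine series, sampling patterns and traces are written as
# JSON text (complex arrays as parallel re/im fields); magnitude frames can
# be exported to NIfTI for visual inspection.

cplx_to_list <- function(x) list(re = Re(x), im = Im(x))
list_to_cplx <- function(l) complex(real = unlist(l$re),
                                    imaginary = unlist(l$im))

#' Write / read a cine series
#'
#' JSON container with datasets `frames` (complex, stored as re/im), and
#' `phase_labels`, plus attributes `period_T`, `N`, `is_training`.
#'
#' @param cine a `cine_series`.
#' @param path file path (conventionally `.json`).
#' @return `write_cine` returns `path` invisibly; `read_cine` returns the
#'   `cine_series`.
#' @export
write_cine <- function(cine, path) {
  stopifnot(inherits(cine, "cine_series"))
  obj <- list(N = grid_size(cine), M = n_frames(cine),
              period_T = cine$period_T,
              phase_labels = cine$phase_labels,
              pixel_scale = cine$pixel_scale,
              is_training = cine$is_training,
              frames = cplx_to_list(as.vector(cine$frames)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cine
#' @export
read_cine <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fr <- array(list_to_cplx(obj$frames), c(obj$N, obj$N, obj$M))
  cine_series(fr, obj$phase_labels, obj$period_T,
              pixel_scale = obj$pixel_scale, is_training = obj$is_training)
}

#' Write / read a sampling pattern
#'
#' Masks are stored as boolean grids, trajectories as float coordinate
#' arrays (cycles/pixel).
#'
#' @param pattern a `sampling_pattern`.
#' @param path file path.
#' @export
write_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "sampling_pattern"))
  obj <- list(kind = pattern$kind, N = pattern$N,
              n_lines_or_spokes = pattern$n_lines_or_spokes,
              samples_per_line = pattern$samples_per_line,
              per_frame_variation = pattern$per_frame_variation,
              frame_index = pattern$frame_index)
  if (!is.null(pattern$mask)) obj$mask <- as.vector(pattern$mask)
  if (!is.null(pattern$traj)) obj$traj <- list(k1 = pattern$traj[, 1],
                                               k2 = pattern$traj[, 2])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mask <- if (!is.null(obj$mask)) matrix(obj$mask, obj$N, obj$N) else NULL
  traj <- if (!is.null(obj$traj)) cbind(obj$traj$k1, obj$traj$k2) else NULL
  new_pattern(obj$kind, obj$N, mask = mask, traj = traj,
              n_lines_or_spokes = obj$n_lines_or_spokes,
              samples_per_line = obj$samples_per_line,
              per_frame_variation = obj$per_frame_variation,
              frame_index = obj$frame_index)
}

#' Export magnitude frames as NIfTI
#'
#' Writes |frames| as an N x N x M volume for viewing in standard imaging
#' tools. Requires the RNifti package.
#'
#' @param cine a `cine_series`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
export_nifti_magnitude <- function(cine, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  RNifti::writeNifti(RNifti::asNifti(Mod(cine$frames)), path)
  invisible(path)
}
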