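# Undersampling patterns (Cartesian phase-encode, golden-angle radial,
# Archimedean spiral) and the measurement operator EF: centered orthonormal
# 2-D DFT followed by mask selection or bilinear gridding interpolation at
# the trajectory coordinates. The adjoint is the exact conjugate transpose
# (zero-filling / bilinear spreading followed by the inverse DFT); no
# density compensation is applied.

#' Golden angle used for radial spoke progression (degrees)
#' @export
GOLDEN_ANGLE_DEG <- 111.246

new_pattern <- function(kind, N, mask = NULL, traj = NULL,
                        n_lines_or_spokes = NA_integer_,
                        samples_per_line = NA_integer_,
                        per_frame_variation = FALSE, frame_index = 1L,
                        extra = list()) {
  structure(c(list(kind = kind, N = as.integer(N), mask = mask, traj = traj,
                   n_lines_or_spokes = as.integer(n_lines_or_spokes),
                   samples_per_line = as.integer(samples_per_line),
                   per_frame_variation = per_frame_variation,
                   frame_index = as.integer(frame_index)), extra),
            class = "sampling_pattern")
}

#' @export
print.sampling_pattern <- function(x, ...) {
  n <- if (!is.null(x$mask)) sum(x$mask) else nrow(x$traj)
  cat(sprintf("<sampling_pattern> %s N=%d, %d samples\n", x$kind, x$N, n))
  invisible(x)
}

# Wrap k-space coordinates into [-0.5, 0.5).
wrap_k <- function(k) ((k + 0.5) %% 1) - 0.5

#' Cartesian phase-encode undersampling mask
#'
#' Selects `n_pe` full readout lines (rows are the phase-encode direction).
#' In variable-density mode the DC line is always included and the remaining
#' lines are drawn without replacement with a Gaussian density decaying away
#' from the k-space center; otherwise lines are drawn uniformly (DC still
#' guaranteed). The draw is fixed across frames unless `per_frame` is set,
#' in which case the line set changes deterministically with `frame_index`
#' (per-frame mask variation as found in raw prospectively undersampled
#' acquisitions).
#'
#' @param N grid size.
#' @param n_pe number of phase-encode lines (1..N).
#' @param variable_density use center-weighted random line selection.
#' @param center_fraction width of the density kernel as a fraction of N.
#' @param seed integer seed for the line draw.
#' @param per_frame vary the line set between frames.
#' @param frame_index frame number (used only when `per_frame`).
#' @return a `sampling_pattern` of kind `"cartesian"`.
#' @export
cartesian_mask <- function(N, n_pe, variable_density = TRUE,
                           center_fraction = 0.25, seed = 0,
                           per_frame = FALSE, frame_index = 1L) {
  N <- as.integer(N); n_pe <- as.integer(n_pe)
  if (n_pe < 1L || n_pe > N) stop("n_pe must lie in [1, N]")
  dc <- floor(N / 2) + 1L
  eff_seed <- if (per_frame)
    (as.integer(seed) + 10007L * as.integer(frame_index)) %% .Machine$integer.max
  else as.integer(seed)
  rows <- withr::with_seed(eff_seed, {
    pool <- setdiff(seq_len(N), dc)
    if (n_pe == N) seq_len(N)
    else if (variable_density) {
      wts <- exp(-((pool - dc) / (center_fraction * N))^2)
      c(dc, sample(pool, n_pe - 1L, prob = wts))
    } else c(dc, sample(pool, n_pe - 1L))
  })
  mask <- matrix(FALSE, N, N)
  mask[rows, ] <- TRUE
  new_pattern("cartesian", N, mask = mask, n_lines_or_spokes = n_pe,
              samples_per_line = N, per_frame_variation = per_frame,
              frame_index = frame_index, extra = list(rows = sort(rows)))
}

#' Golden-angle radial trajectory for one frame
#'
#' `n_spokes` full diameters through the k-space center; spoke angles
#' advance by the golden angle (111.246 degrees) continuously across frames,
#' so frame f starts at global spoke index (f-1)*n_spokes. Each spoke
#' carries `round(1.28 * N)` equispaced samples straddling the center
#' symmetrically and spanning the full diameter.
#'
#' @param N grid size.
#' @param n_spokes spokes per frame.
#' @param frame_index 1-based frame number for the golden-angle progression.
#' @return a `sampling_pattern` of kind `"radial"` with a two-column
#'   trajectory in cycles/pixel and attributes `angles` and `radii`.
#' @export
radial_trajectory <- function(N, n_spokes, frame_index = 1L) {
  N <- as.integer(N); n_spokes <- as.integer(n_spokes)
  if (n_spokes < 1L) stop("n_spokes must be >= 1")
  ns <- as.integer(round(1.28 * N))
  ga <- GOLDEN_ANGLE_DEG * pi / 180
  idx0 <- (as.integer(frame_index) - 1L) * n_spokes
  angles <- (idx0 + seq_len(n_spokes) - 1L) * ga
  radii <- (seq_len(ns) - (ns + 1) / 2) / ns    # symmetric, spacing 1/ns
  k1 <- as.vector(outer(radii, cos(angles)))
  k2 <- as.vector(outer(radii, sin(angles)))
  traj <- cbind(wrap_k(k1), wrap_k(k2))
  new_pattern("radial", N, traj = traj, n_lines_or_spokes = n_spokes,
              samples_per_line = ns, frame_index = frame_index,
              extra = list(angles = angles, radii = radii))
}

#' Archimedean spiral trajectory
#'
#' A single interleave from the k-space center to the edge completing
#' `n_rotations` full turns; the sample count is chosen to match the ~8%
#' Cartesian sampling budget (`round(0.08 * N^2)` samples), with the final
#' sample at radius 0.5 (edge of k-space).
#'
#' @param N grid size.
#' @param n_rotations number of turns (default 6).
#' @return a `sampling_pattern` of kind `"spiral"` with attributes `angles`
#'   and `radii` (pre-wrap polar coordinates).
#' @export
spiral_trajectory <- function(N, n_rotations = 6) {
  N <- as.integer(N)
  if (n_rotations < 1) stop("n_rotations must be >= 1")
  m <- as.integer(round(0.08 * N * N))
  tt <- seq(0, 1, length.out = m)
  angles <- 2 * pi * n_rotations * tt
  radii <- 0.5 * tt
  traj <- cbind(wrap_k(radii * cos(angles)), wrap_k(radii * sin(angles)))
  new_pattern("spiral", N, traj = traj, n_lines_or_spokes = 1L,
              samples_per_line = m,
              extra = list(angles = angles, radii = radii,
                           n_rotations = n_rotations))
}

# Sparse real matrix times complex vector/matrix (Matrix has no complex
# sparse classes; the gridding weights are real).
sp_mul <- function(W, x) {
  out <- as.matrix(W %*% Re(x)) + 1i * as.matrix(W %*% Im(x))
  if (is.null(dim(x)) || ncol(as.matrix(x)) == 1L) as.vector(out) else out
}
sp_crossmul <- function(W, x) {
  out <- as.matrix(Matrix::crossprod(W, Re(x))) +
    1i * as.matrix(Matrix::crossprod(W, Im(x)))
  if (is.null(dim(x)) || ncol(as.matrix(x)) == 1L) as.vector(out) else out
}

# Sparse bilinear interpolation matrix (m x N^2, row-major grid order) from
# the centered Cartesian k-space grid to the trajectory points, with
# periodic wrap (the DFT spectrum is N-periodic).
gridding_matrix <- function(traj, N) {
  if (any(traj < -0.5 | traj >= 0.5)) stop("trajectory coordinates out of range")
  m <- nrow(traj)
  u1 <- traj[, 1] * N + floor(N / 2)   # 0-based fractional row index
  u2 <- traj[, 2] * N + floor(N / 2)
  i0 <- floor(u1); j0 <- floor(u2)
  a <- u1 - i0; b <- u2 - j0
  ridx <- function(i, j) (i %% N) * N + (j %% N) + 1   # row-major, 1-based
  rows <- rep(seq_len(m), 4)
  cols <- c(ridx(i0, j0), ridx(i0 + 1, j0), ridx(i0, j0 + 1), ridx(i0 + 1, j0 + 1))
  wts <- c((1 - a) * (1 - b), a * (1 - b), (1 - a) * b, a * b)
  keep <- wts > 0
  Matrix::sparseMatrix(i = rows[keep], j = cols[keep], x = wts[keep],
                       dims = c(m, N * N))
}

#' Build the measurement operator EF for a sampling pattern
#'
#' Cartesian patterns compose the centered orthonormal 2-D DFT with mask
#' selection; non-Cartesian patterns compose the DFT with bilinear
#' interpolation of the Cartesian grid values at the trajectory coordinates
#' (apodization-free gridding). The adjoint is the exact conjugate
#' transpose: bilinear spreading (or zero-filling) followed by the inverse
#' DFT. No density compensation is applied.
#'
#' @param pattern a `sampling_pattern`.
#' @param N grid size (must match the pattern).
#' @return a `measurement_operator` with fields `m` (samples per frame) and
#'   `n2` (= N^2).
#' @export
build_operator <- function(pattern, N = pattern$N) {
  stopifnot(inherits(pattern, "sampling_pattern"))
  N <- as.integer(N)
  if (N != pattern$N) stop("grid size does not match pattern")
  if (pattern$kind == "cartesian") {
    midx <- which(vec_img(pattern$mask))
    op <- list(kind = "cartesian", N = N, pattern = pattern,
               mask_idx = midx, m = length(midx), n2 = N * N)
  } else {
    W <- gridding_matrix(pattern$traj, N)
    op <- list(kind = pattern$kind, N = N, pattern = pattern,
               W = W, m = nrow(W), n2 = N * N)
  }
  structure(op, class = "measurement_operator")
}

#' @export
print.measurement_operator <- function(x, ...) {
  cat(sprintf("<measurement_operator> %s N=%d, m=%d samples\n",
              x$kind, x$N, x$m))
  invisible(x)
}

#' Forward and adjoint application of a measurement operator
#'
#' `op_forward` maps an N x N image to the complex sample vector;
#' `op_adjoint` is its exact conjugate transpose, mapping samples back to an
#' N x N image (zero-filled / gridded inverse DFT, not an inverse).
#'
#' @param op a `measurement_operator`.
#' @param img complex N x N matrix.
#' @param s complex sample vector of length `op$m`.
#' @return `op_forward`: complex vector; `op_adjoint`: complex matrix.
#' @export
op_forward <- function(op, img) {
  K <- vec_img(cdft2(img))
  if (op$kind == "cartesian") K[op$mask_idx]
  else sp_mul(op$W, K)
}

#' @rdname op_forward
#' @export
op_adjoint <- function(op, s) {
  g <- if (op$kind == "cartesian") {
    v <- rep(0 + 0i, op$n2); v[op$mask_idx] <- s; v
  } else sp_crossmul(op$W, s)
  cidft2(unvec_img(g, op$N))
}

# Matrix versions: apply EF (or its adjoint) to every column of a matrix of
# row-major vectorized images. Used for covariance propagation.
op_forward_mat <- function(op, Pm) {
  K <- fft2_cols(Pm, op$N)
  if (op$kind == "cartesian") K[op$mask_idx, , drop = FALSE]
  else as.matrix(sp_mul(op$W, K))
}

op_adjoint_mat <- function(op, Sm) {
  Sm <- as.matrix(Sm)
  G <- if (op$kind == "cartesian") {
    Z <- matrix(0 + 0i, op$n2, ncol(Sm)); Z[op$mask_idx, ] <- Sm; Z
  } else as.matrix(sp_crossmul(op$W, Sm))
  fft2_cols(G, op$N, inverse = TRUE)
}

#' Simulate an undersampled noisy acquisition of a cine series
#'
#' Applies the per-frame measurement operators to the ground-truth frames
#' and adds circular complex Gaussian noise with total standard deviation
#' `noise_sigma` (independent real/imaginary parts with sd
#' `noise_sigma/sqrt(2)` each). Deterministic for a fixed seed.
#'
#' @param truth ground-truth `cine_series`.
#' @param patterns a single `sampling_pattern` (shared by all frames) or a
#'   list with one pattern per frame.
#' @param noise_sigma k-space noise standard deviation (>= 0).
#' @param seed integer seed for the noise draw.
#' @return a `kspace_series`: list with `samples` (per-frame complex
#'   vectors), `ops` (per-frame measurement operators), `noise_sigma`,
#'   `seed`.
#' @export
measure_series <- function(truth, patterns, noise_sigma = 0, seed = 0) {
  stopifnot(inherits(truth, "cine_series"))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  M <- n_frames(truth)
  if (inherits(patterns, "sampling_pattern")) patterns <- list(patterns)
  if (length(patterns) == 1L) patterns <- rep(patterns, M)
  if (length(patterns) != M) stop("need one pattern per frame")
  ops <- lapply(patterns, build_operator)
  samples <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(M), function(i) {
      s <- op_forward(ops[[i]], cine_frame(truth, i))
      if (noise_sigma > 0) {
        n <- length(s)
        s <- s + complex(real = stats::rnorm(n, 0, noise_sigma / sqrt(2)),
                         imaginary = stats::rnorm(n, 0, noise_sigma / sqrt(2)))
      }
      s
    })
  })
  structure(list(samples = samples, ops = ops, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "kspace_series")
}

#' @export
print.kspace_series <- function(x, ...) {
  cat(sprintf("<kspace_series> %d frames, %s sampling, sigma=%g\n",
              length(x$samples), x$ops[[1]]$kind, x$noise_sigma))
  invisible(x)
}

#' Golden-angle radial patterns for a whole acquisition
#'
#' Convenience wrapper producing one radial pattern per frame with the
#' golden-angle progression continuing across frames.
#'
#' @inheritParams radial_trajectory
#' @param n_frames number of frames.
#' @return list of `sampling_pattern`s.
#' @export
radial_patterns <- function(N, n_spokes, n_frames) {
  lapply(seq_len(n_frames), function(f) radial_trajectory(N, n_spokes, f))
}
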