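# Low-level numerics shared across modules: centered orthonormal 2-D DFTs,
# row-major vectorization, Moore-Penrose pseudoinverse, and the factored
# affine-transition representation f = c*I + L R^H used throughout.

# fftshift / ifftshift index permutations for a length-N axis (exact
# inverses of each other; identity for N = 1).
fftshift_perm <- function(N) ((seq_len(N) - 1 + floor(N / 2)) %% N) + 1
ifftshift_perm <- function(N) ((seq_len(N) - 1 + ceiling(N / 2)) %% N) + 1

#' Centered orthonormal 2-D discrete Fourier transform
#'
#' Forward transform of an N1 x N2 complex image with the zero-frequency
#' sample at the center of the grid and unitary (1/sqrt(N1 N2)) scaling, so
#' Parseval's identity holds exactly and k-space noise levels are directly
#' comparable to image-domain noise levels.
#'
#' @param x complex matrix (image).
#' @return complex matrix of the same size (centered k-space).
#' @export
cdft2 <- function(x) {
  p1 <- ifftshift_perm(nrow(x)); p2 <- ifftshift_perm(ncol(x))
  f1 <- fftshift_perm(nrow(x)); f2 <- fftshift_perm(ncol(x))
  stats::fft(x[p1, p2, drop = FALSE])[f1, f2, drop = FALSE] / sqrt(length(x))
}

#' @rdname cdft2
#' @param X complex matrix (centered k-space).
#' @export
cidft2 <- function(X) {
  p1 <- ifftshift_perm(nrow(X)); p2 <- ifftshift_perm(ncol(X))
  f1 <- fftshift_perm(nrow(X)); f2 <- fftshift_perm(ncol(X))
  stats::fft(X[p1, p2, drop = FALSE], inverse = TRUE)[f1, f2, drop = FALSE] /
    sqrt(length(X))
}

# Centered orthonormal 2-D DFT applied to every column of Pm, where each
# column holds a row-major vectorized N x N image. Used to push whole
# covariance matrices through the Fourier operator cheaply.
fft2_cols <- function(Pm, N, inverse = FALSE) {
  Pm <- as.matrix(Pm)
  M <- ncol(Pm)
  ish <- ifftshift_perm(N); fsh <- fftshift_perm(N)
  A <- array(Pm, c(N, N, M))[ish, ish, , drop = FALSE]
  A <- array(stats::mvfft(matrix(A, N, N * M), inverse = inverse), c(N, N, M))
  A <- aperm(A, c(2, 1, 3))
  A <- array(stats::mvfft(matrix(A, N, N * M), inverse = inverse), c(N, N, M))
  A <- aperm(A, c(2, 1, 3))
  matrix(A[fsh, fsh, , drop = FALSE], N * N, M) / N
}

# Row-major vectorization: pixel order (1,1), (1,2), ..., (N,N).
vec_img <- function(x) as.vector(t(x))
unvec_img <- function(v, N) t(matrix(v, N, N))

conj_t <- function(x) Conj(t(x))

#' Moore-Penrose pseudoinverse of a complex matrix
#'
#' Singular values below `tol` times the largest singular value are truncated.
#' Used wherever the method inverts structurally rank-deficient matrices
#' (the zero-lag covariance has rank at most T - 1 for a T-frame training
#' cycle, far below its N^2 dimension).
#'
#' @param A complex (or real) matrix.
#' @param tol relative singular-value cutoff.
#' @return the pseudoinverse of `A`.
#' @export
pinv <- function(A, tol = 1e-10) {
  if (length(A) == 1L) {
    a <- as.complex(A)
    return(matrix(if (Mod(a) > 0) 1 / a else 0 + 0i, 1, 1))
  }
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0 + 0i, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * conj_t(s$u[, keep, drop = FALSE]))
}

# ---------------------------------------------------------------------------
# Factored affine transition: x |-> c*x + L (R^H x) + b.
# Dictionary transitions have c = 0 and rank(L) <= T; identity transitions
# (first step, random walk) have c = 1 and empty L; interpolated sub-step
# transitions have both parts.

new_transition <- function(c0, L, R, b, lag = NA_integer_, n2 = NULL) {
  if (is.null(n2)) n2 <- if (!is.null(L)) nrow(L) else length(b)
  structure(list(c0 = c0, L = L, R = R, b = b, lag = lag, n2 = n2),
            class = "cine_transition")
}

identity_transition <- function(n2, lag = NA_integer_) {
  new_transition(1, NULL, NULL, rep(0 + 0i, n2), lag = lag, n2 = n2)
}

#' Apply an affine transition to an image vector
#'
#' @param tr a `cine_transition` (from [transition_for_lag()] or
#'   [step_transition()]).
#' @param x complex vector of length N^2 (row-major vectorized image).
#' @return the predicted image vector `f x + b`.
#' @export
predict_image <- function(tr, x) {
  stopifnot(inherits(tr, "cine_transition"), length(x) == tr$n2)
  y <- tr$c0 * x
  if (!is.null(tr$L)) y <- y + tr$L %*% (conj_t(tr$R) %*% x)
  as.vector(y + tr$b)
}

#' Materialize a transition as a dense matrix
#'
#' Intended for small problems and cross-checks; the filter itself never
#' forms the dense N^2 x N^2 matrix.
#'
#' @param tr a `cine_transition`.
#' @return dense complex matrix.
#' @export
transition_matrix <- function(tr) {
  M <- diag(tr$c0 + 0i, tr$n2)
  if (!is.null(tr$L)) M <- M + tr$L %*% conj_t(tr$R)
  M
}

# Propagate a Hermitian covariance through the transition: f P f^H.
propagate_cov <- function(tr, P) {
  out <- if (tr$c0 != 0) (tr$c0 * Conj(tr$c0)) * P else matrix(0 + 0i, tr$n2, tr$n2)
  if (!is.null(tr$L)) {
    RP <- conj_t(tr$R) %*% P           # r x n2
    RPR <- RP %*% tr$R                 # r x r
    core <- tr$L %*% RPR %*% conj_t(tr$L)
    if (tr$c0 != 0) {
      cross <- tr$c0 * (tr$L %*% RP)   # c * L (R^H P)
      out <- out + cross + conj_t(cross)
    }
    out <- out + core
  }
  out
}

#' Wrap a dense affine map as a transition
#'
#' Mainly for small-scale experiments and cross-checks; the estimators
#' return factored transitions directly.
#'
#' @param f dense complex matrix.
#' @param b bias vector (default zero).
#' @param lag optional signed lag bookkeeping.
#' @return a `cine_transition`.
#' @export
as_transition <- function(f, b = NULL, lag = NA_integer_) {
  n2 <- nrow(f)
  if (is.null(b)) b <- rep(0 + 0i, n2)
  new_transition(0, f, diag(1 + 0i, n2), as.complex(b), lag = lag, n2 = n2)
}

#' @export
print.cine_transition <- function(x, ...) {
  r <- if (is.null(x$L)) 0L else ncol(x$L)
  cat(sprintf("<cine_transition> n2=%d lag=%s c=%g rank(LR^H)<=%d\n",
              x$n2, as.character(x$lag), x$c0, r))
  invisible(x)
}
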