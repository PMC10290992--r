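# Learned cardiac-motion dictionary: temporal means, per-lag covariance
# matrices C_l estimated from one fully sampled training cycle under a
# (jointly) wide-sense-stationary assumption per pixel, and the LMMSE affine
# transitions f = C_l pinv(C_0), b = mu - f mu they induce.
#
# C_l = D_l D^H / T, where D holds the centered training frames and D_l its
# circular shift by l, so every C_l has rank <= T - 1. The dictionary stores
# the thin SVD of D/sqrt(T) and materializes dense matrices only on request.

#' Preprocess a training cycle through a denoiser hook
#'
#' The default hook is the identity (raw training frames are used as-is). A
#' small-sigma Gaussian smoother is available as a built-in option; any
#' user-supplied function mapping an N x N complex matrix to another N x N
#' matrix is accepted. A hook that changes the frame shape is rejected.
#'
#' @param train a training `cine_series`.
#' @param denoiser `NULL` (identity), `"gaussian"`, or a function
#'   `frame -> frame`.
#' @param sigma spatial standard deviation in pixels of the Gaussian hook.
#' @return the preprocessed `cine_series`.
#' @export
preprocess_training <- function(train, denoiser = NULL, sigma = 0.8) {
  stopifnot(inherits(train, "cine_series"))
  if (is.null(denoiser)) return(train)
  fn <- if (is.function(denoiser)) denoiser
  else if (identical(denoiser, "gaussian")) function(fr) gaussian_smooth(fr, sigma)
  else stop("denoiser must be NULL, \"gaussian\", or a function")
  N <- grid_size(train)
  out <- train$frames
  for (i in seq_len(n_frames(train))) {
    fr <- fn(out[, , i])
    if (!is.matrix(fr) || any(dim(fr) != c(N, N)))
      stop("denoiser must preserve the frame shape")
    out[, , i] <- fr
  }
  res <- cine_series(out, train$phase_labels, train$period_T,
                     pixel_scale = train$pixel_scale,
                     is_training = train$is_training)
  for (a in c("fine_phase", "temporal_factor", "contraction", "geometry"))
    attr(res, a) <- attr(train, a)
  res
}

# Separable Gaussian smoothing with reflected boundaries, applied to real
# and imaginary parts.
gaussian_smooth <- function(fr, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  sm1 <- function(m) {
    N <- nrow(m)
    pad <- rbind(m[r:1, , drop = FALSE], m, m[N:(N - r + 1), , drop = FALSE])
    out <- matrix(0 + 0i, N, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * pad[j:(j + N - 1), , drop = FALSE]
    out
  }
  t(sm1(t(sm1(fr))))
}

#' Estimate the motion dictionary from a training cycle
#'
#' Computes per-pixel temporal means and the lag-l temporal covariance and
#' cross-covariance of every pixel pair with the 1/T normalization and
#' circular time indexing (t + l taken modulo T; the training scan is one
#' full cycle, and circularity is what makes the WSS assumption and the
#' conjugate-symmetry relation C_{-l} = C_l^H exactly consistent).
#'
#' @param train a `cine_series` with T >= 2 frames (one full cycle).
#' @param pinv_tol relative singular-value cutoff used when inverting C_0
#'   (applied to the singular values of C_0).
#' @return a `motion_dictionary` with fields `mu` (complex N^2 means,
#'   row-major pixel order), `T`, `N`, `pinv_tol`, plus internal factors.
#'   Use [cov_for_lag()] to materialize any C_l.
#' @export
temporal_moments <- function(train, pinv_tol = 1e-10) {
  stopifnot(inherits(train, "cine_series"))
  T <- n_frames(train)
  if (T < 2L) stop("training series must have at least 2 frames")
  N <- grid_size(train)
  B <- frames_matrix(train)                 # N^2 x T, row-major pixels
  mu <- rowMeans(B)
  D <- (B - mu) / sqrt(T)                   # C_l = D_l D^H
  sv <- svd(D)                              # thin SVD: D = U diag(d) V^H
  structure(list(mu = mu, D = D, U = sv$u, d = sv$d, V = sv$v,
                 T = T, N = N, pinv_tol = pinv_tol,
                 fine_phase = attr(train, "fine_phase"),
                 temporal_factor = attr(train, "temporal_factor")),
            class = "motion_dictionary")
}

#' @export
print.motion_dictionary <- function(x, ...) {
  cat(sprintf("<motion_dictionary> N=%d T=%d rank(C_0)=%d pinv_tol=%g\n",
              x$N, x$T, sum(x$d > sqrt(x$pinv_tol) * max(x$d)), x$pinv_tol))
  invisible(x)
}

# Centered frame matrix circularly shifted by lag l: column t holds frame
# (t + l) mod T.
shifted_D <- function(dict, l) {
  idx <- ((seq_len(dict$T) - 1 + l) %% dict$T) + 1
  dict$D[, idx, drop = FALSE]
}

#' Lag-l covariance matrix from the dictionary
#'
#' Returns the dense N^2 x N^2 matrix C_l for l >= 0 and the conjugate
#' transpose C_{|l|}^H for negative lags (conjugate symmetry of jointly WSS
#' processes).
#'
#' @param dict a `motion_dictionary`.
#' @param l signed lag with |l| <= T - 1.
#' @return dense complex matrix.
#' @export
cov_for_lag <- function(dict, l) {
  stopifnot(inherits(dict, "motion_dictionary"))
  if (abs(l) >= dict$T) stop("|l| must be smaller than T")
  if (l >= 0) shifted_D(dict, l) %*% conj_t(dict$D)
  else conj_t(cov_for_lag(dict, -l))
}

# Retained singular directions of C_0 = U diag(d^2) U^H under the relative
# tolerance on C_0's singular values (d^2).
kept_rank <- function(dict) {
  d2 <- dict$d^2
  which(d2 > dict$pinv_tol * max(d2))
}

#' LMMSE transition for a signed lag
#'
#' The Wiener-filter state transition f = C_l pinv(C_0) with bias
#' b = mu - f mu, mapping the image at some phase to the image `l` phases
#' later (negative lags step backwards in time, which is what allows a
#' single training cycle to model transitions across heartbeats). The
#' pseudoinverse truncates singular values of C_0 below `pinv_tol` times the
#' largest. `first_step = TRUE` returns the identity transition with zero
#' bias, used to initialize the filter.
#'
#' @param dict a `motion_dictionary`.
#' @param l signed lag, |l| <= T - 1.
#' @param first_step request the identity transition.
#' @return a `cine_transition` (factored; see [transition_matrix()] to
#'   materialize it).
#' @export
transition_for_lag <- function(dict, l = 1L, first_step = FALSE) {
  stopifnot(inherits(dict, "motion_dictionary"))
  n2 <- dict$N^2
  if (isTRUE(first_step)) return(identity_transition(n2, lag = 0L))
  if (abs(l) >= dict$T) stop("|l| must be smaller than T")
  keep <- kept_rank(dict)
  U <- dict$U[, keep, drop = FALSE]
  if (l >= 0) {
    # C_l pinv(C_0) = D_l D^H U d^-2 U^H = D_l V d^-1 U^H
    L <- shifted_D(dict, l) %*%
      (dict$V[, keep, drop = FALSE] %*% diag(1 / dict$d[keep],
                                             length(keep)))
    R <- U
  } else {
    # C_{-|l|} = C_{|l|}^H = D D_l^H, so f = D (D_l^H U d^-2) U^H
    Dl <- shifted_D(dict, abs(l))
    G <- conj_t(Dl) %*% (U %*% diag(1 / dict$d[keep]^2, length(keep)))
    L <- dict$D %*% G
    R <- U
  }
  b <- dict$mu - as.vector(L %*% (conj_t(R) %*% dict$mu))
  new_transition(0, L, R, b, lag = as.integer(l), n2 = n2)
}

#' Process covariance for the two-stage filter
#'
#' Q = diag(C_0): the zero-lag covariance diagonalized to protect against
#' overfitting, acknowledging that the dictionary prediction is only an
#' initial approximation. Requires nothing beyond the single training cycle.
#'
#' @param dict a `motion_dictionary`.
#' @return a `process_cov` with a real nonnegative `diag` vector and
#'   `variant = "two_stage"`.
#' @export
process_cov_two_stage <- function(dict) {
  stopifnot(inherits(dict, "motion_dictionary"))
  q <- Re(rowSums(dict$D * Conj(dict$D)))
  structure(list(diag = pmax(q, 0), variant = "two_stage", N = dict$N),
            class = "process_cov")
}

#' Process covariance for the random-walk filter
#'
#' Diagonal Q whose entries are the per-pixel temporal variance over the
#' T - 1 successive-difference images of the training scan (population
#' variance; off-diagonal entries are taken as low-power and ignored).
#'
#' @param train a training `cine_series` with T >= 2 frames.
#' @return a `process_cov` with `variant = "random_walk"`.
#' @export
process_cov_random_walk <- function(train) {
  stopifnot(inherits(train, "cine_series"))
  T <- n_frames(train)
  if (T < 2L) stop("need at least 2 training frames")
  B <- frames_matrix(train)
  Dif <- B[, 2:T, drop = FALSE] - B[, 1:(T - 1), drop = FALSE]
  mu <- rowMeans(Dif)
  q <- Re(rowMeans((Dif - mu) * Conj(Dif - mu)))
  structure(list(diag = pmax(q, 0), variant = "random_walk",
                 N = grid_size(train)),
            class = "process_cov")
}

#' Full (non-diagonal) zero-lag covariance as a process covariance
#'
#' Q = C_0 with all off-diagonal entries retained. This is the ablation
#' used to probe whether the transition's off-diagonal structure is needed
#' to control the power of Q; it is known to destabilize the filter.
#'
#' @param dict a `motion_dictionary`.
#' @return a `process_cov` with a dense `matrix` field and
#'   `variant = "full_c0"`.
#' @export
process_cov_full_c0 <- function(dict) {
  stopifnot(inherits(dict, "motion_dictionary"))
  structure(list(matrix = cov_for_lag(dict, 0), variant = "full_c0",
                 N = dict$N),
            class = "process_cov")
}

#' @export
print.process_cov <- function(x, ...) {
  cat(sprintf("<process_cov> variant=%s N=%d\n", x$variant, x$N))
  invisible(x)
}

# Add Q to a dense covariance matrix.
add_process_cov <- function(P, Q) {
  if (!is.null(Q$matrix)) P + Q$matrix
  else {
    diag(P) <- diag(P) + Q$diag
    P
  }
}
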