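# Two-stage (predictive signal model) and random-walk Kalman filters over a
# sequence of undersampled k-space frames. Stage one predicts the next
# cardiac image from the learned motion dictionary; stage two blends that
# prediction with the acquired k-space through the Kalman gain, formed in
# the m-dimensional sample space.

#' Signed lag schedule from phase labels
#'
#' The lag used for frame t is the signed phase difference
#' `phase_t - phase_{t-1}`; backward transitions are negative (a wrap from
#' phase T to phase 1 of the next heartbeat gives l = -(T-1), an early
#' return to systole from phase p gives l = -(p-1)). The first frame is
#' flagged NA and uses the identity transition.
#'
#' @param phase_labels integer phase per frame, in [1, T].
#' @param T phases per cycle in the training scan.
#' @return integer vector of lags (first element NA).
#' @export
lag_schedule <- function(phase_labels, T) {
  phase_labels <- as.integer(phase_labels)
  if (any(phase_labels < 1L | phase_labels > T))
    stop("phase labels must lie in [1, T]")
  l <- c(NA_integer_, diff(phase_labels))
  if (any(abs(l) >= T, na.rm = TRUE)) stop("|lag| must be smaller than T")
  l
}

#' Filter configuration
#'
#' @param variant `"two_stage"` (dictionary transitions, Q = diag(C_0)),
#'   `"random_walk"` (identity transition, difference-image Q), or
#'   `"static_full_cov"` (identity transition with the full non-diagonal
#'   C_0 as Q; the destabilizing ablation).
#' @param R_sigma2 measurement-noise variance (NULL to estimate from the
#'   background ROI of the first test frame's adjoint image).
#' @param P0_sigma2 initial covariance scale (NULL to estimate likewise).
#' @param background_roi integer vector `c(row0, row1, col0, col1)` of the
#'   background rectangle used for noise estimation.
#' @param temporal_factor V >= 1; when V > 1 the dictionary is assumed to
#'   be built from a training scan decimated by V and consecutive fine
#'   phases are bridged through sub-step transitions.
#' @param pinv_tol pseudoinverse tolerance for the innovation covariance.
#' @return a `filter_config` list.
#' @export
filter_config <- function(variant = c("two_stage", "random_walk",
                                      "static_full_cov"),
                          R_sigma2 = NULL, P0_sigma2 = NULL,
                          background_roi = NULL, temporal_factor = 1L,
                          pinv_tol = 1e-10) {
  variant <- match.arg(variant)
  if (!is.null(R_sigma2) && R_sigma2 < 0) stop("R_sigma2 must be >= 0")
  if (!is.null(P0_sigma2) && P0_sigma2 < 0) stop("P0_sigma2 must be >= 0")
  structure(list(variant = variant, R_sigma2 = R_sigma2,
                 P0_sigma2 = P0_sigma2, background_roi = background_roi,
                 temporal_factor = as.integer(temporal_factor),
                 pinv_tol = pinv_tol),
            class = "filter_config")
}

default_roi <- function(N) {
  w <- max(2L, N %/% 8L)
  c(1L, w, 1L, w)   # top-left corner: outside the thorax in the phantom
}

roi_variance <- function(img, roi) {
  if (roi[1] < 1 || roi[3] < 1 || roi[2] > nrow(img) || roi[4] > ncol(img) ||
      roi[1] > roi[2] || roi[3] > roi[4])
    stop("background ROI outside the grid")
  v <- as.vector(img[roi[1]:roi[2], roi[3]:roi[4]])
  if (length(v) < 2) stop("background ROI is empty or degenerate")
  mean(Mod(v - mean(v))^2)
}

#' Initialize the Kalman filter state
#'
#' The initial estimate x_0 is the first training frame; R = sigma^2 I with
#' sigma^2 either supplied or estimated as the variance of a background
#' image segment (taken from the zero-filled adjoint reconstruction of the
#' supplied k-space frame, our image-domain reading of "variance of k-space
#' corresponding to a background region"); P_0 is diagonal with the same
#' background spatial variance unless overridden.
#'
#' @param train training `cine_series`.
#' @param kspace a `kspace_series` (its first frame is used for background
#'   estimation) or NULL when both variances are supplied.
#' @param config a [filter_config()].
#' @return list with `state` (fields `x`, `P`, `t`, `phase`) and `R_sigma2`.
#' @export
init_filter <- function(train, kspace = NULL, config = filter_config()) {
  N <- grid_size(train)
  n2 <- N * N
  x0 <- vec_img(cine_frame(train, 1))
  need_est <- is.null(config$R_sigma2) || is.null(config$P0_sigma2)
  bg_var <- NULL
  if (need_est) {
    if (is.null(kspace)) stop("kspace needed to estimate background variance")
    roi <- if (is.null(config$background_roi)) default_roi(N)
    else config$background_roi
    img <- op_adjoint(kspace$ops[[1]], kspace$samples[[1]])
    bg_var <- roi_variance(img, roi)
  }
  R_sigma2 <- if (is.null(config$R_sigma2)) bg_var else config$R_sigma2
  P0_sigma2 <- if (is.null(config$P0_sigma2)) bg_var else config$P0_sigma2
  P0 <- diag(P0_sigma2 + 0i, n2)
  list(state = list(x = x0, P = P0, t = 0L, phase = train$phase_labels[1]),
       R_sigma2 = R_sigma2)
}

#' Kalman prediction step
#'
#' x^f = f x^a + b and P^f = f P^a f^H + Q (the Jacobian of the affine
#' stage-one model is exactly f, so no numerical differentiation is
#' involved).
#'
#' @param state list with `x` and `P`.
#' @param transition a `cine_transition`.
#' @param Q a `process_cov` (or NULL for Q = 0).
#' @return the predicted state.
#' @export
predict_step <- function(state, transition, Q = NULL) {
  x <- predict_image(transition, state$x)
  P <- propagate_cov(transition, state$P)
  if (!is.null(Q)) P <- add_process_cov(P, Q)
  list(x = x, P = P, t = state$t + 1L, phase = state$phase)
}

# Hermitian pseudoinverse via eigendecomposition (S is Hermitian PSD + R).
herm_pinv <- function(S, tol = 1e-10) {
  S <- (S + conj_t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), .Machine$double.xmin)
  if (!any(keep)) return(matrix(0 + 0i, nrow(S), ncol(S)))
  V <- e$vectors[, keep, drop = FALSE]
  V %*% ((1 / e$values[keep]) * conj_t(V))
}

#' Kalman update step
#'
#' Forms the m x m innovation covariance S = EF P^f (EF)^H + R explicitly
#' in sample space, applies the gain K = P^f (EF)^H S^+ (Moore-Penrose),
#' and re-Hermitianizes the updated covariance to control floating-point
#' drift.
#'
#' @param state_pred predicted state (from [predict_step()]).
#' @param samples complex k-space sample vector for this frame.
#' @param op the frame's `measurement_operator`.
#' @param R_sigma2 measurement-noise variance (R = sigma^2 I).
#' @param pinv_tol pseudoinverse tolerance for S.
#' @return the updated state.
#' @export
update_step <- function(state_pred, samples, op, R_sigma2,
                        pinv_tol = 1e-10) {
  if (length(samples) != op$m) stop("sample count does not match operator")
  B <- op_forward_mat(op, state_pred$P)            # m x n2 = EF P^f
  S <- op_forward_mat(op, conj_t(B))               # EF (P^f (EF)^H), m x m
  diag(S) <- diag(S) + R_sigma2
  Sinv <- herm_pinv(S, pinv_tol)
  PA <- conj_t(B)                                  # P^f (EF)^H, n2 x m
  K <- PA %*% Sinv
  resid <- samples - op_forward(op, unvec_img(state_pred$x, op$N))
  x <- state_pred$x + as.vector(K %*% resid)
  P <- state_pred$P - K %*% B
  P <- (P + conj_t(P)) / 2
  list(x = x, P = P, t = state_pred$t, phase = state_pred$phase)
}

# Transition provider for a reconstruction run: caches dictionary
# transitions per lag and sub-step transitions per (lag, v).
transition_provider <- function(dict, config) {
  cache <- new.env(parent = emptyenv())
  n2 <- dict$N^2
  V <- config$temporal_factor
  get_base <- function(lag) {
    key <- paste0("b", lag)
    if (is.null(cache[[key]])) cache[[key]] <- transition_for_lag(dict, lag)
    cache[[key]]
  }
  if (config$variant != "two_stage") {
    idt <- identity_transition(n2)
    return(function(lag, v = NULL) idt)
  }
  function(lag, v = NULL) {
    if (is.null(v) || V == 1L) return(get_base(lag))
    key <- paste0("s", lag, "_", v)
    if (is.null(cache[[key]]))
      cache[[key]] <- step_transition(get_base(lag), V, v,
                                      tol = config$pinv_tol)
    cache[[key]]
  }
}

#' Run a full Kalman reconstruction
#'
#' Filters the undersampled k-space sequence with the requested variant.
#' For the two-stage variant the per-frame transition comes from the lag
#' schedule of the phase labels; with `temporal_factor` V > 1 the phase
#' labels are fine-resolution (consecutive, wrapping at the cycle boundary)
#' and each fine step is bridged by the sub-step transition of the enclosing
#' anchor block, whose base transition is the dictionary transition for the
#' coarse lag between anchors (+1 within a cycle, -(T-1) across the wrap).
#'
#' @param train training `cine_series` (decimated when V > 1).
#' @param kspace a `kspace_series`.
#' @param phase_labels test phase label per k-space frame.
#' @param config a [filter_config()].
#' @param truth optional ground-truth `cine_series` for the MSE trace.
#' @param dict optional prebuilt `motion_dictionary` (rebuilt from `train`
#'   otherwise).
#' @return a `recon_result`: reconstructed `cine_series`, `mse_trace`,
#'   `lag_trace`, and the config used.
#' @export
run_reconstruction <- function(train, kspace, phase_labels,
                               config = filter_config(), truth = NULL,
                               dict = NULL) {
  stopifnot(inherits(kspace, "kspace_series"))
  M <- length(kspace$samples)
  N <- grid_size(train)
  if (N > 64L)
    stop("dense spatiotemporal covariance filtering is capped at N = 64 ",
         "(the N^2 x N^2 covariance would not fit a desk-scale machine)")
  if (M == 0L) {
    empty <- cine_series(array(0 + 0i, c(N, N, 1)), 1L, train$period_T)
    empty$frames <- empty$frames[, , 0, drop = FALSE]
    empty$phase_labels <- integer(0)
    return(structure(list(frames = empty, mse_trace = numeric(0),
                          lag_trace = integer(0), config = config),
                     class = "recon_result"))
  }
  if (length(phase_labels) != M) stop("one phase label per k-space frame")
  V <- config$temporal_factor
  if (is.null(dict)) dict <- temporal_moments(train)
  n2 <- N * N

  Q <- switch(config$variant,
              two_stage = process_cov_two_stage(dict),
              random_walk = process_cov_random_walk(train),
              static_full_cov = process_cov_full_c0(dict))
  init <- init_filter(train, kspace, config)
  state <- init$state
  R_sigma2 <- init$R_sigma2
  trans_of <- transition_provider(dict, config)

  T_train <- dict$T
  T_eff <- max(train$period_T, T_train * V, max(phase_labels))
  lags <- lag_schedule(phase_labels, T_eff)

  frames <- array(0 + 0i, c(N, N, M))
  mse <- if (!is.null(truth)) numeric(M) else NULL
  lag_used <- integer(M)

  for (i in seq_len(M)) {
    tr <- if (i == 1L) identity_transition(n2, lag = 0L)
    else if (config$variant != "two_stage" || V == 1L) trans_of(lags[i])
    else {
      p <- phase_labels[i]
      if (!(lags[i] == 1L || p == 1L))
        stop("temporal_factor > 1 supports consecutive fine phase schedules")
      k <- ((p - 2L) %% V) + 1L          # fine steps from the lower anchor
      vv <- V - k + 1L                   # step index; v = V is the anchor step
      anchor_fine <- ((p - 1L - k) %% (T_train * V)) + 1L
      coarse_lag <- if (anchor_fine == (T_train - 1L) * V + 1L)
        -(T_train - 1L) else 1L
      trans_of(coarse_lag, vv)
    }
    lag_used[i] <- if (i == 1L) 0L else if (is.na(tr$lag)) lags[i] else tr$lag
    pred <- predict_step(state, tr, if (i == 1L) NULL else Q)
    state <- update_step(pred, kspace$samples[[i]], kspace$ops[[i]],
                         R_sigma2, config$pinv_tol)
    state$phase <- phase_labels[i]
    frames[, , i] <- unvec_img(state$x, N)
    if (!is.null(mse))
      mse[i] <- mean(Mod(frames[, , i] - cine_frame(truth, i))^2)
  }
  recon <- cine_series(frames, phase_labels, T_eff)
  structure(list(frames = recon, mse_trace = mse, lag_trace = lag_used,
                 config = config, R_sigma2 = R_sigma2),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> %d frames (%s)", n_frames(x$frames),
              x$config$variant))
  if (!is.null(x$mse_trace) && length(x$mse_trace))
    cat(sprintf(", mean MSE %.3g", mean(x$mse_trace)))
  cat("\n")
  invisible(x)
}
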