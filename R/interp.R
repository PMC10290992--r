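# Sub-step transitions when the test temporal resolution exceeds the
# training resolution. The dictionary models a base phase transition of size
# V (in test-scan phase units) through (f_V, b_V); intermediate frames are
# assumed to fall linearly between the two anchors, which induces an affine
# transition between every pair of consecutive fine phases.
#
# With v counting fine phases backwards from the upper anchor t
# (input phase t - v, output t - v + 1):
#   f_new = ((V-v+1)/V f_V + (v-1)/V I) ((V-v)/V f_V + v/V I)^+
#   b_new = -f_new (V-v)/V b_V + (V-v+1)/V b_V
# v = V is admitted and reduces to the anchor step (the inverted factor is
# the identity), so a full block is the chain v = V, V-1, ..., 1.

# alpha * f + beta * I for a factored transition (bias dropped).
scaled_shift <- function(tr, alpha, beta) {
  new_transition(alpha * tr$c0 + beta,
                 if (is.null(tr$L)) NULL else alpha * tr$L, tr$R,
                 rep(0 + 0i, tr$n2), n2 = tr$n2)
}

# Pseudoinverse of c*I + L R^H, kept factored via Woodbury when the small
# core is well conditioned; falls back to a dense pseudoinverse otherwise.
invert_transition <- function(tr, tol = 1e-10) {
  if (is.null(tr$L)) {
    if (Mod(tr$c0) <= tol) stop("cannot invert a zero transition")
    return(new_transition(1 / tr$c0, NULL, NULL, rep(0 + 0i, tr$n2),
                          n2 = tr$n2))
  }
  c0 <- tr$c0
  if (Mod(c0) > tol) {
    r <- ncol(tr$L)
    core <- diag(r) + conj_t(tr$R) %*% tr$L / c0
    sv <- svd(core)$d
    if (min(sv) > 1e-12 * max(sv, 1)) {
      # (cI + LR^H)^-1 = c^-1 I - c^-1 L (cI_r + R^H L)^-1 R^H
      Linv <- -(tr$L %*% solve(core)) / c0^2
      return(new_transition(1 / c0, Linv, tr$R, rep(0 + 0i, tr$n2),
                            n2 = tr$n2))
    }
  }
  Minv <- pinv(transition_matrix(tr), tol = tol)
  # dense fallback: represent as c = 0 with full-rank L R^H
  new_transition(0, Minv, diag(1 + 0i, tr$n2), rep(0 + 0i, tr$n2),
                 n2 = tr$n2)
}

# Product of two factored transitions (biases dropped).
compose_linear <- function(a, b) {
  c0 <- a$c0 * b$c0
  parts_L <- list(); parts_R <- list()
  if (!is.null(b$L) && a$c0 != 0) {
    parts_L <- c(parts_L, list(a$c0 * b$L)); parts_R <- c(parts_R, list(b$R))
  }
  if (!is.null(a$L)) {
    RB <- if (b$c0 != 0) b$c0 * a$L else NULL
    if (!is.null(RB)) {
      parts_L <- c(parts_L, list(RB)); parts_R <- c(parts_R, list(a$R))
    }
    if (!is.null(b$L)) {
      parts_L <- c(parts_L, list(a$L %*% (conj_t(a$R) %*% b$L)))
      parts_R <- c(parts_R, list(b$R))
    }
  }
  if (length(parts_L) == 0)
    return(new_transition(c0, NULL, NULL, rep(0 + 0i, a$n2), n2 = a$n2))
  new_transition(c0, do.call(cbind, parts_L), do.call(cbind, parts_R),
                 rep(0 + 0i, a$n2), n2 = a$n2)
}

#' Predict an intermediate phase directly from the anchor
#'
#' The linear-intermediate-frame model evaluated at offset v: the image v
#' fine phases before the upper anchor t is predicted from the lower anchor
#' as `((V-v)/V f_V + v/V I) x + (V-v)/V b_V`. At v = 0 this is the full
#' base-step prediction `f_V x + b_V`.
#'
#' @param fV the base `cine_transition` (from [transition_for_lag()]).
#' @param V size of the base phase transition in fine-phase units.
#' @param v intermediate offset, `0 <= v <= V - 1`.
#' @param x_anchor complex image vector at the lower anchor.
#' @return the predicted complex image vector.
#' @export
anchor_prediction <- function(fV, V, v, x_anchor) {
  stopifnot(inherits(fV, "cine_transition"))
  if (v < 0 || v > V - 1) stop("v must lie in [0, V - 1]")
  a <- (V - v) / V
  lin <- scaled_shift(fV, a, v / V)
  as.vector(predict_image(lin, x_anchor) + a * fV$b)
}

#' Per-step transition between consecutive fine phases
#'
#' The affine map carrying the reconstruction at fine phase t - v to fine
#' phase t - v + 1 under the linear-intermediate-frame model. `v = V` is
#' admitted and reduces to the anchor step (the pseudoinverted factor is the
#' identity), so applying the returned transitions for v = V, V - 1, ..., 1
#' walks a full base step. The inversion uses the Moore-Penrose
#' pseudoinverse with tolerance `tol` (the base transition is rank-deficient
#' by construction).
#'
#' @param fV the base `cine_transition`.
#' @param V base phase-transition size.
#' @param v step index, `1 <= v <= V`.
#' @param tol pseudoinverse tolerance.
#' @return a `cine_transition` for the single fine step.
#' @export
step_transition <- function(fV, V, v, tol = 1e-10) {
  stopifnot(inherits(fV, "cine_transition"))
  if (v < 1 || v > V) stop("v must lie in [1, V]")
  A2 <- scaled_shift(fV, (V - v + 1) / V, (v - 1) / V)
  A1 <- scaled_shift(fV, (V - v) / V, v / V)
  f_new <- compose_linear(A2, invert_transition(A1, tol))
  bV <- fV$b
  b_new <- -predict_image(new_transition(f_new$c0, f_new$L, f_new$R,
                                         rep(0 + 0i, f_new$n2), n2 = f_new$n2),
                          ((V - v) / V) * bV) + ((V - v + 1) / V) * bV
  new_transition(f_new$c0, f_new$L, f_new$R, as.vector(b_new),
                 lag = fV$lag, n2 = f_new$n2)
}
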