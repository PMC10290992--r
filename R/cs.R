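# Compressed-sensing reconstruction: data fidelity + temporal total
# variation + state-space consistency, minimized by nonlinear conjugate
# gradient (Polak-Ribiere+ with restarts) with Armijo backtracking line
# search. Complex images are handled with Wirtinger-consistent gradients:
# for a real objective phi(X), the returned gradient G satisfies
# phi(X + dX) ~ phi(X) + Re <G, dX> for small complex perturbations dX.

#' Define a CS reconstruction problem
#'
#' @param kspace a `kspace_series` (stacked samples y and per-frame
#'   operators realizing the block-diagonal H).
#' @param transitions list of `cine_transition`s for frames m = 2..M (NULL
#'   when `lambda_ss = 0`; element m-1 maps frame m-1 to frame m).
#' @param lambda_spar temporal-total-variation weight (>= 0). The default
#'   `NULL` resolves to `0.01 * max |H^H y|`.
#' @param lambda_ss state-space-consistency weight (>= 0); `NULL` resolves
#'   to `0.05 * max |H^H y|`; set 0 for conventional CS.
#' @param ttv_eps smoothing constant of the TTV corner.
#' @return a `cs_problem`.
#' @export
cs_problem <- function(kspace, transitions = NULL, lambda_spar = NULL,
                       lambda_ss = NULL, ttv_eps = 1e-8) {
  stopifnot(inherits(kspace, "kspace_series"))
  M <- length(kspace$samples)
  N <- kspace$ops[[1]]$N
  Xadj <- vapply(seq_len(M), function(i)
    vec_img(op_adjoint(kspace$ops[[i]], kspace$samples[[i]])),
    complex(N * N))
  ref <- max(Mod(Xadj))
  if (is.null(lambda_spar)) lambda_spar <- 0.01 * ref
  if (is.null(lambda_ss)) lambda_ss <- 0.05 * ref
  if (lambda_spar < 0 || lambda_ss < 0) stop("lambdas must be >= 0")
  if (lambda_ss > 0 && (is.null(transitions) || length(transitions) != M - 1))
    stop("transitions for frames 2..M required when lambda_ss > 0")
  structure(list(kspace = kspace, transitions = transitions,
                 lambda_spar = lambda_spar, lambda_ss = lambda_ss,
                 ttv_eps = ttv_eps, M = M, N = N, X_init = Xadj),
            class = "cs_problem")
}

#' Temporal total variation value and gradient
#'
#' Smoothed TTV: sum over pixels and frame pairs of
#' `sqrt(|X_m - X_{m-1}|^2 + eps^2)`, with its exact (Wirtinger-consistent)
#' gradient.
#'
#' @param X complex N^2 x M matrix, one vectorized frame per column.
#' @param eps smoothing constant.
#' @return list with `value` and `grad` (same shape as X).
#' @export
ttv_value_grad <- function(X, eps = 1e-8) {
  M <- ncol(X)
  G <- matrix(0 + 0i, nrow(X), M)
  if (M < 2)
    return(list(value = 0, grad = G))
  Dm <- X[, 2:M, drop = FALSE] - X[, 1:(M - 1), drop = FALSE]
  S <- sqrt(Mod(Dm)^2 + eps^2)
  W <- Dm / S
  G[, 2:M] <- G[, 2:M, drop = FALSE] + W
  G[, 1:(M - 1)] <- G[, 1:(M - 1), drop = FALSE] - W
  list(value = sum(S), grad = G)
}

#' State-space consistency value and gradient
#'
#' `sum_m ||f_m X_{m-1} + b_m - X_m||^2` over m = 2..M with its exact
#' gradient (each column appears in up to two summands).
#'
#' @param X complex N^2 x M matrix.
#' @param transitions list of M-1 `cine_transition`s.
#' @return list with `value` and `grad`.
#' @export
ss_value_grad <- function(X, transitions) {
  M <- ncol(X)
  if (M < 2) return(list(value = 0, grad = matrix(0 + 0i, nrow(X), M)))
  if (is.null(transitions) || length(transitions) != M - 1)
    stop("need one transition per frame pair")
  G <- matrix(0 + 0i, nrow(X), M)
  val <- 0
  for (m in 2:M) {
    tr <- transitions[[m - 1]]
    r <- predict_image(tr, X[, m - 1]) - X[, m]
    val <- val + sum(Mod(r)^2)
    # d/dX_{m-1}: 2 f^H r ; d/dX_m: -2 r
    fh_r <- Conj(tr$c0) * r
    if (!is.null(tr$L)) fh_r <- fh_r + tr$R %*% (conj_t(tr$L) %*% r)
    G[, m - 1] <- G[, m - 1] + 2 * as.vector(fh_r)
    G[, m] <- G[, m] - 2 * r
  }
  list(value = val, grad = G)
}

#' Full CS objective and gradient
#'
#' `||HX - y||^2 + lambda_spar * TTV(X) + lambda_ss * SS(X)`. Setting
#' `lambda_ss = 0` removes the state-space term entirely (conventional CS).
#'
#' @param problem a `cs_problem`.
#' @param X complex N^2 x M matrix.
#' @return list with `value` and `grad`.
#' @export
objective_grad <- function(problem, X) {
  ks <- problem$kspace
  val <- 0
  G <- matrix(0 + 0i, nrow(X), ncol(X))
  for (m in seq_len(problem$M)) {
    op <- ks$ops[[m]]
    r <- op_forward(op, unvec_img(X[, m], problem$N)) - ks$samples[[m]]
    val <- val + sum(Mod(r)^2)
    G[, m] <- 2 * vec_img(op_adjoint(op, r))
  }
  if (problem$lambda_spar > 0) {
    tv <- ttv_value_grad(X, problem$ttv_eps)
    val <- val + problem$lambda_spar * tv$value
    G <- G + problem$lambda_spar * tv$grad
  }
  if (problem$lambda_ss > 0) {
    ss <- ss_value_grad(X, problem$transitions)
    val <- val + problem$lambda_ss * ss$value
    G <- G + problem$lambda_ss * ss$grad
  }
  list(value = val, grad = G)
}

#' Solver configuration for the nonlinear conjugate gradient
#'
#' @param max_iters iteration cap.
#' @param grad_tol stop when the RMS gradient magnitude falls below this.
#' @param ls_c Armijo sufficient-decrease constant in (0, 1).
#' @param ls_rho backtracking shrink factor in (0, 1).
#' @param cg_variant `"PR+"` (Polak-Ribiere with nonnegativity restart) or
#'   `"FR"` (Fletcher-Reeves).
#' @param restart_every force a steepest-descent restart every so many
#'   iterations.
#' @param ls_max_evals cap on backtracking evaluations per iteration.
#' @return a `solver_config` list.
#' @export
solver_config <- function(max_iters = 50, grad_tol = 1e-9, ls_c = 1e-4,
                          ls_rho = 0.5, cg_variant = c("PR+", "FR"),
                          restart_every = 20L, ls_max_evals = 40L) {
  cg_variant <- match.arg(cg_variant)
  if (ls_c <= 0 || ls_c >= 1 || ls_rho <= 0 || ls_rho >= 1)
    stop("line-search constants must lie in (0, 1)")
  structure(list(max_iters = as.integer(max_iters), grad_tol = grad_tol,
                 ls_c = ls_c, ls_rho = ls_rho, cg_variant = cg_variant,
                 restart_every = as.integer(restart_every),
                 ls_max_evals = as.integer(ls_max_evals)),
            class = "solver_config")
}

re_inner <- function(a, b) sum(Re(Conj(a) * b))

#' Nonlinear conjugate gradient CS reconstruction
#'
#' Minimizes the CS objective by Polak-Ribiere+ conjugate gradient with
#' Armijo backtracking (initial step 1, grown after easy accepts, shrunk by
#' `ls_rho` until sufficient decrease). The objective trace is monotone
#' non-increasing by construction; the solver aborts on a non-finite
#' objective.
#'
#' @param problem a `cs_problem`.
#' @param config a [solver_config()].
#' @param X_init starting point (default: per-frame adjoint
#'   reconstruction).
#' @return a `cs_result`: `frames` (`cine_series` when phase labels are
#'   attached, otherwise the raw matrix `X`), `X`, `objective_trace`,
#'   `iterations`, `converged`.
#' @export
nlcg_reconstruct <- function(problem, config = solver_config(),
                             X_init = NULL) {
  stopifnot(inherits(problem, "cs_problem"))
  X <- if (is.null(X_init)) problem$X_init else X_init
  og <- objective_grad(problem, X)
  if (!is.finite(og$value)) stop("non-finite objective at initialization")
  trace <- og$value
  g <- og$grad
  d <- -g
  step <- 1
  iters <- 0L
  n <- length(g)
  for (it in seq_len(config$max_iters)) {
    gnorm <- sqrt(re_inner(g, g) / n)
    if (gnorm < config$grad_tol) break
    slope <- re_inner(g, d)
    if (slope >= 0) { d <- -g; slope <- re_inner(g, d) }
    t <- step
    f0 <- og$value
    accepted <- FALSE
    for (ev in seq_len(config$ls_max_evals)) {
      cand <- X + t * d
      ogc <- objective_grad(problem, cand)
      if (is.finite(ogc$value) &&
          ogc$value <= f0 + config$ls_c * t * slope) {
        accepted <- TRUE
        break
      }
      t <- t * config$ls_rho
    }
    if (!accepted) break
    X <- cand
    g_new <- ogc$grad
    beta <- if (it %% config$restart_every == 0) 0
    else if (config$cg_variant == "PR+")
      max(0, re_inner(g_new, g_new - g) / re_inner(g, g))
    else re_inner(g_new, g_new) / re_inner(g, g)
    d <- -g_new + beta * d
    g <- g_new
    og <- ogc
    trace <- c(trace, og$value)
    step <- min(1, t / config$ls_rho)   # warm-start next line search
    iters <- it
  }
  structure(list(X = X, objective_trace = trace, iterations = iters,
                 converged = sqrt(re_inner(g, g) / n) < config$grad_tol,
                 problem = problem),
            class = "cs_result")
}

#' @export
print.cs_result <- function(x, ...) {
  cat(sprintf("<cs_result> %d frames, %d iterations, objective %.4g\n",
              x$problem$M, x$iterations, utils::tail(x$objective_trace, 1)))
  invisible(x)
}

#' Frames of a CS result as a cine series
#'
#' @param result a `cs_result`.
#' @param phase_labels phase label per frame.
#' @param period_T phases per cycle.
#' @return a `cine_series`.
#' @export
cs_frames <- function(result, phase_labels, period_T) {
  N <- result$problem$N
  M <- result$problem$M
  arr <- array(0 + 0i, c(N, N, M))
  for (m in seq_len(M)) arr[, , m] <- unvec_img(result$X[, m], N)
  cine_series(arr, phase_labels, period_T)
}
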