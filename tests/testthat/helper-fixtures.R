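# Shared fixture builders. Everything is generated in code at test time.

random_cine <- function(N, T, seed = 1, sd = 1) {
  withr::with_seed(seed, {
    fr <- array(complex(real = rnorm(N * N * T, sd = sd),
                        imaginary = rnorm(N * N * T, sd = sd)),
                c(N, N, T))
    cine_series(fr, seq_len(T), T, is_training = TRUE)
  })
}

random_image <- function(N, seed = 1) {
  withr::with_seed(seed, matrix(complex(real = rnorm(N * N),
                                        imaginary = rnorm(N * N)), N, N))
}

# Row-major vectorization used throughout the package (pixel order
# (1,1), (1,2), ..., (N,N)).
vec_rm <- function(x) as.vector(t(x))

# Brute-force evaluation of the lag-l temporal (cross-)covariance with the
# 1/T normalization and circular indexing, by explicit loops.
brute_cov <- function(frames_arr, l) {
  N <- dim(frames_arr)[1]; T <- dim(frames_arr)[3]
  Bm <- matrix(0 + 0i, N * N, T)
  for (i in seq_len(N)) for (j in seq_len(N))
    Bm[(i - 1) * N + j, ] <- frames_arr[i, j, ]
  mu <- rowMeans(Bm)
  C <- matrix(0 + 0i, N * N, N * N)
  for (p in seq_len(N * N)) for (q in seq_len(N * N)) {
    acc <- 0 + 0i
    for (t in 0:(T - 1)) {
      tl <- (t + l) %% T
      acc <- acc + (Bm[p, tl + 1] - mu[p]) * Conj(Bm[q, t + 1] - mu[q])
    }
    C[p, q] <- acc / T
  }
  C
}

# Eigendecomposition-based Hermitian pseudoinverse: an independent route
# from the package's SVD-based factored transitions.
eig_pinv <- function(A, tol = 1e-10) {
  e <- eigen((A + Conj(t(A))) / 2, symmetric = TRUE)
  keep <- abs(e$values) > tol * max(abs(e$values))
  V <- e$vectors[, keep, drop = FALSE]
  V %*% ((1 / e$values[keep]) * Conj(t(V)))
}

# Dot-product adjointness <A u, v> vs <u, A^H v> relative error.
adjointness_err <- function(op, seed = 1) {
  withr::with_seed(seed, {
    u <- matrix(complex(real = rnorm(op$n2), imaginary = rnorm(op$n2)),
                op$N, op$N)
    v <- complex(real = rnorm(op$m), imaginary = rnorm(op$m))
  })
  lhs <- sum(Conj(op_forward(op, u)) * v)
  rhs <- sum(Conj(vec_rm(u)) * vec_rm(op_adjoint(op, v)))
  Mod(lhs - rhs) / max(Mod(lhs), 1e-30)
}

per_cycle_means <- function(m, lens) {
  i <- cumsum(c(0, lens))
  vapply(seq_along(lens), function(k) mean(m[(i[k] + 1):i[k + 1]]), 0)
}
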