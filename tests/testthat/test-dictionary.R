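# Motion dictionary: temporal moments, LMMSE transitions, process
# covariances.

test_that("temporal moments match the brute-force double-loop oracle", {
  cine <- random_cine(4, 6, seed = 11)
  dict <- temporal_moments(cine)
  for (l in c(0, 1, 3, 5, -2, -4))
    expect_equal(cov_for_lag(dict, l), brute_cov(cine$frames, l),
                 tolerance = 1e-10)
  # mean vector, row-major pixel order
  mu_bf <- vec_rm(apply(cine$frames, c(1, 2), mean))
  expect_equal(dict$mu, mu_bf, tolerance = 1e-12)
  expect_error(cov_for_lag(dict, 6), "smaller than T")
})

test_that("single-pixel two-frame series reproduces the hand computation", {
  # values {1, 3}: mu = 2, c(0) = 1, c(1) = -1 under circular wrap
  cine <- cine_series(array(c(1 + 0i, 3 + 0i), c(1, 1, 2)), 1:2, 2L,
                      is_training = TRUE)
  dict <- temporal_moments(cine)
  expect_equal(dict$mu, 2 + 0i)
  expect_equal(cov_for_lag(dict, 0)[1, 1], 1 + 0i)
  expect_equal(cov_for_lag(dict, 1)[1, 1], -1 + 0i)
})

test_that("C_0 is Hermitian PSD and lags are conjugate symmetric", {
  cine <- random_cine(4, 6, seed = 12)
  dict <- temporal_moments(cine)
  C0 <- cov_for_lag(dict, 0)
  expect_lt(max(Mod(C0 - Conj(t(C0)))), 1e-10 * max(Mod(C0)))
  ev <- eigen(C0, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(ev))
  for (l in 1:5)
    expect_equal(cov_for_lag(dict, -l), Conj(t(cov_for_lag(dict, l))),
                 tolerance = 1e-10)
  # constant training series: zero covariance at every lag
  const <- cine_series(array(2 + 1i, c(3, 3, 4)), 1:4, 4L, is_training = TRUE)
  dc <- temporal_moments(const)
  expect_equal(max(Mod(cov_for_lag(dc, 0))), 0, tolerance = 1e-14)
  expect_equal(max(Mod(cov_for_lag(dc, 2))), 0, tolerance = 1e-14)
})

test_that("transitions preserve the mean and are exact on the training span", {
  cine <- random_cine(4, 6, seed = 13)
  dict <- temporal_moments(cine)
  B <- sapply(1:6, function(i) vec_rm(cine$frames[, , i]))
  for (l in c(0, 1, 4, -2, -5)) {
    tr <- transition_for_lag(dict, l)
    expect_equal(predict_image(tr, dict$mu), dict$mu, tolerance = 1e-8)
    for (t in 1:6) {
      tgt <- ((t - 1 + l) %% 6) + 1
      expect_equal(predict_image(tr, B[, t]), B[, tgt], tolerance = 1e-8)
    }
  }
  # first-step request: identity with zero bias
  id <- transition_for_lag(dict, first_step = TRUE)
  x <- B[, 2]
  expect_equal(predict_image(id, x), x, tolerance = 1e-14)
  expect_equal(transition_matrix(id), diag(1 + 0i, 16))
})

test_that("disjoint-support training frames are predicted exactly at all lags", {
  # frame t lives on row t of a 5x5 grid: pairwise orthogonal frames
  N <- 5; T <- 5
  fr <- array(0 + 0i, c(N, N, T))
  withr::with_seed(21, for (t in 1:T)
    fr[t, , t] <- complex(real = rnorm(N), imaginary = rnorm(N)))
  cine <- cine_series(fr, 1:T, T, is_training = TRUE)
  dict <- temporal_moments(cine)
  B <- sapply(1:T, function(i) vec_rm(fr[, , i]))
  for (l in c(1, 2, -1, -4)) {
    tr <- transition_for_lag(dict, l)
    for (t in 1:T)
      expect_equal(predict_image(tr, B[, t]), B[, ((t - 1 + l) %% T) + 1],
                   tolerance = 1e-8)
  }
})

test_that("the transition solves the restricted least-squares problem", {
  # normal equations built by explicit sums, inverted by an eigen-based
  # pseudoinverse: an independent route to the LMMSE estimator
  cine <- random_cine(4, 8, seed = 14)
  dict <- temporal_moments(cine)
  B <- sapply(1:8, function(i) vec_rm(cine$frames[, , i]))
  Y <- B - rowMeans(B)
  for (l in c(1, 3)) {
    Yl <- Y[, ((seq_len(8) - 1 + l) %% 8) + 1]
    G <- Y %*% Conj(t(Y))
    H <- Yl %*% Conj(t(Y))
    f_oracle <- H %*% eig_pinv(G)
    f_pkg <- transition_matrix(transition_for_lag(dict, l))
    expect_lt(max(Mod(f_pkg - f_oracle)), 1e-6 * max(Mod(f_oracle)))
  }
})

test_that("process covariance variants follow their definitions", {
  cine <- random_cine(3, 5, seed = 15)
  dict <- temporal_moments(cine)
  q2 <- process_cov_two_stage(dict)
  C0 <- cov_for_lag(dict, 0)
  expect_equal(q2$diag, Re(diag(C0)), tolerance = 1e-12)
  expect_true(all(q2$diag >= 0))
  qf <- process_cov_full_c0(dict)
  expect_equal(qf$matrix, C0, tolerance = 1e-12)
  # constant training series: Q = 0 for both variants
  const <- cine_series(array(1 + 2i, c(3, 3, 4)), 1:4, 4L, is_training = TRUE)
  expect_equal(max(process_cov_two_stage(temporal_moments(const))$diag), 0)
  expect_equal(max(process_cov_random_walk(const)$diag), 0)
  # random walk: population variance of the difference images, per pixel
  qrw <- process_cov_random_walk(cine)
  fr <- cine$frames
  for (p in sample(9, 4)) {
    i <- (p - 1) %/% 3 + 1; j <- (p - 1) %% 3 + 1
    d <- fr[i, j, 2:5] - fr[i, j, 1:4]
    expect_equal(qrw$diag[(i - 1) * 3 + j], mean(Mod(d - mean(d))^2),
                 tolerance = 1e-12)
  }
  # linear ramp: constant differences, zero variance
  ramp <- cine_series(array(rep(1:4, each = 4) + 0i, c(2, 2, 4)), 1:4, 4L)
  expect_equal(max(process_cov_random_walk(ramp)$diag), 0, tolerance = 1e-14)
})

test_that("denoiser hooks preserve shape and the Gaussian option smooths", {
  cine <- random_cine(8, 3, seed = 16)
  expect_identical(preprocess_training(cine)$frames, cine$frames)
  sm <- preprocess_training(cine, "gaussian")
  v0 <- mean(apply(cine$frames, 3, function(f) stats::var(Re(as.vector(f)))))
  v1 <- mean(apply(sm$frames, 3, function(f) stats::var(Re(as.vector(f)))))
  expect_lt(v1, v0)
  expect_error(preprocess_training(cine, function(f) f[1:4, 1:4]),
               "preserve the frame shape")
})
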