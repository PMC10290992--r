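# Kalman filtering: lag schedules, initialization, prediction/update steps
# and their limiting behavior.

test_that("lag schedule reproduces the worked phase transitions", {
  expect_equal(lag_schedule(c(50, 1), 50)[2], -49L)
  expect_equal(lag_schedule(c(30, 1), 50)[2], -29L)
  expect_equal(lag_schedule(c(1, 3, 5), 50)[-1], c(2L, 2L))
  expect_true(is.na(lag_schedule(c(7, 8), 50)[1]))
  expect_error(lag_schedule(c(1, 60), 50), "phase labels")
})

test_that("scalar pipeline matches a hand-coded Kalman filter over 100 steps", {
  f <- 0.9 + 0.05i; b <- 0.3 - 0.1i; q <- 0.04; r <- 0.25
  tr <- as_transition(matrix(f, 1, 1), b)
  op <- build_operator(cartesian_mask(1, 1))
  withr::with_seed(77, {
    z <- complex(real = rnorm(100), imaginary = rnorm(100))
  })
  Q <- structure(list(diag = q, variant = "two_stage", N = 1L),
                 class = "process_cov")
  state <- list(x = 0.2 + 0i, P = matrix(1 + 0i, 1, 1), t = 0L, phase = 1L)
  xs <- 0.2 + 0i; ps <- 1
  for (t in 1:100) {
    state <- predict_step(state, tr, Q)
    state <- update_step(state, z[t], op, r)
    # scalar recursion by hand
    xf <- f * xs + b; pf <- Mod(f)^2 * ps + q
    k <- pf / (pf + r)
    xs <- xf + k * (z[t] - xf); ps <- (1 - k) * pf
    expect_equal(state$x, xs, tolerance = 1e-10)
    expect_equal(Re(state$P[1, 1]), ps, tolerance = 1e-10)
  }
})

test_that("update step agrees with the explicit dense Kalman equations", {
  N <- 4; n2 <- 16
  pat <- radial_trajectory(N, 2)
  op <- build_operator(pat)
  # dense EF from basis vectors (row-major ordering)
  A <- sapply(seq_len(n2), function(j) {
    e <- rep(0 + 0i, n2); e[j] <- 1
    op_forward(op, t(matrix(e, N, N)))
  })
  withr::with_seed(55, {
    G <- matrix(complex(real = rnorm(n2 * n2), imaginary = rnorm(n2 * n2)), n2)
    P <- G %*% Conj(t(G)) / n2
    xf <- complex(real = rnorm(n2), imaginary = rnorm(n2))
    z <- complex(real = rnorm(op$m), imaginary = rnorm(op$m))
  })
  r <- 0.1
  S <- A %*% P %*% Conj(t(A)) + diag(r, op$m)
  K <- P %*% Conj(t(A)) %*% solve(S)
  xa <- xf + K %*% (z - A %*% xf)
  Pa <- (diag(1 + 0i, n2) - K %*% A) %*% P
  Pa <- (Pa + Conj(t(Pa))) / 2
  st <- update_step(list(x = xf, P = P, t = 1L, phase = 1L), z, op, r)
  expect_equal(st$x, as.vector(xa), tolerance = 1e-8)
  expect_equal(st$P, Pa, tolerance = 1e-8)
})

test_that("full sampling with vanishing noise recovers the inverse DFT", {
  N <- 8
  op <- build_operator(cartesian_mask(N, N))
  img <- random_image(N, seed = 3)
  z <- op_forward(op, img)
  pred <- list(x = rep(0 + 0i, N * N), P = diag(1 + 0i, N * N),
               t = 1L, phase = 1L)
  st <- update_step(pred, z, op, 1e-12)
  expect_equal(st$x, vec_rm(op_adjoint(op, z)), tolerance = 1e-6)
})

test_that("infinite measurement noise returns the prediction unchanged", {
  N <- 8
  op <- build_operator(radial_trajectory(N, 2))
  xf <- complex(real = rnorm(64), imaginary = rnorm(64))
  z <- complex(real = rnorm(op$m), imaginary = rnorm(op$m))
  pred <- list(x = xf, P = diag(1 + 0i, 64), t = 1L, phase = 1L)
  st <- update_step(pred, z, op, 1e12)
  expect_lt(max(Mod(st$x - xf)), 1e-8 * max(Mod(xf)))
})

test_that("updates never worsen the data fit in the sampled subspace", {
  truth <- make_phantom_cycle(8, 6, seed = 1)
  ks <- measure_series(truth, radial_trajectory(8, 2), noise_sigma = 0,
                       seed = 1)
  dict <- temporal_moments(truth)
  Q <- process_cov_two_stage(dict)
  init <- init_filter(truth, ks, filter_config(R_sigma2 = 1e-12,
                                               P0_sigma2 = 1e-4))
  state <- init$state
  op <- ks$ops[[1]]
  for (t in 2:6) {
    tr <- transition_for_lag(dict, 1)
    pred <- predict_step(state, tr, Q)
    state <- update_step(pred, ks$samples[[t]], op, 1e-12)
    rf <- sqrt(sum(Mod(op_forward(op, t(matrix(pred$x, 8, 8))) -
                         ks$samples[[t]])^2))
    ra <- sqrt(sum(Mod(op_forward(op, t(matrix(state$x, 8, 8))) -
                         ks$samples[[t]])^2))
    expect_lte(ra, rf + 1e-10)
    # covariance stays Hermitian PSD with a real nonnegative diagonal
    expect_lt(max(Mod(state$P - Conj(t(state$P)))), 1e-8 * max(Mod(state$P)))
    ev <- eigen(state$P, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(abs(ev)) - 1e-10)
    expect_true(all(Re(diag(state$P)) >= -1e-12))
  }
})

test_that("filter initialization follows the background-ROI protocol", {
  truth <- make_phantom_cycle(16, 6, seed = 2)
  ks <- measure_series(truth, cartesian_mask(16, 16), noise_sigma = 0,
                       seed = 1)
  # user-supplied variances win
  init <- init_filter(truth, ks, filter_config(R_sigma2 = 0, P0_sigma2 = 2))
  expect_equal(init$R_sigma2, 0)
  expect_equal(Re(init$state$P[1, 1]), 2)
  expect_equal(init$state$x, vec_rm(truth$frames[, , 1]))
  # noiseless constant-background phantom: estimated sigma^2 ~ 0
  est <- init_filter(truth, ks, filter_config())
  expect_lt(est$R_sigma2, 1e-12)
  expect_error(init_filter(truth, ks,
                           filter_config(background_roi = c(1, 40, 1, 4))),
               "ROI")
})

test_that("ROI noise estimate is unbiased to within 10% at 16x16", {
  N <- 20; sig <- 0.2
  blank <- cine_series(array(0 + 0i, c(N, N, 1)), 1L, 1L, is_training = TRUE)
  pat <- cartesian_mask(N, N)
  ests <- vapply(1:100, function(s) {
    ks <- measure_series(blank, pat, noise_sigma = sig, seed = s)
    init_filter(blank, ks,
                filter_config(background_roi = c(1, 16, 1, 16)))$R_sigma2
  }, 0)
  expect_lt(abs(mean(ests) - sig^2), 0.1 * sig^2)
})

test_that("degenerate inputs are handled: empty runs and oversized grids", {
  train <- make_phantom_cycle(8, 4, seed = 1)
  empty <- structure(list(samples = list(), ops = list(), noise_sigma = 0,
                          seed = 0L), class = "kspace_series")
  res <- run_reconstruction(train, empty, integer(0), filter_config())
  expect_equal(length(res$mse_trace), 0)
  expect_equal(dim(res$frames$frames)[3], 0)
  big <- cine_series(array(0 + 0i, c(128, 128, 2)), 1:2, 2L,
                     is_training = TRUE)
  expect_error(run_reconstruction(big, empty, integer(0), filter_config()),
               "capped")
})

test_that("a short two-stage run tracks the truth on a periodic phantom", {
  ph <- list(train = make_phantom_cycle(16, 8, seed = 1),
             test = make_phantom_cycle(16, 8, seed = 2))
  sc <- build_scenario(ph$train, ph$test, scenario_spec("periodic",
                                                        n_cycles = 2))
  truth <- rescale_means(sc$test, ph$train)
  ks <- measure_series(truth, radial_patterns(16, 3, 16),
                       noise_sigma = 0.02, seed = 4)
  res <- run_reconstruction(ph$train, ks, truth$phase_labels,
                            filter_config("two_stage"), truth = truth)
  # reconstruction must beat the zero-filled adjoint baseline clearly
  adj_mse <- mean(vapply(1:16, function(i)
    mean(Mod(op_adjoint(ks$ops[[i]], ks$samples[[i]]) -
               truth$frames[, , i])^2), 0))
  expect_lt(mean(res$mse_trace), 0.2 * adj_mse)
  expect_equal(res$lag_trace[1], 0L)
  expect_equal(res$lag_trace[9], -7L)   # cycle wrap: phase 8 -> 1
})
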