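# Compressed sensing: objective terms, gradients, solver behavior.

fd_check <- function(value_grad, X, seeds = 1:3, h = 1e-6) {
  og <- value_grad(X)
  errs <- vapply(seeds, function(s) {
    dX <- withr::with_seed(s, matrix(complex(real = rnorm(length(X)),
                                             imaginary = rnorm(length(X))),
                                     nrow(X), ncol(X)))
    num <- (value_grad(X + h * dX)$value - value_grad(X - h * dX)$value) /
      (2 * h)
    ana <- sum(Re(Conj(og$grad) * dX))
    abs(num - ana) / max(abs(num), 1e-12)
  }, 0)
  max(errs)
}

small_problem <- function(noise_seed = 2, lambda_ss = NULL, ttv_eps = 1e-6) {
  train <- make_phantom_cycle(8, 6, seed = 1)
  sc <- build_scenario(train, make_phantom_cycle(8, 6, seed = 2),
                       scenario_spec("periodic", n_cycles = 1))
  ks <- measure_series(sc$test, cartesian_mask(8, 3, seed = 1),
                       noise_sigma = 0.01, seed = noise_seed)
  dict <- temporal_moments(train)
  lags <- lag_schedule(sc$test$phase_labels, 6)
  trans <- lapply(lags[-1], function(l) transition_for_lag(dict, l))
  cs_problem(ks, trans, lambda_ss = lambda_ss, ttv_eps = ttv_eps)
}

test_that("temporal total variation has the stated values and exact gradient", {
  X <- matrix(complex(real = rnorm(32), imaginary = rnorm(32)), 16, 2)
  # static stack: value collapses to the smoothing floor, gradient vanishes
  Xs <- cbind(X[, 1], X[, 1], X[, 1])
  tv <- ttv_value_grad(Xs, eps = 1e-8)
  expect_equal(tv$value, 2 * 16 * 1e-8, tolerance = 1e-6)
  expect_lt(max(Mod(tv$grad)), 1e-7)
  # single unit finite difference -> value 1 as eps -> 0
  X2 <- matrix(0 + 0i, 4, 2); X2[3, 2] <- 1
  expect_equal(ttv_value_grad(X2, eps = 1e-12)$value, 1, tolerance = 1e-6)
  withr::with_seed(8, {
    Xr <- matrix(complex(real = rnorm(48), imaginary = rnorm(48)), 16, 3)
  })
  expect_lt(fd_check(function(x) ttv_value_grad(x, eps = 1e-4), Xr), 1e-5)
})

test_that("state-space consistency term vanishes on dictionary orbits", {
  prob <- small_problem()
  # build the orbit from frame 1 of the training cycle through the
  # transitions: the term and its gradient are zero along the recursion
  X <- matrix(0 + 0i, 64, 6)
  X[, 1] <- prob$X_init[, 1]
  for (m in 2:6)
    X[, m] <- predict_image(prob$transitions[[m - 1]], X[, m - 1])
  ss <- ss_value_grad(X, prob$transitions)
  expect_lt(ss$value, 1e-16 * sum(Mod(X)^2))
  expect_lt(max(Mod(ss$grad[, 2:5])), 1e-6)
  # identity transitions reduce it to plain squared temporal differences
  idt <- lapply(1:5, function(i) as_transition(diag(1 + 0i, 64)))
  withr::with_seed(9, {
    Xr <- matrix(complex(real = rnorm(64 * 6), imaginary = rnorm(64 * 6)),
                 64, 6)
  })
  expect_equal(ss_value_grad(Xr, idt)$value,
               sum(Mod(Xr[, 2:6] - Xr[, 1:5])^2), tolerance = 1e-10)
  expect_error(ss_value_grad(Xr, idt[1:3]), "transition")
  expect_lt(fd_check(function(x) ss_value_grad(x, prob$transitions), Xr),
            1e-5)
})

test_that("the full objective and gradient pass the finite-difference check", {
  prob <- small_problem(ttv_eps = 1e-4)
  withr::with_seed(10, {
    X <- matrix(complex(real = rnorm(64 * 6, sd = 0.3),
                        imaginary = rnorm(64 * 6, sd = 0.3)), 64, 6)
  })
  expect_lt(fd_check(function(x) objective_grad(prob, x), X), 1e-5)
  # truth with exact data and no penalties: objective zero
  truth <- small_problem()$kspace
  prob0 <- cs_problem(small_problem()$kspace, NULL, lambda_spar = 0,
                      lambda_ss = 0)
  sc <- build_scenario(make_phantom_cycle(8, 6, seed = 1),
                       make_phantom_cycle(8, 6, seed = 2),
                       scenario_spec("periodic", n_cycles = 1))
  ks0 <- measure_series(sc$test, cartesian_mask(8, 3, seed = 1),
                        noise_sigma = 0, seed = 1)
  probt <- cs_problem(ks0, NULL, lambda_spar = 0, lambda_ss = 0)
  Xt <- sapply(1:6, function(i) vec_rm(sc$test$frames[, , i]))
  expect_lt(objective_grad(probt, Xt)$value, 1e-20)
})

test_that("lambda_ss = 0 is bit-identical to a build without transitions", {
  prob_a <- small_problem(lambda_ss = 0)
  ks <- prob_a$kspace
  prob_b <- cs_problem(ks, NULL, lambda_ss = 0, ttv_eps = 1e-6)
  cfg <- solver_config(max_iters = 10)
  sol_a <- nlcg_reconstruct(prob_a, cfg)
  sol_b <- nlcg_reconstruct(prob_b, cfg)
  expect_identical(sol_a$X, sol_b$X)
  expect_identical(sol_a$objective_trace, sol_b$objective_trace)
})

test_that("NLCG is monotone and solves the quadratic-only problem", {
  # full sampling, no penalties: minimizer is the inverse DFT; start the
  # solver away from it
  train <- make_phantom_cycle(8, 6, seed = 1)
  ks <- measure_series(train, cartesian_mask(8, 8), noise_sigma = 0,
                       seed = 1)
  prob <- cs_problem(ks, NULL, lambda_spar = 0, lambda_ss = 0)
  X0 <- matrix(0.5 + 0.2i, 64, 6)
  sol <- nlcg_reconstruct(prob, solver_config(max_iters = 50,
                                              grad_tol = 1e-12), X_init = X0)
  expect_true(all(diff(sol$objective_trace) <= 1e-12))
  resid <- max(vapply(1:6, function(m)
    max(Mod(op_forward(ks$ops[[m]], t(matrix(sol$X[, m], 8, 8))) -
              ks$samples[[m]])), 0))
  expect_lt(resid, 1e-6)
  # monotone on a regularized problem too
  sol2 <- nlcg_reconstruct(small_problem(), solver_config(max_iters = 25))
  expect_true(all(diff(sol2$objective_trace) <= 1e-12))
})
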