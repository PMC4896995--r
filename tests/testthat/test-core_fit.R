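test_that("solve_ls reproduces hand-solved systems and rejects bad input", {
  expect_equal(solve_ls(matrix(1, 2, 1), c(2, 4)), 3)
  expect_equal(solve_ls(diag(2), c(5, 7)), c(5, 7))
  # exact line fit, hand-solved normal equations
  expect_equal(solve_ls(cbind(1, 0:2), c(1, 3, 5)), c(1, 2))
  expect_error(solve_ls(cbind(1:3, 2 * (1:3)), c(1, 2, 3)), "singular")
  expect_error(solve_ls(matrix(1, 1, 2), 1), "underdetermined")
})

test_that("normal-equation residual is orthogonal to the column space", {
  set.seed(11)
  for (i in 1:100) {
    m <- sample(4:12, 1); n <- sample(1:3, 1)
    a <- matrix(rnorm(m * n), m, n)
    y <- rnorm(m)
    b <- solve_ls(a, y)
    # direct pseudo-inverse oracle
    expect_equal(b, as.numeric(solve(t(a) %*% a) %*% t(a) %*% y),
                 tolerance = 1e-10)
    r <- as.numeric(crossprod(a, y - a %*% b))
    expect_lt(sqrt(sum(r^2)) / sqrt(sum(crossprod(a, y)^2)), 1e-10)
  }
})

test_that("weighted least squares matches the explicit formula", {
  set.seed(12)
  a <- matrix(rnorm(10), 5, 2); y <- rnorm(5)
  expect_equal(solve_wls(a, y, rep(1, 5)), solve_ls(a, y), tolerance = 1e-12)
  w <- runif(5, 0.1, 4)
  oracle <- as.numeric(solve(t(a) %*% diag(w) %*% a) %*% t(a) %*% diag(w) %*% y)
  expect_equal(solve_wls(a, y, w), oracle, tolerance = 1e-10)
  # zero weight drops the observation
  b <- solve_wls(matrix(1, 2, 1), c(3, 9), c(1, 0))
  expect_equal(b, 3)
  expect_error(solve_wls(a, y, rep(0, 5)), "zero")
  expect_error(solve_wls(a, y, c(-1, 1, 1, 1, 1)), "negative")
})

test_that("NNLS clips infeasible coordinates and matches interior LS", {
  expect_equal(solve_nnls(diag(2), c(-1, 2)), c(0, 2))
  a <- matrix(c(1, 0, 1, 1, 1, 2), 3, 2)
  y <- as.numeric(a %*% c(0.3, 0.7))
  expect_equal(solve_nnls(a, y), c(0.3, 0.7), tolerance = 1e-10)
})

test_that("NNLS agrees with exhaustive active-set enumeration", {
  set.seed(13)
  for (i in 1:200) {
    a <- matrix(rnorm(12), 4, 3)
    y <- rnorm(4, sd = 2)
    got <- solve_nnls(a, y)
    want <- nnls_bruteforce(a, y)
    expect_true(all(got >= 0))
    expect_equal(sum((y - a %*% got)^2), sum((y - a %*% want)^2),
                 tolerance = 1e-8)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("NNLS equals LS whenever the LS solution is nonnegative", {
  set.seed(14)
  for (i in 1:50) {
    a <- matrix(runif(12, 0.1, 1), 4, 3)
    b_true <- runif(3, 0.2, 2)
    y <- as.numeric(a %*% b_true)
    ls <- tryCatch(solve_ls(a, y), error = function(e) NULL)
    if (is.null(ls) || any(ls < 0)) next
    expect_equal(solve_nnls(a, y), ls, tolerance = 1e-8)
  }
})

test_that("Gauss-Newton solves a linear model in one accepted step", {
  set.seed(15)
  a <- matrix(rnorm(12), 6, 2); y <- rnorm(6)
  pr <- nonlinear_problem(function(b) as.numeric(a %*% b), c(0, 0),
                          jacobian = function(b) a)
  fit <- fit_nonlinear(pr, y, solver_config(lm_lambda0 = 0))
  expect_equal(fit$params, solve_ls(a, y), tolerance = 1e-10)
  # exact after the first accepted step: later steps change nothing
  expect_equal(fit$r_history[2], fit$residual, tolerance = 1e-12)
})

test_that("LM damping follows the lambda/r schedule across accepted steps", {
  a <- matrix(rnorm(12), 6, 2); y <- rnorm(6)
  pr <- nonlinear_problem(function(b) as.numeric(a %*% b), c(0, 0),
                          jacobian = function(b) a)
  # run exactly 2 iterations of a linear model: both steps accepted
  fit <- fit_nonlinear(pr, y, solver_config(lm_lambda0 = 10, lm_rate = 10,
                                            max_iterations = 2,
                                            residual_tolerance = 0))
  expect_equal(fit$accepted_steps, 2L)
  expect_equal(fit$lambda, 0.1)
})

test_that("LM recovers a mono-exponential from noiseless echoes", {
  te <- 12 * (1:19)
  y <- 1000 * exp(-te / 80)
  pr <- nonlinear_problem(function(b) b[1] * exp(-te / b[2]), c(800, 60))
  fit <- fit_nonlinear(pr, y, solver_config(residual_tolerance = 1e-14))
  expect_equal(fit$params, c(1000, 80), tolerance = 1e-6)
  expect_true(fit$converged)
  # accepted residuals never increase
  expect_true(all(diff(fit$r_history) <= 1e-12))
})

test_that("non-finite model output names the offending parameter state", {
  pr <- nonlinear_problem(function(b) rep(NaN, 3), c(1, 2))
  expect_error(fit_nonlinear(pr, 1:3, solver_config()), "non-finite")
})

test_that("parameter errors follow sigma^2 (A'A)^-1, variances first", {
  expect_equal(compute_param_errors(diag(2), residual = 1, m = 3, n = 2),
               c(1, 1, 0))
  # closed-form oracle on a 5-point line fit
  x <- c(0, 1, 2, 3, 4)
  a <- cbind(1, x)
  y <- c(1.1, 2.9, 5.2, 6.8, 9.1)
  b <- solve_ls(a, y)
  r <- sum((y - a %*% b)^2)
  covm <- r / (5 - 2) * solve(t(a) %*% a)
  got <- compute_param_errors(a, r)
  expect_length(got, 3)   # 2 variances + 1 covariance
  expect_equal(got, c(covm[1, 1], covm[2, 2], covm[1, 2]), tolerance = 1e-12)
  expect_error(compute_param_errors(diag(2), 1, m = 2, n = 2), "m <= n")
})

test_that("bounds are enforced by clipping after each step", {
  te <- 12 * (1:10)
  y <- 1000 * exp(-te / 300)
  pr <- nonlinear_problem(function(b) b[1] * exp(-te / b[2]), c(900, 100),
                          lower = c(0, 10), upper = c(1100, 150))
  fit <- fit_nonlinear(pr, y, solver_config())
  expect_lte(fit$params[2], 150)
  expect_gte(fit$params[1], 0)
})
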