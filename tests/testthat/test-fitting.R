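test_that("build_design assembles Gram, null-space and penalty matrices", {
  k <- tps_kernel(unit_dom)
  set.seed(8)
  X <- cbind(runif(4), runif(4))
  des <- build_design(k, X)
  # TPS with representers = observations: zero diagonal (eta(0) = 0)
  expect_true(all(diag(des$P) == 0))
  expect_equal(des$J, des$P, tolerance = 1e-15)
  expect_equal(des$P, t(des$P), tolerance = 1e-12)
  # direct re-evaluation oracle for the cross Gram
  for (i in 1:4) for (j in 1:4)
    expect_equal(des$J[i, j],
                 kernel_matrix(k, X[i, , drop = FALSE],
                               X[j, , drop = FALSE])[1, 1])
  # single observation: null-space row is (1, x1, y1) on the unit square
  one <- build_design(k, cbind(0.3, 0.8))
  expect_equal(as.numeric(one$T), c(1, 0.3, 0.8))
  expect_warning(build_design(k, X, rbind(X, X[1, ])), "duplicated")
})

test_that("solve_penalized handles degenerate responses and the smooth limit", {
  set.seed(9)
  X <- cbind(runif(25), runif(25))
  k <- tps_kernel(unit_dom)
  des <- build_design(k, X)
  # zero response -> zero solution
  s0 <- solve_penalized(des$J, des$T, des$P, rep(0, 25), lambda = 1)
  expect_equal(max(abs(s0$alpha)), 0, tolerance = 1e-12)
  expect_equal(max(abs(s0$beta)), 0, tolerance = 1e-12)
  expect_equal(s0$sigma2, 0, tolerance = 1e-12)
  # infinite smoothing leaves only the null space: OLS plane oracle
  z <- 1 + 2 * X[, 1] - 0.5 * X[, 2] + rnorm(25, sd = 0.1)
  s_inf <- solve_penalized(des$J, des$T, des$P, z, lambda = 1e12)
  ols <- lm(z ~ X[, 1] + X[, 2])
  pred_spline <- des$J %*% s_inf$alpha + des$T %*% s_inf$beta
  expect_lt(max(abs(pred_spline - fitted(ols))), 1e-4)
})

test_that("the non-degenerate solve reproduces the closed-form ridge expressions", {
  # a strictly positive definite kernel with empty null space reduces the
  # constrained solve to a = (J'J + lambda J)^{-1} J' z, cov = s2 * (...)^{-1}
  gauss <- structure(list(kind = "gauss", dim = 1L,
                          domain = as.matrix(c(0, 1)),
                          kmat = function(X1, X2)
                            exp(-outer(as.matrix(X1)[, 1],
                                       as.matrix(X2)[, 1], "-")^2 / 0.1),
                          nullspace = list()),
                     class = "ssa_kernel")
  set.seed(10)
  X <- matrix(sort(runif(5)), ncol = 1)
  z <- sin(3 * X[, 1]) + rnorm(5, sd = 0.1)
  des <- build_design(gauss, X)
  sol <- solve_penalized(des$J, des$T, des$P, z, lambda = 1)
  # independent dense linear algebra
  J <- des$J
  alpha_direct <- solve(crossprod(J) + 1 * J, crossprod(J, z))
  expect_equal(sol$alpha, as.numeric(alpha_direct), tolerance = 1e-8)
  H <- J %*% solve(crossprod(J) + J, t(J))
  edf_direct <- sum(diag(H))
  expect_equal(sol$edf, edf_direct, tolerance = 1e-8)
  rss <- sum((z - H %*% z)^2)
  s2 <- rss / (5 - edf_direct)
  cov_direct <- s2 * solve(crossprod(J) + J)
  expect_equal(sol$cov, cov_direct, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("GCV selection matches an exhaustive scan and shrinks pure noise", {
  set.seed(11)
  x <- sort(runif(50))
  z <- sin(2 * pi * x) + rnorm(50, sd = 0.3)
  k <- cubic_kernel(c(0, 1))
  des <- build_design(k, matrix(x, ncol = 1))
  lam <- suppressWarnings(
    select_lambda(des$J, des$T, des$P, z, criterion = "gcv"))
  # exhaustive 1000-point scan oracle
  grid <- 10^seq(-9, 5, length.out = 1000)
  sys <- splanova:::penalized_system(des$J, des$T, des$P, des$Tr, z)
  scores <- vapply(grid, function(l) {
    sol <- splanova:::solve_system(sys, l)
    splanova:::gcv_score(sys, sol)
  }, numeric(1))
  lam_scan <- grid[which.min(scores)]
  step <- log10(grid[2] / grid[1])
  expect_lt(abs(log10(as.numeric(lam)) - log10(lam_scan)), 2 * step)
  # minimizer property
  at <- function(l) {
    sol <- splanova:::solve_system(sys, l)
    splanova:::gcv_score(sys, sol)
  }
  expect_lte(at(as.numeric(lam)), at(as.numeric(lam) * 10))
  expect_lte(at(as.numeric(lam)), at(as.numeric(lam) / 10))
  # pure-noise response shrinks toward the null space
  set.seed(12)
  znoise <- rnorm(50)
  fitn <- fit_spline(tibble::tibble(x = x, z = znoise), x = "x", y = NULL,
                     z = "z", kernel = "cubic")
  expect_lte(fitn$edf, 2 + 2)
})

test_that("predictions interpolate at tiny lambda and carry valid variances", {
  set.seed(13)
  d <- tiny_data(20, seed = 13, noise_var = 0.01)
  fit <- fit_spline(d, kernel = "tps", domain = unit_dom, lambda = 1e-10)
  pr <- predict(fit, d)
  expect_lt(max(abs(pr$.fitted - d$z)), 1e-6)
  expect_true(all(pr$.se >= 0))
})

test_that("Monte-Carlo coefficient draws reproduce the analytic predictive sd", {
  d <- tiny_data(40, seed = 14)
  fit <- fit_spline(d, kernel = "tps", domain = unit_dom)
  pts <- cbind(c(0.2, 0.4, 0.55, 0.7, 0.9), c(0.8, 0.3, 0.5, 0.6, 0.2))
  pr <- predict(fit, pts)
  M <- splanova:::fit_rows(fit, pts)
  draws <- mvn_draws(2000, fit$coef, fit$cov, seed = 15)
  emp_sd <- apply(draws %*% t(M), 2, sd)
  expect_lt(max(abs(emp_sd / pr$.se - 1)), 0.05)
})

test_that("edf decreases in lambda and posterior covariance shrinks with n", {
  d <- tiny_data(120, seed = 16)
  X <- as.matrix(d[, c("x", "y")])
  k <- tps_kernel(unit_dom)
  des <- build_design(k, X)
  edfs <- vapply(10^seq(-6, 2, length.out = 9), function(l)
    solve_penalized(des$J, des$T, des$P, d$z, lambda = l)$edf, numeric(1))
  expect_true(all(diff(edfs) < 1e-8))
  # nested data, fixed lambda: covariance trace shrinks as n grows
  f1 <- fit_spline(d[1:40, ], kernel = "tps", domain = unit_dom,
                   lambda = 0.01)
  f2 <- fit_spline(d, kernel = "tps", domain = unit_dom, lambda = 0.01)
  # compare pointwise predictive variance on a common grid
  pts <- cbind(seq(0.1, 0.9, length.out = 9), seq(0.9, 0.1, length.out = 9))
  expect_lt(mean(predict(f2, pts)$.se^2), mean(predict(f1, pts)$.se^2))
})

test_that("tensor fits equal an independently assembled block system", {
  d <- tiny_data(50, seed = 17)
  X <- as.matrix(d[, c("x", "y")])
  theta <- c(x = 2, y = 0.5, xy = 4)
  tk <- tensor_kernel(cubic_kernel(c(0, 1)), cubic_kernel(c(0, 1)),
                      measures = leb2(32), theta = theta)
  fit <- fit_spline(d, kernel = tk, lambda = 0.03, knots = X)
  # assemble J and P from the blocks independently and solve
  J <- theta[["x"]] * tk$penal_block_kmat("x", X, X) +
    theta[["y"]] * tk$penal_block_kmat("y", X, X) +
    theta[["xy"]] * tk$penal_block_kmat("xy", X, X)
  T <- splanova:::nullspace_matrix(tk, X)
  sol <- solve_penalized(J, T, J, d$z, lambda = 0.03)
  expect_equal(fit$fitted, sol$fitted, tolerance = 1e-8)
})

test_that("observation validation catches structural problems", {
  d <- tiny_data(30, seed = 18)
  expect_error(fit_spline(d, z = "missing"), "column 'missing' not found")
  d_bad <- d; d_bad$z[3] <- NA
  expect_message(fit_spline(d_bad, kernel = "tps", lambda = 0.01),
                 "dropped 1 row")
  expect_error(fit_spline(d[1:3, ], kernel = "tps"), "at least 4")
})
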