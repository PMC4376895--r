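test_that("a constant surface decomposes into its offset alone", {
  d <- tibble::tibble(x = runif(20, 0, 1), y = runif(20, 0, 1), z = 3)
  fit <- fit_spline(d, kernel = "tps", domain = unit_dom, lambda = 1)
  dec <- posthoc_decompose(fit)
  expect_equal(dec$components$intercept$evaluate(NULL), 3,
               tolerance = 1e-6)
  xs <- seq(0, 1, length.out = 11)
  expect_lt(max(abs(dec$components$main_x$evaluate(xs))), 1e-6)
  expect_lt(max(abs(dec$components$main_y$evaluate(xs))), 1e-6)
  gi <- as.matrix(expand.grid(xs, xs))
  expect_lt(max(abs(dec$components$interaction$evaluate(gi))), 1e-6)
})

test_that("post-hoc decomposition of a tensor fit equals the block readout", {
  d <- tiny_data(80, seed = 19)
  cs <- suppressWarnings(classic_ssanova(d, domain = unit_dom))
  dec_blocks <- cs$decomposition
  dec_quad <- posthoc_decompose(cs$fit)
  g <- seq(0, 1, length.out = 21)
  gi <- as.matrix(expand.grid(g, g))
  expect_lt(abs(dec_blocks$components$intercept$evaluate(NULL) -
                dec_quad$components$intercept$evaluate(NULL)), 1e-6)
  expect_lt(max(abs(dec_blocks$components$main_x$evaluate(g) -
                    dec_quad$components$main_x$evaluate(g))), 1e-6)
  expect_lt(max(abs(dec_blocks$components$main_y$evaluate(g) -
                    dec_quad$components$main_y$evaluate(g))), 1e-6)
  expect_lt(max(abs(dec_blocks$components$interaction$evaluate(gi) -
                    dec_quad$components$interaction$evaluate(gi))), 1e-6)
})

test_that("component row matrices sum to the prediction rows", {
  d <- tiny_data(60, seed = 20)
  for (dec in list(
    posthoc_decompose(fit_spline(d, kernel = "tps", domain = unit_dom)),
    suppressWarnings(classic_ssanova(d, domain = unit_dom))$decomposition)) {
    gi <- as.matrix(expand.grid(seq(0, 1, 0.25), seq(0, 1, 0.25)))
    M <- dec$components$intercept$row_matrix(NULL)[rep(1, nrow(gi)), ] +
      dec$components$main_x$row_matrix(gi[, 1]) +
      dec$components$main_y$row_matrix(gi[, 2]) +
      dec$components$interaction$row_matrix(gi)
    carrier <- dec$carrier
    Mpred <- cbind(kernel_matrix(carrier$kernel, gi, carrier$sources),
                   splanova:::nullspace_matrix(carrier$kernel, gi))
    expect_lt(max(abs(M - Mpred)), 1e-10)
  }
})

test_that("distinct components are L2-orthogonal under the product measure", {
  d <- tiny_data(70, seed = 21)
  mus <- leb2(48)
  dec <- posthoc_decompose(fit_spline(d, kernel = "tps", domain = unit_dom),
                           measures = mus)
  labs <- c("intercept", "main_x", "main_y", "interaction")
  fns <- lapply(labs, comp_fun, dec = dec)
  for (i in 1:3) for (j in (i + 1):4) {
    ip <- component_inner(fns[[i]], fns[[j]], mus$x, mus$y)
    expect_lt(abs(ip), 1e-6)
  }
})

test_that("decomposing a component again returns its own subspace pattern", {
  d <- tiny_data(70, seed = 22)
  mus <- leb2(48)
  dec <- posthoc_decompose(fit_spline(d, kernel = "tps", domain = unit_dom),
                           measures = mus)
  # main_x: a function of x alone with zero mean
  fx <- comp_fun(dec, "main_x")
  expect_lt(abs(average_function(fx, "AxAy", mus)()), 1e-8)
  ayfx <- average_function(fx, "Ay", mus) # unchanged: no y dependence
  xs <- seq(0.1, 0.9, length.out = 7)
  expect_lt(max(abs(ayfx(xs) - fx(xs, 0))), 1e-10)
  # its interaction projection vanishes
  axfx <- average_function(fx, "Ax", mus)
  proj_int <- fx(xs, 0.3) - ayfx(xs) - axfx(0.3) +
    average_function(fx, "AxAy", mus)()
  expect_lt(max(abs(proj_int)), 1e-8)
})

test_that("component variances obey the sum rule and vanish with zero covariance", {
  d <- tiny_data(50, seed = 23)
  fit <- fit_spline(d, kernel = "tps", domain = unit_dom)
  dec <- posthoc_decompose(fit)
  gi <- as.matrix(expand.grid(seq(0.2, 0.8, 0.3), seq(0.2, 0.8, 0.3)))
  # same linear functional => same variance: sum the component rows and
  # compare with the prediction variance
  M <- dec$components$intercept$row_matrix(NULL)[rep(1, nrow(gi)), ] +
    dec$components$main_x$row_matrix(gi[, 1]) +
    dec$components$main_y$row_matrix(gi[, 2]) +
    dec$components$interaction$row_matrix(gi)
  v_sum <- rowSums((M %*% fit$cov) * M)
  v_pred <- predict(fit, gi)$.se^2
  expect_equal(v_sum, v_pred, tolerance = 1e-10)
  # zero covariance -> zero variance
  fit0 <- fit
  fit0$cov[] <- 0
  dec0 <- posthoc_decompose(fit0)
  expect_equal(component_variance(dec0, "main_x", c(0.2, 0.5, 0.8)),
               c(0, 0, 0))
  expect_error(component_variance(dec, "bogus"), "unknown component")
})

test_that("Monte-Carlo draws validate the averaged-kernel variance formula", {
  d <- tiny_data(50, seed = 24)
  fit <- fit_spline(d, kernel = "tps", domain = unit_dom)
  dec <- posthoc_decompose(fit)
  draws <- mvn_draws(2000, fit$coef, fit$cov, seed = 25)
  # intercept: var(c) = R0 Sigma R0'
  R0 <- dec$components$intercept$row_matrix(NULL)
  emp <- var(as.numeric(draws %*% t(R0)))
  expect_lt(abs(emp / component_variance(dec, "intercept") - 1), 0.05)
  # a main-effect point
  Mx <- dec$components$main_x$row_matrix(0.35)
  empx <- var(as.numeric(draws %*% t(Mx)))
  expect_lt(abs(empx / component_variance(dec, "main_x", 0.35) - 1), 0.05)
})

test_that("classic SS-ANOVA suppresses spurious interaction and centres mains", {
  set.seed(26)
  n <- 200
  d <- tibble::tibble(x = runif(n), y = runif(n))
  d$z <- 2 * (d$x - 0.5)^2 + rnorm(n, sd = 0.1) # pure x main effect
  cs <- suppressWarnings(classic_ssanova(d, domain = unit_dom))
  g <- seq(0, 1, length.out = 41)
  gi <- as.matrix(expand.grid(g, g))
  e_main <- mean(cs$decomposition$components$main_x$evaluate(g)^2)
  e_int <- mean(cs$decomposition$components$interaction$evaluate(gi)^2)
  expect_lt(e_int, 0.1 * e_main)
  # fitted main effects integrate to zero under the centering measure
  mu <- cs$decomposition$measures$x
  fx_nodes <- cs$decomposition$components$main_x$evaluate(mu$nodes)
  expect_lt(abs(sum(mu$weights * fx_nodes)), 1e-6)
})

test_that("significance masks use |mean| >= k * sd with the boundary included", {
  fake <- structure(list(components = list(
    flat = list(evaluate = function(p) c(0, 0, 0),
                variance = function(p) c(1, 4, 9)),
    strong = list(evaluate = function(p) c(5, -7),
                  variance = function(p) c(0, 0)),
    edge = list(evaluate = function(p) c(2, 1.999, -2),
                variance = function(p) c(1, 1, 1)))),
    class = "ssa_decomposition")
  expect_equal(significance_mask(fake, "flat", 1:3), c(FALSE, FALSE, FALSE))
  expect_equal(significance_mask(fake, "strong", 1:2), c(TRUE, TRUE))
  # exact 2-sd point counts as significant; just below does not
  expect_equal(significance_mask(fake, "edge", 1:3), c(TRUE, FALSE, TRUE))
  expect_error(significance_mask(fake, "none"), "unknown component")
})

test_that("dimension guards route users to the right decomposition entry point", {
  d <- tibble::tibble(x = runif(30), z = rnorm(30))
  fit1 <- fit_spline(d, x = "x", y = NULL, z = "z", kernel = "cubic",
                     lambda = 0.1)
  expect_error(posthoc_decompose(fit1), "bivariate")
})

test_that("tidy and autoplot produce the documented component layout", {
  d <- tiny_data(50, seed = 27)
  dec <- posthoc_decompose(fit_spline(d, kernel = "tps", domain = unit_dom))
  td <- tidy(dec, n_main = 11, n_inter = 5)
  expect_named(td, c("component", "x", "y", "estimate", "std_error",
                     "significant"))
  expect_equal(nrow(td), 1 + 11 + 11 + 25)
  expect_true(all(is.na(td$x[td$component == "intercept"])))
  expect_true(all(is.na(td$y[td$component == "main_x"])))
  p <- autoplot(dec, n_main = 11, n_inter = 5)
  expect_s3_class(p, "ggplot")
})
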