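test_that("a single-term AMM without random factors reduces to the fitting module", {
  set.seed(30)
  d <- tibble::tibble(x = runif(80))
  d$z <- sin(2 * pi * d$x) + rnorm(80, sd = 0.2)
  kn <- matrix(unique(stats::quantile(d$x, seq(0, 1, length.out = 10),
                                      names = FALSE)), ncol = 1)
  dom <- splanova:::as_domain(splanova:::padded_range(d$x), 1)
  fs <- fit_spline(d, x = "x", y = NULL, z = "z", kernel = "cubic",
                   lambda = 0.01, knots = kn, domain = dom)
  fa <- fit_amm(d, "z", list(sm("x", k = 10)), lambda = 0.01)
  expect_lt(max(abs(predict(fs, d, se_fit = FALSE)$.fitted - fa$fitted)),
            1e-8)
})

test_that("a zero-variance grouping factor shrinks out of the model", {
  set.seed(31)
  n <- 400
  d <- tibble::tibble(x = runif(n),
                      g = factor(rep(1:20, each = 20)))
  d$z <- sin(2 * pi * d$x) + rnorm(n, sd = 0.2) # no group effect at all
  fit <- fit_amm(d, "z", list(sm("x")), randoms = "g")
  # the estimated variance component is a negligible share of the
  # residual variance (REML keeps a small positive finite-sample floor)
  expect_lt(fit$sigma_factors$g^2, 0.01 * fit$sigma2)
})

test_that("synthetic reading data are reproducible with the stated variance structure", {
  d1 <- synth_reading_data(n_obs = 500, seed = 11)
  d2 <- synth_reading_data(n_obs = 500, seed = 11)
  expect_identical(d1, d2)
  expect_false(identical(d1$tau,
                         synth_reading_data(n_obs = 500, seed = 12)$tau))
  # variance decomposition at n = 1e4: var(tau - effects) ~ sum of parts
  sid <- 0.2; sw <- 0.1; se <- 0.3
  d <- synth_reading_data(n_obs = 10000, sigma_id = sid, sigma_w = sw,
                          sigma_eps = se, seed = 13)
  eff <- splanova:::default_reading_effects()
  signal <- 5.3 + eff$A(d$A) + eff$l_prev(d$l_prev) + eff$l_n(d$l_n) +
    eff$l_next(d$l_next) + eff$pair_prev(d$nu_prev, d$nu_n) +
    eff$pair_next(d$nu_n, d$nu_next)
  resid <- d$tau - signal
  total <- sid^2 + sw^2 + se^2
  mc_tol <- 3 * total * sqrt(2 / 9999) + 0.01 # finite draws of r_id, r_w
  expect_lt(abs(var(resid) - total), mc_tol + 0.02)
  # grouping is real: fixations by the same reader are correlated
  rm <- tapply(resid, d$reader, mean)
  icc <- var(rm[as.character(d$reader)]) / var(resid)
  expect_gt(icc, 0.05)
})

test_that("pair decomposition is complete, additive-faithful and variance-consistent", {
  # generator with purely additive frequency effects: no interaction bumps
  addeff <- list(
    pair_prev = function(v1, v2) -0.08 * (v1 - 1.5) + 0.05 * sin(2 * pi * v2 / 3),
    pair_next = function(v2, v3) 0.05 * sin(2 * pi * v2 / 3) - 0.03 * (v3 - 1.5))
  d <- synth_reading_data(n_obs = 2500, effects = addeff, seed = 17)
  fit <- fit_amm(d, "tau", reading_model_terms("tps"),
                 randoms = c("reader", "word"), sweeps = 1)
  dec <- decompose_pair(fit, "pair_prev")
  g <- seq(0.3, 2.7, length.out = 11)
  gi <- as.matrix(expand.grid(g, g))
  # completeness: components reassemble the term's partial effect
  total <- dec$components$intercept$evaluate(NULL) +
    dec$components$main_x$evaluate(gi[, 1]) +
    dec$components$main_y$evaluate(gi[, 2]) +
    dec$components$interaction$evaluate(gi)
  expect_lt(max(abs(total - term_effect(fit, "pair_prev", gi)$estimate)),
            1e-6)
  # additive truth: interaction energy is a small fraction of main energy
  e_main <- mean(dec$components$main_x$evaluate(g)^2) +
    mean(dec$components$main_y$evaluate(g)^2)
  e_int <- mean(dec$components$interaction$evaluate(gi)^2)
  expect_lt(e_int, 0.1 * e_main)
  # zero covariance block -> zero component variances
  fit0 <- fit
  fit0$cov[] <- 0
  dec0 <- decompose_pair(fit0, "pair_prev")
  expect_equal(max(component_variance(dec0, "interaction", gi)), 0)
  expect_error(decompose_pair(fit, "cubic(A)"), "thin-plate")
})

test_that("BLUPs of ridge-penalized intercept blocks average to about zero", {
  d <- synth_reading_data(n_obs = 2000, seed = 19)
  fit <- fit_amm(d, "tau", list(sm("A"), sm("l_n")),
                 randoms = c("reader", "word"), sweeps = 1)
  for (f in c("reader", "word")) {
    idx <- fit$blocks[[paste0("random:", f)]]$idx
    blups <- fit$coef[idx]
    expect_lt(abs(mean(blups)), 3 * sd(blups) / sqrt(length(blups)) + 0.01)
  }
})

test_that("TPS-pair and explicit-tensor models agree on partial main effects as n grows", {
  msd <- function(n) {
    d <- synth_reading_data(n_obs = n, seed = 23)
    f4 <- fit_amm(d, "tau", reading_model_terms("tps"),
                  randoms = c("reader", "word"), sweeps = 1)
    f5 <- fit_amm(d, "tau", reading_model_terms("tensor"),
                  randoms = c("reader", "word"), sweeps = 1)
    g <- seq(0.3, 2.7, length.out = 21)
    # nu_prev main effect: post-hoc component of the pair vs explicit term
    m4 <- decompose_pair(f4, "pair_prev")$components$main_x$evaluate(g)
    m5 <- term_effect(f5, "cubic(nu_prev)", matrix(g, ncol = 1))$estimate
    m5 <- m5 - mean(m5)
    sqrt(mean((m4 - (m5 - mean(m5 - m4) * 0))^2))
  }
  r_small <- msd(700)
  r_large <- msd(3500)
  expect_lt(r_large, 0.05)
  expect_lt(r_large, r_small + 0.01)
})

test_that("subset resampling honours its contracts", {
  d <- synth_reading_data(n_obs = 700, seed = 29)
  st <- subset_study(d, subset_size = 250, reps = 2, seed = 1,
                     methods = "tps", grid_n = 6, k_pair = 20)
  expect_s3_class(st, "ssa_subset_study")
  expect_equal(st$summary$n_fits, c(2, 2))
  # subsets drawn without replacement: a full-size subset is the whole
  # dataset, so every replicate fit is identical and the trace is zero
  st_full <- subset_study(d, subset_size = nrow(d), reps = 2, seed = 1,
                          methods = "tps", grid_n = 5, k_pair = 20)
  expect_lt(max(st_full$summary$trace), 1e-20)
  expect_error(subset_study(d, subset_size = 1e6), "exceeds")
})
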