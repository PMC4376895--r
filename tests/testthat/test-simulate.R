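test_that("test surfaces evaluate to their closed-form values", {
  # example 1 at the centre: 0 + sin(pi) + sin(pi) cos(pi) = 0
  expect_equal(true_function(1, 0.5, 0.5), 0, tolerance = 1e-14)
  # unit periodicity of the oscillatory terms
  x <- c(0.123, 0.77); y <- c(0.31, 0.9)
  expect_equal(true_function(1, x, y) - 2 * (x - 0.5),
               true_function(1, x, y + 1) - 2 * (x - 0.5),
               tolerance = 1e-12)
  # example 2 at the centre: 0 + 0 + exp(0) = 1
  expect_equal(true_function(2, 0.5, 0.5), 1, tolerance = 1e-14)
  expect_error(true_function(3, 0, 0), "unknown example")
})

test_that("the analytic decomposition of example 1 is exact", {
  td <- true_decomposition(1)
  xs <- seq(0, 1, length.out = 33)
  gi <- expand.grid(x = xs, y = xs)
  # components integrate to zero; interaction has zero marginals
  mu <- leb(128)
  expect_lt(abs(sum(mu$weights * td$main_x(mu$nodes))), 1e-12)
  expect_lt(abs(sum(mu$weights * td$main_y(mu$nodes))), 1e-12)
  for (x0 in c(0.2, 0.7))
    expect_lt(abs(sum(mu$weights * td$interaction(x0, mu$nodes))), 1e-12)
  # sum reassembles the surface
  total <- td$intercept + td$main_x(gi$x) + td$main_y(gi$y) +
    td$interaction(gi$x, gi$y)
  expect_lt(max(abs(total - true_function(1, gi$x, gi$y))), 1e-12)
  # the quadrature route agrees with the closed form
  tq <- true_decomposition(1, order = 96, method = "quadrature")
  expect_lt(max(abs(tq$main_x(xs) - td$main_x(xs))), 1e-9)
})

test_that("example-2 components converge under quadrature refinement", {
  t64 <- true_decomposition(2, order = 64)
  t128 <- true_decomposition(2, order = 128)
  xs <- seq(0, 1, length.out = 21)
  expect_lt(abs(t64$intercept - t128$intercept), 1e-9)
  expect_lt(max(abs(t64$main_x(xs) - t128$main_x(xs))), 1e-9)
  gi <- expand.grid(x = xs, y = xs)
  expect_lt(max(abs(t64$interaction(gi$x, gi$y) -
                    t128$interaction(gi$x, gi$y))), 1e-9)
})

test_that("replicate datasets are reproducible, bounded and correctly noisy", {
  d1 <- sim_dataset(1, n = 50, seed = 33, rep_index = 4)
  d2 <- sim_dataset(1, n = 50, seed = 33, rep_index = 4)
  expect_identical(d1, d2)
  d3 <- sim_dataset(1, n = 50, seed = 33, rep_index = 5)
  expect_false(identical(d1$z, d3$z))
  expect_true(all(d1$x >= 0 & d1$x <= 1 & d1$y >= 0 & d1$y <= 1))
  # pooled noise variance across 100 replicates of n = 300
  eps <- unlist(lapply(1:100, function(r) {
    d <- sim_dataset(1, n = 300, seed = 7, rep_index = r)
    d$z - true_function(1, d$x, d$y)
  }))
  v <- var(eps)
  mc_sd <- 0.25 * sqrt(2 / (length(eps) - 1))
  expect_lt(abs(v - 0.25), 3 * mc_sd)
})

test_that("run_study returns per-replicate grids for each method", {
  sp <- study_spec(1, n = 30, reps = 2, seed = 3)
  st <- suppressWarnings(run_study(sp))
  expect_s3_class(st, "ssa_study")
  for (m in c("tensor", "posthoc")) {
    expect_equal(dim(st$results[[m]]$main_x), c(2, 101))
    expect_equal(dim(st$results[[m]]$interaction), c(2, 21^2))
    # noise was actually drawn: replicates differ
    expect_false(identical(st$results[[m]]$main_x[1, ],
                           st$results[[m]]$main_x[2, ]))
  }
})

test_that("both methods recover the surface in the noiseless limit", {
  sp <- study_spec(1, n = 300, noise_var = 1e-12, reps = 1, seed = 5)
  st <- suppressWarnings(run_study(sp))
  truth <- true_decomposition(1)$main_x(st$grids$main_x)
  interior <- st$grids$main_x >= 0.05 & st$grids$main_x <= 0.95
  for (m in c("tensor", "posthoc")) {
    err <- abs(st$results[[m]]$main_x[1, ] - truth)
    # away from the boundary the surface is recovered tightly; the domain
    # edges keep a small extrapolation error (no data beyond them)
    expect_lt(max(err[interior]), 0.02)
    expect_lt(max(err), 0.05)
  }
})

test_that("trace_variability matches hand linear algebra", {
  # two replicates with printed grid values
  v1 <- c(1, 2, 4); v2 <- c(2, 0, 1)
  fake <- structure(list(
    spec = study_spec(1, n = 30, reps = 2, seed = 1),
    methods = "posthoc",
    grids = list(main_x = c(0.25, 0.5, 0.75)),
    results = list(posthoc = list(main_x = rbind(v1, v2)))),
    class = "ssa_study")
  # trace = sum_g (v1g - v2g)^2 / 2 for two replicates
  want <- sum((v1 - v2)^2) / 2
  got <- trace_variability(fake, "posthoc", "main_x")
  expect_equal(as.numeric(got), want)
  expect_equal(attr(got, "per_point"), want / 3)
  # scaling: doubling the values quadruples the trace
  fake2 <- fake
  fake2$results$posthoc$main_x <- 2 * fake$results$posthoc$main_x
  expect_equal(as.numeric(trace_variability(fake2, "posthoc", "main_x")),
               4 * want)
  # identical replicates have zero variability
  fake3 <- fake
  fake3$results$posthoc$main_x <- rbind(v1, v1)
  expect_equal(as.numeric(trace_variability(fake3, "posthoc", "main_x")), 0)
  expect_error(trace_variability(fake, "tensor", "main_x"), "not in study")
})

test_that("mean_squared_bias follows its closed forms", {
  truth <- true_decomposition(1)$main_x(seq(0, 1, length.out = 101))
  fake <- structure(list(
    spec = study_spec(1, n = 30, reps = 2, seed = 1),
    methods = "posthoc",
    grids = list(main_x = seq(0, 1, length.out = 101)),
    results = list(posthoc = list(main_x = rbind(truth, truth)))),
    class = "ssa_study")
  expect_equal(mean_squared_bias(fake, "posthoc", "main_x"), 0)
  # constant offset delta in every replicate gives delta^2
  fake$results$posthoc$main_x <- rbind(truth + 0.3, truth + 0.3)
  expect_equal(mean_squared_bias(fake, "posthoc", "main_x"), 0.09,
               tolerance = 1e-12)
  expect_error(mean_squared_bias(fake, "posthoc", "main_x", truth = 1:5),
               "wrong length")
})

test_that("the metric table is complete and round-trips through CSV", {
  sp <- study_spec(1, n = 30, reps = 3, seed = 9)
  st <- suppressWarnings(run_study(sp))
  mt <- metrics_table(st)
  expect_equal(nrow(mt), 6) # 3 components x 2 methods
  expect_named(mt, c("method", "component", "trace", "trace_per_point",
                     "msb"))
  # values equal the individual operation outputs
  expect_equal(mt$msb[mt$method == "tensor" & mt$component == "main_x"],
               mean_squared_bias(st, "tensor", "main_x"))
  expect_equal(mt$trace[mt$method == "posthoc" &
                          mt$component == "interaction"],
               as.numeric(trace_variability(st, "posthoc", "interaction")))
  path <- tempfile(fileext = ".csv")
  readr::write_csv(mt, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  # CSV carries 15 significant digits
  expect_equal(as.data.frame(back), as.data.frame(mt), tolerance = 1e-12)
})

test_that("study specifications validate their fields", {
  expect_error(study_spec(1, n = 5), "at least 10")
  expect_error(study_spec(1, noise_var = 0), "positive")
  expect_error(study_spec(5), "unknown example")
})
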