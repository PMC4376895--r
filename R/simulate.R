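# Replicated simulation study comparing the tensor-product SS-ANOVA with
# the post-hoc decomposition of a thin-plate spline on two closed-form test
# surfaces sampled with Gaussian noise on the unit square.

#' Closed-form test surfaces of the simulation study
#'
#' Example 1, `2(x - 1/2) + sin(2 pi y) + sin(2 pi x) cos(2 pi y)`, has
#' *almost* isotropic smoothness: its interaction is a product of
#' full-period waves, but the linear-plus-sine structure makes the x and y
#' directions genuinely different. Example 2,
#' `2(x - 1/2) + 2(1/2 - y) + exp(-((x - 1/2)^2 + (y - 1/2)^2) / 0.08)`,
#' is isotropic by construction (a radial Gaussian bump over a plane).
#'
#' @param example 1 or 2 (also accepts `"example1"`, `"example2"`).
#' @param x,y Numeric vectors.
#' @return Numeric vector of surface values.
#' @export
true_function <- function(example, x, y) {
  ex <- normalize_example(example)
  if (ex == 1L)
    2 * (x - 0.5) + sin(2 * pi * y) + sin(2 * pi * x) * cos(2 * pi * y)
  else
    2 * (x - 0.5) + 2 * (0.5 - y) +
      exp(-((x - 0.5)^2 + (y - 0.5)^2) / 0.08)
}

normalize_example <- function(example) {
  if (is.character(example))
    example <- match(match.arg(example, c("example1", "example2")),
                     c("example1", "example2"))
  example <- as.integer(example)
  if (!example %in% c(1L, 2L)) stop("unknown example id.", call. = FALSE)
  example
}

#' Analytic/quadrature ANOVA decomposition of a test surface
#'
#' Under Lebesgue measures on the unit square, example 1 decomposes in
#' closed form (all full-period sine/cosine means vanish):
#' `c = 0`, `f_x = 2(x - 1/2)`, `f_y = sin(2 pi y)`,
#' `f_xy = sin(2 pi x) cos(2 pi y)`. Example 2's components involve the
#' marginal integrals of the Gaussian bump and are computed by
#' high-order Gauss--Legendre quadrature of the averaging operators.
#'
#' @inheritParams true_function
#' @param order Quadrature order for the numerical route.
#' @param method `"auto"` uses the closed form for example 1; force
#'   `"quadrature"` to apply the averaging operators numerically.
#' @return A list with `intercept` (scalar) and vectorized functions
#'   `main_x(x)`, `main_y(y)`, `interaction(x, y)`.
#' @export
true_decomposition <- function(example, order = 128,
                               method = c("auto", "quadrature")) {
  ex <- normalize_example(example)
  method <- match.arg(method)
  if (ex == 1L && method == "auto") {
    return(list(intercept = 0,
                main_x = function(x) 2 * (x - 0.5),
                main_y = function(y) sin(2 * pi * y),
                interaction = function(x, y)
                  sin(2 * pi * x) * cos(2 * pi * y)))
  }
  f <- function(x, y) true_function(ex, x, y)
  mus <- list(x = quad_measure("lebesgue", c(0, 1), order = order),
              y = quad_measure("lebesgue", c(0, 1), order = order))
  ayf <- average_function(f, "Ay", mus)
  axf <- average_function(f, "Ax", mus)
  c0 <- average_function(f, "AxAy", mus)()
  list(intercept = c0,
       main_x = function(x) ayf(x) - c0,
       main_y = function(y) axf(y) - c0,
       interaction = function(x, y) f(x, y) - ayf(x) - axf(y) + c0)
}

# evaluate a true component on points
true_component <- function(example, component, points, order = 128) {
  td <- true_decomposition(example, order = order)
  switch(component,
    intercept = td$intercept,
    main_x = td$main_x(as.numeric(points)),
    main_y = td$main_y(as.numeric(points)),
    interaction = {
      P <- as.matrix(points)
      td$interaction(P[, 1], P[, 2])
    },
    stop("unknown component label: ", component, call. = FALSE))
}

#' Define a replicated simulation study
#'
#' @param example Test surface id (1 or 2).
#' @param n Sample size per replicate (>= 10).
#' @param noise_var Observation noise variance (default 1/4, i.e. sd 0.5).
#' @param reps Number of independent replicates (default 100).
#' @param seed Base seed; per-replicate streams are derived from it by a
#'   counter scheme so replicates are independent and reproducible.
#' @param grid_main,grid_inter Metric-grid resolutions (per axis).
#' @return A list of class `ssa_study_spec`.
#' @export
study_spec <- function(example = 1, n = 30, noise_var = 1 / 4, reps = 100,
                       seed = 1, grid_main = 101, grid_inter = 21) {
  example <- normalize_example(example)
  if (n < 10) stop("`n` must be at least 10.", call. = FALSE)
  if (noise_var <= 0) stop("`noise_var` must be positive.", call. = FALSE)
  if (reps < 1) stop("`reps` must be positive.", call. = FALSE)
  structure(list(example = example, n = as.integer(n),
                 noise_var = noise_var, reps = as.integer(reps),
                 seed = as.integer(seed), grid_main = as.integer(grid_main),
                 grid_inter = as.integer(grid_inter)),
            class = "ssa_study_spec")
}

# counter-based per-replicate seed, kept inside 32-bit integer range
rep_seed <- function(seed, rep_index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + rep_index * 1664525
  as.integer(s %% 2147483646) + 1L
}

#' Draw one replicate dataset of a simulation study
#'
#' Covariates are iid Uniform on the unit square and the response is the
#' test surface plus iid Gaussian noise. The random stream is derived from
#' `(seed, rep_index)`, so any replicate can be regenerated independently.
#'
#' @param example Test surface id, or an [study_spec()] (whose `n`,
#'   `noise_var` and `seed` then apply).
#' @param n,noise_var,seed See [study_spec()].
#' @param rep_index Replicate counter (1-based).
#' @return A tibble with columns `x`, `y`, `z`.
#' @export
sim_dataset <- function(example = 1, n = 30, noise_var = 1 / 4, seed = 1,
                        rep_index = 1) {
  if (inherits(example, "ssa_study_spec")) {
    spec <- example
    example <- spec$example; n <- spec$n
    noise_var <- spec$noise_var; seed <- spec$seed
  }
  ex <- normalize_example(example)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rep_seed(seed, rep_index))
  x <- stats::runif(n); y <- stats::runif(n)
  z <- true_function(ex, x, y) + stats::rnorm(n, sd = sqrt(noise_var))
  tibble::tibble(x = x, y = y, z = z)
}

unit_domain <- cbind(c(0, 1), c(0, 1))

#' Run a replicated decomposition study
#'
#' For every replicate the requested methods are applied: `"tensor"` fits
#' the classic tensor-product SS-ANOVA ([classic_ssanova()]) and reads the
#' components off its blocks; `"posthoc"` fits a single bivariate
#' thin-plate spline and decomposes it with the Lebesgue averaging
#' operators ([posthoc_decompose()]). Components are evaluated on fixed
#' metric grids (main effects on `grid_main` points per axis, the
#' interaction on a `grid_inter` x `grid_inter` lattice). Replicates whose
#' fit fails are recorded and excluded; more than 5% failures abort the
#' study.
#'
#' @param spec An [study_spec()].
#' @param methods Subset of `c("tensor", "posthoc")`.
#' @param theta_grid Passed to [classic_ssanova()].
#' @param quad_order Quadrature order of the decomposition measures.
#' @return An object of class `ssa_study`.
#' @export
run_study <- function(spec, methods = c("tensor", "posthoc"),
                      theta_grid = c(0.1, 1, 10), quad_order = 32) {
  stopifnot(inherits(spec, "ssa_study_spec"))
  methods <- match.arg(methods, several.ok = TRUE)
  xs <- seq(0, 1, length.out = spec$grid_main)
  ys <- xs
  gi <- seq(0, 1, length.out = spec$grid_inter)
  inter <- as.matrix(expand.grid(x = gi, y = gi))
  measures <- default_measures(unit_domain, quad_order)

  empty <- function() list(
    intercept = rep(NA_real_, spec$reps),
    main_x = matrix(NA_real_, spec$reps, length(xs)),
    main_y = matrix(NA_real_, spec$reps, length(ys)),
    interaction = matrix(NA_real_, spec$reps, nrow(inter)))
  results <- stats::setNames(lapply(methods, function(m) empty()), methods)
  failures <- list()

  for (r in seq_len(spec$reps)) {
    dat <- sim_dataset(spec, rep_index = r)
    for (m in methods) {
      dec <- tryCatch({
        if (m == "tensor") {
          classic_ssanova(dat, domain = unit_domain, measures = measures,
                          theta_grid = theta_grid)$decomposition
        } else {
          fit <- fit_spline(dat, kernel = "tps", domain = unit_domain)
          posthoc_decompose(fit, measures = measures)
        }
      }, error = function(e) e)
      if (inherits(dec, "error")) {
        failures <- c(failures, list(list(rep = r, method = m,
                                          message = conditionMessage(dec))))
        next
      }
      results[[m]]$intercept[r] <- dec$components$intercept$evaluate(NULL)
      results[[m]]$main_x[r, ] <- dec$components$main_x$evaluate(xs)
      results[[m]]$main_y[r, ] <- dec$components$main_y$evaluate(ys)
      results[[m]]$interaction[r, ] <-
        dec$components$interaction$evaluate(inter)
    }
  }
  n_fail <- length(failures)
  if (n_fail > 0.05 * spec$reps * length(methods))
    stop(sprintf("study failed: %d of %d replicate fits errored",
                 n_fail, spec$reps * length(methods)), call. = FALSE)
  structure(list(spec = spec, methods = methods,
                 grids = list(main_x = xs, main_y = ys, interaction = inter),
                 results = results, failures = failures),
            class = "ssa_study")
}

#' @export
print.ssa_study <- function(x, ...) {
  cat(sprintf("<ssa_study: example %d, n = %d, %d reps, methods: %s>\n",
              x$spec$example, x$spec$n, x$spec$reps,
              paste(x$methods, collapse = ", ")))
  if (length(x$failures) > 0)
    cat(sprintf("  %d replicate fit(s) failed and were excluded\n",
                length(x$failures)))
  invisible(x)
}

study_values <- function(study, method, component) {
  res <- study$results[[method]]
  if (is.null(res)) stop("method not in study: ", method, call. = FALSE)
  V <- res[[component]]
  if (is.null(V)) stop("unknown component: ", component, call. = FALSE)
  if (component == "intercept") V <- matrix(V, ncol = 1)
  V[stats::complete.cases(V), , drop = FALSE]
}

#' Across-replicate variability of a component estimator
#'
#' The trace of the empirical covariance matrix of the component's grid
#' values across replicates, i.e. the sum over grid points of the
#' across-replicate variance. The per-grid-point average is attached as
#' attribute `"per_point"` to decouple the summary from grid resolution.
#'
#' @param study An [run_study()] result.
#' @param method `"tensor"` or `"posthoc"`.
#' @param component Component label.
#' @return Scalar trace (with attribute `per_point`).
#' @export
trace_variability <- function(study, method, component) {
  V <- study_values(study, method, component)
  if (nrow(V) < 2) stop("need at least 2 replicates.", call. = FALSE)
  v <- apply(V, 2, stats::var)
  out <- sum(v)
  attr(out, "per_point") <- mean(v)
  out
}

#' Grid-averaged squared bias of a component estimator
#'
#' The squared difference between the across-replicate mean estimate and
#' the true component, averaged over the metric grid.
#'
#' @inheritParams trace_variability
#' @param truth Optional numeric vector of true component values on the
#'   study's grid; defaults to the study surface's decomposition.
#' @return Scalar mean squared bias.
#' @export
mean_squared_bias <- function(study, method, component, truth = NULL) {
  V <- study_values(study, method, component)
  if (is.null(truth)) {
    truth <- true_component(study$spec$example, component,
                            study$grids[[component]] %||% NULL)
  }
  if (length(truth) != ncol(V))
    stop("truth has wrong length for the study grid.", call. = FALSE)
  mean((colMeans(V) - truth)^2)
}

#' Summary metric table of a study
#'
#' Assembles the across-replicate variability trace (raw and per grid
#' point) and the mean squared bias of every component for every method.
#'
#' @inheritParams trace_variability
#' @return A tibble with one row per (method, component).
#' @export
metrics_table <- function(study) {
  purrr::map_dfr(study$methods, function(m) {
    purrr::map_dfr(c("main_x", "main_y", "interaction"), function(cp) {
      tr <- trace_variability(study, m, cp)
      tibble::tibble(method = m, component = cp,
                     trace = as.numeric(tr),
                     trace_per_point = attr(tr, "per_point"),
                     msb = mean_squared_bias(study, m, cp))
    })
  })
}
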