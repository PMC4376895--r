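# Functional ANOVA decomposition of fitted splines.
#
# Any fitted bivariate spline f = sum_i alpha_i K(., .; s_i) + sum_k beta_k
# phi_k decomposes uniquely, given probability measures on the two axes,
# into f = c + f_x + f_y + f_xy with zero-mean main effects and
# zero-marginal interaction. Each component is a *linear* functional of the
# coefficients, with row matrices assembled from averaged kernels and
# averaged null-space functions; pointwise posterior variances follow as
# M Sigma M' from the fit's joint coefficient covariance.

component_labels <- c("intercept", "main_x", "main_y", "interaction")

# internal coefficient carrier: everything a decomposition needs of a fit
make_carrier <- function(kernel, sources, nsfuns, coef, cov, domain) {
  list(kernel = kernel, sources = as.matrix(sources), nsfuns = nsfuns,
       coef = coef, cov = cov, domain = domain)
}

carrier_from_fit <- function(fit) {
  make_carrier(fit$kernel, fit$representers, fit$kernel$nullspace,
               fit$coef, fit$cov, fit$kernel$domain)
}

# a component: cached row-matrix builder plus mean/variance evaluators
new_component <- function(label, builder, carrier) {
  cache <- new.env(parent = emptyenv())
  row_matrix <- function(points) {
    if (!is.null(cache$points) && identical(cache$points, points))
      return(cache$M)
    M <- builder(points)
    cache$points <- points
    cache$M <- M
    M
  }
  list(label = label,
       row_matrix = row_matrix,
       evaluate = function(points)
         as.numeric(row_matrix(points) %*% carrier$coef),
       variance = function(points) {
         M <- row_matrix(points)
         unname(pmax(rowSums((M %*% carrier$cov) * M), 0))
       })
}

# generic quadrature route: averaged kernels + averaged null-space functions
posthoc_components <- function(carrier, measures) {
  kern <- carrier$kernel; S <- carrier$sources; nsf <- carrier$nsfuns
  mx <- measures$x; my <- measures$y
  m0 <- NULL
  row0 <- function() {
    if (is.null(m0))
      m0 <<- cbind(avg_rows_AxAy(kern, S, mx, my), ns_rows_AxAy(nsf, mx, my))
    m0
  }
  build <- list(
    intercept = function(points) row0(),
    main_x = function(xs) {
      xs <- as.numeric(xs)
      M <- cbind(avg_rows_Ay(kern, xs, S, my), ns_rows_Ay(nsf, xs, my))
      sweep(M, 2, as.numeric(row0()), "-")
    },
    main_y = function(ys) {
      ys <- as.numeric(ys)
      M <- cbind(avg_rows_Ax(kern, ys, S, mx), ns_rows_Ax(nsf, ys, mx))
      sweep(M, 2, as.numeric(row0()), "-")
    },
    interaction = function(points) {
      P <- as.matrix(points)
      K <- cbind(kernel_matrix(kern, P, S),
                 if (length(nsf) > 0)
                   do.call(cbind, lapply(nsf, function(f) f(P)))
                 else matrix(0, nrow(P), 0))
      ay <- cbind(avg_rows_Ay(kern, P[, 1], S, my),
                  ns_rows_Ay(nsf, P[, 1], my))
      ax <- cbind(avg_rows_Ax(kern, P[, 2], S, mx),
                  ns_rows_Ax(nsf, P[, 2], mx))
      sweep(K - ay - ax, 2, -as.numeric(row0()), "-")
    })
  lapply(component_labels, function(lb)
    new_component(lb, build[[lb]], carrier)) |>
    stats::setNames(component_labels)
}

# block readout for tensor-product fits: every component is the sum of its
# penalized block and its unpenalized parametric direction
tensor_components <- function(carrier) {
  kern <- carrier$kernel; S <- carrier$sources
  th <- kern$theta; p <- length(carrier$nsfuns)
  m <- nrow(S)
  has_c <- !is.finite(kern$theta0) # constant in the null space?
  build <- list(
    intercept = function(points) {
      if (has_c) matrix(c(rep(0, m), 1, rep(0, p - 1)), 1)
      else matrix(c(kern$theta0 * rep(1, m), rep(0, p)), 1)
    },
    main_x = function(xs) {
      xs <- as.numeric(xs)
      P <- cbind(xs, 0)
      B <- matrix(0, length(xs), p)
      B[, has_c + 1L] <- kern$k1x(xs)
      cbind(th[["x"]] * kern$penal_block_kmat("x", P, S), B)
    },
    main_y = function(ys) {
      ys <- as.numeric(ys)
      P <- cbind(0, ys)
      B <- matrix(0, length(ys), p)
      B[, has_c + 2L] <- kern$k1y(ys)
      cbind(th[["y"]] * kern$penal_block_kmat("y", P, S), B)
    },
    interaction = function(points) {
      P <- as.matrix(points)
      B <- matrix(0, nrow(P), p)
      B[, has_c + 3L] <- kern$k1x(P[, 1]) * kern$k1y(P[, 2])
      cbind(th[["xy"]] * kern$penal_block_kmat("xy", P, S), B)
    })
  lapply(component_labels, function(lb)
    new_component(lb, build[[lb]], carrier)) |>
    stats::setNames(component_labels)
}

new_decomposition <- function(components, carrier, measures, method,
                              xcols = c("x", "y")) {
  structure(list(components = components, carrier = carrier,
                 measures = measures, method = method, xcols = xcols),
            class = "ssa_decomposition")
}

#' Post-hoc smoothing spline ANOVA decomposition of a fitted spline
#'
#' Decomposes a fitted bivariate spline of *any* kernel into intercept,
#' main effects and interaction by applying the averaging operators
#' numerically to the reproducing kernel and to the null-space basis
#' functions. The intercept is `AxAy f`, the main effects `Ay(1 - Ax) f`
#' and `Ax(1 - Ay) f`, and the interaction `(1 - Ax)(1 - Ay) f`; main
#' effects integrate to zero under the decomposition measures and the
#' interaction has zero marginals. When the fitted kernel is itself a
#' tensor product of marginal spaces this reproduces the classic
#' SS-ANOVA decomposition.
#'
#' @param fit A bivariate `spline_fit`.
#' @param measures List of [quad_measure()]s `x` and `y`; defaults to
#'   Lebesgue (order 32) on the fit's domain.
#' @param quad_order Gauss--Legendre order of the default measures.
#' @return An object of class `ssa_decomposition` whose `components` are
#'   named evaluators (`intercept`, `main_x`, `main_y`, `interaction`),
#'   each with `evaluate(points)`, `variance(points)` and
#'   `row_matrix(points)`.
#' @examples
#' d <- sim_dataset(1, n = 80, seed = 2)
#' dec <- posthoc_decompose(fit_spline(d, kernel = "tps"))
#' dec$components$intercept$evaluate(NULL)
#' @export
posthoc_decompose <- function(fit, measures = NULL, quad_order = 32) {
  stopifnot(inherits(fit, "spline_fit"))
  if (fit$kernel$dim > 2L)
    stop("not implemented for more than 2 covariates; decompose bivariate ",
         "terms of a larger model with decompose_pair().", call. = FALSE)
  if (fit$kernel$dim < 2L)
    stop("posthoc_decompose() expects a bivariate fit.", call. = FALSE)
  measures <- measures %||% default_measures(fit$kernel$domain, quad_order)
  check_measure(measures$x, "measures$x")
  check_measure(measures$y, "measures$y")
  carrier <- carrier_from_fit(fit)
  dec <- new_decomposition(posthoc_components(carrier, measures), carrier,
                           measures, "posthoc", fit$xcols)
  dec$lambda <- fit$lambda
  dec
}

#' Classic tensor-product smoothing spline ANOVA
#'
#' Fits the block tensor-product model (unpenalized intercept, centered
#' marginal main-effect blocks, product interaction block) with a separate
#' weight `theta` per penalized block, selecting `(theta, lambda)` jointly:
#' for every `theta` combination on a log grid the scalar `lambda` is
#' profiled out with the criterion, the best combination is locally
#' refined, and the components are then read directly off the blocks.
#'
#' @inheritParams fit_spline
#' @param theta_grid Positive multipliers forming the per-block weight grid
#'   (used for each of `theta_x`, `theta_y`, `theta_xy`).
#' @param refine Refine the best grid point by a second local grid?
#' @param quad_order Quadrature order of the Lebesgue centering measures.
#' @return An object of class `ssanova_fit`: a list with the underlying
#'   `fit` (a `spline_fit`), the block-readout `decomposition`
#'   (`ssa_decomposition`), the selected `theta`, and the search path.
#' @export
classic_ssanova <- function(data, x = "x", y = "y", z = "z",
                            criterion = c("gcv", "reml"),
                            theta_grid = c(0.1, 1, 10), refine = TRUE,
                            knots = NULL, measures = NULL, domain = NULL,
                            quad_order = 32) {
  criterion <- match.arg(criterion)
  obs <- as_observations(data, c(x, y), z)
  X <- obs$X; zv <- obs$z; n <- nrow(X)
  if (is.null(domain)) {
    domain <- apply(X, 2, range)
    w <- domain[2, ] - domain[1, ]
    domain[1, ] <- domain[1, ] - 1e-8 * pmax(w, 1)
    domain[2, ] <- domain[2, ] + 1e-8 * pmax(w, 1)
  }
  measures <- measures %||% default_measures(domain, quad_order)
  kx <- cubic_kernel(domain[, 1]); ky <- cubic_kernel(domain[, 2])
  base_kernel <- tensor_kernel(kx, ky, measures = measures)
  if (is.null(knots)) knots <- tensor_knots(X)

  # block Gram matrices are theta-free; assemble J(theta), P(theta) cheaply
  JB <- lapply(c("x", "y", "xy"), function(b)
    base_kernel$penal_block_kmat(b, X, knots))
  PB <- lapply(c("x", "y", "xy"), function(b)
    base_kernel$penal_block_kmat(b, knots, knots))
  names(JB) <- names(PB) <- c("x", "y", "xy")
  Tn <- nullspace_matrix(base_kernel, X)
  Tr <- nullspace_matrix(base_kernel, knots)

  search_grid <- 10^seq(-8, 4, length.out = 17)
  eval_theta <- function(th, refine = FALSE) {
    J <- th[1] * JB$x + th[2] * JB$y + th[3] * JB$xy
    P <- th[1] * PB$x + th[2] * PB$y + th[3] * PB$xy
    sys <- penalized_system(J, Tn, P, Tr, zv)
    lam <- withCallingHandlers(
      select_lambda_sys(sys, criterion,
                        grid = if (refine) 10^seq(-9, 5, length.out = 29)
                        else search_grid,
                        refine = refine),
      warning = function(w) invokeRestart("muffleWarning"))
    c(lambda = as.numeric(lam), score = attr(lam, "criterion_value"))
  }

  grid <- as.matrix(expand.grid(x = theta_grid, y = theta_grid,
                                xy = theta_grid))
  path <- t(apply(grid, 1, eval_theta))
  best <- which.min(path[, "score"])
  th_best <- grid[best, ]; lam_best <- path[best, "lambda"]
  score_best <- path[best, "score"]
  if (refine) {
    # walk a factor-3 local grid until the optimum is interior (or 4 rounds)
    for (round in 1:4) {
      grid2 <- as.matrix(expand.grid(x = th_best[1] * c(1 / 3, 1, 3),
                                     y = th_best[2] * c(1 / 3, 1, 3),
                                     xy = th_best[3] * c(1 / 3, 1, 3)))
      path2 <- t(apply(grid2, 1, eval_theta))
      b2 <- which.min(path2[, "score"])
      path <- rbind(path, path2)
      grid <- rbind(grid, grid2)
      if (path2[b2, "score"] >= score_best) break
      moved <- any(grid2[b2, ] != th_best)
      th_best <- grid2[b2, ]; lam_best <- path2[b2, "lambda"]
      score_best <- path2[b2, "score"]
      if (!moved || b2 == 14L) break # 14 = centre of the 3^3 local grid
    }
  }

  theta <- c(x = unname(th_best[1]), y = unname(th_best[2]),
             xy = unname(th_best[3]))
  # refine lambda at the selected theta before the final fit
  fin <- eval_theta(th_best, refine = TRUE)
  if (fin[["score"]] <= score_best) {
    lam_best <- fin[["lambda"]]; score_best <- fin[["score"]]
  }
  kernel <- tensor_kernel(kx, ky, measures = measures, theta = theta)
  fit <- fit_spline(obs$data, x = x, y = y, z = z, kernel = kernel,
                    lambda = lam_best, knots = knots, domain = domain)
  fit$criterion <- criterion
  fit$criterion_value <- score_best
  carrier <- carrier_from_fit(fit)
  dec <- new_decomposition(tensor_components(carrier), carrier, measures,
                           "tensor", c(x, y))
  dec$lambda <- lam_best
  structure(list(fit = fit, decomposition = dec, theta = theta,
                 lambda = lam_best, criterion = criterion,
                 search = tibble::as_tibble(cbind(grid, path))),
            class = "ssanova_fit")
}

#' @export
print.ssanova_fit <- function(x, ...) {
  cat(sprintf("<ssanova_fit: tensor-product SS-ANOVA, n = %d>\n", x$fit$n))
  cat(sprintf("  theta = (%.3g, %.3g, %.3g), lambda = %.4g (%s)\n",
              x$theta[["x"]], x$theta[["y"]], x$theta[["xy"]],
              x$lambda, x$criterion))
  invisible(x)
}

#' Pointwise posterior variance of a decomposition component
#'
#' Computes `diag(M Sigma M')` where `M` is the component's row matrix over
#' the fit's coefficients and `Sigma` their joint posterior covariance;
#' for the intercept this is the scalar `R0 Sigma R0'` with `R0` the
#' double-averaged kernel row.
#'
#' @param decomposition An `ssa_decomposition`.
#' @param component One of `"intercept"`, `"main_x"`, `"main_y"`,
#'   `"interaction"`.
#' @param points Evaluation points: a numeric vector for main effects, a
#'   2-column matrix for the interaction, ignored for the intercept.
#' @return Numeric vector of pointwise variances (all `>= 0`).
#' @export
component_variance <- function(decomposition, component, points = NULL) {
  comp <- decomposition$components[[component]]
  if (is.null(comp))
    stop("unknown component label: ", component, call. = FALSE)
  comp$variance(points)
}

#' Pointwise significance mask of a component
#'
#' A point is flagged significant when the component's posterior mean is at
#' least `k` posterior standard deviations away from zero
#' (`|mean| >= k * sd`, boundary included).
#'
#' @inheritParams component_variance
#' @param k Standard-deviation multiplier (default 2).
#' @return Logical vector over the points.
#' @export
significance_mask <- function(decomposition, component, points = NULL, k = 2) {
  comp <- decomposition$components[[component]]
  if (is.null(comp))
    stop("unknown component label: ", component, call. = FALSE)
  mu <- comp$evaluate(points)
  sd <- sqrt(comp$variance(points))
  abs(mu) >= k * sd
}

# default evaluation grids on the decomposition domain
decomp_grids <- function(decomposition, n_main = 101, n_inter = 21) {
  dom <- decomposition$carrier$domain
  xs <- seq(dom[1, 1], dom[2, 1], length.out = n_main)
  ys <- seq(dom[1, 2], dom[2, 2], length.out = n_main)
  xi <- seq(dom[1, 1], dom[2, 1], length.out = n_inter)
  yi <- seq(dom[1, 2], dom[2, 2], length.out = n_inter)
  list(xs = xs, ys = ys,
       inter = as.matrix(expand.grid(x = xi, y = yi)))
}

#' @method tidy ssa_decomposition
#' @export
tidy.ssa_decomposition <- function(x, n_main = 101, n_inter = 21, k = 2, ...) {
  g <- decomp_grids(x, n_main, n_inter)
  one <- function(label, pts, px, py) {
    comp <- x$components[[label]]
    mu <- comp$evaluate(pts)
    sd <- sqrt(comp$variance(pts))
    tibble::tibble(component = label, x = px, y = py,
                   estimate = mu, std_error = sd,
                   significant = abs(mu) >= k * sd)
  }
  dplyr::bind_rows(
    one("intercept", NULL, NA_real_, NA_real_),
    one("main_x", g$xs, g$xs, NA_real_),
    one("main_y", g$ys, NA_real_, g$ys),
    one("interaction", g$inter, g$inter[, 1], g$inter[, 2]))
}

#' @export
print.ssa_decomposition <- function(x, ...) {
  c0 <- x$components$intercept$evaluate(NULL)
  cat(sprintf("<ssa_decomposition (%s): intercept %.4g + main_x + main_y + interaction>\n",
              x$method, c0))
  invisible(x)
}

#' Plot a decomposition
#'
#' Main effects are drawn as lines with a `+- k` posterior-sd ribbon; the
#' interaction as a filled raster with significance contours.
#'
#' @param object An `ssa_decomposition`.
#' @param k Ribbon half-width in posterior standard deviations.
#' @param n_main,n_inter Grid resolutions.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ssa_decomposition
#' @export
autoplot.ssa_decomposition <- function(object, k = 1, n_main = 101,
                                       n_inter = 41, ...) {
  td <- tidy(object, n_main = n_main, n_inter = n_inter, k = k)
  mains <- dplyr::filter(td, .data$component %in% c("main_x", "main_y"))
  mains <- dplyr::mutate(mains,
                         at = dplyr::coalesce(.data$x, .data$y))
  inter <- dplyr::filter(td, .data$component == "interaction")
  p1 <- ggplot2::ggplot(mains, ggplot2::aes(x = .data$at)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$estimate - k * .data$std_error,
      ymax = .data$estimate + k * .data$std_error), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate)) +
    ggplot2::facet_wrap(~component, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "partial effect")
  p2 <- ggplot2::ggplot(inter, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$estimate)) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(fill = "interaction")
  if (requireNamespace("patchwork", quietly = TRUE))
    return(p1 + patchwork::wrap_plots(p2))
  p1
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
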