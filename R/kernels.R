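# Reproducing kernels and their penalty structure.
#
# A kernel object separates the *penalized* part of the function space (given
# by its reproducing kernel, evaluated by `$kmat`) from the unpenalized null
# space of the roughness penalty (`$nullspace`, a list of basis functions).
# All kernels accept covariates on their original scale and rescale to the
# unit interval/square internally; the penalty null space is spanned by the
# same functions either way.

`%||%` <- function(a, b) if (is.null(a)) b else a

# rescale columns of X (n x d matrix) to [0,1] using the kernel domain
resc <- function(X, domain) {
  X <- as.matrix(X)
  lo <- domain[1, ]
  w <- domain[2, ] - domain[1, ]
  sweep(sweep(X, 2, lo, "-"), 2, w, "/")
}

as_domain <- function(domain, dim) {
  d <- as.matrix(domain)
  if (length(d) == 2) d <- matrix(as.numeric(d), 2, 1)
  if (nrow(d) != 2 || ncol(d) != dim)
    stop("`domain` must supply a (lo, hi) interval per covariate.",
         call. = FALSE)
  if (any(!is.finite(d)) || any(d[2, ] - d[1, ] <= 0))
    stop("invalid domain: each interval must have positive width.",
         call. = FALSE)
  d
}

# thin-plate radial profile for the 2-D second-order penalty;
# the 1/(8*pi) normalization is absorbed into the smoothing parameter
tps_eta <- function(r) {
  out <- r
  out[] <- 0
  pos <- r > 0
  out[pos] <- r[pos]^2 * log(r[pos]) / (8 * pi)
  out
}

#' Thin-plate spline kernel on a rectangle
#'
#' The reproducing kernel of the bivariate thin-plate spline, i.e. the
#' penalized-least-squares smoother under the rotation-invariant penalty
#' `int f_xx^2 + 2 f_xy^2 + f_yy^2`. The penalty treats wiggliness in every
#' direction of the plane equally ("isotropic smoothness"); its null space
#' is the affine functions `{1, x, y}`, which are fitted unpenalized under
#' the usual side conditions on the kernel coefficients.
#'
#' The radial profile is `eta(r) = r^2 log(r) / (8 pi)` with `eta(0) = 0`;
#' covariates are affinely mapped to the unit square internally, so the
#' kernel is isotropic on the rescaled domain.
#'
#' @param domain 2-column matrix (or list of two length-2 vectors) giving the
#'   covariate intervals.
#' @return An object of class `ssa_kernel`.
#' @examples
#' k <- tps_kernel(cbind(c(0, 1), c(0, 1)))
#' kernel_matrix(k, cbind(0.2, 0.3), cbind(0.2, 0.3)) # eta(0) = 0
#' @export
tps_kernel <- function(domain = cbind(c(0, 1), c(0, 1))) {
  if (is.list(domain)) domain <- do.call(cbind, domain)
  domain <- as_domain(domain, 2)
  kmat <- function(X1, X2) {
    U1 <- resc(X1, domain); U2 <- resc(X2, domain)
    d2 <- outer(U1[, 1], U2[, 1], "-")^2 + outer(U1[, 2], U2[, 2], "-")^2
    tps_eta(sqrt(d2))
  }
  ns <- list(
    function(X) rep(1, nrow(as.matrix(X))),
    function(X) resc(X, domain)[, 1],
    function(X) resc(X, domain)[, 2]
  )
  structure(list(kind = "tps", dim = 2L, domain = domain,
                 kmat = kmat, nullspace = ns),
            class = "ssa_kernel")
}

# Bernoulli-polynomial pieces of the cubic smoothing-spline RK on [0,1]
bern_k1 <- function(u) u - 0.5
bern_k2 <- function(u) (bern_k1(u)^2 - 1 / 12) / 2
bern_k4 <- function(u) (bern_k1(u)^4 - bern_k1(u)^2 / 2 + 7 / 240) / 24
# RK of the fully smooth (zero-mean, zero-slope-moment) subspace
cubic_R1 <- function(u1, u2) {
  outer(bern_k2(u1), bern_k2(u2)) - bern_k4(abs(outer(u1, u2, "-")))
}

#' Univariate cubic smoothing-spline kernel
#'
#' Reproducing kernel of the cubic smoothing spline on an interval, in the
#' standard Bernoulli-polynomial form on the rescaled unit interval. The
#' penalized part `R1(u, v) = k2(u) k2(v) - k4(|u - v|)` spans the smooth
#' functions orthogonal to constants and linears under the uniform measure;
#' the null space is `{1, u - 1/2}`. The object also carries the full
#' marginal-space kernel `1 + k1(u) k1(v) + R1(u, v)` used when two marginal
#' spaces are combined into a tensor product.
#'
#' @param domain Length-2 numeric interval.
#' @return An object of class `ssa_kernel` with `dim = 1`.
#' @export
cubic_kernel <- function(domain = c(0, 1)) {
  domain <- as_domain(domain, 1)
  u_of <- function(X) resc(X, domain)[, 1]
  kmat <- function(X1, X2) cubic_R1(u_of(X1), u_of(X2))
  full_kmat <- function(X1, X2) {
    u1 <- u_of(X1); u2 <- u_of(X2)
    1 + outer(bern_k1(u1), bern_k1(u2)) + cubic_R1(u1, u2)
  }
  ns <- list(function(X) rep(1, nrow(as.matrix(X))),
             function(X) bern_k1(u_of(X)))
  structure(list(kind = "cubic", dim = 1L, domain = domain,
                 kmat = kmat, full_kmat = full_kmat,
                 k1 = function(X) bern_k1(u_of(X)),
                 nullspace = ns),
            class = "ssa_kernel")
}

#' Center a univariate kernel under a probability measure
#'
#' Projects the full marginal reproducing kernel onto the subspace of
#' zero-mean functions: the returned kernel is
#' `Rc(s, t) = R(s, t) - m(s) - m(t) + m0` with `m(s) = int R(s, u) dmu(u)`
#' and `m0` the double average, so every section integrates to zero under
#' `mu`. Centering is a projection and hence idempotent. For the cubic
#' kernel under the uniform measure this reproduces the zero-mean-space
#' kernel `k1(u) k1(v) + R1(u, v)` up to quadrature error.
#'
#' @param kernel A univariate `ssa_kernel`.
#' @param measure An [quad_measure()] on the kernel's domain.
#' @return A centered `ssa_kernel` with an empty null space.
#' @export
center_kernel <- function(kernel, measure) {
  stopifnot(inherits(kernel, "ssa_kernel"))
  if (kernel$dim != 1L)
    stop("center_kernel() expects a univariate kernel.", call. = FALSE)
  check_measure(measure)
  base <- kernel$full_kmat %||% kernel$kmat
  nodes <- matrix(measure$nodes, ncol = 1)
  w <- measure$weights
  mfun <- function(X) as.numeric(base(X, nodes) %*% w)
  m0 <- as.numeric(w %*% base(nodes, nodes) %*% w)
  kmat <- function(X1, X2) {
    base(X1, X2) - outer(mfun(X1), rep(1, nrow(as.matrix(X2)))) -
      outer(rep(1, nrow(as.matrix(X1))), mfun(X2)) + m0
  }
  structure(list(kind = "centered", dim = 1L, domain = kernel$domain,
                 kmat = kmat, full_kmat = kmat, nullspace = list(),
                 base = kernel, measure = measure),
            class = "ssa_kernel")
}

#' Tensor-product smoothing spline ANOVA kernel
#'
#' Builds the block-structured reproducing kernel of the product space of
#' two univariate marginal spaces, decomposed along the ANOVA subspaces
#' `1 (x) 1`, `Vx (x) 1`, `1 (x) Vy` and `Vx (x) Vy`, where `Vx` and `Vy`
#' are the zero-mean subspaces obtained by centering each marginal kernel
#' under its measure.
#'
#' Following the standard construction, the parametric (linear) directions
#' of the marginal spaces stay unpenalized: the joint null space is spanned
#' by `1`, the centered linear functions `k1x`, `k1y` and their product,
#' while the penalized blocks carry the centered smooth marginal kernels
#' `R1x`, `R1y` for the main effects and the mixed products
#' `k1x k1x' R1y + R1x k1y k1y' + R1x R1y` for the interaction. Each
#' penalized block enters the joint kernel with its weight `theta`, so the
#' effective penalty on block `b` is `lambda / theta_b`. With
#' `theta0 = Inf` (the default) the constants are unpenalized; a finite
#' `theta0` penalizes the intercept block instead.
#'
#' @param kx,ky Univariate `ssa_kernel` objects (typically [cubic_kernel()]).
#' @param measures List with [quad_measure()] entries `x` and `y`; default
#'   Lebesgue (order 32) on each marginal domain.
#' @param theta Named positive weights `c(x = , y = , xy = )` for the three
#'   penalized blocks.
#' @param theta0 Weight of the constant block; `Inf` (default) moves the
#'   intercept to the null space.
#' @return An `ssa_kernel` of class `ssa_kernel`/`ssa_tensor_kernel` with
#'   two block accessors: `block_kmat(which, X1, X2)` returns the full
#'   reproducing kernel of the ANOVA *subspace* (`which` in `"const"`,
#'   `"x"`, `"y"`, `"xy"`; products of centered marginal kernels), and
#'   `penal_block_kmat(which, X1, X2)` the penalized part of that block as
#'   used in the joint kernel.
#' @export
tensor_kernel <- function(kx, ky, measures = NULL,
                          theta = c(x = 1, y = 1, xy = 1), theta0 = Inf) {
  stopifnot(inherits(kx, "ssa_kernel"), inherits(ky, "ssa_kernel"))
  if (kx$dim != 1L || ky$dim != 1L)
    stop("marginal kernels must be univariate.", call. = FALSE)
  theta <- theta[c("x", "y", "xy")]
  if (any(is.na(theta)))
    stop("`theta` must supply named entries x, y, xy.", call. = FALSE)
  if (any(!is.finite(theta)))
    stop("only the constant block may be unpenalized (theta0 = Inf); ",
         "block weights x, y, xy must be finite.", call. = FALSE)
  if (any(theta <= 0) || (is.finite(theta0) && theta0 <= 0))
    stop("block weights must be positive.", call. = FALSE)
  domain <- cbind(kx$domain, ky$domain)
  if (is.null(measures)) measures <- default_measures(domain)
  check_measure(measures$x, "measures$x"); check_measure(measures$y, "measures$y")
  cx <- center_kernel(kx, measures$x)
  cy <- center_kernel(ky, measures$y)

  # centered linear direction and centered smooth kernel of each marginal;
  # under a full-domain Lebesgue measure the Bernoulli-form cubic pieces
  # are centered exactly, so the quadrature projection is skipped (its
  # ~1e-9 residual would otherwise be amplified by large coefficient
  # norms in rough fits)
  leb_full <- function(measure, dom) {
    measure$kind == "lebesgue" &&
      max(abs(measure$domain - as.numeric(dom))) < 1e-12
  }
  ctr_fun <- function(f, measure, exact) {
    if (exact) return(function(v) f(matrix(v, ncol = 1)))
    mu <- sum(measure$weights * f(matrix(measure$nodes, ncol = 1)))
    function(v) f(matrix(v, ncol = 1)) - mu
  }
  ctr_smooth <- function(kern, measure, exact) {
    if (exact)
      return(function(v1, v2)
        kern$kmat(matrix(v1, ncol = 1), matrix(v2, ncol = 1)))
    nodes <- matrix(measure$nodes, ncol = 1); w <- measure$weights
    mfun <- function(v) as.numeric(kern$kmat(matrix(v, ncol = 1), nodes) %*% w)
    m0 <- as.numeric(w %*% kern$kmat(nodes, nodes) %*% w)
    function(v1, v2) {
      kern$kmat(matrix(v1, ncol = 1), matrix(v2, ncol = 1)) -
        outer(mfun(v1), rep(1, length(v2))) -
        outer(rep(1, length(v1)), mfun(v2)) + m0
    }
  }
  ex_x <- kx$kind == "cubic" && leb_full(measures$x, kx$domain)
  ex_y <- ky$kind == "cubic" && leb_full(measures$y, ky$domain)
  k1x <- ctr_fun(kx$k1 %||% function(X) resc(X, kx$domain)[, 1],
                 measures$x, ex_x)
  k1y <- ctr_fun(ky$k1 %||% function(X) resc(X, ky$domain)[, 1],
                 measures$y, ex_y)
  R1x <- ctr_smooth(kx, measures$x, ex_x)
  R1y <- ctr_smooth(ky, measures$y, ex_y)

  # full subspace RKs (parametric + smooth), products of centered marginals
  block_kmat <- function(which, X1, X2) {
    X1 <- as.matrix(X1); X2 <- as.matrix(X2)
    switch(which,
      const = matrix(1, nrow(X1), nrow(X2)),
      x = cx$kmat(X1[, 1, drop = FALSE], X2[, 1, drop = FALSE]),
      y = cy$kmat(X1[, 2, drop = FALSE], X2[, 2, drop = FALSE]),
      xy = cx$kmat(X1[, 1, drop = FALSE], X2[, 1, drop = FALSE]) *
        cy$kmat(X1[, 2, drop = FALSE], X2[, 2, drop = FALSE]),
      stop("unknown block: ", which, call. = FALSE))
  }
  # penalized parts only (parametric directions live in the null space)
  penal_block_kmat <- function(which, X1, X2) {
    X1 <- as.matrix(X1); X2 <- as.matrix(X2)
    switch(which,
      const = matrix(1, nrow(X1), nrow(X2)),
      x = R1x(X1[, 1], X2[, 1]),
      y = R1y(X1[, 2], X2[, 2]),
      xy = outer(k1x(X1[, 1]), k1x(X2[, 1])) * R1y(X1[, 2], X2[, 2]) +
        R1x(X1[, 1], X2[, 1]) * outer(k1y(X1[, 2]), k1y(X2[, 2])) +
        R1x(X1[, 1], X2[, 1]) * R1y(X1[, 2], X2[, 2]),
      stop("unknown block: ", which, call. = FALSE))
  }
  kmat <- function(X1, X2) {
    out <- theta[["x"]] * penal_block_kmat("x", X1, X2) +
      theta[["y"]] * penal_block_kmat("y", X1, X2) +
      theta[["xy"]] * penal_block_kmat("xy", X1, X2)
    if (is.finite(theta0)) out <- out + theta0 * penal_block_kmat("const", X1, X2)
    out
  }
  # closed-form averaged kernel under the exact-centering Lebesgue
  # measures: every block but one has a vanishing marginal average
  avg_hook <- function(which, points, sources, measure) {
    sources <- as.matrix(sources)
    c0 <- if (is.finite(theta0)) theta0 else 0
    if (which == "Ay") {
      if (!(ex_y && leb_full(measure, ky$domain))) return(NULL)
      xs <- as.numeric(points)
      theta[["x"]] * R1x(xs, sources[, 1]) + c0
    } else if (which == "Ax") {
      if (!(ex_x && leb_full(measure, kx$domain))) return(NULL)
      ys <- as.numeric(points)
      theta[["y"]] * R1y(ys, sources[, 2]) + c0
    } else if (which == "AxAy") {
      if (!(ex_x && ex_y && leb_full(measure$x, kx$domain) &&
            leb_full(measure$y, ky$domain))) return(NULL)
      matrix(c0, 1, nrow(sources))
    } else NULL
  }
  ns <- c(
    if (!is.finite(theta0)) list(function(X) rep(1, nrow(as.matrix(X)))),
    list(function(X) k1x(as.matrix(X)[, 1]),
         function(X) k1y(as.matrix(X)[, 2]),
         function(X) k1x(as.matrix(X)[, 1]) * k1y(as.matrix(X)[, 2])))
  structure(list(kind = "tensor", dim = 2L, domain = domain,
                 kmat = kmat, nullspace = ns,
                 kx = kx, ky = ky, cx = cx, cy = cy,
                 k1x = k1x, k1y = k1y, R1x = R1x, R1y = R1y,
                 measures = measures, theta = theta, theta0 = theta0,
                 avg_hook = avg_hook,
                 block_kmat = block_kmat, penal_block_kmat = penal_block_kmat),
            class = c("ssa_tensor_kernel", "ssa_kernel"))
}

#' Evaluate a kernel's penalized-part Gram matrix
#'
#' @param kernel An `ssa_kernel`.
#' @param X1,X2 Matrices of points (rows), on the original covariate scale.
#' @return The `nrow(X1) x nrow(X2)` cross Gram matrix of the penalized part.
#' @export
kernel_matrix <- function(kernel, X1, X2 = X1) {
  stopifnot(inherits(kernel, "ssa_kernel"))
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (ncol(X1) != kernel$dim || ncol(X2) != kernel$dim)
    stop("points have the wrong number of columns for this kernel.",
         call. = FALSE)
  kernel$kmat(X1, X2)
}

# n x p matrix of null-space basis evaluations (p = 0 allowed)
nullspace_matrix <- function(kernel, X) {
  X <- as.matrix(X)
  if (length(kernel$nullspace) == 0)
    return(matrix(0, nrow(X), 0))
  do.call(cbind, lapply(kernel$nullspace, function(f) f(X)))
}

#' @export
print.ssa_kernel <- function(x, ...) {
  cat(sprintf("<ssa_kernel: %s, dim %d, null space dim %d>\n",
              x$kind, x$dim, length(x$nullspace)))
  invisible(x)
}

#' Serialize / deserialize kernel specifications
#'
#' Kernel specifications round-trip through plain lists suitable for YAML
#' configuration blocks: `kind` in `tps`, `cubic`, `tensor`, plus the
#' domain and, for tensor kernels, the block weights.
#'
#' @param kernel An `ssa_kernel`.
#' @return `kernel_to_config()`: a named list; `kernel_from_config()`: an
#'   `ssa_kernel`.
#' @export
kernel_to_config <- function(kernel) {
  stopifnot(inherits(kernel, "ssa_kernel"))
  cfg <- list(kind = kernel$kind,
              domain = lapply(seq_len(kernel$dim),
                              function(j) as.numeric(kernel$domain[, j])))
  if (kernel$kind == "tensor") {
    cfg$theta <- as.list(kernel$theta)
    cfg$theta0 <- if (is.finite(kernel$theta0)) kernel$theta0 else "inf"
    cfg$order <- length(kernel$measures$x$nodes)
  }
  cfg
}

#' @param config A named list (e.g. parsed from YAML) with at least `kind`
#'   and `domain`.
#' @rdname kernel_to_config
#' @export
kernel_from_config <- function(config) {
  kind <- match.arg(config$kind, c("tps", "cubic", "tensor"))
  dom <- do.call(cbind, lapply(config$domain, as.numeric))
  switch(kind,
    tps = tps_kernel(dom),
    cubic = cubic_kernel(dom),
    tensor = {
      kx <- cubic_kernel(dom[, 1]); ky <- cubic_kernel(dom[, 2])
      theta <- unlist(config$theta %||% list(x = 1, y = 1, xy = 1))
      theta0 <- config$theta0 %||% "inf"
      theta0 <- if (identical(theta0, "inf")) Inf else as.numeric(theta0)
      ms <- default_measures(dom, order = config$order %||% 32)
      tensor_kernel(kx, ky, measures = ms, theta = theta, theta0 = theta0)
    })
}
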