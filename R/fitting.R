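# Penalized least-squares spline estimation in the representer form.
#
# A fit minimizes ||z - J a - T b||^2 + lambda a' P a subject to Tr' a = 0,
# where J is the Gram matrix of the penalized kernel part between
# observations and representers, T the null-space basis at the observations,
# P the penalized-block Gram at the representers and Tr the null-space basis
# at the representers. The side condition makes the (conditionally positive
# definite) thin-plate system well posed; for kernels with an empty null
# space the solve reduces to the textbook ridge-in-RKHS expressions
# a = (J'J + lambda J)^{-1} J' z, cov(a) = sigma^2 (J'J + lambda J)^{-1}.

# representers: all observation points up to `n_max`, otherwise a
# deterministic thinning to `m_target` marginal-quantile knots snapped to
# the nearest observations
default_knots <- function(X, m_target = 200, n_max = 1000) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n <= n_max) return(unique(X))
  if (d == 1) {
    q <- stats::quantile(X[, 1], probs = seq(0, 1, length.out = m_target),
                         names = FALSE, type = 7)
    return(matrix(unique(q), ncol = 1))
  }
  # per-axis quantile grid sized to fit within the target without
  # truncation (dropping trailing grid rows would leave a coverage hole)
  k_per <- floor(sqrt(m_target))
  qs <- lapply(seq_len(d), function(j)
    stats::quantile(X[, j], probs = seq(0.01, 0.99, length.out = k_per),
                    names = FALSE))
  grid <- as.matrix(expand.grid(qs))
  # snap to nearest observation for data-adaptive coverage
  sx <- apply(X, 2, stats::sd)
  sx[sx == 0] <- 1
  Xs <- sweep(X, 2, sx, "/"); Gs <- sweep(grid, 2, sx, "/")
  idx <- vapply(seq_len(nrow(Gs)), function(i) {
    which.min(colSums((t(Xs) - Gs[i, ])^2))
  }, integer(1))
  unique(X[idx, , drop = FALSE])
}

# marginal quantile knots for tensor-product fits (m1 x m2 grid of pairs);
# the basis is kept below the sample size so GCV keeps a well-defined
# denominator (10 knots per margin for larger samples, 5 for small ones)
tensor_knots <- function(X) {
  marginal_grid_knots(X, k_per = if (nrow(as.matrix(X)) >= 150) 10 else 5)
}

marginal_grid_knots <- function(X, k_per = 10) {
  X <- as.matrix(X)
  qs <- lapply(seq_len(ncol(X)), function(j)
    stats::quantile(X[, j], probs = seq(0, 1, length.out = k_per),
                    names = FALSE))
  qs <- lapply(qs, unique)
  as.matrix(expand.grid(qs))
}

#' Assemble the penalized design for a kernel and observation set
#'
#' @param kernel An `ssa_kernel`.
#' @param X Matrix of observed covariate points (rows).
#' @param representers Optional matrix of representer (knot) points;
#'   defaults to the observation points. Duplicated representers are
#'   dropped with a warning.
#' @return A list with `J` (n x m penalized Gram), `T` (n x p null-space
#'   basis), `P` (m x m penalty Gram), `Tr` (m x p null-space basis at the
#'   representers) and `representers`.
#' @export
build_design <- function(kernel, X, representers = NULL) {
  X <- as.matrix(X)
  if (is.null(representers)) representers <- X
  representers <- as.matrix(representers)
  dup <- duplicated(representers)
  if (any(dup)) {
    warning(sprintf("dropping %d duplicated representer point(s)", sum(dup)))
    representers <- representers[!dup, , drop = FALSE]
  }
  list(J = kernel_matrix(kernel, X, representers),
       T = nullspace_matrix(kernel, X),
       P = kernel_matrix(kernel, representers, representers),
       Tr = nullspace_matrix(kernel, representers),
       representers = representers)
}

# Reusable solver environment: everything that does not depend on lambda is
# computed once, so smoothing-parameter search costs one Cholesky per value.
penalized_system <- function(J, T, P, Tr = NULL, z, weights = NULL) {
  J <- as.matrix(J); T <- as.matrix(T)
  n <- nrow(J); m <- ncol(J); p <- ncol(T)
  if (is.null(Tr)) {
    if (m == n) Tr <- T
    else stop("`Tr` (null-space basis at representers) is required when ",
              "representers differ from observations.", call. = FALSE)
  }
  if (!is.null(weights)) {
    if (length(weights) != n || any(weights <= 0))
      stop("weights must be positive, one per observation.", call. = FALSE)
    sw <- sqrt(weights)
    J <- J * sw; T <- T * sw; z <- z * sw
  }
  if (p > 0) {
    if (m <= p) stop("fewer representers than null-space dimension; ",
                     "the constrained system is ill posed.", call. = FALSE)
    Z <- qr.Q(qr(Tr), complete = TRUE)[, (p + 1):m, drop = FALSE]
  } else {
    Z <- diag(m)
  }
  XX <- cbind(J %*% Z, T)
  q <- ncol(XX)
  Dp <- crossprod(Z, P %*% Z)
  Dp <- (Dp + t(Dp)) / 2
  D <- matrix(0, q, q)
  if (m - p > 0) D[seq_len(m - p), seq_len(m - p)] <- Dp
  A <- crossprod(XX)
  b <- crossprod(XX, z)
  zz <- sum(z^2)
  # unit-diagonal rescaling keeps the normal equations well conditioned
  # across the whole lambda grid
  s <- sqrt(pmax(diag(A), 1e-300))
  As <- A / tcrossprod(s)
  Ds <- D / tcrossprod(s)
  bs <- b / s
  list(J = J, T = T, P = P, Tr = Tr, Z = Z, XX = XX, A = A, b = b, D = D,
       Dp = Dp, s = s, As = As, Ds = Ds, bs = bs,
       z = z, zz = zz, n = n, m = m, p = p, q = q)
}

# solve at one lambda; returns reduced-coordinate results
solve_system <- function(sys, lambda) {
  M <- sys$As + lambda * sys$Ds
  R <- tryCatch(chol(M), error = function(e) {
    ridge <- 1e-10 * mean(diag(M))
    tryCatch(chol(M + diag(ridge, nrow(M))), error = function(e2)
      stop("ill-posed fit: the penalized system is singular even after ",
           "null-space constraints (collinear design or lambda too small).",
           call. = FALSE))
  })
  Minv_s <- chol2inv(R)
  coef <- (Minv_s %*% sys$bs) / sys$s
  edf <- sum(Minv_s * sys$As)
  rss <- sum((sys$z - sys$XX %*% coef)^2)
  Minv <- t(Minv_s / sys$s) / sys$s
  list(coef = coef, Minv = Minv, edf = edf, rss = rss, lambda = lambda)
}

# a solution whose effective degrees of freedom are numerically out of range
# (saturated or corrupted by ill-conditioning) is never an admissible
# smoothing solution
admissible <- function(sys, sol) {
  is.finite(sol$edf) && sol$edf >= max(sys$p - 0.5, 0) &&
    sol$edf <= 0.99 * min(sys$n, sys$q + 1)
}

gcv_score <- function(sys, sol) {
  if (!admissible(sys, sol)) return(1e300)
  denom <- max(sys$n - sol$edf, 1e-8)
  sys$n * sol$rss / denom^2
}

reml_score <- function(sys, sol, logdetDp = NULL) {
  if (!admissible(sys, sol)) return(1e300)
  gamma <- sol$coef[seq_len(sys$m - sys$p), 1]
  pen <- sol$lambda * sum(gamma * (sys$Dp %*% gamma))
  dev <- max(sol$rss + pen, 1e-300)
  Ms <- sys$As + sol$lambda * sys$Ds
  ld_M <- as.numeric(determinant(Ms, logarithm = TRUE)$modulus) +
    2 * sum(log(sys$s))
  if (is.null(logdetDp))
    logdetDp <- as.numeric(determinant(sys$Dp, logarithm = TRUE)$modulus)
  ld_pen <- (sys$m - sys$p) * log(sol$lambda) + logdetDp
  (sys$n - sys$p) * log(dev) + ld_M - ld_pen
}

#' Solve the constrained penalized least-squares system
#'
#' @param J,T,P Design matrices from [build_design()].
#' @param z Response vector.
#' @param lambda Positive smoothing parameter.
#' @param Tr Null-space basis at the representers (defaults to `T` when the
#'   representers are the observations).
#' @param weights Optional positive observation weights.
#' @return List with `alpha` (penalized coefficients, satisfying
#'   `t(Tr) %*% alpha = 0`), `beta` (null-space coefficients), `cov` (joint
#'   posterior covariance of `c(alpha, beta)`), `edf`, `sigma2`, `rss` and
#'   `fitted`.
#' @export
solve_penalized <- function(J, T, P, z, lambda, Tr = NULL, weights = NULL) {
  if (lambda <= 0) stop("`lambda` must be positive.", call. = FALSE)
  sys <- penalized_system(J, T, P, Tr, z, weights)
  sol <- solve_system(sys, lambda)
  finish_solution(sys, sol)
}

finish_solution <- function(sys, sol) {
  mp <- sys$m - sys$p
  gamma <- sol$coef[seq_len(mp), 1]
  beta <- if (sys$p > 0) sol$coef[mp + seq_len(sys$p), 1] else numeric(0)
  alpha <- as.numeric(sys$Z %*% gamma)
  sigma2 <- sol$rss / max(sys$n - sol$edf, 1e-8)
  # map reduced-coordinate covariance to the (alpha, beta) parameterization
  B <- matrix(0, sys$m + sys$p, sys$q)
  B[seq_len(sys$m), seq_len(mp)] <- sys$Z
  if (sys$p > 0) B[sys$m + seq_len(sys$p), mp + seq_len(sys$p)] <- diag(sys$p)
  cov <- sigma2 * (B %*% sol$Minv %*% t(B))
  cov <- (cov + t(cov)) / 2
  fitted <- as.numeric(sys$XX %*% sol$coef)
  list(alpha = alpha, beta = beta, coef = c(alpha, beta), cov = cov,
       edf = sol$edf, sigma2 = sigma2, rss = sol$rss, fitted = fitted,
       lambda = sol$lambda)
}

#' Select the smoothing parameter on a log grid with local refinement
#'
#' Evaluates the criterion (generalized cross-validation by default, or
#' REML) over a log-spaced grid and refines the minimizer by golden-section
#' search between its grid neighbours. Deterministic given its inputs; a
#' monotone criterion yields a boundary warning and the boundary value.
#'
#' @inheritParams solve_penalized
#' @param criterion `"gcv"` or `"reml"`.
#' @param grid Positive, increasing grid of candidate `lambda` values
#'   spanning at least 8 orders of magnitude.
#' @return The selected `lambda` (scalar, with the criterion value as
#'   attribute `"criterion_value"`).
#' @export
select_lambda <- function(J, T, P, z, criterion = c("gcv", "reml"),
                          grid = 10^seq(-9, 5, length.out = 29),
                          Tr = NULL, weights = NULL) {
  criterion <- match.arg(criterion)
  sys <- penalized_system(J, T, P, Tr, z, weights)
  select_lambda_sys(sys, criterion, grid)
}

select_lambda_sys <- function(sys, criterion,
                              grid = 10^seq(-9, 5, length.out = 29),
                              refine = TRUE) {
  if (log10(max(grid) / min(grid)) < 8)
    stop("`grid` must span at least 8 orders of magnitude.", call. = FALSE)
  logdetDp <- if (criterion == "reml")
    as.numeric(determinant(sys$Dp, logarithm = TRUE)$modulus) else NULL
  score_at <- function(lam) {
    sol <- solve_system(sys, lam)
    if (criterion == "gcv") gcv_score(sys, sol)
    else reml_score(sys, sol, logdetDp)
  }
  scores <- vapply(grid, score_at, numeric(1))
  i <- which.min(scores)
  if (i == 1L || i == length(grid)) {
    warning("boundary solution: the criterion is monotone over the grid; ",
            "returning the boundary lambda.")
    lam <- grid[i]
    attr(lam, "criterion_value") <- scores[i]
    return(lam)
  }
  if (!refine) {
    lam <- grid[i]
    attr(lam, "criterion_value") <- scores[i]
    return(lam)
  }
  opt <- stats::optimize(function(l10) score_at(10^l10),
                         interval = log10(grid[c(i - 1L, i + 1L)]),
                         tol = 1e-4)
  lam <- 10^opt$minimum
  if (opt$objective > scores[i]) { # guard: keep the grid minimum if better
    lam <- grid[i]
    attr(lam, "criterion_value") <- scores[i]
  } else {
    attr(lam, "criterion_value") <- opt$objective
  }
  lam
}

# validate and extract an observation set from a data frame
as_observations <- function(data, xcols, zcol) {
  miss <- setdiff(c(xcols, zcol), names(data))
  if (length(miss) > 0)
    stop(sprintf("column '%s' not found", miss[1]), call. = FALSE)
  sub <- data[, c(xcols, zcol)]
  for (cn in c(xcols, zcol)) {
    v <- sub[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop(sprintf("non-numeric value in column '%s' (row %s)", cn,
                   ifelse(is.na(bad), "?", bad)), call. = FALSE)
    }
  }
  keep <- stats::complete.cases(sub)
  if (any(!keep)) {
    message(sprintf("dropped %d row(s) with missing values", sum(!keep)))
    sub <- sub[keep, , drop = FALSE]
  }
  n <- nrow(sub); d <- length(xcols)
  if (n < d + 2)
    stop(sprintf("need at least %d complete observations, got %d", d + 2, n),
         call. = FALSE)
  list(X = as.matrix(sub[, xcols, drop = FALSE]),
       z = as.numeric(sub[[zcol]]),
       data = tibble::as_tibble(sub))
}

#' Fit a penalized spline to tabular observations
#'
#' Fits a thin-plate spline, a tensor-product smoothing spline ANOVA
#' kernel, or a univariate cubic smoothing spline to a data frame by
#' penalized least squares, selecting the smoothing parameter by GCV (the
#' default) or REML unless `lambda` is given. The returned object carries
#' the joint posterior covariance of all coefficients, from which component
#' decompositions ([posthoc_decompose()]) inherit their pointwise
#' uncertainties.
#'
#' @param data A data frame.
#' @param x,y,z Column names (strings). Set `y = NULL` for a univariate fit.
#' @param kernel `"tps"`, `"tensor"`, `"cubic"`, or an `ssa_kernel` object.
#' @param lambda Optional fixed smoothing parameter; selected when `NULL`.
#' @param theta Optional named block weights for tensor kernels.
#' @param criterion Smoothing selection criterion, `"gcv"` or `"reml"`.
#' @param knots Optional representer points (matrix). Defaults to the
#'   observations for n <= 1000 and to 200 quantile-spread knots otherwise.
#' @param measures Optional list of [quad_measure()]s for tensor centering.
#' @param weights Optional positive observation weights.
#' @param domain Optional covariate domain (2-row matrix); defaults to the
#'   observed range.
#' @return An object of class `spline_fit`.
#' @examples
#' d <- sim_dataset(1, n = 60, seed = 1)
#' fit <- fit_spline(d, kernel = "tps")
#' glance(fit)
#' @export
fit_spline <- function(data, x = "x", y = "y", z = "z",
                       kernel = c("tps", "tensor", "cubic"),
                       lambda = NULL, theta = NULL,
                       criterion = c("gcv", "reml"),
                       knots = NULL, measures = NULL, weights = NULL,
                       domain = NULL) {
  criterion <- match.arg(criterion)
  xcols <- c(x, y)
  obs <- as_observations(data, xcols, z)
  X <- obs$X; zv <- obs$z; n <- nrow(X)

  if (!inherits(kernel, "ssa_kernel")) {
    kind <- match.arg(kernel)
    if (is.null(domain)) {
      domain <- apply(X, 2, range)
      # guard zero-width domains
      w <- domain[2, ] - domain[1, ]
      domain[1, ] <- domain[1, ] - 1e-8 * pmax(w, 1)
      domain[2, ] <- domain[2, ] + 1e-8 * pmax(w, 1)
    }
    if (length(xcols) == 1 && kind != "cubic") kind <- "cubic"
    kernel <- switch(kind,
      tps = tps_kernel(domain),
      cubic = cubic_kernel(domain[, 1]),
      tensor = {
        kx <- cubic_kernel(domain[, 1]); ky <- cubic_kernel(domain[, 2])
        ms <- measures %||% default_measures(domain)
        tensor_kernel(kx, ky, measures = ms,
                      theta = theta %||% c(x = 1, y = 1, xy = 1))
      })
  }
  if (kernel$dim != length(xcols))
    stop("kernel dimension does not match the number of covariates.",
         call. = FALSE)

  if (is.null(knots)) {
    knots <- if (inherits(kernel, "ssa_tensor_kernel")) tensor_knots(X)
    else default_knots(X)
  }
  des <- build_design(kernel, X, knots)
  sys <- penalized_system(des$J, des$T, des$P, des$Tr, zv, weights)
  crit_value <- NA_real_
  if (is.null(lambda)) {
    lambda <- select_lambda_sys(sys, criterion)
    crit_value <- attr(lambda, "criterion_value")
    lambda <- as.numeric(lambda)
  }
  sol <- finish_solution(sys, solve_system(sys, lambda))

  structure(list(kernel = kernel, data = obs$data, xcols = xcols, zcol = z,
                 X = X, z = zv, representers = des$representers,
                 alpha = sol$alpha, beta = sol$beta, coef = sol$coef,
                 cov = sol$cov, lambda = lambda, criterion = criterion,
                 criterion_value = crit_value, edf = sol$edf,
                 sigma2 = sol$sigma2, rss = sol$rss, fitted = sol$fitted,
                 n = n),
            class = "spline_fit")
}

# design rows (over c(alpha, beta)) at arbitrary points
fit_rows <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  cbind(kernel_matrix(fit$kernel, Xnew, fit$representers),
        nullspace_matrix(fit$kernel, Xnew))
}

#' Predict from a fitted spline
#'
#' @param object A `spline_fit`.
#' @param newdata Data frame with the fit's covariate columns, or a matrix
#'   of points; defaults to the training data.
#' @param se_fit Compute pointwise posterior standard errors?
#' @param ... Unused.
#' @return A tibble with columns `.fitted` and (optionally) `.se`.
#' @export
predict.spline_fit <- function(object, newdata = NULL, se_fit = TRUE, ...) {
  Xnew <- if (is.null(newdata)) object$X
  else if (is.matrix(newdata)) newdata
  else as.matrix(newdata[, object$xcols, drop = FALSE])
  M <- fit_rows(object, Xnew)
  out <- tibble::tibble(.fitted = as.numeric(M %*% object$coef))
  if (se_fit) {
    v <- rowSums((M %*% object$cov) * M)
    out$.se <- sqrt(pmax(v, 0))
  }
  out
}

#' @export
print.spline_fit <- function(x, ...) {
  cat(sprintf("<spline_fit: %s kernel, n = %d, m = %d representers>\n",
              x$kernel$kind, x$n, nrow(x$representers)))
  cat(sprintf("  lambda = %.4g (%s), edf = %.2f, sigma^2 = %.4g\n",
              x$lambda, x$criterion, x$edf, x$sigma2))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics augment
#' @export
generics::augment

#' @method glance spline_fit
#' @export
glance.spline_fit <- function(x, ...) {
  tibble::tibble(kernel = x$kernel$kind, n = x$n, lambda = x$lambda,
                 edf = x$edf, sigma2 = x$sigma2, rss = x$rss,
                 criterion = x$criterion, criterion_value = x$criterion_value)
}

#' @method tidy spline_fit
#' @export
tidy.spline_fit <- function(x, ...) {
  tibble::tibble(term = x$kernel$kind,
                 edf = x$edf, lambda = x$lambda, sigma2 = x$sigma2)
}

#' @method augment spline_fit
#' @export
augment.spline_fit <- function(x, data = NULL, ...) {
  data <- data %||% x$data
  pr <- predict(x, newdata = data)
  dplyr::bind_cols(tibble::as_tibble(data), pr,
                   tibble::tibble(.resid = data[[x$zcol]] - pr$.fitted))
}
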