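# Additive mixed models: several smooth terms plus crossed random
# intercepts, fitted by one joint penalized least-squares solve.
#
# Every random-intercept factor enters as a ridge-penalized dummy block
# whose shrinkage parameter is tied to the variance components through
# lambda_factor = sigma^2 / sigma_factor^2 (the Bayesian spline/mixed-model
# equivalence); smooth terms get one shrinkage parameter each. All
# parameters are selected jointly by coordinate descent on REML (default)
# or GCV, giving a single coefficient vector with a joint posterior
# covariance from which any bivariate term can be decomposed post hoc.

#' Declare a smooth model term
#'
#' @param ... One or two covariate names (strings).
#' @param kernel `"cubic"` (univariate), `"tps"` (bivariate thin-plate) or
#'   `"tensor"` (bivariate interaction-only tensor block with its
#'   unpenalized bilinear direction).
#' @param k Basis size: number of knots (univariate) or target number of
#'   2-D knots (bivariate); defaults to 10 (univariate), 40 (tps),
#'   25 (tensor).
#' @param label Optional term label; defaults to `kernel(vars)`.
#' @return A term specification used by [fit_amm()].
#' @export
sm <- function(..., kernel = c("cubic", "tps", "tensor"), k = NULL,
               label = NULL) {
  vars <- unlist(list(...))
  kernel <- match.arg(kernel)
  if (kernel == "cubic" && length(vars) != 1)
    stop("cubic terms take exactly one covariate.", call. = FALSE)
  if (kernel %in% c("tps", "tensor") && length(vars) != 2)
    stop(kernel, " terms take exactly two covariates.", call. = FALSE)
  k <- k %||% switch(kernel, cubic = 10, tps = 40, tensor = 25)
  label <- label %||% paste0(kernel, "(", paste(vars, collapse = ","), ")")
  structure(list(vars = vars, kernel = kernel, k = k, label = label),
            class = "ssa_term")
}

padded_range <- function(v) {
  r <- range(v)
  w <- max(r[2] - r[1], 1e-8)
  c(r[1] - 1e-8 * w, r[2] + 1e-8 * w)
}

# build the design block of one smooth term; returns fixed columns (their
# parametric directions), penalized columns, penalty, and decomposition
# metadata
build_term <- function(term, data, quad_order = 16) {
  X <- as.matrix(data[, term$vars, drop = FALSE])
  if (term$kernel == "cubic") {
    dom <- as_domain(padded_range(X[, 1]), 1)
    kern <- cubic_kernel(dom)
    knots <- matrix(unique(stats::quantile(
      X[, 1], probs = seq(0, 1, length.out = term$k), names = FALSE)),
      ncol = 1)
    des <- build_design(kern, X, knots)
    p <- ncol(des$Tr)
    Z <- qr.Q(qr(des$Tr), complete = TRUE)[, (p + 1):nrow(knots), drop = FALSE]
    cols <- des$J %*% Z # zero-mean sections: no extra centering needed
    S <- crossprod(Z, des$P %*% Z)
    fixed <- matrix(kern$k1(X), ncol = 1,
                    dimnames = list(NULL, paste0("lin:", term$vars[1])))
    list(term = term, kernel = kern, knots = knots, Z = Z,
         fixed = fixed, cols = cols, S = (S + t(S)) / 2,
         center = rep(0, ncol(cols)), domain = dom)
  } else if (term$kernel == "tps") {
    dom <- cbind(padded_range(X[, 1]), padded_range(X[, 2]))
    kern <- tps_kernel(dom)
    knots <- default_knots(X, term$k, n_max = term$k)
    des <- build_design(kern, X, knots)
    p <- ncol(des$Tr)
    Z <- qr.Q(qr(des$Tr), complete = TRUE)[, (p + 1):nrow(knots), drop = FALSE]
    colsJ <- des$J %*% Z
    S <- crossprod(Z, des$P %*% Z)
    # centre penalized columns to zero double-average and the linear
    # directions to zero mean, absorbing the confound with the intercept
    ms <- default_measures(dom, quad_order)
    a <- as.numeric(avg_rows_AxAy(kern, knots, ms$x, ms$y)) # per-knot avg
    aZ <- as.numeric(a %*% Z)
    cols <- sweep(colsJ, 2, aZ, "-")
    U <- resc(X, dom)
    fixed <- cbind(U[, 1] - 0.5, U[, 2] - 0.5)
    colnames(fixed) <- paste0("lin:", term$vars)
    list(term = term, kernel = kern, knots = knots, Z = Z,
         fixed = fixed, cols = cols, S = (S + t(S)) / 2,
         center = aZ, measures = ms, domain = dom)
  } else { # tensor interaction block
    dom <- cbind(padded_range(X[, 1]), padded_range(X[, 2]))
    ms <- default_measures(dom, quad_order)
    tk <- tensor_kernel(cubic_kernel(dom[, 1]), cubic_kernel(dom[, 2]),
                        measures = ms)
    k_per <- max(3, round(sqrt(term$k)))
    knots <- marginal_grid_knots(X, k_per)
    cols <- tk$penal_block_kmat("xy", X, knots)
    S <- tk$penal_block_kmat("xy", knots, knots)
    fixed <- matrix(tk$k1x(X[, 1]) * tk$k1y(X[, 2]), ncol = 1,
                    dimnames = list(NULL,
                                    paste0("bilin:", paste(term$vars, collapse = ":"))))
    list(term = term, kernel = tk, knots = knots, Z = NULL,
         fixed = fixed, cols = cols, S = (S + t(S)) / 2,
         center = rep(0, ncol(cols)), measures = ms, domain = dom)
  }
}

# solve the multi-block penalized system at a given lambda vector
amm_solve <- function(sys, lambdas) {
  M <- sys$As
  for (b in seq_along(sys$blocks)) {
    idx <- sys$blocks[[b]]$idx_s
    M[idx, idx] <- M[idx, idx] + lambdas[b] * sys$blocks[[b]]$Ss
  }
  R <- tryCatch(chol(M), error = function(e)
    chol(M + diag(1e-9 * mean(diag(M)), nrow(M))))
  Minv_s <- chol2inv(R)
  coef <- (Minv_s %*% sys$bs) / sys$s
  edf <- sum(Minv_s * sys$As)
  rss <- sum((sys$z - sys$X %*% coef)^2)
  logdetM <- 2 * sum(log(diag(R))) + 2 * sum(log(sys$s))
  list(coef = coef, Minv_s = Minv_s, edf = edf, rss = rss,
       logdetM = logdetM)
}

amm_score <- function(sys, sol, lambdas, criterion) {
  n <- sys$n
  if (!is.finite(sol$edf) || sol$edf < 0 ||
      sol$edf > 0.99 * min(n, ncol(sys$X)))
    return(1e300)
  if (criterion == "gcv") {
    return(n * sol$rss / max(n - sol$edf, 1e-8)^2)
  }
  pen <- 0
  for (b in seq_along(sys$blocks)) {
    cb <- sol$coef[sys$blocks[[b]]$idx, 1]
    pen <- pen + lambdas[b] * sum(cb * (sys$blocks[[b]]$S %*% cb))
  }
  dev <- max(sol$rss + pen, 1e-300)
  ld_pen <- sum(vapply(seq_along(sys$blocks), function(b)
    ncol(sys$blocks[[b]]$S) * log(lambdas[b]), numeric(1)))
  (n - sys$p_fixed) * log(dev) + sol$logdetM - ld_pen
}

#' Fit an additive mixed model
#'
#' Fits `response = intercept + sum of smooth terms + random intercepts +
#' noise` by joint penalized least squares. Smooth terms are declared with
#' [sm()]; each carries its own shrinkage parameter. Random-intercept
#' factors become ridge-penalized dummy blocks; their shrinkage parameters
#' map to variance components via `sigma_f = sqrt(sigma^2 / lambda_f)`.
#' All shrinkage parameters are selected jointly by coordinate descent on
#' the criterion (REML by default), each coordinate solved by
#' golden-section search on the log scale.
#'
#' @param data A data frame.
#' @param response Response column name.
#' @param smooths List of [sm()] term declarations.
#' @param randoms Character vector of factor column names entering as
#'   random intercepts.
#' @param criterion `"reml"` (default) or `"gcv"`.
#' @param lambda Optional fixed vector of shrinkage parameters (one per
#'   penalized block, smooth terms first then random factors); selection
#'   is skipped when supplied.
#' @param sweeps Number of coordinate-descent sweeps.
#' @param quad_order Quadrature order used to centre bivariate terms.
#' @return An object of class `amm_fit`.
#' @export
fit_amm <- function(data, response, smooths, randoms = character(),
                    criterion = c("reml", "gcv"), lambda = NULL,
                    sweeps = 2, quad_order = 16) {
  criterion <- match.arg(criterion)
  if (length(smooths) < 1) stop("need at least one smooth term.", call. = FALSE)
  if (inherits(smooths, "ssa_term")) smooths <- list(smooths)
  z <- data[[response]]
  if (is.null(z)) stop(sprintf("column '%s' not found", response), call. = FALSE)
  keep <- stats::complete.cases(
    data[, c(response, unlist(lapply(smooths, `[[`, "vars")), randoms)])
  if (any(!keep)) {
    message(sprintf("dropped %d row(s) with missing values", sum(!keep)))
    data <- data[keep, , drop = FALSE]
    z <- z[keep]
  }
  n <- nrow(data)

  terms <- lapply(smooths, build_term, data = data, quad_order = quad_order)
  labels <- vapply(terms, function(t) t$term$label, character(1))
  if (anyDuplicated(labels))
    stop("duplicated term labels.", call. = FALSE)
  names(terms) <- labels

  # fixed (unpenalized) part: intercept + parametric directions of the
  # terms; a linear direction shared by two terms (e.g. the fixated word's
  # frequency appearing in both bivariate pairs) enters only once
  fixed <- matrix(rep(1, n), ncol = 1, dimnames = list(NULL, "(Intercept)"))
  for (t in terms) {
    new <- setdiff(colnames(t$fixed), colnames(fixed))
    if (length(new) > 0)
      fixed <- cbind(fixed, t$fixed[, new, drop = FALSE])
  }
  qrf <- qr(fixed)
  if (qrf$rank < ncol(fixed)) {
    aliased <- colnames(fixed)[qrf$pivot[(qrf$rank + 1):ncol(fixed)]]
    stop("rank-deficient fixed part; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  blocks <- lapply(terms, function(t)
    list(label = t$term$label, type = "smooth", cols = t$cols, S = t$S))
  for (f in randoms) {
    fac <- droplevels(as.factor(data[[f]]))
    if (nlevels(fac) < 2)
      stop(sprintf("random factor '%s' needs at least 2 levels", f),
           call. = FALSE)
    Zf <- stats::model.matrix(~ 0 + fac)
    colnames(Zf) <- paste0(f, ":", levels(fac))
    blocks[[paste0("random:", f)]] <-
      list(label = paste0("random:", f), type = "random", cols = Zf,
           S = diag(ncol(Zf)), factor = f, levels = levels(fac))
  }

  # assemble the joint design; normalize each penalty so lambda = 1 is a
  # balanced starting point
  p_fixed <- ncol(fixed)
  X <- cbind(fixed, do.call(cbind, lapply(blocks, `[[`, "cols")))
  off <- p_fixed
  for (b in seq_along(blocks)) {
    qb <- ncol(blocks[[b]]$cols)
    blocks[[b]]$idx <- off + seq_len(qb)
    xb <- X[, blocks[[b]]$idx, drop = FALSE]
    sc <- mean(colSums(xb^2)) / max(mean(diag(blocks[[b]]$S)), 1e-300)
    blocks[[b]]$S <- blocks[[b]]$S * sc
    blocks[[b]]$scale <- sc
    off <- off + qb
  }
  A <- crossprod(X)
  s <- sqrt(pmax(diag(A), 1e-300))
  As <- A / tcrossprod(s)
  bs <- crossprod(X, z) / s
  sys <- list(X = X, z = z, A = A, As = As, bs = bs, s = s, n = n,
              p_fixed = p_fixed, blocks = blocks)
  for (b in seq_along(sys$blocks)) {
    idx <- sys$blocks[[b]]$idx
    sys$blocks[[b]]$idx_s <- idx
    sys$blocks[[b]]$Ss <-
      sys$blocks[[b]]$S / tcrossprod(s[idx])
  }

  nb <- length(blocks)
  if (!is.null(lambda)) {
    if (length(lambda) != nb)
      stop(sprintf("`lambda` must have %d entries (one per block).", nb),
           call. = FALSE)
    # user-facing lambdas act on the raw penalty scale
    lambdas <- lambda / vapply(blocks, `[[`, numeric(1), "scale")
  } else {
    lambdas <- rep(1, nb)
    for (sw in seq_len(sweeps)) {
      for (b in seq_len(nb)) {
        obj <- function(l10) {
          lam <- lambdas; lam[b] <- 10^l10
          sol <- amm_solve(sys, lam)
          amm_score(sys, sol, lam, criterion)
        }
        opt <- stats::optimize(obj, interval = c(-6, 8), tol = 0.02)
        lambdas[b] <- 10^opt$minimum
      }
    }
  }
  sol <- amm_solve(sys, lambdas)
  sigma2 <- sol$rss / max(n - sol$edf, 1e-8)
  Minv <- t(sol$Minv_s / s) / s
  cov <- sigma2 * Minv
  cov <- (cov + t(cov)) / 2

  # variance components of the random factors
  vc <- list()
  for (b in seq_len(nb)) {
    if (blocks[[b]]$type == "random")
      vc[[blocks[[b]]$factor]] <-
        sqrt(sigma2 / (lambdas[b] * blocks[[b]]$scale))
  }

  # record the fixed-column indices attached to each term
  fix_names <- colnames(fixed)
  for (tl in labels) {
    terms[[tl]]$fixed_idx <-
      which(fix_names %in% colnames(terms[[tl]]$fixed))
  }

  structure(list(data = tibble::as_tibble(data), response = response,
                 terms = terms, blocks = blocks, randoms = randoms,
                 coef = as.numeric(sol$coef), cov = cov,
                 lambdas = lambdas, sigma2 = sigma2, edf = sol$edf,
                 rss = sol$rss, fitted = as.numeric(X %*% sol$coef),
                 sigma_factors = vc, criterion = criterion, n = n,
                 p_fixed = p_fixed, fixed_names = fix_names),
            class = "amm_fit")
}

#' @export
print.amm_fit <- function(x, ...) {
  cat(sprintf("<amm_fit: %d smooth term(s), %d random factor(s), n = %d>\n",
              length(x$terms), length(x$randoms), x$n))
  cat(sprintf("  edf = %.1f, sigma = %.4g (%s)\n", x$edf, sqrt(x$sigma2),
              x$criterion))
  for (f in names(x$sigma_factors))
    cat(sprintf("  sigma_%s = %.4g\n", f, x$sigma_factors[[f]]))
  invisible(x)
}

#' @method glance amm_fit
#' @export
glance.amm_fit <- function(x, ...) {
  tibble::tibble(n = x$n, edf = x$edf, sigma2 = x$sigma2, rss = x$rss,
                 criterion = x$criterion)
}

#' @method tidy amm_fit
#' @export
tidy.amm_fit <- function(x, ...) {
  nb <- names(x$blocks)
  tibble::tibble(
    block = nb,
    type = vapply(x$blocks, `[[`, character(1), "type"),
    lambda = x$lambdas / 1, # selected shrinkage per block
    size = vapply(x$blocks, function(b) ncol(b$cols), integer(1)),
    sigma = vapply(x$blocks, function(b)
      if (b$type == "random") sqrt(x$sigma2 / (x$lambdas[match(b$label, nb)] * b$scale))
      else NA_real_, numeric(1)))
}

# row matrix of one term's contribution (its penalized block + its own
# parametric directions) over the full coefficient vector
term_rows <- function(fit, label, X_new) {
  t <- fit$terms[[label]]
  if (is.null(t)) stop("unknown term: ", label, call. = FALSE)
  b <- fit$blocks[[label]]
  X_new <- as.matrix(X_new)
  M <- matrix(0, nrow(X_new), length(fit$coef))
  if (t$term$kernel == "cubic") {
    Jn <- kernel_matrix(t$kernel, X_new, t$knots) %*% t$Z
    M[, b$idx] <- Jn
    M[, t$fixed_idx] <- t$kernel$k1(X_new)
  } else if (t$term$kernel == "tps") {
    Jn <- kernel_matrix(t$kernel, X_new, t$knots) %*% t$Z
    M[, b$idx] <- sweep(Jn, 2, t$center, "-")
    U <- resc(X_new, t$domain)
    M[, t$fixed_idx] <- cbind(U[, 1] - 0.5, U[, 2] - 0.5)
  } else {
    M[, b$idx] <- t$kernel$penal_block_kmat("xy", X_new, t$knots)
    M[, t$fixed_idx] <- t$kernel$k1x(X_new[, 1]) * t$kernel$k1y(X_new[, 2])
  }
  M
}

#' Evaluate one smooth term of an additive mixed model
#'
#' Returns the term's partial effect (its penalized block plus its own
#' parametric directions, excluding the global intercept) at the given
#' covariate points, with pointwise posterior standard errors.
#'
#' @param fit An `amm_fit`.
#' @param label Term label (see `names(fit$terms)`).
#' @param points Matrix/data frame of covariate values for that term.
#' @return A tibble with `estimate` and `std_error`.
#' @export
term_effect <- function(fit, label, points) {
  t <- fit$terms[[label]]
  if (is.null(t)) stop("unknown term: ", label, call. = FALSE)
  pts <- if (is.data.frame(points)) as.matrix(points[, t$term$vars, drop = FALSE])
  else as.matrix(points)
  M <- term_rows(fit, label, pts)
  tibble::tibble(estimate = as.numeric(M %*% fit$coef),
                 std_error = sqrt(pmax(rowSums((M %*% fit$cov) * M), 0)))
}

#' Post-hoc decomposition of a bivariate thin-plate term of an AMM
#'
#' Extracts the term's coefficients and their covariance sub-block and
#' applies the averaging-operator decomposition to the term alone; the
#' resulting main effects are partial effects in the presence of the
#' model's other terms. The term's contribution to the model intercept
#' (its double average) appears as the decomposition's intercept.
#'
#' @param fit An `amm_fit`.
#' @param label Label of a bivariate `"tps"` term.
#' @param measures Optional decomposition measures; default Lebesgue on the
#'   term's domain.
#' @param quad_order Quadrature order of the default measures.
#' @return An `ssa_decomposition` of the term.
#' @export
decompose_pair <- function(fit, label, measures = NULL, quad_order = 32) {
  stopifnot(inherits(fit, "amm_fit"))
  t <- fit$terms[[label]]
  if (is.null(t)) stop("unknown term: ", label, call. = FALSE)
  if (t$term$kernel != "tps" || length(t$term$vars) != 2)
    stop("decompose_pair() needs a bivariate thin-plate term.", call. = FALSE)
  b <- fit$blocks[[label]]
  idx <- c(b$idx, t$fixed_idx)
  coef_sub <- fit$coef[idx]
  cov_sub <- fit$cov[idx, idx, drop = FALSE]

  # map (gamma, beta_lin1, beta_lin2) to the (alpha, beta0, beta1, beta2)
  # parameterization over the uncentred kernel columns and null space
  m <- nrow(t$knots); q <- ncol(t$Z)
  L <- matrix(0, m + 3, q + 2)
  L[seq_len(m), seq_len(q)] <- t$Z
  L[m + 1, seq_len(q)] <- -t$center       # constant from column centring
  L[m + 1, q + 1] <- -0.5                 # constant part of (u1 - 1/2)
  L[m + 1, q + 2] <- -0.5
  L[m + 2, q + 1] <- 1
  L[m + 3, q + 2] <- 1
  coef_ext <- as.numeric(L %*% coef_sub)
  cov_ext <- L %*% cov_sub %*% t(L)

  measures <- measures %||% default_measures(t$domain, quad_order)
  carrier <- make_carrier(t$kernel, t$knots, t$kernel$nullspace,
                          coef_ext, cov_ext, t$domain)
  new_decomposition(posthoc_components(carrier, measures), carrier,
                    measures, "posthoc", t$term$vars)
}
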