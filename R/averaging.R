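# Averaging operators applied to reproducing kernels.
#
# For a bivariate kernel K(., .; s) with source point s, the operators
#   Ay K (x; s) = int K((x, t); s) dmu_y(t)
#   Ax K (y; s) = int K((t, y); s) dmu_x(t)
#   AxAy K (s)  = int int K((t, u); s) dmu_x(t) dmu_y(u)
# are evaluated by the measures' quadrature rules. Row matrices of averaged
# kernels over all representers are what turns a fitted spline's coefficient
# vector into ANOVA components and their posterior variances.

which_ops <- c("Ax", "Ay", "AxAy", "main_x", "main_y", "interaction")

# G x m matrix of Ay K(x_g; s_j) for x values xs and source points S.
# A kernel may carry an `avg_hook(which, points, sources, measure)`
# returning closed-form averaged values (or NULL to decline); otherwise
# the measure's quadrature rule is applied.
avg_rows_Ay <- function(kernel, xs, S, my) {
  if (!is.null(kernel$avg_hook)) {
    out <- kernel$avg_hook("Ay", xs, S, my)
    if (!is.null(out)) return(out)
  }
  Q <- length(my$nodes); G <- length(xs)
  pts <- cbind(rep(xs, each = Q), rep(my$nodes, times = G))
  K <- kernel_matrix(kernel, pts, S)
  unname(rowsum(K * rep(my$weights, times = G), rep(seq_len(G), each = Q)))
}

avg_rows_Ax <- function(kernel, ys, S, mx) {
  if (!is.null(kernel$avg_hook)) {
    out <- kernel$avg_hook("Ax", ys, S, mx)
    if (!is.null(out)) return(out)
  }
  Q <- length(mx$nodes); G <- length(ys)
  pts <- cbind(rep(mx$nodes, times = G), rep(ys, each = Q))
  K <- kernel_matrix(kernel, pts, S)
  unname(rowsum(K * rep(mx$weights, times = G), rep(seq_len(G), each = Q)))
}

# 1 x m row of the double average
avg_rows_AxAy <- function(kernel, S, mx, my) {
  if (!is.null(kernel$avg_hook)) {
    out <- kernel$avg_hook("AxAy", NULL, S, list(x = mx, y = my))
    if (!is.null(out)) return(out)
  }
  w <- my$weights
  rows <- avg_rows_Ay(kernel, mx$nodes, S, my)
  matrix(mx$weights %*% rows, nrow = 1)
}

# same three averages for a list of null-space basis functions
ns_rows_Ay <- function(nsfuns, xs, my) {
  if (length(nsfuns) == 0) return(matrix(0, length(xs), 0))
  Q <- length(my$nodes); G <- length(xs)
  pts <- cbind(rep(xs, each = Q), rep(my$nodes, times = G))
  M <- do.call(cbind, lapply(nsfuns, function(f) f(pts)))
  unname(rowsum(M * rep(my$weights, times = G), rep(seq_len(G), each = Q)))
}

ns_rows_Ax <- function(nsfuns, ys, mx) {
  if (length(nsfuns) == 0) return(matrix(0, length(ys), 0))
  Q <- length(mx$nodes); G <- length(ys)
  pts <- cbind(rep(mx$nodes, times = G), rep(ys, each = Q))
  M <- do.call(cbind, lapply(nsfuns, function(f) f(pts)))
  unname(rowsum(M * rep(mx$weights, times = G), rep(seq_len(G), each = Q)))
}

ns_rows_AxAy <- function(nsfuns, mx, my) {
  if (length(nsfuns) == 0) return(matrix(0, 1, 0))
  rows <- ns_rows_Ay(nsfuns, mx$nodes, my)
  matrix(mx$weights %*% rows, nrow = 1)
}

#' Apply an averaging operator to a reproducing kernel
#'
#' Returns the averaged kernel as a function of the non-integrated
#' argument(s), with the source point(s) fixed: e.g. `which = "AxAy"` gives
#' the scalar `AxAy K(.; s)` per source, `which = "Ay"` a function of `x`
#' per source, and the projector combinations `"main_x"` (`Ay(1 - Ax)`),
#' `"main_y"` (`Ax(1 - Ay)`) and `"interaction"` (`(1 - Ax)(1 - Ay)`) the
#' corresponding residual averages. A kernel may provide an
#' `analytic_average(which, points, sources, measures)` override; otherwise
#' the measures' quadrature rules are used.
#'
#' @param kernel A bivariate `ssa_kernel`.
#' @param which One of `"Ax"`, `"Ay"`, `"AxAy"`, `"main_x"`, `"main_y"`,
#'   `"interaction"`.
#' @param measures List of [quad_measure()]s `x` and `y`.
#' @param check If `TRUE`, verify the quadrature by doubling the order on a
#'   small probe set; disagreement beyond `tol` triggers one refinement and
#'   then an error.
#' @param tol Tolerance for the refinement check.
#' @return An object of class `ssa_averaged_kernel` with an
#'   `$evaluate(points, sources)` element returning the matrix of averaged
#'   kernel values (rows = evaluation points, columns = sources). For
#'   `"AxAy"` the single row is returned regardless of `points`.
#' @export
average_kernel <- function(kernel, which = which_ops, measures,
                           check = FALSE, tol = 1e-6) {
  which <- match.arg(which)
  stopifnot(inherits(kernel, "ssa_kernel"))
  if (kernel$dim != 2L)
    stop("average_kernel() expects a bivariate kernel.", call. = FALSE)
  if (which %in% c("Ax", "AxAy", "main_x", "main_y", "interaction"))
    check_measure(measures$x, "measures$x")
  if (which %in% c("Ay", "AxAy", "main_x", "main_y", "interaction"))
    check_measure(measures$y, "measures$y")

  eval_with <- function(ms) {
    force(ms)
    function(points, sources) {
      sources <- as.matrix(sources)
      if (!is.null(kernel$analytic_average)) {
        out <- kernel$analytic_average(which, points, sources, ms)
        if (!is.null(out)) return(out)
      }
      switch(which,
        Ay = avg_rows_Ay(kernel, as.numeric(points), sources, ms$y),
        Ax = avg_rows_Ax(kernel, as.numeric(points), sources, ms$x),
        AxAy = avg_rows_AxAy(kernel, sources, ms$x, ms$y),
        main_x = {
          a <- avg_rows_Ay(kernel, as.numeric(points), sources, ms$y)
          m0 <- avg_rows_AxAy(kernel, sources, ms$x, ms$y)
          sweep(a, 2, as.numeric(m0), "-")
        },
        main_y = {
          a <- avg_rows_Ax(kernel, as.numeric(points), sources, ms$x)
          m0 <- avg_rows_AxAy(kernel, sources, ms$x, ms$y)
          sweep(a, 2, as.numeric(m0), "-")
        },
        interaction = {
          P <- as.matrix(points)
          K <- kernel_matrix(kernel, P, sources)
          ay <- avg_rows_Ay(kernel, P[, 1], sources, ms$y)
          ax <- avg_rows_Ax(kernel, P[, 2], sources, ms$x)
          m0 <- avg_rows_AxAy(kernel, sources, ms$x, ms$y)
          sweep(K - ay - ax, 2, -as.numeric(m0), "-")
        })
    }
  }

  evaluate <- eval_with(measures)
  if (check) {
    refined <- lapply(measures, function(m) {
      if (m$kind == "lebesgue")
        quad_measure("lebesgue", m$domain, order = 2 * length(m$nodes))
      else m
    })
    eval2 <- eval_with(refined)
    dom <- kernel$domain
    probe_1 <- seq(dom[1, 1], dom[2, 1], length.out = 5)
    probe_2 <- cbind(probe_1, seq(dom[1, 2], dom[2, 2], length.out = 5))
    probe <- if (which %in% c("Ax", "main_y")) {
      seq(dom[1, 2], dom[2, 2], length.out = 5)
    } else if (which %in% c("Ay", "main_x")) probe_1 else probe_2
    src <- matrix(c(mean(dom[, 1]), mean(dom[, 2])), 1)
    dev <- max(abs(evaluate(probe, src) - eval2(probe, src)))
    if (dev > tol) {
      warning(sprintf(
        "quadrature disagreement %.3g > %.3g; refining the rule once", dev, tol))
      refined2 <- lapply(refined, function(m) {
        if (m$kind == "lebesgue")
          quad_measure("lebesgue", m$domain, order = 2 * length(m$nodes))
        else m
      })
      eval4 <- eval_with(refined2)
      dev2 <- max(abs(eval2(probe, src) - eval4(probe, src)))
      if (dev2 > tol)
        stop(sprintf("quadrature failed to converge (residual %.3g)", dev2),
             call. = FALSE)
      evaluate <- eval2
      measures <- refined
    }
  }

  structure(list(base = kernel, which = which, measures = measures,
                 evaluate = evaluate),
            class = "ssa_averaged_kernel")
}

#' @export
print.ssa_averaged_kernel <- function(x, ...) {
  cat(sprintf("<ssa_averaged_kernel: %s applied to %s kernel>\n",
              x$which, x$base$kind))
  invisible(x)
}
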