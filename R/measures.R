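#' Quadrature probability measures on an interval
#'
#' A measure is the numerical object behind every averaging operator: a set of
#' nodes and non-negative weights summing to one on a closed interval.
#' `lebesgue` measures discretize the uniform distribution by Gauss--Legendre
#' quadrature (exact for polynomials up to degree `2 * order - 1`);
#' `empirical` measures place equal mass on observed covariate values, which
#' lets the ANOVA constraints follow the distribution of the data instead of
#' the uniform one; `custom` accepts explicit nodes and weights.
#'
#' @param kind One of `"lebesgue"`, `"empirical"`, `"custom"`.
#' @param domain Length-2 numeric, the closed interval carrying the measure.
#' @param order Number of Gauss--Legendre nodes for `kind = "lebesgue"`.
#' @param sample Numeric vector of observed values for `kind = "empirical"`.
#' @param nodes,weights Explicit quadrature rule for `kind = "custom"`;
#'   weights are renormalized to sum to one and must be non-negative.
#'
#' @return An object of class `ssa_measure`: a list with elements `kind`,
#'   `nodes`, `weights` and `domain`.
#' @examples
#' mu <- quad_measure("lebesgue", c(0, 1), order = 16)
#' sum(mu$weights * mu$nodes) # E[x] = 1/2
#' @export
quad_measure <- function(kind = c("lebesgue", "empirical", "custom"),
                         domain = c(0, 1), order = 32,
                         sample = NULL, nodes = NULL, weights = NULL) {
  kind <- match.arg(kind)
  domain <- as.numeric(domain)
  if (length(domain) != 2 || !all(is.finite(domain)) || diff(domain) <= 0)
    stop("`domain` must be a finite interval of positive width.", call. = FALSE)
  if (kind == "lebesgue") {
    if (order < 2) stop("`order` must be at least 2.", call. = FALSE)
    gl <- pracma::gaussLegendre(order, domain[1], domain[2])
    nodes <- gl$x
    weights <- gl$w / diff(domain) # total mass 1
  } else if (kind == "empirical") {
    if (is.null(sample) || length(sample) == 0)
      stop("`sample` must be a non-empty numeric vector.", call. = FALSE)
    if (any(sample < domain[1] - 1e-12) || any(sample > domain[2] + 1e-12))
      stop("`sample` contains values outside `domain`.", call. = FALSE)
    nodes <- as.numeric(sample)
    weights <- rep(1 / length(nodes), length(nodes))
  } else {
    if (is.null(nodes) || is.null(weights) || length(nodes) != length(weights))
      stop("custom measures need `nodes` and `weights` of equal length.",
           call. = FALSE)
    if (any(weights < 0)) stop("weights must be non-negative.", call. = FALSE)
    s <- sum(weights)
    if (s <= 0) stop("weights must have positive total mass.", call. = FALSE)
    weights <- weights / s
  }
  structure(list(kind = kind, nodes = nodes, weights = weights,
                 domain = domain),
            class = "ssa_measure")
}

#' @export
print.ssa_measure <- function(x, ...) {
  cat(sprintf("<ssa_measure: %s on [%g, %g], %d nodes>\n",
              x$kind, x$domain[1], x$domain[2], length(x$nodes)))
  invisible(x)
}

is_measure <- function(x) inherits(x, "ssa_measure")

check_measure <- function(x, arg = "measure") {
  if (!is_measure(x))
    stop(sprintf("`%s` must be built with quad_measure().", arg), call. = FALSE)
  if (abs(sum(x$weights) - 1) > 1e-12)
    stop(sprintf("`%s` is not normalized to total mass 1.", arg), call. = FALSE)
  invisible(x)
}

# mean of f under the measure; f vectorized over nodes
measure_mean <- function(measure, f) {
  v <- f(measure$nodes)
  if (any(!is.finite(v))) {
    bad <- measure$nodes[which(!is.finite(v))[1]]
    stop(sprintf("non-finite function value at quadrature node %g", bad),
         call. = FALSE)
  }
  sum(measure$weights * v)
}

#' Apply an averaging operator to a bivariate function
#'
#' Computes marginal or double averages of `f(x, y)` under probability
#' measures, i.e. the operators `Ax f(y) = int f(x, y) dmu_x(x)`,
#' `Ay f(x) = int f(x, y) dmu_y(y)` and their composition `AxAy`.
#' These are the building blocks of the functional ANOVA projectors:
#' the intercept of a surface is `AxAy f`, the x main effect is
#' `Ay(1 - Ax) f`, and so on.
#'
#' @param f Vectorized function of two numeric vectors `(x, y)`.
#' @param which One of `"Ax"`, `"Ay"`, `"AxAy"`.
#' @param measures List with elements `x` and `y`, each an [quad_measure()]
#'   (only the axis being integrated is required).
#'
#' @return For `"Ay"` a function of `x`; for `"Ax"` a function of `y`;
#'   for `"AxAy"` a function returning the scalar average regardless of
#'   its argument.
#' @examples
#' mus <- list(x = quad_measure("lebesgue"), y = quad_measure("lebesgue"))
#' avg <- average_function(function(x, y) x * y, "AxAy", mus)
#' avg() # 1/4
#' @export
average_function <- function(f, which = c("Ay", "Ax", "AxAy"),
                             measures) {
  which <- match.arg(which)
  if (which %in% c("Ax", "AxAy")) check_measure(measures$x, "measures$x")
  if (which %in% c("Ay", "AxAy")) check_measure(measures$y, "measures$y")
  check_nodes <- function(v, nodes) {
    if (any(!is.finite(v))) {
      stop(sprintf("non-finite function value at quadrature node %g",
                   nodes[which(!is.finite(rowSums(matrix(v, ncol = 1))))[1]]),
           call. = FALSE)
    }
    v
  }
  if (which == "Ay") {
    my <- measures$y
    function(x) {
      vapply(x, function(xi)
        sum(my$weights * check_nodes(f(rep(xi, length(my$nodes)), my$nodes),
                                     my$nodes)),
        numeric(1))
    }
  } else if (which == "Ax") {
    mx <- measures$x
    function(y) {
      vapply(y, function(yi)
        sum(mx$weights * check_nodes(f(mx$nodes, rep(yi, length(mx$nodes))),
                                     mx$nodes)),
        numeric(1))
    }
  } else {
    mx <- measures$x; my <- measures$y
    gx <- rep(mx$nodes, times = length(my$nodes))
    gy <- rep(my$nodes, each = length(mx$nodes))
    w <- rep(mx$weights, times = length(my$nodes)) *
      rep(my$weights, each = length(mx$nodes))
    val <- sum(w * check_nodes(f(gx, gy), gx))
    function(...) val
  }
}

# default pair of Lebesgue measures on given 2-column domain matrix
default_measures <- function(domain, order = 32) {
  list(x = quad_measure("lebesgue", domain[, 1], order = order),
       y = quad_measure("lebesgue", domain[, 2], order = order))
}

#' Serialize / deserialize measure specifications
#'
#' Measure specifications round-trip through plain lists suitable for YAML
#' configuration blocks: `{kind: lebesgue, order: N}` or
#' `{kind: empirical, column: name}` (the sample is taken from `data`).
#'
#' @param measure An [quad_measure()].
#' @return `measure_to_config()`: a named list; `measure_from_config()`:
#'   an `ssa_measure`.
#' @export
measure_to_config <- function(measure) {
  check_measure(measure)
  cfg <- list(kind = measure$kind, domain = as.numeric(measure$domain))
  if (measure$kind == "lebesgue") cfg$order <- length(measure$nodes)
  cfg
}

#' @param config A named list (e.g. parsed from YAML) with at least `kind`.
#' @param domain Interval for the measure; defaults to the config's.
#' @param data Data frame supplying the `column` of an empirical measure.
#' @rdname measure_to_config
#' @export
measure_from_config <- function(config, domain = NULL, data = NULL) {
  kind <- match.arg(config$kind, c("lebesgue", "empirical", "custom"))
  domain <- as.numeric(domain %||% config$domain)
  if (kind == "lebesgue")
    return(quad_measure("lebesgue", domain, order = config$order %||% 32))
  if (kind == "empirical") {
    if (is.null(data) || is.null(config$column) ||
        is.null(data[[config$column]]))
      stop("empirical measure configs need `data` with the named `column`.",
           call. = FALSE)
    return(quad_measure("empirical", domain, sample = data[[config$column]]))
  }
  quad_measure("custom", domain, nodes = as.numeric(config$nodes),
               weights = as.numeric(config$weights))
}
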