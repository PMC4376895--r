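# shared fixtures, all generated in code
unit_dom <- cbind(c(0, 1), c(0, 1))

leb <- function(order = 32, dom = c(0, 1))
  quad_measure("lebesgue", dom, order = order)

leb2 <- function(order = 32) list(x = leb(order), y = leb(order))

# small example-1 dataset, deterministic
tiny_data <- function(n = 60, seed = 42, noise_var = 0.25, example = 1)
  sim_dataset(example, n = n, noise_var = noise_var, seed = seed)

# a minimal 2-D constant kernel for degenerate-case checks
const_kernel_2d <- function() {
  structure(list(kind = "const", dim = 2L, domain = unit_dom,
                 kmat = function(X1, X2)
                   matrix(1, nrow(as.matrix(X1)), nrow(as.matrix(X2))),
                 nullspace = list()),
            class = "ssa_kernel")
}

# L2 inner product of two component evaluators under the product measure
component_inner <- function(f, g, mx, my) {
  gx <- rep(mx$nodes, times = length(my$nodes))
  gy <- rep(my$nodes, each = length(mx$nodes))
  w <- rep(mx$weights, times = length(my$nodes)) *
    rep(my$weights, each = length(mx$nodes))
  sum(w * f(gx, gy) * g(gx, gy))
}

# wrap a decomposition component as a bivariate function
comp_fun <- function(dec, label) {
  comp <- dec$components[[label]]
  switch(label,
    intercept = function(x, y) rep(comp$evaluate(NULL), length(x)),
    main_x = function(x, y) comp$evaluate(x),
    main_y = function(x, y) comp$evaluate(y),
    interaction = function(x, y) comp$evaluate(cbind(x, y)))
}

# draw from N(mean, cov) robustly (cov may have tiny negative eigenvalues)
mvn_draws <- function(n, mean, cov, seed) {
  set.seed(seed)
  eg <- eigen(cov, symmetric = TRUE)
  U <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  sweep(matrix(rnorm(n * length(mean)), n) %*% t(U), 2, mean, "+")
}
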