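# Synthetic single-fixation reading data and the subset-resampling study.
#
# The generator emulates the covariate and random-effect structure of
# first-pass single-fixation durations: a log-duration response driven by
# the incoming saccade amplitude, the log lengths of the previous, fixated
# and next word, two bivariate word-frequency effects (previous-with-
# fixated and fixated-with-next), plus crossed random intercepts for
# readers and for fixated words. It stands in for a real corpus; all
# effect shapes and variance components are known, so recovery can be
# tested exactly.

default_reading_effects <- function() {
  list(
    A = function(a) 0.025 * (a - 7),
    l_prev = function(l) 0.03 * (l - 1.5),
    l_n = function(l) 0.08 * (l - 1.5),
    l_next = function(l) 0.02 * (l - 1.5),
    # previous-word frequency: monotone decreasing; fixated word:
    # non-monotonic; next word: weak
    pair_prev = function(v1, v2)
      -0.06 * (v1 - 1.5) + 0.03 * sin(2 * pi * v2 / 3) +
        0.05 * exp(-((v1 - 0.8)^2 + (v2 - 1.6)^2) / 0.4),
    pair_next = function(v2, v3)
      0.03 * sin(2 * pi * v2 / 3) - 0.02 * (v3 - 1.5) +
        0.04 * exp(-((v2 - 2.2)^2 + (v3 - 2.2)^2) / 0.4))
}

#' Generate synthetic single-fixation reading data
#'
#' Simulates log fixation durations `tau` on a fixated word N with the
#' covariates of the reading models: incoming saccade amplitude `A`
#' (letters), log word lengths `l_prev`, `l_n`, `l_next` and log word
#' frequencies `nu_prev`, `nu_n`, `nu_next` (all on \[0, 3\]), a `reader`
#' factor and a `word` factor. The response is the sum of the effect
#' functions, a reader random intercept (sd `sigma_id`), a word random
#' intercept (sd `sigma_w`) and Gaussian noise (sd `sigma_eps`). Length
#' and frequency of the fixated word are word properties (drawn once per
#' word); neighbour covariates vary per fixation.
#'
#' @param n_obs Number of fixations.
#' @param n_readers,n_words Number of reader / word levels.
#' @param effects Named list of effect functions (`A`, `l_prev`, `l_n`,
#'   `l_next`, bivariate `pair_prev(nu_prev, nu_n)` and
#'   `pair_next(nu_n, nu_next)`); sensible smooth defaults are used when
#'   `NULL`.
#' @param sigma_id,sigma_w,sigma_eps Random-intercept and residual sds.
#' @param intercept Baseline log duration.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A tibble with the columns listed above plus `tau`.
#' @export
synth_reading_data <- function(n_obs = 5000, n_readers = 50, n_words = 200,
                               effects = NULL, sigma_id = 0.2,
                               sigma_w = 0.1, sigma_eps = 0.3,
                               intercept = 5.3, seed = 1) {
  stopifnot(sigma_id >= 0, sigma_w >= 0, sigma_eps > 0)
  eff <- utils::modifyList(default_reading_effects(), effects %||% list())
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  word_len <- stats::runif(n_words, 0, 3)
  word_freq <- stats::runif(n_words, 0, 3)
  r_id <- stats::rnorm(n_readers, sd = sigma_id)
  r_w <- stats::rnorm(n_words, sd = sigma_w)

  reader <- sample.int(n_readers, n_obs, replace = TRUE)
  word <- sample.int(n_words, n_obs, replace = TRUE)
  A <- stats::runif(n_obs, 2, 12)
  l_prev <- stats::runif(n_obs, 0, 3)
  l_next <- stats::runif(n_obs, 0, 3)
  nu_prev <- stats::runif(n_obs, 0, 3)
  nu_next <- stats::runif(n_obs, 0, 3)
  l_n <- word_len[word]
  nu_n <- word_freq[word]

  tau <- intercept + eff$A(A) + eff$l_prev(l_prev) + eff$l_n(l_n) +
    eff$l_next(l_next) + eff$pair_prev(nu_prev, nu_n) +
    eff$pair_next(nu_n, nu_next) + r_id[reader] + r_w[word] +
    stats::rnorm(n_obs, sd = sigma_eps)

  tibble::tibble(tau = tau, A = A,
                 l_prev = l_prev, l_n = l_n, l_next = l_next,
                 nu_prev = nu_prev, nu_n = nu_n, nu_next = nu_next,
                 reader = factor(reader), word = factor(word))
}

#' Smooth-term lists of the two reading models
#'
#' `"tps"` mirrors the model whose two word-frequency pairs enter as
#' bivariate thin-plate terms (decomposed post hoc); `"tensor"` mirrors
#' the model with explicit univariate frequency main effects plus
#' tensor-product interaction blocks.
#'
#' @param method `"tps"` or `"tensor"`.
#' @param k_pair Basis size of each bivariate frequency term.
#' @return A list of [sm()] declarations for [fit_amm()].
#' @export
reading_model_terms <- function(method = c("tps", "tensor"), k_pair = 30) {
  method <- match.arg(method)
  base <- list(sm("A"), sm("l_prev"), sm("l_n"), sm("l_next"))
  if (method == "tps") {
    c(base, list(
      sm("nu_prev", "nu_n", kernel = "tps", k = k_pair, label = "pair_prev"),
      sm("nu_n", "nu_next", kernel = "tps", k = k_pair, label = "pair_next")))
  } else {
    c(base, list(
      sm("nu_prev"), sm("nu_n"), sm("nu_next"),
      sm("nu_prev", "nu_n", kernel = "tensor", k = k_pair,
         label = "pair_prev"),
      sm("nu_n", "nu_next", kernel = "tensor", k = k_pair,
         label = "pair_next")))
  }
}

#' Subset-resampling comparison of the two reading models
#'
#' Repeatedly fits the reading model to random subsets (drawn without
#' replacement) and evaluates the two word-frequency interaction
#' components on a fixed grid: for the `"tps"` method the interaction is
#' the post-hoc `(1 - Ax)(1 - Ay)` component of each bivariate term; for
#' the `"tensor"` method it is the explicit tensor interaction term.
#' The across-subset trace (sum over grid points of the across-subset
#' variance) summarizes each method's variability.
#'
#' @param data A reading data table (see [synth_reading_data()]).
#' @param subset_size Rows per subset (no default: pick it consciously).
#' @param reps Number of subsets.
#' @param seed Base seed for subset draws.
#' @param methods Subset of `c("tps", "tensor")`.
#' @param grid_n Interaction grid resolution per axis.
#' @param k_pair,sweeps Passed to the model builders / [fit_amm()].
#' @return An object of class `ssa_subset_study` with per-subset grid
#'   evaluations, across-subset traces, and a tidy `summary` table.
#' @export
subset_study <- function(data, subset_size, reps = 20, seed = 1,
                         methods = c("tps", "tensor"), grid_n = 15,
                         k_pair = 30, sweeps = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (subset_size > nrow(data))
    stop("`subset_size` exceeds the number of rows.", call. = FALSE)
  pairs <- c("pair_prev", "pair_next")
  rng <- function(v) stats::quantile(v, c(0.05, 0.95))
  grids <- list(
    pair_prev = as.matrix(expand.grid(
      seq(rng(data$nu_prev)[1], rng(data$nu_prev)[2], length.out = grid_n),
      seq(rng(data$nu_n)[1], rng(data$nu_n)[2], length.out = grid_n))),
    pair_next = as.matrix(expand.grid(
      seq(rng(data$nu_n)[1], rng(data$nu_n)[2], length.out = grid_n),
      seq(rng(data$nu_next)[1], rng(data$nu_next)[2], length.out = grid_n))))

  vals <- list()
  skipped <- list()
  for (m in methods) for (p in pairs)
    vals[[m]][[p]] <- matrix(NA_real_, reps, grid_n^2)

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (r in seq_len(reps)) {
    set.seed(rep_seed(seed, r))
    idx <- sample.int(nrow(data), subset_size, replace = FALSE)
    sub <- data[idx, , drop = FALSE]
    for (m in methods) {
      res <- tryCatch({
        fit <- fit_amm(sub, "tau", reading_model_terms(m, k_pair),
                       randoms = c("reader", "word"), sweeps = sweeps)
        lapply(pairs, function(p) {
          if (m == "tps") {
            dec <- decompose_pair(fit, p)
            dec$components$interaction$evaluate(grids[[p]])
          } else {
            term_effect(fit, p, grids[[p]])$estimate
          }
        })
      }, error = function(e) e)
      if (inherits(res, "error")) {
        skipped <- c(skipped, list(list(rep = r, method = m,
                                        message = conditionMessage(res))))
        next
      }
      for (i in seq_along(pairs)) vals[[m]][[pairs[i]]][r, ] <- res[[i]]
    }
  }

  summarise_one <- function(m, p) {
    V <- vals[[m]][[p]]
    V <- V[stats::complete.cases(V), , drop = FALSE]
    tibble::tibble(method = m, pair = p, n_fits = nrow(V),
                   trace = if (nrow(V) >= 2) sum(apply(V, 2, stats::var))
                   else NA_real_,
                   mean_abs = mean(abs(colMeans(V))),
                   sd_mean = mean(apply(V, 2, stats::sd)))
  }
  summary <- dplyr::bind_rows(
    lapply(methods, function(m)
      dplyr::bind_rows(lapply(pairs, function(p) summarise_one(m, p)))))
  structure(list(methods = methods, pairs = pairs, grids = grids,
                 values = vals, summary = summary, skipped = skipped,
                 subset_size = subset_size, reps = reps, seed = seed),
            class = "ssa_subset_study")
}

#' @export
print.ssa_subset_study <- function(x, ...) {
  cat(sprintf("<ssa_subset_study: %d subsets of size %d>\n",
              x$reps, x$subset_size))
  print(x$summary)
  if (length(x$skipped) > 0)
    cat(sprintf("  %d fit(s) skipped\n", length(x$skipped)))
  invisible(x)
}
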