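# Tabular input, component output, YAML configuration and the command-line
# dispatch shared by the fitting/decomposition/simulation tools.

#' Read observations from a delimited file
#'
#' Reads a CSV/TSV file, maps the named columns onto covariate/response
#' roles, validates them (numeric, no missing values; incomplete rows are
#' dropped with a message) and returns a tibble with standardized column
#' names.
#'
#' @param path File path (`.tsv`/`.tab` are read as tab-separated,
#'   anything else as comma-separated).
#' @param columns Named character vector mapping roles to file columns,
#'   e.g. `c(x = "long", y = "lat", z = "conc")`. Roles become the output
#'   column names.
#' @return A tibble with one column per role.
#' @export
read_observations <- function(path, columns = c(x = "x", y = "y", z = "z")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  reader <- if (grepl("\\.(tsv|tab)$", path)) readr::read_tsv else readr::read_csv
  raw <- suppressMessages(reader(path, show_col_types = FALSE))
  miss <- setdiff(unname(columns), names(raw))
  if (length(miss) > 0)
    stop(sprintf("column '%s' not found", miss[1]), call. = FALSE)
  out <- raw[, unname(columns), drop = FALSE]
  names(out) <- names(columns)
  for (cn in names(out)) {
    if (!is.numeric(out[[cn]])) {
      v <- suppressWarnings(as.numeric(as.character(out[[cn]])))
      bad <- which(is.na(v) & !is.na(out[[cn]]))
      if (length(bad) > 0)
        stop(sprintf("non-numeric value in column '%s' (row %d)",
                     columns[[cn]], bad[1]), call. = FALSE)
      out[[cn]] <- v
    }
  }
  keep <- stats::complete.cases(out)
  if (any(!keep)) {
    message(sprintf("dropped %d row(s) with missing values", sum(!keep)))
    out <- out[keep, , drop = FALSE]
  }
  tibble::as_tibble(out)
}

#' Write a decomposition to component CSV + metadata JSON
#'
#' Writes the long-format component table (`component, x, y, mean, sd,
#' significant`; intercept rows carry empty `x`, `y`) and a JSON metadata
#' file recording the kernel, smoothing parameters, measures, seed and
#' package version — enough to re-run the computation.
#'
#' @param decomposition An `ssa_decomposition`.
#' @param path Output CSV path; metadata goes to `<path basename>.json`.
#' @param n_main,n_inter Evaluation grid resolutions.
#' @param k Significance multiplier (see [significance_mask()]).
#' @param meta Extra named metadata entries (e.g. `seed`).
#' @return Invisibly, the paths written.
#' @export
write_components <- function(decomposition, path, n_main = 101,
                             n_inter = 21, k = 2, meta = list()) {
  td <- tidy(decomposition, n_main = n_main, n_inter = n_inter, k = k)
  td <- dplyr::rename(td, mean = "estimate", sd = "std_error")
  readr::write_csv(td, path, na = "")
  fit_meta <- list()
  kern <- decomposition$carrier$kernel
  fit_meta$kernel <- kernel_to_config(kern)
  fit_meta$measures <- lapply(decomposition$measures, function(m)
    list(kind = m$kind, order = length(m$nodes),
         domain = as.numeric(m$domain)))
  fit_meta$method <- decomposition$method
  fit_meta$lambda <- decomposition$lambda
  fit_meta$package_version <- as.character(utils::packageVersion("splanova"))
  json_path <- sub("\\.csv$", "", path)
  json_path <- paste0(json_path, ".json")
  jsonlite::write_json(c(fit_meta, meta), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(csv = path, json = json_path))
}

# parse --flag value pairs into a named list; returns NULL on bad syntax
parse_flags <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    if (!grepl("^--", args[i]) || i == length(args)) return(NULL)
    out[[sub("^--", "", args[i])]] <- args[i + 1]
    i <- i + 2
  }
  out
}

cli_usage <- function() {
  cat("usage: splanova <subcommand> [--flag value ...]\n",
      "subcommands:\n",
      "  fit       --input data.csv --x x --y y --z z [--kernel tps|tensor]\n",
      "            [--criterion gcv|reml] --out dir\n",
      "  decompose --input data.csv --x x --y y --z z [--kernel tps|tensor]\n",
      "            [--measure lebesgue|empirical] [--grid 101] [--band 1]\n",
      "            [--two-step true] --out dir\n",
      "  simulate  --example 1|2 --n 30 --reps 100 --seed 1\n",
      "            [--methods tensor,posthoc] --out dir\n",
      "  synth     --n 5000 --seed 1 --out synth.csv\n",
      sep = "")
}

cli_measures_for <- function(measure, data, domain) {
  if (measure == "empirical") {
    list(x = quad_measure("empirical", domain[, 1], sample = data$x),
         y = quad_measure("empirical", domain[, 2], sample = data$y))
  } else {
    default_measures(domain)
  }
}

#' Command-line entry point
#'
#' Dispatches the `fit`, `decompose`, `simulate` and `synth` subcommands;
#' every output directory receives a `provenance.json` sufficient to
#' re-run the command. `decompose --two-step true` first fits the
#' tensor-product model, reports an anisotropy diagnostic (the ratio of
#' the selected marginal block weights and of the main-effect roughness
#' energies), then refits a thin-plate spline and reports its post-hoc
#' decomposition.
#'
#' @param args Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code: 0 success, 1 computation failure, 2 usage
#'   error.
#' @export
splanova_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) { cli_usage(); return(2L) }
  sub <- args[1]
  flags <- parse_flags(args[-1])
  if (is.null(flags) ||
      !sub %in% c("fit", "decompose", "simulate", "synth")) {
    cli_usage(); return(2L)
  }
  need <- function(nm) {
    v <- flags[[nm]]
    if (is.null(v)) stop(sprintf("missing required flag --%s", nm),
                         call. = FALSE)
    v
  }
  run <- function() {
    if (sub == "synth") {
      out <- need("out")
      dat <- synth_reading_data(
        n_obs = as.integer(flags$n %||% 5000),
        seed = as.integer(flags$seed %||% 1))
      readr::write_csv(dat, out)
      return(invisible(0L))
    }
    outdir <- need("out")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    prov <- list(subcommand = sub, flags = flags,
                 package_version =
                   as.character(utils::packageVersion("splanova")))
    if (sub == "simulate") {
      spec <- study_spec(example = as.integer(need("example")),
                         n = as.integer(need("n")),
                         reps = as.integer(flags$reps %||% 100),
                         seed = as.integer(flags$seed %||% 1))
      methods <- strsplit(flags$methods %||% "tensor,posthoc", ",")[[1]]
      st <- run_study(spec, methods = methods)
      readr::write_csv(metrics_table(st), file.path(outdir, "metrics.csv"))
      for (m in st$methods) for (cp in c("main_x", "main_y", "interaction"))
        readr::write_csv(
          tibble::as_tibble(st$results[[m]][[cp]], .name_repair = "minimal"),
          file.path(outdir, sprintf("grids_%s_%s.csv", m, cp)),
          col_names = FALSE)
    } else {
      cols <- c(x = need("x"), y = need("y"), z = need("z"))
      dat <- read_observations(need("input"), cols)
      kern_kind <- flags$kernel %||% "tps"
      domain <- apply(as.matrix(dat[, c("x", "y")]), 2, range)
      measures <- cli_measures_for(flags$measure %||% "lebesgue", dat, domain)
      if (sub == "fit") {
        fit <- if (kern_kind == "tensor")
          classic_ssanova(dat, measures = measures)$fit
        else fit_spline(dat, kernel = kern_kind,
                        criterion = flags$criterion %||% "gcv")
        jsonlite::write_json(as.list(glance(fit)),
                             file.path(outdir, "fit.json"),
                             auto_unbox = TRUE, digits = NA)
      } else { # decompose
        grid_n <- as.integer(flags$grid %||% 101)
        band <- as.numeric(flags$band %||% 1)
        two_step <- isTRUE(as.logical(flags[["two-step"]] %||% "FALSE"))
        if (two_step || kern_kind == "tensor") {
          cs <- classic_ssanova(dat, measures = measures)
          if (two_step) {
            e_x <- mean(cs$decomposition$components$main_x$evaluate(
              seq(domain[1, 1], domain[2, 1], length.out = 101))^2)
            e_y <- mean(cs$decomposition$components$main_y$evaluate(
              seq(domain[1, 2], domain[2, 2], length.out = 101))^2)
            prov$anisotropy <- list(
              theta_ratio = unname(cs$theta[["y"]] / cs$theta[["x"]]),
              main_energy_ratio = e_y / max(e_x, 1e-300))
            message(sprintf(
              "two-step: theta_y/theta_x = %.3g, main-effect energy ratio = %.3g; refitting thin-plate spline",
              prov$anisotropy$theta_ratio, prov$anisotropy$main_energy_ratio))
          }
        }
        dec <- if (kern_kind == "tensor" && !two_step) {
          cs$decomposition
        } else {
          fit <- fit_spline(dat, kernel = "tps",
                            criterion = flags$criterion %||% "gcv")
          prov$lambda <- fit$lambda
          posthoc_decompose(fit, measures = measures)
        }
        write_components(dec, file.path(outdir, "components.csv"),
                         n_main = grid_n, k = band)
      }
    }
    jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(0L)
  }
  code <- tryCatch({ run(); 0L },
    error = function(e) {
      if (grepl("missing required flag", conditionMessage(e))) {
        message(conditionMessage(e)); cli_usage(); 2L
      } else {
        message("error: ", conditionMessage(e)); 1L
      }
    })
  code
}
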