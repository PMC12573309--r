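# atomic writers: write to a temp file in the target directory, then rename,
# so a crashed run never leaves a partial artifact behind

atomic_write <- function(write_fun, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fun(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

atomic_write_csv <- function(df, path) {
  atomic_write(function(tmp)
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE), path)
}

atomic_write_json <- function(x, path) {
  atomic_write(function(tmp)
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE), path)
}

atomic_write_yaml <- function(x, path) {
  atomic_write(function(tmp) yaml::write_yaml(x, tmp), path)
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with run parameters (see [run_fit()] for the
#'   recognized fields).
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  structure(yaml::read_yaml(path), class = "run_config")
}

resolve_config <- function(config, defaults, required = character(0)) {
  config <- unclass(config)
  miss <- setdiff(required, names(config))
  if (length(miss))
    stop("missing required config field(s): ", paste(miss, collapse = ", "))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

spec_from_config <- function(x) {
  if (is.null(x)) return(trajectory_spec("random_intercept_linear"))
  if (inherits(x, "trajectory_spec")) return(x)
  do.call(trajectory_spec, x)
}

run_manifest <- function(dir, config, inputs = character(0)) {
  checksums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  atomic_write_yaml(config, file.path(dir, "resolved_config.yaml"))
  atomic_write_json(list(seed = config$seed,
                         package_version = as.character(utils::packageVersion("tosccamm")),
                         input_md5 = checksums),
                    file.path(dir, "run_manifest.json"))
}

#' Generate and write a simulated dataset (workflow entry point)
#'
#' Runs the synthetic-data generator with the given configuration and writes
#' all artifacts (long-format CSVs, truth tables, resolved config, manifest)
#' into `output_dir`. Any [sim_config()] field may appear in `config`;
#' `seed` is required.
#'
#' @param config named list or `run_config` (from [read_run_config()]).
#' @param output_dir output directory.
#' @return The [generate_dataset()] result, invisibly.
#' @export
run_simulate <- function(config = list(), output_dir) {
  config <- resolve_config(config, defaults = list(), required = "seed")
  cfg_fields <- intersect(names(config), names(formals(sim_config)))
  cfg <- do.call(sim_config, config[cfg_fields])
  sim <- generate_dataset(cfg)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_simulation(sim, output_dir)
  run_manifest(output_dir, unclass(cfg))
  invisible(sim)
}

load_paired <- function(config) {
  for (f in c("x", "y"))
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("input file for view '", f, "' not found: ",
           if (is.null(config[[f]])) "(unset)" else config[[f]])
  id_col <- config$id_col %||% "id"
  time_col <- config$time_col %||% "time"
  paired_longitudinal(read_long_csv(config$x, id_col, time_col),
                      read_long_csv(config$y, id_col, time_col))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the model from a configuration and write its artifacts
#'
#' Reads the two long-format input files, standardizes, fits [tosccamm()]
#' and writes weights, latent scores, a JSON fit summary, the resolved
#' configuration and a manifest with input checksums.
#'
#' Recognized config fields: `x`, `y` (paths), `id_col`, `time_col`, `k`,
#' `px`, `qy`, `spec_x`, `spec_y` (lists of [trajectory_spec()] arguments),
#' `tol`, `max_iter`, `standardize`, `seed` (required).
#'
#' @param config named list or `run_config`.
#' @param output_dir output directory.
#' @return The fitted [tosccamm()] object, invisibly.
#' @export
run_fit <- function(config, output_dir) {
  config <- resolve_config(config,
                           defaults = list(k = 1L, tol = 1e-6, max_iter = 100L,
                                           standardize = TRUE),
                           required = c("x", "y", "px", "qy", "seed"))
  data <- load_paired(config)
  fit <- tosccamm(data, k = config$k, px = config$px, qy = config$qy,
                  spec_x = spec_from_config(config$spec_x),
                  spec_y = spec_from_config(config$spec_y),
                  seed = config$seed, tol = config$tol,
                  max_iter = config$max_iter,
                  standardize = isTRUE(config$standardize))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_tosccamm(fit, output_dir)
  run_manifest(output_dir, config, inputs = c(config$x, config$y))
  invisible(fit)
}

#' Cross-validated sparsity selection from a configuration
#'
#' Wraps [cv_select()]: reads the inputs, runs individual-level CV over the
#' sparsity grid and writes `cv_scores.csv` (px, qy, component, mean_score,
#' se), `cv_result.json` and the usual manifest files.
#'
#' Additional config fields over [run_fit()]: `grid` (list of `[px, qy]`
#' pairs), `n_folds`.
#'
#' @inheritParams run_fit
#' @return The `cv_tosccamm` object, invisibly.
#' @export
run_cv <- function(config, output_dir) {
  config <- resolve_config(config,
                           defaults = list(k = 1L, n_folds = 5L, tol = 1e-6,
                                           max_iter = 100L, standardize = TRUE),
                           required = c("x", "y", "grid", "seed"))
  data <- load_paired(config)
  cv <- cv_select(data, grid = config$grid, n_folds = config$n_folds,
                  k = config$k,
                  spec_x = spec_from_config(config$spec_x),
                  spec_y = spec_from_config(config$spec_y),
                  seed = config$seed, tol = config$tol,
                  max_iter = config$max_iter,
                  standardize = isTRUE(config$standardize))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- do.call(rbind, lapply(seq_len(ncol(cv$scores)), function(kk)
    data.frame(px = cv$grid[, 1L], qy = cv$grid[, 2L], component = kk,
               mean_score = cv$scores[, kk], se = cv$se[, kk])))
  atomic_write_csv(tab, file.path(output_dir, "cv_scores.csv"))
  atomic_write_json(list(chosen = lapply(seq_len(nrow(cv$chosen)), function(kk)
                           list(component = kk,
                                px = unname(cv$chosen[kk, 1L]),
                                qy = unname(cv$chosen[kk, 2L]))),
                         n_folds = cv$n_folds, seed = cv$seed),
                    file.path(output_dir, "cv_result.json"))
  run_manifest(output_dir, config, inputs = c(config$x, config$y))
  invisible(cv)
}

#' Permutation test from a configuration
#'
#' Wraps [permutation_test()] and writes `permutation.json` (observed
#' correlations, p-values, B, seed) plus the usual manifest files.
#'
#' Additional config fields over [run_fit()]: `B` (permutations).
#'
#' @inheritParams run_fit
#' @return The `tosccamm_perm` object, invisibly.
#' @export
run_permtest <- function(config, output_dir) {
  config <- resolve_config(config,
                           defaults = list(k = 1L, B = 99L, tol = 1e-6,
                                           max_iter = 100L, standardize = TRUE),
                           required = c("x", "y", "px", "qy", "seed"))
  data <- load_paired(config)
  pt <- permutation_test(data, k = config$k, px = config$px, qy = config$qy,
                         spec_x = spec_from_config(config$spec_x),
                         spec_y = spec_from_config(config$spec_y),
                         B = config$B, seed = config$seed,
                         tol = config$tol, max_iter = config$max_iter,
                         standardize = isTRUE(config$standardize))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  atomic_write_json(list(observed_rho = pt$observed_rho,
                         p_values = pt$p_values,
                         B = pt$B, seed = pt$seed),
                    file.path(output_dir, "permutation.json"))
  run_manifest(output_dir, config, inputs = c(config$x, config$y))
  invisible(pt)
}
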