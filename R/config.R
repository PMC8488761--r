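#' Parse and validate a run configuration
#'
#' A run configuration describes one reproducible computation: a model, its
#' parameters, a mode (`trajectory`, `sweep`, `equilibria` or `invade`) and
#' the numerical settings. Configurations are YAML files (see the shipped
#' examples under `system.file("extdata", "configs", package = "cytosweep")`)
#' or plain named lists. The dynamics are deterministic mean-field
#' recursions, so the schema has no seed field — identical configurations
#' regenerate identical outputs byte for byte.
#'
#' Schema (version 1):
#' \preformatted{
#' schema: 1
#' model: fixed_benefit | freq_dep | ci
#' params: {B: ..., mu: ..., t: ...}        # fields must match the model
#' mode: trajectory | sweep | equilibria | invade
#' origin: infected | uninfected            # default "infected"
#' epsilon: 1e-5                            # default
#' horizon: 1000000                         # default
#' tol: 1e-12                               # default
#' output: path.csv                         # optional
#' grid:                                    # sweep mode only
#'   axis1: {name: mu, from: 0, to: 0.08, n: 51}
#'   axis2: {name: t, from: 0, to: 0.05, n: 51}
#' }
#'
#' Unknown keys anywhere in the file are rejected with a message naming the
#' offending field, as are parameters that do not belong to the chosen model.
#'
#' Note: YAML 1.1 readers interpret a bare `n` key as a boolean, so the axis
#' point count must be written quoted (`"n": 51`), as in the shipped configs.
#'
#' @param path Path to a YAML configuration file.
#' @param config A named list (alternative to `path`).
#' @return A validated `cyto_config` list with every default filled in.
#' @examples
#' cfg <- parse_config(config = list(model = "fixed_benefit",
#'                                   params = list(B = 0.075, mu = 0.05, t = 0.02),
#'                                   mode = "equilibria"))
#' cfg$epsilon
#' @export
parse_config <- function(path = NULL, config = NULL) {
  if (is.null(config)) {
    if (is.null(path)) {
      cyto_abort("Provide either `path` or `config`.", "cytosweep_error_config")
    }
    if (!file.exists(path)) {
      cyto_abort(sprintf("Config file `%s` does not exist.", path),
                 "cytosweep_error_config")
    }
    config <- yaml::read_yaml(path)
  }
  known <- c("schema", "model", "params", "mode", "origin", "epsilon",
             "horizon", "tol", "output", "grid")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    cyto_abort(sprintf("Unknown config key(s): %s.",
                       paste0("`", unknown, "`", collapse = ", ")),
               "cytosweep_error_config")
  }
  schema <- config$schema %||% 1L
  if (!identical(as.integer(schema), 1L)) {
    cyto_abort("Only config schema version 1 is supported.",
               "cytosweep_error_config")
  }
  model <- config$model
  if (is.null(model) ||
      !model %in% c("fixed_benefit", "freq_dep", "ci")) {
    cyto_abort("`model` must be one of fixed_benefit, freq_dep, ci.",
               "cytosweep_error_config")
  }
  mode <- config$mode
  if (is.null(mode) ||
      !mode %in% c("trajectory", "sweep", "equilibria", "invade")) {
    cyto_abort("`mode` must be one of trajectory, sweep, equilibria, invade.",
               "cytosweep_error_config")
  }

  required <- switch(model,
    fixed_benefit = c("B", "mu"),
    freq_dep = c("b", "c", "mu"),
    ci = c("h", "mu"))
  pfields <- config$params %||% list()
  bad <- setdiff(names(pfields), c(required, "t"))
  if (length(bad) > 0) {
    cyto_abort(
      sprintf("Parameter field(s) %s do not belong to the %s model.",
              paste0("`", bad, "`", collapse = ", "), model),
      "cytosweep_error_config")
  }
  missing <- setdiff(required, names(pfields))
  if (length(missing) > 0) {
    cyto_abort(sprintf("Missing parameter field(s) for the %s model: %s.",
                       model, paste0("`", missing, "`", collapse = ", ")),
               "cytosweep_error_config")
  }
  pfields$t <- pfields$t %||% 0
  params <- do.call(cyto_params, c(list(model = model), pfields))

  grid <- NULL
  if (mode == "sweep") {
    g <- config$grid
    if (is.null(g) || !all(c("axis1", "axis2") %in% names(g))) {
      cyto_abort("Sweep mode needs a `grid` with `axis1` and `axis2`.",
                 "cytosweep_error_config")
    }
    extra_g <- setdiff(names(g), c("axis1", "axis2"))
    if (length(extra_g) > 0) {
      cyto_abort(sprintf("Unknown grid key(s): %s.",
                         paste0("`", extra_g, "`", collapse = ", ")),
                 "cytosweep_error_config")
    }
    grid <- lapply(g, function(ax) {
      extra_a <- setdiff(names(ax), c("name", "from", "to", "n"))
      if (length(extra_a) > 0) {
        cyto_abort(sprintf("Unknown axis key(s): %s.",
                           paste0("`", extra_a, "`", collapse = ", ")),
                   "cytosweep_error_config")
      }
      sweep_axis(ax$name, ax$from, ax$to, ax$n)
    })
  } else if (!is.null(config$grid)) {
    cyto_abort("`grid` is only valid in sweep mode.", "cytosweep_error_config")
  }

  origin <- config$origin %||% "infected"
  if (!origin %in% c("infected", "uninfected")) {
    cyto_abort("`origin` must be `infected` or `uninfected`.",
               "cytosweep_error_config")
  }

  structure(list(
    schema = 1L,
    model = model,
    params = params,
    mode = mode,
    origin = origin,
    epsilon = check_scalar(config$epsilon %||% 1e-5, "epsilon", 0, 1),
    horizon = check_scalar(config$horizon %||% 1e6, "horizon", 1),
    tol = check_scalar(config$tol %||% 1e-12, "tol", 0, strict_lower = TRUE),
    output = config$output
  ), grid = grid, class = "cyto_config")
}

#' Execute a run configuration
#'
#' Dispatches a parsed configuration to [run_trajectory()], [run_sweep()],
#' [cyto_equilibria()] or [classify_invasion()], writes the CSV artifact if
#' `output` is set, and logs the resolved settings to `stderr`.
#'
#' @param config A `cyto_config` from [parse_config()], or a path/list
#'   accepted by it.
#' @param dir Directory that relative output paths are resolved against.
#' @param quiet Suppress the log line.
#' @return The computed result (trajectory, sweep, equilibria tibble, or
#'   `cyto_invasion`), invisibly.
#' @export
run_config <- function(config, dir = ".", quiet = FALSE) {
  if (!inherits(config, "cyto_config")) {
    config <- if (is.character(config)) parse_config(path = config)
              else parse_config(config = config)
  }
  t0 <- proc.time()[["elapsed"]]
  params <- config$params
  result <- switch(config$mode,
    trajectory = run_trajectory(params, origin = config$origin,
                                epsilon = config$epsilon,
                                horizon = config$horizon, tol = config$tol),
    sweep = run_sweep(params, attr(config, "grid")$axis1,
                      attr(config, "grid")$axis2, origin = config$origin,
                      epsilon = config$epsilon, horizon = config$horizon,
                      tol = config$tol),
    equilibria = cyto_equilibria(params),
    invade = classify_invasion(params, origin = config$origin,
                               epsilon = config$epsilon,
                               horizon = config$horizon, tol = config$tol))

  out_path <- NULL
  if (!is.null(config$output)) {
    out_path <- if (grepl("^(/|[A-Za-z]:)", config$output)) config$output
                else file.path(dir, config$output)
    if (config$mode == "trajectory") write_trajectory_csv(result, out_path)
    else if (config$mode == "sweep") write_sweep_csv(result, out_path)
    else {
      tab <- if (config$mode == "invade") glance(result) else result
      write_commented_csv(tab, c(paste0("# cytosweep ", config$mode),
                                 header_params(params)), out_path)
    }
  }
  if (!quiet) {
    fields <- unclass(params)[-1]
    message(sprintf(
      "cytosweep: mode=%s model=%s %s origin=%s epsilon=%g elapsed=%.2fs%s",
      config$mode, config$model,
      paste0(names(fields), "=", vapply(fields, fmt_num, character(1)),
             collapse = " "),
      config$origin, config$epsilon, proc.time()[["elapsed"]] - t0,
      if (is.null(out_path)) "" else paste0(" output=", out_path)))
  }
  invisible(result)
}
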