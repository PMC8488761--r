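#' Write trajectory and sweep results as tidy CSV
#'
#' Both writers emit a commented header block (`#`-prefixed lines) recording
#' the model, every parameter, the introduction frequency, the tolerances
#' and the package version, followed by a plain CSV table — one row per
#' generation (trajectories) or per grid cell (sweeps). Numbers are printed
#' at 12 significant digits and the output is byte-identical for identical
#' inputs, so regenerated artifacts can be compared with `diff`.
#'
#' @param x A `cyto_trajectory` or `cyto_sweep`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(x, path) {
  stopifnot(inherits(x, "cyto_trajectory"))
  header <- c(
    "# cytosweep trajectory",
    header_params(attr(x, "params")),
    paste0("# origin: ", attr(x, "origin")),
    paste0("# epsilon: ", fmt_num(attr(x, "epsilon"))),
    paste0("# baseline_p_star: ", fmt_num(attr(x, "baseline"))),
    paste0("# converged: ", attr(x, "converged")),
    paste0("# package_version: ", as.character(utils::packageVersion("cytosweep")))
  )
  write_commented_csv(x, header, path)
}

#' @rdname write_trajectory_csv
#' @export
write_sweep_csv <- function(x, path) {
  stopifnot(inherits(x, "cyto_sweep"))
  axes <- attr(x, "axes")
  header <- c(
    "# cytosweep sweep",
    header_params(attr(x, "params")),
    paste0("# axes: ", paste(axes, collapse = ", ")),
    paste0("# origin: ", attr(x, "origin")),
    paste0("# epsilon: ", fmt_num(attr(x, "epsilon"))),
    "# eps_extinct: 1e-09",
    paste0("# package_version: ", as.character(utils::packageVersion("cytosweep")))
  )
  write_commented_csv(x, header, path)
}

header_params <- function(params) {
  fields <- unclass(params)[-1]
  c(paste0("# model: ", params$model),
    paste0("# ", names(fields), ": ", vapply(fields, fmt_num, character(1))))
}

fmt_num <- function(x) {
  if (is.na(x)) return("NA")
  if (is.integer(x)) return(as.character(x))
  sprintf("%.12g", x)
}

write_commented_csv <- function(df, header, path) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) vapply(col, fmt_num, character(1))
    else as.character(col)
  })
  body <- do.call(paste, c(cols, sep = ","))
  lines <- c(header, paste(names(df), collapse = ","), body)
  con <- tryCatch(suppressWarnings(file(path, open = "wb")),
                  error = function(e) {
                    cyto_abort(sprintf("Cannot open `%s` for writing: %s",
                                       path, conditionMessage(e)),
                               "cytosweep_error_io")
                  })
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
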