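#' Model parameter sets
#'
#' Constructors for the parameters of the three deterministic models of a
#' maternally inherited symbiont co-transmitted with mitochondria. All three
#' share the segregational loss rate `mu` (the fraction of an infected
#' mother's offspring that fail to inherit the symbiont) and the selective
#' benefit `t` of the novel mitotype; they differ in how symbiont carriage
#' affects host fitness:
#'
#' * `fixed_benefit_params()` — offspring of infected mothers receive a fixed
#'   net fitness factor `1 + B` (drive balanced against segregational loss).
#' * `freq_dep_params()` — the benefit declines linearly with overall symbiont
#'   frequency, `B = b (1 - (p + r))`, against a fixed carriage cost `c`
#'   (e.g. a defensive symbiont whose enemy declines as protection spreads).
#' * `ci_params()` — cytoplasmic incompatibility: offspring of uninfected
#'   mothers crossed with infected fathers survive at rate `1 - h`, a
#'   positively frequency-dependent advantage.
#'
#' All quantities are dimensionless. `t` defaults to 0 (no mitotype under
#' selection); analyses in this package assume `t >= 0`, although the step
#' operators accept any `t > -1`.
#'
#' @param B Net fitness benefit of symbiont carriage; must satisfy `1 + B > 0`.
#' @param b Maximum symbiont benefit when the symbiont is vanishingly rare
#'   (`b >= 0`).
#' @param c Fixed cost of symbiont carriage (`c >= 0`, `1 + b - c > 0`).
#' @param h Strength of cytoplasmic incompatibility in `[0, 1]`.
#' @param mu Segregational loss rate in `[0, 1]`.
#' @param t Selective benefit of the novel mitotype (`t > -1`).
#'
#' @return An object of class `cyto_params` (subclass `fixed_benefit_params`,
#'   `freq_dep_params` or `ci_params`): a named list of the parameter fields
#'   plus a `model` label.
#'
#' @examples
#' fixed_benefit_params(B = 0.075, mu = 0.05, t = 0.02)
#' freq_dep_params(b = 0.1, c = 0.05, mu = 0.02, t = 0.02)
#' ci_params(h = 0.25, mu = 0.05, t = 0.02)
#' @name cyto-params
NULL

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    cyto_abort(sprintf("`%s` must be a single finite number.", name),
               "cytosweep_error_params")
  }
  bad <- if (strict_lower) x <= lower else x < lower
  if (bad || x > upper) {
    cyto_abort(
      sprintf("`%s` = %g is outside its admissible range %s%g, %g].",
              name, x, if (strict_lower) "(" else "[", lower, upper),
      "cytosweep_error_params")
  }
  as.double(x)
}

new_cyto_params <- function(model, subclass, fields) {
  structure(c(list(model = model), fields),
            class = c(subclass, "cyto_params"))
}

#' @rdname cyto-params
#' @export
fixed_benefit_params <- function(B, mu, t = 0) {
  B <- check_scalar(B, "B", lower = -1, strict_lower = TRUE)
  mu <- check_scalar(mu, "mu", 0, 1)
  t <- check_scalar(t, "t", lower = -1, strict_lower = TRUE)
  new_cyto_params("fixed_benefit", "fixed_benefit_params",
                  list(B = B, mu = mu, t = t))
}

#' @rdname cyto-params
#' @export
freq_dep_params <- function(b, c, mu, t = 0) {
  b <- check_scalar(b, "b", lower = 0)
  c <- check_scalar(c, "c", lower = 0)
  if (1 + b - c <= 0) {
    cyto_abort("`1 + b - c` must be positive.", "cytosweep_error_params")
  }
  mu <- check_scalar(mu, "mu", 0, 1)
  t <- check_scalar(t, "t", lower = -1, strict_lower = TRUE)
  new_cyto_params("freq_dep", "freq_dep_params",
                  list(b = b, c = c, mu = mu, t = t))
}

#' @rdname cyto-params
#' @export
ci_params <- function(h, mu, t = 0) {
  h <- check_scalar(h, "h", 0, 1)
  mu <- check_scalar(mu, "mu", 0, 1)
  t <- check_scalar(t, "t", lower = -1, strict_lower = TRUE)
  new_cyto_params("ci", "ci_params", list(h = h, mu = mu, t = t))
}

#' Build a parameter set from a model label and named fields
#'
#' Convenience dispatcher used by the configuration layer: maps a model label
#' (`"fixed_benefit"`, `"freq_dep"` or `"ci"`) plus named numeric fields to
#' the corresponding constructor.
#'
#' @param model One of `"fixed_benefit"`, `"freq_dep"`, `"ci"`.
#' @param ... Named numeric parameter fields for that model.
#' @return A `cyto_params` object.
#' @examples
#' cyto_params("ci", h = 0.25, mu = 0.05, t = 0.02)
#' @export
cyto_params <- function(model, ...) {
  fields <- list(...)
  ctor <- switch(model,
    fixed_benefit = fixed_benefit_params,
    freq_dep = freq_dep_params,
    ci = ci_params,
    cyto_abort(sprintf("Unknown model `%s`.", model), "cytosweep_error_params")
  )
  allowed <- setdiff(names(formals(ctor)), character())
  extra <- setdiff(names(fields), allowed)
  if (length(extra) > 0) {
    cyto_abort(
      sprintf("Field(s) %s are not parameters of the %s model.",
              paste0("`", extra, "`", collapse = ", "), model),
      "cytosweep_error_params")
  }
  do.call(ctor, fields)
}

# Replace some fields of a parameter set, revalidating through the constructor.
with_params <- function(params, ...) {
  fields <- utils::modifyList(unclass(params)[-1], list(...))
  do.call(cyto_params, c(list(model = params$model), fields))
}

model_id <- function(params) {
  switch(params$model, fixed_benefit = 1L, freq_dep = 2L, ci = 3L)
}

par_vector <- function(params) {
  switch(params$model,
    fixed_benefit = c(params$B, params$mu, params$t),
    freq_dep = c(params$b, params$c, params$mu, params$t),
    ci = c(params$h, params$mu, params$t))
}

#' @export
print.cyto_params <- function(x, ...) {
  fields <- unclass(x)[-1]
  cat("<cyto_params: ", x$model, " model>\n", sep = "")
  cat(paste0("  ", names(fields), " = ", format(unlist(fields))), sep = "\n")
  invisible(x)
}
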