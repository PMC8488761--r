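#' Axis specification for a parameter sweep
#'
#' @param name Parameter field to vary (e.g. `"mu"`, `"t"`, `"h"`).
#' @param from,to Range of the axis.
#' @param n Number of grid points (at least 1).
#' @return A `cytosweep_axis` list.
#' @export
sweep_axis <- function(name, from, to, n) {
  if (!is.character(name) || length(name) != 1L) {
    cyto_abort("Axis `name` must be a single string.", "cytosweep_error_axis")
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1L) {
    cyto_abort("Axis `n` must be a positive integer.", "cytosweep_error_axis")
  }
  from <- check_scalar(from, "from")
  to <- check_scalar(to, "to")
  if (to < from) {
    cyto_abort("Axis `to` must be >= `from`.", "cytosweep_error_axis")
  }
  structure(list(name = name, from = from, to = to, n = n),
            class = "cytosweep_axis")
}

axis_values <- function(axis) {
  if (axis$n == 1L) (axis$from + axis$to) / 2
  else seq(axis$from, axis$to, length.out = axis$n)
}

#' Two-dimensional invasion outcome sweep
#'
#' Runs [classify_invasion()] over a complete grid of two varied parameters
#' (typically segregational loss `mu` against mitotype benefit `t`, or
#' against CI strength `h`), holding the remaining parameters fixed. Cells
#' where the symbiont cannot persist are kept in the grid and marked
#' `symbiont_not_persistent`; cells where the origin compartment is smaller
#' than `epsilon` (e.g. an uninfected origin with the symbiont fixed) are
#' marked `impossible_origin`. Cells are independent and the result is
#' deterministic, sorted by `axis1` then `axis2`.
#'
#' @inheritParams classify_invasion
#' @param axis1,axis2 [sweep_axis()] specifications; their names must be
#'   parameter fields of the model and must differ.
#' @return A tibble of class `cyto_sweep` with one row per grid cell: the two
#'   axis columns (named after the varied parameters), `p_star` (pre-invasion
#'   symbiont equilibrium), `growth_factor`, `outcome`, `mutant_freq`
#'   (equilibrium novel-mitotype frequency `N* = r* + s*`), `symbiont_freq`
#'   (final) and `generations`. Attributes: `params`, `origin`, `epsilon`,
#'   `axes`.
#' @examples
#' sw <- run_sweep(fixed_benefit_params(B = 0.1, mu = 0, t = 0),
#'                 sweep_axis("mu", 0.01, 0.08, 5),
#'                 sweep_axis("t", 0.005, 0.05, 5),
#'                 origin = "uninfected")
#' dplyr::count(sw, outcome)
#' @export
run_sweep <- function(params, axis1, axis2,
                      origin = c("infected", "uninfected"),
                      epsilon = 1e-5, horizon = 1e6,
                      eps_extinct = 1e-9, tol = 1e-12) {
  origin <- match.arg(origin)
  if (!inherits(axis1, "cytosweep_axis") || !inherits(axis2, "cytosweep_axis")) {
    cyto_abort("`axis1` and `axis2` must be sweep_axis() objects.",
               "cytosweep_error_axis")
  }
  fields <- setdiff(names(unclass(params)), "model")
  for (ax in list(axis1, axis2)) {
    if (!ax$name %in% fields) {
      cyto_abort(
        sprintf("Axis `%s` is not a parameter of the %s model.",
                ax$name, params$model),
        "cytosweep_error_axis")
    }
  }
  if (axis1$name == axis2$name) {
    cyto_abort("The two axes must vary different parameters.",
               "cytosweep_error_axis")
  }

  grid <- tidyr::expand_grid(a1 = axis_values(axis1), a2 = axis_values(axis2))
  cells <- purrr::pmap_dfr(grid, function(a1, a2) {
    cell_pars <- do.call(with_params,
                         c(list(params),
                           setNames(list(a1, a2),
                                    c(axis1$name, axis2$name))))
    blank <- tibble(p_star = NA_real_, growth_factor = NA_real_,
                    outcome = NA_character_, mutant_freq = NA_real_,
                    symbiont_freq = NA_real_, generations = NA_integer_)
    inv <- tryCatch(
      classify_invasion(cell_pars, origin = origin, epsilon = epsilon,
                        horizon = horizon, eps_extinct = eps_extinct,
                        tol = tol),
      cytosweep_error_no_resident_equilibrium = function(e) "symbiont_not_persistent",
      cytosweep_error_impossible_origin = function(e) "impossible_origin")
    if (is.character(inv)) {
      blank$outcome <- inv
      if (inv == "impossible_origin") {
        blank$p_star <- resident_equilibrium(cell_pars)[[1]]
      }
      return(blank)
    }
    tibble(p_star = inv$p_star_before, growth_factor = inv$growth_factor,
           outcome = inv$outcome, mutant_freq = mutant_freq(inv$final_state),
           symbiont_freq = symbiont_freq(inv$final_state),
           generations = as.integer(inv$generations))
  })

  out <- dplyr::bind_cols(setNames(grid, c(axis1$name, axis2$name)), cells)
  structure(out,
            class = c("cyto_sweep", class(out)),
            params = params, origin = origin, epsilon = epsilon,
            axes = c(axis1$name, axis2$name))
}
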