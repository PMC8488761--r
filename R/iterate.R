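#' Iterate a one-generation map to its fixed point
#'
#' Repeatedly applies a step operator until successive states differ by less
#' than `tol` in the max-norm. `step` may be either a `cyto_params` object —
#' in which case the iteration runs in compiled code — or an arbitrary
#' function mapping a state to the next state (the slow path used for
#' cross-checking).
#'
#' Convergence is geometric away from bifurcation points, so the default
#' budget of one million generations is generous; near-tangent cytoplasmic
#' incompatibility cases (where the two interior equilibria almost collide)
#' are the slow cases that need it. On failure to converge the function
#' signals a condition of class `cytosweep_error_nonconvergence` carrying the
#' last state and the generation count, so callers can inspect how far the
#' iteration got.
#'
#' @param step A `cyto_params` object or a function `state -> state`.
#' @param initial The starting [cytotype_state()].
#' @param tol Convergence tolerance (max-norm on successive states).
#' @param max_gen Generation budget.
#' @return The converged [cytotype_state()], with attributes `generations`
#'   (steps taken) and `converged = TRUE`.
#' @examples
#' pars <- fixed_benefit_params(B = 0.075, mu = 0.05)
#' find_fixed_point(pars, cytotype_state(0.5, 0.5))
#' @export
find_fixed_point <- function(step, initial, tol = 1e-12, max_gen = 1e6) {
  if (!is.numeric(tol) || tol <= 0) {
    cyto_abort("`tol` must be positive.", "cytosweep_error_params")
  }
  initial <- as_cytotype_state(initial)

  if (inherits(step, "cyto_params")) {
    res <- iterate_compiled(step, initial, tol = tol, max_gen = max_gen)
    state <- res$state; gens <- res$generations; converged <- res$converged
  } else if (is.function(step)) {
    x <- initial
    gens <- 0L
    converged <- FALSE
    while (gens < max_gen) {
      y <- as_cytotype_state(step(x))
      gens <- gens + 1L
      if (max(abs(unclass(y) - unclass(x))) < tol) {
        x <- y
        converged <- TRUE
        break
      }
      x <- y
    }
    state <- x
  } else {
    cyto_abort("`step` must be a cyto_params object or a function.",
               "cytosweep_error_params")
  }

  if (!converged) {
    cyto_abort(
      sprintf("No fixed point reached within %d generations.", as.integer(max_gen)),
      "cytosweep_error_nonconvergence",
      last_state = state, generations = gens)
  }
  structure(state, generations = gens, converged = TRUE,
            class = "cytotype_state")
}

# Thin wrapper over the compiled iterator; returns a list and never throws on
# non-convergence (classification code needs the final state either way).
iterate_compiled <- function(params, state, tol, max_gen,
                             stop_mutant_below = 0, record = FALSE) {
  res <- cpp_iterate(unclass(as_cytotype_state(state)), model_id(params),
                     par_vector(params), tol, as.integer(max_gen),
                     stop_mutant_below, record)
  if (res$code == 1L) {
    cyto_abort("Degenerate state: offspring normalizer is not positive.",
               "cytosweep_error_degenerate")
  }
  if (res$code == 2L) {
    cyto_abort("Cytotype frequencies stopped summing to 1; formula bug.",
               "cytosweep_error_conservation")
  }
  res$state <- settle_state(setNames(res$state, c("p", "q", "r", "s")))
  res
}
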