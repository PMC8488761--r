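#' Tidy an invasion result
#'
#' @param x A `cyto_invasion` object from [classify_invasion()].
#' @param ... Unused.
#' @return `tidy()`: one row per cytotype compartment with its initial and
#'   final frequency. `glance()`: a one-row summary (model, origin, growth
#'   factor, outcome, generations, pre-invasion symbiont prevalence and
#'   final marginal frequencies).
#' @export
tidy.cyto_invasion <- function(x, ...) {
  tibble(
    compartment = c("p", "q", "r", "s"),
    description = c("resident mitotype, infected",
                    "resident mitotype, uninfected",
                    "novel mitotype, infected",
                    "novel mitotype, uninfected"),
    initial = unname(unclass(x$initial_state)),
    final = unname(unclass(x$final_state))
  )
}

#' @rdname tidy.cyto_invasion
#' @export
glance.cyto_invasion <- function(x, ...) {
  tibble(
    model = x$params$model,
    origin = x$origin,
    growth_factor = x$growth_factor,
    outcome = x$outcome,
    generations = as.integer(x$generations),
    converged = x$converged,
    p_star_before = x$p_star_before,
    symbiont_freq_final = symbiont_freq(x$final_state),
    mutant_freq_final = mutant_freq(x$final_state)
  )
}
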