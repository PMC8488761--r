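#' Simulate an invasion trajectory
#'
#' Runs the full recursion from the resident equilibrium perturbed by
#' [introduce_mutant()] and records every generation until a fixed point is
#' reached (successive states within `tol`) or `horizon` generations elapse.
#' With `epsilon = 0` the trajectory is flat at the resident equilibrium.
#'
#' @inheritParams classify_invasion
#' @return A tibble of class `cyto_trajectory` with columns `generation`
#'   (starting at 0), the four cytotype frequencies `p`, `q`, `r`, `s`, and
#'   the marginals `symbiont_freq = p + r` and `mutant_freq = r + s`.
#'   Attributes: `params`, `origin`, `epsilon`, `converged`, and `baseline`
#'   (the pre-invasion symbiont equilibrium frequency — the dashed reference
#'   line in the plots).
#' @examples
#' tr <- run_trajectory(fixed_benefit_params(B = 0.075, mu = 0.05, t = 0.02),
#'                      origin = "infected")
#' tail(tr)
#' @export
run_trajectory <- function(params, origin = c("infected", "uninfected"),
                           epsilon = 1e-5, horizon = 1e6, tol = 1e-12) {
  origin <- match.arg(origin)
  eq <- resident_equilibrium(params)
  state0 <- if (epsilon > 0) introduce_mutant(eq, origin, epsilon) else eq
  res <- iterate_compiled(params, state0, tol = tol, max_gen = horizon,
                          record = TRUE)
  m <- res$trajectory
  out <- tibble(
    generation = seq_len(nrow(m)) - 1L,
    p = m[, 1], q = m[, 2], r = m[, 3], s = m[, 4],
    symbiont_freq = m[, 1] + m[, 3],
    mutant_freq = m[, 3] + m[, 4]
  )
  structure(out,
            class = c("cyto_trajectory", class(out)),
            params = params, origin = origin, epsilon = epsilon,
            converged = res$converged, baseline = eq[[1]])
}
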