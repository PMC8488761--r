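#' One-generation recursion operators
#'
#' `cyto_step()` advances a [cytotype_state()] by one host generation under
#' the model given by `params`. The three recursions share a structure: each
#' cytotype contributes offspring proportional to its frequency times its
#' maternal fitness, infected mothers lose the symbiont in a fraction `mu` of
#' offspring (moving `p`-type offspring into `q`, and `r`-type into `s`), and
#' the novel mitotype multiplies every carrier's output by `1 + t`. The next
#' generation is the offspring pool renormalized by its total.
#'
#' * Fixed benefit: infected mothers produce `1 + B` offspring relative to
#'   uninfected mothers; the normalizer is
#'   `p (1 + B) + q + (r (1 + B) + s)(1 + t)`.
#' * Frequency-dependent benefit: identical, with `B` replaced by
#'   `b (1 - (p + r)) - c` evaluated at the *current* generation's overall
#'   symbiont frequency.
#' * Cytoplasmic incompatibility: uninfected mothers mate at random, and
#'   their offspring survive at `1 - h` when the father is infected
#'   (probability `p + r`), i.e. at the factor
#'   `(p + r)(1 - h) + q + s` overall. Offspring of infected mothers that
#'   lose the symbiont are *not* protected from incompatibility: the loss
#'   terms `p mu` and `r mu` enter the uninfected classes and experience the
#'   survival factor, exactly as the recursions are written. Male cytotype
#'   frequencies are taken equal to female frequencies (equal sex ratio).
#'
#' The step signals a degenerate-state error if the normalizer is not
#' positive; this cannot arise for valid parameters and states and exists to
#' guard misuse.
#'
#' @param state A [cytotype_state()].
#' @param params A parameter set from [fixed_benefit_params()],
#'   [freq_dep_params()] or [ci_params()].
#' @return The next-generation [cytotype_state()].
#' @examples
#' st <- cytotype_state(p = 0.5, q = 0.5)
#' cyto_step(st, fixed_benefit_params(B = 0, mu = 0.1, t = 0))
#' @export
cyto_step <- function(state, params) {
  state <- as_cytotype_state(state)
  UseMethod("cyto_step", params)
}

# Shared form of the fixed-benefit and frequency-dependent recursions:
# w is the fitness factor of symbiont-infected mothers.
step_benefit_form <- function(state, w, mu, t) {
  p <- state[[1]]; q <- state[[2]]; r <- state[[3]]; s <- state[[4]]
  den <- p * w + q + (r * w + s) * (1 + t)
  if (!is.finite(den) || den <= 0) {
    cyto_abort(sprintf("Degenerate state: offspring normalizer is %g.", den),
               "cytosweep_error_degenerate")
  }
  settle_state(c(
    p = p * (1 - mu) * w / den,
    q = (p * w * mu + q) / den,
    r = r * w * (1 - mu) * (1 + t) / den,
    s = (r * w * mu + s) * (1 + t) / den
  ))
}

#' @export
cyto_step.fixed_benefit_params <- function(state, params) {
  step_benefit_form(state, 1 + params$B, params$mu, params$t)
}

#' @export
cyto_step.freq_dep_params <- function(state, params) {
  w <- 1 + params$b * (1 - (state[[1]] + state[[3]])) - params$c
  step_benefit_form(state, w, params$mu, params$t)
}

#' @export
cyto_step.ci_params <- function(state, params) {
  p <- state[[1]]; q <- state[[2]]; r <- state[[3]]; s <- state[[4]]
  h <- params$h; mu <- params$mu; t <- params$t
  compat <- (p + r) * (1 - h) + q + s
  n <- c(
    p = p * (1 - mu),
    q = (p * mu + q) * compat,
    r = r * (1 - mu) * (1 + t),
    s = (r * mu + s) * (1 + t) * compat
  )
  phi <- sum(n)
  if (!is.finite(phi) || phi <= 0) {
    cyto_abort(sprintf("Degenerate state: offspring normalizer is %g.", phi),
               "cytosweep_error_degenerate")
  }
  settle_state(n / phi)
}

#' Resident-subsystem recursion (single equation)
#'
#' With the novel mitotype absent (`r = s = 0`) each model collapses to a
#' one-dimensional map of the symbiont frequency `p` (with `q = 1 - p`):
#'
#' * fixed benefit: `p' = p (1 - mu)(1 + B) / (1 + B p)`
#' * frequency-dependent: `p' = p (1 - mu) w / (p w + 1 - p)` with
#'   `w = 1 + b (1 - p) - c`
#' * cytoplasmic incompatibility:
#'   `p' = p (1 - mu) / (1 - h p (1 - p (1 - mu)))`
#'
#' A step of the full four-dimensional recursion restricted to `r = s = 0`
#' reproduces these maps exactly; the package tests hold the two routes to
#' within 1e-14.
#'
#' @param p Symbiont frequency (or vector of frequencies).
#' @param params A `cyto_params` object.
#' @return The next-generation symbiont frequency (vectorized over `p`).
#' @export
resident_map <- function(p, params) {
  UseMethod("resident_map", params)
}

#' @export
resident_map.fixed_benefit_params <- function(p, params) {
  p * (1 - params$mu) * (1 + params$B) / (1 + params$B * p)
}

#' @export
resident_map.freq_dep_params <- function(p, params) {
  w <- 1 + params$b * (1 - p) - params$c
  p * (1 - params$mu) * w / (p * w + 1 - p)
}

#' @export
resident_map.ci_params <- function(p, params) {
  p * (1 - params$mu) / (1 - params$h * p * (1 - p * (1 - params$mu)))
}
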