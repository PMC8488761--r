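#' Closed-form resident equilibria and persistence criteria
#'
#' With the novel mitotype absent, each model reduces to a one-dimensional
#' map of the symbiont frequency `p` whose equilibria are known in closed
#' form:
#'
#' * fixed benefit: `p* = 0` and `p* = 1 - (1 + B) mu / B`; the interior
#'   equilibrium is stable iff `mu < B / (1 + B)` (the symbiont persistence
#'   criterion).
#' * frequency-dependent benefit: `p* = 0` and
#'   `p* = (b (2 - mu) - c - sqrt(c^2 + b mu (4 + b mu - 2 c))) / (2 b)`,
#'   stable iff `mu < (b - c) / (1 + b - c)`.
#' * cytoplasmic incompatibility: three equilibria,
#'   `E1: p* = 0`,
#'   `E2: p* = (h - sqrt(h^2 - 4 h mu (1 - mu))) / (2 h (1 - mu))` and
#'   `E3: p* = (h + sqrt(h^2 - 4 h mu (1 - mu))) / (2 h (1 - mu))`.
#'   The interior pair is real iff `mu < (1 - sqrt(1 - h)) / 2`. Because the
#'   advantage is positively frequency-dependent the system is bistable: `E2`
#'   is an unstable separatrix and the symbiont only reaches the stable upper
#'   equilibrium `E3` from initial frequencies above `E2`.
#'
#' Equilibria within `1e-9` of 0 or 1 are snapped to the boundary to avoid
#' spurious "polymorphic" classifications. Interior roots falling outside
#' `[0, 1]` are returned flagged infeasible rather than dropped.
#'
#' @param params A `cyto_params` object.
#' @return A tibble with one row per equilibrium and columns `equilibrium`
#'   (label), `p_star`, `feasible`, `stable` and `kind` (one of `"trivial"`,
#'   `"internal_stable"`, `"internal_unstable"`).
#' @examples
#' cyto_equilibria(fixed_benefit_params(B = 0.075, mu = 0.05))
#' cyto_equilibria(ci_params(h = 0.25, mu = 0.05))
#' @export
cyto_equilibria <- function(params) {
  UseMethod("cyto_equilibria", params)
}

snap_boundary <- function(p) {
  p[abs(p) < 1e-9] <- 0
  p[abs(p - 1) < 1e-9] <- 1
  p
}

eq_row <- function(label, p_star, stable) {
  p_star <- snap_boundary(p_star)
  feasible <- is.finite(p_star) & p_star >= 0 & p_star <= 1
  kind <- ifelse(label %in% c("trivial", "E1"), "trivial",
                 ifelse(stable, "internal_stable", "internal_unstable"))
  tibble(equilibrium = label, p_star = p_star,
         feasible = feasible, stable = stable, kind = kind)
}

#' @export
cyto_equilibria.fixed_benefit_params <- function(params) {
  B <- params$B; mu <- params$mu
  persist <- B > 0 && mu < B / (1 + B)
  out <- eq_row("trivial", 0, stable = !persist)
  if (B != 0) {
    out <- dplyr::bind_rows(out,
      eq_row("internal", 1 - (1 + B) * mu / B, stable = persist))
  }
  out
}

#' @export
cyto_equilibria.freq_dep_params <- function(params) {
  b <- params$b; c <- params$c; mu <- params$mu
  persist <- b > c && mu < (b - c) / (1 + b - c)
  out <- eq_row("trivial", 0, stable = !persist)
  if (b > 0) {
    disc <- c^2 + b * mu * (4 + b * mu - 2 * c)
    p_star <- (b * (2 - mu) - c - sqrt(disc)) / (2 * b)
    out <- dplyr::bind_rows(out, eq_row("internal", p_star, stable = persist))
  }
  out
}

#' @export
cyto_equilibria.ci_params <- function(params) {
  h <- params$h; mu <- params$mu
  out <- eq_row("E1", 0, stable = TRUE)
  if (h > 0) {
    disc <- h^2 - 4 * h * mu * (1 - mu)
    if (disc > -1e-12) {        # roundoff guard at exact tangency
      disc <- max(disc, 0)
      e2 <- (h - sqrt(disc)) / (2 * h * (1 - mu))
      e3 <- (h + sqrt(disc)) / (2 * h * (1 - mu))
      out <- dplyr::bind_rows(out,
        eq_row("E2", e2, stable = FALSE),
        eq_row("E3", e3, stable = TRUE))
    }
  }
  out
}

#' Critical segregational loss rate for symbiont persistence
#'
#' Returns the closed-form bound on the segregational loss rate `mu` below
#' which the symbiont can persist: `B / (1 + B)` (fixed benefit),
#' `(b - c) / (1 + b - c)` (frequency-dependent benefit) or
#' `(1 - sqrt(1 - h)) / 2` (cytoplasmic incompatibility; for the bistable CI
#' model this is a feasibility bound — the symbiont must additionally start
#' above the separatrix `E2`).
#'
#' @param params A `cyto_params` object (its `mu` field is ignored).
#' @return The critical loss rate.
#' @export
persistence_bound <- function(params) {
  switch(params$model,
    fixed_benefit = max(params$B, 0) / (1 + params$B),
    freq_dep = max(params$b - params$c, 0) / (1 + params$b - params$c),
    ci = (1 - sqrt(1 - params$h)) / 2)
}

#' Resident equilibrium as a full cytotype state
#'
#' The stable symbiont/uninfected balance before the novel mitotype appears
#' (`r = s = 0`). For the cytoplasmic incompatibility model this is the upper
#' stable equilibrium `E3`. Signals a `cytosweep_error_no_resident_equilibrium`
#' condition when the symbiont cannot persist at these parameters.
#'
#' @param params A `cyto_params` object.
#' @return A [cytotype_state()] `(p*, 1 - p*, 0, 0)`.
#' @examples
#' resident_equilibrium(fixed_benefit_params(B = 0.075, mu = 0.05))
#' @export
resident_equilibrium <- function(params) {
  eq <- cyto_equilibria(params)
  cand <- eq[eq$kind == "internal_stable" & eq$feasible & eq$stable, ]
  if (nrow(cand) == 0 || params$mu >= persistence_bound(params)) {
    cyto_abort(
      "The symbiont cannot persist at these parameters (no stable resident equilibrium).",
      "cytosweep_error_no_resident_equilibrium")
  }
  p_star <- max(cand$p_star)  # E3 for the CI model
  cytotype_state(p = p_star, q = 1 - p_star)
}

#' Locate the persistence threshold by simulated bisection
#'
#' Brackets the critical segregational loss rate by simulating the full
#' recursion at trial values of `mu` and bisecting on the
#' extinction/persistence outcome, as an independent check on the closed-form
#' criteria of [persistence_bound()]. The symbiont is started at frequency
#' `p0` (0.9 by default for the bistable CI model, where the start must lie
#' above the separatrix; 0.5 otherwise) and counted persistent when its
#' frequency still exceeds `extinct_below` after `horizon` generations.
#'
#' @param params A `cyto_params` object; its `mu` field is ignored and `t`
#'   plays no role because the scan runs in the resident subsystem.
#' @param resolution Width of the final bisection bracket.
#' @param p0 Initial symbiont frequency.
#' @param horizon Generations simulated per probe.
#' @param extinct_below Frequency below which the symbiont counts as extinct.
#' @return The midpoint of the final bracket, with attribute `bracket`.
#' @export
critical_loss_rate <- function(params, resolution = 1e-4, p0 = NULL,
                               horizon = 5e5, extinct_below = 1e-6) {
  p0 <- p0 %||% if (params$model == "ci") 0.9 else 0.5
  persists_at <- function(mu) {
    pars <- with_params(params, mu = mu, t = 0)
    res <- iterate_compiled(pars, cytotype_state(p = p0, q = 1 - p0),
                            tol = 1e-13, max_gen = horizon)
    symbiont_freq(res$state) > extinct_below
  }
  lo <- resolution / 2
  hi <- 0.49
  if (!persists_at(lo)) {
    cyto_abort("Symbiont does not persist even at negligible segregational loss.",
               "cytosweep_error_no_resident_equilibrium")
  }
  if (persists_at(hi)) {
    cyto_abort("Symbiont persists across the whole bisection bracket.",
               "cytosweep_error_params")
  }
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (persists_at(mid)) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, bracket = c(lo, hi))
}
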