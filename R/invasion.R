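#' Introduce a rare novel mitotype into a resident equilibrium
#'
#' Moves a frequency `epsilon` of hosts from the chosen origin compartment of
#' a resident equilibrium (`r = s = 0`) into the corresponding novel-mitotype
#' compartment: an infected origin yields `(p* - eps, q*, eps, 0)`, an
#' uninfected origin `(p*, q* - eps, 0, eps)`. Because the dynamics are
#' deterministic, `epsilon` only sets the length of the transient.
#'
#' Signals `cytosweep_error_impossible_origin` when the origin compartment
#' holds less than `epsilon` (e.g. an uninfected origin when the symbiont is
#' fixed).
#'
#' @param resident_eq A [cytotype_state()] with `r = s = 0`.
#' @param origin `"infected"` or `"uninfected"`: the compartment in which the
#'   mutation arises.
#' @param epsilon Introduction frequency.
#' @return The perturbed [cytotype_state()].
#' @examples
#' eq <- resident_equilibrium(fixed_benefit_params(B = 0.075, mu = 0.05))
#' introduce_mutant(eq, "infected")
#' @export
introduce_mutant <- function(resident_eq, origin = c("infected", "uninfected"),
                             epsilon = 1e-5) {
  origin <- match.arg(origin)
  st <- as_cytotype_state(resident_eq)
  if (st[[3]] != 0 || st[[4]] != 0) {
    cyto_abort("`resident_eq` must have r = s = 0.", "cytosweep_error_state")
  }
  epsilon <- check_scalar(epsilon, "epsilon", 0, 1)
  donor <- if (origin == "infected") st[[1]] else st[[2]]
  if (donor < epsilon) {
    cyto_abort(
      sprintf("Cannot introduce the mutant: the %s compartment holds only %.3g.",
              origin, donor),
      "cytosweep_error_impossible_origin")
  }
  if (origin == "infected") {
    cytotype_state(p = st[[1]] - epsilon, q = st[[2]], r = epsilon, s = 0)
  } else {
    cytotype_state(p = st[[1]], q = st[[2]] - epsilon, r = 0, s = epsilon)
  }
}

# Per-generation multiplication rates of the rare (r, s) compartments,
# linearized at the resident equilibrium p_star. The linearization is lower
# triangular (nothing flows from the uninfected mutant class back into the
# infected one), so its eigenvalues are the two diagonal rates.
mutant_rates <- function(params, p_star) {
  q_star <- 1 - p_star
  mu <- params$mu; t <- params$t
  if (params$model == "fixed_benefit") {
    w <- 1 + params$B
    den <- p_star * w + q_star
  } else if (params$model == "freq_dep") {
    w <- 1 + params$b * (1 - p_star) - params$c
    den <- p_star * w + q_star
  } else {
    h <- params$h
    den <- 1 - h * p_star * (1 - p_star * (1 - mu))  # Phi at the resident eq
    w <- NULL
  }
  if (params$model == "ci") {
    r_rate <- (1 - mu) * (1 + t) / den
    s_rate <- (1 + t) * (1 - params$h * p_star) / den
  } else {
    r_rate <- w * (1 - mu) * (1 + t) / den
    s_rate <- (1 + t) / den
  }
  c(r = r_rate, s = s_rate)
}

#' Linearized growth factor of a rare novel mitotype
#'
#' The dominant per-generation multiplicative growth of the rare mutant
#' lineage at the resident equilibrium. For an uninfected origin there is no
#' flow back into the infected mutant class, so the growth factor is the
#' uninfected compartment's own multiplication rate (for the fixed-benefit
#' model, `(1 + t) / ((1 + B)(1 - mu))`, giving the invasion boundary
#' `t = B (1 - mu) - mu`). For an infected origin it is the dominant
#' eigenvalue of the two-dimensional linearization, which equals `1 + t` in
#' all three models — an advantageous mitotype arising in an infected host
#' always invades.
#'
#' @inheritParams introduce_mutant
#' @param params A `cyto_params` object (the resident equilibrium must exist).
#' @return The growth factor (a positive number; values above 1 mean the
#'   mutant increases when rare).
#' @examples
#' mutant_growth_factor(fixed_benefit_params(B = 0.075, mu = 0.05, t = 0.02),
#'                      origin = "uninfected")
#' @export
mutant_growth_factor <- function(params, origin = c("infected", "uninfected")) {
  origin <- match.arg(origin)
  eq <- resident_equilibrium(params)
  rates <- mutant_rates(params, eq[[1]])
  if (origin == "uninfected") unname(rates[["s"]]) else unname(max(rates))
}

#' Analytic invasion and displacement thresholds
#'
#' Closed-form contours in `t` along which the rare-mutant growth factor
#' equals one, for a novel mitotype arising in a symbiont-uninfected host:
#'
#' * `threshold_t_fixed_benefit()` — `t = B (1 - mu) - mu`. Above this the
#'   mutant both invades and excludes the symbiont (fixed-benefit model).
#' * `threshold_t_freq_dep_invasion()` — the invasion boundary of the
#'   frequency-dependent model, `t = (1 - mu)(1 + b (1 - p*) - c) - 1`
#'   evaluated at the resident equilibrium `p*`: the mutant invades when its
#'   benefit overcomes the segregational input sustaining the uninfected
#'   class at equilibrium.
#' * `threshold_t_freq_dep_displacement()` — `t = (1 + b - c)(1 - mu) - 1`.
#'   Above this the mutant beats the symbiont even at vanishing symbiont
#'   frequency (where the frequency-dependent benefit is maximal) and
#'   displaces it; between the two curves the mutant invades but coexists
#'   with the symbiont, partitioned between infection classes.
#'
#' All three signal an error when the symbiont cannot persist at `(b, c, mu)`
#' or `(B, mu)`, since the thresholds are defined against a resident
#' equilibrium. At `mu = 0` the frequency-dependent invasion threshold is 0
#' (any advantageous mitotype invades the uninfected fraction) and the
#' displacement threshold reduces to `t = b - c`.
#'
#' @param B,b,c,mu Model parameters, as in [fixed_benefit_params()] and
#'   [freq_dep_params()].
#' @return The threshold value of `t`.
#' @examples
#' threshold_t_fixed_benefit(B = 0.075, mu = 0.05)  # 0.02125
#' threshold_t_freq_dep_displacement(b = 0.1, c = 0.05, mu = 0.02)  # 0.029
#' @export
threshold_t_fixed_benefit <- function(B, mu) {
  pars <- fixed_benefit_params(B = B, mu = mu)
  if (mu >= persistence_bound(pars)) {
    cyto_abort("No resident equilibrium: mu >= B / (1 + B).",
               "cytosweep_error_no_resident_equilibrium")
  }
  B * (1 - mu) - mu
}

#' @rdname threshold_t_fixed_benefit
#' @export
threshold_t_freq_dep_displacement <- function(b, c, mu) {
  pars <- freq_dep_params(b = b, c = c, mu = mu)
  if (mu >= persistence_bound(pars)) {
    cyto_abort("No resident equilibrium: mu >= (b - c) / (1 + b - c).",
               "cytosweep_error_no_resident_equilibrium")
  }
  (1 + b - c) * (1 - mu) - 1
}

#' @rdname threshold_t_fixed_benefit
#' @export
threshold_t_freq_dep_invasion <- function(b, c, mu) {
  pars <- freq_dep_params(b = b, c = c, mu = mu)
  eq <- resident_equilibrium(pars)  # errors when the symbiont cannot persist
  (1 - mu) * (1 + b * (1 - eq[[1]]) - c) - 1
}

#' Classify the long-run outcome of a mitotype invasion
#'
#' Starts the full four-dimensional recursion from the resident equilibrium
#' perturbed by [introduce_mutant()], iterates to a fixed point (or the
#' generation `horizon`), and classifies the final state:
#'
#' * `mitotype_lost` — the novel mitotype frequency `r + s` fell below
#'   `eps_extinct`;
#' * `mitotype_fixed_symbiont_excluded` — the mitotype fixed and the symbiont
#'   frequency `p + r` fell below `eps_extinct`;
#' * `mitotype_fixed_symbiont_retained` — the mitotype fixed with the
#'   symbiont still present;
#' * `coexistence_partitioned` — converged with the mitotype polymorphic
#'   (the frequency-dependent model's partitioned state, with the ancestral
#'   mitotype persisting among infected hosts and segregants);
#' * `indeterminate` — the growth factor sits within `1e-6` of one (a
#'   measure-zero boundary case that is not forced into a class), or the
#'   recursion failed to converge within `horizon`.
#'
#' Extinction and fixation are decided against `eps_extinct` while the
#' recursion is running; at a converged fixed point the cutoff is widened to
#' the introduction scale `epsilon`, because a lineage decaying geometrically
#' towards a boundary stalls the iteration marginally above `eps_extinct`
#' while every genuine interior equilibrium is macroscopic.
#'
#' For the cytoplasmic incompatibility model the resident equilibrium used is
#' the upper stable equilibrium `E3`; when an invading mutant drives the
#' symbiont below the separatrix `E2` the positive frequency dependence
#' collapses the infection, and the final (post-collapse) state is what gets
#' classified.
#'
#' @inheritParams introduce_mutant
#' @param params A `cyto_params` object.
#' @param epsilon Introduction frequency of the mutant.
#' @param horizon Generation budget.
#' @param eps_extinct Frequency below which a lineage counts as extinct
#'   (fixation is `1 - eps_extinct`).
#' @param tol Fixed-point tolerance.
#' @return An object of class `cyto_invasion`: a list with the origin, the
#'   linearized `growth_factor`, the `outcome` label, the `final_state`, the
#'   generation count, convergence flag, and the pre-invasion symbiont
#'   frequency `p_star_before`. [tidy()] returns per-compartment start/final
#'   frequencies; [glance()] a one-row summary.
#' @examples
#' classify_invasion(fixed_benefit_params(B = 0.075, mu = 0.05, t = 0.02),
#'                   origin = "uninfected")
#' @export
classify_invasion <- function(params, origin = c("infected", "uninfected"),
                              epsilon = 1e-5, horizon = 1e6,
                              eps_extinct = 1e-9, tol = 1e-12) {
  origin <- match.arg(origin)
  eq <- resident_equilibrium(params)
  state0 <- introduce_mutant(eq, origin, epsilon)
  gf <- mutant_growth_factor(params, origin)

  if (abs(gf - 1) < 1e-6) {
    res <- list(state = state0, generations = 0L, converged = FALSE)
    outcome <- "indeterminate"
  } else {
    res <- iterate_compiled(params, state0, tol = tol, max_gen = horizon,
                            stop_mutant_below = eps_extinct * 1e-2)
    m <- mutant_freq(res$state)
    sy <- symbiont_freq(res$state)
    # A lineage decaying geometrically towards a boundary makes the iteration
    # step size fall inside `tol` while the lineage can still sit marginally
    # above `eps_extinct`; once converged, anything below its introduction
    # scale is counted extinct (genuine interior equilibria are macroscopic).
    cut <- if (res$converged) max(eps_extinct, min(epsilon, 1e-5))
           else eps_extinct
    outcome <-
      if (m < cut) "mitotype_lost"
      else if (m > 1 - cut) {
        if (sy < cut) "mitotype_fixed_symbiont_excluded"
        else "mitotype_fixed_symbiont_retained"
      }
      else if (!res$converged) "indeterminate"
      else "coexistence_partitioned"
  }

  structure(
    list(params = params, origin = origin, epsilon = epsilon,
         growth_factor = gf, outcome = outcome,
         initial_state = state0, final_state = res$state,
         generations = res$generations, converged = isTRUE(res$converged),
         p_star_before = eq[[1]]),
    class = "cyto_invasion")
}

#' @export
print.cyto_invasion <- function(x, ...) {
  cat("<cyto_invasion> ", x$params$model, " model, ", x$origin, " origin\n",
      sep = "")
  cat(sprintf("  growth factor %.6f -> %s after %d generations\n",
              x$growth_factor, x$outcome, x$generations))
  cat(sprintf("  symbiont frequency %.6f -> %.6f; mutant frequency %.6f\n",
              x$p_star_before, symbiont_freq(x$final_state),
              mutant_freq(x$final_state)))
  invisible(x)
}

#' Largest symbiont prevalence at which a mitotype can exclude the symbiont
#'
#' For the fixed-benefit model, a novel mitotype of benefit `t` arising in an
#' uninfected host excludes the symbiont only above the boundary
#' `t = B (1 - mu) - mu`. Inverting the boundary for `mu` at fixed `t` and
#' evaluating the resident equilibrium there gives, for each symbiont benefit
#' `B`, the largest pre-invasion prevalence at which exclusion is still
#' possible; this function tabulates that bound over a grid of `B` and
#' reports its maximum. With the default `t = 0.02` (a strong, 2% mitotype
#' advantage) the bound shows exclusion is confined to low-prevalence
#' symbionts.
#'
#' @param t Mitotype benefit.
#' @param B_range Range of symbiont benefits scanned.
#' @param n_B Number of grid points over `B_range`.
#' @return A tibble with columns `B`, `mu_boundary` (loss rate on the
#'   invasion boundary) and `prevalence` (resident equilibrium there), with
#'   attribute `max_prevalence`.
#' @examples
#' bound <- exclusion_prevalence_bound()
#' attr(bound, "max_prevalence")
#' @export
exclusion_prevalence_bound <- function(t = 0.02, B_range = c(0.1, 0.5),
                                       n_B = 81) {
  B_grid <- seq(B_range[1], B_range[2], length.out = n_B)
  out <- purrr::map_dfr(B_grid, function(B) {
    mu_b <- (B - t) / (1 + B)  # solves t = B (1 - mu) - mu
    if (mu_b < 0 || mu_b >= B / (1 + B)) {
      return(tibble(B = B, mu_boundary = mu_b, prevalence = NA_real_))
    }
    eq <- cyto_equilibria(fixed_benefit_params(B = B, mu = mu_b))
    tibble(B = B, mu_boundary = mu_b,
           prevalence = eq$p_star[eq$equilibrium == "internal"])
  })
  structure(out, max_prevalence = max(out$prevalence, na.rm = TRUE))
}

#' Ceiling on CI strength for uninfected-origin mitotype invasion
#'
#' Scans the strength of cytoplasmic incompatibility `h` and asks, for each
#' value, whether a novel mitotype with benefit `t <= t_max` arising in an
#' uninfected host can invade a population sitting at the symbiont's upper
#' stable equilibrium `E3` for *any* segregational loss rate compatible with
#' symbiont persistence. Each `(mu, t)` cell is decided by running the full
#' recursion from the perturbed equilibrium to a fixed point. The reported
#' ceiling is the largest scanned `h` with at least one invading cell.
#'
#' The ceiling is an operationalization on a finite grid: `n_mu` loss rates
#' are placed evenly strictly inside `(0, (1 - sqrt(1 - h)) / 2)` and `n_t`
#' benefits in `(0, t_max]`. Because the uninfected-origin growth factor
#' rises towards one as `mu` approaches the feasibility bound (where `E3`
#' collapses onto the separatrix), a finer or boundary-clustered `mu` grid
#' admits invasion at somewhat larger `h`; the default resolution reflects
#' biologically distinguishable loss rates rather than that limit.
#'
#' @param t_max Largest mitotype benefit considered.
#' @param h_max,h_step Range and step of the `h` scan (grid is
#'   `seq(h_step, h_max, by = h_step)`).
#' @param n_mu,n_t Grid resolution in `mu` and `t` per `h`.
#' @param epsilon Introduction frequency.
#' @param horizon Generation budget per cell.
#' @return A tibble with one row per scanned `h`: whether any cell invaded
#'   and the first invading `(mu, t)`; attribute `h_ceiling` holds the
#'   largest invading `h` (`NA` if none).
#' @export
ci_invasion_ceiling <- function(t_max = 0.02, h_max = 0.2, h_step = 0.005,
                                n_mu = 26, n_t = 26, epsilon = 1e-5,
                                horizon = 1e6) {
  h_grid <- seq(h_step, h_max, by = h_step)
  rows <- purrr::map_dfr(h_grid, function(h) {
    mu_max <- (1 - sqrt(1 - h)) / 2
    mu_grid <- mu_max * seq_len(n_mu) / (n_mu + 1)
    t_grid <- t_max * seq_len(n_t) / n_t
    # invasion is most likely at large t and large mu; scan from there so the
    # common (invading) case exits early
    for (tt in rev(t_grid)) {
      for (mu in rev(mu_grid)) {
        inv <- classify_invasion(ci_params(h = h, mu = mu, t = tt),
                                 origin = "uninfected", epsilon = epsilon,
                                 horizon = horizon)
        if (!inv$outcome %in% c("mitotype_lost", "indeterminate")) {
          return(tibble(h = h, invaded = TRUE, mu = mu, t = tt))
        }
      }
    }
    tibble(h = h, invaded = FALSE, mu = NA_real_, t = NA_real_)
  })
  ceiling_h <- if (any(rows$invaded)) max(rows$h[rows$invaded]) else NA_real_
  structure(rows, h_ceiling = ceiling_h)
}
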