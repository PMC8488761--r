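test_that("fixed-benefit equilibria and persistence criterion", {
  eq <- cyto_equilibria(fixed_benefit_params(B = 0.075, mu = 0.05))
  internal <- eq[eq$equilibrium == "internal", ]
  expect_equal(internal$p_star, 1 - (1.075 * 0.05) / 0.075, tolerance = 1e-12)
  expect_equal(internal$p_star, 0.2833333, tolerance = 1e-6)
  expect_true(internal$stable)  # mu = 0.05 < B/(1+B) = 0.069767
  expect_false(eq$stable[eq$equilibrium == "trivial"])

  # no segregational loss: symbiont fixes
  eq0 <- cyto_equilibria(fixed_benefit_params(B = 0.2, mu = 0))
  expect_equal(eq0$p_star[eq0$equilibrium == "internal"], 1)

  # boundary collapse at mu = B/(1+B): internal coincides with trivial
  B <- 0.3
  eqb <- cyto_equilibria(fixed_benefit_params(B = B, mu = B / (1 + B)))
  expect_equal(eqb$p_star[eqb$equilibrium == "internal"], 0)

  # B = 0 divides the internal form by zero: only the trivial equilibrium
  expect_equal(nrow(cyto_equilibria(fixed_benefit_params(B = 0, mu = 0.1))), 1L)
})

test_that("frequency-dependent equilibria match the radical closed form", {
  eq <- cyto_equilibria(freq_dep_params(b = 0.1, c = 0.05, mu = 0.02))
  internal <- eq[eq$equilibrium == "internal", ]
  expect_equal(internal$p_star, 0.232456898382, tolerance = 1e-10)
  expect_true(internal$stable)  # mu < (b - c)/(1 + b - c) = 0.047619

  # pure benefit, perfect transmission: fixation
  eq0 <- cyto_equilibria(freq_dep_params(b = 0.2, c = 0, mu = 0))
  expect_equal(eq0$p_star[eq0$equilibrium == "internal"], 1)

  # beyond the persistence criterion the internal root is flagged, not dropped,
  # and iteration from any interior start collapses to extinction
  set.seed(7)
  for (i in 1:20) {
    pars <- random_params("freq_dep", persistent = FALSE, t = 0)
    eq <- cyto_equilibria(pars)
    expect_false(any(eq$stable & eq$kind == "internal_stable"))
    p0 <- stats::runif(1, 0.05, 0.95)
    fp <- find_fixed_point(pars, cytotype_state(p = p0, q = 1 - p0))
    expect_lt(symbiont_freq(fp), 1e-8)
  }
})

test_that("CI equilibria E1-E3, feasibility bound and tangency", {
  eq <- cyto_equilibria(ci_params(h = 0.25, mu = 0.05))
  expect_equal(eq$p_star[eq$equilibrium == "E2"], 0.2684748, tolerance = 1e-6)
  expect_equal(eq$p_star[eq$equilibrium == "E3"], 0.7841568, tolerance = 1e-6)
  expect_false(eq$stable[eq$equilibrium == "E2"])
  expect_true(eq$stable[eq$equilibrium == "E3"])
  expect_gt(persistence_bound(ci_params(h = 0.25, mu = 0)), 0.05)
  expect_equal(persistence_bound(ci_params(h = 0.25, mu = 0)),
               (1 - sqrt(0.75)) / 2, tolerance = 1e-12)

  # perfect transmission: separatrix at 0, stable equilibrium at fixation
  eq0 <- cyto_equilibria(ci_params(h = 0.3, mu = 0))
  expect_equal(eq0$p_star[eq0$equilibrium == "E2"], 0)
  expect_equal(eq0$p_star[eq0$equilibrium == "E3"], 1)

  # at the tangency the two interior equilibria coincide
  h <- 0.2; mu_t <- (1 - sqrt(1 - h)) / 2
  eqt <- cyto_equilibria(ci_params(h = h, mu = mu_t))
  expect_equal(eqt$p_star[eqt$equilibrium == "E2"],
               eqt$p_star[eqt$equilibrium == "E3"], tolerance = 1e-7)

  # past it, only extinction remains
  expect_equal(cyto_equilibria(ci_params(h = h, mu = mu_t * 1.2))$equilibrium,
               "E1")
})

test_that("every feasible closed-form equilibrium is step-invariant", {
  set.seed(8)
  for (m in MODELS) {
    for (i in 1:15) {
      pars <- random_params(m, t = 0)
      eq <- cyto_equilibria(pars)
      for (p_star in eq$p_star[eq$feasible]) {
        st <- cytotype_state(p = p_star, q = 1 - p_star)
        expect_equal(unclass(cyto_step(st, pars)), unclass(st),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("resident_equilibrium returns the stable state or a typed error", {
  eq <- resident_equilibrium(fixed_benefit_params(B = 0.075, mu = 0.05))
  expect_equal(eq[[1]], 0.2833333, tolerance = 1e-6)
  expect_equal(eq[[3]], 0)
  # E3 for the CI model
  expect_equal(resident_equilibrium(ci_params(h = 0.25, mu = 0.05))[[1]],
               0.7841568, tolerance = 1e-6)
  expect_error(resident_equilibrium(fixed_benefit_params(B = 0.05, mu = 0.3)),
               class = "cytosweep_error_no_resident_equilibrium")
})

test_that("simulated persistence flips at the closed-form criteria", {
  # one parameter set per model; tighter sweeps live in the acceptance suite
  pars <- fixed_benefit_params(B = 0.075, mu = 0)
  est <- critical_loss_rate(pars, resolution = 5e-4)
  expect_equal(as.numeric(est), 0.075 / 1.075, tolerance = 1e-2)
  expect_lt(abs(as.numeric(est) - 0.075 / 1.075), 5e-4)
})
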