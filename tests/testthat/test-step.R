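# The one-generation recursions, checked against hand evaluations,
# stationarity at the closed-form resident equilibria, and the printed
# model reductions.

test_that("absorbing states are fixed points of the step operators", {
  fixed_all <- cytotype_state(1, 0, 0, 0)
  none <- cytotype_state(0, 1, 0, 0)

  # fixed symbiont with perfect transmission is absorbing
  expect_equal(unclass(cyto_step(fixed_all, fixed_benefit_params(0.2, mu = 0, t = 0.03))),
               unclass(fixed_all))
  expect_equal(unclass(cyto_step(fixed_all, ci_params(h = 0.4, mu = 0, t = 0.05))),
               unclass(fixed_all))
  # symbiont-free, mutant-free state is absorbing in every model
  for (m in MODELS) {
    pars <- random_params(m)
    expect_equal(unclass(cyto_step(none, pars)), unclass(none))
  }
  # frequency-dependent benefit vanishes at fixation: stationary with mu = 0
  expect_equal(unclass(cyto_step(fixed_all, freq_dep_params(b = 0.3, c = 0, mu = 0))),
               unclass(fixed_all))
})

test_that("the fixed-benefit step matches a hand evaluation", {
  out <- cyto_step(cytotype_state(0.5, 0.5),
                   fixed_benefit_params(B = 0, mu = 0.1, t = 0))
  expect_equal(out[[1]], 0.45)
  expect_equal(out[[2]], 0.55)
  expect_equal(out[[3]], 0)
  expect_equal(out[[4]], 0)
})

test_that("closed-form resident equilibria are stationary under the full step", {
  cases <- list(
    fixed_benefit_params(B = 0.075, mu = 0.05, t = 0.02),
    freq_dep_params(b = 0.1, c = 0.05, mu = 0.02, t = 0.02),
    ci_params(h = 0.25, mu = 0.05, t = 0.02)
  )
  for (pars in cases) {
    p_star <- closed_form_p_star(pars)
    st <- cytotype_state(p = p_star, q = 1 - p_star)
    out <- cyto_step(st, pars)
    expect_equal(unclass(out), unclass(st), tolerance = 1e-12)
  }
  # and the frozen values themselves, from direct evaluation of the formulas
  expect_equal(closed_form_p_star(cases[[1]]), 0.2833333333, tolerance = 1e-9)
  expect_equal(closed_form_p_star(cases[[2]]), 0.232456898382, tolerance = 1e-11)
  expect_equal(closed_form_p_star(cases[[3]]), 0.7841568150, tolerance = 1e-9)
})

test_that("with r = s = 0 the full step reduces to the single-equation map", {
  set.seed(41)
  for (m in MODELS) {
    for (i in 1:25) {
      pars <- random_params(m, persistent = sample(c(TRUE, FALSE), 1))
      p <- stats::runif(1)
      out <- cyto_step(cytotype_state(p = p, q = 1 - p), pars)
      expect_equal(out[[1]], resident_map(p, pars), tolerance = 1e-14)
      expect_equal(out[[3]], 0)
      expect_equal(out[[4]], 0)
    }
  }
})

test_that("CI with h = 0 reduces to a neutral fixed-benefit step", {
  set.seed(42)
  for (i in 1:20) {
    st <- random_state()
    mu <- stats::runif(1); t <- stats::runif(1, 0, 0.1)
    a <- cyto_step(st, ci_params(h = 0, mu = mu, t = t))
    b <- cyto_step(st, fixed_benefit_params(B = 0, mu = mu, t = t))
    expect_equal(unclass(a), unclass(b), tolerance = 1e-15)
  }
})

test_that("frequency dependence with b = 0 reduces to a fixed benefit of -c", {
  set.seed(43)
  for (i in 1:20) {
    st <- random_state()
    cc <- stats::runif(1, 0, 0.5); mu <- stats::runif(1); t <- stats::runif(1, 0, 0.1)
    a <- cyto_step(st, freq_dep_params(b = 0, c = cc, mu = mu, t = t))
    b <- cyto_step(st, fixed_benefit_params(B = -cc, mu = mu, t = t))
    expect_equal(unclass(a), unclass(b), tolerance = 1e-15)
  }
})

test_that("compiled and interpreted steps agree to machine precision", {
  set.seed(44)
  for (m in MODELS) {
    for (i in 1:20) {
      pars <- random_params(m, persistent = sample(c(TRUE, FALSE), 1))
      st <- random_state()
      res <- cytosweep:::cpp_step(unclass(st), cytosweep:::model_id(pars),
                                  cytosweep:::par_vector(pars))
      expect_identical(res$code, 0L)
      expect_equal(res$state, unname(unclass(cyto_step(st, pars))),
                   tolerance = 1e-15)
    }
  }
})

test_that("a non-positive offspring normalizer is a degenerate-state error", {
  # cannot arise for validated parameters; forge a t <= -1 to hit the guard
  bad <- structure(list(model = "fixed_benefit", B = 0.1, mu = 0.1, t = -1),
                   class = c("fixed_benefit_params", "cyto_params"))
  expect_error(cyto_step(cytotype_state(0, 0, 0.5, 0.5), bad),
               class = "cytosweep_error_degenerate")
})
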