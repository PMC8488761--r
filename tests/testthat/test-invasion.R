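test_that("introduce_mutant moves epsilon between the right compartments", {
  eq <- cytotype_state(p = 0.2833, q = 0.7167)
  st <- introduce_mutant(eq, "uninfected", epsilon = 1e-5)
  expect_equal(unname(unclass(st)), c(0.2833, 0.7167 - 1e-5, 0, 1e-5))
  st2 <- introduce_mutant(eq, "infected", epsilon = 1e-5)
  expect_equal(unname(unclass(st2)), c(0.2833 - 1e-5, 0.7167, 1e-5, 0))

  expect_error(introduce_mutant(cytotype_state(1, 0), "uninfected"),
               class = "cytosweep_error_impossible_origin")
  expect_error(introduce_mutant(cytotype_state(0.3, 0.6, 0.1, 0), "infected"),
               "r = s = 0")
})

test_that("uninfected-origin growth crosses 1 exactly at t = B(1-mu) - mu", {
  B <- 0.075; mu <- 0.05
  t_star <- threshold_t_fixed_benefit(B, mu)
  expect_equal(t_star, 0.02125)
  gf <- mutant_growth_factor(fixed_benefit_params(B, mu, t = t_star),
                             "uninfected")
  expect_equal(gf, 1, tolerance = 1e-12)
  expect_lt(mutant_growth_factor(fixed_benefit_params(B, mu, t = 0.02),
                                 "uninfected"), 1)
  expect_gt(mutant_growth_factor(fixed_benefit_params(B, mu, t = 0.022),
                                 "uninfected"), 1)
})

test_that("an infected-origin mutant grows at exactly 1 + t in all models", {
  set.seed(11)
  for (m in MODELS) {
    for (i in 1:10) {
      pars <- random_params(m)
      expect_equal(mutant_growth_factor(pars, "infected"), 1 + pars$t,
                   tolerance = 1e-12)
    }
    # and is exactly neutral at t = 0
    pars0 <- random_params(m, t = 0)
    expect_equal(mutant_growth_factor(pars0, "infected"), 1, tolerance = 1e-12)
  }
})

test_that("analytic thresholds evaluate and invert as expected", {
  expect_equal(threshold_t_fixed_benefit(B = 0.075, mu = 0), 0.075)
  # inversion: the mu at which the fixed-benefit threshold equals 0.02
  B <- 0.1
  mu_inv <- (B - 0.02) / (1 + B)
  expect_equal(mu_inv, 0.0727272727, tolerance = 1e-9)
  expect_equal(threshold_t_fixed_benefit(B, mu_inv), 0.02, tolerance = 1e-12)

  expect_equal(threshold_t_freq_dep_displacement(b = 0.1, c = 0.05, mu = 0.02),
               0.029, tolerance = 1e-12)
  expect_equal(threshold_t_freq_dep_displacement(b = 0.1, c = 0.05, mu = 0),
               0.05, tolerance = 1e-12)  # reduces to b - c
  expect_equal(threshold_t_freq_dep_displacement(b = 0.1, c = 0, mu = 0), 0.1)

  # with perfect transmission any advantageous mitotype invades the
  # uninfected fraction: the invasion threshold vanishes
  expect_equal(threshold_t_freq_dep_invasion(b = 0.1, c = 0.05, mu = 0), 0,
               tolerance = 1e-12)
  t_inv <- threshold_t_freq_dep_invasion(b = 0.1, c = 0.05, mu = 0.02)
  expect_equal(t_inv, 0.0062192240, tolerance = 1e-8)
  expect_lt(t_inv, 0.02)

  expect_error(threshold_t_fixed_benefit(B = 0.05, mu = 0.3),
               class = "cytosweep_error_no_resident_equilibrium")
  expect_error(threshold_t_freq_dep_displacement(b = 0.1, c = 0.08, mu = 0.1),
               class = "cytosweep_error_no_resident_equilibrium")
})

test_that("the invasion threshold matches a root-find on the growth factor", {
  set.seed(12)
  for (i in 1:15) {
    pars <- random_params("freq_dep")
    t_star <- threshold_t_freq_dep_invasion(pars$b, pars$c, pars$mu)
    root <- uniroot(function(t) {
      mutant_growth_factor(
        freq_dep_params(b = pars$b, c = pars$c, mu = pars$mu, t = t),
        "uninfected") - 1
    }, lower = -0.5, upper = 1, tol = 1e-14)$root
    expect_equal(t_star, root, tolerance = 1e-10)
    # the invade-but-not-displace band exists whenever mu > 0
    expect_lt(t_star,
              threshold_t_freq_dep_displacement(pars$b, pars$c, pars$mu))
  }
})

test_that("invasion outcomes at the printed caption parameter sets", {
  # fixed benefit, infected origin: fixation with symbiont prevalence restored
  inv1 <- classify_invasion(fixed_benefit_params(B = 0.075, mu = 0.05, t = 0.02),
                            "infected")
  expect_equal(inv1$outcome, "mitotype_fixed_symbiont_retained")
  expect_lt(abs(symbiont_freq(inv1$final_state) - inv1$p_star_before), 1e-6)

  # same parameters, uninfected origin: t = 0.02 < 0.02125, the advantageous
  # mitotype nevertheless dies out
  inv2 <- classify_invasion(fixed_benefit_params(B = 0.075, mu = 0.05, t = 0.02),
                            "uninfected")
  expect_equal(inv2$outcome, "mitotype_lost")
  expect_gt(inv2$growth_factor, 0.99)  # barely subcritical

  # frequency-dependent benefit, uninfected origin: partitioned coexistence
  # at reduced symbiont prevalence; the novel mitotype never enters the
  # infected class
  inv3 <- classify_invasion(freq_dep_params(b = 0.1, c = 0.05, mu = 0.02, t = 0.02),
                            "uninfected")
  expect_equal(inv3$outcome, "coexistence_partitioned")
  expect_lt(symbiont_freq(inv3$final_state), inv3$p_star_before)
  expect_equal(inv3$final_state[[3]], 0)
  expect_gt(inv3$final_state[[1]], 0)  # ancestral mitotype among infected

  # CI, infected origin: fixation with the symbiont back at E3
  inv4 <- classify_invasion(ci_params(h = 0.25, mu = 0.05, t = 0.02), "infected")
  expect_equal(inv4$outcome, "mitotype_fixed_symbiont_retained")
  expect_lt(abs(symbiont_freq(inv4$final_state) - 0.7841568), 1e-6)
})

test_that("growth factors within 1e-6 of one are reported indeterminate", {
  B <- 0.075; mu <- 0.05
  pars <- fixed_benefit_params(B, mu, t = threshold_t_fixed_benefit(B, mu))
  inv <- classify_invasion(pars, "uninfected")
  expect_equal(inv$outcome, "indeterminate")
})

test_that("tidy and glance summarize an invasion", {
  inv <- classify_invasion(fixed_benefit_params(B = 0.075, mu = 0.05, t = 0.02),
                           "infected")
  td <- tidy(inv)
  expect_equal(td$compartment, c("p", "q", "r", "s"))
  expect_equal(sum(td$initial), 1, tolerance = 1e-12)
  expect_equal(sum(td$final), 1, tolerance = 1e-12)
  gl <- glance(inv)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$outcome, "mitotype_fixed_symbiont_retained")
  expect_equal(gl$growth_factor, 1.02)
})
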