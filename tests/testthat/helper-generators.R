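# Random draws of valid parameter sets and states, used by the
# property-style tests. Persistent draws keep mu safely inside the
# persistence region so resident equilibria exist and convergence is quick.

random_state <- function() {
  x <- stats::runif(4)
  as_cytotype_state(x / sum(x))
}

random_params <- function(model, persistent = TRUE, t = NULL) {
  t <- t %||% stats::runif(1, 0, 0.05)
  if (model == "fixed_benefit") {
    B <- stats::runif(1, 0.02, 0.5)
    crit <- B / (1 + B)
    mu <- if (persistent) stats::runif(1, 0.05, 0.9) * crit
          else stats::runif(1, 1.05, 2) * crit
    fixed_benefit_params(B = B, mu = min(mu, 1), t = t)
  } else if (model == "freq_dep") {
    b <- stats::runif(1, 0.05, 0.5)
    c <- stats::runif(1, 0, 0.7 * b)
    crit <- (b - c) / (1 + b - c)
    mu <- if (persistent) stats::runif(1, 0.05, 0.9) * crit
          else stats::runif(1, 1.05, 2) * crit
    freq_dep_params(b = b, c = c, mu = min(mu, 1), t = t)
  } else {
    h <- stats::runif(1, 0.05, 0.95)
    crit <- (1 - sqrt(1 - h)) / 2
    mu <- if (persistent) stats::runif(1, 0.05, 0.9) * crit
          else stats::runif(1, 1.05, 1.9) * crit
    ci_params(h = h, mu = min(mu, 1), t = t)
  }
}

`%||%` <- rlang::`%||%`

MODELS <- c("fixed_benefit", "freq_dep", "ci")

# Stable resident symbiont frequency from the printed closed forms,
# written out independently of the package's equilibria code.
closed_form_p_star <- function(params) {
  if (params$model == "fixed_benefit") {
    1 - (1 + params$B) * params$mu / params$B
  } else if (params$model == "freq_dep") {
    b <- params$b; c <- params$c; mu <- params$mu
    (b * (2 - mu) - c - sqrt(c^2 + b * mu * (4 + b * mu - 2 * c))) / (2 * b)
  } else {
    h <- params$h; mu <- params$mu
    (h + sqrt(h^2 - 4 * h * mu * (1 - mu))) / (2 * h * (1 - mu))
  }
}
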