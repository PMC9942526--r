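# Shared fixtures.  Heavy simulations (the n = 200 recovery cohort used
# by the acceptance criteria and by the measure-validity invariant) are
# computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# winning-combination parameter recovery at the acceptance scale
acceptance_param_recovery <- function() {
  cached("param_recovery_200", {
    parameter_recovery("D5-BMT3", 200, seed = 2024, mode = "map",
                       draws = 50)
  })
}

small_schedule <- function(seed = 1, subjects = 1) {
  build_schedule(seed, subjects = subjects)
}

# one-row trial of a given condition with explicit values, for unit tests
trial_row <- function(condition, g1 = NA, g2 = NA, sure = NA,
                      latent_gain = 30, latent_loss = -30) {
  cs <- ptlearn:::.cond_spec[[condition]]
  amb <- function(x) !is.na(x) && startsWith(x, "amb")
  data.frame(
    subject = 1, block = 1, trial = 1, condition = condition,
    gamble_p = cs$p,
    g1_value = g1, g1_amb = amb(cs$g1),
    g2_value = g2, g2_amb = if (is.na(cs$g2)) NA else amb(cs$g2),
    sure_value = sure, sure_amb = amb(cs$sure),
    latent_gain = latent_gain, latent_loss = latent_loss
  )
}

d5_params <- function(rho = 1, lambda = 1, gamma = 0.2,
                      alpha = c(1, 1, 1, 1)) {
  decision_params(5, rho = rho, lambda = lambda, gamma = gamma,
                  alpha = alpha)
}
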