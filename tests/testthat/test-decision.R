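test_that("utilities match hand-computed Table values", {
  # equal expected value, linear utility: both options worth 20
  u <- utility(trial_row(4, g1 = 40, g2 = 0, sure = 20), d5_params(rho = 1))
  expect_equal(u$u_gamble, 20)
  expect_equal(u$u_sure, 20)
  # mixed gamble with loss aversion 2: 0.5*40 - 0.5*2*40 = -20 vs sure 0
  u <- utility(trial_row(1, g1 = 40, g2 = -40, sure = 0),
               d5_params(rho = 1, lambda = 2))
  expect_equal(u$u_gamble, -20)
  expect_equal(u$u_sure, 0)
  # ambiguous sure gain: alpha_sg * V^rho vs sure^rho
  p <- decision_params(5, rho = 0.9, lambda = 1, gamma = 1,
                       alpha = c(1, 0.8, 1, 1))
  u <- utility(trial_row(7, sure = 25), p, implied = list(V_gain = 30,
                                                          V_loss = -30))
  expect_equal(u$u_gamble, 0.8 * 30^0.9)
  expect_equal(u$u_sure, 25^0.9)
  # ambiguous sure loss (condition 8): -lambda*alpha_sl*|V|^rho
  p8 <- decision_params(5, rho = 1.1, lambda = 1.6, gamma = 1,
                        alpha = c(1, 1, 1, 1.3))
  u <- utility(trial_row(8, sure = -40), p8,
               implied = list(V_gain = 30, V_loss = -20))
  expect_equal(u$u_gamble, -1.6 * 1.3 * 20^1.1)
  expect_equal(u$u_sure, -1.6 * 40^1.1)
})

test_that("utility validates inputs", {
  expect_error(utility(trial_row(7, sure = 25), d5_params()),
               "implied")
  expect_error(decision_params(5, rho = -1, lambda = 1, gamma = 1,
                               alpha = rep(1, 4)), "rho")
  expect_error(decision_params(5, rho = 1, lambda = 0, gamma = 1,
                               alpha = rep(1, 4)), "lambda")
})

test_that("softmax follows the logistic rule", {
  u <- data.frame(u_gamble = 5, u_sure = 5)
  expect_equal(choice_probability(u, 2), 0.5)
  expect_equal(choice_probability(data.frame(u_gamble = 90, u_sure = 2), 0),
               0.5)
  u <- data.frame(u_gamble = 12, u_sure = 2)
  expect_equal(choice_probability(u, 0.1), 1 / (1 + exp(-1)))
  # monotone in the utility difference, clipped exponent stays finite
  du <- seq(-1e4, 1e4, length.out = 21)
  p <- choice_probability(data.frame(u_gamble = du, u_sure = 0), 1)
  expect_true(all(diff(p) >= 0))
  expect_true(all(is.finite(p) & p > 0 & p < 1))
})

test_that("variant tying fills the four ambiguity slots correctly", {
  p1 <- decision_params(1, rho = 1, lambda = 1, gamma = 1)
  expect_equal(unlist(p1[c("alpha_rg", "alpha_sg", "alpha_rl", "alpha_sl")]),
               c(alpha_rg = 1, alpha_sg = 1, alpha_rl = 1, alpha_sl = 1))
  p2 <- decision_params(2, rho = 1, lambda = 1, gamma = 1, alpha = 0.7)
  expect_true(all(unlist(p2[c("alpha_rg", "alpha_sg", "alpha_rl",
                              "alpha_sl")]) == 0.7))
  p3 <- decision_params(3, rho = 1, lambda = 1, gamma = 1,
                        alpha = c(0.8, 1.2))
  expect_equal(p3$alpha_rg, 0.8); expect_equal(p3$alpha_sg, 0.8)
  expect_equal(p3$alpha_rl, 1.2); expect_equal(p3$alpha_sl, 1.2)
  p5 <- decision_params(5, rho = 1, lambda = 1, gamma = 1,
                        alpha = c(0.7, 0.8, 1.2, 1.3))
  expect_equal(unlist(p5[c("alpha_rg", "alpha_sg", "alpha_rl", "alpha_sl")]),
               c(alpha_rg = 0.7, alpha_sg = 0.8, alpha_rl = 1.2,
                 alpha_sl = 1.3))
  expect_error(decision_params(2, rho = 1, lambda = 1, gamma = 1,
                               alpha = c(1, 1)), "1 free")
  expect_error(decision_params(5, rho = 1, lambda = 1, gamma = 1,
                               alpha = 1), "4 free")
  # variant 4 routes by loss context: condition 3 (ambiguous gain, loss
  # present) takes the loss-context weight
  p4 <- decision_params(4, rho = 1, lambda = 1, gamma = 1,
                        alpha = c(0.8, 1.2))
  a <- ptlearn:::.alpha_by_condition(p4)
  expect_equal(a[c(2, 3, 8)], rep(1.2, 3))
  expect_equal(a[5:7], rep(0.8, 3))
})

test_that("choice probability is monotone in gamble magnitudes", {
  p <- d5_params(rho = 0.8, lambda = 1.5, gamma = 0.3)
  gains <- seq(10, 90, 5)
  pg <- vapply(gains, function(g) {
    choice_probability(utility(trial_row(4, g1 = g, g2 = 0, sure = 30), p),
                       p$gamma)
  }, numeric(1))
  expect_true(all(diff(pg) > 0))
  losses <- seq(-90, -10, 5)
  pl <- vapply(losses, function(l) {
    choice_probability(utility(trial_row(1, g1 = 50, g2 = l, sure = 0), p),
                       p$gamma)
  }, numeric(1))
  expect_true(all(diff(pl) > 0))  # shallower loss -> more gambling
})

test_that("zero outcomes contribute exactly zero utility", {
  for (rho in c(0.5, 1, 1.7)) {
    p <- d5_params(rho = rho)
    u <- utility(trial_row(1, g1 = 40, g2 = -40, sure = 0), p)
    expect_identical(u$u_sure, 0)
    u4 <- utility(trial_row(4, g1 = 40, g2 = 0, sure = 20), p)
    expect_equal(u4$u_gamble, 0.5 * 40^rho)
  }
})

test_that("variants nest exactly: D1 = D2(alpha=1) = D5(alpha=1)", {
  sched <- small_schedule(seed = 11)
  lp <- learning_params("rw", alpha = 0.4)
  dgen <- decision_params(3, rho = 0.85, lambda = 1.8, gamma = 0.2,
                          alpha = c(0.7, 1.3))
  d <- simulate_subject(sched, dgen, lp, seed = 3)
  prep <- ptlearn:::.prep_subject(d)
  base <- c(rho = 0.9, lambda = 1.4, gamma = 0.25)
  ll1 <- ptlearn:::.pointwise_ll(base, prep, 1, 1)
  ll2 <- ptlearn:::.pointwise_ll(c(base, alpha = 1), prep, 2, 1)
  ll5 <- ptlearn:::.pointwise_ll(c(base, alpha_rg = 1, alpha_sg = 1,
                                   alpha_rl = 1, alpha_sl = 1), prep, 5, 1)
  expect_identical(ll1, ll2)
  expect_identical(ll1, ll5)
})

test_that("compiled likelihood agrees with the reference path", {
  sched <- small_schedule(seed = 21)
  dgen <- d5_params(rho = 0.9, lambda = 1.6, gamma = 0.2)
  lp <- learning_params("bmt", theta = 40)
  d <- simulate_subject(sched, dgen, lp, seed = 5)
  prep <- ptlearn:::.prep_subject(d)
  set.seed(42)
  for (dec in 1:5) for (lrn in c(1, 2, 4, 5, 7, 8, 10)) {
    pars <- model_parameters(dec, lrn)
    par <- ptlearn:::.untransform_vec(
      pars$prior_mean + stats::rnorm(nrow(pars), 0, 0.3), pars)
    cl <- ptlearn:::.compile_ll(prep, dec, lrn, pars)
    expect_equal(cl$pointwise(par),
                 unname(ptlearn:::.pointwise_ll(par, prep, dec, lrn)),
                 tolerance = 1e-12)
  }
})
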