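test_that("WAIC matches brute-force evaluation of its formula", {
  set.seed(1)
  ll <- matrix(rnorm(50, -1, 0.2), 5, 10)
  # independent brute force: per observation, log of the plain average
  # of exp(ll) minus the sample variance, summed, times -2
  brute <- 0
  for (j in 1:10) {
    lpd <- log(sum(exp(ll[, j])) / 5)
    pw <- var(ll[, j])
    brute <- brute + (lpd - pw)
  }
  w <- waic(ll)
  expect_equal(w$waic, -2 * brute)
  # identical draws: zero penalty, WAIC = -2 * total log-likelihood
  ll0 <- matrix(rep(c(-1.2, -0.4, -2), each = 4), nrow = 4)
  w0 <- waic(ll0)
  expect_equal(w0$p_waic, 0)
  expect_equal(w0$waic, -2 * sum(c(-1.2, -0.4, -2)))
  # additivity: duplicating every observation doubles WAIC
  expect_equal(waic(cbind(ll, ll))$waic, 2 * w$waic)
  expect_error(waic(matrix(-1, 1, 5)), "draws")
})

test_that("stacking weights sit on the simplex and match grid search", {
  set.seed(2)
  base <- matrix(rnorm(40 * 60, -0.7, 0.3), 40, 60)
  lls <- list(a = base,
              b = base + matrix(rnorm(40 * 60, -0.1, 0.2), 40, 60),
              c = base + matrix(rnorm(40 * 60, 0.05, 0.2), 40, 60))
  w <- stacking_weights(lls)
  expect_equal(sum(w), 1, tolerance = 1e-6)
  expect_true(all(w >= -1e-9))
  # brute-force grid at resolution 0.01 over the simplex
  lpd <- vapply(lls, function(m) waic(m)$pointwise, numeric(60))
  P <- exp(lpd - apply(lpd, 1, max))
  obj <- function(ww) -sum(log(P %*% ww))
  best <- Inf; bw <- NULL
  for (w1 in seq(0, 1, 0.01)) for (w2 in seq(0, 1 - w1, 0.01)) {
    v <- obj(c(w1, w2, 1 - w1 - w2))
    if (v < best) { best <- v; bw <- c(w1, w2, 1 - w1 - w2) }
  }
  expect_lte(obj(w), best + 1e-6)
  expect_equal(unname(w), bw, tolerance = 0.02)
  # two identical models split evenly; a dominant model takes all
  expect_equal(unname(stacking_weights(list(m1 = base, m2 = base))),
               c(0.5, 0.5), tolerance = 1e-6)
  wd <- stacking_weights(list(good = base, bad = base - 0.5))
  expect_gt(wd["good"], 0.99)
  expect_error(stacking_weights(list(a = base, b = base[, 1:10])),
               "observations")
})

test_that("Efron's R2 follows its definition", {
  y <- c(1, 0, 1, 0)
  p <- c(0.8, 0.2, 0.6, 0.4)
  expect_equal(efron_r2(y, p), 0.6)
  expect_equal(efron_r2(y, c(0.999999, 1e-6, 0.999999, 1e-6)), 1,
               tolerance = 1e-4)
  expect_equal(efron_r2(y, rep(0.5, 4)), 0)
  expect_error(efron_r2(c(1, 1, 1), c(0.5, 0.5, 0.5)), "constant")
  expect_error(efron_r2(y, c(0, 0.2, 0.6, 0.4)), "probabilities")
})

test_that("calibration bins predictions against observed rates", {
  cal <- calibration(rep(0.5, 100), rbinom(100, 1, 0.5), bins = 10)
  expect_equal(sum(cal$n > 0), 1)
  expect_equal(cal$mean_predicted[cal$n > 0], 0.5)
  # near-deterministic predictions occupy only the extreme bins
  p <- c(rep(0.01, 50), rep(0.99, 50))
  cal2 <- calibration(p, c(rep(0, 50), rep(1, 50)), bins = 10)
  expect_setequal(which(cal2$n > 0), c(1, 10))
  expect_true(all(is.na(cal2$observed_rate[cal2$n == 0])))
  # simulation oracle: probabilities drawn from the model itself are
  # well calibrated in every occupied bin
  set.seed(4)
  pp <- runif(20000)
  yy <- rbinom(20000, 1, pp)
  cal3 <- calibration(pp, yy, bins = 10)
  expect_lt(max(abs(cal3$mean_predicted - cal3$observed_rate)), 0.05)
})

test_that("fitting recovers the no-ambiguity generating value", {
  # data generated under variant 1 (all ambiguity weights = 1); the
  # variant-2 shared weight should come back near 1
  pop <- population_spec("D1-none", 100, seed = 41)
  sim <- simulate_cohort(pop)
  fo <- fit(sim$choices, "D2-none", seed = 3, draws = 30, n_starts = 1)
  expect_true(all(fo$converged))
  expect_gte(mean(fo$estimates$alpha), 0.8)
  expect_lte(mean(fo$estimates$alpha), 1.2)
  # nested-model WAIC consistency: with group-level shrinkage the
  # superfluous shared ambiguity weight collapses to 1 and the richer
  # model's WAIC lands within 2 SE of the true model's (unpooled MAP
  # fits overfit the 100 extra per-subject parameters and need not)
  f1 <- fit(sim$choices, "D1-none", mode = "hierarchical", em_iter = 2,
            seed = 3, draws = 30, n_starts = 1)
  f2 <- fit(sim$choices, "D2-none", mode = "hierarchical", em_iter = 2,
            seed = 3, draws = 30, n_starts = 1)
  expect_lt(abs(f1$waic$waic - f2$waic$waic), 2 * f1$waic$se)
  # deterministic refits
  fo2 <- fit(sim$choices, "D2-none", seed = 3, draws = 30, n_starts = 1)
  expect_identical(fo$estimates, fo2$estimates)
  expect_identical(fo$waic$waic, fo2$waic$waic)
})

test_that("an all-gamble subject yields gamble-favoring estimates", {
  sched <- small_schedule(seed = 17)
  d <- sched
  d$chose_gamble <- 1L
  d$outcome <- ifelse(is.na(d$g1_value), d$latent_gain, d$g1_value)
  d$reveal <- "none"
  d$running_score <- cumsum(d$outcome)
  # the full decision rule can favor the gamble in every condition class
  # (ambiguity weights cover conditions 2-3 and 7-8); plain prospect
  # theory cannot, so the richest variant is the right probe here
  fo <- fit(d, "D5-none", seed = 5, draws = 10, n_starts = 2)
  expect_gt(fo$estimates$gamma, 0)
  expect_gt(mean(fo$p_hat), 0.5)
})

test_that("hierarchical mode tightens group priors and still fits", {
  pop <- population_spec("D1-none", 25, seed = 51)
  sim <- simulate_cohort(pop)
  fh <- fit(sim$choices, "D1-none", mode = "hierarchical", seed = 4,
            draws = 20, em_iter = 2, n_starts = 1)
  expect_s3_class(fh, "ptlearn_fit")
  # EM adapts the group prior away from the fixed defaults
  expect_false(identical(fh$prior$prior_mean,
                         model_parameters(1, 1)$prior_mean))
  # group scale shrinks toward the (tighter) population spread
  expect_lt(fh$prior$prior_sd[1], model_parameters(1, 1)$prior_sd[1] + 0.1)
  expect_error(fit(sim$choices[0, ], "D1-none"), "empty")
})

test_that("derived measures reverse and difference parameters correctly", {
  fake <- structure(list(
    model_id = "D1-RW4",
    estimates = data.frame(subject = 1:3,
                           rho = c(0.5, 0.8, 1.1),
                           lambda = c(1, 2, 3),
                           gamma = 1,
                           alpha_pos = c(0.6, 0.5, 0.4),
                           alpha_neg = c(0.2, 0.1, 0.4))
  ), class = "ptlearn_fit")
  expect_equal(learning_bias(fake)$learning_bias, c(0.4, 0.4, 0))
  dm <- derived_measures(fake, data = NULL, n_draws = 2)
  expect_equal(dm$aversion$rho, c(0.6, 0.3, 0))       # reversed
  expect_equal(dm$aversion$lambda, c(1, 2, 3))        # raw
  expect_equal(dm$learning_bias$learning_bias, c(0.4, 0.4, 0))
  fake$model_id <- "D1-RW1"
  expect_error(learning_bias(fake), "asymmetric")
})

test_that("mean-tracker learning rate vanishes as theta grows", {
  sched <- small_schedule(seed = 19)
  lp <- learning_params("bmt", theta = 1e9)
  d <- simulate_subject(sched, d5_params(gamma = 0.1), lp, seed = 2)
  tr <- run_learning(sched, d, lp)
  expect_lt(max(tr$G), 1e-6)
  expect_lt(max(abs(tr$V_gain - 5)), 1e-4)
})
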