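# Model fitting.  MAP mode fits each subject independently by penalized
# maximum likelihood on unconstrained (log / logit) scales with normal
# priors; hierarchical mode wraps the same subject-level optimization in
# an empirical-Bayes EM loop that re-estimates the group-level prior
# location and scale per parameter.  Posterior uncertainty is carried by
# a Laplace approximation at each subject's mode, from which pointwise
# log-likelihood draws for WAIC / stacking are generated.

# Per-subject static structures used by the likelihood.
.prep_subject <- function(df) {
  df <- df[order(df$trial), ]
  n <- nrow(df)
  cond <- df$condition
  rg <- which(df$reveal == "gain")
  rl <- which(df$reveal == "loss")
  base <- implied_baseline(df)
  list(n = n, cond = cond,
       g1 = df$g1_value, g2a = abs(df$g2_value), sua = abs(df$sure_value),
       su = df$sure_value, y = df$chose_gamble,
       idx = lapply(1:8, function(cc) which(cond == cc)),
       rg_pos = rg, rg_out = df$outcome[rg],
       rl_pos = rl, rl_out = df$outcome[rl],
       baseline = base)
}

# Pointwise log-likelihood for one subject at natural-scale parameters.
.pointwise_ll <- function(par, prep, decision, learning) {
  ps <- .split_params(par, decision, learning)
  dp <- ps$decision; lp <- ps$learning
  if (lp$family == "none") {
    Vg <- rep(prep$baseline$V_gain, prep$n)
    Vl <- rep(prep$baseline$V_loss, prep$n)
  } else {
    traj <- .implied_trajectory(prep$n, prep$rg_pos, prep$rg_out,
                                prep$rl_pos, prep$rl_out, lp)
    Vg <- traj$V_gain; Vl <- traj$V_loss
  }
  Vg <- pmax(Vg, 1e-9)
  Vlm <- pmax(abs(Vl), 1e-9)
  rho <- dp$rho; lam <- dp$lambda
  av <- .alpha_by_condition(dp)[prep$cond]
  ug <- numeric(prep$n); us <- numeric(prep$n)
  for (cc in 1:8) {
    i <- prep$idx[[cc]]
    if (!length(i)) next
    ug[i] <- switch(cc,
      0.5 * prep$g1[i]^rho - 0.5 * lam * prep$g2a[i]^rho,
      0.5 * prep$g1[i]^rho - 0.5 * lam * av[i] * Vlm[i]^rho,
      0.5 * av[i] * Vg[i]^rho - 0.5 * lam * prep$g2a[i]^rho,
      0.5 * prep$g1[i]^rho,
      0.5 * av[i] * Vg[i]^rho,
      0.5 * prep$g1[i]^rho,
      av[i] * Vg[i]^rho,
      -lam * av[i] * Vlm[i]^rho)
    us[i] <- switch(cc,
      0, 0, 0,
      prep$su[i]^rho,
      prep$su[i]^rho,
      av[i] * Vg[i]^rho,
      prep$su[i]^rho,
      -lam * prep$sua[i]^rho)
  }
  x <- dp$gamma * (ug - us)
  x <- pmin(pmax(x, -500), 500)
  ll <- ifelse(prep$y == 1, stats::plogis(x, log.p = TRUE),
               stats::plogis(-x, log.p = TRUE))
  # lapse floor: choice probabilities are bounded below at 1e-6, which
  # leaves estimation untouched but keeps pointwise WAIC variances finite
  # for near-deterministic subjects
  pmax(ll, log(1e-6))
}

.untransform_vec <- function(theta, pars) {
  out <- numeric(length(theta))
  for (i in seq_along(theta))
    out[i] <- .to_natural(theta[i], pars$transform[i])
  stats::setNames(out, pars$name)
}

# Compiled per-subject likelihood: precomputes parameter indices, the
# ambiguity-weight routing, and condition masks so each evaluation is a
# handful of vector operations.  Returns pointwise(theta) -> ll vector
# and neg_penalized(theta) -> scalar.  Semantically identical to
# .pointwise_ll (cross-checked in the test suite).
.compile_ll <- function(prep, decision, learning, pars) {
  nm <- pars$name
  np <- length(nm)
  is_log <- pars$transform == "log"
  i_rho <- match("rho", nm); i_lam <- match("lambda", nm)
  i_gam <- match("gamma", nm)
  fam <- .learning_table$family[learning]
  scheme <- .learning_table$start_scheme[learning]
  # parameter index (into c(par, 1)) of the ambiguity weight by condition
  one <- np + 1L
  ac <- switch(decision,
    rep(one, 8),
    c(one, rep(match("alpha", nm), 2), one, rep(match("alpha", nm), 4)),
    c(one, match("alpha_l", nm), match("alpha_g", nm), one,
      match("alpha_g", nm), match("alpha_g", nm), match("alpha_g", nm),
      match("alpha_l", nm)),
    c(one, match("alpha_l", nm), match("alpha_l", nm), one,
      match("alpha_g", nm), match("alpha_g", nm), match("alpha_g", nm),
      match("alpha_l", nm)),
    c(one, match("alpha_rl", nm), match("alpha_rg", nm), one,
      match("alpha_rg", nm), match("alpha_sg", nm), match("alpha_sg", nm),
      match("alpha_sl", nm)))
  a_idx <- ac[prep$cond]
  i1 <- prep$idx[[1]]; i2 <- prep$idx[[2]]; i3 <- prep$idx[[3]]
  i4 <- prep$idx[[4]]; i5 <- prep$idx[[5]]; i6 <- prep$idx[[6]]
  i7 <- prep$idx[[7]]; i8 <- prep$idx[[8]]
  sgn <- ifelse(prep$y == 1, 1, -1)
  pm <- pars$prior_mean; psd <- pars$prior_sd
  n <- prep$n
  llfloor <- log(1e-6)
  i_lr <- match("alpha_lr", nm); i_lp <- match("alpha_pos", nm)
  i_ln <- match("alpha_neg", nm); i_th <- match("theta", nm)
  i_v0m <- match("v0_mag", nm); i_v0g <- match("v0_gain", nm)
  i_v0l <- match("v0_loss_mag", nm)
  traj <- function(par) {
    v0 <- switch(scheme,
                 none = c(5, -5), fixed = c(5, -5),
                 estimated_shared = c(par[i_v0m], -par[i_v0m]),
                 estimated_separate = c(par[i_v0g], -par[i_v0l]))
    lp <- list(family = fam, alpha = if (!is.na(i_lr)) par[i_lr],
               alpha_pos = if (!is.na(i_lp)) par[i_lp],
               alpha_neg = if (!is.na(i_ln)) par[i_ln],
               theta = if (!is.na(i_th)) par[i_th],
               v0_gain = v0[1], v0_loss = v0[2], v0_var = 100)
    .implied_trajectory(n, prep$rg_pos, prep$rg_out,
                        prep$rl_pos, prep$rl_out, lp)
  }
  pointwise <- function(par) {
    rho <- par[i_rho]; lam <- par[i_lam]
    if (fam == "none") {
      Vg <- prep$baseline$V_gain; Vl <- prep$baseline$V_loss
      Vgr <- rep(max(Vg, 1e-9), n); Vlm <- rep(max(abs(Vl), 1e-9), n)
    } else {
      tj <- traj(par)
      Vgr <- pmax(tj$V_gain, 1e-9); Vlm <- pmax(abs(tj$V_loss), 1e-9)
    }
    a <- c(par, 1)[a_idx]
    g1r <- prep$g1^rho
    ug <- numeric(n); us <- numeric(n)
    if (length(i1)) ug[i1] <- 0.5 * g1r[i1] - 0.5 * lam * prep$g2a[i1]^rho
    if (length(i2)) ug[i2] <- 0.5 * g1r[i2] - 0.5 * lam * a[i2] * Vlm[i2]^rho
    if (length(i3)) ug[i3] <- 0.5 * a[i3] * Vgr[i3]^rho -
      0.5 * lam * prep$g2a[i3]^rho
    if (length(i4)) { ug[i4] <- 0.5 * g1r[i4]; us[i4] <- prep$su[i4]^rho }
    if (length(i5)) { ug[i5] <- 0.5 * a[i5] * Vgr[i5]^rho
      us[i5] <- prep$su[i5]^rho }
    if (length(i6)) { ug[i6] <- 0.5 * g1r[i6]
      us[i6] <- a[i6] * Vgr[i6]^rho }
    if (length(i7)) { ug[i7] <- a[i7] * Vgr[i7]^rho
      us[i7] <- prep$su[i7]^rho }
    if (length(i8)) { ug[i8] <- -lam * a[i8] * Vlm[i8]^rho
      us[i8] <- -lam * prep$sua[i8]^rho }
    x <- par[i_gam] * (ug - us) * sgn
    pmax(stats::plogis(pmin(pmax(x, -500), 500), log.p = TRUE), llfloor)
  }
  neg_penalized <- function(theta) {
    th <- pmin(pmax(theta, -15), 15)
    par <- numeric(np)
    par[is_log] <- exp(th[is_log])
    par[!is_log] <- stats::plogis(th[!is_log])
    val <- -(sum(pointwise(par)) - sum(((th - pm) / psd)^2) / 2)
    if (!is.finite(val)) val <- 1e10 + sum(theta^2)
    val
  }
  list(pointwise = pointwise, neg_penalized = neg_penalized)
}

.fit_subject <- function(prep, decision, learning, pars, start = NULL,
                         n_starts = 2, seed = 1) {
  cl <- .compile_ll(prep, decision, learning, pars)
  obj <- cl$neg_penalized
  starts <- list(if (is.null(start)) pars$prior_mean else start)
  if (n_starts > 1) {
    jit <- .with_seed(seed, matrix(stats::rnorm((n_starts - 1) *
                                                  nrow(pars), 0, 0.5),
                                   ncol = nrow(pars)))
    for (k in seq_len(n_starts - 1))
      starts[[k + 1]] <- starts[[1]] + jit[k, ]
  }
  best <- NULL
  for (st in starts) {
    o <- try(stats::optim(st, obj, method = "BFGS",
                          control = list(maxit = 500)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("optimization failed for a subject")
  h <- try(stats::optimHess(best$par, obj), silent = TRUE)
  if (inherits(h, "try-error")) h <- diag(nrow(pars))
  list(theta = best$par, value = best$value, hessian = h,
       converged = best$convergence == 0, pointwise = cl$pointwise)
}

# Laplace draws on the unconstrained scale (draws x p).  Eigenvalues of
# the curvature are floored at the smallest prior precision: the
# penalized posterior cannot be flatter than the prior in any direction,
# and numerical Hessians of flat likelihoods otherwise produce absurdly
# overdispersed draws.
.laplace_draws <- function(theta, hessian, n_draws, seed, ev_floor = 1) {
  p <- length(theta)
  e <- eigen(hessian, symmetric = TRUE)
  ev <- pmax(e$values, ev_floor)
  # covariance = inverse of the (regularized) hessian
  L <- e$vectors %*% diag(1 / sqrt(ev), p)
  z <- .with_seed(seed, matrix(stats::rnorm(n_draws * p), n_draws, p))
  sweep(z %*% t(L), 2, theta, "+")
}

#' Fit a model to choice data
#'
#' @param data Per-trial records for one or more subjects: the
#'   [build_schedule()] columns plus `chose_gamble`, `outcome`, `reveal`
#'   (the format written by [simulate_subject()]).
#' @param model_id Model to fit, e.g. `"D5-BMT3"`.
#' @param mode `"map"` (independent subjects, fixed weakly-informative
#'   priors) or `"hierarchical"` (empirical-Bayes EM over group-level
#'   prior location/scale on the unconstrained scale).
#' @param seed Integer seed (multi-start jitter and posterior draws).
#' @param draws Number of Laplace posterior draws per subject for the
#'   pointwise log-likelihood matrix.
#' @param em_iter EM iterations in hierarchical mode.
#' @param n_starts Optimization restarts per subject.
#' @return Object of class `ptlearn_fit`: per-subject posterior-mean
#'   `estimates` (natural scale), `theta` (posterior modes, unconstrained
#'   scale), pointwise log-likelihood matrix `ll` (draws x total trials,
#'   subjects concatenated in column blocks), fitted choice probabilities
#'   `p_hat` at the point estimates, observed choices `y`, `waic`,
#'   `efron_r2`, convergence flags, and the group-level prior table.
#' @export
fit <- function(data, model_id, mode = c("map", "hierarchical"), seed = 1,
                draws = 100, em_iter = 3, n_starts = 2) {
  mode <- match.arg(mode)
  if (is.null(data) || nrow(data) == 0) stop("empty dataset")
  m <- parse_model_id(model_id)
  pars <- model_parameters(m$decision, m$learning)
  subjects <- sort(unique(data$subject))
  preps <- lapply(subjects, function(s) .prep_subject(data[data$subject == s, ]))
  if (m$learning != 1) {
    n_amb <- vapply(preps, function(pr) length(pr$rg_pos) + length(pr$rl_pos),
                    integer(1))
    if (any(n_amb == 0))
      warning("some subjects have no ambiguous reveals; learning ",
              "parameters are unidentified for them (apply the ",
              "exclusion filter upstream)")
  }
  ns <- length(subjects)
  fits <- vector("list", ns)
  run_pass <- function(prior_tab, starts) {
    lapply(seq_len(ns), function(i) {
      .fit_subject(preps[[i]], m$decision, m$learning, prior_tab,
                   start = starts[[i]], n_starts = n_starts,
                   seed = seed + 7L * i)
    })
  }
  prior_tab <- pars
  starts <- vector("list", ns)
  fits <- run_pass(prior_tab, starts)
  if (mode == "hierarchical") {
    for (it in seq_len(em_iter)) {
      th <- do.call(rbind, lapply(fits, `[[`, "theta"))
      se2 <- do.call(rbind, lapply(fits, function(f) {
        v <- try(diag(solve(f$hessian)), silent = TRUE)
        if (inherits(v, "try-error")) rep(1, ncol(th)) else pmax(v, 0)
      }))
      prior_tab$prior_mean <- colMeans(th)
      prior_tab$prior_sd <- pmax(sqrt(apply(th, 2, stats::var) +
                                        colMeans(se2)), 0.05)
      starts <- lapply(fits, `[[`, "theta")
      fits <- run_pass(prior_tab, starts)
    }
  }
  # Laplace draws, pointwise log-likelihood, posterior-mean estimates
  p <- nrow(pars)
  n_trials <- vapply(preps, `[[`, integer(1), "n")
  ll <- matrix(NA_real_, draws, sum(n_trials))
  est <- matrix(NA_real_, ns, p, dimnames = list(NULL, pars$name))
  theta_hat <- matrix(NA_real_, ns, p, dimnames = list(NULL, pars$name))
  p_hat <- numeric(sum(n_trials))
  y <- integer(sum(n_trials))
  col0 <- c(0, cumsum(n_trials))
  for (i in seq_len(ns)) {
    f <- fits[[i]]
    dr <- .laplace_draws(f$theta, f$hessian, draws, seed + 31L * i,
                         ev_floor = 1 / max(prior_tab$prior_sd)^2)
    nat <- t(apply(dr, 1, .untransform_vec, pars = pars))
    est[i, ] <- colMeans(nat)
    theta_hat[i, ] <- f$theta
    cols <- (col0[i] + 1):col0[i + 1]
    for (s in seq_len(draws))
      ll[s, cols] <- f$pointwise(nat[s, ])
    llp <- f$pointwise(est[i, ])
    ph <- ifelse(preps[[i]]$y == 1, exp(llp), 1 - exp(llp))
    p_hat[cols] <- pmin(pmax(ph, 1e-12), 1 - 1e-12)
    y[cols] <- preps[[i]]$y
  }
  w <- waic(ll)
  structure(list(
    model_id = model_id, mode = mode, subjects = subjects,
    estimates = cbind(data.frame(subject = subjects),
                      as.data.frame(est)),
    theta = theta_hat, ll = ll, p_hat = p_hat, y = y,
    n_trials = n_trials, waic = w,
    efron_r2 = tryCatch(efron_r2(y, p_hat), error = function(e) NA_real_),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    hessians = lapply(fits, `[[`, "hessian"),
    par_table = pars,
    prior = prior_tab, seed = seed, draws = draws
  ), class = "ptlearn_fit")
}

#' @export
print.ptlearn_fit <- function(x, ...) {
  cat("ptlearn fit:", x$model_id, "(", x$mode, ")\n")
  cat("  subjects:", length(x$subjects),
      " trials:", sum(x$n_trials), "\n")
  cat("  WAIC:", round(x$waic$waic, 1),
      " p_waic:", round(x$waic$p_waic, 1), "\n")
  cat("  Efron R2:", round(x$efron_r2, 3), "\n")
  invisible(x)
}

# numerically stable column log-mean-exp
.col_log_mean_exp <- function(m) {
  mx <- apply(m, 2, max)
  mx + log(colMeans(exp(sweep(m, 2, mx))))
}

#' Widely applicable information criterion
#'
#' Deviance-scale WAIC from a pointwise log-likelihood matrix:
#' `-2 * sum_i (log mean_s exp(ll_si) - var_s(ll_si))`; lower is better.
#'
#' @param ll Matrix of pointwise log-likelihoods, draws x observations
#'   (at least 2 draws).
#' @return List: `waic`, `elpd` (sum of pointwise lpd minus penalty),
#'   `p_waic` (effective parameters), `se` (sampling SE of WAIC),
#'   `pointwise` (per-observation elpd contributions).
#' @export
waic <- function(ll) {
  if (!is.matrix(ll) || nrow(ll) < 2 || any(!is.finite(ll)))
    stop("need a finite pointwise log-likelihood matrix with >= 2 draws")
  lpd <- .col_log_mean_exp(ll)
  pw <- apply(ll, 2, stats::var)
  elpd_i <- lpd - pw
  list(waic = -2 * sum(elpd_i), elpd = sum(elpd_i), p_waic = sum(pw),
       se = 2 * sqrt(ncol(ll) * stats::var(elpd_i)), pointwise = elpd_i)
}

#' Stacking weights over candidate models
#'
#' Simplex weights maximizing the stacked log pointwise predictive
#' density.  Per-observation predictive densities are taken on the WAIC
#' scale: log mean likelihood over draws minus the draw variance (the
#' pointwise effective-parameter penalty), so an overdispersed
#' approximate posterior is not rewarded for its luckiest draws.
#'
#' @param ll_list Named list of pointwise log-likelihood matrices
#'   (draws x observations), one per model, on identical data.
#' @return Named numeric vector of weights (>= 0, summing to 1).
#' @export
stacking_weights <- function(ll_list) {
  K <- length(ll_list)
  stopifnot(K >= 1)
  nobs <- unique(vapply(ll_list, ncol, integer(1)))
  if (length(nobs) != 1)
    stop("models were evaluated on different numbers of observations")
  if (K == 1) return(stats::setNames(1, names(ll_list)))
  lpd <- vapply(ll_list, function(m) waic(m)$pointwise, numeric(nobs))
  lpd <- lpd - apply(lpd, 1, max)
  P <- exp(lpd)
  # mixture-weight EM: the objective is concave in w, so the monotone
  # fixed-point iteration converges to the global optimum
  w <- rep(1 / K, K)
  for (it in 1:5000) {
    p <- pmax(as.numeric(P %*% w), 1e-300)
    w_new <- w * colMeans(P / p)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < 1e-12) { w <- w_new; break }
    w <- w_new
  }
  stats::setNames(w, names(ll_list))
}

#' Efron's pseudo-R-squared
#'
#' `1 - sum((y - p)^2) / sum((y - mean(y))^2)` for binary outcomes.
#'
#' @param y Observed 0/1 choices.
#' @param p Predicted probabilities in (0, 1).
#' @return Scalar pseudo-R2 (<= 1).
#' @export
efron_r2 <- function(y, p) {
  stopifnot(length(y) == length(p))
  if (any(p <= 0 | p >= 1)) stop("probabilities must be in (0, 1)")
  denom <- sum((y - mean(y))^2)
  if (denom == 0) stop("Efron's R2 is undefined for constant outcomes")
  1 - sum((y - p)^2) / denom
}

#' Calibration table
#'
#' Bins predicted gamble probabilities and reports the mean prediction
#' and observed gamble frequency per bin.  Empty bins are kept with `NA`
#' frequency rather than dropped.
#'
#' @param p Predicted probabilities.
#' @param y Observed 0/1 choices.
#' @param bins Number of equal-width bins on \[0, 1\].
#' @return Data frame: `bin`, `lower`, `upper`, `n`, `mean_predicted`,
#'   `observed_rate`.
#' @export
calibration <- function(p, y, bins = 10) {
  stopifnot(length(p) == length(y), bins >= 1)
  br <- seq(0, 1, length.out = bins + 1)
  idx <- findInterval(p, br, rightmost.closed = TRUE, all.inside = TRUE)
  out <- data.frame(bin = seq_len(bins), lower = br[-length(br)],
                    upper = br[-1], n = 0L,
                    mean_predicted = NA_real_, observed_rate = NA_real_)
  for (b in seq_len(bins)) {
    i <- which(idx == b)
    out$n[b] <- length(i)
    if (length(i)) {
      out$mean_predicted[b] <- mean(p[i])
      out$observed_rate[b] <- mean(y[i])
    }
  }
  out
}
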