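# Measures derived from a fitted model: posterior-sample learning-rate
# trajectories (mean-tracker models), learning bias (asymmetric
# Rescorla-Wagner), and reversed aversion scores.

# Parameters where larger raw values mean *preference*; reversed
# (max across subjects minus value) so higher processed scores mean
# aversion.  Gain-side ambiguity weights and curvature qualify; loss
# aversion and loss-side ambiguity weights already increase with
# aversion.  The shared weight of decision variant 2 spans both valences
# and has no coherent direction, so it is left raw.
.reversal_set <- c("rho", "alpha_rg", "alpha_sg", "alpha_g")

# Forward-simulate one subject's learning-rate trajectory for S posterior
# parameter draws simultaneously.  Returns the per-draw mean of the
# prospective mean-tracker gain G = v / (v + theta) (averaged over the
# two valences) across all trials.
.mean_G_subject <- function(schedule, nat, decision, seed) {
  n <- nrow(schedule)
  S <- nrow(nat)
  gamma <- nat[, "gamma"]; rho <- nat[, "rho"]; lam <- nat[, "lambda"]
  theta <- nat[, "theta"]
  v0g <- if ("v0_gain" %in% colnames(nat)) nat[, "v0_gain"]
         else if ("v0_mag" %in% colnames(nat)) nat[, "v0_mag"] else rep(5, S)
  v0l <- if ("v0_loss_mag" %in% colnames(nat)) -nat[, "v0_loss_mag"]
         else if ("v0_mag" %in% colnames(nat)) -nat[, "v0_mag"] else rep(-5, S)
  alpha_of <- function(cc) {
    # per-draw ambiguity weight for condition cc (ambiguous conditions
    # only); variant 3 ties by slot valence, variant 4 by loss context
    switch(decision,
      rep(1, S),
      nat[, "alpha"],
      switch(cc, NULL, nat[, "alpha_l"], nat[, "alpha_g"], NULL,
             nat[, "alpha_g"], nat[, "alpha_g"], nat[, "alpha_g"],
             nat[, "alpha_l"]),
      switch(cc, NULL, nat[, "alpha_l"], nat[, "alpha_l"], NULL,
             nat[, "alpha_g"], nat[, "alpha_g"], nat[, "alpha_g"],
             nat[, "alpha_l"]),
      switch(cc, NULL, nat[, "alpha_rl"], nat[, "alpha_rg"], NULL,
             nat[, "alpha_rg"], nat[, "alpha_sg"], nat[, "alpha_sg"],
             nat[, "alpha_sl"]))
  }
  .with_seed(seed, {
    Vg <- v0g; Vl <- v0l
    varg <- varl <- rep(100, S)
    Gsum <- rep(0, S)
    for (t in seq_len(n)) {
      tr <- schedule[t, ]
      cc <- tr$condition
      a <- alpha_of(cc)
      Vgc <- pmax(Vg, 1e-9); Vlm <- pmax(abs(Vl), 1e-9)
      ug <- switch(cc,
        0.5 * tr$g1_value^rho - 0.5 * lam * abs(tr$g2_value)^rho,
        0.5 * tr$g1_value^rho - 0.5 * lam * a * Vlm^rho,
        0.5 * a * Vgc^rho - 0.5 * lam * abs(tr$g2_value)^rho,
        0.5 * tr$g1_value^rho,
        0.5 * a * Vgc^rho,
        0.5 * tr$g1_value^rho,
        a * Vgc^rho,
        -lam * a * Vlm^rho)
      us <- switch(cc,
        0, 0, 0,
        tr$sure_value^rho, tr$sure_value^rho,
        a * Vgc^rho,
        tr$sure_value^rho,
        -lam * abs(tr$sure_value)^rho)
      pr <- stats::plogis(pmin(pmax(gamma * (ug - us), -500), 500))
      chose <- stats::runif(S) < pr
      Gsum <- Gsum + 0.5 * (varg / (varg + theta) + varl / (varl + theta))
      # resolve reveals per draw
      cs <- .cond_spec[[cc]]
      if (cs$p < 1) {
        slot2 <- stats::runif(S) < 0.5
        pay_type <- ifelse(slot2, cs$g2, cs$g1)
      } else {
        pay_type <- rep(cs$g1, S)
      }
      pay_type[!chose] <- cs$sure
      upd_g <- pay_type == "amb_gain"
      upd_l <- pay_type == "amb_loss"
      if (any(upd_g)) {
        G <- varg[upd_g] / (varg[upd_g] + theta[upd_g])
        Vg[upd_g] <- Vg[upd_g] + G * (tr$latent_gain - Vg[upd_g])
        varg[upd_g] <- (1 - G) * varg[upd_g]
      }
      if (any(upd_l)) {
        G <- varl[upd_l] / (varl[upd_l] + theta[upd_l])
        Vl[upd_l] <- Vl[upd_l] + G * (tr$latent_loss - Vl[upd_l])
        varl[upd_l] <- (1 - G) * varl[upd_l]
      }
    }
    Gsum / n
  })
}

#' Measures derived from a fit
#'
#' For mean-tracker models, the mean learning rate: data are regenerated
#' from the model once per posterior draw to produce a learning-rate
#' trajectory, the trajectory is averaged over trials, and the draw-level
#' means are averaged into a point estimate per subject.  For asymmetric
#' Rescorla-Wagner models, the learning bias `alpha_pos - alpha_neg`.
#' For all models, aversion scores: point estimates with
#' preference-direction parameters (curvature, gain-side ambiguity
#' weights) reversed by subtracting each subject's value from the cohort
#' maximum, so higher always means more averse.
#'
#' @param fit A `ptlearn_fit` object.
#' @param data The per-trial records the model was fitted to (schedules
#'   are taken from here for forward simulation).
#' @param n_draws Posterior draws for the learning-rate trajectories.
#' @param seed Integer seed for the forward simulations.
#' @return List: `aversion` (per-subject processed scores),
#'   `mean_learning_rate` (mean-tracker models, else `NULL`),
#'   `learning_bias` (asymmetric models, else `NULL`).
#' @export
derived_measures <- function(fit, data, n_draws = 2000, seed = 1) {
  stopifnot(inherits(fit, "ptlearn_fit"))
  m <- parse_model_id(fit$model_id)
  fam <- .learning_table$family[m$learning]
  est <- fit$estimates
  av <- est[, setdiff(names(est), c("subject")), drop = FALSE]
  keep <- intersect(names(av),
                    c("rho", "lambda", "alpha", "alpha_g", "alpha_l",
                      "alpha_rg", "alpha_sg", "alpha_rl", "alpha_sl"))
  av <- av[, keep, drop = FALSE]
  for (nm in intersect(names(av), .reversal_set))
    av[[nm]] <- max(av[[nm]]) - av[[nm]]
  av <- cbind(subject = est$subject, av)
  bias <- NULL
  if (fam == "rw_asym") {
    bias <- data.frame(subject = est$subject,
                       learning_bias = est$alpha_pos - est$alpha_neg)
  }
  mlr <- NULL
  if (fam == "bmt") {
    pars <- fit$par_table
    mlr <- data.frame(subject = est$subject,
                      mean_learning_rate = NA_real_)
    for (i in seq_along(fit$subjects)) {
      s <- fit$subjects[i]
      sched <- data[data$subject == s, ]
      sched <- sched[order(sched$trial), ]
      dr <- .laplace_draws(fit$theta[i, ], fit$hessians[[i]], n_draws,
                           seed + 11L * i,
                           ev_floor = 1 / max(fit$prior$prior_sd)^2)
      nat <- t(apply(dr, 1, .untransform_vec, pars = pars))
      colnames(nat) <- pars$name
      mlr$mean_learning_rate[i] <-
        mean(.mean_G_subject(sched, nat, m$decision, seed + 13L * i))
    }
  }
  list(aversion = av, mean_learning_rate = mlr, learning_bias = bias)
}

#' Learning bias of an asymmetric model
#'
#' @param fit A `ptlearn_fit` object for an asymmetric Rescorla-Wagner
#'   model; errors for models without separate positive/negative rates.
#' @return Data frame with `subject` and `learning_bias`.
#' @export
learning_bias <- function(fit) {
  m <- parse_model_id(fit$model_id)
  if (.learning_table$family[m$learning] != "rw_asym")
    stop("learning bias is only defined for asymmetric learning models")
  data.frame(subject = fit$estimates$subject,
             learning_bias = fit$estimates$alpha_pos -
               fit$estimates$alpha_neg)
}
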