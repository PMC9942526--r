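# Value learning for ambiguous outcome magnitudes.  One implied value is
# tracked per valence (gain, loss); risky and sure ambiguous slots of the
# same valence share it.  State updates only when a received outcome's
# paying slot was ambiguous ("reveal"), and only the matching valence
# updates.  State persists across blocks.

#' Learning-rule parameters
#'
#' @param family `"none"` (no-learning baseline), `"rw"` (Rescorla-Wagner,
#'   one learning rate), `"rw_asym"` (separate rates for positive and
#'   negative prediction errors), or `"bmt"` (Bayesian mean tracker with
#'   variance-adaptive learning rate).
#' @param alpha Learning rate in \[0,1\] (`rw`).
#' @param alpha_pos,alpha_neg Learning rates in \[0,1\] (`rw_asym`),
#'   applied when the prediction error is positive resp. negative.
#' @param theta Error variance of the mean tracker, > 0; larger `theta`
#'   means slower learning.
#' @param v0_gain,v0_loss Starting implied values in points (gain > 0,
#'   loss < 0).
#' @param v0_var Initial variance of the mean tracker (points^2).
#' @param start_scheme One of `"fixed"`, `"estimated_shared"`,
#'   `"estimated_separate"` (bookkeeping; the fixed scheme forces
#'   `v0_gain = 5`, `v0_loss = -5`).
#' @return Object of class `ptlearn_learning`.
#' @export
learning_params <- function(family = c("none", "rw", "rw_asym", "bmt"),
                            alpha = NULL, alpha_pos = NULL, alpha_neg = NULL,
                            theta = NULL, v0_gain = 5, v0_loss = -5,
                            v0_var = 100, start_scheme = "fixed") {
  family <- match.arg(family)
  chk_rate <- function(x, nm) {
    if (is.null(x) || x < 0 || x > 1)
      stop(nm, " must be a learning rate in [0, 1]")
  }
  if (family == "rw") chk_rate(alpha, "alpha")
  if (family == "rw_asym") {
    chk_rate(alpha_pos, "alpha_pos"); chk_rate(alpha_neg, "alpha_neg")
  }
  if (family == "bmt") {
    if (is.null(theta) || theta <= 0) stop("theta must be > 0")
    if (v0_var <= 0) stop("v0_var must be > 0")
  }
  if (identical(start_scheme, "fixed")) { v0_gain <- 5; v0_loss <- -5 }
  structure(list(family = family, alpha = alpha, alpha_pos = alpha_pos,
                 alpha_neg = alpha_neg, theta = theta,
                 v0_gain = v0_gain, v0_loss = v0_loss, v0_var = v0_var,
                 start_scheme = start_scheme),
            class = "ptlearn_learning")
}

#' No-learning baseline implied values
#'
#' The implied value of an ambiguous option is the mean of all unambiguous
#' magnitudes of the same valence in the schedule, constant across trials.
#'
#' @param schedule Schedule rows for one subject (see [build_schedule()]).
#' @return List with `V_gain` and `V_loss` (points).
#' @export
implied_baseline <- function(schedule) {
  vals <- c(
    schedule$g1_value[!is.na(schedule$g1_value) &
                        schedule$g1_value != 0 & !schedule$g1_amb],
    schedule$g2_value[!is.na(schedule$g2_value) & schedule$g2_value != 0 &
                        !is.na(schedule$g2_amb) & !schedule$g2_amb],
    schedule$sure_value[!is.na(schedule$sure_value) &
                          schedule$sure_value != 0 & !schedule$sure_amb]
  )
  gains <- vals[vals > 0]
  losses <- vals[vals < 0]
  if (!length(gains)) stop("no unambiguous gain magnitudes in schedule")
  if (!length(losses)) stop("no unambiguous loss magnitudes in schedule")
  list(V_gain = mean(gains), V_loss = mean(losses))
}

#' Single-step learning updates
#'
#' `rw_update` applies the delta rule `V <- V + alpha * (outcome - V)`;
#' `rw_asym_update` uses `alpha_pos` when the prediction error is positive
#' and `alpha_neg` when negative; `bmt_update` is the Kalman-style mean
#' tracker: gain `G = v / (v + theta)` from the prior variance, mean moved
#' by `G * delta`, variance shrunk to `(1 - G) * v`.  Each updates only
#' the state of `valence`.
#'
#' @param state List with `V_gain`, `V_loss` (and, for the mean tracker,
#'   `var_gain`, `var_loss`, `G_gain`, `G_loss`).
#' @param outcome Revealed ambiguous outcome in points.
#' @param params A `ptlearn_learning` object.
#' @param valence `"gain"` or `"loss"`.
#' @return Updated state list.
#' @export
rw_update <- function(state, outcome, params, valence) {
  a <- params$alpha
  if (is.null(a) || a < 0 || a > 1) stop("alpha must be in [0, 1]")
  f <- paste0("V_", valence)
  state[[f]] <- state[[f]] + a * (outcome - state[[f]])
  state
}

#' @rdname rw_update
#' @export
rw_asym_update <- function(state, outcome, params, valence) {
  for (nm in c("alpha_pos", "alpha_neg"))
    if (is.null(params[[nm]]) || params[[nm]] < 0 || params[[nm]] > 1)
      stop(nm, " must be in [0, 1]")
  f <- paste0("V_", valence)
  delta <- outcome - state[[f]]
  a <- if (delta > 0) params$alpha_pos else if (delta < 0) params$alpha_neg else 0
  state[[f]] <- state[[f]] + a * delta
  state
}

#' @rdname rw_update
#' @export
bmt_update <- function(state, outcome, params, valence) {
  th <- params$theta
  if (is.null(th) || th <= 0) stop("theta must be > 0")
  vf <- paste0("var_", valence)
  mf <- paste0("V_", valence)
  v <- state[[vf]]
  if (is.null(v) || v <= 0) stop("mean-tracker variance must be > 0")
  G <- v / (v + th)
  state[[mf]] <- state[[mf]] + G * (outcome - state[[mf]])
  state[[vf]] <- (1 - G) * v
  state[[paste0("G_", valence)]] <- G
  state
}

.init_state <- function(params) {
  list(V_gain = params$v0_gain, V_loss = params$v0_loss,
       var_gain = params$v0_var, var_loss = params$v0_var,
       G_gain = if (params$family == "bmt")
         params$v0_var / (params$v0_var + params$theta) else NA_real_,
       G_loss = if (params$family == "bmt")
         params$v0_var / (params$v0_var + params$theta) else NA_real_)
}

.step_state <- function(state, outcome, params, valence) {
  switch(params$family,
         rw = rw_update(state, outcome, params, valence),
         rw_asym = rw_asym_update(state, outcome, params, valence),
         bmt = bmt_update(state, outcome, params, valence),
         state)
}

#' Run a learning rule over an observed choice sequence
#'
#' Produces the trial-indexed implied-value trajectory: the values
#' returned for trial `t` reflect all reveals on trials strictly before
#' `t`, so they are the values available when the trial-`t` decision was
#' made.  For the no-learning baseline the schedule means are returned for
#' every trial.
#'
#' @param schedule Schedule rows for one subject, in trial order.
#' @param choices Data frame aligned to `schedule` with columns `outcome`
#'   and `reveal` (`"none"`/`"gain"`/`"loss"`), as produced by
#'   [simulate_subject()] or read from disk.
#' @param params A `ptlearn_learning` object.
#' @return Data frame, one row per trial: `V_gain`, `V_loss`, `var_gain`,
#'   `var_loss`, `G` (prospective mean-tracker learning rate, averaged
#'   over the two valences; `NA` for other families).
#' @export
run_learning <- function(schedule, choices, params) {
  n <- nrow(schedule)
  if (!is.null(choices) && nrow(choices) != n)
    stop("choices are not aligned to the schedule")
  if (params$family == "none") {
    base <- implied_baseline(schedule)
    return(data.frame(V_gain = rep(base$V_gain, n),
                      V_loss = rep(base$V_loss, n),
                      var_gain = NA_real_, var_loss = NA_real_,
                      G = NA_real_))
  }
  state <- .init_state(params)
  out <- data.frame(V_gain = numeric(n), V_loss = numeric(n),
                    var_gain = numeric(n), var_loss = numeric(n),
                    G = numeric(n))
  for (t in seq_len(n)) {
    out$V_gain[t] <- state$V_gain
    out$V_loss[t] <- state$V_loss
    out$var_gain[t] <- state$var_gain
    out$var_loss[t] <- state$var_loss
    out$G[t] <- if (params$family == "bmt")
      mean(c(state$var_gain / (state$var_gain + params$theta),
             state$var_loss / (state$var_loss + params$theta)))
    else NA_real_
    rv <- choices$reveal[t]
    if (rv %in% c("gain", "loss"))
      state <- .step_state(state, choices$outcome[t], params, rv)
  }
  out
}

# Fast implied-value trajectories for fitting: given the observed reveal
# trials and outcomes (fixed data), compute pre-decision V per trial
# without a full per-trial loop.  Used inside the likelihood.
.implied_trajectory <- function(n, reveal_trials_g, reveal_out_g,
                                reveal_trials_l, reveal_out_l, params) {
  traj_one <- function(trials, outs, v0) {
    k <- length(trials)
    vals <- numeric(k)
    v <- v0
    if (params$family == "rw") {
      a <- params$alpha
      for (i in seq_len(k)) { v <- v + a * (outs[i] - v); vals[i] <- v }
    } else if (params$family == "rw_asym") {
      ap <- params$alpha_pos; an <- params$alpha_neg
      for (i in seq_len(k)) {
        d <- outs[i] - v
        v <- v + (if (d > 0) ap else if (d < 0) an else 0) * d
        vals[i] <- v
      }
    } else if (params$family == "bmt") {
      th <- params$theta; vv <- params$v0_var
      for (i in seq_len(k)) {
        G <- vv / (vv + th)
        v <- v + G * (outs[i] - v)
        vv <- (1 - G) * vv
        vals[i] <- v
      }
    }
    # value in force at trial t = value after the last reveal before t
    idx <- findInterval(seq_len(n) - 1L, trials)
    c(v0, vals)[idx + 1L]
  }
  list(V_gain = traj_one(reveal_trials_g, reveal_out_g, params$v0_gain),
       V_loss = traj_one(reveal_trials_l, reveal_out_l, params$v0_loss))
}
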