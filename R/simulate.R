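# Synthetic-cohort generator: simulate choice data from any of the 50
# decision x learning combinations, with per-subject parameters drawn from
# population distributions matched to each parameter's support.

#' Population specification for cohort simulation
#'
#' Default population distributions are log-normal for positive parameters
#' (curvature, loss aversion, ambiguity weights, inverse temperature,
#' mean-tracker error variance), logit-normal for learning rates, and
#' normal (truncated at 1 point) for starting-value magnitudes.
#'
#' @param model_id Generating model, e.g. `"D5-BMT3"`.
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @param overrides Optional data frame with columns `name`, `location`,
#'   `scale` replacing defaults for those parameters (a `scale` of 0 gives
#'   every subject the same value).
#' @return Object of class `ptlearn_population`.
#' @export
population_spec <- function(model_id, n_subjects, seed, overrides = NULL) {
  m <- parse_model_id(model_id)
  tab <- .default_population(m$decision, m$learning)
  if (!is.null(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      j <- match(overrides$name[i], tab$name)
      if (is.na(j)) stop("unknown parameter in overrides: ", overrides$name[i])
      tab$location[j] <- overrides$location[i]
      tab$scale[j] <- overrides$scale[i]
    }
  }
  structure(list(model_id = model_id, decision = m$decision,
                 learning = m$learning, n_subjects = n_subjects,
                 seed = seed, table = tab),
            class = "ptlearn_population")
}

.default_population <- function(decision, learning) {
  pars <- model_parameters(decision, learning)
  dist <- character(nrow(pars))
  loc <- numeric(nrow(pars))
  sc <- numeric(nrow(pars))
  for (i in seq_len(nrow(pars))) {
    nm <- pars$name[i]
    if (nm == "rho") { dist[i] <- "lognormal"; loc[i] <- log(0.9); sc[i] <- 0.25 }
    else if (nm == "lambda") { dist[i] <- "lognormal"; loc[i] <- log(1.5); sc[i] <- 0.3 }
    else if (nm == "gamma") { dist[i] <- "lognormal"; loc[i] <- log(0.15); sc[i] <- 0.4 }
    else if (startsWith(nm, "alpha_") &&
             nm %in% c("alpha_rg", "alpha_sg", "alpha_rl", "alpha_sl",
                       "alpha_g", "alpha_l") || nm == "alpha") {
      dist[i] <- "lognormal"; loc[i] <- 0; sc[i] <- 0.3
    } else if (nm %in% c("alpha_lr", "alpha_pos", "alpha_neg")) {
      dist[i] <- "logitnormal"; loc[i] <- stats::qlogis(0.3); sc[i] <- 0.8
    } else if (nm == "theta") { dist[i] <- "lognormal"; loc[i] <- log(50); sc[i] <- 0.5 }
    else { dist[i] <- "normal_pos"; loc[i] <- 30; sc[i] <- 10 }
  }
  data.frame(name = pars$name, dist = dist, location = loc, scale = sc,
             stringsAsFactors = FALSE)
}

# Draw an n x p truth table of natural-scale parameters.
.draw_population <- function(tab, n) {
  draws <- lapply(seq_len(nrow(tab)), function(i) {
    z <- stats::rnorm(n, tab$location[i], tab$scale[i])
    switch(tab$dist[i],
           lognormal = exp(z),
           logitnormal = stats::plogis(z),
           normal_pos = pmax(z, 1))
  })
  out <- as.data.frame(draws)
  names(out) <- tab$name
  out
}

#' Simulate one subject's choices
#'
#' Per trial: implied values come from the current learning state,
#' utilities from the prospect-theory rule, the choice is sampled from the
#' softmax probability, the outcome is resolved (50/50 draw or sure
#' payout), and the learning state is updated if the paying slot was
#' ambiguous.  A running points score accumulates and resets at each block
#' boundary.
#'
#' @param schedule Schedule rows for one subject, in trial order.
#' @param dparams A `ptlearn_decision` object.
#' @param lparams A `ptlearn_learning` object.
#' @param seed Integer seed.
#' @return Data frame: the schedule columns plus `chose_gamble` (1 =
#'   gamble/ambiguous option), `outcome`, `running_score`, `reveal`.
#' @export
simulate_subject <- function(schedule, dparams, lparams, seed) {
  n <- nrow(schedule)
  .with_seed(seed, {
    if (lparams$family == "none") {
      state <- implied_baseline(schedule)
      state$var_gain <- state$var_loss <- NA_real_
    } else {
      state <- .init_state(lparams)
    }
    # utilities depend on state only through (V_gain, V_loss); recompute
    # the full vector lazily whenever a reveal changes the state
    u <- utility(schedule, dparams, implied = state)
    p <- choice_probability(u, dparams$gamma)
    chose <- integer(n); outc <- numeric(n); score <- numeric(n)
    reveal <- character(n)
    run <- 0
    blk <- schedule$block[1]
    for (t in seq_len(n)) {
      if (schedule$block[t] != blk) { run <- 0; blk <- schedule$block[t] }
      chose[t] <- as.integer(stats::runif(1) < p[t])
      res <- resolve_outcome(schedule[t, ], chose[t] == 1L)
      outc[t] <- res$outcome
      reveal[t] <- res$reveal
      run <- run + res$outcome
      score[t] <- run
      if (res$reveal != "none" && lparams$family != "none") {
        state <- .step_state(state, res$outcome, lparams, res$reveal)
        u <- utility(schedule, dparams, implied = state)
        p <- choice_probability(u, dparams$gamma)
      }
    }
    out <- schedule
    out$chose_gamble <- chose
    out$outcome <- outc
    out$running_score <- score
    out$reveal <- reveal
    out
  })
}

#' Simulate a cohort
#'
#' Draws per-subject parameters from the population, builds per-subject
#' schedules (same trial values, subject-specific within-block order), and
#' simulates every subject.  All randomness flows from the population
#' seed, with independent per-subject substreams.
#'
#' @param pop A `ptlearn_population` object.
#' @return List with `choices` (stacked per-trial records for all
#'   subjects), `truth` (per-subject generating parameters, keyed by
#'   `subject`), and `model_id`.
#' @export
simulate_cohort <- function(pop) {
  stopifnot(inherits(pop, "ptlearn_population"))
  n <- pop$n_subjects
  sched <- build_schedule(pop$seed, subjects = n)
  drawn <- .with_seed(pop$seed, {
    list(truth = .draw_population(pop$table, n),
         sub_seeds = sample.int(.Machine$integer.max - 1L, n))
  })
  truth <- drawn$truth
  rows <- vector("list", n)
  for (s in seq_len(n)) {
    par <- as.list(truth[s, , drop = FALSE])
    par <- stats::setNames(as.numeric(par), names(truth))
    ps <- .split_params(par, pop$decision, pop$learning)
    rows[[s]] <- simulate_subject(sched[sched$subject == s, ],
                                  ps$decision, ps$learning,
                                  seed = drawn$sub_seeds[s])
  }
  choices <- do.call(rbind, rows)
  rownames(choices) <- NULL
  truth <- cbind(subject = seq_len(n), truth)
  list(choices = choices, truth = truth, model_id = pop$model_id)
}
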