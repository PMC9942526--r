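# Parameter- and model-recovery studies: simulate from known models and
# parameters, refit, and score how well truth is recovered.

#' Parameter recovery
#'
#' Simulates a cohort from `model_id` with parameters drawn from the
#' default (or overridden) population, refits the same model, and
#' reports the Pearson correlation between true and recovered
#' per-subject values for every free parameter, plus the
#' cross-correlation matrix among recovered parameters (an independence
#' check).
#'
#' @param model_id Generating (and fitted) model, e.g. `"D5-BMT3"`.
#' @param n_subjects Cohort size.
#' @param seed Integer seed.
#' @param mode,draws,n_starts Passed to [fit()].
#' @param overrides Optional population overrides (see
#'   [population_spec()]).
#' @return List: `correlations` (data frame `parameter`, `r`),
#'   `cross_correlation` (matrix over recovered parameters), `truth`,
#'   `estimates`, `fit`, `seed`.
#' @export
parameter_recovery <- function(model_id, n_subjects, seed, mode = "map",
                               draws = 50, n_starts = 2, overrides = NULL) {
  pop <- population_spec(model_id, n_subjects, seed, overrides = overrides)
  sim <- simulate_cohort(pop)
  fo <- fit(sim$choices, model_id, mode = mode, seed = seed,
            draws = draws, n_starts = n_starts)
  pars <- setdiff(names(sim$truth), "subject")
  est <- fo$estimates
  cors <- data.frame(parameter = pars, r = NA_real_)
  for (i in seq_along(pars)) {
    tv <- sim$truth[[pars[i]]]
    if (stats::sd(tv) == 0) {
      warning("degenerate truth variance for ", pars[i], "; skipped")
      next
    }
    cors$r[i] <- stats::cor(tv, est[[pars[i]]])
  }
  em <- as.matrix(est[, pars, drop = FALSE])
  list(correlations = cors, cross_correlation = stats::cor(em),
       truth = sim$truth, estimates = est, fit = fo,
       choices = sim$choices, seed = seed)
}

#' Model recovery
#'
#' For each replicate and each generating model: simulate a cohort, fit
#' every candidate model, and compute stacking weights from the
#' pointwise log-likelihood draws.  Per-cell fit failures are recorded
#' as `NA` weights, not fatal.
#'
#' @param model_ids Candidate (and generating) model ids.  The full
#'   50-model space is supported but compute-heavy (roughly
#'   `reps * K^2` cohort fits); keep CI subsets to a handful of models.
#' @param n_subjects Cohort size per simulated dataset.
#' @param reps Replicates.
#' @param seed Integer seed.
#' @param mode,draws,n_starts Passed to [fit()].
#' @return List: `weights` (data frame `rep`, `generating`, one column
#'   per fitted model), `confusion` (generating x fitted matrix of mean
#'   stacking weights; rows sum to 1 up to dropped failures), `seed`.
#' @export
model_recovery <- function(model_ids, n_subjects, reps = 1, seed = 1,
                           mode = "map", draws = 50, n_starts = 1) {
  stopifnot(length(model_ids) >= 1)
  K <- length(model_ids)
  rows <- list()
  for (r in seq_len(reps)) {
    for (g in seq_len(K)) {
      cell_seed <- seed + 1000L * r + 10L * g
      pop <- population_spec(model_ids[g], n_subjects, cell_seed)
      sim <- simulate_cohort(pop)
      lls <- stats::setNames(vector("list", K), model_ids)
      for (k in seq_len(K)) {
        fo <- try(fit(sim$choices, model_ids[k], mode = mode,
                      seed = cell_seed + k, draws = draws,
                      n_starts = n_starts), silent = TRUE)
        if (!inherits(fo, "try-error")) lls[[k]] <- fo$ll
      }
      ok <- !vapply(lls, is.null, logical(1))
      w <- rep(NA_real_, K)
      if (any(ok)) w[ok] <- stacking_weights(lls[ok])
      row <- data.frame(rep = r, generating = model_ids[g])
      row[model_ids] <- as.list(w)
      rows[[length(rows) + 1]] <- row
    }
  }
  weights <- do.call(rbind, rows)
  conf <- matrix(NA_real_, K, K, dimnames = list(model_ids, model_ids))
  for (g in seq_len(K)) {
    sub <- weights[weights$generating == model_ids[g], model_ids,
                   drop = FALSE]
    conf[g, ] <- colMeans(as.matrix(sub), na.rm = TRUE)
  }
  list(weights = weights, confusion = conf, seed = seed)
}
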