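#' @keywords internal
"_PACKAGE"

# Learning-rule registry: id 1 is the no-learning baseline, 2-7 the
# Rescorla-Wagner variants (single then asymmetric learning rate), 8-10 the
# Bayesian mean tracker.  Starting-value schemes cycle fixed (+5/-5),
# estimated-shared (one magnitude, sign flipped for losses), and
# estimated-separate.
.learning_table <- data.frame(
  learning = 1:10,
  label    = c("none", paste0("RW", 1:6), paste0("BMT", 1:3)),
  family   = c("none", rep("rw", 3), rep("rw_asym", 3), rep("bmt", 3)),
  start_scheme = c("none", rep(c("fixed", "estimated_shared",
                                 "estimated_separate"), 3)),
  stringsAsFactors = FALSE
)

.decision_labels <- paste0("D", 1:5)

#' Enumerate the candidate model space
#'
#' The model space crosses five decision rules (differing only in how the
#' four multiplicative ambiguity weights are tied) with ten learning rules
#' for the implied value of ambiguous outcomes, giving 50 candidates.
#'
#' @return A data frame with one row per model: `model_id` (e.g.
#'   `"D5-BMT3"`), `decision` (1-5), `learning` (1-10), learning `family`
#'   and `start_scheme`, and the number of free parameters.
#' @export
#' @examples
#' nrow(list_models())  # 50
list_models <- function() {
  grid <- expand.grid(learning = 1:10, decision = 1:5)
  lt <- .learning_table[grid$learning, ]
  out <- data.frame(
    model_id = paste0(.decision_labels[grid$decision], "-", lt$label),
    decision = grid$decision,
    learning = grid$learning,
    family = lt$family,
    start_scheme = lt$start_scheme,
    stringsAsFactors = FALSE
  )
  out$n_params <- vapply(seq_len(nrow(out)), function(i) {
    nrow(model_parameters(out$decision[i], out$learning[i]))
  }, integer(1))
  rownames(out) <- NULL
  out
}

#' Parse a model identifier
#'
#' @param model_id String like `"D5-BMT3"`, `"D1-none"`, `"D3-RW2"`.
#' @return List with integer components `decision` (1-5) and `learning`
#'   (1-10).
#' @export
parse_model_id <- function(model_id) {
  stopifnot(is.character(model_id), length(model_id) == 1)
  parts <- strsplit(model_id, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("model id must look like 'D5-BMT3', got: ", model_id)
  d <- match(parts[1], .decision_labels)
  l <- match(parts[2], .learning_table$label)
  if (is.na(d) || is.na(l))
    stop("unknown model id: ", model_id)
  list(decision = d, learning = l)
}

#' @rdname parse_model_id
#' @param decision,learning Integer codes.
#' @export
make_model_id <- function(decision, learning) {
  paste0(.decision_labels[decision], "-", .learning_table$label[learning])
}

# Number of free ambiguity weights per decision variant.
.n_alpha <- c(0L, 1L, 2L, 2L, 4L)

#' Free-parameter table for one model combination
#'
#' Each free parameter has a name, an unconstrained-scale transform
#' (`log` for positive parameters, `logit` for rates in \[0,1\]), and a
#' normal prior (mean, sd) on the transformed scale used for MAP
#' regularization and as the starting group-level prior in hierarchical
#' fits.
#'
#' @param decision Decision variant 1-5.
#' @param learning Learning variant 1-10.
#' @return Data frame: `name`, `transform`, `prior_mean`, `prior_sd`.
#' @export
model_parameters <- function(decision, learning) {
  stopifnot(decision %in% 1:5, learning %in% 1:10)
  rows <- list(
    c("rho",    "log", log(0.9), 0.5),
    c("lambda", "log", log(1.5), 0.5),
    c("gamma",  "log", log(0.15), 1.0)
  )
  alpha_names <- switch(decision,
    character(0),
    "alpha",
    c("alpha_g", "alpha_l"),
    c("alpha_g", "alpha_l"),
    c("alpha_rg", "alpha_sg", "alpha_rl", "alpha_sl")
  )
  for (a in alpha_names) rows[[length(rows) + 1]] <- c(a, "log", 0, 0.5)
  fam <- .learning_table$family[learning]
  scheme <- .learning_table$start_scheme[learning]
  if (fam == "rw") {
    rows[[length(rows) + 1]] <- c("alpha_lr", "logit", -0.85, 1.0)
  } else if (fam == "rw_asym") {
    rows[[length(rows) + 1]] <- c("alpha_pos", "logit", -0.85, 1.0)
    rows[[length(rows) + 1]] <- c("alpha_neg", "logit", -0.85, 1.0)
  } else if (fam == "bmt") {
    rows[[length(rows) + 1]] <- c("theta", "log", log(50), 1.0)
  }
  if (scheme == "estimated_shared") {
    rows[[length(rows) + 1]] <- c("v0_mag", "log", log(30), 0.7)
  } else if (scheme == "estimated_separate") {
    rows[[length(rows) + 1]] <- c("v0_gain", "log", log(30), 0.7)
    rows[[length(rows) + 1]] <- c("v0_loss_mag", "log", log(30), 0.7)
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("name", "transform", "prior_mean", "prior_sd")
  out$prior_mean <- as.numeric(out$prior_mean)
  out$prior_sd <- as.numeric(out$prior_sd)
  out
}

# transform helpers ---------------------------------------------------------

.to_natural <- function(x, transform) {
  switch(transform, log = exp(x), logit = stats::plogis(x), identity = x)
}

.to_unconstrained <- function(x, transform) {
  switch(transform, log = log(x), logit = stats::qlogis(x), identity = x)
}

# Map a named natural-scale parameter vector to structured decision and
# learning parameter lists for one model combination.
.split_params <- function(par, decision, learning) {
  fam <- .learning_table$family[learning]
  scheme <- .learning_table$start_scheme[learning]
  dp <- decision_params(
    variant = decision,
    rho = par[["rho"]], lambda = par[["lambda"]], gamma = par[["gamma"]],
    alpha = switch(decision,
      NULL,
      par[["alpha"]],
      c(par[["alpha_g"]], par[["alpha_l"]]),
      c(par[["alpha_g"]], par[["alpha_l"]]),
      c(par[["alpha_rg"]], par[["alpha_sg"]],
        par[["alpha_rl"]], par[["alpha_sl"]])
    )
  )
  starts <- switch(scheme,
    none = NULL,
    fixed = c(5, -5),
    estimated_shared = c(par[["v0_mag"]], -par[["v0_mag"]]),
    estimated_separate = c(par[["v0_gain"]], -par[["v0_loss_mag"]])
  )
  lp <- switch(fam,
    none = learning_params("none"),
    rw = learning_params("rw", alpha = par[["alpha_lr"]],
                         v0_gain = starts[1], v0_loss = starts[2],
                         start_scheme = scheme),
    rw_asym = learning_params("rw_asym", alpha_pos = par[["alpha_pos"]],
                              alpha_neg = par[["alpha_neg"]],
                              v0_gain = starts[1], v0_loss = starts[2],
                              start_scheme = scheme),
    bmt = learning_params("bmt", theta = par[["theta"]],
                          v0_gain = starts[1], v0_loss = starts[2],
                          start_scheme = scheme)
  )
  lp$variant <- learning
  list(decision = dp, learning = lp)
}
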