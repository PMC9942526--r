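# Prospect-theory utilities with multiplicative ambiguity weights.
#
# Sign convention: losses enter as magnitudes with negated utility,
# u_loss = -lambda * |loss|^rho, so lambda > 1 overweights losses and the
# power is well defined for non-integer rho.  Ambiguity weights multiply
# outside the power for both valences: gains alpha * V^rho, losses
# lambda * alpha * |V|^rho.

#' Decision-rule parameters
#'
#' Constructs the parameter set for one of the five decision variants,
#' which differ only in how the four multiplicative ambiguity weights
#' (risky gain, sure gain, risky loss, sure loss) are tied:
#' variant 1 fixes all weights at 1 (plain prospect theory); variant 2
#' shares a single weight; variant 3 ties by valence; variant 4 ties by
#' trial context (any loss present vs none); variant 5 frees all four.
#'
#' @param variant Integer 1-5.
#' @param rho Utility curvature, > 0 (`rho < 1` = risk aversion).
#' @param lambda Loss-aversion weight, > 0 (`lambda > 1` = loss aversion).
#' @param gamma Softmax inverse temperature, >= 0.
#' @param alpha Free ambiguity weights: none for variant 1, a single value
#'   for variant 2, `c(gain, loss)` for variants 3-4, and
#'   `c(rg, sg, rl, sl)` for variant 5.  All must be > 0.
#' @return Object of class `ptlearn_decision` with the four slot weights
#'   resolved (variants 1-3, 5) or context weights (variant 4).
#' @export
decision_params <- function(variant, rho, lambda, gamma, alpha = NULL) {
  stopifnot(variant %in% 1:5)
  if (!is.numeric(rho) || rho <= 0) stop("rho must be > 0")
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (!is.numeric(gamma) || gamma < 0) stop("gamma must be >= 0")
  n_free <- .n_alpha[variant]
  if (length(alpha) != n_free)
    stop("variant ", variant, " takes ", n_free,
         " free ambiguity parameter(s), got ", length(alpha))
  if (n_free > 0 && any(alpha <= 0)) stop("ambiguity weights must be > 0")
  p <- list(variant = variant, rho = rho, lambda = lambda, gamma = gamma)
  if (variant == 1) {
    p[c("alpha_rg", "alpha_sg", "alpha_rl", "alpha_sl")] <- 1
  } else if (variant == 2) {
    p[c("alpha_rg", "alpha_sg", "alpha_rl", "alpha_sl")] <- alpha
  } else if (variant == 3) {
    p$alpha_rg <- p$alpha_sg <- alpha[1]
    p$alpha_rl <- p$alpha_sl <- alpha[2]
  } else if (variant == 4) {
    # context-routed: resolved per condition, not per slot
    p$alpha_g <- alpha[1]
    p$alpha_l <- alpha[2]
  } else {
    p$alpha_rg <- alpha[1]; p$alpha_sg <- alpha[2]
    p$alpha_rl <- alpha[3]; p$alpha_sl <- alpha[4]
  }
  structure(p, class = "ptlearn_decision")
}

#' @rdname decision_params
#' @param free_params Numeric vector of free ambiguity weights (may be
#'   empty) plus named `rho`, `lambda`, `gamma` entries.
#' @export
apply_variant <- function(variant, free_params) {
  decision_params(variant,
                  rho = free_params[["rho"]],
                  lambda = free_params[["lambda"]],
                  gamma = free_params[["gamma"]],
                  alpha = free_params[["alpha"]])
}

# Ambiguity weight applied in each condition (NA where no ambiguous slot).
# Conditions 2 (risky loss), 3/5 (risky gain), 6/7 (sure gain), 8 (sure
# loss).  Variant 4 routes by loss context: conditions 2, 3, 8 contain a
# loss, 5-7 do not.
.alpha_by_condition <- function(params) {
  if (params$variant == 4) {
    c(NA, params$alpha_l, params$alpha_l, NA,
      params$alpha_g, params$alpha_g, params$alpha_g, params$alpha_l)
  } else {
    c(NA, params$alpha_rl, params$alpha_rg, NA,
      params$alpha_rg, params$alpha_sg, params$alpha_sg, params$alpha_sl)
  }
}

#' Subjective utilities of the two options
#'
#' Vectorized over trials.  Implied values stand in for the hidden
#' magnitudes of ambiguous slots; gains use `V_gain` (positive points),
#' losses `V_loss` (negative points, entered as a magnitude).
#'
#' @param trials Schedule rows (see [build_schedule()]).
#' @param params A `ptlearn_decision` object.
#' @param implied List or data frame with elements `V_gain` and `V_loss`
#'   (scalar or per-trial), required when any trial has an ambiguous slot.
#' @return Data frame with columns `u_gamble`, `u_sure`.
#' @export
utility <- function(trials, params, implied = NULL) {
  stopifnot(inherits(params, "ptlearn_decision"))
  cond <- trials$condition
  n <- length(cond)
  needs_g <- cond %in% c(3, 5, 6, 7)
  needs_l <- cond %in% c(2, 8)
  Vg <- Vl <- rep(NA_real_, n)
  if (any(needs_g) || any(needs_l)) {
    if (is.null(implied))
      stop("trials contain ambiguous slots but no implied values supplied")
    Vg <- rep_len(implied$V_gain, n)
    Vl <- rep_len(implied$V_loss, n)
    if (any(needs_g & !is.finite(Vg)) || any(needs_l & !is.finite(Vl)))
      stop("missing implied value for an ambiguous slot")
  }
  rho <- params$rho; lam <- params$lambda
  a <- .alpha_by_condition(params)[cond]
  Vg <- pmax(Vg, 1e-9)
  Vlm <- pmax(abs(Vl), 1e-9)  # loss magnitude
  g1 <- trials$g1_value; g2 <- trials$g2_value; su <- trials$sure_value
  ug <- numeric(n); us <- numeric(n)
  for (cc in unique(cond)) {
    i <- which(cond == cc)
    ug[i] <- switch(cc,
      0.5 * g1[i]^rho - 0.5 * lam * abs(g2[i])^rho,
      0.5 * g1[i]^rho - 0.5 * lam * a[i] * Vlm[i]^rho,
      0.5 * a[i] * Vg[i]^rho - 0.5 * lam * abs(g2[i])^rho,
      0.5 * g1[i]^rho,
      0.5 * a[i] * Vg[i]^rho,
      0.5 * g1[i]^rho,
      a[i] * Vg[i]^rho,
      -lam * a[i] * Vlm[i]^rho)
    us[i] <- switch(cc,
      0, 0, 0,
      su[i]^rho,
      su[i]^rho,
      a[i] * Vg[i]^rho,
      su[i]^rho,
      -lam * abs(su[i])^rho)
  }
  data.frame(u_gamble = ug, u_sure = us)
}

#' Softmax probability of choosing the gamble
#'
#' Logistic in `gamma * (u_gamble - u_sure)`; the exponent is clipped to
#' +/- 500 for overflow safety.  The "gamble" is the risky option in
#' conditions 1-6 and the ambiguous option in 7-8.
#'
#' @param u Data frame from [utility()] (or anything with `u_gamble`,
#'   `u_sure`).
#' @param gamma Inverse temperature, >= 0.
#' @return Probabilities in (0, 1); 0.5 at equal utilities or `gamma = 0`.
#' @export
choice_probability <- function(u, gamma) {
  stopifnot(gamma >= 0)
  x <- gamma * (u$u_gamble - u$u_sure)
  p <- stats::plogis(pmin(pmax(x, -500), 500))
  pmin(pmax(p, 1e-300), 1 - 1e-12)
}
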