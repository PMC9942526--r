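# Model-agnostic behavioral measures, subject-exclusion filters, and
# group-level bias tests.

# conditions in which each option contains an ambiguous slot
.amb_if_gamble <- c(2, 3, 5, 7, 8)
.amb_if_sure <- 6

.prop_by_condition <- function(df) {
  p <- rep(NA_real_, 8)
  agg <- tapply(df$chose_gamble, df$condition, mean)
  p[as.integer(names(agg))] <- agg
  p
}

#' Per-subject behavioral aversion measures
#'
#' Six gamble-proportion measures, all coded so higher = more averse:
#' risk aversion (1 minus the gamble rate in condition 4), loss aversion
#' (condition 4 minus condition 1 gamble rates), ambiguity aversion for
#' sure gains / sure losses (1 minus the ambiguous-choice rate in
#' conditions 7 / 8), and ambiguity aversion for risky gains / risky
#' losses (condition 1 minus condition 3 / condition 2 gamble rates).
#' A missing condition yields `NA` for the measures that need it.
#'
#' @param choices Per-trial records with `subject`, `condition`,
#'   `chose_gamble`.
#' @return Data frame, one row per subject, with the six measures.
#' @export
compute_measures <- function(choices) {
  subs <- sort(unique(choices$subject))
  out <- lapply(subs, function(s) {
    p <- .prop_by_condition(choices[choices$subject == s, ])
    data.frame(subject = s,
               risk_aversion = 1 - p[4],
               loss_aversion = p[4] - p[1],
               amb_sure_gain = 1 - p[7],
               amb_sure_loss = 1 - p[8],
               amb_risky_gain = p[1] - p[3],
               amb_risky_loss = p[1] - p[2])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Subject exclusion filters
#'
#' Flag A marks subjects who never chose an option containing an
#' ambiguous slot anywhere in the task (such subjects carry no
#' information about learned ambiguous values).  Flag B marks
#' multivariate questionnaire outliers: squared Mahalanobis distance from
#' the sample mean/covariance above the chi-squared `p < .001` quantile
#' at `df` = number of items.
#'
#' @param choices Per-trial records (`subject`, `condition`,
#'   `chose_gamble`).
#' @param questionnaire Optional numeric matrix/data frame, one row per
#'   subject in `sort(unique(choices$subject))` order; `NULL` skips
#'   flag B.
#' @return Data frame: `subject`, `flag_no_ambiguous`, `flag_outlier`,
#'   `keep`.
#' @export
exclusion_filters <- function(choices, questionnaire = NULL) {
  subs <- sort(unique(choices$subject))
  flag_a <- vapply(subs, function(s) {
    d <- choices[choices$subject == s, ]
    amb <- (d$condition %in% .amb_if_gamble & d$chose_gamble == 1) |
      (d$condition %in% .amb_if_sure & d$chose_gamble == 0)
    !any(amb)
  }, logical(1))
  flag_b <- rep(FALSE, length(subs))
  if (!is.null(questionnaire)) {
    q <- as.matrix(questionnaire)
    if (nrow(q) != length(subs))
      stop("questionnaire must have one row per subject")
    if (anyNA(q)) stop("questionnaire matrix contains missing values")
    S <- stats::cov(q)
    if (abs(det(S)) < .Machine$double.eps * nrow(S))
      stop("questionnaire covariance is singular; drop collinear items ",
           "or reduce the item set before filtering")
    d2 <- stats::mahalanobis(q, colMeans(q), S)
    flag_b <- d2 > stats::qchisq(0.999, df = ncol(q))
  }
  data.frame(subject = subs, flag_no_ambiguous = flag_a,
             flag_outlier = flag_b, keep = !(flag_a | flag_b))
}

#' Group-level bias tests
#'
#' One-sample t-test of each subject's overall gamble proportion against
#' 0.5 (risk preference; negative t = risk seeking under the aversion
#' coding is not applied here, the raw proportion is tested), a paired
#' t-test of condition 4 versus condition 1 gamble proportions (loss
#' aversion; positive t = fewer gambles when a loss is possible), and a
#' paired t-test of condition 4 versus condition 6 (ambiguity aversion;
#' positive t = fewer gambles against an ambiguous sure option).
#'
#' @param choices Per-trial records.
#' @return Data frame: `test`, `t`, `df`, `p_value`, `cohens_d`,
#'   `mean_diff`.
#' @export
group_bias_tests <- function(choices) {
  subs <- sort(unique(choices$subject))
  if (length(subs) < 2) stop("need at least 2 subjects")
  props <- t(vapply(subs, function(s)
    .prop_by_condition(choices[choices$subject == s, ]), numeric(8)))
  overall <- vapply(subs, function(s)
    mean(choices$chose_gamble[choices$subject == s &
                                choices$condition %in% 1:6]), numeric(1))
  one <- function(x, label) {
    if (stats::sd(x) == 0) {
      # exactly at the null with no spread: report t = 0 as the
      # limiting case; off the null the statistic is undefined
      if (mean(x) == 0)
        return(data.frame(test = label, t = 0, df = length(x) - 1,
                          p_value = 1, cohens_d = 0, mean_diff = 0))
      stop("zero variance in ", label, " test")
    }
    tt <- stats::t.test(x, mu = 0)
    data.frame(test = label, t = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               cohens_d = mean(x) / stats::sd(x), mean_diff = mean(x))
  }
  rbind(one(overall - 0.5, "risk"),
        one(props[, 4] - props[, 1], "loss"),
        one(props[, 4] - props[, 6], "ambiguity"))
}
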